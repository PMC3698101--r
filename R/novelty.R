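#' Construct a reference interaction set
#'
#' The reference set records interactions already known for a drug from a
#' prior manual review of one product label per drug; a linked interaction
#' found there is never flagged potentially novel. Entries either name an
#' interacting drug directly or name a drug class (to be expanded with
#' [expand_reference_set()] before use).
#'
#' @param object_drug Drug names the entries belong to.
#' @param interactor Interacting drug name, or class name when `is_class`.
#' @param is_class Logical vector (default all `FALSE`).
#' @return A tibble of class `reference_set`.
#' @export
reference_set <- function(object_drug = character(0),
                          interactor = character(0),
                          is_class = logical(0)) {
  if (length(is_class) == 0L && length(object_drug) > 0L) {
    is_class <- rep(FALSE, length(object_drug))
  }
  if (any(!nzchar(object_drug)) || any(!nzchar(interactor))) {
    stop_lw("reference-set names must be nonempty", class = "lw_refset_error")
  }
  out <- tibble::tibble(
    object_drug = as.character(object_drug),
    interactor = as.character(interactor),
    is_class = as.logical(is_class)
  )
  class(out) <- c("reference_set", class(out))
  out
}

#' Read a reference interaction set from CSV
#'
#' Columns: `object_drug`, `interactor`, `is_class` (`TRUE`/`FALSE`).
#'
#' @param path CSV file path.
#' @return A [reference_set()].
#' @export
read_reference_set_csv <- function(path) {
  df <- utils::read.csv(path, colClasses = "character")
  reference_set(df$object_drug, df$interactor, as.logical(df$is_class))
}

#' Expand class entries of a reference set to member drugs
#'
#' Every class entry is replaced by one non-class entry per member drug of
#' that class (class membership taken from the drug index); non-class
#' entries pass through unchanged. The result contains no class entries,
#' so membership tests are plain name lookups.
#'
#' @param ref_set A [reference_set()].
#' @param index A [drug_index()] supplying class assignments.
#' @return A [reference_set()] with `is_class` all `FALSE`.
#' @export
expand_reference_set <- function(ref_set, index) {
  cls <- ref_set[ref_set$is_class, , drop = FALSE]
  plain <- ref_set[!ref_set$is_class, , drop = FALSE]
  if (nrow(cls) == 0L) return(plain)
  members <- lapply(cls$interactor, drug_class_members, index = index)
  empty <- lengths(members) == 0L
  if (any(empty)) {
    stop_lw("unresolvable drug class(es) in reference set: ",
            paste(unique(cls$interactor[empty]), collapse = ", "),
            class = "lw_refset_error")
  }
  expanded <- reference_set(
    object_drug = rep(cls$object_drug, lengths(members)),
    interactor = unlist(members, use.names = FALSE),
    is_class = rep(FALSE, sum(lengths(members)))
  )
  out <- dplyr::distinct(dplyr::bind_rows(plain, expanded))
  class(out) <- c("reference_set", class(out))
  out
}

# TRUE iff `needle` occurs in `haystack` after normalization. Substring
# (not token) semantics: "digoxin" in the text does NOT match an
# interactor named "digitalis", but "profen" would match "ibuprofen".
# Word-boundary matching is available behind `word_boundary = TRUE`.
mentioned_in_text <- function(needle, haystack, word_boundary = FALSE) {
  if (length(haystack) != 1L || is.na(haystack)) {
    return(rep(FALSE, length(needle)))
  }
  hay <- normalize_text(haystack)
  ndl <- normalize_text(needle)
  if (word_boundary) {
    vapply(ndl, function(p)
      grepl(paste0("\\b", gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", p), "\\b"),
            hay),
      logical(1), USE.NAMES = FALSE)
  } else {
    vapply(ndl, function(p) grepl(p, hay, fixed = TRUE), logical(1),
           USE.NAMES = FALSE)
  }
}

#' Is an interaction claim potentially novel to a label section?
#'
#' A drug-drug interaction claim is *potentially novel* to a label's Drug
#' Interactions section when (1) the interacting drug's name does not occur
#' -- case-insensitive substring match on normalized text -- in the section
#' text, and (2) when a reference set is supplied, the (object drug,
#' interactor) pair is not listed in the class-expanded reference set. When
#' no reference set applies (the set covers only some drug groups),
#' criterion (1) alone decides. A label lacking the section entirely
#' satisfies criterion (1) by definition.
#'
#' Substring semantics deliberately mirror a plain string search: a section
#' that mentions "digoxin" does not match a claim naming "digitalis", so
#' such claims are (wrongly but reproducibly) flagged.
#'
#' @param ddi One row of a [ddi_claims()] table (or a list with `drug_a`,
#'   `drug_b`).
#' @param object_drug Name of the participant whose label is examined; the
#'   other participant is the interactor.
#' @param section_text Text of the label's Drug Interactions section, or
#'   `NA` if absent.
#' @param ref_set Optional [reference_set()], already class-expanded.
#' @param word_boundary Use word-boundary rather than plain substring
#'   matching (default `FALSE`).
#' @return `TRUE` if potentially novel.
#' @export
flag_novel_ddi <- function(ddi, object_drug, section_text,
                           ref_set = NULL, word_boundary = FALSE) {
  interactor <- ddi_interactor(ddi$drug_a, ddi$drug_b, object_drug)
  if (mentioned_in_text(interactor, section_text, word_boundary)) {
    return(FALSE)
  }
  if (!is.null(ref_set) && nrow(ref_set) > 0L) {
    in_ref <- normalize_text(ref_set$object_drug) == normalize_text(object_drug) &
      normalize_text(ref_set$interactor) == normalize_text(interactor)
    if (any(in_ref)) return(FALSE)
  }
  TRUE
}

# The participant that is not the object drug (case-insensitive on
# normalized names; for a self-interaction the partner is returned).
ddi_interactor <- function(drug_a, drug_b, object_drug) {
  obj <- normalize_text(object_drug)
  if (normalize_text(drug_a) == obj) drug_b
  else if (normalize_text(drug_b) == obj) drug_a
  else stop_lw("object drug '", object_drug,
               "' is not a participant of the claim",
               class = "lw_novelty_error")
}

#' Is a PK claim's enzyme mentioned in a label section?
#'
#' Performs a simple case-insensitive substring search of the Clinical
#' Pharmacology section text for the full enzyme name of the claim (e.g.
#' "CYP2C19"). The novelty cue shown to users is the negation of this
#' value. Shorthand notations in the section (a hyphenated list like
#' "CYP3A4, -1A2, -2C19") do not match the full name -- a known
#' under-count that is preserved, not corrected.
#'
#' @param claim One row of a [pk_claims()] table (or a list with `value`).
#' @param section_text Section text, or `NA` if the section is absent
#'   (absent means not mentioned).
#' @return `TRUE` if the enzyme name occurs in the section text.
#' @export
flag_pk_enzyme_mentioned <- function(claim, section_text) {
  mentioned_in_text(claim$value, section_text)
}
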