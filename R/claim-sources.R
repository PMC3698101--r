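#' Construct a drug index
#'
#' The drug index is the shared lookup connecting the claim sources: every
#' drug has an opaque id, a preferred name (the label the interaction
#' terminology keys on), optional synonyms, an optional cross-source URI,
#' and a set of class names (used for reference-set class expansion).
#'
#' @param id Character vector of unique drug ids.
#' @param preferred_name Nonempty preferred names, one per id.
#' @param synonyms List of character vectors (default: none).
#' @param external_ref Optional cross-source URIs (default `NA`).
#' @param classes List of character vectors of class names (default: none).
#' @return A tibble of class `drug_index`.
#' @export
drug_index <- function(id, preferred_name,
                       synonyms = NULL, external_ref = NULL, classes = NULL) {
  n <- length(id)
  if (anyDuplicated(id)) {
    stop_lw("drug ids must be unique", class = "lw_source_error")
  }
  if (length(preferred_name) != n || any(!nzchar(preferred_name))) {
    stop_lw("every drug needs a nonempty preferred name",
            class = "lw_source_error")
  }
  out <- tibble::tibble(
    id = as.character(id),
    preferred_name = as.character(preferred_name),
    synonyms = synonyms %||% rep(list(character(0)), n),
    external_ref = external_ref %||% rep(NA_character_, n),
    classes = classes %||% rep(list(character(0)), n)
  )
  class(out) <- c("drug_index", class(out))
  out
}

#' Members of a drug class
#'
#' @param index A [drug_index()].
#' @param class_name Class name to resolve.
#' @return Character vector of preferred names of member drugs (possibly
#'   empty).
#' @export
drug_class_members <- function(index, class_name) {
  hit <- vapply(index$classes, function(cl) class_name %in% cl, logical(1))
  index$preferred_name[hit]
}

#' Construct trial-registry records
#'
#' One row per registered clinical trial: its interventions are drug ids
#' (the cross-source linkage from intervention to drug is assumed done
#' upstream), and `result_refs` holds ids of indexed publications reporting
#' the trial's results (may be empty).
#'
#' @param trial_id Unique registry ids.
#' @param title,design Free text.
#' @param completion_date Dates (or strings).
#' @param interventions List of character vectors of drug ids; each must be
#'   nonempty.
#' @param result_refs List of character vectors of publication ids.
#' @return A tibble of class `trial_records`.
#' @export
trial_records <- function(trial_id, title = "", design = "",
                          completion_date = NA, interventions = list(),
                          result_refs = NULL) {
  n <- length(trial_id)
  if (any(lengths(interventions) == 0L)) {
    stop_lw("every trial must list at least one intervention drug",
            class = "lw_source_error")
  }
  out <- tibble::tibble(
    trial_id = as.character(trial_id),
    title = rep_len(as.character(title), n),
    design = rep_len(as.character(design), n),
    completion_date = rep_len(as.character(completion_date), n),
    interventions = interventions,
    result_refs = result_refs %||% rep(list(character(0)), n)
  )
  class(out) <- c("trial_records", class(out))
  out
}

#' Construct published-result records
#'
#' @param pub_id Unique publication ids.
#' @param title Titles.
#' @param abstract Abstract text (may be empty: title-only records are
#'   excluded from sentence-level processing downstream).
#' @return A tibble of class `published_results`.
#' @export
published_results <- function(pub_id, title = "", abstract = "") {
  if (anyDuplicated(pub_id)) {
    stop_lw("publication ids must be unique", class = "lw_source_error")
  }
  n <- length(pub_id)
  out <- tibble::tibble(
    pub_id = as.character(pub_id),
    title = rep_len(as.character(title), n),
    abstract = rep_len(as.character(abstract), n)
  )
  class(out) <- c("published_results", class(out))
  out
}

#' Construct drug-drug interaction claims
#'
#' Each claim names exactly two participants by their preferred-label text
#' (not by drug id: the source terminology keys on labels, which is why a
#' synonym like "digitalis" can defeat downstream string matching), carries
#' a two-valued severity reflecting formulary modifiability (Critical
#' interactions are less modifiable than Significant ones), and a status
#' string; only "Active" claims are routed.
#'
#' @param ddi_id Unique claim ids.
#' @param drug_a,drug_b Participant names.
#' @param severity `"Critical"` or `"Significant"`; anything else is a hard
#'   validation error at load time.
#' @param status Status text (default `"Active"`).
#' @return A tibble of class `ddi_claims`.
#' @export
ddi_claims <- function(ddi_id, drug_a, drug_b, severity, status = "Active") {
  bad <- setdiff(unique(severity), c("Critical", "Significant"))
  if (length(bad)) {
    stop_lw("invalid DDI severity value(s): ", paste(bad, collapse = ", "),
            class = "lw_validation_error")
  }
  n <- length(ddi_id)
  out <- tibble::tibble(
    ddi_id = as.character(ddi_id),
    drug_a = as.character(drug_a),
    drug_b = as.character(drug_b),
    severity = as.character(severity),
    status = rep_len(as.character(status), n)
  )
  class(out) <- c("ddi_claims", class(out))
  out
}

#' Construct pharmacokinetic assertions with evidence
#'
#' Each assertion states that an object drug either is a substrate of or
#' inhibits a metabolic enzyme (e.g. CYP2C19), with one or more evidence
#' items each labelled supporting or refuting. The claim identity used for
#' deduplication is the (object drug, slot, value) triple; the same claim
#' may appear in multiple evidence-level records.
#'
#' @param assertion_id Assertion ids.
#' @param object_drug Drug ids.
#' @param slot `"substrate_of"` or `"inhibits"`.
#' @param value Enzyme name text.
#' @param evidence List of data frames with columns `evidence_id`,
#'   `direction` (`"supporting"`/`"refuting"`), `source_text`.
#' @return A tibble of class `pk_claims`.
#' @export
pk_claims <- function(assertion_id, object_drug, slot, value, evidence) {
  bad <- setdiff(unique(slot), c("substrate_of", "inhibits"))
  if (length(bad)) {
    stop_lw("invalid PK slot value(s): ", paste(bad, collapse = ", "),
            class = "lw_validation_error")
  }
  dirs <- unlist(lapply(evidence, function(e) e$direction))
  bad_dir <- setdiff(unique(dirs), c("supporting", "refuting"))
  if (length(bad_dir)) {
    stop_lw("invalid evidence direction(s): ",
            paste(bad_dir, collapse = ", "), class = "lw_validation_error")
  }
  out <- tibble::tibble(
    assertion_id = as.character(assertion_id),
    object_drug = as.character(object_drug),
    slot = as.character(slot),
    value = as.character(value),
    evidence = evidence
  )
  class(out) <- c("pk_claims", class(out))
  out
}

#' Trials for a drug that have at least one published result
#'
#' @param trials A [trial_records()] table.
#' @param results A [published_results()] table resolving the trials'
#'   result references.
#' @param drug Drug id to select on (membership in `interventions`).
#' @return A tibble with one row per (trial, published result) pair:
#'   columns `trial_id`, `pub_id`, `pub_title`, `abstract`. Trials without
#'   results are excluded. A result reference with no matching publication
#'   record is kept with placeholder title/abstract and a warning, so the
#'   mapping is not silently dropped.
#' @export
trials_with_results <- function(trials, results, drug) {
  hit <- vapply(trials$interventions, function(iv) drug %in% iv, logical(1))
  hit <- hit & lengths(trials$result_refs) > 0L
  sel <- trials[hit, , drop = FALSE]
  if (nrow(sel) == 0L) {
    return(tibble::tibble(trial_id = character(0), pub_id = character(0),
                          pub_title = character(0), abstract = character(0)))
  }
  pairs <- tibble::tibble(
    trial_id = rep(sel$trial_id, lengths(sel$result_refs)),
    pub_id = unlist(sel$result_refs, use.names = FALSE)
  )
  idx <- match(pairs$pub_id, results$pub_id)
  dangling <- is.na(idx)
  if (any(dangling)) {
    warning(sprintf("%d result reference(s) have no publication record: %s",
                    sum(dangling),
                    paste(unique(pairs$pub_id[dangling]), collapse = ", ")),
            call. = FALSE)
  }
  pairs$pub_title <- ifelse(dangling, "(publication record unavailable)",
                            results$title[idx])
  pairs$abstract <- ifelse(dangling, "", results$abstract[idx])
  pairs[order(pairs$trial_id, pairs$pub_id), , drop = FALSE]
}

#' Active interaction claims naming a drug
#'
#' Selection follows the source terminology's semantics: the drug must
#' equal one participant's preferred label (string equality on trimmed
#' labels, case-insensitive by default -- no synonym resolution, so a claim
#' written against "digitalis" is not found for "digoxin").
#'
#' @param ddis A [ddi_claims()] table.
#' @param drug_name Preferred-label text of the drug.
#' @param ignore_case Compare labels case-insensitively (default `TRUE`).
#' @return The matching rows with status `"Active"`, in input order.
#' @export
ddis_for_drug <- function(ddis, drug_name, ignore_case = TRUE) {
  canon <- function(x) {
    x <- trimws(x)
    if (ignore_case) tolower(x) else x
  }
  target <- canon(drug_name)
  hit <- ddis$status == "Active" &
    (canon(ddis$drug_a) == target | canon(ddis$drug_b) == target)
  ddis[hit, , drop = FALSE]
}

#' Pharmacokinetic claims about a drug
#'
#' Returns claims for both slots (`substrate_of` and `inhibits`) whose
#' object is the given drug. Claims with no evidence items are excluded
#' with a message: only claims with supporting or refuting evidence are
#' routed.
#'
#' @param pk A [pk_claims()] table.
#' @param drug Drug id.
#' @return The matching rows.
#' @export
pk_claims_for_drug <- function(pk, drug) {
  sel <- pk[pk$object_drug == drug, , drop = FALSE]
  n_ev <- vapply(sel$evidence, NROW, integer(1))
  if (any(n_ev == 0L)) {
    message(sprintf("excluding %d PK claim(s) for '%s' with no evidence",
                    sum(n_ev == 0L), drug))
  }
  sel[n_ev > 0L, , drop = FALSE]
}

#' Expand PK claims to one record per evidence item
#'
#' The evidence-level view of the knowledge base: each (claim, evidence
#' item) pair becomes one record carrying the claim's deduplication key
#' `(object_drug, slot, value)`. Use [unique_claim_count()] to collapse
#' back to unique claims.
#'
#' @param pk A [pk_claims()] table.
#' @return A tibble with columns `object_drug`, `slot`, `value`,
#'   `evidence_id`, `direction`.
#' @export
pk_evidence_records <- function(pk) {
  n_ev <- vapply(pk$evidence, NROW, integer(1))
  ev <- dplyr::bind_rows(pk$evidence[n_ev > 0L])
  keep <- n_ev > 0L
  tibble::tibble(
    object_drug = rep(pk$object_drug[keep], n_ev[keep]),
    slot = rep(pk$slot[keep], n_ev[keep]),
    value = rep(pk$value[keep], n_ev[keep]),
    evidence_id = ev$evidence_id,
    direction = ev$direction
  )
}

# ---- CSV readers/writers -------------------------------------------------
# One record per row; multi-valued fields are ';'-separated.

split_multi <- function(x) {
  lapply(strsplit(ifelse(is.na(x) | x == "", "", x), ";", fixed = TRUE),
         function(v) v[nzchar(v)])
}
join_multi <- function(x) vapply(x, paste, character(1), collapse = ";")

#' Read claim sources from CSV files
#'
#' Column layouts: trials -- `trial_id,title,design,completion_date,
#' interventions,result_refs` (multi-valued fields `;`-separated); results
#' -- `pub_id,title,abstract`; DDIs -- `ddi_id,drug_a,drug_b,severity,
#' status`; PK -- one row per evidence item, `assertion_id,object_drug,
#' slot,value,evidence_id,direction,source_text`, grouped into one claim
#' per assertion id; drugs -- `id,preferred_name,synonyms,external_ref,
#' classes`.
#'
#' @param path CSV file path.
#' @return The corresponding typed table.
#' @name source_csv
NULL

#' @rdname source_csv
#' @export
read_trials_csv <- function(path) {
  df <- utils::read.csv(path, colClasses = "character")
  trial_records(df$trial_id, df$title, df$design, df$completion_date,
                split_multi(df$interventions), split_multi(df$result_refs))
}

#' @rdname source_csv
#' @export
read_results_csv <- function(path) {
  df <- utils::read.csv(path, colClasses = "character")
  published_results(df$pub_id, df$title, df$abstract)
}

#' @rdname source_csv
#' @export
read_ddis_csv <- function(path) {
  df <- utils::read.csv(path, colClasses = "character")
  ddi_claims(df$ddi_id, df$drug_a, df$drug_b, df$severity, df$status)
}

#' @rdname source_csv
#' @export
read_pk_csv <- function(path) {
  df <- utils::read.csv(path, colClasses = "character")
  key <- factor(df$assertion_id, levels = unique(df$assertion_id))
  first <- !duplicated(key)
  ev <- lapply(split(seq_len(nrow(df)), key), function(i) {
    tibble::tibble(evidence_id = df$evidence_id[i],
                   direction = df$direction[i],
                   source_text = df$source_text[i])
  })
  pk_claims(df$assertion_id[first], df$object_drug[first], df$slot[first],
            df$value[first], unname(ev))
}

#' @rdname source_csv
#' @export
read_drugs_csv <- function(path) {
  df <- utils::read.csv(path, colClasses = "character")
  drug_index(df$id, df$preferred_name, split_multi(df$synonyms),
             ifelse(df$external_ref == "", NA_character_, df$external_ref),
             split_multi(df$classes))
}

#' Write claim sources to CSV files
#'
#' Inverses of the `read_*_csv` readers; see [source_csv] for layouts.
#'
#' @param x The typed table to write.
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @name source_csv_write
NULL

#' @rdname source_csv_write
#' @export
write_trials_csv <- function(x, path) {
  df <- data.frame(trial_id = x$trial_id, title = x$title, design = x$design,
                   completion_date = x$completion_date,
                   interventions = join_multi(x$interventions),
                   result_refs = join_multi(x$result_refs))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname source_csv_write
#' @export
write_results_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname source_csv_write
#' @export
write_ddis_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname source_csv_write
#' @export
write_pk_csv <- function(x, path) {
  n_ev <- vapply(x$evidence, NROW, integer(1))
  ev <- dplyr::bind_rows(x$evidence)
  df <- data.frame(
    assertion_id = rep(x$assertion_id, n_ev),
    object_drug = rep(x$object_drug, n_ev),
    slot = rep(x$slot, n_ev),
    value = rep(x$value, n_ev),
    evidence_id = ev$evidence_id,
    direction = ev$direction,
    source_text = ev$source_text
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname source_csv_write
#' @export
write_drugs_csv <- function(x, path) {
  df <- data.frame(id = x$id, preferred_name = x$preferred_name,
                   synonyms = join_multi(x$synonyms),
                   external_ref = ifelse(is.na(x$external_ref), "",
                                         x$external_ref),
                   classes = join_multi(x$classes))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
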