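# Claim->section mapping graph.
#
# Each mapping routes one claim to one section of one label; the claim
# kind determines the section (trial results -> Clinical Studies, DDIs ->
# Drug Interactions, PK claims -> Clinical Pharmacology). Mapping identity
# is (spl_id, claim_kind, claim_ref): evidence items never multiply
# mappings, and a PK claim's deduplication key is its
# (object drug, slot, value) triple.

empty_mappings <- function() {
  tibble::tibble(
    spl_id = character(0), section = character(0),
    claim_kind = character(0), claim_ref = character(0),
    drug = character(0), drug_name = character(0),
    severity = character(0), pair_label = character(0),
    potentially_novel = logical(0), trial_ids = character(0),
    slot = character(0), value = character(0),
    n_support = integer(0), n_refute = integer(0)
  )
}

new_mapping_graph <- function(mappings) {
  if (nrow(mappings)) {
    bad <- mappings$section != unname(SECTION_FOR_KIND[mappings$claim_kind])
    if (any(bad)) {
      stop_lw("claim kind does not match its section for ",
              sum(bad), " mapping(s)", class = "lw_graph_error")
    }
    # idempotent insertion: duplicate (spl, kind, ref) rows are ignored
    mappings <- mappings[!duplicated(
      mappings[c("spl_id", "claim_kind", "claim_ref")]), , drop = FALSE]
    mappings <- mappings[order(mappings$spl_id, mappings$claim_kind,
                               mappings$claim_ref), , drop = FALSE]
  }
  structure(
    list(mappings = mappings, triple_count = count_triples(mappings)),
    class = "mapping_graph"
  )
}

# Field -> predicate expansion: every mapping contributes one triple per
# populated field (spl link, section, kind, claim ref, drug, plus the
# optional severity / pair-label fields when present). The novelty flag
# is a bound-only predicate: it contributes a triple only when TRUE, so
# audits can filter on the predicate being bound.
count_triples <- function(mappings) {
  if (nrow(mappings) == 0L) return(0L)
  base <- 5L * nrow(mappings)
  opt <- sum(!is.na(mappings$severity)) + sum(!is.na(mappings$pair_label)) +
    sum(mappings$potentially_novel, na.rm = TRUE)
  as.integer(base + opt)
}

#' @export
print.mapping_graph <- function(x, ...) {
  cat(sprintf("<mapping_graph> %d mappings (%d triples)\n",
              nrow(x$mappings), x$triple_count))
  if (nrow(x$mappings)) {
    print(table(x$mappings$claim_kind))
  }
  invisible(x)
}

#' Build the claim-to-section mapping graph
#'
#' For every drug in the index and every label of a product containing
#' that drug, routes (a) each published trial result to the Clinical
#' Studies section, (b) each active interaction claim naming the drug to
#' the Drug Interactions section, and (c) each evidenced PK claim about
#' the drug to the Clinical Pharmacology section. Novelty flags are
#' computed during the build: a DDI mapping is flagged by
#' [flag_novel_ddi()] against that label's section text and the (expanded)
#' reference set; a PK mapping is flagged when the enzyme is not found by
#' [flag_pk_enzyme_mentioned()].
#'
#' By default a claim is only mapped to labels that actually carry the
#' target section (a mapping "to a section" requires the section);
#' `attach_missing_section = TRUE` attaches to the label regardless, with
#' novelty computed against an absent section.
#'
#' @param corpus A [label_corpus()].
#' @param drugs A [drug_index()].
#' @param trials,results,ddis,pk Claim-source tables (any may be `NULL`).
#' @param ref_set Optional [reference_set()]; class entries are expanded
#'   against `drugs` before use.
#' @param attach_missing_section Map claims to labels lacking the target
#'   section (default `FALSE`).
#' @param word_boundary Passed to [flag_novel_ddi()].
#' @return A `mapping_graph`: list with `mappings` (tibble) and
#'   `triple_count`.
#' @export
build_mapping_graph <- function(corpus, drugs, trials = NULL, results = NULL,
                                ddis = NULL, pk = NULL, ref_set = NULL,
                                attach_missing_section = FALSE,
                                word_boundary = FALSE) {
  stopifnot(inherits(corpus, "label_corpus"))
  if (!is.null(ref_set)) {
    ref_set <- expand_reference_set(ref_set, drugs)
  }
  chunks <- list()
  for (i in seq_len(nrow(drugs))) {
    did <- drugs$id[i]
    dname <- drugs$preferred_name[i]
    if (is.null(corpus$ingredient_index[[did]])) next
    labels <- labels_for_ingredient(corpus, did)

    sec_txt <- function(l, section) section_text(l, section)
    labels_with <- function(section) {
      if (attach_missing_section) labels
      else Filter(function(l) section %in% names(l$sections), labels)
    }

    # Clinical Studies <- published trial results
    if (!is.null(trials) && !is.null(results)) {
      pairs <- trials_with_results(trials, results, did)
      if (nrow(pairs)) {
        by_pub <- stats::aggregate(trial_id ~ pub_id, data = pairs,
                                   FUN = function(v)
                                     paste(sort(unique(v)), collapse = ";"))
        for (l in labels_with("ClinicalStudies")) {
          chunks[[length(chunks) + 1L]] <- tibble::tibble(
            spl_id = l$spl_id, section = "ClinicalStudies",
            claim_kind = "trialResult", claim_ref = by_pub$pub_id,
            drug = did, drug_name = dname,
            severity = NA_character_, pair_label = NA_character_,
            potentially_novel = NA, trial_ids = by_pub$trial_id,
            slot = NA_character_, value = NA_character_,
            n_support = NA_integer_, n_refute = NA_integer_
          )
        }
      }
    }

    # Drug Interactions <- active DDI claims naming the drug
    if (!is.null(ddis)) {
      dd <- ddis_for_drug(ddis, dname)
      if (nrow(dd)) {
        interactors <- mapply(ddi_interactor, dd$drug_a, dd$drug_b,
                              MoreArgs = list(object_drug = dname))
        for (l in labels_with("DrugInteractions")) {
          txt <- sec_txt(l, "DrugInteractions")
          mentioned <- mentioned_in_text(interactors, txt, word_boundary)
          novel <- !mentioned
          if (!is.null(ref_set) && nrow(ref_set) && any(novel)) {
            covered <- vapply(interactors[novel], function(int) {
              any(normalize_text(ref_set$object_drug) == normalize_text(dname) &
                    normalize_text(ref_set$interactor) == normalize_text(int))
            }, logical(1), USE.NAMES = FALSE)
            novel[novel] <- !covered
          }
          chunks[[length(chunks) + 1L]] <- tibble::tibble(
            spl_id = l$spl_id, section = "DrugInteractions",
            claim_kind = "ddi", claim_ref = dd$ddi_id,
            drug = did, drug_name = dname,
            severity = dd$severity,
            pair_label = paste(dd$drug_a, dd$drug_b, sep = " / "),
            potentially_novel = novel, trial_ids = NA_character_,
            slot = NA_character_, value = NA_character_,
            n_support = NA_integer_, n_refute = NA_integer_
          )
        }
      }
    }

    # Clinical Pharmacology <- evidenced PK claims about the drug
    if (!is.null(pk)) {
      pc <- pk_claims_for_drug(pk, did)
      if (nrow(pc)) {
        key <- paste(pc$object_drug, pc$slot, pc$value, sep = "|")
        keep <- !duplicated(key)
        pc <- pc[keep, , drop = FALSE]
        key <- key[keep]
        n_sup <- vapply(pc$evidence, function(e)
          sum(e$direction == "supporting"), integer(1))
        n_ref <- vapply(pc$evidence, function(e)
          sum(e$direction == "refuting"), integer(1))
        for (l in labels_with("ClinicalPharmacology")) {
          txt <- sec_txt(l, "ClinicalPharmacology")
          mentioned <- mentioned_in_text(pc$value, txt)
          chunks[[length(chunks) + 1L]] <- tibble::tibble(
            spl_id = l$spl_id, section = "ClinicalPharmacology",
            claim_kind = "pkClaim", claim_ref = key,
            drug = did, drug_name = dname,
            severity = NA_character_, pair_label = NA_character_,
            potentially_novel = !mentioned, trial_ids = NA_character_,
            slot = pc$slot, value = pc$value,
            n_support = n_sup, n_refute = n_ref
          )
        }
      }
    }
  }
  mappings <- if (length(chunks)) dplyr::bind_rows(chunks) else empty_mappings()
  new_mapping_graph(mappings)
}

#' Count distinct mappings per label
#'
#' @param graph A `mapping_graph`.
#' @return A tibble (`spl_id`, `n`) with one row per label having at least
#'   one mapping, counting distinct mappings across all three claim kinds,
#'   sorted by `spl_id`.
#' @export
mappings_per_label <- function(graph) {
  m <- graph$mappings
  if (nrow(m) == 0L) return(tibble::tibble(spl_id = character(0),
                                           n = integer(0)))
  out <- dplyr::count(m, .data$spl_id, name = "n")
  dplyr::arrange(out, .data$spl_id)
}

#' Audit potentially novel interactions for a drug, by pair
#'
#' Surfaces label-to-label inconsistency: for each interacting pair, how
#' many of the drug's labels carry a mapping flagged potentially novel. A
#' pair flagged on some labels but not others appears with a count smaller
#' than the drug's label count.
#'
#' @param graph A `mapping_graph`.
#' @param drug Drug id or preferred name (matched case-insensitively).
#' @return A tibble (`pair_label`, `n_labels_flagged`), ordered by
#'   `pair_label`; only flagged DDI mappings contribute.
#' @export
audit_novelty_by_pair <- function(graph, drug) {
  m <- graph$mappings
  sel <- m$claim_kind == "ddi" & !is.na(m$potentially_novel) &
    m$potentially_novel &
    (m$drug == drug | normalize_text(m$drug_name) == normalize_text(drug))
  m <- m[sel, , drop = FALSE]
  if (nrow(m) == 0L) {
    return(tibble::tibble(pair_label = character(0),
                          n_labels_flagged = integer(0)))
  }
  out <- dplyr::summarise(dplyr::group_by(m, .data$pair_label),
                          n_labels_flagged = dplyr::n_distinct(.data$spl_id),
                          .groups = "drop")
  dplyr::arrange(out, .data$pair_label)
}

# ---- serialization -------------------------------------------------------

POC_PREFIX <- "http://example.org/poc#"

nt_escape <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\"", "\\\"", x, fixed = TRUE)
  gsub("\n", "\\n", x, fixed = TRUE)
}

#' Write a mapping graph as N-Triples
#'
#' Uses a small fixed predicate vocabulary (one predicate per mapping
#' field, kind-specific map/drug/ref predicates). Rows are serialized in
#' (spl_id, claim_kind, claim_ref) order so output is byte-stable.
#'
#' @param graph A `mapping_graph`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_graph_ntriples <- function(graph, path) {
  m <- graph$mappings
  kind_tag <- c(trialResult = "linkedct-result", ddi = "ndfrt-ddi",
                pkClaim = "dikb-pk")
  lines <- character(0)
  if (nrow(m)) {
    tag <- unname(kind_tag[m$claim_kind])
    subj <- sprintf("<%sspl/%s>", POC_PREFIX, m$spl_id)
    mapping <- sprintf("<%smapping/%s>", POC_PREFIX,
                       gsub("[^A-Za-z0-9._-]", "-",
                            paste(m$spl_id, m$claim_kind, m$claim_ref,
                                  sep = "_")))
    lit <- function(x) sprintf("\"%s\"", nt_escape(x))
    rows <- list(
      sprintf("%s <%s%s-map> %s .", subj, POC_PREFIX, tag, mapping),
      sprintf("%s <%s%s-drug> %s .", mapping, POC_PREFIX, tag,
              lit(m$drug_name)),
      sprintf("%s <%s%s-ref> %s .", mapping, POC_PREFIX, tag,
              lit(m$claim_ref)),
      sprintf("%s <%ssection> %s .", mapping, POC_PREFIX, lit(m$section)),
      sprintf("%s <%skind> %s .", mapping, POC_PREFIX, lit(m$claim_kind))
    )
    lines <- c(
      unlist(rows),
      sprintf("%s <%sseverity> %s .", mapping[!is.na(m$severity)],
              POC_PREFIX, lit(m$severity[!is.na(m$severity)])),
      sprintf("%s <%spair-label> %s .", mapping[!is.na(m$pair_label)],
              POC_PREFIX, lit(m$pair_label[!is.na(m$pair_label)])),
      sprintf("%s <%s%s-potentially-novel> %s .",
              mapping[!is.na(m$potentially_novel) & m$potentially_novel],
              POC_PREFIX,
              unname(kind_tag[m$claim_kind[!is.na(m$potentially_novel) &
                                             m$potentially_novel]]),
              "\"true\"")
    )
  }
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Write a mapping graph as CSV or JSON
#'
#' @param graph A `mapping_graph`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_graph_csv <- function(graph, path) {
  utils::write.csv(as.data.frame(graph$mappings), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_graph_csv
#' @export
write_graph_json <- function(graph, path) {
  jsonlite::write_json(
    list(triple_count = graph$triple_count, mappings = graph$mappings),
    path, auto_unbox = TRUE, na = "null", digits = NA)
  invisible(path)
}
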