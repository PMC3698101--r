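#' Precision, recall and balanced F-measure of a predicted sentence set
#'
#' @param gold Character vector (set) of gold-standard sentence ids.
#' @param pred Character vector (set) of predicted sentence ids.
#' @return An object of class `classifier_score`: list with raw values
#'   (`precision`, `recall`, `f_measure`) and the same rounded to two
#'   decimals (`precision_2dp`, ...). Precision is 0 for an empty
#'   prediction set and recall 0 for an empty gold set; F is the harmonic
#'   mean, defined as 0 when both P and R are 0.
#' @examples
#' prf(gold = c("a", "b", "c", "d"), pred = c("a", "b", "e"))
#' @export
prf <- function(gold, pred) {
  gold <- unique(as.character(gold))
  pred <- unique(as.character(pred))
  tp <- length(intersect(gold, pred))
  p <- if (length(pred) == 0L) 0 else tp / length(pred)
  r <- if (length(gold) == 0L) 0 else tp / length(gold)
  f <- f_measure(p, r, rounded = FALSE)
  structure(
    list(precision = p, recall = r, f_measure = f,
         precision_2dp = round_half_up(p, 2),
         recall_2dp = round_half_up(r, 2),
         f_measure_2dp = round_half_up(f, 2)),
    class = "classifier_score"
  )
}

#' @export
print.classifier_score <- function(x, ...) {
  cat(sprintf("P = %.2f, R = %.2f, F = %.2f\n",
              x$precision_2dp, x$recall_2dp, x$f_measure_2dp))
  invisible(x)
}

#' Balanced F-measure from precision and recall
#'
#' @param precision,recall Fractions in \[0, 1\].
#' @param rounded Round to two decimals (default `TRUE`).
#' @return Harmonic mean `2PR/(P+R)`, 0 when `P + R == 0`.
#' @examples
#' f_measure(0.75, 0.63)  # 0.68
#' @export
f_measure <- function(precision, recall, rounded = TRUE) {
  f <- ifelse(precision + recall == 0, 0,
              2 * precision * recall / (precision + recall))
  if (rounded) round_half_up(f, 2) else f
}

#' Overall pipeline precision
#'
#' Combines the routing step's precision -- the fraction of interpretable
#' routed conclusions judged relevant -- with the sentence classifier's
#' precision: `(routing_relevant / routing_total) * classifier_precision`.
#'
#' @param routing_relevant Count of routed conclusions judged relevant.
#' @param routing_total Count of interpretable routed conclusions (> 0).
#' @param classifier_precision Classifier precision in \[0, 1\].
#' @return List with `raw` and `rounded` (two decimals) values.
#' @examples
#' pipeline_precision(51, 166, 0.75)$rounded  # 0.23
#' @export
pipeline_precision <- function(routing_relevant, routing_total,
                               classifier_precision) {
  if (routing_total <= 0) {
    stop_lw("pipeline precision undefined for routing_total == 0",
            class = "lw_stats_error")
  }
  if (classifier_precision < 0 || classifier_precision > 1) {
    stop_lw("classifier_precision must lie in [0, 1]",
            class = "lw_stats_error")
  }
  raw <- (routing_relevant / routing_total) * classifier_precision
  list(raw = raw, rounded = round_half_up(raw, 2))
}

#' Cohen's kappa for two raters
#'
#' Chance-corrected agreement: `kappa = (po - pe) / (1 - pe)` with `po`
#' the observed fraction of identical ratings and `pe` the expected
#' agreement from the raters' marginal distributions. When both raters
#' are constant and identical (`pe == 1`, `po == 1`), kappa is defined
#' as 1.
#'
#' @param rater_a,rater_b Equal-length vectors of category labels.
#' @return An object of class `kappa_result`: list with
#'   `observed_agreement`, `expected_agreement`, `kappa`.
#' @examples
#' cohen_kappa(c(1, 1, 0, 0), c(1, 0, 1, 0))$kappa  # 0
#' @export
cohen_kappa <- function(rater_a, rater_b) {
  if (length(rater_a) != length(rater_b)) {
    stop_lw("raters must have the same number of ratings",
            class = "lw_stats_error")
  }
  if (length(rater_a) == 0L) {
    stop_lw("at least one rating is required", class = "lw_stats_error")
  }
  a <- as.character(rater_a)
  b <- as.character(rater_b)
  n <- length(a)
  po <- mean(a == b)
  cats <- union(a, b)
  pe <- sum(vapply(cats, function(k) mean(a == k) * mean(b == k),
                   numeric(1)))
  kappa <- if (pe >= 1) {
    if (po == 1) 1 else NA_real_
  } else {
    (po - pe) / (1 - pe)
  }
  structure(list(observed_agreement = po, expected_agreement = pe,
                 kappa = kappa),
            class = "kappa_result")
}

#' @export
print.kappa_result <- function(x, ...) {
  cat(sprintf("kappa = %.3f (po = %.3f, pe = %.3f)\n",
              x$kappa, x$observed_agreement, x$expected_agreement))
  invisible(x)
}

#' Relevance-review bookkeeping for routed abstracts
#'
#' Reproduces the flow-diagram arithmetic of a manual relevance review:
#' abstracts routed to the Clinical Studies section, minus those that were
#' not clinical studies (or were title-only), give the conclusions
#' considered; removing uninterpretable and non-relevant ones gives the
#' relevant conclusions; removing off-label ones gives the
#' indication-relevant conclusions, of which some number were judged
#' novel.
#'
#' @param routed_abstracts,dropped_non_study,uninterpretable,non_relevant
#'   Nonnegative counts.
#' @param off_label Count of relevant conclusions about unapproved uses
#'   (default 0).
#' @param novel Count of indication-relevant conclusions judged novel
#'   (default `NA`, not validated).
#' @return List of class `relevance_bookkeeping` with the input counts and
#'   derived `conclusions_considered`, `relevant`, `indication_relevant`.
#'   Any negative intermediate raises a validation error naming the
#'   violated identity.
#' @examples
#' relevance_bookkeeping(170, 4, 2, 113)$relevant  # 51
#' @export
relevance_bookkeeping <- function(routed_abstracts, dropped_non_study,
                                  uninterpretable, non_relevant,
                                  off_label = 0, novel = NA_integer_) {
  counts <- c(routed_abstracts = routed_abstracts,
              dropped_non_study = dropped_non_study,
              uninterpretable = uninterpretable,
              non_relevant = non_relevant, off_label = off_label)
  if (any(counts < 0)) {
    stop_lw("counts must be nonnegative", class = "lw_stats_error")
  }
  considered <- routed_abstracts - dropped_non_study
  if (considered < 0) {
    stop_lw("identity violated: conclusions_considered = ",
            "routed_abstracts - dropped_non_study is negative",
            class = "lw_stats_error")
  }
  relevant <- considered - uninterpretable - non_relevant
  if (relevant < 0) {
    stop_lw("identity violated: relevant = conclusions_considered - ",
            "uninterpretable - non_relevant is negative",
            class = "lw_stats_error")
  }
  indication <- relevant - off_label
  if (indication < 0) {
    stop_lw("identity violated: indication_relevant = relevant - ",
            "off_label is negative", class = "lw_stats_error")
  }
  if (!is.na(novel) && novel > indication) {
    stop_lw("identity violated: novel exceeds indication_relevant",
            class = "lw_stats_error")
  }
  structure(
    list(routed_abstracts = routed_abstracts,
         dropped_non_study = dropped_non_study,
         conclusions_considered = considered,
         uninterpretable = uninterpretable,
         non_relevant = non_relevant,
         relevant = relevant,
         off_label = off_label,
         indication_relevant = indication,
         novel = novel),
    class = "relevance_bookkeeping"
  )
}

#' Summary of a count distribution across drugs
#'
#' @param x Integer vector of per-drug counts (zeros should already be
#'   excluded by the caller when summarizing only drugs that have the
#'   item).
#' @return List: `n`, `min`, `max`, `mean_raw`, `mean` (rounded half away
#'   from zero to an integer, the printed style), `median` (mean of the
#'   two middle values for even n).
#' @export
distribution_summary <- function(x) {
  x <- as.numeric(x)
  if (length(x) == 0L) {
    return(list(n = 0L, min = NA_real_, max = NA_real_,
                mean_raw = NA_real_, mean = NA_real_, median = NA_real_))
  }
  list(n = length(x), min = min(x), max = max(x),
       mean_raw = mean(x), mean = round_half_up(mean(x)),
       median = middle_median(x))
}

#' Per-drug summary of labels and linked claims
#'
#' One row per drug: number of labels for products containing the drug,
#' distinct Significant and Critical interaction claims, distinct PK
#' claims with supporting and with refuting evidence (a dual-evidence
#' claim counts in both columns), distinct trials, and distinct published
#' results. Distribution summaries (n, min, max, mean, median) are
#' computed for each count column over the drugs with at least one item of
#' that kind, matching how ranges are reported when zero-count drugs are
#' excluded.
#'
#' @param graph A `mapping_graph`.
#' @param corpus The [label_corpus()] the graph was built from.
#' @param drugs Optional [drug_index()]; when given, every indexed drug
#'   gets a row (zeros included), otherwise only drugs appearing in the
#'   graph.
#' @return List with `by_drug` (tibble) and `summaries` (named list of
#'   [distribution_summary()] results for the columns `n_significant`,
#'   `n_critical`, `n_pk_supporting`, `n_pk_refuting`, `n_trials`,
#'   `n_results`).
#' @export
summarize_by_drug <- function(graph, corpus, drugs = NULL) {
  m <- graph$mappings
  ids <- if (!is.null(drugs)) drugs$id else unique(m$drug)
  if (length(ids) == 0L) {
    by_drug <- tibble::tibble(
      drug = character(0), drug_name = character(0), n_labels = integer(0),
      n_significant = integer(0), n_critical = integer(0),
      n_pk_supporting = integer(0), n_pk_refuting = integer(0),
      n_trials = integer(0), n_results = integer(0))
    return(list(by_drug = by_drug, summaries = list()))
  }
  name_of <- if (!is.null(drugs)) {
    stats::setNames(drugs$preferred_name, drugs$id)
  } else {
    stats::setNames(m$drug_name, m$drug)[!duplicated(m$drug)]
  }
  rows <- lapply(ids, function(did) {
    md <- m[m$drug == did, , drop = FALSE]
    ddi <- md[md$claim_kind == "ddi", , drop = FALSE]
    pk <- md[md$claim_kind == "pkClaim", , drop = FALSE]
    pk1 <- pk[!duplicated(pk$claim_ref), , drop = FALSE]
    tr <- md[md$claim_kind == "trialResult", , drop = FALSE]
    tibble::tibble(
      drug = did,
      drug_name = unname(name_of[did]),
      n_labels = length(corpus$ingredient_index[[did]]),
      n_significant = length(unique(
        ddi$claim_ref[ddi$severity == "Significant"])),
      n_critical = length(unique(ddi$claim_ref[ddi$severity == "Critical"])),
      n_pk_supporting = sum(pk1$n_support > 0L),
      n_pk_refuting = sum(pk1$n_refute > 0L),
      n_trials = length(unique(unlist(strsplit(unique(tr$trial_ids), ";")))),
      n_results = length(unique(tr$claim_ref))
    )
  })
  by_drug <- dplyr::bind_rows(rows)
  by_drug <- by_drug[order(by_drug$drug_name), , drop = FALSE]
  cols <- c("n_significant", "n_critical", "n_pk_supporting",
            "n_pk_refuting", "n_trials", "n_results")
  summaries <- lapply(stats::setNames(cols, cols), function(cl) {
    v <- by_drug[[cl]]
    distribution_summary(v[v > 0])
  })
  list(by_drug = by_drug, summaries = summaries)
}

#' Potentially novel interaction claims per drug and severity
#'
#' A claim counts as novel for a drug when it is flagged potentially novel
#' on at least one of the drug's labels. Percentages are
#' `round(100 * novel / found)` half away from zero. Drugs with no found
#' claims of a severity contribute no row.
#'
#' @param graph A `mapping_graph` whose DDI mappings carry novelty flags.
#' @return Tibble (`drug_name`, `severity`, `n_found`,
#'   `n_novel_to_any_label`, `pct_novel`), ordered by drug then severity.
#' @export
novelty_proportions <- function(graph) {
  m <- graph$mappings
  m <- m[m$claim_kind == "ddi", , drop = FALSE]
  if (nrow(m) == 0L) {
    return(tibble::tibble(drug_name = character(0), severity = character(0),
                          n_found = integer(0),
                          n_novel_to_any_label = integer(0),
                          pct_novel = numeric(0)))
  }
  out <- dplyr::summarise(
    dplyr::group_by(m, .data$drug_name, .data$severity, .data$claim_ref),
    novel_any = any(.data$potentially_novel), .groups = "drop_last")
  out <- dplyr::summarise(
    out,
    n_found = dplyr::n(),
    n_novel_to_any_label = sum(.data$novel_any),
    .groups = "drop")
  out$pct_novel <- round_half_up(100 * out$n_novel_to_any_label /
                                   out$n_found)
  dplyr::arrange(out, .data$drug_name, .data$severity)
}

#' Number of unique claims among evidence-level records
#'
#' Evidence-level mapping records repeat a claim once per evidence item;
#' the claim's identity is its (object drug, slot, value) key. Counting
#' distinct keys collapses the duplicates.
#'
#' @param records Data frame with columns `object_drug`, `slot`, `value`
#'   (e.g. from [pk_evidence_records()]).
#' @return Integer count of distinct keys.
#' @export
unique_claim_count <- function(records) {
  nrow(unique(records[, c("object_drug", "slot", "value")]))
}

#' Write a per-drug summary and novelty table as CSV
#'
#' @param summary Result of [summarize_by_drug()].
#' @param novelty Result of [novelty_proportions()].
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_summary_csv <- function(summary, path) {
  utils::write.csv(as.data.frame(summary$by_drug), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_summary_csv
#' @export
write_novelty_csv <- function(novelty, path) {
  utils::write.csv(as.data.frame(novelty), path, row.names = FALSE)
  invisible(path)
}
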