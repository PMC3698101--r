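# Pilot-scale preset: a 29-drug psychotropic corpus whose planted
# per-drug counts equal the published pilot study's summary rows, so the
# summary-arithmetic identities (claim-total sums, distribution medians
# and means, evidence-level deduplication) are exercised end to end at
# desk scale. The preset is fully deterministic: counts are planted, not
# drawn.

# Columns: product labels; Significant / Critical interaction claims; PK
# claims with supporting / refuting evidence (dual = claims counted in
# both columns); trials; published results; interaction claims planted
# novel-to-at-least-one-label per severity (antidepressants only -- the
# reference set covers only that group).
pilot_counts <- function() {
  tibble::tribble(
    ~drug_name,        ~group,            ~labels, ~sig, ~crit, ~pk_for, ~pk_against, ~pk_dual, ~trials, ~results, ~novel_sig, ~novel_crit,
    "amitriptyline",   "antidepressant",       57,   16,     8,       0,           0,        0,       1,        1,          8,           3,
    "amoxapine",       "antidepressant",        2,   15,     8,       0,           0,        0,       0,        0,         11,           4,
    "bupropion",       "antidepressant",      111,    7,     4,       2,           0,        0,       5,       44,          5,           3,
    "citalopram",      "antidepressant",       85,   25,     9,       2,           4,        1,       4,       25,          5,           4,
    "desipramine",     "antidepressant",       15,   16,    10,       0,           0,        0,       0,        0,         16,           6,
    "doxepin",         "antidepressant",       32,   15,     9,       0,           0,        0,       0,        0,         15,           9,
    "duloxetine",      "antidepressant",       17,   26,     8,       3,           4,        0,       4,        4,         12,           3,
    "escitalopram",    "antidepressant",       20,   13,     3,       4,           5,        1,       6,        9,          3,           1,
    "fluoxetine",      "antidepressant",       90,   51,    14,       2,           0,        0,       8,       22,         28,           8,
    "imipramine",      "antidepressant",       19,   18,    10,       0,           0,        0,       1,        4,         18,           6,
    "mirtazapine",     "antidepressant",       55,    2,     5,       4,           9,        0,       1,       22,          1,           1,
    "nefazodone",      "antidepressant",        5,   39,    20,       3,           6,        0,       0,        0,         31,          11,
    "nortriptyline",   "antidepressant",       29,   16,    11,       0,           0,        0,       3,       24,         16,          11,
    "paroxetine",      "antidepressant",       60,   33,    11,       2,           0,        0,       3,       40,         15,           5,
    "selegiline",      "antidepressant",       11,    2,    47,       0,           0,        0,       1,        1,          1,          23,
    "sertraline",      "antidepressant",       74,   28,     8,       2,           0,        0,       3,       27,          7,           3,
    "tranylcypromine", "antidepressant",        2,    3,    61,       0,           0,        0,       3,       71,          1,          33,
    "trazodone",       "antidepressant",       38,    8,    10,       1,           0,        0,       2,        2,          8,          10,
    "trimipramine",    "antidepressant",        2,   17,    10,       0,           0,        0,       0,        0,         17,          10,
    "venlafaxine",     "antidepressant",       66,   21,     6,       3,           3,        0,       2,        2,         21,           6,
    "aripiprazole",    "antipsychotic",        15,    4,     0,       2,          13,        0,       3,        3,          0,           0,
    "clozapine",       "antipsychotic",         9,   29,     2,       3,           1,        0,       3,        9,          0,           0,
    "olanzapine",      "antipsychotic",        42,    0,     1,       1,           0,        0,       5,       13,          0,           0,
    "quetiapine",      "antipsychotic",        33,    8,     0,       1,           9,        0,       4,        9,          0,           0,
    "risperidone",     "antipsychotic",        71,   13,     0,       2,           1,        0,      23,       70,          0,           0,
    "ziprasidone",     "antipsychotic",        22,   54,    23,       2,           9,        1,       1,        6,          0,           0,
    "eszopiclone",     "sedative_hypnotic",    11,    7,     0,       1,           7,        0,       1,        1,          0,           0,
    "zaleplon",        "sedative_hypnotic",    24,    0,     0,       1,           1,        0,       0,        0,          0,           0,
    "zolpidem",        "sedative_hypnotic",    85,    0,     0,       2,           0,        0,       0,        0,          0,           0
  )
}

# Extra supporting-evidence items planted beyond the one item per
# direction each claim carries; chosen so the evidence-level view has 161
# records over 112 unique claims (49 duplicate-key records).
PILOT_EXTRA_EVIDENCE <- 46L

#' Deterministic pilot-scale fixture: 29 psychotropic drugs
#'
#' Builds a complete synthetic environment -- 1,102 product labels, 784
#' interaction claims, 112 unique PK claims carrying 161 evidence items,
#' and 409 published trial results across 29 drugs -- whose per-drug
#' counts equal the planted rows of [pilot_counts()]. Novelty ground
#' truth is planted per claim: a claim designated novel is mentioned in
#' no label and absent from the reference set; for antidepressants, one
#' non-novel claim per severity (when available) is covered by the
#' reference set instead of the section text, so both suppression
#' criteria are exercised.
#'
#' @return A `fixture_corpus` list like [generate_corpus()]'s, with
#'   `ground_truth$by_drug` and `ground_truth$novelty_by_drug` equal to
#'   the planted rows.
#' @export
pilot_fixture <- function() {
  counts <- pilot_counts()
  nd <- nrow(counts)
  drug_ids <- counts$drug_name  # ids double as names at pilot scale
  drugs <- drug_index(drug_ids, counts$drug_name,
                      external_ref = sprintf("http://example.org/drug/%s",
                                             drug_ids))

  labels <- list()
  ddi_rows <- list()
  pk_list <- list()
  trial_rows <- list()
  result_rows <- list()
  ref_rows <- list()
  interactor_counter <- 0L
  pub_counter <- 0L

  for (d in seq_len(nd)) {
    row <- counts[d, ]
    did <- row$drug_name

    # ---- DDI claims with planted novelty ----------------------------
    plan_severity <- function(n_total, n_novel, severity) {
      if (n_total == 0L) return(NULL)
      interactors <- vapply(seq_len(n_total), function(i) {
        interactor_counter <<- interactor_counter + 1L
        synth_name(interactor_counter, offset = 500L)
      }, character(1))
      novel <- seq_len(n_total) <= n_novel
      # among non-novel claims of antidepressants, suppress the first via
      # the reference set rather than a text mention
      via_refset <- rep(FALSE, n_total)
      if (row$group == "antidepressant" && any(!novel)) {
        via_refset[which(!novel)[1L]] <- TRUE
      }
      tibble::tibble(
        ddi_id = sprintf("DDI-%s-%s-%02d", did, substr(severity, 1, 3),
                         seq_len(n_total)),
        drug_a = did, drug_b = interactors, severity = severity,
        status = "Active", novel = novel, via_refset = via_refset)
    }
    dd <- dplyr::bind_rows(plan_severity(row$sig, row$novel_sig, "Significant"),
                           plan_severity(row$crit, row$novel_crit, "Critical"))
    if (!is.null(dd) && nrow(dd)) {
      ddi_rows[[length(ddi_rows) + 1L]] <- dd
      for (i in which(dd$via_refset)) {
        ref_rows[[length(ref_rows) + 1L]] <- tibble::tibble(
          object_drug = did, interactor = dd$drug_b[i], is_class = FALSE)
      }
    }
    mention_names <- if (!is.null(dd) && nrow(dd)) {
      dd$drug_b[!dd$novel & !dd$via_refset]
    } else character(0)

    # ---- PK claims: dual-direction, supporting-only, refuting-only ---
    n_dual <- row$pk_dual
    n_sup_only <- row$pk_for - n_dual
    n_ref_only <- row$pk_against - n_dual
    n_pk <- n_dual + n_sup_only + n_ref_only
    pk_enzymes <- character(0)
    if (n_pk > 0L) {
      combos <- expand.grid(slot = c("substrate_of", "inhibits"),
                            value = CYP_ENZYMES, stringsAsFactors = FALSE)
      pick <- combos[seq_len(n_pk), , drop = FALSE]
      pk_enzymes <- unique(pick$value)
      dirs <- c(rep("both", n_dual), rep("supporting", n_sup_only),
                rep("refuting", n_ref_only))
      ev <- lapply(seq_len(n_pk), function(i) {
        base <- switch(dirs[i], both = c("supporting", "refuting"),
                       supporting = "supporting", refuting = "refuting")
        tibble::tibble(
          evidence_id = sprintf("EV-%s-%02d-%d", did, i, seq_along(base)),
          direction = base,
          source_text = "Pharmacokinetic study report.")
      })
      pk_list[[length(pk_list) + 1L]] <- pk_claims(
        sprintf("PKA-%s-%02d", did, seq_len(n_pk)),
        rep(did, n_pk), pick$slot, pick$value, ev)
    }

    # ---- trials: every trial has >= 1 result -------------------------
    if (row$trials > 0L) {
      per_trial <- rep(1L, row$trials)
      per_trial[1L] <- row$results - (row$trials - 1L)
      tids <- sprintf("NCT-%s-%02d", did, seq_len(row$trials))
      refs <- lapply(per_trial, function(k) {
        ids <- sprintf("PMID%05d", pub_counter + seq_len(k))
        pub_counter <<- pub_counter + k
        ids
      })
      trial_rows[[length(trial_rows) + 1L]] <- trial_records(
        tids, title = sprintf("A study of %s", did),
        design = "randomized controlled trial",
        completion_date = "2011-06-30",
        interventions = rep(list(did), row$trials), result_refs = refs)
      result_rows[[length(result_rows) + 1L]] <- published_results(
        unlist(refs, use.names = FALSE),
        title = sprintf("Findings on %s", did),
        abstract = sprintf(
          "BACKGROUND: The agent %s was assessed. CONCLUSIONS: Treatment with %s was effective.",
          did, did))
    }

    # ---- labels: every label carries all three sections --------------
    di_text <- trimws(paste(
      "Caution is advised with concomitant therapy.",
      if (length(mention_names))
        paste("Reported interactions include",
              paste(mention_names, collapse = ", "), "at usual doses.")
      else "", FILLER))
    di_text <- gsub("[[:space:]]+", " ", di_text)
    cp_text <- gsub("[[:space:]]+", " ", trimws(paste(
      "Absorption is rapid after oral dosing.",
      if (length(pk_enzymes))
        paste("Metabolism involves", paste(pk_enzymes, collapse = ", "),
              "pathways.") else "", FILLER)))
    for (j in seq_len(row$labels)) {
      labels[[length(labels) + 1L]] <- product_label(
        spl_id = sprintf("SPL-%s-%03d", did, j),
        set_id = sprintf("SET-%s-%03d", did, j),
        version = 1L,
        product_name = sprintf("%s %dmg tablets",
                               paste0(toupper(substr(did, 1, 1)),
                                      substr(did, 2, nchar(did))),
                               5L * j),
        organization = sprintf("Maker %02d Pharmaceuticals",
                               (j - 1L) %% 40L + 1L),
        effective_time = "2012-10-25",
        ingredients = did,
        sections = list(
          ClinicalStudies = paste(
            "Controlled trials of this product were reviewed.", FILLER),
          DrugInteractions = di_text,
          ClinicalPharmacology = cp_text))
    }
  }

  pk <- dplyr::bind_rows(pk_list)
  # distribute the extra supporting-evidence items deterministically so
  # the evidence-level view repeats claim keys
  # each replicate repeats the claim's own first evidence direction, so
  # the per-drug supporting/refuting presence columns are unchanged
  extra <- PILOT_EXTRA_EVIDENCE
  for (i in seq_len(min(extra, nrow(pk)))) {
    ev <- pk$evidence[[i]]
    pk$evidence[[i]] <- dplyr::bind_rows(ev, tibble::tibble(
      evidence_id = paste0(ev$evidence_id[1L], "-x"),
      direction = ev$direction[1L],
      source_text = "Replicate pharmacokinetic study report."))
  }

  dd_all <- dplyr::bind_rows(ddi_rows)
  ddis <- ddi_claims(dd_all$ddi_id, dd_all$drug_a, dd_all$drug_b,
                     dd_all$severity, dd_all$status)
  rr <- dplyr::bind_rows(ref_rows)
  ref_set <- reference_set(rr$object_drug, rr$interactor, rr$is_class)
  trials <- dplyr::bind_rows(trial_rows)
  results <- dplyr::bind_rows(result_rows)
  corpus <- label_corpus(labels)

  ground_truth <- list(
    by_drug = tibble::tibble(
      drug = counts$drug_name, drug_name = counts$drug_name,
      n_labels = counts$labels, n_significant = counts$sig,
      n_critical = counts$crit, n_pk_supporting = counts$pk_for,
      n_pk_refuting = counts$pk_against, n_trials = counts$trials,
      n_results = counts$results),
    novelty_by_drug = tibble::tibble(
      drug_name = rep(counts$drug_name, 2L),
      severity = rep(c("Significant", "Critical"), each = nd),
      n_found = c(counts$sig, counts$crit),
      n_novel_to_any_label = c(counts$novel_sig, counts$novel_crit)),
    ddi_novel_claims = dd_all[, c("ddi_id", "novel")]
  )

  structure(
    list(corpus = corpus, drugs = drugs, trials = trials, results = results,
         ddis = ddis, pk = pk, ref_set = ref_set,
         ground_truth = ground_truth, counts = counts),
    class = "fixture_corpus")
}
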