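# Synthetic-corpus generator with exact ground truth.
#
# Drug and interactor names are synthetic, fixed shape <letters><3 digits>:
# because the only digits in a name are its unique final block, no name
# can occur as a substring of a different name, so planted
# mentioned/not-mentioned decisions translate exactly into novelty flags.
# Filler prose contains no digits and no lexicon words.

DRUG_STEMS <- c("velo", "zar", "quin", "mira", "dolo", "fex", "tral", "ambo",
                "ketra", "luma", "pexi", "ronda", "sela", "tivo", "ursa",
                "vanta")
DRUG_SUFFIXES <- c("pramine", "zodone", "oxetine", "azepam", "peridol",
                   "apine", "triptan", "olol")

synth_name <- function(i, offset = 0L) {
  k <- i + offset
  sprintf("%s%s%03d",
          DRUG_STEMS[(k - 1L) %% length(DRUG_STEMS) + 1L],
          DRUG_SUFFIXES[((k - 1L) %/% length(DRUG_STEMS)) %%
                          length(DRUG_SUFFIXES) + 1L],
          k)
}

CYP_ENZYMES <- c("CYP3A4", "CYP2D6", "CYP2C9", "CYP2C19", "CYP1A2",
                 "CYP2B6", "CYP2E1", "CYP2A6", "CYP2C8", "CYP3A5",
                 "CYP1B1", "CYP2J2", "CYP4F2", "CYP2F1", "CYP2A13",
                 "CYP3A7")

FILLER <- paste(
  "Clinical experience with this product is described elsewhere.",
  "Prescribers should consult the full labeling before use.")

#' Configuration for the synthetic-corpus generator
#'
#' Ranges are inclusive `(min, max)` integer pairs sampled uniformly per
#' drug (or per trial for `results_per_trial`).
#'
#' @param n_drugs Number of study drugs.
#' @param labels_per_drug Range of product labels per drug.
#' @param ddi_significant_per_drug,ddi_critical_per_drug Ranges of
#'   interaction claims per severity.
#' @param pk_supporting_per_drug,pk_refuting_per_drug Ranges of PK claims
#'   per evidence direction.
#' @param trials_per_drug Range of registered trials per drug.
#' @param results_per_trial Range of published results per trial (a trial
#'   drawing 0 has no results and is not routed).
#' @param p_mentioned_in_text Probability that a planted DDI interactor or
#'   PK enzyme string is embedded in the relevant section text of a given
#'   label.
#' @param p_in_ref_set Probability that a DDI claim is covered by the
#'   reference interaction set (coverage suppresses novelty regardless of
#'   text mention).
#' @param p_missing_section Probability that a label omits any given
#'   target section (claims are then not mapped to that label/section).
#' @param synonym_trap Plant one extra claim per corpus whose interactor
#'   is an alias of a name that *is* mentioned in the text, reproducing
#'   the synonym failure mode of plain string matching (the claim's
#'   ground-truth flag is "novel" even though the drug is present under
#'   another name).
#' @param include_inactive Also emit one inactive ("Retired") DDI claim
#'   per drug; such claims are never routed.
#' @param include_combo_label Add one two-ingredient combination label
#'   (when `n_drugs >= 2`).
#' @param n_abstracts Number of structured abstracts for
#'   [generate_structured_abstracts()].
#' @param conclusions_block_length Range of sentences in the conclusions
#'   block.
#' @param heading_free_fraction Fraction of abstracts emitted without
#'   section headings (stresses the heading-based baseline classifier).
#' @param seed Integer seed; every generator draw derives from it.
#' @return A list of class `fixture_config`.
#' @export
fixture_config <- function(n_drugs = 8,
                           labels_per_drug = c(2, 10),
                           ddi_significant_per_drug = c(0, 8),
                           ddi_critical_per_drug = c(0, 6),
                           pk_supporting_per_drug = c(0, 4),
                           pk_refuting_per_drug = c(0, 4),
                           trials_per_drug = c(0, 4),
                           results_per_trial = c(0, 5),
                           p_mentioned_in_text = 0.5,
                           p_in_ref_set = 0.5,
                           p_missing_section = 0,
                           synonym_trap = FALSE,
                           include_inactive = FALSE,
                           include_combo_label = FALSE,
                           n_abstracts = 20,
                           conclusions_block_length = c(2, 4),
                           heading_free_fraction = 0,
                           seed = 1L) {
  probs <- c(p_mentioned_in_text, p_in_ref_set, p_missing_section,
             heading_free_fraction)
  if (any(probs < 0 | probs > 1)) {
    stop_lw("probabilities must lie in [0, 1]", class = "lw_config_error")
  }
  ranges <- list(labels_per_drug, ddi_significant_per_drug,
                 ddi_critical_per_drug, pk_supporting_per_drug,
                 pk_refuting_per_drug, trials_per_drug, results_per_trial,
                 conclusions_block_length)
  for (r in ranges) {
    if (length(r) != 2L || any(r < 0) || r[1] > r[2]) {
      stop_lw("ranges must be nonnegative (min, max) pairs",
              class = "lw_config_error")
    }
  }
  if (n_drugs < 1) stop_lw("n_drugs must be >= 1", class = "lw_config_error")
  structure(as.list(environment())[c(
    "n_drugs", "labels_per_drug", "ddi_significant_per_drug",
    "ddi_critical_per_drug", "pk_supporting_per_drug",
    "pk_refuting_per_drug", "trials_per_drug", "results_per_trial",
    "p_mentioned_in_text", "p_in_ref_set", "p_missing_section",
    "synonym_trap", "include_inactive", "include_combo_label",
    "n_abstracts", "conclusions_block_length", "heading_free_fraction",
    "seed")], class = "fixture_config")
}

sample_range <- function(r, n = 1L) {
  if (r[1] == r[2]) rep(r[1], n) else r[1] + floor(runif(n) * (r[2] - r[1] + 1L))
}

#' Generate a synthetic label corpus, claim sources and ground truth
#'
#' Emits a corpus of SPL-dialect labels plus the three claim sources and
#' a reference interaction set, together with the exact ground truth the
#' generator planted: which claims map to which labels, which DDI
#' mappings are potentially novel, which PK enzymes are mentioned, and
#' the per-drug summary rows. Fully reproducible from `config$seed`.
#'
#' @param config A [fixture_config()].
#' @param out_dir Optional directory; when given, SPL XML files, source
#'   CSVs, ground-truth CSVs and a JSON manifest are written there.
#' @return List of class `fixture_corpus`: `corpus`, `drugs`, `trials`,
#'   `results`, `ddis`, `pk`, `ref_set`, `ground_truth`, `spl_xml`
#'   (named character vector), `config`.
#' @export
generate_corpus <- function(config = fixture_config(), out_dir = NULL) {
  stopifnot(inherits(config, "fixture_config"))
  set.seed(config$seed)
  nd <- config$n_drugs

  drug_ids <- sprintf("D%03d", seq_len(nd))
  drug_names <- vapply(seq_len(nd), synth_name, character(1))
  drugs <- drug_index(drug_ids, drug_names,
                      external_ref = sprintf("http://example.org/drug/%s",
                                             drug_ids))

  interactor_counter <- 0L
  next_interactor <- function() {
    interactor_counter <<- interactor_counter + 1L
    synth_name(interactor_counter, offset = 500L)
  }

  labels <- list()
  ddi_rows <- list()
  pk_rows <- list()
  trial_rows <- list()
  result_rows <- list()
  ref_rows <- list()
  gt_ddi <- list()
  gt_pk <- list()
  gt_map <- list()
  by_drug <- list()
  pub_counter <- 0L

  for (d in seq_len(nd)) {
    did <- drug_ids[d]
    dname <- drug_names[d]
    n_labels <- sample_range(config$labels_per_drug)

    # which target sections each label carries
    has_section <- matrix(
      runif(n_labels * 3L) >= config$p_missing_section,
      nrow = n_labels, dimnames = list(NULL, TARGET_SECTIONS))

    # ---- DDI claims --------------------------------------------------
    n_sig <- sample_range(config$ddi_significant_per_drug)
    n_crit <- sample_range(config$ddi_critical_per_drug)
    n_ddi <- n_sig + n_crit
    ddi_ids <- character(0)
    interactors <- character(0)
    severities <- character(0)
    mentioned <- NULL
    covered <- logical(0)
    if (n_ddi > 0L) {
      interactors <- vapply(seq_len(n_ddi), function(i) next_interactor(),
                            character(1))
      severities <- c(rep("Significant", n_sig), rep("Critical", n_crit))
      ddi_ids <- sprintf("DDI-%s-%02d", did, seq_len(n_ddi))
      ddi_rows[[length(ddi_rows) + 1L]] <- tibble::tibble(
        ddi_id = ddi_ids, drug_a = dname, drug_b = interactors,
        severity = severities, status = "Active")
      covered <- runif(n_ddi) < config$p_in_ref_set
      for (i in which(covered)) {
        ref_rows[[length(ref_rows) + 1L]] <- tibble::tibble(
          object_drug = dname, interactor = interactors[i], is_class = FALSE)
      }
      mentioned <- matrix(runif(n_ddi * n_labels) < config$p_mentioned_in_text,
                          nrow = n_ddi)
    }
    if (config$include_inactive) {
      ddi_rows[[length(ddi_rows) + 1L]] <- tibble::tibble(
        ddi_id = sprintf("DDI-%s-RET", did), drug_a = dname,
        drug_b = next_interactor(), severity = "Significant",
        status = "Retired")
    }

    # ---- PK claims ---------------------------------------------------
    n_sup <- sample_range(config$pk_supporting_per_drug)
    n_refu <- sample_range(config$pk_refuting_per_drug)
    n_pk <- n_sup + n_refu
    pk_keys <- character(0)
    enzymes <- character(0)
    pk_mentioned <- NULL
    if (n_pk > 0L) {
      # one enzyme per claim, drawn without replacement, so a mention
      # planted for one claim can never satisfy another claim of the drug
      if (n_pk > length(CYP_ENZYMES)) {
        stop_lw("PK ranges exceed the enzyme lexicon capacity (",
                length(CYP_ENZYMES), ")", class = "lw_config_error")
      }
      enzymes <- sample(CYP_ENZYMES, n_pk)
      slots <- sample(c("substrate_of", "inhibits"), n_pk, replace = TRUE)
      directions <- c(rep("supporting", n_sup), rep("refuting", n_refu))
      aids <- sprintf("PKA-%s-%02d", did, seq_len(n_pk))
      ev <- lapply(seq_len(n_pk), function(i) {
        tibble::tibble(evidence_id = sprintf("EV-%s-%02d", did, i),
                       direction = directions[i],
                       source_text = sprintf("Evidence source for %s.",
                                             aids[i]))
      })
      pk_rows[[length(pk_rows) + 1L]] <- pk_claims(
        aids, rep(did, n_pk), slots, enzymes, ev)
      pk_keys <- paste(did, slots, enzymes, sep = "|")
      pk_mentioned <- matrix(runif(n_pk * n_labels) <
                               config$p_mentioned_in_text, nrow = n_pk)
    }

    # ---- trials and published results --------------------------------
    n_trials <- sample_range(config$trials_per_drug)
    n_results_total <- 0L
    drug_trial_ids <- character(0)
    if (n_trials > 0L) {
      per_trial <- sample_range(config$results_per_trial, n_trials)
      tids <- sprintf("NCT-%s-%02d", did, seq_len(n_trials))
      drug_trial_ids <- tids[per_trial > 0L]
      refs <- lapply(per_trial, function(k) {
        if (k == 0L) return(character(0))
        ids <- sprintf("PMID%05d", pub_counter + seq_len(k))
        pub_counter <<- pub_counter + k
        ids
      })
      trial_rows[[length(trial_rows) + 1L]] <- trial_records(
        trial_id = tids,
        title = sprintf("A study of %s", dname),
        design = "randomized controlled trial",
        completion_date = "2011-06-30",
        interventions = rep(list(did), n_trials),
        result_refs = refs)
      pubs <- unlist(refs, use.names = FALSE)
      n_results_total <- length(pubs)
      if (n_results_total) {
        result_rows[[length(result_rows) + 1L]] <- published_results(
          pubs, title = sprintf("Findings on %s", dname),
          abstract = sprintf(
            "BACKGROUND: The agent %s was assessed. CONCLUSIONS: Treatment with %s was effective.",
            dname, dname))
      }
    }

    # ---- labels with planted section text ----------------------------
    for (j in seq_len(n_labels)) {
      sections <- list()
      if (has_section[j, "ClinicalStudies"]) {
        sections[["ClinicalStudies"]] <-
          paste("Controlled trials of this product were reviewed.", FILLER)
      }
      if (has_section[j, "DrugInteractions"]) {
        mentioned_names <- if (n_ddi > 0L) interactors[mentioned[, j]]
                           else character(0)
        sections[["DrugInteractions"]] <- paste(
          "Caution is advised with concomitant therapy.",
          if (length(mentioned_names))
            paste("Reported interactions include",
                  paste(mentioned_names, collapse = ", "),
                  "at usual doses.") else "",
          FILLER)
        sections[["DrugInteractions"]] <-
          trimws(gsub("[[:space:]]+", " ",
                      sections[["DrugInteractions"]]))
      }
      if (has_section[j, "ClinicalPharmacology"]) {
        mentioned_enz <- if (n_pk > 0L) unique(enzymes[pk_mentioned[, j]])
                         else character(0)
        sections[["ClinicalPharmacology"]] <- trimws(gsub(
          "[[:space:]]+", " ",
          paste("Absorption is rapid after oral dosing.",
                if (length(mentioned_enz))
                  paste("Metabolism involves",
                        paste(mentioned_enz, collapse = ", "),
                        "pathways.") else "",
                FILLER)))
      }
      lab <- product_label(
        spl_id = sprintf("SPL-%s-%02d", did, j),
        set_id = sprintf("SET-%s-%02d", did, j),
        version = 1L,
        product_name = sprintf("%s %dmg tablets",
                               paste0(toupper(substr(dname, 1, 1)),
                                      substr(dname, 2, nchar(dname))),
                               10L * j),
        organization = sprintf("Maker %02d Pharmaceuticals", j),
        effective_time = "2012-10-25",
        ingredients = did,
        sections = sections)
      labels[[length(labels) + 1L]] <- lab

      # ground truth for this label
      n_map <- 0L
      if (has_section[j, "ClinicalStudies"]) n_map <- n_map + n_results_total
      if (has_section[j, "DrugInteractions"] && n_ddi > 0L) {
        n_map <- n_map + n_ddi
        gt_ddi[[length(gt_ddi) + 1L]] <- tibble::tibble(
          ddi_id = ddi_ids, spl_id = lab$spl_id,
          expected_novel = !mentioned[, j] & !covered)
      }
      if (has_section[j, "ClinicalPharmacology"] && n_pk > 0L) {
        n_map <- n_map + n_pk
        gt_pk[[length(gt_pk) + 1L]] <- tibble::tibble(
          claim_key = pk_keys, spl_id = lab$spl_id,
          expected_mentioned = pk_mentioned[, j])
      }
      gt_map[[length(gt_map) + 1L]] <- tibble::tibble(
        spl_id = lab$spl_id, n_expected = n_map)
    }

    by_drug[[length(by_drug) + 1L]] <- tibble::tibble(
      drug = did, drug_name = dname, n_labels = n_labels,
      n_significant = n_sig, n_critical = n_crit,
      n_pk_supporting = n_sup, n_pk_refuting = n_refu,
      n_trials = length(drug_trial_ids), n_results = n_results_total)
  }

  # optional combination product indexed under two drugs
  if (config$include_combo_label && nd >= 2L) {
    labels[[length(labels) + 1L]] <- product_label(
      spl_id = "SPL-COMBO-01", set_id = "SET-COMBO-01", version = 1L,
      product_name = "Combination tablets",
      organization = "Maker 99 Pharmaceuticals",
      effective_time = "2012-10-25",
      ingredients = drug_ids[1:2], sections = list())
  }

  # optional synonym trap: claim names an alias, text mentions the primary
  # name, so the flag is TRUE although the drug is discussed in the text
  if (config$synonym_trap && length(ddi_rows)) {
    trap_alias <- "foxglovia999"
    first <- ddi_rows[[1L]]
    ddi_rows[[length(ddi_rows) + 1L]] <- tibble::tibble(
      ddi_id = "DDI-TRAP-01", drug_a = first$drug_a[1L],
      drug_b = trap_alias, severity = "Critical", status = "Active")
  }

  ddis <- if (length(ddi_rows)) {
    dr <- dplyr::bind_rows(ddi_rows)
    ddi_claims(dr$ddi_id, dr$drug_a, dr$drug_b, dr$severity, dr$status)
  } else ddi_claims(character(0), character(0), character(0), character(0))
  pk <- if (length(pk_rows)) dplyr::bind_rows(pk_rows) else
    pk_claims(character(0), character(0), character(0), character(0), list())
  trials <- if (length(trial_rows)) dplyr::bind_rows(trial_rows) else
    trial_records(character(0), interventions = list())
  results <- if (length(result_rows)) dplyr::bind_rows(result_rows) else
    published_results(character(0))
  ref_set <- if (length(ref_rows)) {
    rr <- dplyr::distinct(dplyr::bind_rows(ref_rows))
    reference_set(rr$object_drug, rr$interactor, rr$is_class)
  } else reference_set()

  corpus <- label_corpus(labels)
  ground_truth <- list(
    mapping_counts = if (length(gt_map)) {
      gm <- dplyr::bind_rows(gt_map)
      gm[gm$n_expected > 0L, , drop = FALSE]
    } else tibble::tibble(spl_id = character(0), n_expected = integer(0)),
    ddi_flags = if (length(gt_ddi)) dplyr::bind_rows(gt_ddi) else
      tibble::tibble(ddi_id = character(0), spl_id = character(0),
                     expected_novel = logical(0)),
    pk_mentions = if (length(gt_pk)) dplyr::bind_rows(gt_pk) else
      tibble::tibble(claim_key = character(0), spl_id = character(0),
                     expected_mentioned = logical(0)),
    by_drug = dplyr::bind_rows(by_drug)
  )

  registry <- section_registry()
  spl_xml <- vapply(corpus$labels, write_spl, character(1),
                    registry = registry)

  out <- structure(
    list(corpus = corpus, drugs = drugs, trials = trials, results = results,
         ddis = ddis, pk = pk, ref_set = ref_set,
         ground_truth = ground_truth, spl_xml = spl_xml, config = config),
    class = "fixture_corpus")
  if (!is.null(out_dir)) write_fixture_dir(out, out_dir)
  out
}

#' Write a generated fixture corpus to disk
#'
#' Writes one SPL XML file per label, one CSV per claim source, the
#' reference set and ground-truth tables as CSV, and a JSON manifest
#' recording the full configuration (including the seed).
#'
#' @param fx A `fixture_corpus` from [generate_corpus()].
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_fixture_dir <- function(fx, out_dir) {
  dir.create(file.path(out_dir, "spl"), recursive = TRUE,
             showWarnings = FALSE)
  for (id in names(fx$spl_xml)) {
    writeLines(fx$spl_xml[[id]], file.path(out_dir, "spl",
                                           paste0(id, ".xml")),
               useBytes = TRUE)
  }
  write_drugs_csv(fx$drugs, file.path(out_dir, "drugs.csv"))
  write_trials_csv(fx$trials, file.path(out_dir, "trials.csv"))
  write_results_csv(fx$results, file.path(out_dir, "results.csv"))
  write_ddis_csv(fx$ddis, file.path(out_dir, "ddis.csv"))
  write_pk_csv(fx$pk, file.path(out_dir, "pk.csv"))
  utils::write.csv(as.data.frame(fx$ref_set),
                   file.path(out_dir, "refset.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(fx$ground_truth$by_drug),
                   file.path(out_dir, "ground_truth_by_drug.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(fx$ground_truth$ddi_flags),
                   file.path(out_dir, "ground_truth_ddi_flags.csv"),
                   row.names = FALSE)
  jsonlite::write_json(unclass(fx$config),
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Generate structured abstracts with gold conclusion sentences
#'
#' Each abstract has BACKGROUND / METHODS / RESULTS / CONCLUSIONS blocks;
#' the gold standard is the set of sentences in the conclusions block
#' (the heading sentence included), following the section-based
#' convention of extracting consecutive conclusion-section sentences. A
#' fraction of abstracts can be emitted without headings to stress the
#' heading-based baseline classifier: their gold sets are unchanged, but
#' the baseline can no longer locate them.
#'
#' @param config A [fixture_config()]; uses `n_abstracts`,
#'   `conclusions_block_length`, `heading_free_fraction`, `seed`.
#' @return List with `abstracts` (tibble `pub_id`, `text`, `has_headings`)
#'   and `gold` (tibble `pub_id`, `index` of each gold conclusion sentence
#'   within the abstract's [split_sentences()] output).
#' @export
generate_structured_abstracts <- function(config = fixture_config()) {
  stopifnot(inherits(config, "fixture_config"))
  set.seed(config$seed + 1L)
  n <- config$n_abstracts
  if (n == 0L) {
    return(list(abstracts = tibble::tibble(pub_id = character(0),
                                           text = character(0),
                                           has_headings = logical(0)),
                gold = tibble::tibble(pub_id = character(0),
                                      index = integer(0))))
  }
  sent_bank <- list(
    background = c("Effective treatment options remain limited.",
                   "Prior reports described inconsistent outcomes."),
    methods = c("Participants were randomized to treatment or placebo.",
                "Outcomes were assessed at twelve weeks."),
    results = c("Symptom scores improved in the treatment arm.",
                "Adverse events were mild and transient."),
    conclusions = c("The treatment was effective in this population.",
                    "These findings support use in routine care.",
                    "Longer trials are needed to confirm durability.",
                    "The safety profile appears acceptable.",
                    "Benefits outweighed observed risks.")
  )
  abstracts <- list()
  gold <- list()
  heading_free <- runif(n) < config$heading_free_fraction
  for (i in seq_len(n)) {
    pid <- sprintf("PMAB%04d", i)
    n_con <- sample_range(config$conclusions_block_length)
    n_con <- max(1L, n_con)
    blocks <- list(
      BACKGROUND = sent_bank$background[1:sample_range(c(1, 2))],
      METHODS = sent_bank$methods[1:sample_range(c(1, 2))],
      RESULTS = sent_bank$results[1:sample_range(c(1, 2))],
      CONCLUSIONS = rep_len(sent_bank$conclusions, n_con)
    )
    texts <- character(0)
    for (h in names(blocks)) {
      sents <- blocks[[h]]
      if (!heading_free[i]) {
        sents[1] <- paste0(h, ": ", sents[1])
      }
      texts <- c(texts, sents)
    }
    full <- paste(texts, collapse = " ")
    n_total <- length(texts)
    gold_idx <- (n_total - n_con + 1L):n_total
    abstracts[[i]] <- tibble::tibble(pub_id = pid, text = full,
                                     has_headings = !heading_free[i])
    gold[[i]] <- tibble::tibble(pub_id = pid, index = gold_idx)
  }
  list(abstracts = dplyr::bind_rows(abstracts),
       gold = dplyr::bind_rows(gold))
}
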