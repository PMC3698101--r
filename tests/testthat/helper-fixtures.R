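# Shared fixture builders. The pilot-scale corpus and its mapping graph
# take a few seconds to build, so they are cached per test run.

.pilot_cache <- new.env(parent = emptyenv())

pilot_cached <- function() {
  if (is.null(.pilot_cache$fx)) {
    .pilot_cache$fx <- pilot_fixture()
    .pilot_cache$graph <- with(.pilot_cache$fx, build_mapping_graph(
      corpus, drugs, trials, results, ddis, pk, ref_set))
  }
  list(fx = .pilot_cache$fx, graph = .pilot_cache$graph)
}

# A hand-sized SPL document used across parser tests.
make_spl_xml <- function(spl_id = "SPL-1", set_id = "SET-1", version = 2,
                         sections = list(), product_name = "Demo tablets") {
  lab <- product_label(spl_id, set_id, version,
                       product_name = product_name,
                       organization = "Maker Pharmaceuticals",
                       effective_time = "2012-10-25",
                       ingredients = "D001", sections = sections)
  write_spl(lab)
}

# Independent brute-force construction of the mapping graph: a plain
# triple loop over drug x label x claim, used as the oracle against
# build_mapping_graph().
brute_force_mappings <- function(fx) {
  rows <- list()
  ref <- if (nrow(fx$ref_set)) expand_reference_set(fx$ref_set, fx$drugs)
         else NULL
  for (d in seq_len(nrow(fx$drugs))) {
    did <- fx$drugs$id[d]
    dname <- fx$drugs$preferred_name[d]
    for (l in fx$corpus$labels) {
      if (!did %in% l$ingredients) next
      # trial results
      if ("ClinicalStudies" %in% names(l$sections)) {
        pairs <- trials_with_results(fx$trials, fx$results, did)
        for (pub in unique(pairs$pub_id)) {
          rows[[length(rows) + 1L]] <- data.frame(
            spl_id = l$spl_id, claim_kind = "trialResult", claim_ref = pub,
            potentially_novel = NA)
        }
      }
      # DDIs
      if ("DrugInteractions" %in% names(l$sections)) {
        dd <- ddis_for_drug(fx$ddis, dname)
        for (i in seq_len(nrow(dd))) {
          novel <- flag_novel_ddi(dd[i, ], dname,
                                  section_text(l, "DrugInteractions"), ref)
          rows[[length(rows) + 1L]] <- data.frame(
            spl_id = l$spl_id, claim_kind = "ddi",
            claim_ref = dd$ddi_id[i], potentially_novel = novel)
        }
      }
      # PK claims
      if ("ClinicalPharmacology" %in% names(l$sections)) {
        pc <- pk_claims_for_drug(fx$pk, did)
        keys <- paste(pc$object_drug, pc$slot, pc$value, sep = "|")
        for (i in which(!duplicated(keys))) {
          mentioned <- flag_pk_enzyme_mentioned(
            pc[i, ], section_text(l, "ClinicalPharmacology"))
          rows[[length(rows) + 1L]] <- data.frame(
            spl_id = l$spl_id, claim_kind = "pkClaim", claim_ref = keys[i],
            potentially_novel = !mentioned)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  out <- unique(out)
  out[order(out$spl_id, out$claim_kind, out$claim_ref), , drop = FALSE]
}

# Check that a generated fixture's ground truth is recovered end to end.
expect_ground_truth_recovered <- function(fx) {
  graph <- build_mapping_graph(fx$corpus, fx$drugs, fx$trials, fx$results,
                               fx$ddis, fx$pk,
                               if (nrow(fx$ref_set)) fx$ref_set else NULL)
  m <- graph$mappings

  # mapping counts per label
  got <- mappings_per_label(graph)
  want <- fx$ground_truth$mapping_counts
  want <- want[order(want$spl_id), ]
  expect_equal(got$spl_id, want$spl_id)
  expect_equal(got$n, as.integer(want$n_expected))

  # DDI novelty flags per (claim, label)
  gt <- fx$ground_truth$ddi_flags
  if (nrow(gt)) {
    dm <- m[m$claim_kind == "ddi", c("claim_ref", "spl_id",
                                     "potentially_novel")]
    key_gt <- paste(gt$ddi_id, gt$spl_id)
    key_m <- paste(dm$claim_ref, dm$spl_id)
    expect_setequal(key_m, key_gt)
    expect_equal(dm$potentially_novel[match(key_gt, key_m)],
                 gt$expected_novel)
  }

  # PK enzyme-mention flags per (claim, label)
  gt <- fx$ground_truth$pk_mentions
  if (nrow(gt)) {
    pm <- m[m$claim_kind == "pkClaim", c("claim_ref", "spl_id",
                                         "potentially_novel")]
    key_gt <- paste(gt$claim_key, gt$spl_id)
    key_m <- paste(pm$claim_ref, pm$spl_id)
    expect_setequal(key_m, key_gt)
    expect_equal(!pm$potentially_novel[match(key_gt, key_m)],
                 gt$expected_mentioned)
  }

  # per-drug summary rows
  s <- summarize_by_drug(graph, fx$corpus, fx$drugs)
  got <- s$by_drug[order(s$by_drug$drug), ]
  want <- fx$ground_truth$by_drug[order(fx$ground_truth$by_drug$drug), ]
  for (col in names(want)) {
    expect_equal(got[[col]], want[[col]], ignore_attr = TRUE,
                 info = paste("by-drug column", col))
  }
  invisible(graph)
}
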