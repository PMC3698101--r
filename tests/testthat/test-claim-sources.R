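test_that("trials without published results are excluded", {
  tr <- trial_records("T1", interventions = list("D1"))
  res <- published_results(character(0))
  expect_equal(nrow(trials_with_results(tr, res, "D1")), 0)
})

test_that("one pair per (trial, result); pilot risperidone row gives 70 pairs over 23 trials", {
  fx <- pilot_cached()$fx
  pairs <- trials_with_results(fx$trials, fx$results, "risperidone")
  expect_equal(nrow(pairs), 70)
  expect_equal(length(unique(pairs$trial_id)), 23)
})

test_that("a multi-intervention trial returns its results for every drug", {
  tr <- trial_records("T1", interventions = list(c("D1", "D2")),
                      result_refs = list(c("P1", "P2")))
  res <- published_results(c("P1", "P2"), title = c("a", "b"),
                           abstract = c("x", "y"))
  for (d in c("D1", "D2")) {
    pairs <- trials_with_results(tr, res, d)
    expect_equal(pairs$pub_id, c("P1", "P2"))
  }
  expect_equal(nrow(trials_with_results(tr, res, "D3")), 0)
})

test_that("dangling result references yield placeholder pairs with a warning", {
  tr <- trial_records("T1", interventions = list("D1"),
                      result_refs = list(c("P1", "PMISSING")))
  res <- published_results("P1", title = "t", abstract = "a")
  expect_warning(pairs <- trials_with_results(tr, res, "D1"), "PMISSING")
  expect_equal(nrow(pairs), 2)
  expect_equal(pairs$pub_title[pairs$pub_id == "PMISSING"],
               "(publication record unavailable)")
})

test_that("ddis_for_drug keeps only Active claims naming the drug", {
  ddis <- ddi_claims(
    c("I1", "I2", "I3", "I4"),
    drug_a = c("mirtazapine", "mirtazapine", "Mirtazapine ", "otherdrug"),
    drug_b = c("warfarin", "linezolid", "tramadol", "warfarin"),
    severity = c("Significant", "Critical", "Critical", "Critical"),
    status = c("Active", "Retired", "Active", "Active"))
  got <- ddis_for_drug(ddis, "mirtazapine")
  expect_setequal(got$ddi_id, c("I1", "I3"))  # Retired excluded, case/trim ok
  expect_equal(nrow(ddis_for_drug(ddis, "mirtazapine",
                                  ignore_case = FALSE)), 1)
  # subset, idempotent, permutation-invariant
  expect_true(all(got$ddi_id %in% ddis$ddi_id))
  expect_equal(ddis_for_drug(got, "mirtazapine"), got)
  shuffled <- ddis[c(4, 2, 3, 1), ]
  expect_setequal(ddis_for_drug(shuffled, "mirtazapine")$ddi_id,
                  got$ddi_id)
})

test_that("pilot mirtazapine carries 2 Significant + 5 Critical claims", {
  fx <- pilot_cached()$fx
  got <- ddis_for_drug(fx$ddis, "mirtazapine")
  expect_equal(sum(got$severity == "Significant"), 2)
  expect_equal(sum(got$severity == "Critical"), 5)
})

test_that("invalid severities are a hard load-time error", {
  expect_error(ddi_claims("I1", "a", "b", "Moderate"),
               class = "lw_validation_error")
})

test_that("pk_claims_for_drug returns both slots and drops evidence-free claims", {
  pk <- pk_claims(
    c("A1", "A2", "A3"), c("D1", "D1", "D1"),
    slot = c("substrate_of", "inhibits", "inhibits"),
    value = c("CYP2D6", "CYP3A4", "CYP1A2"),
    evidence = list(
      tibble::tibble(evidence_id = "E1", direction = "supporting",
                     source_text = "s"),
      tibble::tibble(evidence_id = c("E2", "E3"),
                     direction = c("supporting", "refuting"),
                     source_text = c("s", "r")),
      tibble::tibble(evidence_id = character(0), direction = character(0),
                     source_text = character(0))))
  expect_message(got <- pk_claims_for_drug(pk, "D1"), "no evidence")
  expect_setequal(got$assertion_id, c("A1", "A2"))
  # dual-direction claim kept once with both items
  both <- got$evidence[[which(got$assertion_id == "A2")]]
  expect_setequal(both$direction, c("supporting", "refuting"))
  expect_equal(nrow(pk_claims_for_drug(pk, "D9")), 0)
})

test_that("pilot mirtazapine has 13 evidenced PK claims", {
  fx <- pilot_cached()$fx
  expect_equal(nrow(pk_claims_for_drug(fx$pk, "mirtazapine")), 13)
})

test_that("evidence-level records collapse to unique claims by key", {
  fx <- pilot_cached()$fx
  recs <- pk_evidence_records(fx$pk)
  expect_equal(nrow(recs), 161)
  expect_equal(unique_claim_count(recs), 112)
  # brute-force set oracle
  expect_equal(unique_claim_count(recs),
               length(unique(paste(recs$object_drug, recs$slot,
                                   recs$value))))
})

test_that("claim sources survive a CSV round trip", {
  fx <- generate_corpus(fixture_config(n_drugs = 3, seed = 23))
  dir <- withr::local_tempdir()
  write_trials_csv(fx$trials, file.path(dir, "t.csv"))
  write_results_csv(fx$results, file.path(dir, "r.csv"))
  write_ddis_csv(fx$ddis, file.path(dir, "d.csv"))
  write_pk_csv(fx$pk, file.path(dir, "p.csv"))
  write_drugs_csv(fx$drugs, file.path(dir, "g.csv"))
  expect_equal(read_trials_csv(file.path(dir, "t.csv")), fx$trials,
               ignore_attr = TRUE)
  expect_equal(read_results_csv(file.path(dir, "r.csv")), fx$results,
               ignore_attr = TRUE)
  expect_equal(read_ddis_csv(file.path(dir, "d.csv")), fx$ddis,
               ignore_attr = TRUE)
  got_pk <- read_pk_csv(file.path(dir, "p.csv"))
  expect_equal(got_pk$value, fx$pk$value)
  expect_equal(got_pk$evidence, fx$pk$evidence, ignore_attr = TRUE)
  expect_equal(read_drugs_csv(file.path(dir, "g.csv")), fx$drugs,
               ignore_attr = TRUE)
})
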