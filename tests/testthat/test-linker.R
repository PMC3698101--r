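make_small_fixture <- function() {
  # one drug, one label with all sections; 2 published results, 3 DDIs,
  # 1 evidenced PK claim -> 6 mappings expected
  drugs <- drug_index("D1", "alphadone")
  lab <- product_label(
    "SPL-A", "SET-A", 1, product_name = "Alphadone tablets",
    ingredients = "D1",
    sections = list(
      ClinicalStudies = "Trials were reviewed.",
      DrugInteractions = "Reported interactions include betadone.",
      ClinicalPharmacology = "Metabolism involves CYP2D6."))
  corpus <- label_corpus(list(lab))
  trials <- trial_records("T1", interventions = list("D1"),
                          result_refs = list(c("P1", "P2")))
  results <- published_results(c("P1", "P2"), title = c("r1", "r2"),
                               abstract = c("a", "b"))
  ddis <- ddi_claims(c("I1", "I2", "I3"), "alphadone",
                     c("betadone", "gammadone", "deltadone"),
                     c("Significant", "Critical", "Critical"))
  pk <- pk_claims("A1", "D1", "substrate_of", "CYP2D6",
                  list(tibble::tibble(evidence_id = "E1",
                                      direction = "supporting",
                                      source_text = "s")))
  list(corpus = corpus, drugs = drugs, trials = trials, results = results,
       ddis = ddis, pk = pk)
}

test_that("empty inputs give an empty graph", {
  g <- build_mapping_graph(label_corpus(), drug_index("D1", "x"))
  expect_equal(nrow(g$mappings), 0)
  expect_equal(g$triple_count, 0)
  expect_equal(nrow(mappings_per_label(g)), 0)
})

test_that("a label with 2 results + 3 DDIs + 1 PK claim gets 6 mappings", {
  fx <- make_small_fixture()
  g <- build_mapping_graph(fx$corpus, fx$drugs, fx$trials, fx$results,
                           fx$ddis, fx$pk)
  expect_equal(nrow(g$mappings), 6)
  tab <- mappings_per_label(g)
  expect_equal(tab, tibble::tibble(spl_id = "SPL-A", n = 6L))
  # kind -> section constraint holds exhaustively
  m <- g$mappings
  expect_true(all(m$section[m$claim_kind == "trialResult"] ==
                    "ClinicalStudies"))
  expect_true(all(m$section[m$claim_kind == "ddi"] == "DrugInteractions"))
  expect_true(all(m$section[m$claim_kind == "pkClaim"] ==
                    "ClinicalPharmacology"))
  # novelty flags: betadone mentioned, others not; enzyme mentioned
  ddi_m <- m[m$claim_kind == "ddi", ]
  expect_equal(ddi_m$potentially_novel[order(ddi_m$claim_ref)],
               c(FALSE, TRUE, TRUE))
  expect_false(m$potentially_novel[m$claim_kind == "pkClaim"])
})

test_that("claims are not mapped to labels lacking the target section", {
  fx <- make_small_fixture()
  lab2 <- product_label("SPL-B", "SET-B", 1, ingredients = "D1",
                        sections = list(ClinicalStudies = "Trials."))
  corpus <- label_corpus(c(fx$corpus$labels, list(lab2)))
  g <- build_mapping_graph(corpus, fx$drugs, fx$trials, fx$results,
                           fx$ddis, fx$pk)
  tab <- mappings_per_label(g)
  expect_equal(tab$n[tab$spl_id == "SPL-B"], 2L)  # only the two results
  g2 <- build_mapping_graph(corpus, fx$drugs, fx$trials, fx$results,
                            fx$ddis, fx$pk, attach_missing_section = TRUE)
  tab2 <- mappings_per_label(g2)
  expect_equal(tab2$n[tab2$spl_id == "SPL-B"], 6L)
  # novelty against an absent section is TRUE by definition
  m2 <- g2$mappings
  expect_true(all(m2$potentially_novel[m2$spl_id == "SPL-B" &
                                         m2$claim_kind == "ddi"]))
})

test_that("graph build is deterministic and idempotent", {
  fx <- generate_corpus(fixture_config(n_drugs = 3, seed = 31))
  g1 <- build_mapping_graph(fx$corpus, fx$drugs, fx$trials, fx$results,
                            fx$ddis, fx$pk, fx$ref_set)
  g2 <- build_mapping_graph(fx$corpus, fx$drugs, fx$trials, fx$results,
                            fx$ddis, fx$pk, fx$ref_set)
  expect_identical(g1, g2)
})

test_that("mappings_per_label counts sum to the graph size", {
  fx <- generate_corpus(fixture_config(n_drugs = 4, seed = 13))
  g <- build_mapping_graph(fx$corpus, fx$drugs, fx$trials, fx$results,
                           fx$ddis, fx$pk, fx$ref_set)
  expect_equal(sum(mappings_per_label(g)$n), nrow(g$mappings))
})

test_that("graph equals an independent brute-force triple loop", {
  for (seed in c(2, 9)) {
    fx <- generate_corpus(fixture_config(n_drugs = 3,
                                         labels_per_drug = c(1, 3),
                                         seed = seed))
    g <- build_mapping_graph(fx$corpus, fx$drugs, fx$trials, fx$results,
                             fx$ddis, fx$pk,
                             if (nrow(fx$ref_set)) fx$ref_set else NULL)
    got <- as.data.frame(g$mappings[, c("spl_id", "claim_kind", "claim_ref",
                                        "potentially_novel")])
    want <- brute_force_mappings(fx)
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want)
  }
})

test_that("triple count expands populated fields only", {
  fx <- make_small_fixture()
  g <- build_mapping_graph(fx$corpus, fx$drugs, fx$trials, fx$results,
                           fx$ddis, fx$pk)
  m <- g$mappings
  want <- 5 * nrow(m) + sum(!is.na(m$severity)) +
    sum(!is.na(m$pair_label)) + sum(m$potentially_novel, na.rm = TRUE)
  expect_equal(g$triple_count, want)
  # 6 mappings: 30 base + 3 severity + 3 pair + 2 bound novelty flags
  expect_equal(g$triple_count, 38L)
})

test_that("novelty audit groups flagged labels by pair", {
  drugs <- drug_index("D1", "alphadone")
  labs <- lapply(1:5, function(i) {
    product_label(sprintf("SPL-%02d", i), sprintf("SET-%02d", i), 1,
                  ingredients = "D1",
                  sections = list(DrugInteractions = if (i <= 2)
                    "Reported interactions include betadone." else
                      "No interacting agents are listed."))
  })
  corpus <- label_corpus(labs)
  ddis <- ddi_claims("I1", "alphadone", "betadone", "Significant")
  g <- build_mapping_graph(corpus, drugs, ddis = ddis)
  aud <- audit_novelty_by_pair(g, "alphadone")
  # novel on 3 of 5 labels: an inconsistency across labels of one drug
  expect_equal(aud$n_labels_flagged, 3L)
  expect_lt(aud$n_labels_flagged, length(labs))
  expect_equal(aud$pair_label, "alphadone / betadone")
  # no flagged mappings -> empty table
  expect_equal(nrow(audit_novelty_by_pair(g, "nosuchdrug")), 0)
})

test_that("duplicate mapping insertion is ignored (combo label, one claim)", {
  drugs <- drug_index(c("D1", "D2"), c("alphadone", "betadone"))
  lab <- product_label("SPL-C", "SET-C", 1, ingredients = c("D1", "D2"),
                       sections = list(DrugInteractions = "Nothing listed."))
  corpus <- label_corpus(list(lab))
  # one claim naming both drugs: routed once per drug, same (spl, kind, ref)
  ddis <- ddi_claims("I1", "alphadone", "betadone", "Critical")
  g <- build_mapping_graph(corpus, drugs, ddis = ddis)
  expect_equal(nrow(g$mappings), 1)
})

test_that("graph serializations are deterministic and complete", {
  fx <- make_small_fixture()
  g <- build_mapping_graph(fx$corpus, fx$drugs, fx$trials, fx$results,
                           fx$ddis, fx$pk)
  dir <- withr::local_tempdir()
  nt1 <- file.path(dir, "g1.nt"); nt2 <- file.path(dir, "g2.nt")
  write_graph_ntriples(g, nt1); write_graph_ntriples(g, nt2)
  expect_identical(readLines(nt1), readLines(nt2))
  expect_equal(length(readLines(nt1)), g$triple_count)
  write_graph_csv(g, file.path(dir, "g.csv"))
  back <- utils::read.csv(file.path(dir, "g.csv"))
  expect_equal(nrow(back), nrow(g$mappings))
  write_graph_json(g, file.path(dir, "g.json"))
  j <- jsonlite::read_json(file.path(dir, "g.json"))
  expect_equal(j$triple_count, g$triple_count)
})
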