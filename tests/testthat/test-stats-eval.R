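# Independent oracle: confusion counts from explicit membership tests.
prf_oracle <- function(gold, pred, universe) {
  tp <- sum(universe %in% gold & universe %in% pred)
  fp <- sum(!(universe %in% gold) & universe %in% pred)
  fn <- sum(universe %in% gold & !(universe %in% pred))
  p <- if (tp + fp == 0) 0 else tp / (tp + fp)
  r <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f <- if (p + r == 0) 0 else 2 * p * r / (p + r)
  c(p = p, r = r, f = f)
}

# Independent oracle: kappa from a full contingency table.
kappa_oracle <- function(a, b) {
  tab <- table(factor(a, levels = union(a, b)),
               factor(b, levels = union(a, b)))
  n <- sum(tab)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (pe >= 1) return(if (po == 1) 1 else NA_real_)
  (po - pe) / (1 - pe)
}

test_that("prf matches hand-enumerated confusion counts", {
  s <- prf(gold = c("a", "b", "c", "d"), pred = c("a", "b", "e"))
  expect_equal(s$precision, 2 / 3)
  expect_equal(s$recall, 1 / 2)
  expect_equal(s$f_measure, 4 / 7)
  perfect <- prf(c("x", "y"), c("x", "y"))
  expect_equal(unlist(perfect[c("precision", "recall", "f_measure")]),
               c(precision = 1, recall = 1, f_measure = 1))
  # empty sets: defined as zero, not NaN
  expect_equal(prf(character(0), "a")$recall, 0)
  expect_equal(prf("a", character(0))$precision, 0)
  # F bounded by P and R
  expect_gte(s$f_measure, min(s$precision, s$recall) - 1e-12)
  expect_lte(s$f_measure, max(s$precision, s$recall) + 1e-12)
})

test_that("prf agrees with a brute-force confusion oracle on random sets", {
  set.seed(424)
  universe <- sprintf("s%03d", 1:40)
  for (i in 1:1000) {
    gold <- sample(universe, sample.int(40, 1))
    pred <- sample(universe, sample.int(41, 1) - 1L)
    got <- prf(gold, pred)
    want <- prf_oracle(gold, pred, universe)
    expect_equal(c(got$precision, got$recall, got$f_measure),
                 unname(want))
  }
})

test_that("the balanced F-measure of P=0.75, R=0.63 rounds to 0.68", {
  expect_equal(f_measure(0.75, 0.63), 0.68)
  expect_equal(f_measure(0, 0), 0)
})

test_that("pipeline precision combines routing and classifier precision", {
  pp <- pipeline_precision(51, 166, 0.75)
  expect_equal(pp$rounded, 0.23)
  expect_equal(pp$raw, 51 / 166 * 0.75)
  expect_equal(pipeline_precision(10, 10, 1)$rounded, 1)
  expect_equal(pipeline_precision(0, 25, 0.9)$rounded, 0)
  expect_error(pipeline_precision(1, 0, 0.5), class = "lw_stats_error")
  expect_error(pipeline_precision(1, 10, 1.5), class = "lw_stats_error")
})

test_that("cohen_kappa matches hand-computed marginals", {
  expect_equal(cohen_kappa(c(1, 1, 1), c(1, 1, 1))$kappa, 1)
  k0 <- cohen_kappa(c(1, 1, 0, 0), c(1, 0, 1, 0))
  expect_equal(k0$observed_agreement, 0.5)
  expect_equal(k0$expected_agreement, 0.5)
  expect_equal(k0$kappa, 0)
  k5 <- cohen_kappa(c(1, 1, 1, 0), c(1, 1, 0, 0))
  expect_equal(k5$observed_agreement, 0.75)
  expect_equal(k5$expected_agreement, 0.5)
  expect_equal(k5$kappa, 0.5)
  expect_error(cohen_kappa(1:3, 1:2), class = "lw_stats_error")
})

test_that("cohen_kappa agrees with a contingency-table oracle on random ratings", {
  set.seed(77)
  for (i in 1:1000) {
    n <- sample(2:30, 1)
    k <- sample(2:4, 1)
    a <- sample(letters[1:k], n, replace = TRUE)
    b <- sample(letters[1:k], n, replace = TRUE)
    got <- cohen_kappa(a, b)$kappa
    want <- kappa_oracle(a, b)
    expect_equal(got, want)
  }
  # constant rater: po == pe  =>  kappa 0
  a <- rep("yes", 10)
  b <- c(rep("yes", 7), rep("no", 3))
  res <- cohen_kappa(a, b)
  expect_equal(res$observed_agreement, res$expected_agreement)
  expect_equal(res$kappa, 0)
})

test_that("relevance bookkeeping derives the review-flow identities", {
  bk <- relevance_bookkeeping(170, 4, 2, 113, off_label = 12, novel = 30)
  expect_equal(bk$conclusions_considered, 166)
  expect_equal(bk$relevant, 51)
  expect_equal(bk$indication_relevant, 39)
  zeros <- relevance_bookkeeping(0, 0, 0, 0)
  expect_equal(zeros$relevant, 0)
  expect_error(relevance_bookkeeping(10, 12, 0, 0),
               class = "lw_stats_error")
  expect_error(relevance_bookkeeping(10, 0, 6, 6),
               class = "lw_stats_error")
  expect_error(relevance_bookkeeping(10, 0, 0, 0, off_label = 3, novel = 9),
               class = "lw_stats_error")
})

test_that("distribution summaries use even-n medians and printed-style means", {
  ds <- distribution_summary(c(1, 9, 9, 44))
  expect_equal(ds$median, 9)
  expect_equal(ds$mean_raw, 15.75)
  expect_equal(ds$mean, 16)
  even <- distribution_summary(c(2, 4, 6, 8))
  expect_equal(even$median, 5)  # mean of the two middle values
  expect_equal(distribution_summary(integer(0))$n, 0)
})

test_that("rounding is half away from zero with raw values retained", {
  expect_equal(round_half_up(18.5), 19)
  expect_equal(round_half_up(12.96), 13)
  expect_equal(round_half_up(-2.5), -3)
  expect_equal(round_half_up(0.125, 2), 0.13)
  expect_equal(round_half_up(0.5), 1)  # base round() would give 0
})

test_that("unique_claim_count equals a set oracle on random records", {
  set.seed(99)
  for (i in 1:50) {
    n <- sample(1:40, 1)
    recs <- data.frame(
      object_drug = sample(c("d1", "d2", "d3"), n, replace = TRUE),
      slot = sample(c("substrate_of", "inhibits"), n, replace = TRUE),
      value = sample(c("CYP3A4", "CYP2D6"), n, replace = TRUE))
    expect_equal(unique_claim_count(recs),
                 length(unique(do.call(paste, recs))))
  }
  distinct <- data.frame(object_drug = letters[1:5], slot = "inhibits",
                         value = "CYP3A4")
  expect_equal(unique_claim_count(distinct), 5)
})

test_that("per-drug summaries and novelty proportions recount the graph", {
  p <- pilot_cached()
  s <- summarize_by_drug(p$graph, p$fx$corpus, p$fx$drugs)
  # column totals are claim-level totals
  expect_equal(sum(s$by_drug$n_results), 409)
  expect_equal(sum(s$by_drug$n_significant) + sum(s$by_drug$n_critical),
               784)
  np <- novelty_proportions(p$graph)
  amitriptyline_sig <- np[np$drug_name == "amitriptyline" &
                            np$severity == "Significant", ]
  expect_equal(amitriptyline_sig$n_found, 16L)
  expect_equal(amitriptyline_sig$n_novel_to_any_label, 8L)
  expect_equal(amitriptyline_sig$pct_novel, 50)
  # all claims mentioned on all labels -> no novelty rows with flags
  expect_true(all(np$n_novel_to_any_label <= np$n_found))
  # empty graph edge cases
  g0 <- build_mapping_graph(label_corpus(), drug_index("D1", "x"))
  expect_equal(nrow(novelty_proportions(g0)), 0)
  expect_equal(nrow(summarize_by_drug(g0, label_corpus())$by_drug), 0)
})
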