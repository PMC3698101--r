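test_that("parsing a metadata-only SPL yields a label with no sections", {
  lab <- parse_spl(make_spl_xml())
  expect_s3_class(lab, "product_label")
  expect_equal(lab$spl_id, "SPL-1")
  expect_equal(lab$version, 2L)
  expect_length(lab$sections, 0)
  expect_true(is.na(section_text(lab, "ClinicalStudies")))
})

test_that("section text is retrievable verbatim under its section name", {
  sent <- paste("Escitalopram is metabolized to S-DCT and",
                "S-didemethylcitalopram (S-DDCT).")
  xml <- make_spl_xml(sections = list(ClinicalPharmacology = sent))
  lab <- parse_spl(xml)
  expect_identical(section_text(lab, "ClinicalPharmacology"), sent)
})

test_that("markup is stripped and whitespace collapsed in section text", {
  xml <- paste0(
    '<document><id root="S1"/><setId root="T1"/>',
    '<versionNumber value="1"/><title>x</title>',
    '<component><section><code code="SEC-DI"/>',
    "<text>  line one\n   <content>line two</content>  </text>",
    "</section></component></document>")
  lab <- parse_spl(xml)
  expect_identical(section_text(lab, "DrugInteractions"),
                   "line one line two")
})

test_that("unrecognized section codes are kept under Other names", {
  xml <- paste0(
    '<document><id root="S1"/><setId root="T1"/>',
    '<versionNumber value="1"/><title>x</title>',
    '<component><section><code code="ZZZ-1"/>',
    "<text>boxed warning text</text></section></component></document>")
  lab <- parse_spl(xml)
  expect_identical(section_text(lab, "Other:ZZZ-1"), "boxed warning text")
})

test_that("malformed XML and missing metadata raise informative errors", {
  expect_error(parse_spl("<document><id root='x'>"), class = "lw_parse_error")
  no_meta <- '<document><title>x</title></document>'
  err <- expect_error(parse_spl(no_meta), class = "lw_validation_error")
  expect_match(conditionMessage(err), "splId")
  expect_match(conditionMessage(err), "setId")
  expect_match(conditionMessage(err), "version")
})

test_that("write/parse round trip is the identity on generated corpora", {
  fx <- generate_corpus(fixture_config(n_drugs = 3, labels_per_drug = c(1, 3),
                                       seed = 11))
  for (lab in fx$corpus$labels) {
    expect_equal(parse_spl(write_spl(lab)), lab)
  }
})

test_that("querying all three target sections reports present and absent", {
  xml <- make_spl_xml(sections = list(ClinicalStudies = "Trials were run.",
                                      ClinicalPharmacology = "CYP3A4."))
  lab <- parse_spl(xml)
  texts <- vapply(c("ClinicalStudies", "DrugInteractions",
                    "ClinicalPharmacology"),
                  function(s) section_text(lab, s), character(1))
  expect_equal(sum(!is.na(texts)), 2L)
  expect_true(is.na(texts[["DrugInteractions"]]))
})

test_that("labels_for_ingredient matches a naive full scan and sorts", {
  fx <- generate_corpus(fixture_config(n_drugs = 4, labels_per_drug = c(2, 5),
                                       seed = 7))
  for (did in fx$drugs$id) {
    got <- labels_for_ingredient(fx$corpus, did)
    scan <- Filter(function(l) did %in% l$ingredients,
                   unname(fx$corpus$labels))
    expect_setequal(vapply(got, `[[`, "", "spl_id"),
                    vapply(scan, `[[`, "", "spl_id"))
    keys <- vapply(got, function(l) paste(l$set_id, l$version), "")
    expect_equal(keys, sort(keys))
  }
})

test_that("empty corpus and unknown drugs yield empty results", {
  empty <- label_corpus()
  expect_length(labels_for_ingredient(empty, "nosuch"), 0)
  fx <- generate_corpus(fixture_config(n_drugs = 2, seed = 3))
  expect_warning(res <- labels_for_ingredient(fx$corpus, "nosuchdrug"),
                 "not in ingredient index")
  expect_length(res, 0)
})

test_that("ingredient index inverts ingredient sets; multi-ingredient labels double-count", {
  fx <- generate_corpus(fixture_config(n_drugs = 3, labels_per_drug = c(2, 3),
                                       include_combo_label = TRUE, seed = 5))
  per_drug <- vapply(fx$drugs$id, function(d)
    length(fx$corpus$ingredient_index[[d]]), integer(1))
  n_multi <- sum(vapply(fx$corpus$labels,
                        function(l) length(l$ingredients) > 1, logical(1)))
  expect_equal(sum(per_drug), length(fx$corpus$labels) + n_multi)
  expect_gte(sum(per_drug), length(fx$corpus$labels))
})

test_that("duplicate spl_id or (set_id, version) is rejected", {
  a <- parse_spl(make_spl_xml(spl_id = "A", set_id = "S", version = 1))
  b <- parse_spl(make_spl_xml(spl_id = "A", set_id = "S2", version = 1))
  expect_error(label_corpus(list(a, b)), class = "lw_corpus_error")
  c2 <- parse_spl(make_spl_xml(spl_id = "B", set_id = "S", version = 1))
  expect_error(label_corpus(list(a, c2)), class = "lw_corpus_error")
})

test_that("corpus JSON round trip preserves labels", {
  fx <- generate_corpus(fixture_config(n_drugs = 2, labels_per_drug = c(1, 2),
                                       seed = 19))
  path <- withr::local_tempfile(fileext = ".json")
  write_corpus_json(fx$corpus, path)
  back <- read_corpus_json(path)
  expect_equal(back$labels, fx$corpus$labels)
  expect_equal(back$ingredient_index, fx$corpus$ingredient_index)
})

test_that("per-drug label counts equal the planted pilot counts", {
  fx <- pilot_cached()$fx
  expect_length(fx$corpus$labels, 1102)
  expect_length(labels_for_ingredient(fx$corpus, "amitriptyline"), 57)
  expect_length(labels_for_ingredient(fx$corpus, "escitalopram"), 20)
})
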