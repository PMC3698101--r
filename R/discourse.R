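#' The eleven core scientific discourse tags
#'
#' Sentence-level tags used by scientific-discourse annotation schemes;
#' `Conclusion` is the one this package routes on.
#'
#' @return Character vector of the 11 tag values.
#' @export
sentence_tags <- function() {
  c("Hypothesis", "Motivation", "Background", "Goal", "Object", "Method",
    "Experiment", "Model", "Result", "Observation", "Conclusion")
}

# Abbreviations whose trailing period does not end a sentence.
ABBREVIATIONS <- c("Mr", "Mrs", "Ms", "Dr", "Prof", "St", "vs", "etc",
                   "e.g", "i.e", "Fig", "al", "ca", "approx", "no", "No")

#' Split text into sentences
#'
#' Deterministic rule-based segmentation: a sentence ends at `.`, `!` or
#' `?` followed by whitespace and an upper-case letter or digit, unless
#' the period terminates a known abbreviation (e.g. "Mr.") or a
#' single-letter initial. Structured-abstract headings such as
#' `"CONCLUSIONS:"` are kept as the prefix of their first sentence, so
#' concatenating the result (modulo whitespace) reconstructs the input.
#'
#' @param text A single string; whitespace is normalized first.
#' @return Character vector of sentences (empty for empty input).
#' @export
split_sentences <- function(text) {
  if (length(text) != 1L) stop_lw("text must be a single string",
                                  class = "lw_discourse_error")
  text <- trimws(gsub("[[:space:]]+", " ", text))
  if (!nzchar(text)) return(character(0))

  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  n <- length(chars)
  breaks <- integer(0)
  for (i in seq_len(n - 1L)) {
    if (!chars[i] %in% c(".", "!", "?")) next
    if (chars[i + 1L] != " ") next
    # next non-space char must start a new sentence
    j <- i + 2L
    if (j > n || !grepl("[A-Z0-9\"(]", chars[j])) next
    if (chars[i] == ".") {
      # token preceding the period
      k <- i - 1L
      while (k >= 1L && !chars[k] %in% c(" ")) k <- k - 1L
      token <- paste(chars[(k + 1L):(i - 1L)], collapse = "")
      if (token %in% ABBREVIATIONS) next
      if (grepl("^[A-Z]$", token)) next  # initials like "J."
    }
    breaks <- c(breaks, i)
  }
  starts <- c(1L, breaks + 1L)
  ends <- c(breaks, n)
  out <- vapply(seq_along(starts), function(s)
    trimws(paste(chars[starts[s]:ends[s]], collapse = "")), character(1))
  out[nzchar(out)]
}

# A structured-abstract heading at the start of a sentence, e.g.
# "CONCLUSIONS:" or "PATIENTS AND METHODS:".
heading_of <- function(sentence) {
  m <- regmatches(sentence, regexpr("^[A-Z][A-Z ]{2,}:", sentence))
  if (length(m) == 0L) NA_character_ else sub(":$", "", m)
}

#' Rule-based conclusion-sentence classifier
#'
#' Baseline standing in for a trained discourse classifier: every sentence
#' from a heading containing `CONCLUSION` up to (but excluding) the next
#' heading is tagged `Conclusion`; all other sentences are tagged
#' `Background`. This mirrors the section-based convention used to build
#' reference standards (consecutive sentences of a conclusions section),
#' so it is exact on heading-structured abstracts and finds nothing on
#' heading-free ones.
#'
#' @return A classifier function: `character vector of sentences ->
#'   character vector of tags` (same length).
#' @export
baseline_conclusion_classifier <- function() {
  function(sentences) {
    in_conclusions <- FALSE
    tags <- character(length(sentences))
    for (i in seq_along(sentences)) {
      h <- heading_of(sentences[i])
      if (!is.na(h)) {
        in_conclusions <- grepl("CONCLUSION", h)
      }
      tags[i] <- if (in_conclusions) "Conclusion" else "Background"
    }
    tags
  }
}

#' Tag an abstract's sentences with discourse labels
#'
#' @param sentences Character vector of sentences (from
#'   [split_sentences()]).
#' @param classifier A function mapping a sentence vector to an
#'   equal-length vector of tags drawn from [sentence_tags()]; defaults to
#'   the rule-based baseline.
#' @param pub_id Optional publication id recorded on the result.
#' @return A tibble of class `tagged_abstract` with columns `pub_id`,
#'   `index`, `text`, `tag`, in sentence order.
#' @export
classify_conclusions <- function(sentences,
                                 classifier = baseline_conclusion_classifier(),
                                 pub_id = NA_character_) {
  tags <- classifier(sentences)
  if (length(tags) != length(sentences)) {
    stop_lw("classifier contract violation: returned ", length(tags),
            " tags for ", length(sentences), " sentences",
            class = "lw_classifier_error")
  }
  bad <- setdiff(unique(tags), sentence_tags())
  if (length(bad)) {
    stop_lw("classifier returned unknown tag(s): ",
            paste(bad, collapse = ", "), class = "lw_classifier_error")
  }
  out <- tibble::tibble(
    pub_id = rep(pub_id, length(sentences)),
    index = seq_along(sentences),
    text = sentences,
    tag = tags
  )
  class(out) <- c("tagged_abstract", class(out))
  out
}
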