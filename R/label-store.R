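#' Construct a product label object
#'
#' A `product_label` carries the identity and version metadata of one
#' structured product label (SPL-style) document plus a map from section
#' name to normalized section text. One object corresponds to one document,
#' i.e. one (set id, version) pair; multiple versions of the same lineage
#' are distinct labels.
#'
#' @param spl_id Document id (unique in a corpus).
#' @param set_id Label-lineage id.
#' @param version Positive integer version number.
#' @param product_name Product display name.
#' @param organization Labeler organization.
#' @param effective_time Calendar date (`Date` or `"YYYY-MM-DD"` string).
#' @param homepage Optional URI string (`NA` if absent).
#' @param ingredients Character vector of active-ingredient drug ids.
#' @param sections Named character vector / list mapping section name (as
#'   produced by [section_name()]) to section text.
#' @return An object of class `product_label`.
#' @export
product_label <- function(spl_id, set_id, version, product_name = "",
                          organization = "", effective_time = NA,
                          homepage = NA_character_,
                          ingredients = character(0),
                          sections = list()) {
  version <- as.integer(version)
  if (is.na(version) || version < 1L) {
    stop_lw("version must be a positive integer", class = "lw_label_error")
  }
  for (f in c(spl_id = spl_id, set_id = set_id)) {
    if (!is.character(f) || length(f) != 1L || is.na(f) || !nzchar(f)) {
      stop_lw("spl_id and set_id must be nonempty strings",
              class = "lw_label_error")
    }
  }
  sections <- as.list(sections)
  if (length(sections) && is.null(names(sections))) {
    stop_lw("sections must be named by section name", class = "lw_label_error")
  }
  structure(
    list(
      spl_id = spl_id, set_id = set_id, version = version,
      product_name = as.character(product_name),
      organization = as.character(organization),
      effective_time = if (is.na(effective_time)) NA_character_ else
        as.character(as.Date(effective_time)),
      homepage = homepage,
      ingredients = sort(unique(as.character(ingredients))),
      sections = sections
    ),
    class = "product_label"
  )
}

#' @export
print.product_label <- function(x, ...) {
  cat(sprintf("<product_label> %s (set %s v%d) '%s'\n  ingredients: %s\n  sections: %s\n",
              x$spl_id, x$set_id, x$version, x$product_name,
              paste(x$ingredients, collapse = ", "),
              if (length(x$sections)) paste(names(x$sections), collapse = ", ")
              else "(none)"))
  invisible(x)
}

#' Parse an SPL-dialect XML document into a product label
#'
#' The supported dialect mirrors the shape of HL7 SPL documents: a
#' `<document>` root carrying `<id>`, `<setId>`, `<versionNumber>`,
#' `<title>`, `<author>/<representedOrganization>`, `<effectiveTime>`,
#' optional `<homepage>`, one `<ingredient>` per active ingredient, and one
#' `<component>/<section>` per label section whose `<code>` identifies the
#' section type via the registry. Section content has markup stripped and
#' whitespace collapsed; the same normalization used for claim matching.
#'
#' @param x XML text, or a path to an XML file.
#' @param registry A [section_registry()]; codes not in the registry are
#'   kept under `Other:<code>` names.
#' @return A [product_label()].
#' @export
parse_spl <- function(x, registry = section_registry()) {
  doc <- tryCatch(
    xml2::read_xml(x),
    error = function(e) {
      stop_lw("malformed SPL XML: ", conditionMessage(e),
              class = "lw_parse_error")
    }
  )
  root <- xml2::xml_root(doc)

  attr1 <- function(xpath, attribute = "root") {
    node <- xml2::xml_find_first(root, xpath)
    if (inherits(node, "xml_missing")) NA_character_
    else xml2::xml_attr(node, attribute)
  }
  text1 <- function(xpath) {
    node <- xml2::xml_find_first(root, xpath)
    if (inherits(node, "xml_missing")) NA_character_ else xml2::xml_text(node)
  }

  spl_id <- attr1("./id")
  set_id <- attr1("./setId")
  version <- attr1("./versionNumber", "value")

  missing <- c("splId", "setId", "version")[c(
    is.na(spl_id) || !nzchar(spl_id),
    is.na(set_id) || !nzchar(set_id),
    is.na(version) || !nzchar(version)
  )]
  if (length(missing)) {
    stop_lw("SPL document missing mandatory metadata: ",
            paste(missing, collapse = ", "), class = "lw_validation_error")
  }

  eff <- attr1("./effectiveTime", "value")
  if (!is.na(eff) && grepl("^[0-9]{8}$", eff)) {
    eff <- paste(substr(eff, 1, 4), substr(eff, 5, 6), substr(eff, 7, 8),
                 sep = "-")
  }

  ingredients <- xml2::xml_attr(
    xml2::xml_find_all(root, "./ingredient"), "code")

  sec_nodes <- xml2::xml_find_all(root, "./component/section")
  sections <- list()
  for (node in sec_nodes) {
    code <- xml2::xml_attr(xml2::xml_find_first(node, "./code"), "code")
    if (is.na(code) || !nzchar(code)) next
    txt_node <- xml2::xml_find_first(node, "./text")
    txt <- if (inherits(txt_node, "xml_missing")) "" else
      xml2::xml_text(txt_node)
    txt <- trimws(gsub("[[:space:]]+", " ", txt))
    sections[[section_name(registry, code)]] <- txt
  }

  na_to <- function(x, d) if (is.na(x)) d else x
  product_label(
    spl_id = spl_id, set_id = set_id, version = as.integer(version),
    product_name = na_to(text1("./title"), ""),
    organization = na_to(text1("./author/representedOrganization"), ""),
    effective_time = if (is.na(eff)) NA else eff,
    homepage = attr1("./homepage", "value"),
    ingredients = ingredients,
    sections = sections
  )
}

#' Serialize a product label to SPL-dialect XML text
#'
#' Inverse of [parse_spl()] on the supported dialect: writing a label and
#' reparsing it yields an equal object (section text must already be
#' whitespace-normalized, as [parse_spl()] and the fixture generator
#' guarantee).
#'
#' @param label A [product_label()].
#' @param registry A [section_registry()] used to emit section codes.
#' @return A single string of XML.
#' @export
write_spl <- function(label, registry = section_registry()) {
  doc <- xml2::xml_new_root("document")
  xml2::xml_add_child(doc, "id", root = label$spl_id)
  xml2::xml_add_child(doc, "setId", root = label$set_id)
  xml2::xml_add_child(doc, "versionNumber", value = as.character(label$version))
  xml2::xml_add_child(doc, "title", label$product_name)
  author <- xml2::xml_add_child(doc, "author")
  xml2::xml_add_child(author, "representedOrganization", label$organization)
  if (!is.na(label$effective_time)) {
    xml2::xml_add_child(doc, "effectiveTime",
                        value = gsub("-", "", label$effective_time))
  }
  if (!is.na(label$homepage)) {
    xml2::xml_add_child(doc, "homepage", value = label$homepage)
  }
  for (ing in label$ingredients) {
    xml2::xml_add_child(doc, "ingredient", code = ing)
  }
  for (nm in names(label$sections)) {
    code <- if (nm %in% TARGET_SECTIONS) section_code(registry, nm)
            else sub("^Other:", "", nm)
    comp <- xml2::xml_add_child(doc, "component")
    sec <- xml2::xml_add_child(comp, "section")
    xml2::xml_add_child(sec, "code", code = code)
    xml2::xml_add_child(sec, "text", label$sections[[nm]])
  }
  as.character(doc)
}

#' Retrieve the text of a named section, if present
#'
#' Absence is an ordinary value, not an error: querying a section the label
#' does not carry returns `NA_character_` (mirroring OPTIONAL-clause
#' semantics in graph query languages).
#'
#' @param label A [product_label()].
#' @param which Section name (one of the three targets, or an
#'   `Other:<code>` name).
#' @return The section text, or `NA_character_`.
#' @export
section_text <- function(label, which) {
  stopifnot(inherits(label, "product_label"))
  if (which %in% names(label$sections)) label$sections[[which]]
  else NA_character_
}

#' Build a label corpus with an ingredient index
#'
#' @param labels List of [product_label()] objects. `spl_id` and
#'   (`set_id`, `version`) must each be unique across the corpus.
#' @return An object of class `label_corpus` with elements `labels` (named
#'   by `spl_id`) and `ingredient_index` (drug id -> character vector of
#'   `spl_id`s), the exact inverse of the labels' ingredient sets.
#' @export
label_corpus <- function(labels = list()) {
  ids <- vapply(labels, function(l) l$spl_id, character(1))
  if (anyDuplicated(ids)) {
    stop_lw("duplicate spl_id in corpus: ",
            paste(unique(ids[duplicated(ids)]), collapse = ", "),
            class = "lw_corpus_error")
  }
  sv <- vapply(labels, function(l) paste(l$set_id, l$version, sep = "#"),
               character(1))
  if (anyDuplicated(sv)) {
    stop_lw("duplicate (set_id, version) in corpus: ",
            paste(unique(sv[duplicated(sv)]), collapse = ", "),
            class = "lw_corpus_error")
  }
  names(labels) <- ids
  index <- list()
  for (l in labels) {
    for (ing in l$ingredients) index[[ing]] <- c(index[[ing]], l$spl_id)
  }
  structure(list(labels = labels, ingredient_index = index),
            class = "label_corpus")
}

#' @export
print.label_corpus <- function(x, ...) {
  cat(sprintf("<label_corpus> %d labels, %d indexed ingredients\n",
              length(x$labels), length(x$ingredient_index)))
  invisible(x)
}

#' All labels for products containing a drug
#'
#' @param corpus A [label_corpus()].
#' @param drug Drug id.
#' @return List of [product_label()]s sorted by (`set_id`, `version`). An
#'   unknown drug id yields an empty list with a warning, not an error.
#' @export
labels_for_ingredient <- function(corpus, drug) {
  stopifnot(inherits(corpus, "label_corpus"))
  ids <- corpus$ingredient_index[[drug]]
  if (is.null(ids)) {
    if (length(corpus$labels)) {
      warning(sprintf("drug id '%s' not in ingredient index", drug),
              call. = FALSE)
    }
    return(list())
  }
  labs <- corpus$labels[ids]
  ord <- order(vapply(labs, function(l) l$set_id, character(1)),
               vapply(labs, function(l) l$version, integer(1)))
  unname(labs[ord])
}

#' Read a directory of SPL XML files into a corpus
#'
#' @param dir Directory containing one `.xml` file per label.
#' @param registry A [section_registry()].
#' @return A [label_corpus()].
#' @export
read_spl_dir <- function(dir, registry = section_registry()) {
  files <- sort(list.files(dir, pattern = "\\.xml$", full.names = TRUE))
  label_corpus(lapply(files, parse_spl, registry = registry))
}

#' Write/read a corpus as JSON
#'
#' @param corpus A [label_corpus()].
#' @param path File path.
#' @return `write_corpus_json` returns `path` invisibly; `read_corpus_json`
#'   returns a [label_corpus()].
#' @export
write_corpus_json <- function(corpus, path) {
  payload <- lapply(unname(corpus$labels), function(l) {
    l <- unclass(l)
    l$sections <- as.list(l$sections)
    l
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, null = "null",
                       na = "null", pretty = FALSE)
  invisible(path)
}

#' @rdname write_corpus_json
#' @export
read_corpus_json <- function(path) {
  payload <- jsonlite::read_json(path)
  label_corpus(lapply(payload, function(l) {
    product_label(
      spl_id = l$spl_id, set_id = l$set_id, version = l$version,
      product_name = l$product_name %||% "",
      organization = l$organization %||% "",
      effective_time = l$effective_time %||% NA,
      homepage = l$homepage %||% NA_character_,
      ingredients = unlist(l$ingredients) %||% character(0),
      sections = lapply(l$sections, as.character)
    )
  }))
}
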