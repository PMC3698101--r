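# Static enhanced-label pages: section text plus the claims linked to each
# section, with a "New to Section?" cue on potentially novel claims.
# Plain self-contained HTML with inline CSS (no scripts), so pages are
# portable and machine-checkable by reparsing.

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub("\"", "&quot;", x, fixed = TRUE)
}

PAGE_CSS <- paste(
  "body{font-family:sans-serif;margin:2em;max-width:60em}",
  "h2{border-bottom:1px solid #999}",
  ".section-text{background:#f7f7f7;padding:0.6em}",
  ".claim{border:1px solid #ccc;margin:0.3em 0;padding:0.4em}",
  ".novel{color:#a00;font-weight:bold}",
  ".severity{font-style:italic}", sep = "\n")

claim_display <- function(row) {
  if (row$claim_kind == "ddi") {
    summary <- sprintf("Interaction: %s", row$pair_label)
    detail <- sprintf("<span class=\"severity\">%s</span>",
                      html_escape(row$severity))
  } else if (row$claim_kind == "pkClaim") {
    verb <- if (row$slot == "substrate_of") "is a substrate of" else "inhibits"
    summary <- sprintf("%s %s %s", row$drug_name, verb, row$value)
    detail <- sprintf("evidence: %d supporting, %d refuting",
                      row$n_support, row$n_refute)
  } else {
    summary <- sprintf("Published result %s (trial %s)", row$claim_ref,
                       row$trial_ids)
    detail <- ""
  }
  novel <- !is.na(row$potentially_novel) && row$potentially_novel
  sprintf(
    "<details class=\"claim\"><summary>%s%s</summary><p>%s</p></details>",
    html_escape(summary),
    if (novel) " <span class=\"novel\">*New to Section?*</span>" else "",
    detail)
}

#' Render an enhanced-label page for one product label
#'
#' The three target sections are rendered in fixed order (Clinical
#' Studies, Drug Interactions, Clinical Pharmacology); each shows the
#' label's own section text followed by the claims the graph maps to that
#' section. DDI claims are grouped by severity (Critical first);
#' potentially novel claims carry a "New to Section?" marker. Output is
#' deterministic for a given input.
#'
#' @param label A [product_label()].
#' @param graph A `mapping_graph`.
#' @return A single string of self-contained HTML.
#' @export
render_label_page <- function(label, graph) {
  m <- graph$mappings
  m <- m[m$spl_id == label$spl_id, , drop = FALSE]
  parts <- c(
    "<!DOCTYPE html>", "<html><head><meta charset=\"utf-8\"/>",
    sprintf("<title>%s</title>", html_escape(label$product_name)),
    sprintf("<style>%s</style>", PAGE_CSS), "</head><body>",
    sprintf("<h1>%s</h1>", html_escape(label$product_name)),
    sprintf("<p>Label %s (set %s, version %d)%s</p>",
            html_escape(label$spl_id), html_escape(label$set_id),
            label$version,
            if (is.na(label$effective_time)) "" else
              sprintf(", effective %s", label$effective_time))
  )
  if (nrow(m) == 0L) {
    parts <- c(parts, "<p class=\"no-claims\">No linked claims.</p>")
  }
  for (section in TARGET_SECTIONS) {
    parts <- c(parts, sprintf("<h2>%s</h2>", section))
    txt <- section_text(label, section)
    parts <- c(parts, if (is.na(txt)) {
      "<p class=\"section-text\"><em>Section not present in this label.</em></p>"
    } else {
      sprintf("<p class=\"section-text\">%s</p>", html_escape(txt))
    })
    ms <- m[m$section == section, , drop = FALSE]
    if (nrow(ms) == 0L) next
    if (section == "DrugInteractions") {
      ms <- ms[order(match(ms$severity, c("Critical", "Significant")),
                     ms$claim_ref), , drop = FALSE]
    }
    parts <- c(parts, sprintf("<h3>%d linked claim(s)</h3>", nrow(ms)))
    for (j in seq_len(nrow(ms))) {
      parts <- c(parts, claim_display(ms[j, , drop = FALSE]))
    }
  }
  paste(c(parts, "</body></html>"), collapse = "\n")
}

#' Render an index page linking all label pages
#'
#' @param corpus A [label_corpus()].
#' @param graph A `mapping_graph` (used to show mapping counts).
#' @return A single string of HTML with one link per label, sorted by
#'   product name then spl id (duplicated product names stay
#'   distinguishable through the spl id in the link).
#' @export
render_index <- function(corpus, graph) {
  labels <- unname(corpus$labels)
  counts <- mappings_per_label(graph)
  parts <- c("<!DOCTYPE html>",
             "<html><head><meta charset=\"utf-8\"/>",
             "<title>Enhanced product labels</title></head><body>",
             "<h1>Enhanced product labels</h1>", "<ul>")
  if (length(labels)) {
    ord <- order(vapply(labels, function(l) l$product_name, character(1)),
                 vapply(labels, function(l) l$spl_id, character(1)))
    for (l in labels[ord]) {
      n <- counts$n[match(l$spl_id, counts$spl_id)]
      parts <- c(parts, sprintf(
        "<li><a href=\"%s.html\">%s [%s]</a> (%d linked claims)</li>",
        html_escape(l$spl_id), html_escape(l$product_name),
        html_escape(l$spl_id), if (is.na(n)) 0L else n))
    }
  }
  paste(c(parts, "</ul>", "</body></html>"), collapse = "\n")
}

#' Write one HTML page per label plus an index
#'
#' @param corpus A [label_corpus()].
#' @param graph A `mapping_graph`.
#' @param out_dir Output directory (created if needed).
#' @return Character vector of files written, invisibly.
#' @export
write_report_pages <- function(corpus, graph, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (l in corpus$labels) {
    f <- file.path(out_dir, paste0(l$spl_id, ".html"))
    writeLines(render_label_page(l, graph), f, useBytes = TRUE)
    files <- c(files, f)
  }
  idx <- file.path(out_dir, "index.html")
  writeLines(render_index(corpus, graph), idx, useBytes = TRUE)
  invisible(c(files, idx))
}
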