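#' Normalize free text for string matching
#'
#' Lower-cases, strips any XML/HTML-style markup, collapses runs of
#' whitespace (including newlines) to single spaces, and trims. All
#' claim-to-section string matching in the package goes through this
#' normalization, so matches are deterministic and case-insensitive.
#'
#' @param s Character vector.
#' @return Character vector of the same length; `NA` elements stay `NA`.
#' @examples
#' normalize_text("DigOxin  ")
#' normalize_text("two\n  lines")
#' @export
normalize_text <- function(s) {
  if (length(s) == 0L) return(character(0))
  out <- gsub("<[^>]*>", " ", as.character(s))
  out <- tolower(out)
  out <- gsub("[[:space:]]+", " ", out)
  trimws(out)
}

#' Round half away from zero
#'
#' Commercial rounding used for all printed-style figures (base R's
#' `round()` rounds half to even). Raw values are always kept alongside
#' rounded ones in the package's outputs.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal digits (default 0).
#' @return Numeric vector.
#' @examples
#' round_half_up(18.5)   # 19
#' round_half_up(12.96)  # 13
#' round_half_up(0.2304, 2)
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# Median as mean of the two middle order statistics for even n.
middle_median <- function(x) {
  x <- sort(x)
  n <- length(x)
  if (n == 0L) return(NA_real_)
  if (n %% 2L == 1L) x[(n + 1L) / 2L] else (x[n / 2L] + x[n / 2L + 1L]) / 2
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_lw <- function(..., class) {
  stop(structure(
    class = c(class, "labelweaver_error", "error", "condition"),
    list(message = paste0(...), call = NULL)
  ))
}
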