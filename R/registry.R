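#' Section-code registry
#'
#' Product-label sections are identified by opaque codes (in real SPL
#' documents these come from the LOINC vocabulary). The registry maps codes
#' to the three section names this package routes claims to --
#' `ClinicalStudies`, `DrugInteractions`, `ClinicalPharmacology` -- plus any
#' number of `Other` sections. Codes are configurable because deployments
#' differ; the defaults are synthetic placeholder codes.
#'
#' @param clinical_studies,drug_interactions,clinical_pharmacology Codes for
#'   the three target sections.
#' @return An object of class `section_registry`: a named character vector
#'   mapping code to section name.
#' @examples
#' reg <- section_registry()
#' section_code(reg, "DrugInteractions")
#' @export
section_registry <- function(clinical_studies = "SEC-CS",
                             drug_interactions = "SEC-DI",
                             clinical_pharmacology = "SEC-CP") {
  codes <- c(clinical_studies, drug_interactions, clinical_pharmacology)
  if (any(!nzchar(codes)) || anyNA(codes)) {
    stop_lw("section codes must be nonempty strings", class = "lw_registry_error")
  }
  if (anyDuplicated(codes)) {
    stop_lw("the three target sections must have distinct codes",
            class = "lw_registry_error")
  }
  structure(
    stats::setNames(TARGET_SECTIONS, codes),
    class = "section_registry"
  )
}

# Fixed presentation order of the three routed sections.
TARGET_SECTIONS <- c("ClinicalStudies", "DrugInteractions", "ClinicalPharmacology")

# Section a claim kind routes to; kind determines section, always.
SECTION_FOR_KIND <- c(
  trialResult = "ClinicalStudies",
  ddi         = "DrugInteractions",
  pkClaim     = "ClinicalPharmacology"
)

#' Read a section registry from a YAML config file
#'
#' The file holds a mapping with keys `clinical_studies`,
#' `drug_interactions`, `clinical_pharmacology`, each giving a code string.
#'
#' @param path Path to a YAML file.
#' @return A `section_registry`.
#' @export
read_section_registry <- function(path) {
  cfg <- yaml::read_yaml(path)
  needed <- c("clinical_studies", "drug_interactions", "clinical_pharmacology")
  missing <- setdiff(needed, names(cfg))
  if (length(missing)) {
    stop_lw("registry config missing keys: ", paste(missing, collapse = ", "),
            class = "lw_registry_error")
  }
  section_registry(cfg$clinical_studies, cfg$drug_interactions,
                   cfg$clinical_pharmacology)
}

#' Look up the code for a named section
#'
#' @param registry A `section_registry`.
#' @param name One of `"ClinicalStudies"`, `"DrugInteractions"`,
#'   `"ClinicalPharmacology"`.
#' @return The code string.
#' @export
section_code <- function(registry, name) {
  name <- match.arg(name, TARGET_SECTIONS)
  names(registry)[match(name, registry)]
}

#' Look up the section name for a code
#'
#' Codes absent from the registry are reported as `Other:<code>`, so
#' unrecognized sections are retained without being routed to.
#'
#' @param registry A `section_registry`.
#' @param code Code string.
#' @return Section name, or `"Other:<code>"`.
#' @export
section_name <- function(registry, code) {
  hit <- match(code, names(registry))
  ifelse(is.na(hit), paste0("Other:", code), unname(registry[hit]))
}

#' @export
print.section_registry <- function(x, ...) {
  cat("<section_registry>\n")
  for (i in seq_along(x)) cat(sprintf("  %s -> %s\n", names(x)[i], x[i]))
  invisible(x)
}
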