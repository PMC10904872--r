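#' Registered metals
#'
#' The default registry of element symbols handled by the package: the five
#' toxic metals commonly screened in drinking-water surveys. All functions
#' that take a `registry` argument accept an arbitrary character vector of
#' element symbols, so additional analytes can be added without touching the
#' package internals.
#'
#' @return Character vector of element symbols.
#' @export
#' @examples
#' metals()
metals <- function() {
  c("Pb", "Cr", "Cd", "Ni", "As")
}

#' Normalize element symbols against a registry
#'
#' Case-insensitive matching of element symbols (e.g. `"pb"`, `"PB"`) to the
#' canonical capitalization in the registry. Symbols not in the registry are
#' returned as `NA` so callers can collect and report them.
#'
#' @param x Character vector of element symbols.
#' @param registry Character vector of known symbols; defaults to [metals()].
#' @return Character vector of canonical symbols, `NA` where unmatched.
#' @export
normalize_metal <- function(x, registry = metals()) {
  if (anyDuplicated(toupper(registry))) {
    abort("metal registry contains duplicate symbols")
  }
  registry[match(toupper(trimws(x)), toupper(registry))]
}

#' Drinking-water guideline limits
#'
#' EPA and WHO drinking-water limits for the registered metals, in ug/L.
#' The EPA publishes no limit for Ni, stored as `NA`; comparisons against an
#' absent limit are skipped and flagged `NA` by [compare_to_guidelines()].
#'
#' @return A tibble with columns `metal`, `epa_limit`, `who_limit` (ug/L).
#' @export
default_guidelines <- function() {
  tribble(
    ~metal, ~epa_limit, ~who_limit,
    "Pb",   15,         10,
    "Cr",   100,        50,
    "Cd",   5,          3,
    "Ni",   NA_real_,   70,
    "As",   10,         10
  )
}

#' Reference doses and cancer slope factors
#'
#' Per-metal toxicity values used by the risk stage: oral and dermal
#' reference doses (RfD, mg/kg-day) and the cancer slope factor
#' (CSF, (mg/kg-day)^-1). Only As carries a CSF here; the table is an
#' ordinary tibble, so rows for further carcinogens can be added or values
#' replaced by the caller.
#'
#' @return A tibble with columns `metal`, `rfd_oral`, `rfd_dermal`, `csf`.
#' @export
default_toxicity <- function() {
  tribble(
    ~metal, ~rfd_dermal, ~rfd_oral, ~csf,
    "Pb",   0.42,        1.4,       NA_real_,
    "Cr",   0.015,       3,         NA_real_,
    "Cd",   0.005,       0.5,       NA_real_,
    "Ni",   5.4,         20,        NA_real_,
    "As",   0.000285,    0.0003,    1.5
  )
}

#' Dermal permeability coefficients
#'
#' Kp values (cm/h) governing dermal uptake from water. The survey source
#' tabulates Kp for Pb, Cr and Ni only; Cd and As fall back to the generic
#' inorganic default of 0.001 cm/h. The symbols filled by the default are
#' recorded in the `"defaulted"` attribute so reports can flag them.
#'
#' @param default Fallback Kp for metals without a tabulated value.
#' @return Named numeric vector of Kp values with attribute `"defaulted"`.
#' @export
default_kp <- function(default = 0.001) {
  kp <- c(Pb = 0.001, Cr = 0.002, Ni = 0.0002, Cd = default, As = default)
  attr(kp, "defaulted") <- c("Cd", "As")
  kp[metals()]
}

#' Isfahan survey concentration summaries
#'
#' Published per-metal summary statistics (mean, SD, min, max, all ug/L) for
#' the Isfahan drinking-water distribution-network survey (80 samples,
#' ICP-OES), together with instrument LODs and guideline limits. These are
#' the calibration targets for [generate_survey()] and the concentration
#' inputs of the reproduction pipeline.
#'
#' The source reports two Cd LODs (0.05 in the summary table, 0.22 in the
#' analytical-methods text); the analytical-methods value is stored here.
#' Note the Cd and As SDs exceed what any distribution bounded on the
#' printed min/max range can attain; see the methods vignette.
#'
#' @return A tibble with columns `metal`, `lod`, `mean`, `sd`, `min`, `max`,
#'   `epa_limit`, `who_limit` (ug/L throughout).
#' @export
isfahan_concentrations <- function() {
  conc <- tribble(
    ~metal, ~lod, ~mean,  ~sd,   ~min,   ~max,
    "Pb",   0.8,  10.04,  4.60,  2.61,   18.98,
    "Cr",   0.15, 37.91,  7.69,  18.11,  52.26,
    "Cd",   0.22, 2.96,   3.02,  2.44,   3.91,
    "Ni",   0.3,  70.03,  8.77,  52.54,  87.42,
    "As",   2,    6.36,   4.27,  2.33,   14.36
  )
  dplyr::left_join(conc, default_guidelines(), by = "metal")
}
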