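#' Hazard quotient
#'
#' HQ = CDI / RfD (dimensionless). In `"strict"` mode the reference dose
#' divides the intake, the textbook definition. In `"as_published"` mode the
#' divisor is 1, so HQ equals CDI numerically; this mode exists solely to
#' reproduce the source assessment's printed hazard tables, whose HQ entries
#' are identical to the CDI entries (the RfD division is not reflected in
#' them). Every report produced by the pipeline records which mode was
#' active.
#'
#' @param cdi Chronic daily intake, mg/kg-day; vectorized.
#' @param rfd Reference dose, mg/kg-day (ignored in `as_published` mode).
#' @param mode `"strict"` or `"as_published"`.
#' @return Dimensionless hazard quotient(s).
#' @export
hazard_quotient <- function(cdi, rfd, mode = c("strict", "as_published")) {
  mode <- match.arg(mode)
  if (mode == "as_published") {
    return(cdi)
  }
  if (any(!is.finite(rfd)) || any(rfd <= 0)) {
    abort("reference dose must be > 0 in strict mode",
      class = "metalrisk_domain_error"
    )
  }
  cdi / rfd
}

#' Hazard index
#'
#' Sum of hazard quotients over metals (and/or routes). An empty input gives
#' 0.
#'
#' @param hqs Numeric vector (possibly named by metal) of hazard quotients.
#' @return Dimensionless hazard index.
#' @export
hazard_index <- function(hqs) {
  if (length(hqs) == 0) {
    return(0)
  }
  sum(hqs)
}

#' Incremental lifetime cancer risk
#'
#' ILCR = CDI * CSF for a registered carcinogen. The CDI should be computed
#' with the carcinogenic (70-year) averaging time.
#'
#' @param cdi Chronic daily intake, mg/kg-day; vectorized.
#' @param csf Cancer slope factor, (mg/kg-day)^-1.
#' @return Dimensionless excess lifetime risk(s).
#' @export
ilcr <- function(cdi, csf) {
  if (any(!is.finite(csf)) || any(csf <= 0)) {
    abort("cancer slope factor must be > 0", class = "metalrisk_domain_error")
  }
  cdi * csf
}

#' Risk classification labels
#'
#' Categorical labels for the computed indices, using the conventional
#' screening thresholds: a hazard index above 1 signals possible
#' non-carcinogenic effects; a single-substance ILCR below 1e-6 is
#' negligible and above 1e-4 harmful; the multi-substance ILCR sum is
#' screened against 1e-5. All comparisons are strict, so a value exactly at
#' a threshold falls in the non-exceeding class.
#'
#' @param hi Hazard index value(s).
#' @param x ILCR value(s).
#' @param thresholds Named list overriding `hi`, `ilcr_low`, `ilcr_high`,
#'   `ilcr_multi`.
#' @return Character label(s).
#' @name classify
NULL

default_thresholds <- function() {
  list(hi = 1, ilcr_low = 1e-6, ilcr_high = 1e-4, ilcr_multi = 1e-5)
}

#' @rdname classify
#' @export
classify_hi <- function(hi, thresholds = default_thresholds()) {
  ifelse(hi > thresholds$hi, "potential concern", "acceptable")
}

#' @rdname classify
#' @export
classify_ilcr <- function(x, thresholds = default_thresholds()) {
  ifelse(x > thresholds$ilcr_high, "harmful",
    ifelse(x < thresholds$ilcr_low, "negligible", "intermediate")
  )
}

#' @rdname classify
#' @export
classify_ilcr_sum <- function(x, thresholds = default_thresholds()) {
  ifelse(x > thresholds$ilcr_multi, "exceeds multi-substance limit",
    "acceptable"
  )
}

#' Deterministic risk assessment for one cohort
#'
#' Computes per-metal, per-route hazard quotients, route-wise and total
#' hazard indices, and incremental lifetime cancer risks from a table of
#' concentrations, with classification labels. Ingestion CDI is divided by
#' the oral RfD and dermal CDI by the dermal RfD (strict mode). ILCR uses
#' CDI recomputed with the carcinogenic averaging time and is reported only
#' for metals carrying a CSF; other metals are listed in
#' `skipped_carcinogens`.
#'
#' @param cw Named numeric vector of concentrations (ug/L), one per metal.
#' @param params An [exposure_parameters()] set.
#' @param toxicity Toxicity table, see [default_toxicity()].
#' @param hq_mode Passed to [hazard_quotient()].
#' @param include_et Passed to [cdi_dermal()].
#' @param thresholds Classification thresholds, see [classify_hi()].
#' @return A list of class `risk_result` with elements `cohort`, `hq_mode`,
#'   `cdi` (nc-averaged CDI table), `hq` (per metal/route), `hi` (tibble of
#'   route HI + label), `ilcr` (per carcinogen + label), `ilcr_sum`,
#'   `ilcr_sum_label`, `skipped_carcinogens`.
#' @export
assess_risk <- function(cw, params, toxicity = default_toxicity(),
                        hq_mode = c("strict", "as_published"),
                        include_et = FALSE,
                        thresholds = default_thresholds()) {
  hq_mode <- match.arg(hq_mode)
  cdi_nc <- cdi_table(cw, params, at_mode = "nc", include_et = include_et)
  cdi_car <- cdi_table(cw, params, at_mode = "car", include_et = include_et)

  tox <- toxicity[match(cdi_nc$metal, toxicity$metal), , drop = FALSE]
  if (hq_mode == "strict" && anyNA(tox$rfd_oral)) {
    abort(
      paste0(
        "no reference dose for metal(s): ",
        paste(cdi_nc$metal[is.na(tox$rfd_oral)], collapse = ", ")
      ),
      class = "metalrisk_config_error"
    )
  }

  hq <- tibble(
    metal = cdi_nc$metal,
    ingestion = hazard_quotient(cdi_nc$ingestion, tox$rfd_oral, hq_mode),
    dermal = hazard_quotient(cdi_nc$dermal, tox$rfd_dermal, hq_mode)
  )
  hq$total <- hq$ingestion + hq$dermal

  hi <- tibble(
    route = c("ingestion", "dermal", "total"),
    hi = c(
      hazard_index(hq$ingestion),
      hazard_index(hq$dermal),
      hazard_index(hq$ingestion) + hazard_index(hq$dermal)
    )
  )
  hi$label <- classify_hi(hi$hi, thresholds)

  carcinogen <- !is.na(tox$csf)
  ilcr_tbl <- tibble(
    metal = cdi_car$metal[carcinogen],
    ilcr = ilcr(cdi_car$total[carcinogen], tox$csf[carcinogen])
  )
  ilcr_tbl$label <- if (nrow(ilcr_tbl)) classify_ilcr(ilcr_tbl$ilcr, thresholds) else character(0)
  ilcr_sum <- sum(ilcr_tbl$ilcr)

  structure(
    list(
      cohort = params$cohort,
      hq_mode = hq_mode,
      cdi = cdi_nc,
      cdi_car = cdi_car,
      hq = hq,
      hi = hi,
      ilcr = ilcr_tbl,
      ilcr_sum = ilcr_sum,
      ilcr_sum_label = classify_ilcr_sum(ilcr_sum, thresholds),
      skipped_carcinogens = cdi_nc$metal[!carcinogen]
    ),
    class = "risk_result"
  )
}

#' @export
print.risk_result <- function(x, ...) {
  cat(
    "<risk_result> cohort:", x$cohort, " HQ mode:", x$hq_mode, "\n",
    sep = " "
  )
  cat("Hazard index by route:\n")
  for (i in seq_len(nrow(x$hi))) {
    cat(sprintf(
      "  %-9s %s  [%s]\n", x$hi$route[i],
      formatC(x$hi$hi[i], format = "e", digits = 2), x$hi$label[i]
    ))
  }
  if (nrow(x$ilcr) > 0) {
    cat("ILCR (carcinogenic averaging time):\n")
    for (i in seq_len(nrow(x$ilcr))) {
      cat(sprintf(
        "  %-3s %s  [%s]\n", x$ilcr$metal[i],
        formatC(x$ilcr$ilcr[i], format = "e", digits = 2), x$ilcr$label[i]
      ))
    }
    cat(sprintf(
      "  sum %s  [%s]\n",
      formatC(x$ilcr_sum, format = "e", digits = 2), x$ilcr_sum_label
    ))
  }
  if (length(x$skipped_carcinogens) > 0) {
    cat(
      "No CSF (skipped for ILCR):",
      paste(x$skipped_carcinogens, collapse = ", "), "\n"
    )
  }
  invisible(x)
}
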