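#' Validate a table of water samples
#'
#' Checks a data frame of site-level concentration records against the
#' water-sample contract: one row per (site, metal) measurement with a
#' non-negative concentration in ug/L, an optional censoring flag for
#' below-LOD observations, and optional planar coordinates. Censored rows
#' must carry an LOD and a concentration not exceeding it.
#'
#' @param x A data frame with columns `site_id`, `metal`,
#'   `concentration_ug_L`, and optionally `x`, `y`, `censored`, `lod_ug_L`.
#' @param registry Metal registry used to normalize symbols.
#' @return A validated tibble of class `water_samples`. Rows whose metal is
#'   not in the registry are dropped with a warning; the dropped symbols are
#'   kept in the `"unknown_metals"` attribute.
#' @export
as_water_samples <- function(x, registry = metals()) {
  x <- as_tibble(x)
  required <- c("site_id", "metal", "concentration_ug_L")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    abort(
      paste0(
        "missing required column(s): ",
        paste(missing_cols, collapse = ", ")
      ),
      class = "metalrisk_schema_error"
    )
  }
  if (!"censored" %in% names(x)) x$censored <- FALSE
  if (!"lod_ug_L" %in% names(x)) x$lod_ug_L <- NA_real_
  x$censored[is.na(x$censored)] <- FALSE
  x$site_id <- as.character(x$site_id)

  bad <- which(!is.na(x$concentration_ug_L) & x$concentration_ug_L < 0)
  if (length(bad) > 0) {
    abort(
      paste0("negative concentration at row(s): ", paste(bad, collapse = ", ")),
      class = "metalrisk_validation_error"
    )
  }
  no_lod <- which(x$censored & is.na(x$lod_ug_L))
  if (length(no_lod) > 0) {
    abort(
      paste0(
        "censored row(s) without an LOD: ", paste(no_lod, collapse = ", ")
      ),
      class = "metalrisk_validation_error"
    )
  }
  over_lod <- which(x$censored & x$concentration_ug_L > x$lod_ug_L)
  if (length(over_lod) > 0) {
    abort(
      paste0(
        "censored concentration above its LOD at row(s): ",
        paste(over_lod, collapse = ", ")
      ),
      class = "metalrisk_validation_error"
    )
  }

  canon <- normalize_metal(x$metal, registry)
  unknown <- unique(x$metal[is.na(canon)])
  if (length(unknown) > 0) {
    warn(
      paste0(
        "dropping rows with unregistered metal symbol(s): ",
        paste(unknown, collapse = ", ")
      )
    )
  }
  x$metal <- canon
  x <- x[!is.na(x$metal), , drop = FALSE]
  attr(x, "unknown_metals") <- unknown
  class(x) <- c("water_samples", class(x))
  x
}

#' Read water samples from delimited text
#'
#' Reads site-level concentration records from a delimited text file with
#' header `site_id, x, y, metal, concentration_ug_L, censored, lod_ug_L`
#' (coordinates, censoring flag and LOD optional). Column names can be
#' remapped through `col_map` for files using a different dialect.
#'
#' @param path Path to the delimited file (UTF-8).
#' @param delim Field delimiter, comma by default.
#' @param col_map Optional named character vector mapping standard names to
#'   the names used in the file, e.g. `c(concentration_ug_L = "conc")`.
#' @param registry Metal registry used to normalize symbols.
#' @return A `water_samples` tibble (see [as_water_samples()]).
#' @export
read_water_samples <- function(path, delim = ",", col_map = NULL,
                               registry = metals()) {
  if (!file.exists(path)) {
    abort(paste0("no such file: ", path), class = "metalrisk_io_error")
  }
  x <- readr::read_delim(
    path,
    delim = delim, show_col_types = FALSE, progress = FALSE
  )
  if (!is.null(col_map)) {
    for (std in names(col_map)) {
      if (col_map[[std]] %in% names(x)) {
        names(x)[names(x) == col_map[[std]]] <- std
      }
    }
  }
  as_water_samples(x, registry = registry)
}

#' Substitute censored (below-LOD) concentrations
#'
#' @param samples A `water_samples` tibble.
#' @param rule Substitution rule for censored values: half the LOD
#'   (default), zero, or the full LOD.
#' @return The samples with censored concentrations replaced.
#' @export
substitute_censored <- function(samples,
                                rule = c("half_lod", "zero", "lod")) {
  rule <- match.arg(rule)
  sub <- switch(rule,
    half_lod = samples$lod_ug_L / 2,
    zero = 0,
    lod = samples$lod_ug_L
  )
  samples$concentration_ug_L[samples$censored] <- sub[samples$censored]
  samples
}

#' Per-metal concentration summaries
#'
#' Arithmetic mean, sample standard deviation (n - 1 denominator), minimum
#' and maximum concentration per metal, after substituting censored values
#' according to `censoring`. This is the survey-table stage of the pipeline.
#'
#' @param samples A `water_samples` tibble (or any data frame passing
#'   [as_water_samples()]).
#' @param censoring Censored-value substitution rule, see
#'   [substitute_censored()].
#' @return A tibble with columns `metal`, `n`, `mean`, `sd`, `min`, `max`
#'   (ug/L). Empty input yields an empty tibble. `sd` is 0 for a single
#'   observation.
#' @export
summarize_concentrations <- function(samples,
                                     censoring = c("half_lod", "zero", "lod")) {
  if (!inherits(samples, "water_samples")) {
    samples <- as_water_samples(samples)
  }
  samples <- substitute_censored(samples, match.arg(censoring))
  if (nrow(samples) == 0) {
    return(tibble(
      metal = character(0), n = integer(0), mean = numeric(0),
      sd = numeric(0), min = numeric(0), max = numeric(0)
    ))
  }
  out <- samples |>
    dplyr::group_by(.data$metal) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data$concentration_ug_L),
      sd = ifelse(dplyr::n() > 1, stats::sd(.data$concentration_ug_L), 0),
      min = min(.data$concentration_ug_L),
      max = max(.data$concentration_ug_L),
      .groups = "drop"
    )
  # stable registry order for reporting
  ord <- order(match(out$metal, metals()))
  out[ord, , drop = FALSE]
}

#' Compare concentration summaries to guideline limits
#'
#' Flags, per metal, whether the mean and the maximum concentration exceed
#' the EPA and WHO drinking-water limits. Exceedance uses a strict `>`:
#' a value exactly at the limit does not exceed it. Metals without a
#' published limit get `NA` flags.
#'
#' @param summary A summary tibble from [summarize_concentrations()] (or any
#'   tibble with `metal`, `mean`, `max`).
#' @param guidelines A guideline tibble, see [default_guidelines()].
#' @return The summary joined with the limits plus logical columns
#'   `mean_exceeds_epa`, `mean_exceeds_who`, `max_exceeds_epa`,
#'   `max_exceeds_who`.
#' @export
compare_to_guidelines <- function(summary, guidelines = default_guidelines()) {
  out <- dplyr::left_join(
    summary[setdiff(names(summary), c("epa_limit", "who_limit"))],
    guidelines,
    by = "metal"
  )
  out$mean_exceeds_epa <- out$mean > out$epa_limit
  out$mean_exceeds_who <- out$mean > out$who_limit
  out$max_exceeds_epa <- out$max > out$epa_limit
  out$max_exceeds_who <- out$max > out$who_limit
  out
}
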