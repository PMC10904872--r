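# Small in-code fixtures shared across test files.

tiny_samples <- function() {
  tibble::tibble(
    site_id = c("A", "B", "C"),
    x = c(0, 1, 2),
    y = c(0, 1, 0),
    metal = c("Pb", "Ni", "Cd"),
    concentration_ug_L = c(10.0, 70.0, 2.5),
    censored = FALSE,
    lod_ug_L = c(0.8, 0.3, 0.22)
  )
}

write_sample_csv <- function(df, path = tempfile(fileext = ".csv")) {
  readr::write_csv(df, path)
  path
}

# one metal, repeated values, for summary arithmetic checks
flat_samples <- function(values, metal = "Pb") {
  tibble::tibble(
    site_id = sprintf("S%d", seq_along(values)),
    metal = metal,
    concentration_ug_L = values
  )
}

table3_means <- function() {
  conc <- isfahan_concentrations()
  stats::setNames(conc$mean, conc$metal)
}

# all-point spec set collapsing the Monte Carlo engine to the deterministic
# pipeline
point_spec_set <- function(cw = c(Pb = 10, Ni = 70), cohort = "adult") {
  params <- exposure_parameters(cohort)
  list(
    name = "point_only",
    cohort = cohort,
    params = params,
    specs = list(
      cw = lapply(cw, function(v) dist_spec("point", value = v)),
      di = dist_spec("point", value = params$di),
      bw = dist_spec("point", value = params$bw),
      ef = dist_spec("point", value = params$ef)
    ),
    include_et = FALSE,
    calibration = NULL
  )
}
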