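#' Published assessment tables
#'
#' The printed result tables of the Isfahan drinking-water assessment, as
#' machine-readable tibbles: the adult chronic-daily-intake table
#' (`cdi_adult`), the adult and child hazard tables (`hq_adult`,
#' `hq_child`, each with per-metal rows plus `HI` rows per route), and the
#' cancer-risk table (`ilcr`). Column `p95` carries the tables' leading
#' statistic column (headed "95th value" although the adult entries
#' coincide with the intake table's mean column); `min`/`max` are kept as
#' printed even where they are internally inconsistent (several rows print
#' min > mean). These tables are inputs to the identity checks and
#' discrepancy reports, not outputs of the pipeline.
#'
#' @return A named list of tibbles.
#' @export
published_tables <- function() {
  cdi_adult <- tribble(
    ~metal, ~route,      ~mean,    ~min,     ~max,
    "Pb",   "ingestion", 3.15e-04, 8.17e-05, 5.96e-04,
    "Pb",   "dermal",    1.39e-06, 3.71e-07, 2.71e-06,
    "Pb",   "total",     3.16e-04, 8.21e-05, 5.99e-04,
    "Cr",   "ingestion", 1.19e-03, 1.64e-03, 5.65e-04,
    "Cr",   "dermal",    5.42e-06, 2.57e-06, 7.47e-06,
    "Cr",   "total",     1.20e-03, 1.64e-03, 5.72e-04,
    "Cd",   "ingestion", 9.32e-05, 7.54e-05, 1.22e-04,
    "Cd",   "dermal",    4.24e-07, 3.43e-07, 5.57e-07,
    "Cd",   "total",     9.36e-05, 7.57e-05, 1.23e-04,
    "Ni",   "ingestion", 2.20e-03, 1.65e-03, 2.74e-03,
    "Ni",   "dermal",    1.00e-05, 7.51e-06, 1.25e-05,
    "Ni",   "total",     2.21e-03, 1.66e-03, 2.75e-03,
    "As",   "ingestion", 1.99e-04, 4.51e-04, 1.02e-05,
    "As",   "dermal",    9.09e-07, 4.67e-08, 2.05e-06,
    "As",   "total",     2.00e-04, 4.51e-04, 1.23e-05
  )

  hq_adult <- tribble(
    ~metal, ~route,      ~p95,     ~min,     ~max,
    "Pb",   "ingestion", 3.15e-04, 8.17e-05, 5.96e-04,
    "Cr",   "ingestion", 1.19e-03, 1.64e-03, 5.65e-04,
    "Cd",   "ingestion", 9.32e-05, 7.54e-05, 1.22e-04,
    "Ni",   "ingestion", 2.20e-03, 1.65e-03, 2.74e-03,
    "As",   "ingestion", 1.99e-04, 4.51e-04, 1.02e-05,
    "HI",   "ingestion", 4.00e-03, 3.90e-03, 4.03e-03,
    "Pb",   "dermal",    1.39e-06, 3.71e-07, 2.71e-06,
    "Cr",   "dermal",    5.42e-06, 2.57e-06, 7.47e-06,
    "Cd",   "dermal",    4.24e-07, 3.43e-07, 5.57e-07,
    "Ni",   "dermal",    1.00e-05, 7.51e-06, 1.25e-05,
    "As",   "dermal",    9.09e-07, 4.67e-08, 2.05e-06,
    "HI",   "dermal",    1.81e-05, 1.08e-05, 2.53e-05,
    "Pb",   "total",     3.16e-04, 8.21e-05, 5.99e-04,
    "Cr",   "total",     1.20e-03, 1.64e-03, 5.72e-04,
    "Cd",   "total",     9.36e-05, 7.57e-05, 1.23e-04,
    "Ni",   "total",     2.21e-03, 1.66e-03, 2.75e-03,
    "As",   "total",     2.00e-04, 4.51e-04, 1.23e-05,
    "HI",   "total",     4.02e-03, 3.91e-03, 4.06e-03
  )

  hq_child <- tribble(
    ~metal, ~route,      ~p95,     ~min,     ~max,
    "Pb",   "ingestion", 2.14e-04, 5.16e-05, 9.60e-04,
    "Cr",   "ingestion", 2.20e-03, 8.90e-04, 5.99e-04,
    "Cd",   "ingestion", 7.30e-05, 6.47e-05, 2.35e-04,
    "Ni",   "ingestion", 1.20e-03, 1.88e-03, 3.47e-03,
    "As",   "ingestion", 1.12e-04, 5.44e-04, 2.51e-03,
    "HI",   "ingestion", 3.80e-03, 3.43e-03, 7.77e-03,
    "Pb",   "dermal",    1.28e-06, 4.71e-07, 3.51e-06,
    "Cr",   "dermal",    5.75e-06, 3.47e-06, 8.74e-06,
    "Cd",   "dermal",    5.12e-07, 1.47e-06, 9.51e-06,
    "Ni",   "dermal",    2.10e-05, 8.57e-06, 1.25e-04,
    "As",   "dermal",    8.59e-07, 5.58e-08, 4.25e-06,
    "HI",   "dermal",    2.94e-05, 1.40e-05, 1.51e-04,
    "Pb",   "total",     2.15e-04, 5.21e-05, 9.64e-04,
    "Cr",   "total",     2.21e-03, 8.93e-04, 6.08e-04,
    "Cd",   "total",     7.35e-05, 6.62e-05, 2.45e-04,
    "Ni",   "total",     1.22e-03, 1.89e-03, 3.60e-03,
    "As",   "total",     1.13e-04, 5.44e-04, 2.51e-03,
    "HI",   "total",     3.83e-03, 3.44e-03, 7.93e-03
  )

  ilcr_tbl <- tribble(
    ~row,            ~p95,     ~max,     ~min,
    "As (adults)",   1.86e-03, 1.39e-03, 2.31e-03,
    "As (children)", 3.00e-04, 6.77e-04, 1.85e-05,
    "sum",           2.16e-03, 2.07e-03, 2.33e-03
  )

  abstract <- list(
    hi_total_adult = 4.02e-03, hi_total_child = 3.83e-03,
    hi_ingestion_adult = 4.00e-03, hi_ingestion_child = 3.80e-03,
    hi_dermal_adult = 1.81e-05, hi_dermal_child = 2.94e-05,
    ilcr_as_csf = 1.5
  )

  list(
    cdi_adult = cdi_adult, hq_adult = hq_adult, hq_child = hq_child,
    ilcr = ilcr_tbl, abstract = abstract
  )
}

#' Round to 3 significant figures (the published display precision)
#'
#' @param x Numeric vector.
#' @return `signif(x, 3)`.
#' @export
signif3 <- function(x) signif(x, 3)

#' Arithmetic identity checks on the published tables
#'
#' Recomputes every hazard-index row of the published hazard tables as the
#' sum of its five per-metal entries, the route sums against the reported
#' totals, the cancer-risk table's sum row as the sum of its two cohort
#' rows (column by column), and the slope-factor product on the published
#' As mean total intake, and compares each to the printed value at 3
#' significant figures.
#'
#' @return A tibble with columns `check`, `computed`, `published`,
#'   `agrees_3sf`.
#' @export
published_identity_checks <- function() {
  pt <- published_tables()
  checks <- list()
  add <- function(check, computed, published) {
    checks[[length(checks) + 1]] <<- tibble(
      check = check, computed = computed, published = published,
      agrees_3sf = signif3(computed) == signif3(published)
    )
  }

  for (cohort in c("adult", "child")) {
    hq <- pt[[paste0("hq_", cohort)]]
    for (rt in unique(hq$route)) {
      for (col in c("p95", "min", "max")) {
        entries <- hq[[col]][hq$route == rt & hq$metal != "HI"]
        printed <- hq[[col]][hq$route == rt & hq$metal == "HI"]
        add(
          sprintf("HI[%s, %s, %s] = sum of metal HQs", cohort, rt, col),
          hazard_index(entries), printed
        )
      }
    }
    # route sums reproduce the reported totals
    hi_ing <- pt$abstract[[paste0("hi_ingestion_", cohort)]]
    hi_derm <- pt$abstract[[paste0("hi_dermal_", cohort)]]
    add(
      sprintf("HI_total[%s] = HI_ingestion + HI_dermal", cohort),
      hi_ing + hi_derm, pt$abstract[[paste0("hi_total_", cohort)]]
    )
  }

  for (col in c("p95", "max", "min")) {
    add(
      sprintf("ILCR sum row [%s] = adult + child rows", col),
      sum(pt$ilcr[[col]][pt$ilcr$row != "sum"]),
      pt$ilcr[[col]][pt$ilcr$row == "sum"]
    )
  }

  as_cdi_total <- pt$cdi_adult$mean[
    pt$cdi_adult$metal == "As" & pt$cdi_adult$route == "total"
  ]
  add(
    "ILCR = published As mean total CDI x CSF 1.5",
    ilcr(as_cdi_total, pt$abstract$ilcr_as_csf),
    pt$ilcr$p95[pt$ilcr$row == "As (children)"]
  )

  dplyr::bind_rows(checks)
}
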