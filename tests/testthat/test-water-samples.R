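test_that("delimited sample files parse into validated records", {
  path <- write_sample_csv(tiny_samples())
  s <- read_water_samples(path)
  expect_s3_class(s, "water_samples")
  expect_equal(nrow(s), 3)
  expect_setequal(s$metal, c("Pb", "Ni", "Cd"))
  expect_equal(s$concentration_ug_L, c(10.0, 70.0, 2.5))

  # metal symbols are case-normalized on read
  df <- tiny_samples()
  df$metal <- c("pb", "NI", "cd")
  s2 <- read_water_samples(write_sample_csv(df))
  expect_setequal(s2$metal, c("Pb", "Ni", "Cd"))

  # column remapping for foreign dialects
  df <- tiny_samples()
  names(df)[names(df) == "concentration_ug_L"] <- "conc"
  s3 <- read_water_samples(
    write_sample_csv(df),
    col_map = c(concentration_ug_L = "conc")
  )
  expect_equal(s3$concentration_ug_L, c(10.0, 70.0, 2.5))
})

test_that("schema and value violations are rejected with context", {
  df <- tiny_samples()
  df$concentration_ug_L[2] <- -1
  expect_error(
    as_water_samples(df),
    class = "metalrisk_validation_error"
  )
  expect_error(as_water_samples(df), "row\\(s\\): 2")

  expect_error(
    as_water_samples(tiny_samples()[, c("site_id", "metal")]),
    class = "metalrisk_schema_error"
  )
  expect_error(
    as_water_samples(tiny_samples()[, c("site_id", "metal")]),
    "concentration_ug_L"
  )

  expect_error(
    read_water_samples(tempfile()),
    class = "metalrisk_io_error"
  )
})

test_that("below-LOD records are accepted when consistent, rejected otherwise", {
  df <- tiny_samples()
  df$censored[1] <- TRUE
  df$concentration_ug_L[1] <- 0.4 # below its LOD of 0.8
  s <- as_water_samples(df)
  expect_true(s$censored[1])

  df$concentration_ug_L[1] <- 0.9 # above the LOD: contradiction
  expect_error(as_water_samples(df), class = "metalrisk_validation_error")

  df$concentration_ug_L[1] <- 0.4
  df$lod_ug_L[1] <- NA
  expect_error(as_water_samples(df), class = "metalrisk_validation_error")
})

test_that("unregistered metal symbols are collected and dropped with a warning", {
  df <- tiny_samples()
  df$metal[3] <- "Zz"
  expect_warning(s <- as_water_samples(df), "Zz")
  expect_equal(nrow(s), 2)
  expect_equal(attr(s, "unknown_metals"), "Zz")
})

test_that("summaries use the arithmetic mean and the n-1 standard deviation", {
  out <- summarize_concentrations(flat_samples(rep(5.0, 4)))
  expect_equal(out$mean, 5.0)
  expect_equal(out$sd, 0.0)
  expect_equal(out$min, 5.0)
  expect_equal(out$max, 5.0)

  # hand computation: mean 4, sample SD sqrt(((2-4)^2+(4-4)^2+(6-4)^2)/2) = 2
  out <- summarize_concentrations(flat_samples(c(2, 4, 6)))
  expect_equal(out$mean, 4.0)
  expect_equal(out$sd, 2.0)
  expect_equal(out$min, 2)
  expect_equal(out$max, 6)
  expect_equal(out$n, 3L)

  expect_equal(nrow(summarize_concentrations(flat_samples(numeric(0)))), 0)
})

test_that("censoring substitution follows the configured rule", {
  df <- tibble::tibble(
    site_id = c("A", "B"),
    metal = "Pb",
    concentration_ug_L = c(0.4, 10),
    censored = c(TRUE, FALSE),
    lod_ug_L = 0.8
  )
  expect_equal(summarize_concentrations(df, "half_lod")$mean, (0.4 + 10) / 2)
  expect_equal(summarize_concentrations(df, "zero")$mean, 5)
  expect_equal(summarize_concentrations(df, "lod")$mean, (0.8 + 10) / 2)
})

test_that("summaries are permutation-invariant and obey order statistics", {
  set.seed(11)
  for (i in 1:5) {
    vals <- round(runif(12, 0, 50), 2)
    df <- flat_samples(vals)
    base <- summarize_concentrations(df)
    perm <- summarize_concentrations(df[sample(nrow(df)), ])
    expect_equal(base, perm)
    expect_lte(base$min, base$mean)
    expect_lte(base$mean, base$max)
    expect_identical(base$sd == 0, length(unique(vals)) == 1)
  }
})

test_that("guideline exceedance is strict and respects absent limits", {
  summ <- tibble::tibble(
    metal = c("Ni", "Cd", "Pb"),
    n = 80L,
    mean = c(70.03, 2.96, 10.04),
    sd = 1,
    min = 0,
    max = c(87.42, 3.9, 18.98)
  )
  cmp <- compare_to_guidelines(summ)
  expect_true(cmp$mean_exceeds_who[cmp$metal == "Ni"]) # 70.03 > 70
  expect_true(cmp$max_exceeds_who[cmp$metal == "Cd"]) # 3.9 > 3
  expect_false(cmp$mean_exceeds_who[cmp$metal == "Cd"]) # 2.96 < 3
  expect_false(cmp$mean_exceeds_epa[cmp$metal == "Pb"]) # 10.04 < 15
  expect_true(is.na(cmp$mean_exceeds_epa[cmp$metal == "Ni"])) # no EPA limit

  # a flag flips exactly when a value crosses its limit
  at_limit <- summ
  at_limit$mean[1] <- 70
  expect_false(
    compare_to_guidelines(at_limit)$mean_exceeds_who[1]
  )
  above <- summ
  above$mean[1] <- 70 + 1e-9
  expect_true(compare_to_guidelines(above)$mean_exceeds_who[1])
})
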