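test_that("generated surveys honor the sample contract and the seed", {
  cfg <- generator_config(n_sites = 40, seed = 7)
  s <- generate_survey(cfg)
  expect_s3_class(s, "water_samples")
  expect_equal(nrow(s), 40 * length(metals()))

  conc <- isfahan_concentrations()
  for (m in metals()) {
    vals <- s$concentration_ug_L[s$metal == m]
    expect_true(all(vals >= conc$min[conc$metal == m]))
    expect_true(all(vals <= conc$max[conc$metal == m]))
  }
  expect_true(all(s$concentration_ug_L >= 0))

  # seed contract: identical configuration, identical survey
  s2 <- generate_survey(generator_config(n_sites = 40, seed = 7))
  expect_identical(as.data.frame(s), as.data.frame(s2))
  s3 <- generate_survey(generator_config(n_sites = 40, seed = 8))
  expect_false(identical(s$concentration_ug_L, s3$concentration_ug_L))
})

test_that("a vanishing target SD degenerates to the target mean", {
  targets <- tibble::tibble(
    metal = "Pb", mean = 5, sd = 1e-6, min = 0, max = 10
  )
  s <- generate_survey(generator_config(targets = targets, n_sites = 30, seed = 2))
  expect_equal(s$concentration_ug_L, rep(5, 30), tolerance = 1e-5)
})

test_that("large surveys recover the summary targets within sampling error", {
  cfg <- generator_config(n_sites = 1e4, seed = 42)
  s <- generate_survey(cfg)
  report <- attr(s, "generator_report")
  summ <- summarize_concentrations(s)
  conc <- isfahan_concentrations()
  for (m in metals()) {
    target <- conc$mean[conc$metal == m]
    got <- summ$mean[summ$metal == m]
    se <- report$mean_se[report$metal == m]
    expect_lt(abs(got - target), max(0.01 * target, 3 * se))
    # where the SD target is attainable on the bounded range, it is met
    if (report$sd_attained[report$metal == m]) {
      sd_se <- report$achieved_sd[report$metal == m] / sqrt(2 * 1e4)
      expect_lt(
        abs(summ$sd[summ$metal == m] - conc$sd[conc$metal == m]),
        max(0.01 * conc$sd[conc$metal == m], 3 * sd_se)
      )
    }
  }
  # calibration itself is exact: analytic truncated mean == target
  expect_equal(report$achieved_mean, conc$mean, tolerance = 1e-7)
  expect_equal(report$mean_bias_rel, rep(0, 5), tolerance = 1e-7)
  # the infeasible SD targets are reported, not hidden
  expect_setequal(report$metal[!report$sd_attained], c("Cd", "As"))
})

test_that("the 80-site survey recovers each mean within its tolerance", {
  cfg <- generator_config(n_sites = 80, seed = 42)
  s <- generate_survey(cfg)
  report <- attr(s, "generator_report")
  summ <- summarize_concentrations(s)
  conc <- isfahan_concentrations()
  for (m in metals()) {
    target <- conc$mean[conc$metal == m]
    se <- report$mean_se[report$metal == m]
    expect_lt(
      abs(summ$mean[summ$metal == m] - target),
      max(0.03 * target, 3 * se)
    )
  }
  # the low-variance Ni target meets the plain 3% band outright
  expect_equal(
    summ$mean[summ$metal == "Ni"],
    conc$mean[conc$metal == "Ni"],
    tolerance = 0.03
  )
})

test_that("hotspot enrichment raises in-cluster concentrations", {
  cfg <- generator_config(n_sites = 60, layout = "clustered", seed = 9)
  hs <- generate_hotspot_survey(cfg, hotspot_metal = "Ni", enrichment = 3)
  s <- hs$samples
  ni <- s[s$metal == "Ni", ]
  inside <- ni$site_id %in% hs$cluster_sites
  expect_gt(mean(ni$concentration_ug_L[inside]),
    mean(ni$concentration_ug_L[!inside]))
  # non-hotspot metals are untouched by the enrichment
  base <- generate_survey(generator_config(
    n_sites = 60, layout = "clustered", seed = 9
  ))
  expect_equal(
    s$concentration_ug_L[s$metal == "Pb"],
    base$concentration_ug_L[base$metal == "Pb"]
  )

  # unit enrichment is a no-op
  hs1 <- generate_hotspot_survey(cfg, hotspot_metal = "Ni", enrichment = 1)
  expect_identical(
    as.data.frame(hs1$samples), as.data.frame(base)
  )

  expect_error(
    generate_hotspot_survey(cfg, enrichment = 0.5),
    class = "metalrisk_config_error"
  )
  expect_error(
    generate_hotspot_survey(cfg, hotspot_metal = "Hg"),
    class = "metalrisk_config_error"
  )
})

test_that("rasterizing a hotspot survey localizes the planted cluster", {
  cfg <- generator_config(
    n_sites = 80, layout = "clustered", k = 4, spread = 4, seed = 14
  )
  hs <- generate_hotspot_survey(cfg, hotspot_metal = "Ni", enrichment = 3)
  field <- idw_raster(hs$samples, "Ni", nx = 40, ny = 40)
  peak <- grid_argmax(field)
  bbox <- hs$cluster_bbox
  margin <- c(field$cell_size[1], field$cell_size[2])
  expect_gte(peak[["x"]], bbox[1] - margin[1])
  expect_lte(peak[["x"]], bbox[2] + margin[1])
  expect_gte(peak[["y"]], bbox[3] - margin[2])
  expect_lte(peak[["y"]], bbox[4] + margin[2])
})
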