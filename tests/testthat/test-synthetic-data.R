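test_that("a noiseless record equals the forward model and refits exactly", {
  rec <- generate_curve(0.05, 8, 0.5, L0 = 7.6, A0 = 6.2,
                        noise_sd_rel = 0, n_points = 200, seed = 1)
  expect_equal(rec$force_N[1], 0)
  expect_equal(rec$displacement_mm[1], 0)
  expect_equal(max(rec$displacement_mm), 0.5 * 7.6)
  strain <- rec$displacement_mm / 7.6
  expect_equal(rec$force_N, vw_nominal_stress(0.05, 8, strain) * 6.2)

  fit <- vw_fit(to_stress_strain(rec, L0 = 7.6, A0 = 6.2))
  expect_equal(fit$mu, 0.05, tolerance = 1e-6)
  expect_equal(fit$gamma, 8, tolerance = 1e-6)
})

test_that("records are reproducible from the seed and differ across seeds", {
  a <- generate_curve(0.05, 8, 0.5, L0 = 7.6, A0 = 6, seed = 99)
  b <- generate_curve(0.05, 8, 0.5, L0 = 7.6, A0 = 6, seed = 99)
  c <- generate_curve(0.05, 8, 0.5, L0 = 7.6, A0 = 6, seed = 100)
  expect_identical(a, b)
  expect_false(identical(a$force_N, c$force_N))
})

test_that("invalid specifications are rejected", {
  expect_error(generate_curve(-1, 8, 0.5, 7.6, 6), "positive")
  expect_error(generate_curve(0.05, 8, 0.5, 7.6, 6, n_points = 5), "n_points")
  expect_error(generate_curve(0.05, 8, 0, 7.6, 6), "positive")
  expect_error(population_spec("human", 0.3, 5, mu_median = 0,
                               mu_logsd = 0.3, gamma_median = 4,
                               gamma_logsd = 0.1, rupture_mean = 0.5,
                               rupture_sd = 0.05), "positive")
  expect_error(population_spec("human", 0.3, -1, mu_median = 1,
                               mu_logsd = 0.3, gamma_median = 4,
                               gamma_logsd = 0.1, rupture_mean = 0.5,
                               rupture_sd = 0.05), "n_samples")
})

test_that("default study has the study's per-group sample counts", {
  study <- generate_study(seed = 1)
  counts <- dplyr::count(study$meta, tissue, rate_mm_s)
  expect_equal(counts$n[counts$tissue == "human"], c(95, 92, 102))
  expect_equal(counts$n[counts$tissue == "porcine"], c(38, 39, 38))
  expect_equal(nrow(study$truth), 404)
  expect_equal(nrow(study$curves), 404 * 200)
})

test_that("an all-zero config yields an empty study", {
  study <- generate_study(dplyr::mutate(default_populations(), n_samples = 0L))
  expect_equal(nrow(study$curves), 0)
  expect_equal(nrow(study$truth), 0)
})

test_that("study generation is seed-deterministic and values are physical", {
  pops <- small_populations(5L)
  s1 <- generate_study(pops, seed = 12)
  s2 <- generate_study(pops, seed = 12)
  s3 <- generate_study(pops, seed = 13)
  expect_identical(s1$curves, s2$curves)
  expect_identical(s1$truth, s2$truth)
  expect_false(identical(s1$truth, s3$truth))

  expect_true(all(is.finite(s1$curves$force_N)))
  expect_true(all(s1$curves$force_N >= 0))
  expect_true(all(s1$curves$displacement_mm >= 0))
  expect_true(all(s1$meta$L0_mm > 0))
  expect_true(all(s1$meta$A0_mm2 > 0))
  expect_true(all(s1$truth$rupture_strain > 0))
})

test_that("noiseless generation allows near-exact parameter recovery at scale", {
  pops <- small_populations(9L) |> dplyr::mutate(noise_sd_rel = 0)
  study <- generate_study(pops, seed = 5)   # 54 specimens
  props <- extract_properties(study$curves, study$meta)
  joined <- dplyr::inner_join(props, study$truth, by = "sample_id")
  rel_mu <- abs(joined$mu_MPa.x - joined$mu_MPa.y) / joined$mu_MPa.y
  rel_ga <- abs(joined$gamma.x - joined$gamma.y) / joined$gamma.y
  expect_gte(nrow(joined), 50)
  expect_lt(max(rel_mu), 1e-4)
  expect_lt(max(rel_ga), 1e-4)
})

test_that("2% noise leaves parameter recovery within a few percent", {
  pops <- small_populations(9L)   # default noise_sd_rel = 0.02
  study <- generate_study(pops, seed = 6)
  props <- extract_properties(study$curves, study$meta)
  joined <- dplyr::inner_join(props, study$truth, by = "sample_id")
  rel_mu <- abs(joined$mu_MPa.x - joined$mu_MPa.y) / joined$mu_MPa.y
  rel_ga <- abs(joined$gamma.x - joined$gamma.y) / joined$gamma.y
  expect_lt(median(rel_mu), 0.05)
  expect_lt(median(rel_ga), 0.05)
})

test_that("study tables round-trip through delimited text", {
  study <- generate_study(small_populations(3L), seed = 2)
  dir <- withr::local_tempdir()
  write_study(study, dir)
  curves <- read_curves(file.path(dir, "curves.csv"))
  meta <- read_meta(file.path(dir, "meta.csv"))
  expect_equal(as.data.frame(curves), as.data.frame(study$curves))
  expect_equal(as.data.frame(meta), as.data.frame(study$meta))
})
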