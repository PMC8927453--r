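test_that("stress-strain conversion divides by the reference geometry", {
  rec <- tibble::tibble(displacement_mm = c(0, 0.5, 1), force_N = c(0, 1, 2))
  ss <- to_stress_strain(rec, L0 = 1, A0 = 1)
  expect_equal(ss$strain, c(0, 0.5, 1))
  expect_equal(ss$stress, c(0, 1, 2))

  ss2 <- to_stress_strain(tibble::tibble(displacement_mm = c(0, 1, 2),
                                         force_N = c(0, 2, 4)), L0 = 1, A0 = 2)
  expect_equal(ss2$stress, c(0, 1, 2))

  # doubling A0 halves stress; doubling L0 halves strain
  base <- to_stress_strain(rec, L0 = 2, A0 = 3)
  expect_equal(to_stress_strain(rec, L0 = 2, A0 = 6)$stress, base$stress / 2)
  expect_equal(to_stress_strain(rec, L0 = 4, A0 = 3)$strain, base$strain / 2)
})

test_that("conversion collapses duplicated displacements and validates input", {
  rec <- tibble::tibble(displacement_mm = c(0, 0.5, 0.5, 1),
                        force_N = c(0, 1, 1.2, 2))
  ss <- to_stress_strain(rec, L0 = 1, A0 = 1)
  expect_equal(ss$strain, c(0, 0.5, 1))
  expect_equal(ss$stress, c(0, 1, 2))   # first reading kept
  expect_true(all(diff(ss$strain) > 0))

  expect_error(to_stress_strain(rec, L0 = 0, A0 = 1), "geometry")
  expect_error(to_stress_strain(rec, L0 = 1, A0 = -2), "geometry")
  bad <- tibble::tibble(displacement_mm = c(0, 1, 0.5), force_N = c(0, 1, 2))
  expect_error(to_stress_strain(bad, L0 = 1, A0 = 1), "nondecreasing")
})

test_that("ultimate point is the first stress maximum", {
  curve <- tibble::tibble(strain = c(0, .1, .2, .3), stress = c(0, 1, 3, 2))
  expect_equal(ultimate_point(curve), tibble::tibble(ut_stress = 3, ut_strain = 0.2))

  monotone <- tibble::tibble(strain = c(0, .1, .2), stress = c(0, 1, 5))
  expect_equal(ultimate_point(monotone)$ut_strain, 0.2)

  tie <- tibble::tibble(strain = c(0, .1, .2, .3), stress = c(0, 4, 2, 4))
  expect_equal(ultimate_point(tie)$ut_strain, 0.1)

  flat <- tibble::tibble(strain = c(0, .1), stress = c(0, 0))
  expect_error(ultimate_point(flat), "degenerate")
})

test_that("toughness integrates the curve and respects closed forms", {
  expect_equal(toughness(tibble::tibble(strain = c(0, 0.5), stress = c(0, 2))),
               0.5)

  k <- 7
  lin <- tibble::tibble(strain = seq(0, 0.4, length.out = 400))
  lin$stress <- k * lin$strain
  expect_equal(toughness(lin), k * 0.4^2 / 2, tolerance = 1e-3)

  # monotone nondecreasing in the upper limit for nonnegative stress
  set.seed(7)
  for (i in 1:20) {
    strain <- sort(runif(30, 0, 1))
    strain[1] <- 0
    curve <- tibble::tibble(strain = strain, stress = cumsum(abs(rnorm(30))))
    limits <- sort(runif(5, min(strain) + 1e-6, max(strain)))
    vals <- vapply(limits, function(u) toughness(curve, u), numeric(1))
    expect_true(all(diff(vals) >= -1e-12))
  }

  expect_error(toughness(lin, up_to_strain = 0.5), "outside")
})

test_that("toughness never exceeds the ultimate-point rectangle bound", {
  set.seed(11)
  for (i in 1:20) {
    strain <- c(0, sort(runif(40, 0, 0.9)))
    curve <- tibble::tibble(strain = strain, stress = c(0, abs(rnorm(40))))
    ut <- ultimate_point(curve)
    expect_lte(toughness(curve, ut$ut_strain), ut$ut_stress * ut$ut_strain + 1e-12)
  }
})

test_that("extreme outliers are fenced at quartile +/- 3 IQR per group", {
  # hand-computed: type-7 quartiles of {1,2,3,4,100} are Q1 = 2, Q3 = 4,
  # so the upper fence is 4 + 3*2 = 10 and only the 100 is removed
  tab <- tibble::tibble(
    sample_id = paste0("s", 1:5), tissue = "human", rate_mm_s = 0.3,
    ut_stress_MPa = c(1, 2, 3, 4, 100),
    ut_strain = 0.5, toughness_MJm3 = 1, mu_MPa = 0.05, gamma = 5
  )
  res <- remove_outliers(tab)
  expect_equal(res$removed$sample_id, "s5")
  expect_equal(res$removed$flagged_property, "ut_stress_MPa")
  expect_equal(sort(res$kept$sample_id), paste0("s", 1:4))
})

test_that("identical values are never flagged and the split is a partition", {
  const <- tibble::tibble(
    sample_id = paste0("s", 1:6), tissue = "porcine", rate_mm_s = 2,
    ut_stress_MPa = 3, ut_strain = 0.4, toughness_MJm3 = 0.6,
    mu_MPa = 0.02, gamma = 4
  )
  res <- remove_outliers(const)
  expect_equal(nrow(res$removed), 0)
  expect_equal(nrow(res$kept), 6)

  set.seed(3)
  tab <- tibble::tibble(
    sample_id = sprintf("r%02d", 1:40),
    tissue = rep(c("human", "porcine"), each = 20),
    rate_mm_s = rep(c(0.3, 8), 20),
    ut_stress_MPa = rlnorm(40, 0, 1), ut_strain = runif(40, 0.2, 0.8),
    toughness_MJm3 = rlnorm(40, -1, 1), mu_MPa = rlnorm(40, -3, 0.5),
    gamma = rlnorm(40, 1.5, 0.3)
  )
  res2 <- remove_outliers(tab)
  expect_setequal(c(res2$kept$sample_id, res2$removed$sample_id), tab$sample_id)
  expect_length(intersect(res2$kept$sample_id, res2$removed$sample_id), 0)
})

test_that("tiny groups pass through unfiltered with a warning", {
  tab <- tibble::tibble(
    sample_id = paste0("s", 1:3), tissue = "human", rate_mm_s = 0.3,
    ut_stress_MPa = c(1, 2, 1000), ut_strain = 0.5, toughness_MJm3 = 1,
    mu_MPa = 0.05, gamma = 5
  )
  expect_warning(res <- remove_outliers(tab), "fewer than 4")
  expect_equal(nrow(res$kept), 3)
})

test_that("extraction driver reproduces per-specimen ground truth structure", {
  study <- generate_study(small_populations(3L), seed = 21)
  props <- extract_properties(study$curves, study$meta)
  expect_equal(nrow(props), nrow(study$meta))
  expect_equal(props$sample_id, study$meta$sample_id)
  expect_named(props, c("sample_id", "tissue", "rate_mm_s", "ut_stress_MPa",
                        "ut_strain", "toughness_MJm3", "mu_MPa", "gamma",
                        "r_squared"))
  expect_true(all(props$ut_stress_MPa > 0))
  expect_true(all(props$toughness_MJm3 > 0))
  expect_true(all(props$r_squared <= 1))
  # ultimate strain equals the ground-truth rupture strain (last grid point)
  joined <- dplyr::inner_join(props, study$truth, by = "sample_id")
  expect_equal(joined$ut_strain, joined$rupture_strain, tolerance = 0.05)
})
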