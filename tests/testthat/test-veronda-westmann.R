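test_that("uniaxial invariants match closed forms and their lower bound", {
  undeformed <- vw_invariants(1)
  expect_equal(undeformed$I1_bar, 3)
  expect_equal(undeformed$I2_bar, 3)

  stretched <- vw_invariants(2)
  expect_equal(stretched$I1_bar, 5)
  expect_equal(stretched$I2_bar, 4.25)

  sweep <- vw_invariants(exp(seq(log(0.2), log(5), length.out = 200)))
  away_from_rest <- abs(sweep$stretch - 1) > 1e-6
  expect_true(all(sweep$I1_bar[away_from_rest] > 3))
  expect_true(all(sweep$I2_bar[away_from_rest] > 3))

  expect_error(vw_invariants(0), "positive")
  expect_error(vw_invariants(-1), "positive")
})

test_that("strain energy vanishes at rest and matches a frozen evaluation", {
  expect_equal(vw_strain_energy(1, 1, 3, 3), 0)
  expect_equal(vw_strain_energy(0.5, 7, 3, 3), 0)

  # lambda = 1.5, (mu, gamma) = (1, 1):
  # I1 = 2.25 + 4/3, I2 = 3 + 1/2.25; Psi = exp(I1 - 3) - 1 - (I2 - 3)
  inv <- vw_invariants(1.5)
  expect_equal(vw_strain_energy(1, 1, inv$I1_bar, inv$I2_bar),
               0.3475573812, tolerance = 1e-7)

  # gamma -> 0+ limit: Psi -> mu * (I1 - I2)
  inv2 <- vw_invariants(1.8)
  expect_equal(vw_strain_energy(2, 1e-8, inv2$I1_bar, inv2$I2_bar),
               2 * (inv2$I1_bar - inv2$I2_bar), tolerance = 1e-6)

  expect_error(vw_strain_energy(1, 400, 5, 4.25), "overflow")
})

test_that("nominal stress has a quadratic toe with modulus 6*mu", {
  expect_equal(vw_nominal_stress(0.3, 5, 0), 0)
  for (mu in c(0.05, 1, 3)) {
    expect_equal(vw_nominal_stress(mu, 2, 1e-4) / 1e-8, 6 * mu,
                 tolerance = 1e-2)
  }
})

test_that("nominal stress is the stretch-derivative of the strain energy", {
  # central-difference oracle on a (mu, gamma, lambda) grid
  psi_of_lambda <- function(mu, gamma, lam) {
    inv <- vw_invariants(lam)
    vw_strain_energy(mu, gamma, inv$I1_bar, inv$I2_bar)
  }
  h <- 1e-6
  for (mu in c(0.01, 0.1, 1)) {
    for (gamma in c(0.5, 2, 8, 20)) {
      for (lam in c(1.05, 1.2, 1.5, 2, 3)) {
        if (gamma * (lam^2 + 2 / lam - 3) > 600) next
        num <- (psi_of_lambda(mu, gamma, lam + h) -
                  psi_of_lambda(mu, gamma, lam - h)) / (2 * h)
        ana <- vw_nominal_stress(mu, gamma, lam - 1)
        expect_equal(ana, num, tolerance = 1e-5)
      }
    }
  }
})

test_that("nominal stress is monotone in strain, linear in mu, increasing in gamma", {
  eps <- seq(0.01, 1, length.out = 120)
  for (gamma in c(0.5, 4, 12)) {
    s <- vw_nominal_stress(0.05, gamma, eps)
    expect_true(all(diff(s) > 0))
    expect_equal(vw_nominal_stress(0.15, gamma, eps), 3 * s)
  }
  s_lo <- vw_nominal_stress(0.05, 2, eps)
  s_hi <- vw_nominal_stress(0.05, 6, eps)
  expect_true(all(s_hi > s_lo))
})

test_that("fit recovers known parameters from a noiseless curve", {
  for (pars in list(c(0.05, 8), c(0.5, 2), c(0.02, 15))) {
    fit <- vw_fit(noiseless_curve(pars[1], pars[2]))
    expect_equal(fit$mu, pars[1], tolerance = 1e-6)
    expect_equal(fit$gamma, pars[2], tolerance = 1e-6)
    expect_gt(fit$r_squared, 1 - 1e-9)
    expect_true(fit$converged)
  }
})

test_that("fitted mu scales with stress, gamma is scale-free", {
  curve <- noiseless_curve(0.08, 6)
  base <- vw_fit(curve)
  scaled <- vw_fit(dplyr::mutate(curve, stress = stress * 4.2))
  expect_equal(scaled$mu, 4.2 * base$mu, tolerance = 1e-5)
  expect_equal(scaled$gamma, base$gamma, tolerance = 1e-5)
})

test_that("fit is deterministic and survives noisy pre/post-peak data", {
  strain <- seq(0, 0.6, length.out = 150)
  stress <- vw_nominal_stress(0.05, 8, strain)
  set.seed(42)
  noisy <- stress * (1 + rnorm(150, 0, 0.02))
  # append post-peak softening that must be excluded from the fit
  curve <- tibble::tibble(
    strain = c(strain, 0.62, 0.64),
    stress = c(noisy, max(noisy) * 0.7, max(noisy) * 0.4)
  )
  f1 <- vw_fit(curve)
  f2 <- vw_fit(curve)
  expect_identical(glance(f1), glance(f2))
  expect_lte(f1$n_points_used, 151)
  expect_equal(f1$mu, 0.05, tolerance = 0.15)
  expect_gt(f1$r_squared, 0.98)
})

test_that("fit rejects unusable curves", {
  expect_error(vw_fit(tibble::tibble(strain = c(0, 1), stress = c(0, 1))),
               "5 points")
  expect_error(vw_fit(tibble::tibble(x = 1)), "strain")
})

test_that("tidiers expose parameters, summary and per-point residuals", {
  fit <- vw_fit(noiseless_curve(0.05, 8))
  td <- tidy(fit)
  expect_equal(td$term, c("mu", "gamma"))
  expect_equal(nrow(glance(fit)), 1)
  aug <- augment(fit)
  expect_equal(nrow(aug), fit$n_points_used)
  expect_lt(max(abs(aug$.resid)), 1e-8)
})
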