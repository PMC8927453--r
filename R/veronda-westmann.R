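#' Deviatoric strain invariants under incompressible uniaxial stretch
#'
#' For an incompressible material stretched uniaxially to principal stretch
#' \eqn{\lambda}, the transverse stretches are \eqn{\lambda^{-1/2}} and the
#' first and second deviatoric invariants reduce to
#' \eqn{\bar I_1 = \lambda^2 + 2/\lambda} and
#' \eqn{\bar I_2 = 2\lambda + 1/\lambda^2}. Both equal 3 in the undeformed
#' state and exceed 3 for any other stretch.
#'
#' @param stretch Principal stretch \eqn{\lambda > 0} along the loading axis
#'   (vectorized).
#' @return A tibble with columns `stretch`, `I1_bar`, `I2_bar`.
#' @examples
#' vw_invariants(c(1, 1.5, 2))
#' @export
vw_invariants <- function(stretch) {
  if (!is.numeric(stretch) || any(!is.finite(stretch)) || any(stretch <= 0)) {
    abort("`stretch` must be finite and strictly positive.")
  }
  tibble(
    stretch = stretch,
    I1_bar = stretch^2 + 2 / stretch,
    I2_bar = 2 * stretch + 1 / stretch^2
  )
}

#' Veronda-Westmann strain energy density
#'
#' Evaluates \eqn{\Psi = (\mu/\gamma)(e^{\gamma(\bar I_1 - 3)} - 1) -
#' \mu(\bar I_2 - 3)}, the exponential-in-\eqn{\bar I_1} strain energy that
#' reproduces the J-shaped toe of soft tissue. \eqn{\mu} carries units of
#' stress (MPa here); \eqn{\gamma} is dimensionless and controls how sharply
#' the tissue stiffens.
#'
#' @param mu Shear-modulus-like coefficient, MPa, > 0.
#' @param gamma Dimensionless exponential stiffening coefficient, > 0.
#' @param I1_bar,I2_bar Deviatoric invariants (vectorized, each >= 3 for
#'   physical deformations).
#' @return Strain energy density in MPa (numerically MJ/m^3).
#' @examples
#' vw_strain_energy(1, 1, I1_bar = 3, I2_bar = 3) # 0 at rest
#' @export
vw_strain_energy <- function(mu, gamma, I1_bar, I2_bar) {
  stop_if_not_number(mu, "mu", positive = TRUE)
  stop_if_not_number(gamma, "gamma", positive = TRUE)
  expo <- gamma * (I1_bar - 3)
  if (any(expo > 700)) {
    abort(sprintf(
      "exponential overflow in strain energy: gamma * (I1_bar - 3) reaches %.1f (> 700)",
      max(expo)
    ))
  }
  (mu / gamma) * (exp(expo) - 1) - mu * (I2_bar - 3)
}

#' Veronda-Westmann nominal stress under uniaxial tension
#'
#' The nominal (first Piola-Kirchhoff) stress conjugate to the stretch for an
#' incompressible Veronda-Westmann solid under uniaxial tension:
#' \deqn{\sigma_{NU} = 2\mu(1 - \lambda^{-3})(\lambda e^{\gamma(\bar I_1 - 3)} - 1),}
#' with \eqn{\lambda = 1 + \varepsilon_N}. It vanishes at zero strain with a
#' quadratic toe (\eqn{\sigma \approx 6\mu\varepsilon^2} for small strain) and
#' is identically the derivative \eqn{d\Psi/d\lambda} of the strain energy
#' under incompressible uniaxial kinematics.
#'
#' @inheritParams vw_strain_energy
#' @param strain Nominal strain \eqn{\varepsilon_N > -1} (vectorized).
#' @return Nominal stress in MPa.
#' @examples
#' vw_nominal_stress(0.05, 8, strain = seq(0, 0.5, 0.1))
#' @export
vw_nominal_stress <- function(mu, gamma, strain) {
  stop_if_not_number(mu, "mu", positive = TRUE)
  stop_if_not_number(gamma, "gamma", positive = TRUE)
  if (any(!is.finite(strain)) || any(strain <= -1)) {
    abort("`strain` must be finite and > -1.")
  }
  lambda <- 1 + strain
  expo <- gamma * (lambda^2 + 2 / lambda - 3)
  if (any(expo > 700)) {
    abort(sprintf(
      "exponential overflow in nominal stress: gamma * (I1_bar - 3) reaches %.1f (> 700)",
      max(expo)
    ))
  }
  2 * mu * (1 - lambda^(-3)) * (lambda * exp(expo) - 1)
}

# profile SSE over gamma: stress is linear in mu, so the optimal mu for a
# fixed gamma is the least-squares slope of stress on the mu = 1 basis
vw_profile_mu <- function(gamma, strain, stress) {
  basis <- vw_nominal_stress(1, gamma, strain)
  denom <- sum(basis^2)
  if (denom <= 0) {
    return(list(mu = NA_real_, sse = Inf))
  }
  mu <- sum(basis * stress) / denom
  if (!is.finite(mu) || mu <= 0) {
    return(list(mu = NA_real_, sse = Inf))
  }
  list(mu = mu, sse = sum((stress - mu * basis)^2))
}

#' Fit the Veronda-Westmann model to a stress-strain curve
#'
#' Estimates \eqn{(\mu, \gamma)} by nonlinear least squares on plain stress
#' residuals over the pre-peak portion of the curve (points with strain up to
#' and including the ultimate tensile strain; the model cannot represent
#' post-peak softening). The fit is deterministic: because the stress is
#' linear in \eqn{\mu}, \eqn{\mu} is profiled out in closed form on a log-grid
#' of \eqn{\gamma} values, and the best profiled candidate is polished with a
#' Levenberg-Marquardt iteration on \eqn{(\log\mu, \log\gamma)} (positivity by
#' construction).
#'
#' @param data A data frame with numeric columns `strain` and `stress` (MPa),
#'   e.g. the output of [to_stress_strain()].
#' @param gamma_grid Log-spaced grid of \eqn{\gamma} starting values for the
#'   profile search.
#' @param max_iter Maximum Levenberg-Marquardt iterations.
#' @param ftol Relative residual-change convergence tolerance.
#' @param fit_to_peak If `TRUE` (default), only points up to the first
#'   stress maximum enter the fit.
#' @return An object of class `vw_fit` with elements `mu`, `gamma`,
#'   `r_squared`, `residual_norm`, `n_points_used`, `converged`, and the
#'   fitted range. `tidy()` returns the parameter table, `glance()` the
#'   one-row fit summary, `augment()` the per-point observed and fitted
#'   stresses.
#' @examples
#' strain <- seq(0, 0.5, length.out = 100)
#' curve <- tibble::tibble(strain = strain,
#'                         stress = vw_nominal_stress(0.05, 8, strain))
#' fit <- vw_fit(curve)
#' tidy(fit)
#' @export
vw_fit <- function(data,
                   gamma_grid = exp(seq(log(0.05), log(80), length.out = 60)),
                   max_iter = 200,
                   ftol = 1e-12,
                   fit_to_peak = TRUE) {
  if (!all(c("strain", "stress") %in% names(data))) {
    abort("`data` must have columns `strain` and `stress`.")
  }
  strain <- as.numeric(data$strain)
  stress <- as.numeric(data$stress)
  if (any(!is.finite(strain)) || any(!is.finite(stress))) {
    abort("`strain` and `stress` must be finite.")
  }
  if (fit_to_peak) {
    peak <- which.max(stress)
    strain <- strain[seq_len(peak)]
    stress <- stress[seq_len(peak)]
  }
  if (length(strain) < 5) {
    abort("need at least 5 points up to the ultimate point to fit.")
  }

  prof <- purrr::map(gamma_grid, vw_profile_mu, strain = strain, stress = stress)
  sse <- purrr::map_dbl(prof, "sse")
  if (all(!is.finite(sse))) {
    abort("fit failure: no gamma start yields a positive profiled mu.")
  }
  best <- which.min(sse)  # which.min takes the first minimum: ties -> smaller gamma
  theta0 <- c(log(prof[[best]]$mu), log(gamma_grid[best]))

  resid_fn <- function(theta) {
    stress - vw_nominal_stress(exp(theta[1]), exp(theta[2]), strain)
  }
  lm_fit <- tryCatch(
    minpack.lm::nls.lm(
      par = theta0, fn = resid_fn,
      control = minpack.lm::nls.lm.control(
        maxiter = max_iter, ftol = ftol, ptol = 1e-12, gtol = 0
      )
    ),
    error = function(e) NULL
  )
  if (!is.null(lm_fit) && is.finite(lm_fit$deviance) &&
      lm_fit$deviance <= min(sse[is.finite(sse)])) {
    theta <- lm_fit$par
    dev <- lm_fit$deviance
    converged <- lm_fit$info %in% 1:4
  } else {
    theta <- theta0
    dev <- sse[best]
    converged <- FALSE
  }

  ss_tot <- sum((stress - mean(stress))^2)
  r2 <- if (ss_tot > 0) 1 - dev / ss_tot else NA_real_

  structure(
    list(
      mu = exp(theta[1]),
      gamma = exp(theta[2]),
      r_squared = r2,
      residual_norm = sqrt(dev),
      n_points_used = length(strain),
      converged = converged,
      strain = strain,
      stress = stress
    ),
    class = "vw_fit"
  )
}

#' @export
print.vw_fit <- function(x, ...) {
  cat("Veronda-Westmann fit\n")
  cat(sprintf("  mu     = %.5g MPa\n", x$mu))
  cat(sprintf("  gamma  = %.5g\n", x$gamma))
  cat(sprintf("  R^2    = %.6f over %d points%s\n", x$r_squared,
              x$n_points_used,
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' @rdname vw_fit
#' @param x A `vw_fit` object.
#' @param ... Unused.
#' @method tidy vw_fit
#' @export
tidy.vw_fit <- function(x, ...) {
  tibble(
    term = c("mu", "gamma"),
    estimate = c(x$mu, x$gamma),
    unit = c("MPa", "1")
  )
}

#' @rdname vw_fit
#' @method glance vw_fit
#' @export
glance.vw_fit <- function(x, ...) {
  tibble(
    mu = x$mu, gamma = x$gamma, r_squared = x$r_squared,
    residual_norm = x$residual_norm, n_points_used = x$n_points_used,
    converged = x$converged
  )
}

#' @rdname vw_fit
#' @method augment vw_fit
#' @export
augment.vw_fit <- function(x, ...) {
  tibble(
    strain = x$strain,
    stress = x$stress,
    .fitted = vw_nominal_stress(x$mu, x$gamma, x$strain)
  ) |>
    dplyr::mutate(.resid = .data$stress - .data$.fitted)
}
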