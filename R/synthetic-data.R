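#' Describe one synthetic specimen population
#'
#' A population is one tissue type tested at one loading rate. Per-specimen
#' Veronda-Westmann parameters are drawn from lognormal distributions
#' (positive, right-skewed, matching the skew seen in soft-tissue property
#' distributions), the rupture strain from a truncated normal, and the
#' specimen geometry from truncated normals. Measurement noise is
#' multiplicative on force (a load-cell relative-error model).
#'
#' @param tissue `"human"` or `"porcine"` (any label is accepted).
#' @param rate_mm_s Loading rate in mm/s (label only: the forward model is
#'   hyperelastic and rate-independent; rates differ through their population
#'   parameters).
#' @param n_samples Number of specimens (>= 0).
#' @param mu_median,mu_logsd Median (MPa) and log-scale SD of the lognormal
#'   \eqn{\mu} distribution.
#' @param gamma_median,gamma_logsd Median and log-scale SD of the lognormal
#'   \eqn{\gamma} distribution.
#' @param rupture_mean,rupture_sd,rupture_min,rupture_max Truncated-normal
#'   rupture strain (dimensionless), lower bound > 0.
#' @param noise_sd_rel Relative SD of the multiplicative force noise (>= 0).
#' @param L0_mean,L0_sd Gauge length, mm (truncated at 1 mm).
#' @param A0_mean,A0_sd Cross-sectional area, mm^2 (truncated at 0.5 mm^2).
#' @return A one-row tibble describing the population.
#' @export
population_spec <- function(tissue, rate_mm_s, n_samples,
                            mu_median, mu_logsd,
                            gamma_median, gamma_logsd,
                            rupture_mean, rupture_sd,
                            rupture_min = 0.15, rupture_max = 1.2,
                            noise_sd_rel = 0.02,
                            L0_mean = 7.6, L0_sd = 0.4,
                            A0_mean = 6.0, A0_sd = 1.2) {
  if (n_samples < 0) abort("`n_samples` must be >= 0.")
  for (v in c("mu_median", "mu_logsd", "gamma_median", "gamma_logsd",
              "rupture_mean", "rupture_sd", "rupture_min",
              "L0_mean", "A0_mean")) {
    val <- get(v)
    if (!is.numeric(val) || !is.finite(val) || val <= 0) {
      abort(sprintf("`%s` must be strictly positive.", v))
    }
  }
  if (noise_sd_rel < 0) abort("`noise_sd_rel` must be >= 0.")
  if (rupture_max <= rupture_min) abort("`rupture_max` must exceed `rupture_min`.")
  tibble(
    tissue = as.character(tissue), rate_mm_s = rate_mm_s,
    n_samples = as.integer(n_samples),
    mu_median = mu_median, mu_logsd = mu_logsd,
    gamma_median = gamma_median, gamma_logsd = gamma_logsd,
    rupture_mean = rupture_mean, rupture_sd = rupture_sd,
    rupture_min = rupture_min, rupture_max = rupture_max,
    noise_sd_rel = noise_sd_rel,
    L0_mean = L0_mean, L0_sd = L0_sd, A0_mean = A0_mean, A0_sd = A0_sd
  )
}

#' Default synthetic populations: two tissues at three loading rates
#'
#' Six populations (human and porcine at 0.3, 2.0 and 8.0 mm/s) with sample
#' counts 95/92/102 (human) and 38/39/38 (porcine). The numeric population
#' constants are synthetic calibration values, not measurements: they were
#' chosen once so that (a) every property distribution is positive and
#' right-skewed, (b) the pooled Cohen's d between the tissues over the five
#' extracted properties is close to 1.4, and (c) \eqn{\mu} is the most
#' discriminative property. The human tissue is modelled as stiffer
#' (larger \eqn{\mu}, \eqn{\gamma}) and more extensible (larger rupture
#' strain) than the porcine tissue, with a mild stiffening trend across
#' loading rates applied to both tissues alike.
#'
#' @return A six-row tibble of population specs (one per tissue x rate).
#' @export
default_populations <- function() {
  rates <- c(0.3, 2.0, 8.0)
  mu_rate <- c(1, 1.12, 1.25)        # stiffening with rate, both tissues
  eps_rate <- c(1, 0.97, 0.94)       # slightly less extensible at speed
  human_n <- c(95L, 92L, 102L)
  porc_n <- c(38L, 39L, 38L)
  dplyr::bind_rows(
    purrr::map(1:3, function(i) {
      population_spec(
        "human", rates[i], human_n[i],
        mu_median = 0.063 * mu_rate[i], mu_logsd = 0.38,
        gamma_median = 4.65, gamma_logsd = 0.125,
        rupture_mean = 0.55 * eps_rate[i], rupture_sd = 0.072,
        A0_mean = 6.7, A0_sd = 1.6
      )
    }),
    purrr::map(1:3, function(i) {
      population_spec(
        "porcine", rates[i], porc_n[i],
        mu_median = 0.0235 * mu_rate[i], mu_logsd = 0.36,
        gamma_median = 3.55, gamma_logsd = 0.125,
        rupture_mean = 0.432 * eps_rate[i], rupture_sd = 0.062,
        A0_mean = 4.8, A0_sd = 1.2
      )
    })
  )
}

rtruncnorm1 <- function(n, mean, sd, lower, upper) {
  # inverse-CDF sampling keeps the draw count deterministic per specimen
  p_lo <- stats::pnorm(lower, mean, sd)
  p_hi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(p_lo + runif(n) * (p_hi - p_lo), mean, sd)
}

#' Simulate one tensile-test record
#'
#' Forward-simulates a specimen with known Veronda-Westmann parameters: a
#' uniform displacement grid spanning `[0, rupture_strain * L0]`, the exact
#' nominal stress converted to force through the cross-sectional area, and
#' independent multiplicative Gaussian noise on each force reading (forces
#' truncated at zero). With `noise_sd_rel = 0` the record is the exact
#' forward model and refitting recovers the parameters.
#'
#' @param mu,gamma Veronda-Westmann parameters (MPa, dimensionless), > 0.
#' @param rupture_strain Nominal strain at rupture, > 0.
#' @param L0 Gauge length, mm, > 0.
#' @param A0 Cross-sectional area, mm^2, > 0.
#' @param noise_sd_rel Relative SD of multiplicative force noise, >= 0.
#' @param n_points Number of grid points (>= 10).
#' @param seed Integer seed; the same seed reproduces the record exactly.
#' @param sample_id Identifier stored in the record.
#' @return A tibble with columns `sample_id`, `displacement_mm`, `force_N`.
#' @examples
#' generate_curve(0.05, 8, 0.5, L0 = 7.6, A0 = 6, noise_sd_rel = 0, seed = 1)
#' @export
generate_curve <- function(mu, gamma, rupture_strain, L0, A0,
                           noise_sd_rel = 0.02, n_points = 200,
                           seed = 1L, sample_id = "S1") {
  stop_if_not_number(mu, "mu", positive = TRUE)
  stop_if_not_number(gamma, "gamma", positive = TRUE)
  stop_if_not_number(rupture_strain, "rupture_strain", positive = TRUE)
  stop_if_not_number(L0, "L0", positive = TRUE)
  stop_if_not_number(A0, "A0", positive = TRUE)
  if (noise_sd_rel < 0) abort("`noise_sd_rel` must be >= 0.")
  if (n_points < 10) abort("`n_points` must be >= 10.")

  strain <- seq(0, rupture_strain, length.out = n_points)
  stress <- vw_nominal_stress(mu, gamma, strain)
  force <- stress * A0
  if (noise_sd_rel > 0) {
    eta <- withr::with_seed(seed, rnorm(n_points, 0, noise_sd_rel))
    force <- pmax(force * (1 + eta), 0)
  }
  tibble(
    sample_id = sample_id,
    displacement_mm = strain * L0,
    force_N = force
  )
}

#' Simulate a full two-tissue tensile study
#'
#' Draws per-specimen ground-truth parameters and geometry from each
#' population in `populations`, forward-simulates every record with
#' [generate_curve()], and returns the three tables the downstream pipeline
#' consumes. The whole study is reproducible from `seed` alone.
#'
#' @param populations A tibble of population specs, one row each; defaults to
#'   [default_populations()].
#' @param n_points Grid points per curve.
#' @param seed Integer master seed.
#' @return A list of class `tensile_study`:
#' \describe{
#'   \item{curves}{tibble `sample_id`, `displacement_mm`, `force_N`}
#'   \item{meta}{tibble `sample_id`, `tissue`, `rate_mm_s`, `L0_mm`, `A0_mm2`}
#'   \item{truth}{tibble `sample_id`, `mu_MPa`, `gamma`, `rupture_strain`
#'     (the ground truth, for recovery checks)}
#' }
#' @examples
#' pops <- default_populations() |> dplyr::mutate(n_samples = 3L)
#' study <- generate_study(pops, seed = 7)
#' @export
generate_study <- function(populations = default_populations(),
                           n_points = 200, seed = 1L) {
  if (n_points < 10) abort("`n_points` must be >= 10.")
  if (nrow(populations) == 0 || sum(populations$n_samples) == 0) {
    empty_curves <- tibble(sample_id = character(), displacement_mm = double(),
                           force_N = double())
    empty_meta <- tibble(sample_id = character(), tissue = character(),
                         rate_mm_s = double(), L0_mm = double(), A0_mm2 = double())
    empty_truth <- tibble(sample_id = character(), mu_MPa = double(),
                          gamma = double(), rupture_strain = double())
    return(structure(list(curves = empty_curves, meta = empty_meta,
                          truth = empty_truth, seed = seed),
                     class = "tensile_study"))
  }

  draws <- withr::with_seed(seed, {
    purrr::pmap(populations, function(tissue, rate_mm_s, n_samples,
                                      mu_median, mu_logsd, gamma_median,
                                      gamma_logsd, rupture_mean, rupture_sd,
                                      rupture_min, rupture_max, noise_sd_rel,
                                      L0_mean, L0_sd, A0_mean, A0_sd) {
      n <- n_samples
      if (n == 0) return(NULL)
      tibble(
        tissue = tissue, rate_mm_s = rate_mm_s,
        mu_MPa = rlnorm(n, log(mu_median), mu_logsd),
        gamma = rlnorm(n, log(gamma_median), gamma_logsd),
        rupture_strain = rtruncnorm1(n, rupture_mean, rupture_sd,
                                     rupture_min, rupture_max),
        L0_mm = rtruncnorm1(n, L0_mean, L0_sd, 1, Inf),
        A0_mm2 = rtruncnorm1(n, A0_mean, A0_sd, 0.5, Inf),
        noise_sd_rel = noise_sd_rel,
        curve_seed = sample.int(.Machine$integer.max - 1L, n)
      )
    }) |>
      dplyr::bind_rows()
  })
  draws$sample_id <- sprintf("%s_%04d", substr(draws$tissue, 1, 1),
                             seq_len(nrow(draws)))

  curves <- purrr::pmap(
    draws[c("mu_MPa", "gamma", "rupture_strain", "L0_mm", "A0_mm2",
            "noise_sd_rel", "curve_seed", "sample_id")],
    function(mu_MPa, gamma, rupture_strain, L0_mm, A0_mm2,
             noise_sd_rel, curve_seed, sample_id) {
      generate_curve(mu_MPa, gamma, rupture_strain, L0 = L0_mm, A0 = A0_mm2,
                     noise_sd_rel = noise_sd_rel, n_points = n_points,
                     seed = curve_seed, sample_id = sample_id)
    }
  ) |>
    dplyr::bind_rows()

  structure(
    list(
      curves = curves,
      meta = draws[c("sample_id", "tissue", "rate_mm_s", "L0_mm", "A0_mm2")],
      truth = draws[c("sample_id", "mu_MPa", "gamma", "rupture_strain")],
      seed = seed
    ),
    class = "tensile_study"
  )
}

#' @export
print.tensile_study <- function(x, ...) {
  cat(sprintf("Synthetic tensile study: %d specimens, %d force readings (seed %d)\n",
              nrow(x$meta), nrow(x$curves), x$seed))
  if (nrow(x$meta) > 0) {
    print(dplyr::count(x$meta, .data$tissue, .data$rate_mm_s))
  }
  invisible(x)
}

#' Write a study's tables to delimited text files
#'
#' Writes `curves.csv`, `meta.csv` and (if present) `truth.csv` under `dir`.
#'
#' @param study A `tensile_study` from [generate_study()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_study <- function(study, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    curves = file.path(dir, "curves.csv"),
    meta = file.path(dir, "meta.csv"),
    truth = file.path(dir, "truth.csv")
  )
  readr::write_csv(study$curves, paths[["curves"]])
  readr::write_csv(study$meta, paths[["meta"]])
  if (!is.null(study$truth)) readr::write_csv(study$truth, paths[["truth"]])
  invisible(paths)
}
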