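#' Convert a force-displacement record to nominal stress-strain
#'
#' Nominal (engineering) measures use the undeformed geometry throughout:
#' stress \eqn{\sigma_N = F / A_0} (N/mm^2 = MPa) and strain
#' \eqn{\varepsilon_N = \Delta L / L_0}. Strictly duplicated displacement
#' values are collapsed, keeping the first reading, so the returned strain is
#' strictly increasing.
#'
#' @param data A data frame with columns `displacement_mm` and `force_N`,
#'   displacement nondecreasing from 0.
#' @param L0 Initial gauge length, mm, > 0.
#' @param A0 Initial cross-sectional area, mm^2, > 0.
#' @return A tibble with columns `strain` (dimensionless) and `stress` (MPa).
#' @examples
#' rec <- tibble::tibble(displacement_mm = c(0, 1), force_N = c(0, 1))
#' to_stress_strain(rec, L0 = 1, A0 = 1)
#' @export
to_stress_strain <- function(data, L0, A0) {
  if (!all(c("displacement_mm", "force_N") %in% names(data))) {
    abort("`data` must have columns `displacement_mm` and `force_N`.")
  }
  stop_if_not_number(L0, "L0")
  stop_if_not_number(A0, "A0")
  if (L0 <= 0 || A0 <= 0) abort("invalid geometry: `L0` and `A0` must be > 0.")
  dl <- as.numeric(data$displacement_mm)
  f <- as.numeric(data$force_N)
  if (length(dl) < 3) abort("record must have at least 3 points.")
  if (any(!is.finite(dl)) || any(!is.finite(f))) abort("record values must be finite.")
  if (dl[1] != 0 || any(diff(dl) < 0)) {
    abort("displacement must be nondecreasing and start at 0.")
  }
  keep <- !duplicated(dl)
  tibble(strain = dl[keep] / L0, stress = f[keep] / A0)
}

#' Locate the ultimate tensile point of a stress-strain curve
#'
#' The ultimate tensile stress is the maximum nominal stress on the curve
#' (the rupture point); the ultimate tensile strain is the strain at its
#' first occurrence.
#'
#' @param data A data frame with columns `strain` and `stress`.
#' @return A one-row tibble with `ut_stress` (MPa) and `ut_strain`.
#' @examples
#' ultimate_point(tibble::tibble(strain = c(0, .1, .2, .3),
#'                               stress = c(0, 1, 3, 2)))
#' @export
ultimate_point <- function(data) {
  stress <- as.numeric(data$stress)
  strain <- as.numeric(data$strain)
  if (all(stress == 0)) abort("degenerate curve: all stresses are zero.")
  i <- which.max(stress)  # first maximum on ties
  tibble(ut_stress = stress[i], ut_strain = strain[i])
}

#' Toughness: area under the nominal stress-strain curve
#'
#' Trapezoidal integral of stress over strain on `[0, up_to_strain]`, the
#' energy absorbed per unit volume up to that strain. Numerically MPa x
#' strain = MJ/m^3. The integration endpoint defaults to the ultimate
#' tensile strain.
#'
#' @param data A data frame with columns `strain` and `stress`.
#' @param up_to_strain Upper integration limit; must lie within the recorded
#'   strain range. Defaults to the ultimate tensile strain.
#' @return Toughness in MJ/m^3 (scalar).
#' @examples
#' toughness(tibble::tibble(strain = c(0, 0.5), stress = c(0, 2)))  # 0.5
#' @export
toughness <- function(data, up_to_strain = NULL) {
  strain <- as.numeric(data$strain)
  stress <- as.numeric(data$stress)
  if (is.null(up_to_strain)) {
    up_to_strain <- ultimate_point(data)$ut_strain
  }
  if (up_to_strain < min(strain) || up_to_strain > max(strain)) {
    abort(sprintf("`up_to_strain` = %g lies outside the recorded range [%g, %g].",
                  up_to_strain, min(strain), max(strain)))
  }
  inside <- strain <= up_to_strain
  s <- strain[inside]
  y <- stress[inside]
  if (max(s) < up_to_strain) {
    # linear interpolation to close the interval at the requested strain
    j <- which(!inside)[1]
    w <- (up_to_strain - strain[j - 1]) / (strain[j] - strain[j - 1])
    s <- c(s, up_to_strain)
    y <- c(y, (1 - w) * stress[j - 1] + w * stress[j])
  }
  sum(diff(s) * (head(y, -1) + tail(y, -1)) / 2)
}

#' Extract the five mechanical properties of every specimen
#'
#' The extraction driver: for each specimen, converts the raw record to
#' nominal stress-strain, reads off the ultimate tensile stress and strain,
#' integrates the toughness up to the ultimate point, and fits the
#' Veronda-Westmann model to the pre-peak curve.
#'
#' @param curves Long tibble of raw records (`sample_id`, `displacement_mm`,
#'   `force_N`), e.g. `study$curves`.
#' @param meta Per-specimen metadata (`sample_id`, `tissue`, `rate_mm_s`,
#'   `L0_mm`, `A0_mm2`), e.g. `study$meta`.
#' @param ... Passed on to [vw_fit()].
#' @return A tibble with one row per specimen: `sample_id`, `tissue`,
#'   `rate_mm_s`, `ut_stress_MPa`, `ut_strain`, `toughness_MJm3`, `mu_MPa`,
#'   `gamma`, `r_squared`.
#' @examples
#' pops <- default_populations() |> dplyr::mutate(n_samples = 2L)
#' study <- generate_study(pops, seed = 3)
#' extract_properties(study$curves, study$meta)
#' @export
extract_properties <- function(curves, meta, ...) {
  required <- c("sample_id", "tissue", "rate_mm_s", "L0_mm", "A0_mm2")
  missing_cols <- setdiff(required, names(meta))
  if (length(missing_cols) > 0) {
    abort(sprintf("`meta` is missing required column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  curves |>
    dplyr::inner_join(meta, by = "sample_id") |>
    dplyr::group_by(.data$sample_id, .data$tissue, .data$rate_mm_s) |>
    dplyr::group_modify(function(df, key) {
      ss <- to_stress_strain(df, L0 = df$L0_mm[1], A0 = df$A0_mm2[1])
      ut <- ultimate_point(ss)
      fit <- vw_fit(ss, ...)
      tibble(
        ut_stress_MPa = ut$ut_stress,
        ut_strain = ut$ut_strain,
        toughness_MJm3 = toughness(ss, ut$ut_strain),
        mu_MPa = fit$mu,
        gamma = fit$gamma,
        r_squared = fit$r_squared
      )
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(match(.data$sample_id, meta$sample_id))
}

#' Remove extreme outliers from a property table
#'
#' Within each tissue x rate group and for each of the five properties,
#' computes the quartiles (linear-interpolation "type 7" convention) and
#' flags any specimen with a property outside the extreme-outlier fences
#' `[Q1 - 3 IQR, Q3 + 3 IQR]`. A specimen is removed if any of its five
#' properties is flagged. The filter is applied once (fences are not
#' recomputed after removal). Groups smaller than 4 specimens are passed
#' through unfiltered with a warning.
#'
#' @param properties A property table from [extract_properties()].
#' @param group_vars Grouping columns; defaults to tissue and loading rate.
#' @return A list with `kept` (filtered tibble), `removed` (tibble of removed
#'   rows with a `flagged_property` column naming the offending properties).
#' @export
remove_outliers <- function(properties, group_vars = c("tissue", "rate_mm_s")) {
  props <- property_cols()
  missing_cols <- setdiff(c(props, group_vars), names(properties))
  if (length(missing_cols) > 0) {
    abort(sprintf("property table is missing column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  flagged <- properties |>
    dplyr::group_by(dplyr::across(dplyr::all_of(group_vars))) |>
    dplyr::group_modify(function(df, key) {
      if (nrow(df) < 4) {
        warn(sprintf("group %s has fewer than 4 specimens; passed through unfiltered.",
                     paste(unlist(key), collapse = "/")))
        df$flagged_property <- ""
        return(df)
      }
      flags <- purrr::map(props, function(p) {
        q <- quantile(df[[p]], c(0.25, 0.75), type = 7, names = FALSE)
        iqr <- q[2] - q[1]
        df[[p]] < q[1] - 3 * iqr | df[[p]] > q[2] + 3 * iqr
      })
      names(flags) <- props
      flag_mat <- do.call(cbind, flags)
      df$flagged_property <- apply(flag_mat, 1, function(r) {
        paste(props[r], collapse = ",")
      })
      df
    }) |>
    dplyr::ungroup()
  list(
    kept = flagged |>
      dplyr::filter(.data$flagged_property == "") |>
      dplyr::select(-"flagged_property") |>
      dplyr::select(dplyr::all_of(names(properties))),
    removed = flagged |>
      dplyr::filter(.data$flagged_property != "")
  )
}
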