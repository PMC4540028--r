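#' Simulate internal-standard calibration standards
#'
#' A dilution series of `n_levels` amounts starting at `low_amount` and
#' increasing by `dilution_factor` per level (e.g. 15.6 pg doubling seven
#' levels up to 998.4 pg, about 1 ng on column). The response ratio
#' (analyte area / internal-standard area) follows the linear model
#' `ratio = true_slope * amount + true_intercept` with multiplicative
#' lognormal noise of coefficient of variation `noise_cv`.
#'
#' @param low_amount lowest amount on column (pg), > 0.
#' @param n_levels number of standards (>= 3).
#' @param dilution_factor fold step between consecutive levels (> 1).
#' @param true_slope,true_intercept parameters of the underlying line.
#' @param noise_cv coefficient of variation of the multiplicative noise on
#'   the ratio.
#' @param is_response internal-standard response (area units) assigned to
#'   every level.
#' @param seed integer seed.
#' @return tibble `level`, `amount_pg`, `analyte_response`, `is_response`.
#' @export
#' @examples
#' simulate_calibration(15.6, 7, 2, noise_cv = 0)
simulate_calibration <- function(low_amount, n_levels = 7L,
                                 dilution_factor = 2, true_slope = 0.002,
                                 true_intercept = 0.01, noise_cv = 0.01,
                                 is_response = 1e5, seed = 1L) {
  assert_that_(low_amount > 0, "`low_amount` must be > 0")
  assert_that_(n_levels >= 3, "`n_levels` must be >= 3")
  assert_that_(dilution_factor > 1, "`dilution_factor` must be > 1")
  with_seed_(seed, {
    amount <- low_amount * dilution_factor^(seq_len(n_levels) - 1)
    ratio <- true_slope * amount + true_intercept
    if (noise_cv > 0) {
      sdl <- sqrt(log(1 + noise_cv^2))
      ratio <- ratio * stats::rlnorm(n_levels, -sdl^2 / 2, sdl)
    }
    tibble(level = seq_len(n_levels), amount_pg = amount,
           analyte_response = ratio * is_response, is_response = is_response)
  })
}

#' Fit an internal-standard calibration curve
#'
#' Ordinary least squares of the response ratio (analyte / internal
#' standard) on the amount on column, with the product-moment correlation
#' coefficient `r` of ratio vs amount as the linearity statistic. Unweighted
#' by default, as is conventional when no weighting scheme is specified;
#' `weighting = "1/x"` applies inverse-amount weights.
#'
#' @param standards tibble with `amount_pg`, `analyte_response`,
#'   `is_response` (e.g. [simulate_calibration()] output).
#' @param metabolite optional analyte name carried into the result.
#' @param weighting `"none"` (default) or `"1/x"`.
#' @return object of class `calibration_fit`: slope, intercept, `r`,
#'   `range_low`/`range_high` (pg), `n_levels`, the underlying
#'   [stats::lm] fit, and the standards.
#' @export
fit_calibration <- function(standards, metabolite = NULL,
                            weighting = c("none", "1/x")) {
  weighting <- match.arg(weighting)
  assert_that_(all(c("amount_pg", "analyte_response", "is_response") %in%
                     names(standards)),
               "`standards` needs amount_pg, analyte_response, is_response")
  assert_that_(all(standards$amount_pg > 0), "standard amounts must be > 0")
  assert_that_(all(standards$is_response > 0),
               "internal-standard responses must be > 0 to form ratios")
  amounts <- standards$amount_pg
  if (length(unique(amounts)) < 3) {
    abort("calibration fit needs >= 3 distinct standard amounts")
  }
  df <- data.frame(amount = amounts,
                   ratio = standards$analyte_response / standards$is_response)
  w <- if (weighting == "1/x") 1 / df$amount else NULL
  fit <- stats::lm(ratio ~ amount, data = df, weights = w)
  structure(list(
    metabolite = metabolite %||% "analyte",
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r = stats::cor(df$amount, df$ratio),
    range_low = min(amounts), range_high = max(amounts),
    n_levels = length(unique(amounts)),
    weighting = weighting, model = fit, standards = as_tibble(standards)),
    class = "calibration_fit")
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf("<calibration_fit: %s>\n", x$metabolite))
  cat(sprintf("  ratio = %.6g * amount + %.6g   (r = %.4f)\n",
              x$slope, x$intercept, x$r))
  cat(sprintf("  linear %g - %g pg (%d levels, %d-fold range)\n",
              x$range_low, x$range_high, x$n_levels,
              fold_range(x$range_low, x$range_high)))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname fit_calibration
#' @param x a `calibration_fit`.
#' @param ... unused.
#' @method tidy calibration_fit
#' @export
tidy.calibration_fit <- function(x, ...) {
  se <- suppressWarnings(summary(x$model)$coefficients[, "Std. Error"])
  tibble(term = c("intercept", "slope"),
         estimate = c(x$intercept, x$slope),
         std.error = unname(se))
}

#' @rdname fit_calibration
#' @method glance calibration_fit
#' @export
glance.calibration_fit <- function(x, ...) {
  tibble(metabolite = x$metabolite, slope = x$slope, intercept = x$intercept,
         r = x$r, r_squared = x$r^2, range_low = x$range_low,
         range_high = x$range_high,
         fold_range = fold_range(x$range_low, x$range_high),
         n_levels = x$n_levels)
}

#' Sample preparation chain for absolute quantification
#'
#' The dilution bookkeeping between dried tissue and the column: `tissue_mass`
#' mg of dry powder extracted in `extract_volume` uL of solvent, an
#' `aliquot_volume` uL aliquot made up to `final_volume` uL (with internal
#' standard), and `injection_volume` uL injected. Defaults follow the
#' reference protocol: 2 mg in 1 mL methanol, 5 uL aliquot into a 50 uL final
#' mix, 10 uL injected.
#'
#' @param tissue_mass_mg,extract_volume_ul,aliquot_volume_ul,final_volume_ul,injection_volume_ul
#'   chain parameters, all positive.
#' @return a list of class `sample_prep`.
#' @export
sample_prep <- function(tissue_mass_mg = 2, extract_volume_ul = 1000,
                        aliquot_volume_ul = 5, final_volume_ul = 50,
                        injection_volume_ul = 10) {
  vals <- c(tissue_mass_mg, extract_volume_ul, aliquot_volume_ul,
            final_volume_ul, injection_volume_ul)
  assert_that_(all(vals > 0), "all prep quantities must be positive")
  assert_that_(aliquot_volume_ul <= extract_volume_ul,
               "aliquot cannot exceed the extract volume")
  assert_that_(injection_volume_ul <= final_volume_ul,
               "injection cannot exceed the final volume")
  structure(list(tissue_mass_mg = tissue_mass_mg,
                 extract_volume_ul = extract_volume_ul,
                 aliquot_volume_ul = aliquot_volume_ul,
                 final_volume_ul = final_volume_ul,
                 injection_volume_ul = injection_volume_ul),
            class = "sample_prep")
}

#' Absolute quantification through a calibration curve
#'
#' Converts sample response ratios to amount on column via the fitted line,
#' then scales through the preparation chain to a tissue concentration:
#' `total_in_extract = amount * (final/injection) * (extract/aliquot)` and
#' `concentration = total_in_extract / tissue_mass` in pg per microgram of
#' dry tissue. Amounts outside the calibrated range are flagged
#' `extrapolated`; ratios at or below the intercept (non-positive amounts,
#' including zero analyte response) are flagged `below_quantification` and
#' reported as `NA` rather than negative values.
#'
#' @param curve a `calibration_fit`.
#' @param samples tibble with `analyte_response` and `is_response` columns
#'   (plus any identifier columns, which are carried through).
#' @param prep a [sample_prep()].
#' @return `samples` with `ratio`, `amount_on_column_pg`, `pg_per_ug` and
#'   `flag` (`ok`/`extrapolated`/`below_quantification`) appended.
#' @export
quantify <- function(curve, samples, prep = sample_prep()) {
  stopifnot(inherits(curve, "calibration_fit"), inherits(prep, "sample_prep"))
  assert_that_(curve$slope != 0, "calibration slope must be non-zero")
  ratio <- samples$analyte_response / samples$is_response
  amount <- (ratio - curve$intercept) / curve$slope
  below <- amount <= 0
  tol <- 1e-9  # float guard so the top/bottom standards themselves are in range
  extrap <- !below & (amount < curve$range_low * (1 - tol) |
                        amount > curve$range_high * (1 + tol))
  scale <- (prep$final_volume_ul / prep$injection_volume_ul) *
    (prep$extract_volume_ul / prep$aliquot_volume_ul)
  conc <- amount * scale / (prep$tissue_mass_mg * 1000)
  amount[below] <- NA_real_
  conc[below] <- NA_real_
  dplyr::mutate(as_tibble(samples), ratio = ratio,
                amount_on_column_pg = amount, pg_per_ug = conc,
                flag = dplyr::case_when(below ~ "below_quantification",
                                        extrap ~ "extrapolated",
                                        TRUE ~ "ok"))
}

#' Fold span of a calibration range
#'
#' Integer part of `range_high / range_low` -- the truncation rule that
#' reproduces the conventional "64-fold" (15.6 pg to 1 ng) and "73-fold"
#' (3.4 pg to 0.25 ng) descriptions of dilution series.
#'
#' @param range_low,range_high range endpoints, `0 < range_low < range_high`.
#' @return integer fold span.
#' @export
#' @examples
#' fold_range(15.6, 1000)
#' fold_range(3.4, 250)
fold_range <- function(range_low, range_high) {
  assert_that_(all(range_low > 0) && all(range_high > range_low),
               "need 0 < range_low < range_high")
  as.integer(range_high / range_low)
}
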