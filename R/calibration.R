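#' Fit a centre-specific TcB calibration coefficient
#'
#' Derives a single multiplicative coefficient aligning raw device readings
#' with laboratory serum bilirubin in the non-jaundiced range. Only pairs
#' with lab TSB strictly below 3 mg/dL enter the fit (above that, skin
#' bilirubin contaminates the comparison); excluded pairs are counted in the
#' result. The default estimator is least squares through the origin,
#' \eqn{\hat c = \sum tbl \cdot tsb / \sum tbl^2}, minimising
#' \eqn{\sum (c \cdot tbl_{raw} - tsb)^2}; a ratio-of-means alternative
#' (`mean(tsb) / mean(tbl_raw)`) is available for sensitivity analysis.
#'
#' @param pairs Data frame with columns `tbl_raw` and `tsb` (mg/dL), e.g.
#'   from [generate_calibration_pairs()].
#' @param site_id Site identifier recorded in the model.
#' @param method `"origin"` (regression through the origin, default) or
#'   `"ratio"` (ratio of means).
#' @return An object of class `srbv_calibration`: a list with `site_id`,
#'   `coefficient`, `n_pairs`, `n_excluded`, `fit_residual_cv` (residual SD
#'   of `c * tbl_raw - tsb` relative to the mean TSB) and `method`.
#' @export
#' @examples
#' pairs <- generate_calibration_pairs(50, device_gain = 1.25,
#'                                     noise_model(tcb_cv = 0, seed = 7))
#' fit_calibration(pairs, "site-A")$coefficient # 1/1.25 = 0.8
fit_calibration <- function(pairs, site_id = "site",
                            method = c("origin", "ratio")) {
  method <- match.arg(method)
  stopifnot(is.data.frame(pairs), all(c("tbl_raw", "tsb") %in% names(pairs)))
  if (any(!is.finite(pairs$tbl_raw)) || any(!is.finite(pairs$tsb)) ||
      any(pairs$tbl_raw <= 0) || any(pairs$tsb <= 0)) {
    rlang::abort("calibration pairs must be positive and finite",
                 class = "srbvkit_invalid_calibration")
  }
  eligible <- pairs$tsb < 3
  n_excluded <- sum(!eligible)
  pairs <- pairs[eligible, ]
  if (nrow(pairs) < 2L) {
    rlang::abort("need >= 2 eligible pairs (lab TSB < 3 mg/dL) to calibrate",
                 class = "srbvkit_insufficient_pairs")
  }
  coefficient <- switch(
    method,
    origin = sum(pairs$tbl_raw * pairs$tsb) / sum(pairs$tbl_raw^2),
    ratio = mean(pairs$tsb) / mean(pairs$tbl_raw)
  )
  resid <- coefficient * pairs$tbl_raw - pairs$tsb
  structure(
    list(site_id = as.character(site_id), coefficient = coefficient,
         n_pairs = nrow(pairs), n_excluded = n_excluded,
         fit_residual_cv = stats::sd(resid) / mean(pairs$tsb),
         method = method),
    class = "srbv_calibration"
  )
}

#' Construct a calibration model from known quantities
#'
#' Useful when coefficients come from a calibration table on disk rather
#' than a fresh fit.
#'
#' @param site_id Site identifier.
#' @param coefficient Multiplicative coefficient, > 0.
#' @param n_pairs Number of pairs behind the coefficient.
#' @param fit_residual_cv Residual CV of the original fit, if known.
#' @param method Fitting method label.
#' @return An `srbv_calibration` object.
#' @export
calibration_model <- function(site_id, coefficient, n_pairs = NA_integer_,
                              fit_residual_cv = NA_real_,
                              method = "origin") {
  if (!is.finite(coefficient) || coefficient <= 0) {
    rlang::abort("`coefficient` must be > 0",
                 class = "srbvkit_invalid_calibration")
  }
  structure(
    list(site_id = as.character(site_id), coefficient = coefficient,
         n_pairs = n_pairs, n_excluded = NA_integer_,
         fit_residual_cv = fit_residual_cv, method = method),
    class = "srbv_calibration"
  )
}

#' Apply a calibration coefficient to raw TcB readings
#'
#' Pure multiplication: `coefficient * tbl_raw`. Vectorised.
#'
#' @param model An `srbv_calibration` from [fit_calibration()].
#' @param tbl_raw Raw device readings, mg/dL, all > 0.
#' @return Calibrated TcB values, mg/dL.
#' @export
apply_calibration <- function(model, tbl_raw) {
  stopifnot(inherits(model, "srbv_calibration"))
  if (any(!is.finite(tbl_raw)) || any(tbl_raw <= 0)) {
    rlang::abort("`tbl_raw` must be positive and finite",
                 class = "srbvkit_invalid_reading")
  }
  model$coefficient * tbl_raw
}

#' @export
print.srbv_calibration <- function(x, ...) {
  cat(sprintf(
    "<srbv_calibration> %s: coefficient %.4f (%s, n = %d, excluded %d, residual CV %.3f)\n",
    x$site_id, x$coefficient, x$method, x$n_pairs, x$n_excluded,
    x$fit_residual_cv
  ))
  invisible(x)
}
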