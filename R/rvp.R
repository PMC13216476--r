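#' Construct a serial paired-measurement course series
#'
#' The unit of recovery value flip (RVP) analysis: an ordered sequence of
#' phototherapy cycles, each carrying the TcB reading at session end
#' (`TBL-out`) and at the end of the following break (`TBL-return`), plus
#' the pre-treatment baseline reading.
#'
#' @param neonate_id,site_id Identifiers.
#' @param baseline_tbl Pre-treatment calibrated TcB, mg/dL.
#' @param t_out,tbl_out Times (h) and readings at session ends.
#' @param t_return,tbl_return Times (h) and readings at break ends.
#' @param tsb_anchors Optional tibble of `(stage, tsb)` laboratory anchors.
#' @return An object of class `srbv_series` with a `cycles` tibble
#'   (`cycle`, `t_out`, `tbl_out`, `t_return`, `tbl_return`, `delta`).
#' @export
course_series <- function(neonate_id, site_id, baseline_tbl,
                          t_out, tbl_out, t_return, tbl_return,
                          tsb_anchors = NULL) {
  n <- length(t_out)
  stopifnot(length(tbl_out) == n, length(t_return) == n,
            length(tbl_return) == n)
  if (!is.finite(baseline_tbl) || baseline_tbl <= 0) {
    rlang::abort("`baseline_tbl` must be > 0", class = "srbvkit_invalid_series")
  }
  if (any(t_return <= t_out) || is.unsorted(t_out, strictly = TRUE)) {
    rlang::abort("cycles must be time-ordered with t_return > t_out",
                 class = "srbvkit_invalid_series")
  }
  cycles <- tibble::tibble(
    cycle = seq_len(n), t_out = t_out, tbl_out = tbl_out,
    t_return = t_return, tbl_return = tbl_return,
    delta = tbl_return - tbl_out
  )
  structure(
    list(neonate_id = as.character(neonate_id),
         site_id = as.character(site_id),
         baseline_tbl = baseline_tbl, cycles = cycles,
         tsb_anchors = tsb_anchors),
    class = "srbv_series"
  )
}

#' Build course series from a long measurement table
#'
#' Pairs `out` and `return` readings per neonate in time order and applies
#' per-site calibration coefficients to raw TcB readings.
#'
#' @param measurements Long-format tibble with columns `neonate_id`,
#'   `site_id`, `time_h`, `phase` (`pre`/`out`/`return`), `kind`
#'   (`TBL_raw`), `value_mg_dl`, e.g. from [measurements_frame()] or
#'   [read_measurements()].
#' @param calibrations Optional named list (by `site_id`) of
#'   `srbv_calibration` models; omitted sites use coefficient 1.
#' @return A named list of [course_series()] objects.
#' @export
series_from_measurements <- function(measurements, calibrations = NULL) {
  tcb <- measurements[measurements$kind == "TBL_raw", ]
  split(tcb, tcb$neonate_id) |>
    purrr::map(function(d) {
      d <- d[order(d$time_h), ]
      coeff <- 1
      if (!is.null(calibrations) && d$site_id[1] %in% names(calibrations)) {
        coeff <- calibrations[[d$site_id[1]]]$coefficient
      }
      outs <- d[d$phase == "out", ]
      rets <- d[d$phase == "return", ]
      n <- min(nrow(outs), nrow(rets))
      pre <- d$value_mg_dl[d$phase == "pre"]
      course_series(
        d$neonate_id[1], d$site_id[1],
        baseline_tbl = coeff * (if (length(pre)) pre[1] else outs$value_mg_dl[1]),
        t_out = outs$time_h[seq_len(n)],
        tbl_out = coeff * outs$value_mg_dl[seq_len(n)],
        t_return = rets$time_h[seq_len(n)],
        tbl_return = coeff * rets$value_mg_dl[seq_len(n)]
      )
    })
}

#' Per-cycle return-minus-out deltas
#'
#' `delta_i = tbl_return_i - tbl_out_i` in cycle order. Positive deltas mean
#' the reading rebounds during the treatment break (skin reservoir still
#' charged); negative deltas mean it keeps falling (reservoir depleted).
#'
#' @param series An [course_series()] object.
#' @return Numeric vector of deltas, mg/dL.
#' @export
compute_deltas <- function(series) {
  stopifnot(inherits(series, "srbv_series"))
  if (nrow(series$cycles) == 0) {
    rlang::abort("series has no cycles", class = "srbvkit_invalid_series")
  }
  series$cycles$delta
}

#' Detect the recovery value flip (RVP)
#'
#' The RVP is the point at which the break reading stops rebounding above
#' the session-end reading and becomes consistently lower. Operationally,
#' the flip is the smallest cycle `j >= 2` whose previous delta is
#' non-negative, whose own delta is negative, and whose negative delta
#' starts a run of at least two consecutive negative deltas (or is the final
#' cycle). A single negative excursion does not flip. Courses with baseline
#' at or below 9 mg/dL are classified ineligible (the flip is attenuated at
#' low baselines rather than informative), and courses with fewer than three
#' cycles lack adequate serial data.
#'
#' @param series An [course_series()] object.
#' @return An object of class `srbv_rvp`: list with `neonate_id`, `status`
#'   (`rvp_detected`, `no_flip`, `immediate_decline`,
#'   `ineligible_low_baseline`, `insufficient_data`), `rvp_cycle` (or `NA`),
#'   `deltas`, and `post_rvp_monotone` (whether `tbl_out` is non-increasing
#'   from the flip cycle onward; `NA` unless detected).
#' @export
#' @examples
#' s <- course_series("n1", "s", 14,
#'                    t_out = seq(3, by = 10 / 3, length.out = 5),
#'                    tbl_out = c(12, 11.5, 11, 10.2, 9.6),
#'                    t_return = seq(10 / 3, by = 10 / 3, length.out = 5),
#'                    tbl_return = c(12.9, 11.9, 10.8, 9.7, 8.9))
#' detect_rvp(s)$rvp_cycle # 3
detect_rvp <- function(series) {
  stopifnot(inherits(series, "srbv_series"))
  deltas <- compute_deltas(series)
  n <- length(deltas)
  result <- function(status, cycle = NA_integer_) {
    monotone <- NA
    if (!is.na(cycle)) {
      outs <- series$cycles$tbl_out[cycle:n]
      monotone <- all(diff(outs) <= 0)
    }
    structure(
      list(neonate_id = series$neonate_id, status = status,
           rvp_cycle = cycle, deltas = deltas,
           post_rvp_monotone = monotone),
      class = "srbv_rvp"
    )
  }
  if (series$baseline_tbl <= 9) return(result("ineligible_low_baseline"))
  if (n < 3) return(result("insufficient_data"))
  if (all(deltas < 0)) return(result("immediate_decline"))
  for (j in 2:n) {
    if (deltas[j - 1] >= 0 && deltas[j] < 0) {
      persistent <- (j < n && deltas[j + 1] < 0) || j == n
      if (persistent) return(result("rvp_detected", as.integer(j)))
    }
  }
  result("no_flip")
}

#' Course-level TcB decline rate
#'
#' Least-squares slope of the session-end readings against time, negated so
#' that decline is positive; a net rise comes back negative. An endpoint
#' (two-point) alternative is available since the reporting convention of
#' the summarised cohort is unstated.
#'
#' @param series An [course_series()] object with >= 2 session-end readings.
#' @param method `"ols"` (default) or `"endpoint"`.
#' @return Decline rate, mg/dL/h.
#' @export
decline_rate <- function(series, method = c("ols", "endpoint")) {
  method <- match.arg(method)
  stopifnot(inherits(series, "srbv_series"))
  cy <- series$cycles
  if (nrow(cy) < 2) {
    rlang::abort("need >= 2 session-end readings",
                 class = "srbvkit_invalid_series")
  }
  if (diff(range(cy$t_out)) == 0) {
    rlang::abort("all session-end times identical",
                 class = "srbvkit_invalid_series")
  }
  if (method == "endpoint") {
    n <- nrow(cy)
    return(-(cy$tbl_out[n] - cy$tbl_out[1]) / (cy$t_out[n] - cy$t_out[1]))
  }
  -unname(stats::coef(stats::lm(tbl_out ~ t_out, data = cy))[2])
}

#' Site-level summary of serial TcB behaviour
#'
#' Aggregates, per site: patient count, mean and SD of postnatal age (when
#' available in `ages`), mean pre-treatment TcB, observed TcB range, mean
#' decline rate, and the percentage of courses with an observed flip among
#' those eligible with adequate serial data (baseline above 9 mg/dL and at
#' least three cycles).
#'
#' @param series_list List of [course_series()] objects.
#' @param rvp_results List of [detect_rvp()] results aligned with
#'   `series_list`.
#' @param ages Optional tibble with `neonate_id`, `postnatal_age_days`.
#' @return A tibble with one row per site.
#' @export
summarise_site <- function(series_list, rvp_results, ages = NULL) {
  stopifnot(length(series_list) >= 1,
            length(series_list) == length(rvp_results))
  rows <- purrr::map2_dfr(series_list, rvp_results, function(s, r) {
    tibble::tibble(
      neonate_id = s$neonate_id, site_id = s$site_id,
      baseline_tbl = s$baseline_tbl,
      tbl_min = min(s$cycles$tbl_out, s$cycles$tbl_return, s$baseline_tbl),
      tbl_max = max(s$cycles$tbl_out, s$cycles$tbl_return, s$baseline_tbl),
      decline = if (nrow(s$cycles) >= 2) decline_rate(s) else NA_real_,
      status = r$status
    )
  })
  if (!is.null(ages)) rows <- dplyr::left_join(rows, ages, by = "neonate_id")
  if (!"postnatal_age_days" %in% names(rows)) {
    rows$postnatal_age_days <- NA_real_
  }
  rows |>
    dplyr::group_by(.data$site_id) |>
    dplyr::summarise(
      n_patients = dplyr::n(),
      age_mean = mean(.data$postnatal_age_days),
      age_sd = ifelse(dplyr::n() > 1, stats::sd(.data$postnatal_age_days),
                      NA_real_),
      pre_tbl_mean = mean(.data$baseline_tbl),
      tbl_min = min(.data$tbl_min),
      tbl_max = max(.data$tbl_max),
      decline_rate = mean(.data$decline, na.rm = TRUE),
      n_eligible = sum(.data$status %in%
                         c("rvp_detected", "no_flip", "immediate_decline")),
      rvp_observed_pct = ifelse(
        .data$n_eligible > 0,
        100 * sum(.data$status == "rvp_detected") / .data$n_eligible,
        NA_real_
      ),
      .groups = "drop"
    )
}

#' @export
print.srbv_rvp <- function(x, ...) {
  cat(sprintf("<srbv_rvp> %s: %s%s\n", x$neonate_id, x$status,
              if (!is.na(x$rvp_cycle)) {
                sprintf(" at cycle %d (post-flip monotone: %s)",
                        x$rvp_cycle, x$post_rvp_monotone)
              } else ""))
  invisible(x)
}
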