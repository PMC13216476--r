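#' Interpret a single TcB reading without serial context
#'
#' Below 3 mg/dL the skin holds essentially no residual bilirubin, so the
#' reading reliably approximates serum and can be managed on directly. At or
#' above 3 mg/dL the reading contains a variable SRBV component: it must not
#' be read as a serum equivalent, but since the composite is never below
#' serum it is a safe-side upper bound.
#'
#' @param tbl Calibrated TcB reading, mg/dL, > 0.
#' @return A list with `state`, `action`, `thresholds_used` and `rationale`.
#' @export
#' @examples
#' interpret_single(2.6)$state  # SERUM_EQUIVALENT
#' interpret_single(14)$action  # treat_as_upper_bound
interpret_single <- function(tbl) {
  if (!is.finite(tbl) || tbl <= 0) {
    rlang::abort("`tbl` must be > 0", class = "srbvkit_invalid_reading")
  }
  if (tbl < 3) {
    list(
      state = "SERUM_EQUIVALENT", action = "manage_on_tbl",
      thresholds_used = list(serum_equivalence = 3),
      rationale = sprintf(
        "single-reading: TBL %.1f < 3 mg/dL, negligible SRBV, reading approximates serum",
        tbl
      )
    )
  } else {
    list(
      state = "COMPOSITE_UNRESOLVED", action = "treat_as_upper_bound",
      thresholds_used = list(serum_equivalence = 3),
      rationale = sprintf(
        "single-reading: TBL %.1f >= 3 mg/dL, variable SRBV component, treat as upper bound on serum",
        tbl
      )
    )
  }
}

conservatism_rank <- c(
  continue_therapy = 4, treat_as_upper_bound = 3, monitor_trend = 2,
  discharge_eligible = 1, manage_on_tbl = 0
)

#' SRBV-adjusted interpretation of a serial treatment course
#'
#' Deterministic first-match-wins rule cascade over the serial paired
#' readings and the flip-detection result, ordered most conservative first:
#'
#' 1. Latest break reading below 3 mg/dL: the reading is serum-equivalent;
#'    manage on it directly.
#' 2. No flip detected and the latest delta is non-negative (a delta of
#'    exactly zero counts as persistence, conservatively): the skin
#'    reservoir persists; continue therapy.
#' 3. Flip detected but the latest session-end reading is at or above the
#'    discharge threshold, or the post-flip trend is not monotone: the flip
#'    has been reached; prioritise the trend over absolute values and keep
#'    monitoring.
#' 4. Flip detected, monotone post-flip decline, latest session-end reading
#'    below the discharge threshold: recovery confirmed; discharge eligible.
#' 5. Otherwise the composite cannot be resolved; treat the reading as an
#'    upper bound on serum.
#'
#' @param series An [course_series()] object.
#' @param rvp The [detect_rvp()] result for the same series.
#' @param discharge_threshold Discharge decision threshold, mg/dL
#'   (default 11; exposed because it is a study question, not a universal
#'   cut-off).
#' @return A list with `state`, `action`, `thresholds_used` and `rationale`
#'   (every evaluated rule, in order, with the values that fired or passed).
#' @export
interpret_course <- function(series, rvp, discharge_threshold = 11) {
  stopifnot(inherits(series, "srbv_series"), inherits(rvp, "srbv_rvp"))
  if (series$neonate_id != rvp$neonate_id) {
    rlang::abort("series and RVP result belong to different neonates",
                 class = "srbvkit_mismatched_inputs")
  }
  cy <- series$cycles
  if (nrow(cy) == 0) {
    rlang::abort("series has no cycles", class = "srbvkit_invalid_series")
  }
  latest_return <- cy$tbl_return[nrow(cy)]
  latest_out <- cy$tbl_out[nrow(cy)]
  latest_delta <- cy$delta[nrow(cy)]
  detected <- rvp$status == "rvp_detected"
  trace <- character(0)
  note <- function(txt) trace <<- c(trace, txt)
  thresholds <- list(serum_equivalence = 3, discharge = discharge_threshold)
  out <- function(state, action) {
    list(state = state, action = action, thresholds_used = thresholds,
         rationale = trace)
  }

  note(sprintf("rule1 latest TBL-return %.2f < 3? %s", latest_return,
               latest_return < 3))
  if (latest_return < 3) return(out("SERUM_EQUIVALENT", "manage_on_tbl"))

  note(sprintf("rule2 no flip (%s) and latest delta %+.2f >= 0? %s",
               rvp$status, latest_delta, !detected && latest_delta >= 0))
  if (!detected && latest_delta >= 0) {
    return(out("SRBV_PERSISTENT", "continue_therapy"))
  }

  note(sprintf(
    "rule3 flip detected (%s) and (latest TBL-out %.2f >= %.1f or post-flip not monotone (%s))? %s",
    detected, latest_out, discharge_threshold,
    detected && !isTRUE(rvp$post_rvp_monotone),
    detected && (latest_out >= discharge_threshold ||
                   !isTRUE(rvp$post_rvp_monotone))
  ))
  if (detected && (latest_out >= discharge_threshold ||
                     !isTRUE(rvp$post_rvp_monotone))) {
    return(out("RVP_REACHED", "monitor_trend"))
  }

  note(sprintf(
    "rule4 flip detected, monotone decline, latest TBL-out %.2f < %.1f? %s",
    latest_out, discharge_threshold,
    detected && isTRUE(rvp$post_rvp_monotone) &&
      latest_out < discharge_threshold
  ))
  if (detected && isTRUE(rvp$post_rvp_monotone) &&
        latest_out < discharge_threshold) {
    return(out("RECOVERY_CONFIRMED", "discharge_eligible"))
  }

  note("rule5 fallback: composite unresolved, treat as upper bound")
  out("COMPOSITE_UNRESOLVED", "treat_as_upper_bound")
}

#' Batch interpretation of a cohort
#'
#' @param series_list Named or unnamed list of [course_series()] objects
#'   with unique neonate ids.
#' @param rvp_results Aligned list of [detect_rvp()] results.
#' @param discharge_threshold Passed to [interpret_course()].
#' @return A tibble ordered by `neonate_id` with `state`, `action` and a
#'   collapsed `rationale` string.
#' @export
batch_interpret <- function(series_list, rvp_results,
                            discharge_threshold = 11) {
  stopifnot(length(series_list) == length(rvp_results))
  if (length(series_list) == 0) {
    return(tibble::tibble(neonate_id = character(), state = character(),
                          action = character(), rationale = character()))
  }
  ids <- vapply(series_list, function(s) s$neonate_id, character(1))
  if (anyDuplicated(ids)) {
    rlang::abort("duplicate neonate_id in batch",
                 class = "srbvkit_mismatched_inputs")
  }
  rows <- purrr::map2_dfr(series_list, rvp_results, function(s, r) {
    res <- interpret_course(s, r, discharge_threshold)
    tibble::tibble(neonate_id = s$neonate_id, site_id = s$site_id,
                   state = res$state, action = res$action,
                   rationale = paste(res$rationale, collapse = " | "))
  })
  dplyr::arrange(rows, .data$neonate_id)
}
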