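#' Round half away from zero
#'
#' Display rounding used for percentage cells (base R's `round()` rounds
#' half to even).
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Assign a bilirubin severity band
#'
#' Bands follow the reporting convention of the band-by-stage SRBV table:
#' `lt9` is `[0, 9)`, `b9_115` is `[9, 11.5]`, `b116_15` is `(11.5, 15]`
#' and `gt15` is `(15, Inf)`. Readings are conventionally recorded to
#' 0.1 mg/dL, so the `[9, 11.5]` vs `(11.5, 15]` boundary is lossless on
#' recorded data; for continuous simulated values the half-open convention
#' above applies.
#'
#' @param tbl Calibrated TcB values, mg/dL, all > 0.
#' @return Factor with levels `lt9`, `b9_115`, `b116_15`, `gt15`.
#' @export
#' @examples
#' assign_band(c(8.9, 9, 11.5, 11.55, 30.4))
assign_band <- function(tbl) {
  if (any(!is.finite(tbl)) || any(tbl <= 0)) {
    rlang::abort("`tbl` must be positive and finite",
                 class = "srbvkit_invalid_reading")
  }
  cut(tbl, breaks = c(0, 9, 11.5, 15, Inf),
      labels = c("lt9", "b9_115", "b116_15", "gt15"),
      right = FALSE) -> b
  # cut(right = FALSE) puts 11.5 in the upper band; the table's headers put
  # 11.5 with the 9-11.5 band and 15 with the 11.6-15 band, so use explicit
  # half-open-on-the-left intervals instead
  factor(
    dplyr::case_when(
      tbl < 9 ~ "lt9",
      tbl <= 11.5 ~ "b9_115",
      tbl <= 15 ~ "b116_15",
      TRUE ~ "gt15"
    ),
    levels = c("lt9", "b9_115", "b116_15", "gt15")
  )
}

#' Compute skin residual bilirubin volume records
#'
#' For each paired observation, SRBV is the difference between the
#' calibrated TcB reading and the laboratory serum value,
#' `srbv = tbl - tsb`, and its fractional contribution is `srbv / tbl`.
#' Negative SRBV (device reading below serum) is physiologically possible
#' but treated as artefact in the composite model: such records are retained
#' and flagged, and excluded from fraction summaries.
#'
#' @param pairs Data frame with columns `neonate_id`, `site_id`, `stage`
#'   (`pre_treatment`, `mid_treatment` or `end_treatment`), `tbl`
#'   (calibrated, mg/dL) and `tsb` (mg/dL).
#' @return The input with added columns `srbv`, `srbv_fraction`, `band`
#'   (from `tbl`) and `negative_flag`.
#' @export
#' @examples
#' compute_srbv(data.frame(neonate_id = "n1", site_id = "s",
#'                         stage = "pre_treatment", tbl = 10, tsb = 8))
compute_srbv <- function(pairs) {
  stopifnot(is.data.frame(pairs),
            all(c("neonate_id", "site_id", "stage", "tbl", "tsb") %in%
                  names(pairs)))
  if (any(!is.finite(pairs$tbl)) || any(pairs$tbl <= 0) ||
      any(!is.finite(pairs$tsb)) || any(pairs$tsb <= 0)) {
    rlang::abort("`tbl` and `tsb` must be positive and finite",
                 class = "srbvkit_invalid_reading")
  }
  dplyr::mutate(
    tibble::as_tibble(pairs),
    srbv = .data$tbl - .data$tsb,
    negative_flag = .data$srbv < 0,
    srbv_fraction = ifelse(.data$negative_flag, NA_real_,
                           .data$srbv / .data$tbl),
    band = assign_band(.data$tbl)
  )
}

#' Summarise SRBV fractions by site, stage and severity band
#'
#' Per `(site_id, stage, band)` cell: mean and SD of the SRBV fractions over
#' non-negative records, and the pair count. Cells without data are emitted
#' as `NA` (`n = 0`). `mean_pct` carries full precision;
#' `mean_pct_display` is rounded half-up to integer percent as in the
#' published table.
#'
#' @param records Output of [compute_srbv()].
#' @return A tibble with columns `site_id`, `stage`, `band`, `mean_pct`,
#'   `mean_pct_display`, `sd_fraction`, `n`, `n_negative_excluded`.
#' @export
summarise_bands <- function(records) {
  if (nrow(records) == 0) {
    return(tibble::tibble(
      site_id = character(), stage = character(), band = character(),
      mean_pct = double(), mean_pct_display = double(),
      sd_fraction = double(), n = integer(), n_negative_excluded = integer()
    ))
  }
  grid <- tidyr::expand_grid(
    site_id = unique(records$site_id),
    stage = unique(records$stage),
    band = levels(records$band)
  )
  cells <- records |>
    dplyr::group_by(.data$site_id, .data$stage, band = as.character(.data$band)) |>
    dplyr::summarise(
      mean_pct = 100 * mean(.data$srbv_fraction[!.data$negative_flag]),
      sd_fraction = ifelse(sum(!.data$negative_flag) > 1,
                           stats::sd(.data$srbv_fraction[!.data$negative_flag]),
                           0),
      n = sum(!.data$negative_flag),
      n_negative_excluded = sum(.data$negative_flag),
      .groups = "drop"
    )
  out <- dplyr::left_join(grid, cells, by = c("site_id", "stage", "band")) |>
    dplyr::mutate(
      n = dplyr::coalesce(.data$n, 0L),
      n_negative_excluded = dplyr::coalesce(.data$n_negative_excluded, 0L),
      mean_pct = ifelse(.data$n == 0, NA_real_, .data$mean_pct),
      mean_pct_display = round_half_up(.data$mean_pct)
    )
  dplyr::relocate(out, "mean_pct", "mean_pct_display", "sd_fraction",
                  .after = "band")
}

#' Average band summaries across sites
#'
#' Unweighted arithmetic mean of the site-level mean percentages per
#' (stage, band) cell, the construction that reproduces the published
#' end-treatment "Average" row exactly (weighting by pair count does not,
#' because counts differ across sites). `NA` site cells are skipped; a cell
#' that is `NA` at every site stays `NA`.
#'
#' @param summaries Output of [summarise_bands()] (or any tibble with
#'   `site_id`, `stage`, `band`, `mean_pct`).
#' @return A tibble with `site_id = "Average"`, one row per (stage, band),
#'   with full-precision `mean_pct` and half-up integer `mean_pct_display`.
#' @export
#' @examples
#' cells <- data.frame(site_id = c("a", "b"), stage = "end_treatment",
#'                     band = "lt9", mean_pct = c(17, 21))
#' average_across_sites(cells)$mean_pct_display # 19
average_across_sites <- function(summaries) {
  stopifnot(all(c("site_id", "stage", "band", "mean_pct") %in%
                  names(summaries)))
  summaries |>
    dplyr::group_by(.data$stage, .data$band) |>
    dplyr::summarise(
      n_sites = sum(!is.na(.data$mean_pct)),
      mean_pct = if (all(is.na(.data$mean_pct))) NA_real_ else
        mean(.data$mean_pct, na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::mutate(site_id = "Average",
                  mean_pct_display = round_half_up(.data$mean_pct)) |>
    dplyr::relocate("site_id")
}

#' Extract paired TcB/TSB observations from simulated courses
#'
#' Pulls the protocol's paired observations out of simulated courses: the
#' pre-treatment, mid-course and course-end laboratory TSB samples, each
#' paired with the TcB reading taken at the same instant. Raw device
#' readings are calibrated with the site's coefficient before pairing when
#' calibration models are supplied.
#'
#' @param courses A single `srbv_course`, a list of them, or a long-format
#'   measurement tibble (as from [measurements_frame()] or
#'   [read_measurements()]), in which case each TSB row is paired with the
#'   TcB reading taken at the same time.
#' @param calibrations Optional named list (by `site_id`) of
#'   `srbv_calibration` models; omitted sites use coefficient 1.
#' @return A tibble suitable for [compute_srbv()]: `neonate_id`, `site_id`,
#'   `stage`, `tbl`, `tsb`.
#' @export
paired_stage_measurements <- function(courses, calibrations = NULL) {
  if (is.data.frame(courses)) {
    return(pair_stages_from_frame(courses, calibrations))
  }
  if (inherits(courses, "srbv_course")) courses <- list(courses)
  purrr::map_dfr(courses, function(co) {
    m <- co$measurements
    tsb <- m[m$kind == "TSB", ]
    coeff <- 1
    if (!is.null(calibrations) && co$profile$site_id %in% names(calibrations)) {
      coeff <- calibrations[[co$profile$site_id]]$coefficient
    }
    tcb <- m[m$kind == "TBL_raw", ]
    tbl_at <- vapply(tsb$time_h, function(tt) {
      coeff * tcb$value[which.min(abs(tcb$time_h - tt))]
    }, numeric(1))
    tibble::tibble(
      neonate_id = co$profile$neonate_id,
      site_id = co$profile$site_id,
      stage = paste0(tsb$phase, "_treatment"),
      tbl = tbl_at,
      tsb = tsb$value
    )
  })
}

pair_stages_from_frame <- function(measurements, calibrations = NULL) {
  split(measurements, measurements$neonate_id) |>
    purrr::map_dfr(function(d) {
      tsb <- d[d$kind == "TSB", ]
      tcb <- d[d$kind == "TBL_raw", ]
      if (nrow(tsb) == 0 || nrow(tcb) == 0) return(NULL)
      coeff <- 1
      if (!is.null(calibrations) && d$site_id[1] %in% names(calibrations)) {
        coeff <- calibrations[[d$site_id[1]]]$coefficient
      }
      tbl_at <- vapply(tsb$time_h, function(tt) {
        coeff * tcb$value_mg_dl[which.min(abs(tcb$time_h - tt))]
      }, numeric(1))
      tibble::tibble(
        neonate_id = d$neonate_id[1], site_id = d$site_id[1],
        stage = paste0(tsb$phase, "_treatment"),
        tbl = tbl_at, tsb = tsb$value_mg_dl
      )
    })
}
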