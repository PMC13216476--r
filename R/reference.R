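#' Published site-level cohort characteristics
#'
#' Site-level summaries of the six-centre observational cohort of neonates
#' treated with intermittent phototherapy in southeastern Nigeria that
#' motivates this package: per-site patient counts, postnatal age, mean
#' pre-treatment transcutaneous bilirubin level (TBL), the observed TBL
#' range, mean TBL decline rate, and the proportion of cases in which the
#' recovery value flip (RVP) was observed.
#'
#' These printed summaries are the reference the synthetic cohort generator
#' emulates and the anchor for the package's bookkeeping checks.
#'
#' @return A tibble with one row per site.
#' @export
#' @examples
#' sum(reference_site_table()$n_patients) # 102 neonates in total
reference_site_table <- function() {
  tibble::tribble(
    ~site_id,       ~n_patients, ~age_mean, ~age_sd, ~pre_tbl_mean, ~tbl_min, ~tbl_max, ~decline_rate, ~tsb_availability, ~rvp_observed_pct,
    "BSH Nsukka",    23L,         5.7,       2.4,     14.03,         10.0,     28.0,     0.27,          "Complete",        91,
    "SPH Abakaliki", 23L,         3.8,       1.6,     12.37,         8.9,      18.4,     0.52,          "Limited",         100,
    "MJH Okigwe",    10L,         5.7,       3.3,     12.29,         10.4,     14.9,     0.23,          "Limited",         100,
    "IHH Urualla",   20L,         2.7,       2.1,     8.97,          6.8,      14.3,     0.21,          "Limited",         71,
    "MCH Enugu",     13L,         3.8,       1.8,     16.33,         10.7,     23.5,     0.18,          "Partial",         92,
    "IHMH Nkpor",    13L,         3.7,       2.2,     15.22,         8.3,      30.4,     0.18,          "Complete",        100
  )
}

#' Published SRBV fractions by severity band and treatment stage
#'
#' Site-level mean percentage contribution of skin residual bilirubin volume
#' (SRBV) to the measured TBL, stratified by bilirubin severity band and
#' treatment stage, as printed for the three centres with paired laboratory
#' data. `mean_pct` is the printed integer percentage and `sd` the printed
#' standard deviation of the fractions; `NA` cells are bands with no data
#' captured.
#'
#' @return A tibble with one row per (site, stage, band) cell.
#' @export
reference_srbv_table <- function() {
  tibble::tribble(
    ~site_id,      ~stage,           ~band,      ~mean_pct, ~sd,
    "BSH Nsukka",  "pre_treatment",  "lt9",      NA,        NA,
    "BSH Nsukka",  "pre_treatment",  "b9_115",   30,        0.02,
    "BSH Nsukka",  "pre_treatment",  "b116_15",  9,         0.04,
    "BSH Nsukka",  "end_treatment",  "lt9",      17,        0.09,
    "BSH Nsukka",  "end_treatment",  "b9_115",   27,        0.07,
    "BSH Nsukka",  "end_treatment",  "b116_15",  24,        0.03,
    "MCH Enugu",   "pre_treatment",  "lt9",      NA,        NA,
    "MCH Enugu",   "pre_treatment",  "b9_115",   11,        0.02,
    "MCH Enugu",   "pre_treatment",  "b116_15",  12,        0.05,
    "MCH Enugu",   "end_treatment",  "lt9",      NA,        NA,
    "MCH Enugu",   "end_treatment",  "b9_115",   NA,        NA,
    "MCH Enugu",   "end_treatment",  "b116_15",  NA,        NA,
    "IHMH Nkpor",  "pre_treatment",  "lt9",      NA,        NA,
    "IHMH Nkpor",  "pre_treatment",  "b9_115",   NA,        NA,
    "IHMH Nkpor",  "pre_treatment",  "b116_15",  NA,        NA,
    "IHMH Nkpor",  "end_treatment",  "lt9",      21,        0.05,
    "IHMH Nkpor",  "end_treatment",  "b9_115",   11,        0.04,
    "IHMH Nkpor",  "end_treatment",  "b116_15",  28,        0.03
  )
}

#' Published cohort-average SRBV percentages
#'
#' The printed "Average" row of the band-by-stage SRBV table. The
#' pre-treatment cells (20% and 11%) are not reproducible from the printed
#' site cells under any single rounding rule (the site cells average to 20.5
#' and 10.5); the end-treatment cells are exact unweighted means. See the
#' methods vignette for the discrepancy analysis.
#'
#' @return A tibble with one row per (stage, band) cell.
#' @export
reference_srbv_average <- function() {
  tibble::tribble(
    ~stage,          ~band,      ~mean_pct,
    "pre_treatment", "lt9",      NA,
    "pre_treatment", "b9_115",   20,
    "pre_treatment", "b116_15",  11,
    "end_treatment", "lt9",      19,
    "end_treatment", "b9_115",   19,
    "end_treatment", "b116_15",  26
  )
}
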