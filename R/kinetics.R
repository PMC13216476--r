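#' Two-compartment bilirubin kinetic parameters
#'
#' Parameters of the serum/skin exchange model that drives the synthetic
#' cohort generator. Serum bilirubin `S` (mg/dL) receives endogenous
#' production, loses to hepatic/excretory clearance and (during phototherapy
#' sessions) to light-driven clearance, and exchanges with a cutaneous
#' compartment `K` (mg/dL serum-equivalent). Extravasation into the skin only
#' occurs above a serum threshold: the forward flux is
#' `serum_to_skin * max(S - skin_threshold, 0)`, so that at low bilirubin
#' levels bilirubin stays intravascular and the transcutaneous reading
#' approximates serum. Setting `skin_threshold = 0` recovers plain linear
#' first-order exchange.
#'
#' The TcB optics report a fraction `optical_gain` of the skin compartment on
#' top of serum, so the true composite signal is
#' `TBL_true = S + optical_gain * K` and the skin residual bilirubin volume
#' is `SRBV = optical_gain * K`.
#'
#' @param production_rate Endogenous bilirubin input to serum, mg/dL/h.
#' @param serum_clearance Hepatic/excretory elimination rate from serum, 1/h.
#' @param serum_to_skin Forward diffusion rate into the cutaneous
#'   compartment, 1/h (applied to serum above `skin_threshold`).
#' @param skin_to_serum Back-diffusion rate from skin to serum, 1/h.
#' @param photo_clearance Light-driven removal from serum during phototherapy
#'   sessions, 1/h. The measurement site is shielded by the eyepatch during
#'   sessions, so the skin compartment is never photo-bleached directly.
#' @param optical_gain Fraction of the skin compartment reported by the TcB
#'   optics, dimensionless in `[0, 1]`.
#' @param skin_threshold Serum level above which bilirubin extravasates into
#'   the skin, mg/dL. Default 8, consistent with skin bilirubin being
#'   undetectable pre-treatment below roughly 9 mg/dL.
#'
#' @return An object of class `srbv_kinetics`.
#' @export
#' @examples
#' kinetic_params()
#' kinetic_params(serum_to_skin = 0, optical_gain = 0) # pure serum model
kinetic_params <- function(production_rate = 0.03,
                           serum_clearance = 0.07,
                           serum_to_skin = 2.5,
                           skin_to_serum = 0.5,
                           photo_clearance = 0.12,
                           optical_gain = 0.12,
                           skin_threshold = 8) {
  rates <- c(
    production_rate = production_rate, serum_clearance = serum_clearance,
    serum_to_skin = serum_to_skin, skin_to_serum = skin_to_serum,
    photo_clearance = photo_clearance, skin_threshold = skin_threshold
  )
  if (any(!is.finite(rates)) || any(rates < 0)) {
    rlang::abort("all kinetic rates must be finite and >= 0",
                 class = "srbvkit_invalid_kinetics")
  }
  if (!is.finite(optical_gain) || optical_gain < 0 || optical_gain > 1) {
    rlang::abort("`optical_gain` must lie in [0, 1]",
                 class = "srbvkit_invalid_kinetics")
  }
  if (serum_to_skin > 0 && skin_to_serum <= 0) {
    rlang::abort("`skin_to_serum` must be > 0 whenever `serum_to_skin` > 0",
                 class = "srbvkit_invalid_kinetics")
  }
  structure(
    list(
      production_rate = production_rate,
      serum_clearance = serum_clearance,
      serum_to_skin = serum_to_skin,
      skin_to_serum = skin_to_serum,
      photo_clearance = photo_clearance,
      optical_gain = optical_gain,
      skin_threshold = skin_threshold
    ),
    class = "srbv_kinetics"
  )
}

#' Intermittent phototherapy schedule
#'
#' Phototherapy is delivered as continuous light sessions separated by short
#' breaks for feeding and rehydration. The default protocol is 3-hour
#' sessions separated by 20-minute (1/3 h) breaks.
#'
#' @param session_hours Duration of one light session, hours.
#' @param break_hours Duration of the break after each session, hours.
#' @param n_cycles Number of session + break cycles.
#'
#' @return An object of class `srbv_schedule`.
#' @export
phototherapy_schedule <- function(session_hours = 3,
                                  break_hours = 1 / 3,
                                  n_cycles = 8L) {
  if (!is.finite(session_hours) || session_hours <= 0 ||
      !is.finite(break_hours) || break_hours <= 0) {
    rlang::abort("session and break durations must be > 0",
                 class = "srbvkit_invalid_schedule")
  }
  n_cycles <- as.integer(n_cycles)
  if (is.na(n_cycles) || n_cycles < 1L) {
    rlang::abort("`n_cycles` must be >= 1", class = "srbvkit_invalid_schedule")
  }
  structure(
    list(session_hours = session_hours, break_hours = break_hours,
         n_cycles = n_cycles),
    class = "srbv_schedule"
  )
}

#' Neonate profile for the synthetic cohort
#'
#' @param neonate_id,site_id Opaque identifiers.
#' @param postnatal_age_days Postnatal age at presentation, days.
#' @param baseline_serum Pre-treatment serum bilirubin, mg/dL.
#' @param kinetics A [kinetic_params()] object.
#' @param device_gain Multiplicative raw-device bias of the site's TcB meter
#'   (the bias that centre-specific calibration corrects), dimensionless.
#'
#' @return An object of class `srbv_profile`.
#' @export
neonate_profile <- function(neonate_id,
                            site_id = "site-1",
                            postnatal_age_days = 4,
                            baseline_serum = 11,
                            kinetics = kinetic_params(),
                            device_gain = 1) {
  stopifnot(inherits(kinetics, "srbv_kinetics"))
  if (!is.finite(baseline_serum) || baseline_serum <= 0) {
    rlang::abort("`baseline_serum` must be > 0",
                 class = "srbvkit_invalid_profile")
  }
  if (!is.finite(device_gain) || device_gain <= 0) {
    rlang::abort("`device_gain` must be > 0",
                 class = "srbvkit_invalid_profile")
  }
  structure(
    list(
      neonate_id = as.character(neonate_id),
      site_id = as.character(site_id),
      postnatal_age_days = postnatal_age_days,
      baseline_serum = baseline_serum,
      kinetics = kinetics,
      device_gain = device_gain
    ),
    class = "srbv_profile"
  )
}

#' Multiplicative measurement noise model
#'
#' Reading noise is multiplicative log-normal, parameterised by a coefficient
#' of variation, which keeps simulated readings positive and mean-unbiased:
#' a reading is `true * exp(z * sdlog - sdlog^2 / 2)` with
#' `sdlog = sqrt(log(1 + cv^2))`.
#'
#' Defaults reflect repeatability-level noise of a handheld TcB meter
#' (about +/-0.2 mg/dL at 10 mg/dL) and routine laboratory bilirubin assay
#' variability.
#'
#' @param tcb_cv Coefficient of variation of TcB readings.
#' @param tsb_cv Coefficient of variation of laboratory TSB values.
#' @param seed Integer seed; identical seed and parameters give identical
#'   simulated output.
#'
#' @return An object of class `srbv_noise`.
#' @export
noise_model <- function(tcb_cv = 0.02, tsb_cv = 0.03, seed = 1L) {
  if (any(!is.finite(c(tcb_cv, tsb_cv))) || tcb_cv < 0 || tsb_cv < 0) {
    rlang::abort("noise CVs must be finite and >= 0",
                 class = "srbvkit_invalid_noise")
  }
  structure(
    list(tcb_cv = tcb_cv, tsb_cv = tsb_cv, seed = as.integer(seed)),
    class = "srbv_noise"
  )
}

# multiplicative lognormal factors with mean exactly 1 (cv = 0 -> exactly 1)
noise_factor <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, 0, sdlog) - sdlog^2 / 2)
}

# deterministic per-neonate RNG substream derived from (seed, id)
id_seed <- function(seed, id) {
  h <- 0
  for (ch in utf8ToInt(as.character(id))) h <- (h * 31 + ch) %% 1977326743
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

#' Serum level consistent with a target pre-treatment TcB reading
#'
#' Inverts the composite relation `TBL = S + g * (f/b) * max(S - theta, 0)`
#' at the pre-treatment skin equilibrium, so cohorts can be specified by
#' their (observable) baseline TcB rather than by latent serum.
#'
#' @param tbl Target true composite TcB level, mg/dL.
#' @param kinetics A [kinetic_params()] object.
#' @return Serum bilirubin, mg/dL.
#' @export
serum_for_baseline_tbl <- function(tbl, kinetics = kinetic_params()) {
  gr <- with(kinetics, optical_gain * serum_to_skin /
               max(skin_to_serum, .Machine$double.eps))
  theta <- kinetics$skin_threshold
  ifelse(tbl <= theta, tbl, (tbl + gr * theta) / (1 + gr))
}
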