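#' Simulate one phototherapy treatment course
#'
#' Integrates the two-compartment serum/skin model over an intermittent
#' phototherapy schedule and emits the measurement events of the monitoring
#' protocol: a pre-treatment TcB reading, a TcB reading at the end of every
#' session (`TBL-out`) and at the end of every break (`TBL-return`), and
#' laboratory TSB samples pre-treatment, once mid-course, and at course end.
#'
#' The dynamics are
#' \deqn{dS/dt = p - (c_S + \phi(t)) S - f \max(S - \theta, 0) + b K}
#' \deqn{dK/dt = f \max(S - \theta, 0) - b K}
#' with `phi(t)` equal to `photo_clearance` during light sessions and 0
#' during breaks (the measurement site is shielded by the eyepatch, so the
#' skin compartment is never photo-bleached directly). The true composite
#' TcB signal is `TBL_true = S + optical_gain * K`; the raw device reading
#' multiplies it by the site's `device_gain` and a multiplicative noise
#' factor, and laboratory TSB is `S` times its own noise factor.
#'
#' The skin compartment starts at its pre-treatment equilibrium
#' `K0 = (f/b) * max(S0 - theta, 0)`.
#'
#' @param profile A [neonate_profile()].
#' @param schedule A [phototherapy_schedule()].
#' @param noise A [noise_model()]. The per-course random stream is derived
#'   deterministically from `noise$seed` and the neonate id, and the global
#'   RNG state is left untouched.
#' @param mid_frac Fraction of total course time at which the mid-course TSB
#'   sample is drawn; the sample lands on the nearest break-end boundary so
#'   it pairs with a `TBL-return` reading. The protocol only fixes the sample
#'   to "mid-treatment", so the timing is exposed as a parameter.
#' @param grid_step Output grid spacing for the stored trajectories, hours.
#'
#' @return An object of class `srbv_course`: a list with the profile,
#'   schedule, dense `times`, `serum` and `skin` trajectories, per-point
#'   `phase` labels (`"session"`/`"break"`), and a `measurements` tibble with
#'   columns `time_h`, `phase` (`pre`/`out`/`return`/`mid`/`end`), `kind`
#'   (`TBL_raw`/`TSB`), `value_true` and `value`.
#' @export
#' @examples
#' prof <- neonate_profile("n1", baseline_serum = 11.5)
#' course <- simulate_course(prof, phototherapy_schedule(n_cycles = 5),
#'                           noise_model(tcb_cv = 0, tsb_cv = 0))
#' subset(course$measurements, phase %in% c("out", "return"))
simulate_course <- function(profile,
                            schedule = phototherapy_schedule(),
                            noise = noise_model(),
                            mid_frac = 0.5,
                            grid_step = 1 / 30) {
  stopifnot(inherits(profile, "srbv_profile"),
            inherits(schedule, "srbv_schedule"),
            inherits(noise, "srbv_noise"))
  kin <- profile$kinetics

  S0 <- profile$baseline_serum
  K0 <- with(kin, serum_to_skin / max(skin_to_serum, .Machine$double.eps) *
               max(S0 - skin_threshold, 0))
  if (kin$serum_to_skin == 0) K0 <- 0

  deriv <- function(t, state, parms) {
    S <- state[[1]]; K <- state[[2]]
    flux <- kin$serum_to_skin * max(S - kin$skin_threshold, 0)
    phi <- if (parms$session) kin$photo_clearance else 0
    dS <- kin$production_rate - (kin$serum_clearance + phi) * S - flux +
      kin$skin_to_serum * K
    dK <- flux - kin$skin_to_serum * K
    list(c(dS, dK))
  }

  atol <- 1e-8
  times <- numeric(0); serum <- numeric(0); skin <- numeric(0)
  phase <- character(0)
  t_out <- numeric(0); t_return <- numeric(0)
  state <- c(S = S0, K = K0)
  t0 <- 0

  for (cyc in seq_len(schedule$n_cycles)) {
    for (ph in c("session", "break")) {
      dur <- if (ph == "session") schedule$session_hours else schedule$break_hours
      grid <- unique(c(seq(t0, t0 + dur, by = grid_step), t0 + dur))
      sol <- deSolve::lsoda(state, grid, deriv,
                            parms = list(session = ph == "session"),
                            rtol = 1e-8, atol = atol)
      if (any(!is.finite(sol[, 2:3]))) {
        rlang::abort("kinetic integration produced non-finite trajectories",
                     class = "srbvkit_integration_failure")
      }
      neg <- pmin(sol[, 2:3], 0)
      if (any(neg < -100 * atol)) {
        rlang::abort("kinetic integration produced negative concentrations",
                     class = "srbvkit_integration_failure")
      }
      if (any(neg < 0)) {
        rlang::warn("trajectory clipped at 0 (within solver tolerance)")
        sol[, 2:3] <- pmax(sol[, 2:3], 0)
      }
      keep <- if (length(times) == 0) seq_len(nrow(sol)) else -1L
      times <- c(times, sol[keep, 1])
      serum <- c(serum, sol[keep, 2])
      skin <- c(skin, sol[keep, 3])
      phase <- c(phase, rep(ph, length(sol[keep, 1])))
      state <- c(S = sol[nrow(sol), 2], K = sol[nrow(sol), 3])
      t0 <- t0 + dur
      if (ph == "session") t_out <- c(t_out, t0) else t_return <- c(t_return, t0)
    }
  }

  tbl_true_at <- function(tt) {
    i <- vapply(tt, function(x) which.min(abs(times - x)), integer(1))
    serum[i] + kin$optical_gain * skin[i]
  }
  serum_at <- function(tt) {
    i <- vapply(tt, function(x) which.min(abs(times - x)), integer(1))
    serum[i]
  }

  # measurement plan: TcB at t = 0 (pre) and every session/break boundary;
  # TSB at pre, the break end nearest mid_frac of the course, and course end
  t_end <- max(times)
  t_mid <- t_return[which.min(abs(t_return - mid_frac * t_end))]
  tcb_times <- c(0, t_out, t_return)
  tcb_phase <- c("pre", rep("out", length(t_out)), rep("return", length(t_return)))
  tsb_times <- c(0, t_mid, t_end)
  tsb_phase <- c("pre", "mid", "end")

  old_seed <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(id_seed(noise$seed, profile$neonate_id))

  tcb_true <- tbl_true_at(tcb_times)
  tcb_obs <- profile$device_gain * tcb_true * noise_factor(length(tcb_true), noise$tcb_cv)
  tsb_true <- serum_at(tsb_times)
  tsb_obs <- tsb_true * noise_factor(length(tsb_true), noise$tsb_cv)

  measurements <- tibble::tibble(
    time_h = c(tcb_times, tsb_times),
    phase = c(tcb_phase, tsb_phase),
    kind = c(rep("TBL_raw", length(tcb_times)), rep("TSB", length(tsb_times))),
    value_true = c(tcb_true, tsb_true),
    value = c(tcb_obs, tsb_obs)
  )
  measurements <- measurements[order(measurements$time_h, measurements$kind), ]

  structure(
    list(profile = profile, schedule = schedule, noise = noise,
         times = times, serum = serum, skin = skin, phase = phase,
         measurements = measurements),
    class = "srbv_course"
  )
}

#' Long-format measurement table for one or more simulated courses
#'
#' @param courses A single `srbv_course` or a list of them.
#' @return A tibble with columns `neonate_id`, `site_id`, `time_h`, `phase`,
#'   `kind`, `value_mg_dl` (the observed value, raw device scale for TcB).
#' @export
measurements_frame <- function(courses) {
  if (inherits(courses, "srbv_course")) courses <- list(courses)
  purrr::map_dfr(courses, function(co) {
    tibble::tibble(
      neonate_id = co$profile$neonate_id,
      site_id = co$profile$site_id,
      time_h = co$measurements$time_h,
      phase = co$measurements$phase,
      kind = co$measurements$kind,
      value_mg_dl = co$measurements$value
    )
  })
}

#' @export
print.srbv_course <- function(x, ...) {
  cat(sprintf(
    "<srbv_course> %s @ %s: baseline S0 = %.2f mg/dL, %d cycles, %d measurements\n",
    x$profile$neonate_id, x$profile$site_id, x$profile$baseline_serum,
    x$schedule$n_cycles, nrow(x$measurements)
  ))
  invisible(x)
}
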