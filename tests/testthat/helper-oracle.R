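# Independent fixed-step Euler oracle over the same two-compartment model,
# written directly from the model equations (no calls into the package's
# integration path). Returns boundary values of serum, skin and composite
# signal at every session end and break end.
euler_course <- function(baseline_serum, kin, n_cycles,
                         session_hours = 3, break_hours = 1 / 3,
                         dt = 0.005) {
  S <- baseline_serum
  K <- if (kin$serum_to_skin > 0) {
    kin$serum_to_skin / kin$skin_to_serum *
      max(baseline_serum - kin$skin_threshold, 0)
  } else 0
  out <- list(
    t_out = numeric(n_cycles), t_return = numeric(n_cycles),
    S_out = numeric(n_cycles), K_out = numeric(n_cycles),
    S_return = numeric(n_cycles), K_return = numeric(n_cycles)
  )
  t <- 0
  for (cyc in seq_len(n_cycles)) {
    for (ph in c("session", "break")) {
      dur <- if (ph == "session") session_hours else break_hours
      clr <- kin$serum_clearance +
        if (ph == "session") kin$photo_clearance else 0
      nstep <- round(dur / dt)
      for (i in seq_len(nstep)) {
        flux <- kin$serum_to_skin * max(S - kin$skin_threshold, 0)
        S2 <- S + dt * (kin$production_rate - clr * S - flux +
                          kin$skin_to_serum * K)
        K <- K + dt * (flux - kin$skin_to_serum * K)
        S <- S2
        t <- t + dt
      }
      if (ph == "session") {
        out$t_out[cyc] <- t; out$S_out[cyc] <- S; out$K_out[cyc] <- K
      } else {
        out$t_return[cyc] <- t; out$S_return[cyc] <- S; out$K_return[cyc] <- K
      }
    }
  }
  out$tbl_out <- out$S_out + kin$optical_gain * out$K_out
  out$tbl_return <- out$S_return + kin$optical_gain * out$K_return
  out$deltas <- out$tbl_return - out$tbl_out
  out
}

# convenience: a high-baseline profile specified by its pre-treatment TcB
profile_for_tbl <- function(tbl0, id = "n1", site = "site-1",
                            kinetics = kinetic_params(), device_gain = 1) {
  neonate_profile(id, site, baseline_serum = serum_for_baseline_tbl(tbl0, kinetics),
                  kinetics = kinetics, device_gain = device_gain)
}

zero_noise <- function(seed = 1L) noise_model(tcb_cv = 0, tsb_cv = 0, seed = seed)

# build an srbv_series directly from a delta pattern (outs given, returns
# derived), on the default 3h + 20min cycle grid
series_from_deltas <- function(deltas, baseline = 14, outs = NULL,
                               id = "n1", site = "s1") {
  n <- length(deltas)
  if (is.null(outs)) outs <- baseline - cumsum(rep(0.8, n))
  t_out <- 3 + (seq_len(n) - 1) * (10 / 3)
  course_series(id, site, baseline,
                t_out = t_out, tbl_out = outs,
                t_return = t_out + 1 / 3, tbl_return = outs + deltas)
}
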