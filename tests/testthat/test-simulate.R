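test_that("without a skin compartment the device reads pure serum", {
  kin <- kinetic_params(serum_to_skin = 0, optical_gain = 0)
  for (gain in c(1, 2)) {
    prof <- neonate_profile("n1", baseline_serum = 10, kinetics = kin,
                            device_gain = gain)
    co <- simulate_course(prof, phototherapy_schedule(n_cycles = 3),
                          zero_noise())
    m <- co$measurements
    tsb <- m[m$kind == "TSB", ]
    for (i in seq_len(nrow(tsb))) {
      tcb_here <- m$value[m$kind == "TBL_raw" &
                            abs(m$time_h - tsb$time_h[i]) < 1e-9]
      expect_equal(tcb_here[1] / gain, tsb$value[i], tolerance = 1e-8)
    }
  }
})

test_that("high-baseline courses rebound during early breaks and decline after the flip", {
  for (tbl0 in c(12, 14, 18)) {
    n_c <- if (tbl0 < 15) 6 else 9
    co <- simulate_course(profile_for_tbl(tbl0),
                          phototherapy_schedule(n_cycles = n_c), zero_noise())
    m <- co$measurements
    deltas <- m$value_true[m$phase == "return"] - m$value_true[m$phase == "out"]
    expect_gt(deltas[1], 0)
    expect_lt(deltas[length(deltas)], 0)
    # independent fine-step Euler oracle confirms the sign pattern
    orc <- euler_course(serum_for_baseline_tbl(tbl0), kinetic_params(), n_c)
    expect_identical(sign(deltas), sign(orc$deltas))
  }
})

test_that("with no production the session-end composite decreases strictly after the flip", {
  kin <- kinetic_params(production_rate = 0)
  prof <- neonate_profile("n1", baseline_serum = serum_for_baseline_tbl(14, kin),
                          kinetics = kin)
  co <- simulate_course(prof, phototherapy_schedule(n_cycles = 8), zero_noise())
  m <- co$measurements
  outs <- m$value_true[m$phase == "out"]
  deltas <- m$value_true[m$phase == "return"] - outs
  flip <- which(deltas < 0)[1]
  expect_true(all(diff(outs[flip:length(outs)]) < 0))
  orc <- euler_course(serum_for_baseline_tbl(14, kin), kin, 8)
  expect_true(all(diff(orc$tbl_out[flip:length(outs)]) < 0))
})

test_that("serum plus skin is conserved when all clearances vanish", {
  kin <- kinetic_params(production_rate = 0, serum_clearance = 0,
                        photo_clearance = 0)
  prof <- neonate_profile("n1", baseline_serum = 14, kinetics = kin)
  co <- simulate_course(prof, phototherapy_schedule(n_cycles = 4), zero_noise())
  total <- co$serum + co$skin
  expect_lt(max(abs(total - total[1])), 1e-6)
})

test_that("the composite signal strictly exceeds serum wherever skin bilirubin is present", {
  co <- simulate_course(profile_for_tbl(16), phototherapy_schedule(n_cycles = 6),
                        zero_noise())
  has_skin <- co$skin > 1e-12
  expect_true(any(has_skin))
  tbl_true <- co$serum + co$profile$kinetics$optical_gain * co$skin
  expect_true(all(tbl_true[has_skin] > co$serum[has_skin]))
})

test_that("noise-free high-baseline delta sequences flip sign exactly once", {
  for (tbl0 in c(12, 14, 18, 25)) {
    n_c <- if (tbl0 < 15) 6 else 10
    co <- simulate_course(profile_for_tbl(tbl0),
                          phototherapy_schedule(n_cycles = n_c), zero_noise())
    m <- co$measurements
    deltas <- m$value_true[m$phase == "return"] - m$value_true[m$phase == "out"]
    expect_identical(sum(diff(deltas > 0) != 0), 1L)
  }
})

test_that("below the intravascular threshold the reading approximates serum", {
  prof <- neonate_profile("n1", baseline_serum = 2.5)
  co <- simulate_course(prof, phototherapy_schedule(n_cycles = 6), zero_noise())
  tbl_true <- co$serum + co$profile$kinetics$optical_gain * co$skin
  expect_true(all(co$serum < 3))
  expect_lt(max(abs(tbl_true - co$serum) / co$serum), 0.01)
})

test_that("adaptive integrator matches the fixed-step Euler oracle on a 24-hour course", {
  kin <- kinetic_params()
  co <- simulate_course(profile_for_tbl(18, kinetics = kin),
                        phototherapy_schedule(n_cycles = 7), zero_noise())
  m <- co$measurements
  outs <- m$value_true[m$phase == "out"]
  rets <- m$value_true[m$phase == "return"]
  orc <- euler_course(serum_for_baseline_tbl(18, kin), kin, 7, dt = 0.001)
  rel <- abs(c(outs, rets) - c(orc$tbl_out, orc$tbl_return)) /
    c(orc$tbl_out, orc$tbl_return)
  expect_lt(max(rel), 0.005)
})

test_that("simulation is reproducible and leaves the global RNG untouched", {
  prof <- profile_for_tbl(14)
  sched <- phototherapy_schedule(n_cycles = 4)
  noise <- noise_model(tcb_cv = 0.05, tsb_cv = 0.03, seed = 42L)
  set.seed(999)
  before <- stats::runif(1)
  set.seed(999)
  a <- simulate_course(prof, sched, noise)
  b <- simulate_course(prof, sched, noise)
  expect_identical(a$measurements, b$measurements)
  expect_identical(stats::runif(1), before)
  # different neonates get different noise substreams
  prof2 <- profile_for_tbl(14, id = "n2")
  c2 <- simulate_course(prof2, sched, noise)
  expect_false(identical(a$measurements$value, c2$measurements$value))
  # but identical true signals
  expect_equal(a$measurements$value_true, c2$measurements$value_true)
})

test_that("measurement times lie on the stored grid and phases alternate", {
  co <- simulate_course(profile_for_tbl(14), phototherapy_schedule(n_cycles = 4),
                        zero_noise())
  for (tt in co$measurements$time_h) {
    expect_lt(min(abs(co$times - tt)), 1e-9)
  }
  runs <- rle(co$phase)$values
  expect_identical(runs, rep(c("session", "break"), 4))
  expect_true(all(co$serum >= 0) && all(co$skin >= 0))
})

test_that("invalid kinetic, schedule and profile inputs are rejected", {
  expect_error(kinetic_params(serum_clearance = -1),
               class = "srbvkit_invalid_kinetics")
  expect_error(kinetic_params(optical_gain = 1.2),
               class = "srbvkit_invalid_kinetics")
  expect_error(kinetic_params(serum_to_skin = 1, skin_to_serum = 0),
               class = "srbvkit_invalid_kinetics")
  expect_error(phototherapy_schedule(session_hours = 0),
               class = "srbvkit_invalid_schedule")
  expect_error(phototherapy_schedule(n_cycles = 0),
               class = "srbvkit_invalid_schedule")
  expect_error(neonate_profile("x", baseline_serum = -2),
               class = "srbvkit_invalid_profile")
  expect_error(neonate_profile("x", device_gain = 0),
               class = "srbvkit_invalid_profile")
  expect_error(noise_model(tcb_cv = -0.1), class = "srbvkit_invalid_noise")
})
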