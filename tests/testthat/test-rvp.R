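test_that("deltas are return minus out in cycle order", {
  s <- course_series("n1", "s", 14,
                     t_out = c(3, 19), tbl_out = c(12, 9.8),
                     t_return = c(10 / 3, 19 + 1 / 3),
                     tbl_return = c(12.9, 9.3))
  expect_equal(compute_deltas(s), c(0.9, -0.5))
  s2 <- series_from_deltas(0)
  expect_equal(compute_deltas(s2), 0)
  expect_error(course_series("n", "s", 10, t_out = 3, tbl_out = 10,
                             t_return = 2, tbl_return = 10),
               class = "srbvkit_invalid_series")
})

test_that("the flip detector implements the persistence rule", {
  r <- detect_rvp(series_from_deltas(c(0.9, 0.4, -0.2, -0.5, -0.7),
                                     baseline = 14))
  expect_identical(r$status, "rvp_detected")
  expect_identical(r$rvp_cycle, 3L)

  expect_identical(detect_rvp(series_from_deltas(c(0.5, 0.3, 0.1),
                                                 baseline = 12))$status,
                   "no_flip")

  # a single negative excursion does not flip; detection waits for the run
  r <- detect_rvp(series_from_deltas(c(0.6, -0.1, 0.2, -0.4, -0.3),
                                     baseline = 13))
  expect_identical(r$rvp_cycle, 4L)

  # a terminal negative delta counts even without a following one
  r <- detect_rvp(series_from_deltas(c(0.5, 0.2, -0.3), baseline = 12))
  expect_identical(r$rvp_cycle, 3L)

  expect_identical(detect_rvp(series_from_deltas(c(0.4, -0.2, -0.3),
                                                 baseline = 9))$status,
                   "ineligible_low_baseline")
  expect_identical(detect_rvp(series_from_deltas(c(0.4, -0.2),
                                                 baseline = 12))$status,
                   "insufficient_data")
  expect_identical(detect_rvp(series_from_deltas(c(-0.1, -0.2, -0.3),
                                                 baseline = 12))$status,
                   "immediate_decline")
})

test_that("post-flip monotonicity tracks the session-end readings", {
  s <- series_from_deltas(c(0.5, -0.2, -0.3), baseline = 14,
                          outs = c(12, 11, 10))
  expect_true(detect_rvp(s)$post_rvp_monotone)
  s2 <- series_from_deltas(c(0.5, -0.2, -0.3), baseline = 14,
                           outs = c(12, 10.5, 10.8))
  expect_false(detect_rvp(s2)$post_rvp_monotone)
})

test_that("swapping out and return readings negates deltas and abolishes detection", {
  set.seed(4)
  for (i in 1:25) {
    n_pos <- sample(1:4, 1); n_neg <- sample(2:4, 1)
    deltas <- c(stats::runif(n_pos, 0.05, 0.6), -stats::runif(n_neg, 0.05, 0.6))
    s <- series_from_deltas(deltas, baseline = 15,
                            outs = seq(14, by = -0.7,
                                       length.out = length(deltas)))
    swapped <- course_series(
      s$neonate_id, s$site_id, s$baseline_tbl,
      t_out = s$cycles$t_out, tbl_out = s$cycles$tbl_return,
      t_return = s$cycles$t_return, tbl_return = s$cycles$tbl_out
    )
    expect_equal(compute_deltas(swapped), -deltas)
    expect_identical(detect_rvp(s)$status, "rvp_detected")
    expect_true(detect_rvp(swapped)$status %in%
                  c("no_flip", "immediate_decline"))
  }
})

test_that("the detector finds the simulator's true flip cycle exactly", {
  for (tbl0 in c(12, 14, 18)) {
    n_c <- if (tbl0 < 15) 6 else 9
    co <- simulate_course(profile_for_tbl(tbl0),
                          phototherapy_schedule(n_cycles = n_c), zero_noise())
    m <- co$measurements
    true_deltas <- m$value_true[m$phase == "return"] -
      m$value_true[m$phase == "out"]
    true_flip <- which(true_deltas < 0)[1]
    s <- series_from_measurements(measurements_frame(co))[[1]]
    r <- detect_rvp(s)
    expect_identical(r$status, "rvp_detected")
    expect_identical(r$rvp_cycle, as.integer(true_flip))
  }
})

test_that("flip-cycle recovery degrades gracefully with reading noise", {
  co <- simulate_course(profile_for_tbl(14), phototherapy_schedule(n_cycles = 6),
                        zero_noise())
  m <- co$measurements
  outs <- m$value_true[m$phase == "out"]
  rets <- m$value_true[m$phase == "return"]
  t_out <- m$time_h[m$phase == "out"]
  t_ret <- m$time_h[m$phase == "return"]
  true_flip <- which(rets - outs < 0)[1]

  hit_rate <- function(cv, reps = 300) {
    hits <- 0
    for (i in seq_len(reps)) {
      sdlog <- sqrt(log(1 + cv^2))
      o <- outs * exp(stats::rnorm(length(outs), 0, sdlog) - sdlog^2 / 2)
      r <- rets * exp(stats::rnorm(length(rets), 0, sdlog) - sdlog^2 / 2)
      s <- course_series("n1", "s", 14, t_out, o, t_ret, r)
      d <- detect_rvp(s)
      if (d$status == "rvp_detected" && abs(d$rvp_cycle - true_flip) <= 1) {
        hits <- hits + 1
      }
    }
    hits / reps
  }
  set.seed(31)
  rates <- vapply(c(0.005, 0.02, 0.05), hit_rate, numeric(1))
  # repeatability-level noise keeps the detected cycle within +/-1 in >=90%
  expect_gte(rates[1], 0.9)
  # heavier reading noise can only degrade agreement
  expect_gte(rates[1], rates[2])
  expect_gte(rates[2], rates[3])
})

test_that("decline rate matches hand-computed slopes", {
  s <- course_series("n1", "s", 15, t_out = c(0, 3.33, 6.67),
                     tbl_out = c(15, 14, 13),
                     t_return = c(0.33, 3.66, 7), tbl_return = c(15, 14, 13))
  expect_equal(decline_rate(s), 0.3, tolerance = 0.002)

  flat <- course_series("n1", "s", 15, t_out = c(0, 5), tbl_out = c(12, 12),
                        t_return = c(0.3, 5.3), tbl_return = c(12, 12))
  expect_equal(decline_rate(flat), 0)

  two <- course_series("n1", "s", 18.4, t_out = c(0, 19),
                       tbl_out = c(18.4, 8.9),
                       t_return = c(0.33, 19.33), tbl_return = c(18.4, 8.9))
  expect_equal(decline_rate(two), 0.5)
  expect_equal(decline_rate(two, method = "endpoint"), 0.5)

  one <- course_series("n1", "s", 12, t_out = 3, tbl_out = 11,
                       t_return = 3.3, tbl_return = 11)
  expect_error(decline_rate(one), class = "srbvkit_invalid_series")
})

test_that("the OLS decline estimator agrees with the oracle post-flip finite-difference rate", {
  co <- simulate_course(profile_for_tbl(14), phototherapy_schedule(n_cycles = 6),
                        zero_noise())
  m <- co$measurements
  outs <- m$value_true[m$phase == "out"]
  t_out <- m$time_h[m$phase == "out"]
  rets <- m$value_true[m$phase == "return"]
  flip <- which(rets - outs < 0)[1]
  seg <- course_series("n1", "s", 14,
                       t_out = t_out[flip:length(outs)],
                       tbl_out = outs[flip:length(outs)],
                       t_return = t_out[flip:length(outs)] + 1 / 3,
                       tbl_return = rets[flip:length(outs)])
  oracle <- mean(-diff(outs[flip:length(outs)]) / diff(t_out[flip:length(outs)]))
  expect_lt(abs(decline_rate(seg) - oracle) / oracle, 0.05)
})

test_that("site summaries aggregate counts, ranges, rates and flip percentages", {
  sA <- series_from_deltas(c(0.3, 0.1, -0.2, -0.3), baseline = 14,
                           outs = c(13, 12.2, 11.4, 10.7), id = "a1",
                           site = "A")
  sB <- series_from_deltas(c(0.2, 0.1, 0.05), baseline = 12,
                           outs = c(11.5, 11, 10.6), id = "a2", site = "A")
  sC <- series_from_deltas(c(-0.1, -0.1, -0.1), baseline = 8,
                           outs = c(7, 6, 5), id = "a3", site = "A")
  series <- list(sA, sB, sC)
  rvp <- lapply(series, detect_rvp)
  summ <- summarise_site(series, rvp)
  expect_identical(summ$n_patients, 3L)
  # a3 is ineligible (low baseline): denominator is the two eligible courses
  expect_equal(summ$rvp_observed_pct, 50)
  expect_equal(summ$tbl_max, 14)
  expect_equal(summ$pre_tbl_mean, mean(c(14, 12, 8)))

  all_flip <- summarise_site(list(sA), list(detect_rvp(sA)))
  expect_equal(all_flip$rvp_observed_pct, 100)
})
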