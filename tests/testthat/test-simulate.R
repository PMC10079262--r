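test_that("all simulators are bit-reproducible given a seed", {
  expect_identical(brownian_track(50, seed = 3), brownian_track(50, seed = 3))
  expect_false(identical(brownian_track(50, seed = 3), brownian_track(50, seed = 4)))

  b1 <- beauchemin_track(20, seed = 11); b2 <- beauchemin_track(20, seed = 11)
  expect_identical(b1, b2)
  expect_false(identical(b1, beauchemin_track(20, seed = 12)))

  ref <- as_tracks(list(r = rand_track(30, seed = 1)))
  expect_identical(bootstrap_track(20, ref, seed = 5),
                   bootstrap_track(20, ref, seed = 5))

  s1 <- simulate_tracks(4, function(s) brownian_track(10, seed = s), seed = 9)
  s2 <- simulate_tracks(4, function(s) brownian_track(10, seed = s), seed = 9)
  expect_identical(unclass(s1), unclass(s2))
  # simulated tracks always satisfy the data-model invariants
  expect_s3_class(as_tracks(s1), "tracks")
})

test_that("degenerate Brownian parameters give exact ballistic motion", {
  v <- c(1.5, -0.5, 2)
  tr <- brownian_track(10, dim = 3, delta_t = 2, sd = 0, drift = v, seed = 1)
  expect_equal(speed(tr), sqrt(sum(v^2)) / 2)
  expect_equal(straightness(tr), 1)
  expect_equal(unname(tr[11, -1]), 10 * v)
})

test_that("Brownian increments have the nominal moments and no cross-covariance", {
  sdv <- 2
  tr <- brownian_track(20000, dim = 3, sd = sdv, seed = 21)
  inc <- diff(tr[, -1])
  n <- nrow(inc)
  for (j in 1:3) {
    expect_lt(abs(mean(inc[, j])), 3 * sdv / sqrt(n))
    expect_lt(abs(sd(inc[, j]) - sdv), 3 * sdv / sqrt(2 * n))
  }
  cc <- cor(inc)
  expect_true(all(abs(cc[upper.tri(cc)]) < 3 / sqrt(n)))
})

test_that("bootstrap sampling reproduces point-mass and empirical references", {
  # straight constant-speed reference: point-mass step length, zero turning
  ref <- as_tracks(list(s = straight_track(10, step = c(3, 0), dt = 2)))
  bt <- bootstrap_track(15, ref, seed = 2)
  expect_equal(unique(round(sqrt(rowSums(diff(bt[, -1])^2)), 10)), 3)
  expect_equal(max(abs(turning_angles(bt))), 0, tolerance = 1e-8)
  expect_equal(diff(bt[, 1]), rep(2, 15), ignore_attr = TRUE)  # modal dt kept
  expect_equal(straightness(bt), 1, tolerance = 1e-8)

  # rich reference: simulated step-length distribution matches (KS, alpha 0.01)
  ref2 <- as_tracks(list(w = brownian_track(400, dim = 2, sd = 1.5, seed = 3)))
  bt2 <- bootstrap_track(5000, ref2, seed = 4)
  ref_lens <- sqrt(rowSums(diff(ref2[[1]][, -1])^2))
  sim_lens <- sqrt(rowSums(diff(bt2[, -1])^2))
  ks <- suppressWarnings(stats::ks.test(sim_lens, ref_lens))
  expect_gt(ks$p.value, 0.01)

  # mean turning angle conserved within sampling error
  sim_ang <- turning_angles(bt2)
  ref_ang <- unlist(lapply(ref2, turning_angles))
  se <- sqrt(sd(sim_ang)^2 / length(sim_ang) + sd(ref_ang)^2 / length(ref_ang))
  expect_lt(abs(mean(sim_ang) - mean(ref_ang)), 3 * se)

  expect_error(bootstrap_track(5, as_tracks(list(z = mk_track(0:2, rep(0, 3), rep(0, 3))))),
               "zero length|turning")
})

test_that("stop-and-go tracks have the designed phase structure", {
  # no pauses, phase-aligned start, observed at the free-run period:
  # every step is one full run of length v*t_free, headings uniform
  tr <- beauchemin_track(total_time = 400, delta_t = 2, v_free = 9,
                         t_free = 2, t_pause = 0, dim = 3,
                         stationary_start = FALSE, seed = 6)
  lens <- sqrt(rowSums(diff(tr[, -1])^2))
  expect_equal(lens, rep(18, 200), tolerance = 1e-9, ignore_attr = TRUE)
  ang <- turning_angles(tr)
  ang <- ang[!is.na(ang)]
  expect_lt(abs(mean(ang) - 90), 3 * sd(ang) / sqrt(length(ang)))

  # with pauses and fine sampling, observed speed is below v_free
  tr2 <- beauchemin_track(100, delta_t = 0.1, v_free = 10, t_free = 2,
                          t_pause = 2, seed = 7)
  expect_lt(speed(tr2), 10)
  # no pauses and fine sampling approaches constant-speed motion
  tr3 <- beauchemin_track(100, delta_t = 0.05, v_free = 10, t_free = 2,
                          t_pause = 0, seed = 8)
  expect_equal(speed(tr3), 10, tolerance = 0.02)
  expect_error(beauchemin_track(10, delta_t = 0), "delta_t")
})

test_that("directional bias in the stop-and-go model is detected by the step test", {
  biased <- simulate_tracks(30, function(s) {
    beauchemin_track(30, delta_t = 0.5, bias_dir = c(1, -1, 0), p_bias = 0.6,
                     seed = s)
  }, seed = 15)
  ht <- hotellings_test(biased, step_spacing = 4)
  expect_lt(ht$p.value, 0.01)
  expect_gt(sum(ht$mean_vector * c(1, -1, 0)), 0)    # mean aligned with bias

  unbiased <- simulate_tracks(30, function(s) {
    beauchemin_track(30, delta_t = 0.5, seed = s)
  }, seed = 16)
  ht2 <- hotellings_test(unbiased, step_spacing = 4)
  expect_gt(ht2$p.value, 0.001)
})

test_that("Brownian MSD fitting recovers the diffusion coefficient", {
  sdv <- 1.5; dt <- 1; d <- 3
  trk <- simulate_tracks(200, function(s)
    brownian_track(100, dim = d, delta_t = dt, sd = sdv, seed = s), seed = 9)
  cv <- msd(trk, lags = 1:10)
  fit <- fit_msd(cv, "brownian")
  D_true <- sdv^2 / (2 * dt)
  expect_lt(abs(coef(fit)[["D"]] / D_true - 1), 0.05)
  expect_equal(length(residuals(fit)), 10L)
  expect_equal(fitted(fit) + residuals(fit), cv$mean[1:10], ignore_attr = TRUE)

  # ballistic data fitted by a linear model: mismatch is visible, not hidden
  straight <- as_tracks(list(s = straight_track(30, step = c(4, 0))))
  cvs <- msd(straight, lags = 1:15)
  bad <- fit_msd(cvs, "brownian")
  expect_gt(bad$objective, 1e4)
  expect_error(fit_msd(cvs, "brownian", max_fit_lag = 0), "usable lags")
})

test_that("the stop-and-go model outfits Brownian motion on its own data", {
  trk <- simulate_tracks(60, function(s)
    beauchemin_track(total_time = 50, delta_t = 0.5, seed = s), seed = 21)
  cv <- msd(trk, lags = 1:16)
  f_br <- fit_msd(cv, "brownian")
  f_be <- fit_msd(cv, "beauchemin", fit_params = "v_free", n_sim = 40,
                  sim_seed = 4)
  expect_lt(f_be$objective, f_br$objective)
  expect_lt(abs(coef(f_be)[["v_free"]] / 18.8 - 1), 0.1)
  expect_s3_class(f_be, "msd_fit")
  expect_output(print(f_be), "beauchemin")
})
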