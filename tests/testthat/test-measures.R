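test_that("measures reproduce hand-computed values", {
  tr <- mk_track(0:1, c(0, 3), c(0, 4), c(0, 0))      # 3-4-5 displacement
  expect_equal(displacement(tr), 5)
  expect_equal(square_displacement(tr), 25)

  kinked <- mk_track(0:2, c(0, 3, 3), c(0, 4, 9))     # two steps of length 5
  expect_equal(track_length(kinked), 10)
  expect_equal(straightness(kinked), sqrt(90) / 10)   # ~0.9487
  expect_equal(speed(kinked), 10 / 2)

  L_shape <- mk_track(0:2, c(0, 1, 1), c(0, 0, 1))
  expect_equal(turning_angles(L_shape), 90)
  expect_equal(overall_dot(L_shape), 0)
  expect_equal(overall_angle(L_shape), 90)

  back_forth <- mk_track(0:2, c(0, 1, 0), c(0, 0, 0))
  expect_equal(turning_angles(back_forth), 180)
  expect_equal(overall_dot(back_forth), -1)
  expect_equal(displacement(back_forth), 0)           # closed loop
  expect_gt(max_displacement(back_forth), 0)
  expect_equal(displacement_ratio(back_forth), 0)
  expect_gt(outreach_ratio(back_forth), 0)

  straight <- straight_track(4, step = c(1, 2))
  expect_equal(max_displacement(straight), displacement(straight))
  expect_equal(turning_angles(straight), rep(0, 3))
  expect_equal(overall_dot(straight), 5)              # ||step||^2
  expect_equal(straightness(straight), 1)
  expect_equal(displacement_ratio(straight), 1)
  expect_equal(outreach_ratio(straight), 1)
})

test_that("asphericity distinguishes collinear from isotropic configurations", {
  expect_equal(asphericity(straight_track(3, step = c(1, 1))), 1)
  expect_equal(asphericity(straight_track(3, step = c(1, 0, 2))), 1)   # 3D collinear
  square <- mk_track(0:3, c(0, 1, 1, 0), c(0, 0, 1, 1))
  expect_equal(asphericity(square), 0)
  tetra <- mk_track(0:3, c(1, 1, -1, -1), c(1, -1, 1, -1), c(1, -1, -1, 1))
  expect_equal(asphericity(tetra), o_asphericity(tetra))
  expect_equal(asphericity(tetra), 0)
  expect_true(is.na(asphericity(mk_track(0:1, c(1, 1), c(2, 2)))))     # coincident
})

test_that("every measure matches an independent naive oracle on random tracks", {
  oracles <- oracle_measures()
  cases <- c(
    lapply(1:10, function(s) rand_track(sample(3:6, 1), d = 2, seed = s)),
    lapply(11:20, function(s) rand_track(sample(3:6, 1), d = 3, seed = s)),
    list(straight_track(5), mk_track(0:2, c(0, 1, 0), c(0, 0, 0)))
  )
  for (nm in names(oracles)) {
    f <- get_measure(nm)
    for (k in seq_along(cases)) {
      got <- f(cases[[k]])
      want <- oracles[[nm]](cases[[k]])
      if (is.na(want)) {
        expect_true(is.na(got), info = paste(nm, "case", k))
      } else {
        expect_equal(got, want, tolerance = 1e-12, info = paste(nm, "case", k))
      }
    }
  }
})

test_that("measures are invariant under rigid motions", {
  inv <- c("displacement", "square_displacement", "max_displacement",
           "track_length", "duration", "speed", "straightness",
           "displacement_ratio", "outreach_ratio", "mean_turning_angle",
           "overall_angle", "overall_dot", "asphericity")
  for (d in 2:3) {
    x <- as_tracks(lapply(stats::setNames(1:3, paste0("t", 1:3)),
                          function(s) rand_track(5, d = d, seed = s)))
    for (rep in 1:5) {
      R <- random_rotation(d, seed = 100 * d + rep)
      b <- rnorm(d, sd = 10)
      y <- rigid_transform(x, R, b)
      for (nm in inv) {
        f <- get_measure(nm)
        expect_equal(vapply(unclass(y), f, numeric(1)),
                     vapply(unclass(x), f, numeric(1)),
                     tolerance = 1e-9, info = nm)
      }
    }
  }
})

test_that("straightness factorizes and ratio measures stay in [0, 1]", {
  for (s in 1:25) {
    tr <- rand_track(sample(3:8, 1), d = sample(2:3, 1), seed = 1000 + s)
    st <- straightness(tr); dr <- displacement_ratio(tr); orr <- outreach_ratio(tr)
    expect_true(st >= 0 && st <= 1 + 1e-12)
    expect_true(dr >= 0 && dr <= 1 + 1e-12)
    expect_true(orr >= 0 && orr <= 1 + 1e-12)
    expect_equal(st, dr * orr, tolerance = 1e-12)
    expect_gte(track_length(tr), displacement(tr) - 1e-12)
  }
})

test_that("undefined values are marked NA, never silently dropped or zeroed", {
  point <- mk_track(0, 1, 1)
  expect_true(is.na(speed(point)))            # zero duration
  expect_true(is.na(straightness(point)))     # zero length
  stalled <- mk_track(0:2, c(0, 1, 1), c(0, 0, 0))    # second step has length 0
  expect_true(is.na(turning_angles(stalled)))
  expect_true(is.na(mean_turning_angle(stalled)))
  x <- as_tracks(list(ok = straight_track(2), pt = point))
  tab <- apply_measure(x, speed)
  expect_equal(tab$id, c("ok", "pt"))
  expect_true(is.na(tab$value[tab$id == "pt"]))
  expect_false(is.na(tab$value[tab$id == "ok"]))
})

test_that("mean turning angle of an isotropic walk approaches 90 degrees", {
  for (d in 2:3) {
    x <- as_tracks(list(w = brownian_track(4000, dim = d, sd = 1, seed = d)))
    a <- turning_angles(x[[1]])
    se <- sd(a) / sqrt(length(a))
    expect_lt(abs(mean(a) - 90), 3 * se)
  }
})

test_that("apply_measure supports cell, step and staggered scales plus custom measures", {
  x <- as_tracks(list(a = straight_track(4, step = c(2, 0)),
                      b = straight_track(3, step = c(0, 1))))
  cell <- apply_measure(x, speed, scale = "cell")
  expect_equal(cell$value, c(2, 1))           # nominal constant speeds

  stepwise <- apply_measure(x, displacement, scale = "step", length = 1)
  expect_equal(nrow(stepwise), 7L)
  expect_equal(stepwise$value, c(rep(2, 4), rep(1, 3)))

  stag <- apply_measure(x["a"], straightness, scale = "staggered")
  M <- stag[["a"]]
  expect_true(all(M[upper.tri(M)] == 1))      # straight track: all-1 triangle

  n_obs <- function(tr) nrow(tr)              # custom measure: extension point
  expect_equal(apply_measure(x, n_obs)$value, c(5, 4))
})

test_that("aggregation over lags yields exact MSD for ballistic motion", {
  s <- 1.5
  x <- as_tracks(list(a = straight_track(6, step = c(s, 0))))
  cv <- msd(x, lags = 1:5)
  expect_equal(cv$mean, (cv$lag * s)^2)       # quadratic, exact
  expect_equal(cv$n, 6 - (1:5) + 1)           # max-overlap count formula
  cv0 <- msd(x, lags = 1:5, overlap = "none")
  expect_equal(cv0$n, floor(6 / (1:5)))
})

test_that("the vectorized MSD shortcut agrees with generic aggregation", {
  x <- as_tracks(lapply(stats::setNames(1:4, paste0("w", 1:4)),
                        function(s) rand_track(12, d = 3, seed = 40 + s)))
  fast <- msd(x, lags = c(1, 2, 5, 9))
  slow <- aggregate(x, square_displacement, lags = c(1, 2, 5, 9))
  expect_equal(as.data.frame(fast), as.data.frame(slow), tolerance = 1e-12)
  fast0 <- msd(x, lags = c(1, 3), overlap = "none")
  slow0 <- aggregate(x, square_displacement, lags = c(1, 3), overlap = "none")
  expect_equal(as.data.frame(fast0), as.data.frame(slow0), tolerance = 1e-12)
  # generic aggregation also serves any other measure: angle autocorrelation
  ac <- aggregate(x, overall_angle, lags = c(1, 2))
  expect_equal(ac$mean[1], 0)                 # lag 1: first step == last step
})

test_that("aggregation refuses heterogeneous step durations", {
  x <- as_tracks(list(g = mk_track(c(0, 1, 4), c(0, 1, 2), c(0, 0, 0))))
  expect_error(msd(x), "heterogeneous")
  expect_error(aggregate(x, square_displacement), "heterogeneous")
})

test_that("displacement autocovariance of a Brownian walk vanishes beyond lag 1", {
  x <- as_tracks(list(w = brownian_track(8000, dim = 2, sd = 1, seed = 7)))
  ac <- aggregate(x, overall_dot, lags = c(2, 4))
  se <- sqrt(ac$var / ac$n)
  expect_true(all(abs(ac$mean) < 3 * se))     # independent increments
})
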