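test_that("pair diagnostics flag duplicates and antiparallel movers", {
  a <- straight_track(4, step = c(1, 0))
  a[, 2:3] <- a[, 2:3] + 5
  b <- a; b[, 2:3] <- b[, 2:3] + c(0, 10)     # same motion, translated
  opp <- straight_track(4, step = c(-1, 0))   # exactly opposite direction
  x <- as_tracks(list(a = a, dup = a, far = b, opp = opp))
  pd <- pair_diagnostics(x)
  get <- function(i, j) pd[(pd$id_a == i & pd$id_b == j) |
                           (pd$id_a == j & pd$id_b == i), ]
  expect_equal(get("a", "dup")$min_distance, 0)
  expect_equal(get("a", "dup")$pair_angle, 0)
  expect_equal(get("a", "opp")$pair_angle, 180)
  expect_equal(nrow(pd), choose(4, 2))
  expect_identical(attr(pd, "n_skipped"), 0L)

  # pairs without temporal overlap are omitted and counted
  late <- a; late[, 1] <- late[, 1] + 100
  pd2 <- pair_diagnostics(as_tracks(list(a = a, late = late)))
  expect_equal(nrow(pd2), 0L)
  expect_identical(attr(pd2, "n_skipped"), 1L)
})

test_that("pair diagnostics are invariant under rigid motion of the dataset", {
  x <- as_tracks(lapply(stats::setNames(1:4, paste0("c", 1:4)),
                        function(s) rand_track(6, d = 3, seed = 60 + s)))
  pd <- pair_diagnostics(x)
  R <- random_rotation(3, seed = 99)
  y <- rigid_transform(x, R, c(5, -3, 11))
  pd2 <- pair_diagnostics(y)
  expect_equal(pd2$min_distance, pd$min_distance, tolerance = 1e-9)
  expect_equal(pd2$pair_angle, pd$pair_angle, tolerance = 1e-9)
})

test_that("a noisy injected duplicate is the top-ranked pair", {
  fx <- generate_fixture(fixture_spec(n_tracks = 40, seed = 8))
  tc <- fx$tracks[fx$labels$class == "tcell_like"]
  aug <- inject_duplicate(tc, "tcell07", noise_sd = 0.5, seed = 17)
  top <- rank_pairs(pair_diagnostics(aug))[1, ]
  expect_setequal(c(top$id_a, top$id_b), c("tcell07", "tcell07.dup"))
  expect_lt(top$min_distance, 2)
  expect_lt(top$pair_angle, 20)
})

test_that("interpolation is exact on lines and refuses extrapolation", {
  seg <- mk_track(c(0, 2), c(0, 2), c(0, 0))
  out <- interpolate_track(seg, 1)
  expect_equal(out[1, ], c(t = 1, x = 1, y = 0))

  tr <- rand_track(6, d = 3, seed = 5)
  same <- interpolate_track(tr, tr[, 1])
  expect_equal(same, tr, ignore_attr = TRUE)  # original times reproduced

  # constant-velocity 3D track: interpolated points lie exactly on the line
  v <- c(1, -2, 0.5)
  lin <- mk_track(0:5, outer(0:5, v))
  q <- sort(runif(7, 0, 5))
  got <- interpolate_track(lin, q)
  expect_equal(got[, -1], outer(q, v), tolerance = 1e-12, ignore_attr = TRUE)

  expect_error(interpolate_track(seg, 3), "extrapolation|outside")
  expect_error(interpolate_track(seg, -1), "extrapolation|outside")
  expect_error(interpolate_track(seg, 1, method = "spline"), "4 observations")
  sp <- interpolate_track(rand_track(6, seed = 2), c(1.5, 2.5), method = "spline")
  expect_equal(nrow(sp), 2L)
})

test_that("gap detection and repair behave per strategy", {
  gap <- mk_track(c(0, 1, 2, 5, 6), c(0, 1, 2, 3, 4), rep(0, 5))
  ok <- straight_track(4)
  x <- as_tracks(list(gap = gap, ok = ok))

  rep_ <- detect_gaps(x)
  expect_equal(sum(rep_$flagged), 1L)
  expect_equal(rep_$id[rep_$flagged], "gap")

  sp <- repair_gaps(x, how = "split")
  expect_setequal(names(sp$tracks), c("gap.1", "gap.2", "ok"))
  expect_equal(sum(vapply(sp$tracks, nrow, integer(1))),
               sum(vapply(x, nrow, integer(1))))     # observations conserved
  expect_equal(sum(detect_gaps(sp$tracks)$flagged), 0L)

  dr <- repair_gaps(x, how = "drop")
  expect_identical(names(dr$tracks), "ok")

  it <- repair_gaps(x, how = "interpolate")
  g <- it$tracks[["gap"]]
  expect_equal(diff(g[, 1]), rep(1, 6))
  expect_equal(nrow(g), (6 - 0) + 1)          # uniform grid over the span

  # gap-free data unchanged under every mode
  clean <- as_tracks(list(ok = ok))
  for (how in c("split", "drop", "interpolate")) {
    expect_equal(unclass(repair_gaps(clean, how = how)$tracks),
                 unclass(clean), ignore_attr = TRUE)
  }
})

test_that("track filtering honors step counts, predicates and measure ranges", {
  x <- as_tracks(list(s2 = straight_track(2), s4 = straight_track(4, step = c(2, 0)),
                      s6 = straight_track(6, step = c(3, 0))))
  expect_setequal(names(filter_tracks(x, min_steps = 4)), c("s4", "s6"))
  expect_identical(names(filter_tracks(x)), names(x))   # always-true predicate

  kept <- select_tracks(x, speed, 1.5, 2.5)
  speeds <- vapply(unclass(x), o_speed, numeric(1))     # independent recompute
  expect_setequal(names(kept), names(x)[speeds >= 1.5 & speeds <= 2.5])
})

test_that("global drift is estimated exactly on constructed data and removed", {
  v <- c(0.8, -0.3)
  base <- lapply(stats::setNames(1:3, paste0("s", 1:3)), function(k) {
    mk_track(0:5, rep(k, 6), rep(2 * k, 6))   # stationary cells
  })
  drifted <- lapply(base, function(tr) {
    tr[, -1] <- tr[, -1] + outer(tr[, 1], v)
    tr
  })
  x <- as_tracks(drifted)
  est <- estimate_drift(x)
  expect_equal(est, v, tolerance = 1e-12, ignore_attr = TRUE)
  fixed <- correct_drift(x, est)
  expect_true(all(vapply(fixed, displacement, numeric(1)) < 1e-10))
  expect_equal(max(abs(estimate_drift(fixed))), 0, tolerance = 1e-10)

  # drift-free random walk: estimate shrinks toward zero
  w <- as_tracks(list(w = brownian_track(4000, dim = 2, sd = 1, seed = 3)))
  expect_lt(sqrt(sum(estimate_drift(w)^2)), 3 * 1 / sqrt(4000))

  # v = 0 is the identity
  expect_equal(unclass(correct_drift(x, c(0, 0))), unclass(x), ignore_attr = TRUE)
})

test_that("origin-normalization is idempotent and preserves step measures", {
  x <- as_tracks(lapply(stats::setNames(1:3, paste0("n", 1:3)),
                        function(s) rand_track(5, d = 2, seed = 80 + s)))
  nx <- normalize_tracks(x)
  expect_true(all(vapply(nx, function(tr) all(tr[1, -1] == 0), logical(1))))
  expect_equal(unclass(normalize_tracks(nx)), unclass(nx), ignore_attr = TRUE)
  for (nm in c("speed", "track_length", "mean_turning_angle")) {
    f <- get_measure(nm)
    expect_equal(vapply(unclass(nx), f, numeric(1)),
                 vapply(unclass(x), f, numeric(1)), info = nm)
  }
})
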