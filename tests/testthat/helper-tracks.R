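# build a track matrix from a time vector and per-observation coordinates
mk_track <- function(t, ...) {
  pos <- cbind(...)
  m <- cbind(t, pos)
  colnames(m) <- c("t", c("x", "y", "z")[seq_len(ncol(pos))])
  m
}

# straight constant-speed track: n_steps steps of vector `step`, interval dt
straight_track <- function(n_steps, step = c(1, 0), dt = 1) {
  k <- 0:n_steps
  pos <- outer(k, step)
  mk_track(k * dt, pos)
}

rand_track <- function(n_obs, d = 2, seed = NULL, sd = 1) {
  if (!is.null(seed)) set.seed(seed)
  pos <- apply(matrix(rnorm(n_obs * d, sd = sd), n_obs, d), 2, cumsum)
  mk_track(seq_len(n_obs) - 1, matrix(pos, nrow = n_obs))
}

random_rotation <- function(d, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  qr_d <- qr(matrix(rnorm(d * d), d, d))
  Q <- qr.Q(qr_d)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# apply a rigid motion (rotation R then translation b) to every track
rigid_transform <- function(x, R, b) {
  out <- lapply(unclass(x), function(tr) {
    tr[, -1] <- t(R %*% t(tr[, -1, drop = FALSE])) + rep(b, each = nrow(tr))
    tr
  })
  as_tracks(out)
}
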