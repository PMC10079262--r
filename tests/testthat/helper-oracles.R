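# Independent, deliberately naive reimplementations of every track measure,
# used as equivalence oracles.  All use explicit loops and acos-based angles
# so they share no code path with the package implementations.

o_pos <- function(tr) tr[, -1, drop = FALSE]

o_displacement <- function(tr) {
  p <- o_pos(tr)
  sqrt(sum((p[nrow(p), ] - p[1, ])^2))
}

o_square_displacement <- function(tr) o_displacement(tr)^2

o_max_displacement <- function(tr) {
  p <- o_pos(tr)
  best <- 0
  for (k in seq_len(nrow(p))) best <- max(best, sqrt(sum((p[k, ] - p[1, ])^2)))
  best
}

o_track_length <- function(tr) {
  p <- o_pos(tr)
  total <- 0
  if (nrow(p) >= 2) {
    for (k in 2:nrow(p)) total <- total + sqrt(sum((p[k, ] - p[k - 1, ])^2))
  }
  total
}

o_duration <- function(tr) unname(tr[nrow(tr), 1] - tr[1, 1])

o_speed <- function(tr) {
  dur <- o_duration(tr)
  if (dur <= 0) return(NA_real_)
  o_track_length(tr) / dur
}

o_straightness <- function(tr) {
  len <- o_track_length(tr)
  if (len == 0) return(NA_real_)
  o_displacement(tr) / len
}

o_displacement_ratio <- function(tr) {
  mx <- o_max_displacement(tr)
  if (mx == 0) return(NA_real_)
  o_displacement(tr) / mx
}

o_outreach_ratio <- function(tr) {
  len <- o_track_length(tr)
  if (len == 0) return(NA_real_)
  o_max_displacement(tr) / len
}

o_angle <- function(u, v) {
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) return(NA_real_)
  acos(min(1, max(-1, sum(u * v) / (nu * nv)))) * 180 / pi
}

o_turning_angles <- function(tr) {
  p <- o_pos(tr)
  if (nrow(p) < 3) return(numeric(0))
  out <- numeric(nrow(p) - 2)
  for (k in 2:(nrow(p) - 1)) {
    out[k - 1] <- o_angle(p[k, ] - p[k - 1, ], p[k + 1, ] - p[k, ])
  }
  out
}

o_mean_turning_angle <- function(tr) {
  a <- o_turning_angles(tr)
  a <- a[!is.na(a)]
  if (!length(a)) return(NA_real_)
  mean(a)
}

o_overall_angle <- function(tr) {
  p <- o_pos(tr)
  if (nrow(p) < 2) return(NA_real_)
  o_angle(p[2, ] - p[1, ], p[nrow(p), ] - p[nrow(p) - 1, ])
}

o_overall_dot <- function(tr) {
  p <- o_pos(tr)
  if (nrow(p) < 2) return(NA_real_)
  sum((p[2, ] - p[1, ]) * (p[nrow(p), ] - p[nrow(p) - 1, ]))
}

o_asphericity <- function(tr) {
  p <- o_pos(tr)
  if (nrow(p) < 2) return(NA_real_)
  d <- ncol(p)
  ctr <- colMeans(p)
  G <- matrix(0, d, d)
  for (k in seq_len(nrow(p))) {
    v <- p[k, ] - ctr
    G <- G + outer(v, v)
  }
  G <- G / nrow(p)
  lam <- sort(eigen(G, symmetric = TRUE)$values, decreasing = TRUE)
  if (sum(lam) <= 0) return(NA_real_)
  num <- 0
  for (i in 1:(d - 1)) for (j in (i + 1):d) num <- num + (lam[i] - lam[j])^2
  num / ((d - 1) * sum(lam)^2)
}

oracle_measures <- function() {
  list(displacement = o_displacement, square_displacement = o_square_displacement,
       max_displacement = o_max_displacement, track_length = o_track_length,
       duration = o_duration, speed = o_speed, straightness = o_straightness,
       displacement_ratio = o_displacement_ratio,
       outreach_ratio = o_outreach_ratio,
       mean_turning_angle = o_mean_turning_angle,
       overall_angle = o_overall_angle, overall_dot = o_overall_dot,
       asphericity = o_asphericity)
}

# brute-force subtrack count: enumerate candidate start indices directly
o_subtrack_count <- function(n_steps, L, o) {
  stride <- L - o
  count <- 0
  i <- 0
  while (i + L <= n_steps) {
    count <- count + 1
    i <- i + stride
  }
  count
}
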