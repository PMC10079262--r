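#' Track measures
#'
#' A *track measure* is any function mapping a single track matrix (columns
#' `t, x, y[, z]`) to a scalar.  All built-in measures below follow this
#' contract, and any user-written function with the same contract is
#' accepted wherever a built-in measure is (by [apply_measure()],
#' [aggregate.tracks()], [feature_matrix()], [filter_tracks()],
#' [select_tracks()] and the staggered helpers).  Where a measure is
#' undefined for a given track (zero path length, zero duration, degenerate
#' steps) it returns `NA_real_` — the explicit "undefined" marker — rather
#' than 0, so undefined cases are never silently absorbed into summaries.
#'
#' Definitions (positions p_0..p_n, steps s_k = p_k - p_{k-1}):
#' \itemize{
#'  \item `displacement`: ||p_n - p_0|| (micrometers);
#'    `square_displacement` its square; `max_displacement` =
#'    max_k ||p_k - p_0||.
#'  \item `track_length`: sum of step lengths; `duration`: t_n - t_0;
#'    `speed`: length / duration (the cell-based mean speed; on a 1-step
#'    subtrack this is the instantaneous speed).
#'  \item `straightness` = displacement / length;
#'    `displacement_ratio` = displacement / max_displacement;
#'    `outreach_ratio` = max_displacement / length.  All lie in [0, 1] and
#'    straightness = displacement_ratio * outreach_ratio.
#'  \item `turning_angles`: angle (degrees, in [0, 180]) between consecutive
#'    steps at each interior vertex; `mean_turning_angle` their mean over
#'    defined vertices (90 degrees expected under isotropic motion).
#'  \item `overall_angle` / `overall_dot`: angle / dot product between the
#'    first and last step of the (sub)track — the building blocks of angle
#'    autocorrelation and displacement autocovariance curves.
#'  \item `asphericity`: gyration-tensor eigenvalue statistic in [0, 1]
#'    (1 = collinear, 0 = isotropic spread), see [asphericity()].
#' }
#'
#' @param track a track matrix.
#' @return A scalar (`NA_real_` when undefined); `turning_angles` returns a
#'   vector with one entry per interior vertex (NA at degenerate vertices).
#' @name measures
NULL

step_vectors <- function(track) {
  p <- track_pos(track)
  if (nrow(p) < 2L) return(matrix(numeric(0), 0L, ncol(p)))
  diff(p)
}

vec_norm <- function(v) sqrt(sum(v * v))

# angle between two vectors in degrees, via the numerically stable
# atan2(||component of v orthogonal to u||, u.v) form
vec_angle_deg <- function(u, v) {
  nu <- vec_norm(u); nv <- vec_norm(v)
  if (nu == 0 || nv == 0) return(NA_real_)
  u <- u / nu; v <- v / nv
  dotp <- sum(u * v)
  perp <- vec_norm(v - dotp * u)
  atan2(perp, dotp) * 180 / pi
}

#' @rdname measures
#' @export
displacement <- function(track) {
  p <- track_pos(track)
  vec_norm(p[nrow(p), ] - p[1, ])
}

#' @rdname measures
#' @export
square_displacement <- function(track) {
  p <- track_pos(track)
  d <- p[nrow(p), ] - p[1, ]
  sum(d * d)
}

#' @rdname measures
#' @export
max_displacement <- function(track) {
  p <- track_pos(track)
  d <- sweep(p, 2, p[1, ])
  sqrt(max(rowSums(d * d)))
}

#' @rdname measures
#' @export
track_length <- function(track) {
  s <- step_vectors(track)
  if (nrow(s) == 0L) return(0)
  sum(sqrt(rowSums(s * s)))
}

#' @rdname measures
#' @export
duration <- function(track) {
  tt <- track_t(track)
  tt[length(tt)] - tt[1]
}

#' @rdname measures
#' @export
speed <- function(track) {
  dur <- duration(track)
  if (dur <= 0) return(NA_real_)
  track_length(track) / dur
}

#' @rdname measures
#' @export
straightness <- function(track) {
  len <- track_length(track)
  if (len == 0) return(NA_real_)
  displacement(track) / len
}

#' @rdname measures
#' @export
displacement_ratio <- function(track) {
  mx <- max_displacement(track)
  if (mx == 0) return(NA_real_)
  displacement(track) / mx
}

#' @rdname measures
#' @export
outreach_ratio <- function(track) {
  len <- track_length(track)
  if (len == 0) return(NA_real_)
  max_displacement(track) / len
}

#' @rdname measures
#' @export
turning_angles <- function(track) {
  s <- step_vectors(track)
  if (nrow(s) < 2L) return(numeric(0))
  vapply(seq_len(nrow(s) - 1L),
         function(k) vec_angle_deg(s[k, ], s[k + 1L, ]),
         numeric(1))
}

#' @rdname measures
#' @export
mean_turning_angle <- function(track) {
  a <- turning_angles(track)
  a <- a[!is.na(a)]
  if (length(a) == 0L) return(NA_real_)
  mean(a)
}

#' @rdname measures
#' @export
overall_angle <- function(track) {
  s <- step_vectors(track)
  if (nrow(s) < 1L) return(NA_real_)
  vec_angle_deg(s[1, ], s[nrow(s), ])
}

#' @rdname measures
#' @export
overall_dot <- function(track) {
  s <- step_vectors(track)
  if (nrow(s) < 1L) return(NA_real_)
  sum(s[1, ] * s[nrow(s), ])
}

#' Asphericity of a track's point cloud
#'
#' From the eigenvalues l_1 >= ... >= l_d of the gyration tensor (the
#' covariance matrix of the observed positions, unweighted by time),
#' \deqn{A = \sum_{i<j} (l_i - l_j)^2 / ((d-1) (\sum_i l_i)^2).}
#' A = 1 for collinear configurations (one nonzero eigenvalue), A = 0 for
#' isotropic ones (all eigenvalues equal).  `NA` when all points coincide.
#'
#' @param track a track matrix.
#' @export
asphericity <- function(track) {
  p <- track_pos(track)
  if (nrow(p) < 2L) return(NA_real_)
  centered <- sweep(p, 2, colMeans(p))
  gyr <- crossprod(centered) / nrow(p)
  lam <- eigen(gyr, symmetric = TRUE, only.values = TRUE)$values
  tot <- sum(lam)
  if (tot <= 0) return(NA_real_)
  d <- length(lam)
  num <- 0
  for (i in seq_len(d - 1L)) for (j in (i + 1L):d) num <- num + (lam[i] - lam[j])^2
  num / ((d - 1) * tot^2)
}

# registry used by the pipeline and by name-based interfaces
measure_registry <- function() {
  list(
    displacement = displacement,
    square_displacement = square_displacement,
    max_displacement = max_displacement,
    track_length = track_length,
    duration = duration,
    speed = speed,
    straightness = straightness,
    displacement_ratio = displacement_ratio,
    outreach_ratio = outreach_ratio,
    mean_turning_angle = mean_turning_angle,
    overall_angle = overall_angle,
    overall_dot = overall_dot,
    asphericity = asphericity
  )
}

#' Look up a built-in measure by name
#' @param name measure name, e.g. `"speed"`; functions are passed through.
#' @return The measure function.
#' @export
get_measure <- function(name) {
  if (is.function(name)) return(name)
  reg <- measure_registry()
  if (!name %in% names(reg)) {
    stop("unknown measure '", name, "'; available: ",
         paste(names(reg), collapse = ", "))
  }
  reg[[name]]
}

#' Apply a measure at the cell-based, step-based or staggered scale
#'
#' Cell-based: one value per whole track.  Step-based: one value per
#' subtrack of `length` steps (default 1, i.e. per step), pooled across
#' tracks.  Staggered: one triangular matrix per track over all contiguous
#' subtracks.
#'
#' @param x tracks object.
#' @param measure measure function or built-in name.
#' @param scale `"cell"`, `"step"` or `"staggered"`.
#' @param length,overlap subtrack length/overlap for the step-based scale.
#' @return For `"cell"`/`"step"`: a data frame with ids (and, step-based,
#'   the parent id and 0-based range) and the measure `value`, undefined
#'   values kept as NA.  For `"staggered"`: a named list of matrices.
#' @export
apply_measure <- function(x, measure, scale = c("cell", "step", "staggered"),
                          length = 1L, overlap = length - 1L) {
  x <- as_tracks(x)
  measure <- get_measure(measure)
  scale <- match.arg(scale)
  if (scale == "cell") {
    data.frame(id = names(x),
               value = vapply(x, function(tr) as.numeric(measure(tr)), numeric(1)),
               row.names = NULL, stringsAsFactors = FALSE)
  } else if (scale == "step") {
    st <- subtracks(x, length = length, overlap = overlap)
    rng <- attr(st, "ranges")
    data.frame(id = names(st), parent = rng$parent, i = rng$i, j = rng$j,
               value = vapply(st, function(tr) as.numeric(measure(tr)), numeric(1)),
               row.names = NULL, stringsAsFactors = FALSE)
  } else {
    lapply(x, apply_staggered, measure = measure)
  }
}

#' Aggregate a measure over subtrack length: MSD and autocorrelation curves
#'
#' Evaluates `measure` on every subtrack of L steps, for each L in `lags`,
#' and summarizes per lag as mean, variance and subtrack count.  With
#' `measure = square_displacement` this is the mean squared displacement
#' curve; with `overall_dot` the displacement autocovariance versus lag;
#' with `overall_angle` the angle autocorrelation.  The lag axis is
#' reported both in steps and in time units (`lag * dt`, dt the common step
#' duration); datasets with heterogeneous step durations must be
#' gap-repaired first (see [repair_gaps()]) and raise an error here.
#'
#' By default subtracks overlap maximally, which uses all the data (n per
#' lag is reported so the dependence between overlapping subtracks can be
#' accounted for); `overlap = "none"` gives independent subtracks.
#'
#' @param x tracks object.
#' @param measure measure function or name (default squared displacement).
#' @param lags integer vector of subtrack lengths in steps; defaults to
#'   `1:(max steps - 1)`.
#' @param overlap `"max"` or `"none"`.
#' @param ... ignored.
#' @return A data frame of class `"msd_curve"` with columns
#'   `lag, dt, mean, var, n` and attributes `dim`, `delta_t`, `measure`.
#' @export
aggregate.tracks <- function(x, measure = square_displacement, lags = NULL,
                             overlap = c("max", "none"), ...) {
  x <- as_tracks(x)
  mname <- if (is.character(measure)) measure else deparse(substitute(measure))[1]
  measure <- get_measure(measure)
  overlap <- match.arg(overlap)
  if (length(x) == 0L) stop("empty tracks object")
  dts <- unlist(lapply(x, function(tr) diff(track_t(tr))))
  if (length(dts) == 0L) stop("no steps in dataset")
  dt0 <- stats::median(dts)
  if (any(abs(dts - dt0) > 1e-6 * dt0)) {
    stop("heterogeneous step durations; repair gaps (repair_gaps) before aggregating")
  }
  max_steps <- max(vapply(x, nrow, integer(1))) - 1L
  if (is.null(lags)) lags <- seq_len(max(max_steps, 1L))
  lags <- sort(unique(as.integer(lags)))
  if (any(lags < 1L)) stop("lags must be >= 1 step")
  rows <- lapply(lags, function(L) {
    st <- subtracks(x, length = L,
                    overlap = if (overlap == "max") L - 1L else 0L)
    if (length(st) == 0L) {
      return(data.frame(lag = L, dt = L * dt0, mean = NA_real_,
                        var = NA_real_, n = 0L))
    }
    vals <- vapply(st, function(tr) as.numeric(measure(tr)), numeric(1))
    vals <- vals[!is.na(vals)]
    data.frame(lag = L, dt = L * dt0, mean = mean(vals),
               var = if (length(vals) > 1L) stats::var(vals) else NA_real_,
               n = length(vals))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("msd_curve", "data.frame"),
            dim_track = track_dim(x), delta_t = dt0,
            measure_name = mname)
}

#' Mean squared displacement curve
#'
#' Identical in definition to `aggregate(x, square_displacement, ...)` but
#' computed by a vectorized shortcut (squared norms of position differences
#' at each lag offset) rather than by materializing every subtrack, which
#' matters inside simulation-based model fitting.
#' @inheritParams aggregate.tracks
#' @export
msd <- function(x, lags = NULL, overlap = c("max", "none")) {
  x <- as_tracks(x)
  overlap <- match.arg(overlap)
  if (length(x) == 0L) stop("empty tracks object")
  dts <- unlist(lapply(x, function(tr) diff(track_t(tr))))
  if (length(dts) == 0L) stop("no steps in dataset")
  dt0 <- stats::median(dts)
  if (any(abs(dts - dt0) > 1e-6 * dt0)) {
    stop("heterogeneous step durations; repair gaps (repair_gaps) before aggregating")
  }
  n_steps <- vapply(x, nrow, integer(1)) - 1L
  if (is.null(lags)) lags <- seq_len(max(n_steps, 1L))
  lags <- sort(unique(as.integer(lags)))
  if (any(lags < 1L)) stop("lags must be >= 1 step")
  pos <- lapply(x, track_pos)
  rows <- lapply(lags, function(L) {
    vals <- unlist(lapply(seq_along(pos), function(k) {
      n <- n_steps[k]
      if (n < L) return(numeric(0))
      starts <- if (overlap == "max") 1:(n - L + 1L) else seq.int(1L, n - L + 1L, by = L)
      p <- pos[[k]]
      rowSums((p[starts + L, , drop = FALSE] - p[starts, , drop = FALSE])^2)
    }))
    if (length(vals) == 0L) {
      return(data.frame(lag = L, dt = L * dt0, mean = NA_real_,
                        var = NA_real_, n = 0L))
    }
    data.frame(lag = L, dt = L * dt0, mean = mean(vals),
               var = if (length(vals) > 1L) stats::var(vals) else NA_real_,
               n = length(vals))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("msd_curve", "data.frame"),
            dim_track = track_dim(x), delta_t = dt0,
            measure_name = "square_displacement")
}

#' @export
plot.msd_curve <- function(x, se = TRUE, ...) {
  graphics::plot(x$dt, x$mean, xlab = "lag (time units)", ylab = "mean", ...)
  if (se && all(!is.na(x$var))) {
    s <- sqrt(x$var / pmax(x$n, 1))
    graphics::arrows(x$dt, x$mean - s, x$dt, x$mean + s,
                     angle = 90, code = 3, length = 0.02)
  }
  invisible(x)
}
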