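#' Angles and distances to reference directions, points and planes
#'
#' Each of these is a track measure (track matrix -> scalar, see
#' [measures]) built on the track's *overall displacement vector* (first to
#' last observation).  Applied cell-based they quantify a whole track's
#' orientation; applied to 1-step subtracks (`apply_measure(x, m, "step")`)
#' they give the per-step angles used in bias and border-artifact analysis.
#'
#' \itemize{
#'   \item `angle_to_dir(dir)`: angle (degrees, `[0, 180]`) between the
#'     displacement and a fixed direction.  Under unbiased motion the mean
#'     is 90 degrees.
#'   \item `angle_to_point(p)`: angle between the displacement and the
#'     vector from the track's start to a fixed point.
#'   \item `angle_to_plane(p0, normal)`: angle (`[0, 90]`) between the
#'     displacement and the plane through `p0` with normal `normal`, i.e.
#'     90 degrees minus the angle to the normal.  For isotropic 3D motion
#'     the mean is 180/pi * (pi/2 - 1), about 32.70 degrees.
#'   \item `distance_to_point` / `distance_to_plane`: Euclidean distance
#'     from the track's *starting* observation to the reference.
#' }
#'
#' The `angle_to_*` factories return a measure function, so they compose
#' with [apply_measure()], [feature_matrix()] etc.; zero-displacement
#' tracks give `NA`.
#'
#' @param dir,normal nonzero reference vector (need not be normalized).
#' @param p,p0 reference point / a point on the reference plane.
#' @return A measure function.
#' @name reference_angles
NULL

#' @rdname reference_angles
#' @export
angle_to_dir <- function(dir) {
  if (vec_norm(dir) == 0) stop("reference direction must be nonzero")
  force(dir)
  function(track) {
    p <- track_pos(track)
    vec_angle_deg(p[nrow(p), ] - p[1, ], dir)
  }
}

#' @rdname reference_angles
#' @export
angle_to_point <- function(p) {
  force(p)
  function(track) {
    pos <- track_pos(track)
    vec_angle_deg(pos[nrow(pos), ] - pos[1, ], p - pos[1, ])
  }
}

#' @rdname reference_angles
#' @export
angle_to_plane <- function(p0, normal) {
  if (vec_norm(normal) == 0) stop("plane normal must be nonzero")
  force(p0); force(normal)
  function(track) {
    pos <- track_pos(track)
    a <- vec_angle_deg(pos[nrow(pos), ] - pos[1, ], normal)
    if (is.na(a)) return(NA_real_)
    abs(90 - a)
  }
}

#' @rdname reference_angles
#' @export
distance_to_point <- function(p) {
  force(p)
  function(track) vec_norm(track_pos(track)[1, ] - p)
}

#' @rdname reference_angles
#' @export
distance_to_plane <- function(p0, normal) {
  if (vec_norm(normal) == 0) stop("plane normal must be nonzero")
  force(p0); force(normal)
  n <- normal / vec_norm(normal)
  function(track) abs(sum((track_pos(track)[1, ] - p0) * n))
}

#' Per-step angle/distance table for artifact localization
#'
#' Joins, over the step decomposition of the dataset, the angle of each
#' step to a reference (direction, point or plane) with the distance of the
#' step's starting position to that reference.  Under unbiased motion the
#' expected angle is flat in distance (90 degrees for directions/points;
#' about 32.70 degrees for planes in 3D): localized deviations expose
#' drift, chemotactic bias or border artifacts such as reflection at the
#' imaging volume's edge.
#'
#' @param x tracks object.
#' @param ref reference: for `type = "dir"` a direction vector; for
#'   `"point"` a point; for `"plane"` a list with `p0` and `normal`.
#' @param type reference type.
#' @return Data frame with one row per step: parent id, 0-based step start
#'   index, `angle` (degrees) and `distance` (for `"dir"`, distance is from
#'   the dataset's bounding-box center, giving a position scale).
#' @export
step_normal_angles <- function(x, ref, type = c("dir", "point", "plane")) {
  x <- as_tracks(x)
  type <- match.arg(type)
  ang_fn <- switch(type,
    dir = angle_to_dir(ref),
    point = angle_to_point(ref),
    plane = angle_to_plane(ref$p0, ref$normal))
  dist_fn <- switch(type,
    dir = {
      allp <- do.call(rbind, lapply(x, track_pos))
      ctr <- (apply(allp, 2, min) + apply(allp, 2, max)) / 2
      distance_to_point(ctr)
    },
    point = distance_to_point(ref),
    plane = distance_to_plane(ref$p0, ref$normal))
  st <- subtracks(x, length = 1L, overlap = 0L)
  rng <- attr(st, "ranges")
  data.frame(parent = rng$parent, i = rng$i,
             angle = vapply(st, ang_fn, numeric(1)),
             distance = vapply(st, dist_fn, numeric(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Hotelling's T-squared test for directional bias in step displacements
#'
#' Pools the step displacement vectors of all tracks and tests the null
#' hypothesis that their mean is the zero vector, using Hotelling's
#' one-sample T-squared statistic
#' \deqn{T^2 = n \bar x^\top S^{-1} \bar x,}
#' with S the sample covariance of the n step vectors, transformed to
#' \deqn{F = T^2 (n - p) / (p (n - 1))}
#' and compared to the F(p, n - p) distribution.  This detects subtle
#' global directionality that individual-track statistics miss.
#'
#' Consecutive steps of one cell are autocorrelated, which inflates the
#' type-I error of the pooled test; `step_spacing = k` keeps only every
#' (k+1)-th step per track to thin that dependence (default 0 = use all
#' steps, in which case interpret small p-values with care).  3D data can
#' be tested on a coordinate subset via `dim_select` (e.g. `c(1, 2)` for
#' the xy projection).  Alternatively `per_track = TRUE` tests the per-track
#' mean step vectors, one vector per cell, which are independent across
#' cells.
#'
#' @param x tracks object.
#' @param step_spacing integer k >= 0: keep every (k+1)-th step per track.
#' @param dim_select integer vector of coordinate axes to test (default
#'   all).
#' @param alpha level of the confidence ellipse for the mean.
#' @param per_track test per-track mean step vectors instead of pooled
#'   steps.
#' @return An object of classes `"hotelling_test"` and `"htest"` with
#'   `statistic` (T2), `F`, `parameter` (df), `p.value`, `mean_vector`,
#'   `covariance`, `n`, and `ellipse`, a polyline (2D) of the (1 - alpha)
#'   confidence region of the mean step vector.
#' @export
hotellings_test <- function(x, step_spacing = 0L, dim_select = NULL,
                            alpha = 0.05, per_track = FALSE) {
  dname <- deparse(substitute(x))[1]
  x <- as_tracks(x)
  k <- as.integer(step_spacing)
  if (k < 0L) stop("step_spacing must be >= 0")
  steps_by_track <- lapply(x, function(tr) {
    s <- step_vectors(tr)
    if (nrow(s) == 0L) return(s)
    s[seq(1L, nrow(s), by = k + 1L), , drop = FALSE]
  })
  if (per_track) {
    rows <- lapply(steps_by_track, function(s) {
      if (nrow(s) == 0L) return(NULL)
      colMeans(s)
    })
    X <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  } else {
    X <- do.call(rbind, steps_by_track)
  }
  if (!is.null(dim_select)) X <- X[, dim_select, drop = FALSE]
  n <- nrow(X)
  p <- ncol(X)
  if (n <= p) stop("need more step vectors than tested dimensions (n = ",
                   n, ", p = ", p, ")")
  xbar <- colMeans(X)
  S <- stats::cov(X)
  Sinv <- tryCatch(solve(S), error = function(e) {
    stop("singular step covariance; reduce dimensions with dim_select")
  })
  T2 <- n * drop(t(xbar) %*% Sinv %*% xbar)
  Fstat <- T2 * (n - p) / (p * (n - 1))
  pval <- stats::pf(Fstat, p, n - p, lower.tail = FALSE)
  # (1-alpha) confidence region of the mean: ellipse axes from eigen(S)
  ev <- eigen(S, symmetric = TRUE)
  Fcrit <- stats::qf(1 - alpha, p, n - p)
  axis_len <- sqrt(ev$values * p * (n - 1) / (n * (n - p)) * Fcrit)
  ellipse <- NULL
  if (p == 2L) {
    theta <- seq(0, 2 * pi, length.out = 91)
    circ <- cbind(cos(theta), sin(theta))
    ellipse <- sweep(circ %*% diag(axis_len) %*% t(ev$vectors), 2, -xbar)
    colnames(ellipse) <- names(xbar)
  }
  structure(list(
    statistic = c(T2 = T2), F = Fstat,
    parameter = c(df1 = p, df2 = n - p),
    p.value = pval, mean_vector = xbar, covariance = S, n = n,
    alpha = alpha, ellipse = ellipse,
    ellipse_axes = list(directions = ev$vectors, lengths = axis_len),
    method = "Hotelling's one-sample T-squared test on step displacements",
    data.name = dname,
    alternative = "mean step displacement vector differs from zero"
  ), class = c("hotelling_test", "htest"))
}

#' @export
print.hotelling_test <- function(x, ...) {
  cat("\n\t", x$method, "\n\n")
  cat(sprintf("T2 = %.4g, F(%d, %d) = %.4g, p-value = %.4g\n",
              x$statistic, x$parameter[1], x$parameter[2], x$F, x$p.value))
  cat("n =", x$n, "step vectors; mean vector:",
      paste(sprintf("%.4g", x$mean_vector), collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.hotelling_test <- function(x, ...) {
  if (is.null(x$ellipse)) stop("confidence-ellipse plot available for p = 2 only")
  rng <- range(x$ellipse, 0)
  graphics::plot(x$ellipse, type = "l", xlim = rng, ylim = rng,
                 xlab = "mean step x", ylab = "mean step y", asp = 1, ...)
  graphics::points(x$mean_vector[1], x$mean_vector[2], pch = 19)
  graphics::points(0, 0, pch = 3)
  invisible(x)
}
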