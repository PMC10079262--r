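#' @keywords internal
# derive independent per-track substream seeds from one root seed, so a
# replicate set is reproducible regardless of evaluation order
derive_seeds <- function(seed, n) {
  if (is.null(seed)) return(rep(list(NULL), n))
  set.seed(as.integer(seed))
  as.list(sample.int(.Machine$integer.max, n))
}

with_seed <- function(seed, expr) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  expr
}

random_unit_vector <- function(dim, bias_dir = NULL, p_bias = 0) {
  repeat {
    u <- stats::rnorm(dim)
    nu <- vec_norm(u)
    if (nu > 0) { u <- u / nu; break }
  }
  if (!is.null(bias_dir) && p_bias > 0) {
    b <- bias_dir / vec_norm(bias_dir)
    u <- u + p_bias * b
    u <- u / vec_norm(u)
  }
  u
}

#' Simulate a simple random walk (Brownian-type) track
#'
#' Positions follow `p_k = p_{k-1} + drift + N(0, sd^2 I)`; observation
#' times are `k * delta_t`.  With `sd = 0` this degenerates to straight
#' constant-velocity motion.  The expected squared displacement over L
#' steps is `d * sd^2 * L` (plus the deterministic `||drift||^2 L^2` term
#' when drift is nonzero), i.e. diffusion coefficient
#' `D = sd^2 / (2 delta_t)` per axis.
#'
#' @param n_steps number of steps (track has `n_steps + 1` observations).
#' @param dim spatial dimensionality, 2 or 3.
#' @param delta_t observation interval (minutes).
#' @param sd per-axis standard deviation of one step's random increment
#'   (micrometers).
#' @param drift deterministic displacement added every step (micrometers
#'   per step).
#' @param seed optional integer; the same seed reproduces the track
#'   bit-for-bit.
#' @return A track matrix.
#' @export
brownian_track <- function(n_steps, dim = 3L, delta_t = 1, sd = 1,
                           drift = rep(0, dim), seed = NULL) {
  if (n_steps < 1L) stop("n_steps must be >= 1")
  if (sd < 0) stop("sd must be >= 0")
  with_seed(seed, {
    inc <- matrix(stats::rnorm(n_steps * dim, sd = sd), n_steps, dim)
    inc <- sweep(inc, 2, drift, "+")
    pos <- rbind(0, apply(inc, 2, cumsum))
    out <- cbind((0:n_steps) * delta_t, pos)
    colnames(out) <- c("t", c("x", "y", "z")[seq_len(dim)])
    out
  })
}

#' Simulate a track by bootstrapping steps from a reference dataset
#'
#' Draws step lengths and turning angles independently, with replacement,
#' from the empirical step-length and turning-angle distributions of a
#' reference dataset, and chains them into a new track: each step keeps
#' the previous heading rotated by the sampled turning angle (in 3D about
#' a uniformly random axis orthogonal to the heading; in 2D with a random
#' sign) and scaled to the sampled length.  The observation interval is
#' the modal step duration of the reference.  This preserves the
#' reference's speed and turning statistics while destroying any longer-
#' range correlation structure.
#'
#' @param n_steps number of steps to simulate.
#' @param reference tracks object with >= 2 steps and >= 1 defined turning
#'   angle.
#' @param seed optional integer seed (bit-reproducible).
#' @return A track matrix with `n_steps + 1` observations.
#' @export
bootstrap_track <- function(n_steps, reference, seed = NULL) {
  reference <- as_tracks(reference)
  if (n_steps < 1L) stop("n_steps must be >= 1")
  steps <- do.call(rbind, lapply(reference, step_vectors))
  if (is.null(steps) || nrow(steps) < 2L) stop("reference needs at least 2 steps")
  lens <- sqrt(rowSums(steps^2))
  if (all(lens == 0)) stop("degenerate reference: all steps have zero length")
  angles <- unlist(lapply(reference, turning_angles))
  angles <- angles[!is.na(angles)]
  if (length(angles) == 0L) stop("reference has no defined turning angle")
  dts <- unlist(lapply(reference, function(tr) diff(track_t(tr))))
  tab <- table(signif(dts, 10))
  dt <- as.numeric(names(tab)[which.max(tab)])   # modal step duration
  d <- track_dim(reference)
  with_seed(seed, {
    len_draw <- sample(lens, n_steps, replace = TRUE)
    ang_draw <- sample(angles, n_steps - 1L, replace = TRUE) * pi / 180
    dir <- random_unit_vector(d)
    pos <- matrix(0, n_steps + 1L, d)
    pos[2, ] <- len_draw[1] * dir
    if (n_steps >= 2L) {
      for (k in 2:n_steps) {
        theta <- ang_draw[k - 1L]
        if (d == 2L) {
          theta <- theta * sample(c(-1, 1), 1)
          rot <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
          dir <- drop(rot %*% dir)
        } else {
          # orthonormal basis perpendicular to the current heading
          ref <- if (abs(dir[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
          e1 <- ref - sum(ref * dir) * dir
          e1 <- e1 / vec_norm(e1)
          e2 <- c(dir[2] * e1[3] - dir[3] * e1[2],
                  dir[3] * e1[1] - dir[1] * e1[3],
                  dir[1] * e1[2] - dir[2] * e1[1])
          phi <- stats::runif(1, 0, 2 * pi)
          dir <- cos(theta) * dir + sin(theta) * (cos(phi) * e1 + sin(phi) * e2)
          dir <- dir / vec_norm(dir)
        }
        pos[k + 1L, ] <- pos[k, ] + len_draw[k] * dir
      }
    }
    out <- cbind((0:n_steps) * dt, pos)
    colnames(out) <- c("t", c("x", "y", "z")[seq_len(d)])
    out
  })
}

#' Simulate a T-cell-style stop-and-go random walk (Beauchemin model)
#'
#' The cell alternates *free runs* — straight motion at speed `v_free` for
#' `t_free` minutes in a direction drawn uniformly on the sphere (circle in
#' 2D) — with stationary *pauses* of `t_pause` minutes, after which a new
#' direction is drawn.  Directional bias is introduced by adding
#' `p_bias * bias_dir` to the uniform direction draw and renormalizing:
#' exactly uniform at `p_bias = 0`, increasingly aligned with `bias_dir` as
#' `p_bias` grows.  The process is started in a time-stationary state: the
#' initial phase is free with probability `t_free / (t_free + t_pause)`
#' and its remaining duration is uniform.  The continuous piecewise-linear
#' path is sampled exactly at multiples of `delta_t`.
#'
#' Default parameters follow the model's published parameterization for
#' T cells in lymph nodes (v_free = 18.8 um/min, t_free = 2 min,
#' t_pause = 0.5 min); they are defaults, not constants.  The long-run
#' motility is diffusive with mean squared displacement slope
#' `v_free^2 t_free^2 / (t_free + t_pause)` per unit time — in 3D a
#' motility coefficient `M = v_free^2 t_free^2 / (6 (t_free + t_pause))`.
#'
#' @param total_time total simulated time (minutes).
#' @param delta_t observation interval (minutes), > 0.
#' @param v_free free-run speed (micrometers per minute), > 0.
#' @param t_free free-run duration (minutes), > 0.
#' @param t_pause pause duration (minutes), >= 0.
#' @param dim 2 or 3.
#' @param bias_dir direction of bias (any nonzero vector) or NULL.
#' @param p_bias bias strength, >= 0.
#' @param stationary_start start the process in a time-stationary state
#'   (default).  With `FALSE` the track starts exactly at the beginning of
#'   a free run, which aligns phase boundaries with observations when
#'   `delta_t` divides the phase durations.
#' @param seed optional integer seed (bit-reproducible).
#' @return A track matrix observed at `0, delta_t, 2 delta_t, ...`.
#' @export
beauchemin_track <- function(total_time, delta_t = 0.5, v_free = 18.8,
                             t_free = 2, t_pause = 0.5, dim = 3L,
                             bias_dir = NULL, p_bias = 0,
                             stationary_start = TRUE, seed = NULL) {
  if (delta_t <= 0) stop("delta_t must be > 0")
  if (v_free <= 0 || t_free <= 0) stop("v_free and t_free must be > 0")
  if (t_pause < 0) stop("t_pause must be >= 0")
  if (total_time < delta_t) stop("total_time must cover at least one observation interval")
  with_seed(seed, {
    cycle <- t_free + t_pause
    node_t <- 0
    node_p <- matrix(0, 1, dim)
    t_now <- 0
    # stationary start: position within the cycle uniform
    offset <- if (stationary_start) stats::runif(1, 0, cycle) else 0
    if (offset < t_free) {
      phase <- "free"; remaining <- t_free - offset
      dir <- random_unit_vector(dim, bias_dir, p_bias)
    } else {
      phase <- "pause"; remaining <- cycle - offset
      dir <- NULL
    }
    while (t_now < total_time) {
      if (phase == "free") {
        t_next <- t_now + remaining
        p_next <- node_p[nrow(node_p), ] + v_free * remaining * dir
        phase <- "pause"; remaining <- t_pause
      } else {
        t_next <- t_now + remaining
        p_next <- node_p[nrow(node_p), ]
        phase <- "free"; remaining <- t_free
        dir <- random_unit_vector(dim, bias_dir, p_bias)
      }
      if (t_next > t_now) {
        node_t <- c(node_t, t_next)
        node_p <- rbind(node_p, p_next)
      }
      t_now <- t_next
    }
    obs_t <- seq(0, total_time, by = delta_t)
    pos <- vapply(seq_len(dim), function(j) {
      stats::approx(node_t, node_p[, j], xout = obs_t)$y
    }, numeric(length(obs_t)))
    out <- cbind(obs_t, matrix(pos, nrow = length(obs_t)))
    colnames(out) <- c("t", c("x", "y", "z")[seq_len(dim)])
    out
  })
}

#' Simulate a dataset of independent tracks
#'
#' Expands one root seed into independent per-track substreams and calls a
#' single-track generator once per track, so replicate sets are
#' reproducible regardless of execution order.
#'
#' @param n_tracks number of tracks.
#' @param generator function `(seed) -> track matrix` — typically a closure
#'   over [brownian_track()], [beauchemin_track()] or [bootstrap_track()].
#' @param seed root seed.
#' @param prefix id prefix; ids are `<prefix>01, <prefix>02, ...`.
#' @return A tracks object.
#' @export
simulate_tracks <- function(n_tracks, generator, seed = NULL, prefix = "sim") {
  seeds <- derive_seeds(seed, n_tracks)
  width <- max(2L, nchar(as.character(n_tracks)))
  lst <- lapply(seq_len(n_tracks), function(k) generator(seeds[[k]]))
  names(lst) <- sprintf("%s%0*d", prefix, width, seq_len(n_tracks))
  as_tracks(lst)
}

# ---- MSD model fitting ------------------------------------------------------

beauchemin_msd_slope <- function(v_free, t_free, t_pause) {
  v_free^2 * t_free^2 / (t_free + t_pause)
}

# model MSD at the empirical curve's lags, by forward simulation with
# common random numbers (same seed for every parameter evaluation)
simulate_model_msd <- function(pars, lags, delta_t, dim, n_sim, sim_seed,
                               steps_factor = 3L) {
  n_steps <- max(lags) * steps_factor
  trk <- simulate_tracks(n_sim, function(s) {
    beauchemin_track(total_time = n_steps * delta_t, delta_t = delta_t,
                     v_free = pars$v_free, t_free = pars$t_free,
                     t_pause = pars$t_pause, dim = dim, seed = s)
  }, seed = sim_seed, prefix = "m")
  curve <- msd(trk, lags = lags)
  curve$mean
}

#' Fit a random-walk model to an empirical MSD curve
#'
#' Least-squares fit of a motility model's mean squared displacement to an
#' empirical MSD curve over lags up to `max_fit_lag`.  Long lags should be
#' excluded from fitting because a limited imaging window biases the
#' empirical MSD downward at long timescales.
#'
#' Models:
#' \describe{
#'   \item{brownian}{MSD linear through the origin, `MSD(t) = a t` with one
#'     free parameter; the reported diffusion coefficient is
#'     `D = a / (2 d)`.}
#'   \item{beauchemin}{stop-and-go model of [beauchemin_track()]; its MSD
#'     is computed either by forward simulation with common random numbers
#'     (`model_msd = "simulate"`, the default — captures the ballistic bend
#'     at lags below the free-run duration) or from the asymptotic closed
#'     form `MSD(t) = v_free^2 t_free^2 / (t_free + t_pause) * t`
#'     (`model_msd = "asymptotic"`).  Free parameters are a subset of
#'     `v_free`, `t_free`, `t_pause` (default only `v_free`); the others
#'     are held at `fixed` or the model defaults.}
#' }
#'
#' All fitted lags are weighted equally by default;
#' `weighting = "inverse_variance"` down-weights noisy long-lag means by
#' `n / var`.
#'
#' @param empirical an `"msd_curve"` from [msd()] / [aggregate.tracks()].
#' @param model `"brownian"` or `"beauchemin"`.
#' @param max_fit_lag largest lag (in steps) used for fitting; default all.
#' @param fit_params character vector of Beauchemin parameters to fit.
#' @param fixed named list overriding Beauchemin defaults for non-free
#'   parameters.
#' @param model_msd how the Beauchemin model MSD is evaluated.
#' @param n_sim,sim_seed simulation size and common-random-number seed for
#'   `model_msd = "simulate"`.
#' @param weighting `"equal"` or `"inverse_variance"`.
#' @return An object of class `"msd_fit"` with components `model`, `par`
#'   (fitted parameters), `objective` (weighted sum of squared residuals),
#'   `lags` (the fitted subset of the curve), `fitted`, plus fit metadata;
#'   methods: `print`, `coef`, `predict`, `fitted`, `residuals`, `plot`.
#' @export
fit_msd <- function(empirical, model = c("brownian", "beauchemin"),
                    max_fit_lag = NULL, fit_params = "v_free",
                    fixed = list(), model_msd = c("simulate", "asymptotic"),
                    n_sim = 50L, sim_seed = 1L,
                    weighting = c("equal", "inverse_variance")) {
  model <- match.arg(model)
  model_msd <- match.arg(model_msd)
  weighting <- match.arg(weighting)
  cur <- empirical[empirical$n > 0 & !is.na(empirical$mean), , drop = FALSE]
  if (!is.null(max_fit_lag)) cur <- cur[cur$lag <= max_fit_lag, , drop = FALSE]
  if (nrow(cur) < 2L) stop("need at least 2 usable lags within max_fit_lag")
  d <- attr(empirical, "dim_track")
  if (is.null(d)) d <- 3L
  delta_t <- attr(empirical, "delta_t")
  if (is.null(delta_t)) delta_t <- cur$dt[1] / cur$lag[1]
  w <- switch(weighting,
              equal = rep(1, nrow(cur)),
              inverse_variance = {
                wv <- cur$n / cur$var
                wv[!is.finite(wv)] <- 0
                wv
              })

  if (model == "brownian") {
    slope <- sum(w * cur$dt * cur$mean) / sum(w * cur$dt^2)
    fitted_vals <- slope * cur$dt
    obj <- sum(w * (cur$mean - fitted_vals)^2)
    par <- c(D = slope / (2 * d))
    pred_fn <- function(t) slope * t
    details <- list(slope = slope)
  } else {
    defaults <- list(v_free = 18.8, t_free = 2, t_pause = 0.5)
    defaults[names(fixed)] <- fixed
    if (!all(fit_params %in% names(defaults))) {
      stop("fit_params must be a subset of v_free, t_free, t_pause")
    }
    model_vals <- function(pars) {
      if (model_msd == "simulate") {
        simulate_model_msd(pars, cur$lag, delta_t, d, n_sim, sim_seed)
      } else {
        beauchemin_msd_slope(pars$v_free, pars$t_free, pars$t_pause) * cur$dt
      }
    }
    objective <- function(theta) {
      pars <- defaults
      pars[fit_params] <- as.list(pmax(theta, 1e-8))
      sum(w * (cur$mean - model_vals(pars))^2)
    }
    if (length(fit_params) == 1L) {
      p0 <- defaults[[fit_params]]
      opt <- stats::optimize(objective, interval = c(p0 / 10, p0 * 10),
                             tol = p0 * 1e-3)
      theta <- opt$minimum; obj <- opt$objective
    } else {
      p0 <- unlist(defaults[fit_params])
      opt <- stats::optim(p0, objective, method = "Nelder-Mead",
                          control = list(maxit = 500))
      if (opt$convergence != 0) {
        stop("MSD fit did not converge (optim code ", opt$convergence,
             "): ", paste(opt$message, collapse = " "))
      }
      theta <- opt$par; obj <- opt$value
    }
    par <- stats::setNames(as.numeric(theta), fit_params)
    best <- defaults
    best[fit_params] <- as.list(as.numeric(theta))
    fitted_vals <- model_vals(best)
    pred_fn <- function(t) {
      beauchemin_msd_slope(best$v_free, best$t_free, best$t_pause) * t
    }
    details <- list(parameters = best, model_msd = model_msd,
                    n_sim = n_sim, sim_seed = sim_seed)
  }
  structure(list(model = model, par = par, objective = obj,
                 lags = cur, fitted = fitted_vals,
                 residuals = cur$mean - fitted_vals,
                 dim = d, delta_t = delta_t, weighting = weighting,
                 predict_fn = pred_fn, details = details),
            class = "msd_fit")
}

#' @export
print.msd_fit <- function(x, ...) {
  cat(sprintf("MSD fit: %s model, %d lags (steps %d..%d)\n", x$model,
              nrow(x$lags), min(x$lags$lag), max(x$lags$lag)))
  cat("  parameters:",
      paste(sprintf("%s = %.4g", names(x$par), x$par), collapse = ", "), "\n")
  cat(sprintf("  objective (weighted SSR): %.6g\n", x$objective))
  invisible(x)
}

#' @export
coef.msd_fit <- function(object, ...) object$par

#' @export
fitted.msd_fit <- function(object, ...) object$fitted

#' @export
residuals.msd_fit <- function(object, ...) object$residuals

#' @export
predict.msd_fit <- function(object, times = NULL, ...) {
  if (is.null(times)) return(object$fitted)
  object$predict_fn(times)
}

#' @export
plot.msd_fit <- function(x, ...) {
  graphics::plot(x$lags$dt, x$lags$mean, xlab = "lag (time units)",
                 ylab = "MSD", ...)
  graphics::lines(x$lags$dt, x$fitted, col = 2)
  invisible(x)
}
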