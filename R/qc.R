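#' Pairwise diagnostics for double-tracking detection
#'
#' One cell erroneously tracked as two ("double tracking") produces a pair
#' of near-identical tracks.  For every unordered pair of tracks with
#' temporal overlap this computes (i) the minimum distance between the two
#' cells over their shared timepoints and (ii) the angle between the two
#' tracks' overall displacement vectors.  Doubly tracked cells stand out
#' jointly at low distance *and* low angle; plotting the two columns
#' against each other reproduces the classic distance-angle QC plot.
#'
#' Timestamps are matched with tolerance `1e-6 * median step duration`;
#' pairs sharing no timepoint are omitted (their count is reported in the
#' `"n_skipped"` attribute) because positions at different times carry no
#' co-tracking signal.
#'
#' @param x tracks object with >= 2 tracks.
#' @return Data frame with columns `id_a, id_b, min_distance, pair_angle`
#'   (degrees, in `[0, 180]`; NA if either track has zero overall
#'   displacement), one row per qualifying pair.
#' @export
pair_diagnostics <- function(x) {
  x <- as_tracks(x)
  if (length(x) < 2L) stop("need at least 2 tracks")
  dts <- unlist(lapply(x, function(tr) diff(track_t(tr))))
  tol <- if (length(dts)) 1e-6 * stats::median(dts) else 1e-9
  ids <- names(x)
  disp <- lapply(x, function(tr) {
    p <- track_pos(tr)
    p[nrow(p), ] - p[1, ]
  })
  times <- lapply(x, track_t)
  pos <- lapply(x, track_pos)
  n_pairs <- length(x) * (length(x) - 1L) / 2L
  id_a <- character(n_pairs); id_b <- character(n_pairs)
  dmin <- numeric(n_pairs); ang <- numeric(n_pairs)
  keep <- logical(n_pairs)
  skipped <- 0L
  r <- 0L
  for (a in seq_len(length(x) - 1L)) {
    ta <- times[[a]]
    for (b in (a + 1L):length(x)) {
      r <- r + 1L
      tb <- times[[b]]
      # match shared timepoints within tolerance (both grids are sorted)
      ia <- findInterval(ta, tb - tol)
      ok <- ia >= 1L & ia <= length(tb) & abs(ta - tb[pmax(ia, 1L)]) <= tol
      if (!any(ok)) { skipped <- skipped + 1L; next }
      pa <- pos[[a]][ok, , drop = FALSE]
      pb <- pos[[b]][ia[ok], , drop = FALSE]
      keep[r] <- TRUE
      id_a[r] <- ids[a]; id_b[r] <- ids[b]
      dmin[r] <- sqrt(min(rowSums((pa - pb)^2)))
      ang[r] <- vec_angle_deg(disp[[a]], disp[[b]])
    }
  }
  out <- data.frame(id_a = id_a[keep], id_b = id_b[keep],
                    min_distance = dmin[keep], pair_angle = ang[keep],
                    stringsAsFactors = FALSE)
  attr(out, "n_skipped") <- skipped
  out
}

#' Rank track pairs by joint (distance, angle) evidence of double tracking
#'
#' Ranks each pair by the product of its rank on `min_distance` and its
#' rank on `pair_angle` (ties averaged); the pair with the smallest rank
#' product is the strongest double-tracking candidate.
#' @param pairs output of [pair_diagnostics()].
#' @return The same data frame with a `rank_product` column, sorted
#'   ascending.
#' @export
rank_pairs <- function(pairs) {
  rp <- rank(pairs$min_distance, ties.method = "average") *
    rank(pairs$pair_angle, ties.method = "average")
  out <- pairs[order(rp), , drop = FALSE]
  out$rank_product <- sort(rp)
  rownames(out) <- NULL
  out
}

#' Interpolate a track at new timepoints
#'
#' Resamples one track at `new_times` by linear or cubic-spline
#' interpolation of each coordinate against time.  Extrapolation outside
#' the observed time range is refused.  With linear interpolation, original
#' observations contained in `new_times` are reproduced exactly.
#'
#' @param track single track matrix (or 1-track tracks object).
#' @param new_times timestamps within `[t_first, t_last]`.
#' @param method `"linear"` (needs >= 2 observations) or `"spline"`
#'   (needs >= 4).
#' @return A track matrix observed at `new_times`.
#' @export
interpolate_track <- function(track, new_times, method = c("linear", "spline")) {
  if (inherits(track, "tracks")) {
    if (length(track) != 1L) stop("interpolate_track() expects a single track")
    track <- track[[1]]
  }
  method <- match.arg(method)
  tt <- track_t(track)
  if (nrow(track) < 2L) stop("need at least 2 observations to interpolate")
  if (method == "spline" && nrow(track) < 4L) {
    stop("spline interpolation needs at least 4 observations")
  }
  if (any(new_times < tt[1] - 1e-12) || any(new_times > tt[length(tt)] + 1e-12)) {
    stop("new_times outside the observed time range (no extrapolation)")
  }
  new_times <- sort(new_times)
  p <- track_pos(track)
  coords <- vapply(seq_len(ncol(p)), function(j) {
    if (method == "linear") {
      stats::approx(tt, p[, j], xout = new_times)$y
    } else {
      stats::spline(tt, p[, j], xout = new_times, method = "fmm")$y
    }
  }, numeric(length(new_times)))
  out <- cbind(new_times, matrix(coords, nrow = length(new_times)))
  colnames(out) <- colnames(track)
  out
}

#' Detect irregular step durations (tracking gaps)
#'
#' Flags steps whose duration deviates from the per-track median step
#' duration by more than `tolerance` times that median — the signature of
#' dropped frames during tracking.
#'
#' @param x tracks object.
#' @param tolerance relative deviation beyond which a step is flagged
#'   (default 0.5, i.e. steps longer than 1.5x or shorter than 0.5x the
#'   median step duration).
#' @return Data frame with one row per step: `id`, `step` (1-based step
#'   index), `dt`, `ref_dt` (per-track median) and `flagged`.
#' @export
detect_gaps <- function(x, tolerance = 0.5) {
  x <- as_tracks(x)
  rows <- lapply(names(x), function(id) {
    dt <- diff(track_t(x[[id]]))
    if (length(dt) == 0L) return(NULL)
    ref <- stats::median(dt)
    data.frame(id = id, step = seq_along(dt), dt = dt, ref_dt = ref,
               flagged = abs(dt - ref) > tolerance * ref,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(id = character(0), step = integer(0), dt = numeric(0),
                      ref_dt = numeric(0), flagged = logical(0))
  }
  rownames(out) <- NULL
  out
}

#' Repair tracking gaps
#'
#' Three strategies for tracks with irregular step durations:
#' \describe{
#'   \item{drop}{remove every track containing a flagged step;}
#'   \item{split}{cut tracks at flagged steps into separate tracks, ids
#'     suffixed `.1`, `.2`, ... in temporal order (total observation count
#'     is conserved);}
#'   \item{interpolate}{linearly resample each track onto a uniform grid at
#'     its median step duration, from first to last observation.}
#' }
#'
#' @inheritParams detect_gaps
#' @param how repair strategy.
#' @return A list with the repaired `tracks` and the gap `report` from
#'   [detect_gaps()] on the input.
#' @export
repair_gaps <- function(x, how = c("split", "drop", "interpolate"),
                        tolerance = 0.5) {
  x <- as_tracks(x)
  how <- match.arg(how)
  report <- detect_gaps(x, tolerance = tolerance)
  out <- list()
  for (id in names(x)) {
    tr <- x[[id]]
    flags <- report$flagged[report$id == id]
    if (!any(flags)) { out[[id]] <- tr; next }
    if (how == "drop") next
    if (how == "split") {
      cuts <- which(flags)                  # split after observation `cuts`
      bounds <- c(0L, cuts, nrow(tr))
      pieces <- 0L
      for (k in seq_len(length(bounds) - 1L)) {
        seg <- tr[(bounds[k] + 1L):bounds[k + 1L], , drop = FALSE]
        pieces <- pieces + 1L
        new_id <- paste0(id, ".", pieces)
        while (new_id %in% c(names(x), names(out))) {
          new_id <- paste0(new_id, "s")     # collision guard
        }
        out[[new_id]] <- seg
      }
    } else {                                # interpolate
      tt <- track_t(tr)
      ref <- stats::median(diff(tt))
      grid <- seq(tt[1], tt[length(tt)], by = ref)
      out[[id]] <- interpolate_track(tr, grid, method = "linear")
    }
  }
  tracks <- as_tracks(out, time_unit = attr(x, "time_unit"),
                      space_unit = attr(x, "space_unit"))
  list(tracks = tracks, report = report)
}

#' Filter tracks by a predicate or a measure range
#'
#' @param x tracks object.
#' @param predicate either a function (track matrix -> logical) or NULL.
#' @param min_steps minimum number of steps to keep a track (applied in
#'   addition to `predicate`).
#' @return The sub-dataset of tracks passing all conditions.
#' @export
filter_tracks <- function(x, predicate = NULL, min_steps = 0L) {
  x <- as_tracks(x)
  keep <- vapply(x, function(tr) {
    ok <- nrow(tr) - 1L >= min_steps
    if (ok && !is.null(predicate)) ok <- isTRUE(predicate(tr))
    ok
  }, logical(1))
  x[keep]
}

#' Estimate and remove global drift
#'
#' Tissue or stage movement adds a shared directed displacement to every
#' track.  The drift velocity is estimated globally as the sum of all step
#' displacement vectors divided by the total step duration (equivalently,
#' the duration-weighted mean step velocity); per-track estimates are
#' deliberately not offered, since per-track drift is indistinguishable
#' from genuine directed motion.  `correct_drift()` subtracts
#' `v * (t - t_first)` from every observation of each track, so that
#' re-estimating drift on the corrected dataset gives (numerically) zero.
#'
#' @param x tracks object with at least one step.
#' @return `estimate_drift()`: the drift velocity vector (space units per
#'   time unit).
#' @export
estimate_drift <- function(x) {
  x <- as_tracks(x)
  steps <- lapply(x, step_vectors)
  total_disp <- Reduce(`+`, lapply(steps, colSums),
                       accumulate = FALSE)
  total_time <- sum(vapply(x, duration, numeric(1)))
  if (is.null(total_disp) || total_time <= 0) stop("dataset has zero total step duration")
  total_disp / total_time
}

#' @rdname estimate_drift
#' @param v drift velocity vector to subtract.
#' @return `correct_drift()`: the corrected tracks object.
#' @export
correct_drift <- function(x, v) {
  x <- as_tracks(x)
  d <- track_dim(x)
  if (length(v) != d) stop("drift vector has wrong dimensionality")
  out <- lapply(x, function(tr) {
    tt <- track_t(tr)
    shift <- outer(tt - tt[1], v)
    tr[, -1] <- track_pos(tr) - shift
    tr
  })
  as_tracks(out, time_unit = attr(x, "time_unit"), space_unit = attr(x, "space_unit"))
}

#' Translate every track to start at the origin
#'
#' Rigid per-track translation only: all step vectors, and hence all
#' step-based measures, are unchanged.  Origin-anchored tracks are what
#' rose plots display.
#' @param x tracks object.
#' @export
normalize_tracks <- function(x) {
  x <- as_tracks(x)
  out <- lapply(x, function(tr) {
    tr[, -1] <- sweep(track_pos(tr), 2, track_pos(tr)[1, ])
    tr
  })
  as_tracks(out, time_unit = attr(x, "time_unit"), space_unit = attr(x, "space_unit"))
}
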