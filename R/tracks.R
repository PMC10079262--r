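#' Track datasets
#'
#' A *track* is the time-ordered sequence of positions of one tracked cell,
#' stored as a numeric matrix whose first column is the observation time
#' (minutes by convention) and whose remaining 2 or 3 columns are spatial
#' coordinates (micrometers by convention).  A *tracks object* is a named
#' list of such matrices sharing a common dimensionality, with `time_unit`
#' and `space_unit` attributes carried along as metadata.  All analysis
#' functions in this package consume and return tracks objects.
#'
#' Invariants enforced by [as_tracks()]:
#' \itemize{
#'   \item every track has at least one observation;
#'   \item times are strictly increasing within a track (duplicate
#'     timestamps signal tracking faults and are an error, never averaged);
#'   \item all tracks share the same spatial dimensionality (2 or 3);
#'   \item track ids are unique and tracks are kept in lexicographic id
#'     order, so every downstream statistic is deterministic.
#' }
#'
#' @param x a named list of numeric matrices (columns `t, x, y[, z]`), a
#'   long-format data frame, or an existing tracks object.
#' @param time_unit,space_unit unit labels stored as metadata; no unit
#'   conversion is ever performed.
#' @param ... passed on to methods.
#'
#' @return An object of class `"tracks"`.
#' @seealso [read_tracks()], [subtracks()], [as.data.frame.tracks()]
#' @export
as_tracks <- function(x, ...) UseMethod("as_tracks")

#' @rdname as_tracks
#' @export
as_tracks.tracks <- function(x, ...) x

#' @rdname as_tracks
#' @export
as_tracks.list <- function(x, time_unit = "min", space_unit = "micron", ...) {
  if (length(x) == 0L) {
    out <- structure(list(), class = "tracks",
                     time_unit = time_unit, space_unit = space_unit)
    return(out)
  }
  ids <- names(x)
  if (is.null(ids)) ids <- as.character(seq_along(x))
  if (anyDuplicated(ids)) {
    stop("duplicate track ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  x <- lapply(x, function(tr) {
    tr <- as.matrix(tr)
    storage.mode(tr) <- "double"
    tr
  })
  names(x) <- ids
  dims <- vapply(x, function(tr) ncol(tr) - 1L, integer(1))
  if (length(unique(dims)) > 1L) {
    stop("all tracks must share the same spatial dimensionality; found ",
         paste(sort(unique(dims)), collapse = " and "))
  }
  d <- dims[[1]]
  if (!d %in% 2:3) stop("tracks must be 2D or 3D (got d = ", d, ")")
  for (id in ids) validate_track(x[[id]], id)
  x <- lapply(x, function(tr) {
    colnames(tr) <- c("t", c("x", "y", "z")[seq_len(d)])
    tr
  })
  x <- x[order(ids)]
  structure(x, class = "tracks", time_unit = time_unit, space_unit = space_unit)
}

validate_track <- function(tr, id) {
  if (nrow(tr) < 1L) stop("track '", id, "' has no observations")
  if (anyNA(tr)) stop("track '", id, "' contains missing values")
  dt <- diff(tr[, 1])
  if (length(dt) && any(dt <= 0)) {
    bad <- tr[which(dt <= 0)[1] + 1L, 1]
    stop("track '", id, "' has non-increasing times (duplicate or out-of-order timestamp at t = ",
         bad, ")")
  }
  invisible(tr)
}

#' @rdname as_tracks
#' @param id_col,t_col,pos_cols column names holding the track id, the
#'   timestamp and the coordinates when converting a long-format data frame.
#' @export
as_tracks.data.frame <- function(x, id_col = "id", t_col = "t", pos_cols = NULL,
                                 time_unit = "min", space_unit = "micron", ...) {
  if (is.null(pos_cols)) pos_cols <- intersect(c("x", "y", "z"), names(x))
  needed <- c(id_col, t_col, pos_cols)
  missing_cols <- setdiff(needed, names(x))
  if (length(missing_cols)) {
    stop("column(s) not found: ", paste(missing_cols, collapse = ", "))
  }
  for (cl in c(t_col, pos_cols)) {
    v <- x[[cl]]
    if (!is.numeric(v)) {
      conv <- suppressWarnings(as.numeric(as.character(v)))
      if (anyNA(conv) && !all(is.na(v))) {
        row <- which(is.na(conv) & !is.na(v))[1]
        stop("non-numeric value in column '", cl, "' at row ", row)
      }
      x[[cl]] <- conv
    }
  }
  key <- paste(x[[id_col]], x[[t_col]], sep = "\r")
  if (anyDuplicated(key)) {
    dup <- x[duplicated(key), , drop = FALSE][1, ]
    stop("duplicate observation for track '", dup[[id_col]], "' at t = ", dup[[t_col]])
  }
  lst <- split(x[, c(t_col, pos_cols), drop = FALSE], as.character(x[[id_col]]))
  lst <- lapply(lst, function(df) {
    m <- as.matrix(df[order(df[[t_col]]), , drop = FALSE])
    rownames(m) <- NULL
    m
  })
  as_tracks(lst, time_unit = time_unit, space_unit = space_unit)
}

#' Convert a tracks object to a long-format data frame
#'
#' The inverse of [as_tracks()] on data frames: one row per observation with
#' columns `id, t, x, y[, z]`.  `as_tracks(as.data.frame(x))` reproduces `x`.
#'
#' @param x a tracks object.
#' @param row.names,optional,... ignored (present for S3 compatibility).
#' @export
as.data.frame.tracks <- function(x, row.names = NULL, optional = FALSE, ...) {
  if (length(x) == 0L) {
    cols <- c("t", "x", "y")
    df <- data.frame(id = character(0))
    for (cl in cols) df[[cl]] <- numeric(0)
    return(df)
  }
  n <- vapply(x, nrow, integer(1))
  mat <- do.call(rbind, unname(x))
  out <- data.frame(id = rep(names(x), n), stringsAsFactors = FALSE)
  for (j in seq_len(ncol(mat))) out[[colnames(x[[1]])[j]]] <- mat[, j]
  rownames(out) <- NULL
  out
}

#' @export
print.tracks <- function(x, ...) {
  d <- track_dim(x)
  cat(sprintf("Tracks object: %d track(s), %dD, units (%s, %s)\n",
              length(x), if (is.na(d)) 0L else d,
              attr(x, "space_unit"), attr(x, "time_unit")))
  if (length(x)) {
    n <- vapply(x, nrow, integer(1))
    cat(sprintf("  observations per track: min %d / median %g / max %d\n",
                min(n), stats::median(n), max(n)))
    cat("  ids: ", paste(utils::head(names(x), 6), collapse = ", "),
        if (length(x) > 6) ", ..." else "", "\n", sep = "")
  }
  invisible(x)
}

#' @export
summary.tracks <- function(object, ...) {
  df <- data.frame(
    id = names(object),
    n_obs = vapply(object, nrow, integer(1)),
    duration = vapply(object, duration, numeric(1)),
    displacement = vapply(object, displacement, numeric(1)),
    length = vapply(object, track_length, numeric(1)),
    speed = vapply(object, speed, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  df
}

#' @export
`[.tracks` <- function(x, i, ...) {
  out <- unclass(x)[i]
  structure(out, class = class(x),
            time_unit = attr(x, "time_unit"), space_unit = attr(x, "space_unit"))
}

#' @export
c.tracks <- function(...) {
  parts <- list(...)
  lst <- do.call(c, lapply(parts, unclass))
  as_tracks(lst, time_unit = attr(parts[[1]], "time_unit"),
            space_unit = attr(parts[[1]], "space_unit"))
}

#' Spatial dimensionality of a tracks object or single track
#' @param x tracks object or track matrix.
#' @return 2 or 3 (NA for an empty tracks object).
#' @export
track_dim <- function(x) {
  if (inherits(x, "tracks")) {
    if (length(x) == 0L) return(NA_integer_)
    x <- x[[1]]
  }
  ncol(x) - 1L
}

track_pos <- function(tr) tr[, -1, drop = FALSE]
track_t <- function(tr) tr[, 1]

#' Plot tracks in the xy-plane
#'
#' Projects 3D tracks onto xy.  With `normalize = TRUE` every track is first
#' translated to start at the origin (the classic rose plot).
#' @param x tracks object.
#' @param normalize translate each track to start at the origin.
#' @param col per-track colours, recycled.
#' @param ... further arguments to [graphics::plot()].
#' @export
plot.tracks <- function(x, normalize = FALSE, col = NULL, ...) {
  if (normalize) x <- normalize_tracks(x)
  if (length(x) == 0L) stop("empty tracks object")
  if (is.null(col)) col <- grDevices::hcl.colors(max(length(x), 2L), "Dark 3")
  col <- rep_len(col, length(x))
  xs <- unlist(lapply(x, function(tr) tr[, 2]))
  ys <- unlist(lapply(x, function(tr) tr[, 3]))
  graphics::plot(NA, xlim = range(xs), ylim = range(ys),
                 xlab = paste0("x (", attr(x, "space_unit"), ")"),
                 ylab = paste0("y (", attr(x, "space_unit"), ")"), ...)
  for (k in seq_along(x)) graphics::lines(x[[k]][, 2], x[[k]][, 3], col = col[k])
  invisible(x)
}

# ---- delimited-text I/O -----------------------------------------------------

#' Read tracks from a delimited text file
#'
#' Reads a plain-text table with one row per observation and groups rows into
#' tracks, sorting by time within each track.  Dimensionality is inferred
#' from the presence of a mapped z column.  Column names and the delimiter
#' can be remapped through `dialect`, either a named list or the path of a
#' plain-text `key: value` file with any of the keys `sep`, `id`, `t`, `x`,
#' `y`, `z` — this covers track tables exported by other software.
#'
#' @param path file to read.
#' @param sep field delimiter (default comma).
#' @param dialect optional column mapping (named list or file path), see
#'   Details.
#' @param id_col,t_col,pos_cols explicit column mapping; overridden by
#'   `dialect` entries.
#' @inheritParams as_tracks
#' @return A tracks object.
#' @export
read_tracks <- function(path, sep = ",", dialect = NULL,
                        id_col = "id", t_col = "t", pos_cols = NULL,
                        time_unit = "min", space_unit = "micron") {
  if (!is.null(dialect)) {
    if (is.character(dialect) && length(dialect) == 1L) dialect <- read_dialect(dialect)
    if (!is.null(dialect$sep)) sep <- dialect$sep
    if (!is.null(dialect$id)) id_col <- dialect$id
    if (!is.null(dialect$t)) t_col <- dialect$t
    axes <- c(dialect$x, dialect$y, dialect$z)
    if (length(axes)) pos_cols <- axes
  }
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  as_tracks(df, id_col = id_col, t_col = t_col, pos_cols = pos_cols,
            time_unit = time_unit, space_unit = space_unit)
}

read_dialect <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, ":", fixed = TRUE)
  bad <- lengths(kv) < 2L
  if (any(bad)) stop("malformed dialect line: '", lines[bad][1], "'")
  out <- lapply(kv, function(p) trimws(paste(p[-1], collapse = ":")))
  names(out) <- trimws(vapply(kv, `[[`, character(1), 1))
  unknown <- setdiff(names(out), c("sep", "id", "t", "x", "y", "z"))
  if (length(unknown)) stop("unknown dialect key(s): ", paste(unknown, collapse = ", "))
  if (!is.null(out$sep) && out$sep == "\\t") out$sep <- "\t"
  out
}

#' Write tracks to a delimited text file
#'
#' Writes the long-format table with header `id,t,x,y[,z]`.  Reading the file
#' back with [read_tracks()] reproduces the dataset up to floating-point
#' round-trip.
#' @param x tracks object.
#' @param path output file.
#' @param sep field delimiter.
#' @export
write_tracks <- function(x, path, sep = ",") {
  x <- as_tracks(x)
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) format(v, digits = 17, trim = TRUE, scientific = FALSE))
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- subtrack decomposition -------------------------------------------------

#' Decompose tracks into subtracks of a fixed number of steps
#'
#' A subtrack of *length* L is a contiguous slice spanning L steps (L + 1
#' observations).  With maximal overlap (`overlap = length - 1`, the
#' default) a track with n steps yields `n - L + 1` subtracks; with
#' `overlap = 0` it yields `floor(n / L)` non-overlapping ones.  Consecutive
#' subtracks from the same parent start `length - overlap` steps apart.
#' Tracks shorter than L steps contribute none.  This decomposition powers
#' the step-based analysis scale: measures applied to `subtracks(x, L)`
#' are pooled over local track parts instead of whole cells.
#'
#' @param x tracks object (or a single track matrix).
#' @param length subtrack length in steps, >= 1.
#' @param overlap number of steps shared by consecutive subtracks,
#'   in `[0, length - 1]`.
#' @return A tracks object of subtracks with ids `<parent>.<k>`; the
#'   attribute `"ranges"` records parent id and 0-based inclusive
#'   observation indices `[i, j]` of every subtrack.
#' @export
subtracks <- function(x, length, overlap = length - 1L) {
  if (is.matrix(x)) x <- as_tracks(list(track = x))
  x <- as_tracks(x)
  L <- as.integer(length)
  o <- as.integer(overlap)
  if (L < 1L) stop("subtrack length must be >= 1 step")
  if (o < 0L || o > L - 1L) stop("overlap must be in [0, length - 1]")
  stride <- L - o
  per_track <- lapply(names(x), function(id) {
    tr <- x[[id]]
    n <- nrow(tr) - 1L                       # steps in parent
    if (n < L) return(NULL)
    starts <- seq.int(0L, n - L, by = stride)
    subs <- lapply(starts, function(i) tr[(i + 1L):(i + L + 1L), , drop = FALSE])
    names(subs) <- paste0(id, ".", seq_along(starts))
    list(subs = subs, parent = rep(id, length(starts)),
         i = starts, j = starts + L)
  })
  per_track <- per_track[!vapply(per_track, is.null, logical(1))]
  out <- do.call(c, lapply(per_track, `[[`, "subs"))
  res <- as_tracks(if (is.null(out)) list() else out,
                   time_unit = attr(x, "time_unit"),
                   space_unit = attr(x, "space_unit"))
  rng <- data.frame(
    parent = unlist(lapply(per_track, `[[`, "parent")) %||% character(0),
    i = unlist(lapply(per_track, `[[`, "i")) %||% integer(0),
    j = unlist(lapply(per_track, `[[`, "j")) %||% integer(0),
    stringsAsFactors = FALSE)
  rownames(rng) <- NULL
  rng <- rng[match(names(res), paste0(rng$parent, ".",
                                      stats::ave(rng$i, rng$parent, FUN = seq_along))), ,
             drop = FALSE]
  rownames(rng) <- NULL
  attr(res, "ranges") <- rng
  res
}

#' All contiguous subtracks of one track (the staggered decomposition)
#'
#' Enumerates every contiguous slice `[i, j]` with `i < j` (0-based
#' observation indices) of a single track: a track with n steps yields
#' `n (n + 1) / 2` subtracks.  Any measure evaluated over this set can be
#' rendered as a triangular matrix, see [apply_staggered()].
#'
#' @param track a single track matrix (or a 1-track tracks object).
#' @return A tracks object of subtracks named `"<i>.<j>"` with a `"ranges"`
#'   attribute; empty for a single-observation track.
#' @export
staggered_subtracks <- function(track) {
  if (inherits(track, "tracks")) {
    if (length(track) != 1L) stop("staggered_subtracks() expects a single track")
    track <- track[[1]]
  }
  n_obs <- nrow(track)
  out <- list()
  ranges <- list()
  if (n_obs >= 2L) {
    for (i in 0:(n_obs - 2L)) {
      for (j in (i + 1L):(n_obs - 1L)) {
        sid <- paste0(i, ".", j)
        out[[sid]] <- track[(i + 1L):(j + 1L), , drop = FALSE]
        ranges[[sid]] <- data.frame(parent = "track", i = i, j = j,
                                    stringsAsFactors = FALSE)
      }
    }
  }
  res <- as_tracks(out)
  rng <- if (length(ranges)) do.call(rbind, ranges[names(res)]) else
    data.frame(parent = character(0), i = integer(0), j = integer(0))
  rownames(rng) <- NULL
  attr(res, "ranges") <- rng
  res
}

#' Evaluate a measure over the staggered decomposition of a track
#'
#' @param track single track matrix or 1-track tracks object.
#' @param measure a track measure (function: track matrix -> scalar).
#' @return An upper-triangular matrix M with `M[i+1, j+1]` the measure on
#'   the subtrack spanning observations i..j; NA elsewhere.
#' @export
apply_staggered <- function(track, measure) {
  if (inherits(track, "tracks")) {
    if (length(track) != 1L) stop("apply_staggered() expects a single track")
    track <- track[[1]]
  }
  n_obs <- nrow(track)
  M <- matrix(NA_real_, n_obs, n_obs,
              dimnames = list(start = 0:(n_obs - 1L), end = 0:(n_obs - 1L)))
  if (n_obs < 2L) return(M)
  for (i in 0:(n_obs - 2L)) {
    for (j in (i + 1L):(n_obs - 1L)) {
      M[i + 1L, j + 1L] <- measure(track[(i + 1L):(j + 1L), , drop = FALSE])
    }
  }
  M
}
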