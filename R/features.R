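#' Per-track feature matrix
#'
#' Evaluates a set of track measures cell-based on every track and returns
#' the id-by-measure matrix used for embedding and clustering.  Because
#' motility features have incommensurate units (speed in micrometers per
#' minute, angles in degrees, squared displacement in square micrometers),
#' columns are standardized to mean 0 / sd 1 by default; constant columns
#' are centered and their zero scale recorded.  Centering and scaling
#' vectors are stored in attributes so the transform is reproducible.
#' Tracks on which a measure is undefined get NA entries; they are reported
#' and must be filtered before embedding/clustering (never imputed
#' silently).
#'
#' @param x tracks object (non-empty).
#' @param measures named list of measure functions and/or built-in measure
#'   names (see [get_measure()]).
#' @param scale standardize columns (default TRUE).
#' @return Numeric matrix, rows = track ids (dataset order), columns =
#'   measure names; attributes `"center"`, `"scale"` (NULL when
#'   `scale = FALSE`).
#' @export
feature_matrix <- function(x, measures, scale = TRUE) {
  x <- as_tracks(x)
  if (length(x) == 0L) stop("empty tracks object")
  if (length(measures) == 0L) stop("need at least one measure")
  if (is.null(names(measures))) {
    names(measures) <- vapply(seq_along(measures), function(k) {
      if (is.character(measures[[k]])) measures[[k]] else paste0("measure", k)
    }, character(1))
  }
  fns <- lapply(measures, get_measure)
  M <- vapply(fns, function(f) {
    vapply(x, function(tr) as.numeric(f(tr)), numeric(1))
  }, numeric(length(x)))
  M <- matrix(M, nrow = length(x),
              dimnames = list(names(x), names(measures)))
  ctr <- NULL; scl <- NULL
  if (scale) {
    ctr <- colMeans(M, na.rm = TRUE)
    scl <- apply(M, 2, stats::sd, na.rm = TRUE)
    scl[!is.finite(scl) | scl == 0] <- 0
    M <- sweep(M, 2, ctr)
    nz <- scl > 0
    M[, nz] <- sweep(M[, nz, drop = FALSE], 2, scl[nz], "/")
  }
  structure(M, center = ctr, scale = scl)
}

drop_undefined <- function(fm) {
  bad <- rowSums(is.na(fm)) > 0
  if (any(bad)) {
    message(sum(bad), " track(s) with undefined features excluded: ",
            paste(utils::head(rownames(fm)[bad], 5), collapse = ", "))
  }
  fm[!bad, , drop = FALSE]
}

#' Embed tracks in a low-dimensional feature map
#'
#' Dimensionality reduction of a per-track feature matrix by principal
#' component analysis or classical multidimensional scaling.  The PCA sign
#' convention is fixed (for each component, the largest-magnitude loading
#' is made positive) so embeddings are bit-reproducible; MDS on Euclidean
#' distances of the same matrix is deterministic by construction.
#'
#' @param fm feature matrix from [feature_matrix()]; rows with NA entries
#'   are excluded with a message.
#' @param method `"PCA"` or `"MDS"`.
#' @param k number of output dimensions, `<= ncol(fm)`.
#' @return List with `coords` (ids x k), `method`, and for PCA `loadings`
#'   and `explained` (variance fractions, summing to <= 1).
#' @export
track_feature_map <- function(fm, method = c("PCA", "MDS"), k = 2L) {
  method <- match.arg(method)
  fm <- drop_undefined(fm)
  k <- as.integer(k)
  if (k > ncol(fm)) stop("k exceeds the number of features")
  if (nrow(fm) < 2L) stop("need at least 2 tracks with defined features")
  if (method == "PCA") {
    pc <- stats::prcomp(fm, center = TRUE, scale. = FALSE)
    keep <- seq_len(min(k, ncol(pc$rotation)))
    rot <- pc$rotation[, keep, drop = FALSE]
    scores <- pc$x[, keep, drop = FALSE]
    for (j in seq_len(ncol(rot))) {
      s <- sign(rot[which.max(abs(rot[, j])), j])
      if (s < 0) { rot[, j] <- -rot[, j]; scores[, j] <- -scores[, j] }
    }
    list(coords = scores, loadings = rot,
         explained = (pc$sdev^2 / sum(pc$sdev^2))[keep], method = "PCA")
  } else {
    coords <- stats::cmdscale(stats::dist(fm), k = k)
    colnames(coords) <- paste0("MDS", seq_len(ncol(coords)))
    list(coords = coords, method = "MDS")
  }
}

#' Cluster tracks by their motility features
#'
#' Hierarchical clustering (average linkage on Euclidean distance, cut at
#' k groups; fully deterministic) or k-means (best of `nstart` restarts
#' under a fixed seed, recorded in the output so runs are reproducible).
#'
#' @param fm feature matrix from [feature_matrix()]; NA rows excluded with
#'   a message.
#' @param method `"hierarchical"` or `"kmeans"`.
#' @param k number of clusters, `2 <= k <=` number of tracks.
#' @param seed,nstart k-means reproducibility controls.
#' @return List with `labels` (named integer vector), `method`, and
#'   diagnostics: the `hclust` tree, or k-means `tot.withinss` plus the
#'   seed/restart metadata.
#' @export
cluster_tracks <- function(fm, method = c("hierarchical", "kmeans"), k = 2L,
                           seed = 1L, nstart = 10L) {
  method <- match.arg(method)
  fm <- drop_undefined(fm)
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  if (k > nrow(fm)) stop("k exceeds the number of tracks (", nrow(fm), ")")
  if (method == "hierarchical") {
    hc <- stats::hclust(stats::dist(fm), method = "average")
    labels <- stats::cutree(hc, k = k)
    list(labels = labels, method = "hierarchical", tree = hc)
  } else {
    set.seed(as.integer(seed))
    km <- stats::kmeans(fm, centers = k, nstart = as.integer(nstart))
    labels <- km$cluster
    names(labels) <- rownames(fm)
    list(labels = labels, method = "kmeans", inertia = km$tot.withinss,
         seed = as.integer(seed), nstart = as.integer(nstart))
  }
}

#' Select tracks whose measure value lies in a range
#'
#' Keeps tracks with `lower <= measure(track) <= upper`; tracks where the
#' measure is undefined are dropped.  Selections with disjoint ranges
#' partition a dataset, so groups of similar tracks can be compared on any
#' other feature downstream.
#'
#' @param x tracks object.
#' @param measure measure function or built-in name.
#' @param lower,upper inclusive bounds (`-Inf`/`Inf` allowed).
#' @export
select_tracks <- function(x, measure, lower = -Inf, upper = Inf) {
  if (lower > upper) stop("lower bound exceeds upper bound")
  x <- as_tracks(x)
  measure <- get_measure(measure)
  vals <- vapply(x, function(tr) as.numeric(measure(tr)), numeric(1))
  x[!is.na(vals) & vals >= lower & vals <= upper]
}
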