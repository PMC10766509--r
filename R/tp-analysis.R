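#' Project transition paths onto a coordinate plane
#'
#' Evaluates a pair of collective coordinates on every frame of every
#' path, yielding one 2D polyline per path (frame order preserved).
#' Coordinates may be column indices of the frame matrix or functions of
#' the position matrix.
#'
#' @param paths list of [tps_path()]s (or a `guided_tps_run`).
#' @param coords length-2 list/vector: column indices, column names, or
#'   functions `matrix -> numeric`.
#' @return list of two-column matrices (class `tp_polylines`).
#' @export
project_paths <- function(paths, coords = c(1, 2)) {
  if (inherits(paths, "guided_tps_run")) paths <- paths$paths
  eval_coord <- function(frames, co) {
    if (is.function(co)) return(co(frames))
    if (is.character(co)) {
      if (!co %in% colnames(frames)) abort(paste0("missing coordinate: ", co))
      return(frames[, co])
    }
    if (co > ncol(frames)) abort("coordinate index out of range")
    frames[, co]
  }
  out <- lapply(paths, function(p) {
    frames <- if (inherits(p, "tps_path")) p$frames else p
    cbind(eval_coord(frames, coords[[1]]), eval_coord(frames, coords[[2]]))
  })
  structure(out, class = "tp_polylines")
}

#' Dynamic time warping distance between polylines
#'
#' Classic DTW with Euclidean local cost and full dynamic-programming
#' alignment: symmetric, zero iff the sequences are identical, and
#' defined for sequences of unequal length. Note that DTW violates the
#' triangle inequality, so the pairwise matrix is a dissimilarity, not a
#' metric.
#'
#' @param a,b numeric matrices (one row per frame) or vectors.
#' @export
dtw_distance <- function(a, b) {
  if (!is.matrix(a)) a <- matrix(a, ncol = 1)
  if (!is.matrix(b)) b <- matrix(b, ncol = 1)
  if (nrow(a) == 0 || nrow(b) == 0) abort("empty polyline")
  cpp_dtw(a, b)
}

#' Pairwise DTW distance matrix
#'
#' @param polylines list of polylines (e.g. [project_paths()] output).
#' @param resample optional integer: arc-position resampling of each
#'   polyline to this many frames before DTW (DTW itself handles unequal
#'   lengths; resampling only bounds the cost of large ensembles).
#' @export
dtw_matrix <- function(polylines, resample = NULL) {
  if (!is.null(resample)) {
    polylines <- lapply(polylines, resample_polyline, n = resample)
  }
  n <- length(polylines)
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      D[i, j] <- D[j, i] <- dtw_distance(polylines[[i]], polylines[[j]])
    }
  }
  D
}

resample_polyline <- function(m, n) {
  if (!is.matrix(m)) m <- matrix(m, ncol = 1)
  if (nrow(m) <= n) return(m)
  idx <- unique(round(seq(1, nrow(m), length.out = n)))
  m[idx, , drop = FALSE]
}

#' Hierarchical clustering of transition paths
#'
#' Agglomerative clustering (average linkage by default) of a pairwise
#' path-dissimilarity matrix, cut at `n_clusters`. Competing-pathway
#' analyses typically look for two main clusters, the default cut,
#' reported together with the full dendrogram.
#'
#' @param D square symmetric nonnegative dissimilarity matrix.
#' @param n_clusters number of clusters for the cut.
#' @param linkage linkage criterion passed to [stats::hclust()].
#' @return list with `labels` (integer vector) and `hclust` (dendrogram
#'   object).
#' @export
hierarchical_cluster <- function(D, n_clusters = 2L, linkage = "average") {
  if (!is.matrix(D) || nrow(D) != ncol(D)) abort("D must be square")
  if (max(abs(D - t(D))) > 1e-8) abort("D must be symmetric")
  if (any(D < 0)) abort("D must be nonnegative")
  hc <- hclust(as.dist(D), method = linkage)
  list(labels = cutree(hc, k = n_clusters), hclust = hc)
}

#' Per-path density map
#'
#' 2D histogram over a regular grid in which each cell counts the number
#' of paths that visit it: a path visiting a cell any number of times
#' increments that cell by exactly one, so the maximum cell value is the
#' number of paths. This per-path counting rule weights mechanisms by
#' path frequency rather than by dwell time.
#'
#' @param polylines list of 2-column polylines.
#' @param breaks_x,breaks_y bin edges covering the data range (defaults:
#'   30 equal bins over the ensemble range).
#' @return tibble with `x`, `y` (cell centers) and `count`; the count
#'   matrix is attached as attribute `"matrix"`.
#' @export
path_density <- function(polylines, breaks_x = NULL, breaks_y = NULL) {
  if (length(polylines) == 0) {
    breaks_x <- breaks_x %||% seq(0, 1, length.out = 31)
    breaks_y <- breaks_y %||% seq(0, 1, length.out = 31)
  } else {
    all_pts <- do.call(rbind, polylines)
    breaks_x <- breaks_x %||% seq(min(all_pts[, 1]), max(all_pts[, 1]),
                                  length.out = 31)
    breaks_y <- breaks_y %||% seq(min(all_pts[, 2]), max(all_pts[, 2]),
                                  length.out = 31)
  }
  nx <- length(breaks_x) - 1L; ny <- length(breaks_y) - 1L
  counts <- matrix(0L, nx, ny)
  for (p in polylines) {
    ix <- findInterval(p[, 1], breaks_x, rightmost.closed = TRUE)
    iy <- findInterval(p[, 2], breaks_y, rightmost.closed = TRUE)
    ok <- ix >= 1 & ix <= nx & iy >= 1 & iy <= ny
    cells <- unique(cbind(ix[ok], iy[ok]))
    counts[cells] <- counts[cells] + 1L
  }
  mx <- (head(breaks_x, -1) + tail(breaks_x, -1)) / 2
  my <- (head(breaks_y, -1) + tail(breaks_y, -1)) / 2
  out <- tibble(x = rep(mx, times = ny), y = rep(my, each = nx),
                count = as.integer(counts))
  attr(out, "matrix") <- counts
  attr(out, "breaks_x") <- breaks_x
  attr(out, "breaks_y") <- breaks_y
  out
}

#' @rdname path_density
#' @param density a [path_density()] tibble.
#' @export
plot_path_density <- function(density) {
  ggplot2::ggplot(density, ggplot2::aes(x = .data$x, y = .data$y,
                                        fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "grey20") +
    ggplot2::labs(fill = "paths") +
    ggplot2::theme_minimal()
}
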