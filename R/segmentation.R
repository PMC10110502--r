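#' Segment a cell from a single frame
#'
#' Thresholds the frame (Otsu by default), keeps the largest connected
#' component and fills holes — the mask construction used before cortical
#' profiling. An empty mask is a valid, flagged outcome (nothing passed the
#' threshold), not an error, so batch runs survive empty frames.
#'
#' @param frame numeric matrix of intensities.
#' @param threshold `"otsu"` or a numeric cutoff; pixels strictly above it are
#'   foreground.
#' @param connectivity component connectivity, 4 (default) or 8.
#' @return logical matrix with attributes `empty` (flag), `threshold` (value
#'   used), `n_components`, `discarded_px`.
#' @export
segment_cell <- function(frame, threshold = "otsu", connectivity = 4L) {
  if (!is.matrix(frame) || length(frame) == 0L)
    abort_input("`frame` must be a non-empty matrix")
  thr <- if (identical(threshold, "otsu")) otsu_threshold(frame) else as.numeric(threshold)
  raw <- frame > thr
  if (!any(raw)) {
    out <- raw
    attr(out, "empty") <- TRUE
    attr(out, "threshold") <- thr
    attr(out, "n_components") <- 0L
    attr(out, "discarded_px") <- 0L
    return(out)
  }
  lc <- largest_component(raw, connectivity)
  out <- fill_holes(lc$mask)
  attr(out, "empty") <- FALSE
  attr(out, "threshold") <- thr
  attr(out, "n_components") <- lc$n_components
  attr(out, "discarded_px") <- lc$discarded_px
  out
}

#' Cortex ring mask
#'
#' The cortex mask is the set difference between the cell mask and its `n`-fold
#' erosion (default 4 passes, the convention of the cortical profiling
#' protocol). If erosion empties the mask (very small cells) the whole mask is
#' returned with a `degenerate` flag rather than erroring.
#'
#' @param mask logical cell mask (non-empty).
#' @param erosions number of erosion passes (default 4).
#' @param elem structuring element, `"cross"` (default) or `"box"`; see
#'   [erode_mask()].
#' @return logical ring mask with attribute `degenerate`.
#' @export
cortex_mask <- function(mask, erosions = 4L, elem = c("cross", "box")) {
  if (!is.matrix(mask) || !any(mask)) abort_input("`mask` must be a non-empty logical matrix")
  if (erosions < 0L) abort_param("`erosions` must be >= 0")
  elem <- match.arg(elem)
  eroded <- erode_mask(mask, n = erosions, elem = elem)
  if (!any(eroded)) {
    out <- mask
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  out <- mask & !eroded
  attr(out, "degenerate") <- FALSE
  out
}

#' Center of mass of a binary mask
#'
#' Unweighted centroid of the foreground pixel coordinates, in 0-based
#' `(y, x)` pixel coordinates.
#'
#' @param mask logical matrix with at least one `TRUE` pixel.
#' @return numeric `c(y, x)`.
#' @export
cell_center <- function(mask) {
  if (!is.matrix(mask) || !any(mask)) abort_input("`mask` must be a non-empty logical matrix")
  idx <- which(mask, arr.ind = TRUE)
  c(y = mean(idx[, 1]) - 1, x = mean(idx[, 2]) - 1)
}

#' Segment every frame of a movie
#'
#' Convenience wrapper producing the per-frame mask series consumed by the
#' profiling and protrusion code.
#'
#' @param stack an [image_stack()].
#' @inheritParams segment_cell
#' @inheritParams cortex_mask
#' @return an object of class `CellMaskSeries`: list with `masks`,
#'   `cortex_masks`, `centers` (T x 2 matrix, 0-based y/x), `erosions`, and
#'   per-frame `empty` / `degenerate` flags.
#' @export
segment_movie <- function(stack, threshold = "otsu", erosions = 4L,
                          elem = c("cross", "box"), connectivity = 4L) {
  elem <- match.arg(elem)
  nt <- n_frames(stack)
  masks <- vector("list", nt); rings <- vector("list", nt)
  centers <- matrix(NA_real_, nt, 2, dimnames = list(NULL, c("y", "x")))
  empty <- logical(nt); degen <- logical(nt)
  for (i in seq_len(nt)) {
    m <- segment_cell(get_frame(stack, i), threshold, connectivity)
    empty[i] <- attr(m, "empty")
    masks[[i]] <- m
    if (empty[i]) {
      rings[[i]] <- m
      degen[i] <- NA
    } else {
      r <- cortex_mask(m, erosions, elem)
      rings[[i]] <- r
      degen[i] <- attr(r, "degenerate")
      centers[i, ] <- cell_center(m)
    }
  }
  structure(list(masks = masks, cortex_masks = rings, centers = centers,
                 erosions = erosions, elem = elem,
                 empty = empty, degenerate = degen),
            class = "CellMaskSeries")
}

#' @export
print.CellMaskSeries <- function(x, ...) {
  cat(sprintf("<CellMaskSeries> %d frame(s), erosions = %d (%s element), %d empty\n",
              length(x$masks), x$erosions, x$elem, sum(x$empty)))
  invisible(x)
}

#' Local cell density from nuclei centroids
#'
#' For every nucleus, the mean Euclidean distance to its `k` nearest other
#' nuclei (default `k = 5`), the standard packing-density statistic for 3D
#' nuclei point fields.
#'
#' @param centroids numeric matrix or data frame with 2 or 3 coordinate
#'   columns, in micrometers.
#' @param k neighbour count (default 5).
#' @return object of class `NucleiDensityResult`: list with
#'   `per_nucleus_mean_distance` (um, one value per nucleus) and `k`.
#' @export
nuclei_density <- function(centroids, k = 5L) {
  xyz <- as.matrix(centroids)
  if (!is.numeric(xyz) || !(ncol(xyz) %in% c(2L, 3L)))
    abort_input("`centroids` must have 2 or 3 numeric coordinate columns")
  n <- nrow(xyz)
  if (n < k + 1L)
    abort_input(sprintf("need at least k + 1 = %d points, got %d", k + 1L, n))
  d2 <- as.matrix(stats::dist(xyz))
  diag(d2) <- Inf
  res <- apply(d2, 1L, function(row) mean(sort(row, partial = k)[seq_len(k)]))
  structure(list(per_nucleus_mean_distance = unname(res), k = as.integer(k)),
            class = "NucleiDensityResult")
}

#' @export
print.NucleiDensityResult <- function(x, ...) {
  cat(sprintf("<NucleiDensityResult> n = %d nuclei, k = %d, median distance = %.3g um\n",
              length(x$per_nucleus_mean_distance), x$k,
              median(x$per_nucleus_mean_distance)))
  invisible(x)
}
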