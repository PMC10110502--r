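## Binary morphology on logical matrices. No morphology package exists in the
## target R environment and the ring-mask primitive is central to the cortical
## profiling method, so these are implemented here and oracle-tested against
## brute-force set operations.

## Shift a logical matrix by (dy, dx), padding with `fill`.
shift_mask <- function(m, dy, dx, fill = FALSE) {
  out <- matrix(fill, nrow(m), ncol(m))
  nr <- nrow(m); nc <- ncol(m)
  src_r <- seq_len(nr) - dy; src_c <- seq_len(nc) - dx
  ok_r <- src_r >= 1L & src_r <= nr
  ok_c <- src_c >= 1L & src_c <= nc
  out[ok_r, ok_c] <- m[src_r[ok_r], src_c[ok_c]]
  out
}

elem_offsets <- function(elem = c("cross", "box")) {
  elem <- match.arg(elem)
  if (elem == "cross")
    list(c(0L, 0L), c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
  else
    do.call(c, lapply(-1:1, function(dy) lapply(-1:1, function(dx) c(dy, dx))))
}

#' Binary erosion
#'
#' Erodes a logical mask `n` times with a 3x3 structuring element. The default
#' `cross` element (4-connectivity) is isotropic on the pixel grid; use `box`
#' (8-connectivity) to match Fiji's default binary erode.
#'
#' @param mask logical matrix.
#' @param n number of erosion passes.
#' @param elem `"cross"` (4-neighbourhood) or `"box"` (8-neighbourhood).
#' @return eroded logical matrix.
#' @export
erode_mask <- function(mask, n = 1L, elem = c("cross", "box")) {
  offs <- elem_offsets(match.arg(elem))
  m <- mask
  for (k in seq_len(n)) {
    acc <- m
    for (o in offs) acc <- acc & shift_mask(m, o[1], o[2], fill = FALSE)
    m <- acc
    if (!any(m)) break
  }
  m
}

#' Binary dilation
#' @inheritParams erode_mask
#' @return dilated logical matrix.
#' @export
dilate_mask <- function(mask, n = 1L, elem = c("cross", "box")) {
  offs <- elem_offsets(match.arg(elem))
  m <- mask
  for (k in seq_len(n)) {
    acc <- m
    for (o in offs) acc <- acc | shift_mask(m, o[1], o[2], fill = FALSE)
    m <- acc
  }
  m
}

#' Fill holes in a binary mask
#'
#' Background pixels not reachable from the image border (4-connectivity) are
#' holes and get filled.
#'
#' @param mask logical matrix.
#' @return logical matrix with interior holes set to `TRUE`.
#' @export
fill_holes <- function(mask) {
  bg <- !mask
  reach <- matrix(FALSE, nrow(mask), ncol(mask))
  reach[1, ] <- bg[1, ]; reach[nrow(mask), ] <- bg[nrow(mask), ]
  reach[, 1] <- reach[, 1] | bg[, 1]; reach[, ncol(mask)] <- reach[, ncol(mask)] | bg[, ncol(mask)]
  repeat {
    grown <- (reach |
                shift_mask(reach, 1L, 0L) | shift_mask(reach, -1L, 0L) |
                shift_mask(reach, 0L, 1L) | shift_mask(reach, 0L, -1L)) & bg
    if (identical(grown, reach)) break
    reach <- grown
  }
  mask | (bg & !reach)
}

#' Label connected components
#'
#' @param mask logical matrix.
#' @param connectivity 4 or 8.
#' @return integer matrix: 0 = background, 1..k = component labels (labelled in
#'   raster-scan order of their first pixel).
#' @export
label_components <- function(mask, connectivity = 4L) {
  offs <- if (connectivity == 4L) elem_offsets("cross") else elem_offsets("box")
  offs <- offs[-1]  # drop (0,0)
  nr <- nrow(mask); nc <- ncol(mask)
  labels <- matrix(0L, nr, nc)
  todo <- which(mask)
  lab <- 0L
  off_lin <- vapply(offs, function(o) o[1] + o[2] * nr, numeric(1))
  for (start in todo) {
    if (labels[start] != 0L) next
    lab <- lab + 1L
    frontier <- start
    labels[start] <- lab
    while (length(frontier) > 0L) {
      src <- rep(frontier, each = length(off_lin))
      cand_all <- as.integer(src + rep(off_lin, times = length(frontier)))
      # guard column wrap-around: neighbour must stay within one row of source
      rows_s <- ((src - 1L) %% nr) + 1L
      keep <- cand_all >= 1L & cand_all <= nr * nc &
        abs(((cand_all - 1L) %% nr) + 1L - rows_s) <= 1L
      cand <- unique(cand_all[keep])
      cand <- cand[mask[cand] & labels[cand] == 0L]
      labels[cand] <- lab
      frontier <- cand
    }
  }
  labels
}

#' Keep the largest connected component
#'
#' @param mask logical matrix.
#' @param connectivity 4 or 8.
#' @return list with `mask` (largest component only), `n_components` found and
#'   `discarded_px` (total pixels dropped).
#' @export
largest_component <- function(mask, connectivity = 4L) {
  labels <- label_components(mask, connectivity)
  if (max(labels) == 0L)
    return(list(mask = mask & FALSE, n_components = 0L, discarded_px = 0L))
  sizes <- tabulate(labels[labels > 0L])
  best <- which.max(sizes)
  list(mask = labels == best,
       n_components = length(sizes),
       discarded_px = as.integer(sum(sizes) - sizes[best]))
}
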