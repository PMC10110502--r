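## Ratiometric (FRET-style) quantification and projection-based stain
## measurements. Only plain channel ratioing is implemented; spectral
## bleed-through and photobleaching corrections are out of scope.

#' Per-pixel acceptor/donor ratio map
#'
#' Ratio is computed inside the mask wherever the donor exceeds `donor_floor`
#' (default: 5% of the in-mask donor median, guarding against division
#' blow-ups); all other pixels are invalid and excluded from every mean.
#'
#' @param donor,acceptor co-registered numeric matrices of equal shape.
#' @param mask logical cell mask.
#' @param donor_floor minimum donor intensity; `NULL` for the default.
#' @return a `RatioMap`: list with `ratio` (matrix, `NA` where invalid),
#'   `mask`, `valid` (logical matrix), `donor_floor`, `no_valid` flag.
#' @export
ratio_map <- function(donor, acceptor, mask, donor_floor = NULL) {
  if (!all(dim(donor) == dim(acceptor)) || !all(dim(donor) == dim(mask)))
    abort_input("donor, acceptor and mask must have identical shapes")
  if (is.null(donor_floor)) {
    med <- median(donor[mask])
    donor_floor <- 0.05 * med
  }
  valid <- mask & donor > donor_floor
  ratio <- matrix(NA_real_, nrow(donor), ncol(donor))
  ratio[valid] <- acceptor[valid] / donor[valid]
  structure(list(ratio = ratio, mask = mask, valid = valid,
                 donor_floor = donor_floor, no_valid = !any(valid)),
            class = "RatioMap")
}

#' Whole-cell mean ratio
#'
#' @param map a `RatioMap` with at least one valid pixel.
#' @return mean ratio over valid masked pixels.
#' @export
whole_cell_value <- function(map) {
  if (map$no_valid || !any(map$valid))
    abort_input("no valid pixels (donor below floor everywhere)")
  mean(map$ratio[map$valid])
}

#' Per-day (per-repeat) normalization to a reference group
#'
#' Divides every value by the mean of the reference group measured in the
#' same repeat; thin wrapper over [per_repeat_normalize()].
#'
#' @param df data.frame with columns `value`, `group`, `repeat_id`.
#' @param reference_group reference (control) group label.
#' @return `df` with an added `normalized` column.
#' @export
normalize_per_day <- function(df, reference_group) {
  per_repeat_normalize(df, reference_group)
}

## principal (largest second-moment) axis of a binary mask; unit vector (x, y)
mask_principal_axis <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  xy <- cbind(x = idx[, 2] - 1, y = idx[, 1] - 1)
  ctr <- colMeans(xy)
  cc <- crossprod(sweep(xy, 2, ctr)) / nrow(xy)
  ev <- eigen(cc, symmetric = TRUE)
  axis <- ev$vectors[, 1]
  list(axis = axis, center = ctr)
}

#' Front/back ratio along the cell's long axis
#'
#' The mask is divided into four equal-length sections along its longest
#' (principal second-moment) axis; the front and back are the first and last
#' quarter. Returns mean(front quarter) / mean(back quarter) of the ratio
#' map. The axis sign (which end is the front) is set by `movement_axis`
#' (an angle in degrees or a 2-vector `(x, y)`); without it, the principal
#' axis orientation is used as-is (front = positive-projection end).
#'
#' @param map a `RatioMap`.
#' @param mask logical mask to quarter (defaults to the map's mask).
#' @param movement_axis optional direction defining the front.
#' @return list with `ratio` (front/back), `section_means`, `section_counts`.
#' @export
front_back_ratio <- function(map, mask = NULL, movement_axis = NULL) {
  if (is.null(mask)) mask <- map$mask
  if (sum(mask) < 5L) abort_input("mask too small to quarter")
  pa <- mask_principal_axis(mask)
  axis <- pa$axis
  if (!is.null(movement_axis)) {
    mv <- if (length(movement_axis) == 1L)
      c(cos(movement_axis * pi / 180), sin(movement_axis * pi / 180))
    else movement_axis / sqrt(sum(movement_axis^2))
    if (sum(axis * mv) < 0) axis <- -axis
  }
  idx <- which(mask, arr.ind = TRUE)
  proj <- (idx[, 2] - 1 - pa$center[1]) * axis[1] +
    (idx[, 1] - 1 - pa$center[2]) * axis[2]
  rng <- range(proj)
  if (diff(rng) <= 4) abort_input("mask extent along the axis is too small (<= 4 px)")
  brk <- rng[1] + diff(rng) * (1:3) / 4
  section <- findInterval(proj, brk) + 1L   # 1..4; partition by construction
  vals <- map$ratio[mask]
  sec_mean <- vapply(1:4, function(s) {
    v <- vals[section == s]
    v <- v[is.finite(v)]
    if (length(v) == 0L) NA_real_ else mean(v)
  }, numeric(1))
  if (!is.finite(sec_mean[4]) || !is.finite(sec_mean[1]))
    abort_input("front or back quarter has no valid pixels")
  list(ratio = sec_mean[4] / sec_mean[1],
       section_means = sec_mean,
       section_counts = tabulate(section, 4L),
       axis = axis)
}

#' Stain quantification from a z-stack projection
#'
#' Projects the stack (`average` over `slices`, default the first 10, or
#' `sum` over all slices), measures the mean intensity in the cell region,
#' subtracts the mean of the background-region means, and reports the
#' corrected value. A negative corrected mean is allowed but flagged.
#'
#' @param stack 3D array `Z x Y x X` or an [image_stack()] whose frames are
#'   z-slices.
#' @param projection `"average"` (default, E-cadherin-style) or `"sum"`
#'   (RNAscope-style).
#' @param slices slice indices to project (default: first 10 for `average`,
#'   all for `sum`).
#' @param cell_region logical matrix selecting the cell.
#' @param background_regions list of (typically 2) logical matrices adjacent
#'   to the cell; must not overlap the cell region.
#' @return a `StainMeasurement`: list with `projection_mode`, `n_slices`,
#'   `cell_mean`, `background_mean`, `corrected_mean`, `negative` flag.
#' @export
quantify_stain <- function(stack, projection = c("average", "sum"),
                           slices = NULL, cell_region, background_regions) {
  projection <- match.arg(projection)
  arr <- if (inherits(stack, "ImageStack")) stack$data else stack
  if (!is.array(arr) || length(dim(arr)) != 3L)
    abort_input("`stack` must be a Z x Y x X array or ImageStack")
  nz <- dim(arr)[1]
  if (is.null(slices))
    slices <- if (projection == "average") seq_len(min(10L, nz)) else seq_len(nz)
  if (any(slices < 1L | slices > nz)) abort_input("`slices` outside the stack")
  if (!all(dim(cell_region) == dim(arr)[2:3]))
    abort_input("`cell_region` does not match the image shape")
  for (bg in background_regions) {
    if (!all(dim(bg) == dim(arr)[2:3]))
      abort_input("background region does not match the image shape")
    if (any(bg & cell_region))
      abort_input("background region overlaps the cell region")
  }
  sub <- arr[slices, , , drop = FALSE]
  proj <- apply(sub, c(2, 3), if (projection == "average") mean else sum)
  cell_mean <- mean(proj[cell_region])
  bg_means <- vapply(background_regions, function(bg) mean(proj[bg]), numeric(1))
  background_mean <- mean(bg_means)
  corrected <- cell_mean - background_mean
  structure(list(projection_mode = projection, n_slices = length(slices),
                 cell_mean = cell_mean, background_mean = background_mean,
                 background_region_means = bg_means,
                 corrected_mean = corrected, negative = corrected < 0),
            class = "StainMeasurement")
}

#' @export
print.StainMeasurement <- function(x, ...) {
  cat(sprintf("<StainMeasurement> %s projection of %d slice(s): cell %.4g - background %.4g = %.4g%s\n",
              x$projection_mode, x$n_slices, x$cell_mean, x$background_mean,
              x$corrected_mean, if (x$negative) " (negative, flagged)" else ""))
  invisible(x)
}
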