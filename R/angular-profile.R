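#' Angular intensity profile of cortex-masked signal
#'
#' Assigns every cortex pixel to an angular bin about the cell center (bin
#' `floor(angle / bin_width)`) and averages the masked intensities per bin —
#' the 120 x 3-degree slicing used for cortical ezrin profiling. Pixel-free
#' bins are returned as `NA` and flagged through `n_pixels = 0`.
#'
#' @param intensity numeric intensity matrix.
#' @param cortex logical cortex ring mask (non-empty, same shape).
#' @param center cell center, 0-based `(y, x)`.
#' @param bin_width bin width in degrees; must divide 360 (default 3).
#' @return an `AngularProfile`: list with `bin_width`, `bin_means`,
#'   `n_pixels`, `bin_mean_angle` (mean pixel angle per bin, used as the fit
#'   abscissa), `bin_centers`, `n_frames_averaged`.
#' @export
slice_angular <- function(intensity, cortex, center, bin_width = 3) {
  if (!is.matrix(intensity) || !is.matrix(cortex) ||
      !all(dim(intensity) == dim(cortex)))
    abort_input("`intensity` and `cortex` must be matrices of equal shape")
  if (!any(cortex)) abort_input("cortex mask is empty")
  if (360 %% bin_width != 0) abort_param("`bin_width` must divide 360")
  n_bins <- as.integer(360 / bin_width)
  idx <- which(cortex, arr.ind = TRUE)
  dy <- idx[, 1] - 1 - center[1]; dx <- idx[, 2] - 1 - center[2]
  th <- wrap_deg(atan2(dy, dx) * 180 / pi)
  bin <- pmin(floor(th / bin_width), n_bins - 1L) + 1L
  vals <- intensity[cortex]
  ## reorder vals to match arr.ind ordering (both are column-major: identical)
  sums <- rowsum(vals, bin)
  cnts <- tabulate(bin, n_bins)
  means <- rep(NA_real_, n_bins)
  means[as.integer(rownames(sums))] <- sums[, 1] / cnts[as.integer(rownames(sums))]
  asum <- rowsum(th, bin)
  mang <- rep(NA_real_, n_bins)
  mang[as.integer(rownames(asum))] <- asum[, 1] / cnts[as.integer(rownames(asum))]
  structure(list(bin_width = bin_width,
                 bin_means = means,
                 n_pixels = cnts,
                 bin_mean_angle = mang,
                 bin_centers = (seq_len(n_bins) - 0.5) * bin_width,
                 n_frames_averaged = 1L),
            class = "AngularProfile")
}

#' @export
print.AngularProfile <- function(x, ...) {
  cat(sprintf("<AngularProfile> %d bins x %g deg, %d empty, %d frame(s) averaged\n",
              length(x$bin_means), x$bin_width, sum(x$n_pixels == 0L),
              x$n_frames_averaged))
  invisible(x)
}

#' Average several per-frame profiles bin-wise
#'
#' Bin means are averaged across frames (unweighted across frames, the
#' one-profile-per-cell aggregation mode); per-bin mean angles are pooled with
#' pixel-count weights.
#'
#' @param profiles list of `AngularProfile`s with identical binning.
#' @return a single `AngularProfile`.
#' @export
average_profiles <- function(profiles) {
  if (length(profiles) == 0L) abort_input("no profiles to average")
  bw <- profiles[[1]]$bin_width
  if (!all(vapply(profiles, function(p) p$bin_width == bw, logical(1))))
    abort_input("profiles have inconsistent bin widths")
  mm <- sapply(profiles, function(p) p$bin_means)
  aa <- sapply(profiles, function(p) p$bin_mean_angle)
  nn <- sapply(profiles, function(p) p$n_pixels)
  out <- profiles[[1]]
  out$bin_means <- rowMeans(mm, na.rm = TRUE)
  out$bin_means[is.nan(out$bin_means)] <- NA_real_
  wsum <- rowSums(aa * nn, na.rm = TRUE)
  out$bin_mean_angle <- ifelse(rowSums(nn) > 0, wsum / rowSums(nn), NA_real_)
  out$n_pixels <- as.integer(rowSums(nn))
  out$n_frames_averaged <- length(profiles)
  out
}

#' Fit a circular Gaussian to an angular profile
#'
#' Least-squares fit of `f(theta) = c + A * exp(-d(theta, mu)^2 / (2 sigma^2))`
#' where `d` is the circular angle difference, so the peak may straddle
#' 0/360 without edge artifacts. Initialization comes from the profile argmax
#' and a half-maximum width estimate. The abscissa is each bin's mean pixel
#' angle when available (removes angular-quantization bias), else the bin
#' center. The `converged` flag is honest: flat profiles or failed optimizer
#' runs return `converged = FALSE` with the optimizer diagnostics, never a
#' fabricated fit.
#'
#' @param profile an `AngularProfile` with at least 5 finite bins.
#' @return a `GaussianFit`: list with `A`, `mu` (degrees in `[0, 360)`),
#'   `sigma` (degrees), `c`, `converged`, `rss` and `message`.
#' @export
fit_gaussian <- function(profile) {
  y <- profile$bin_means
  x <- ifelse(is.finite(profile$bin_mean_angle), profile$bin_mean_angle,
              profile$bin_centers)
  ok <- is.finite(y)
  if (sum(ok) < 5L) abort_input("need at least 5 finite bins to fit")
  x <- x[ok]; y <- y[ok]
  if (diff(range(y)) == 0)
    return(structure(list(A = 0, mu = NA_real_, sigma = NA_real_, c = y[1],
                          converged = FALSE, rss = 0,
                          message = "flat profile: amplitude indistinguishable from 0"),
                     class = "GaussianFit"))
  c0 <- min(y); A0 <- max(y) - min(y); mu0 <- x[which.max(y)]
  above <- abs(circ_diff_deg(x[y > c0 + A0 / 2], mu0))
  sigma0 <- max(profile$bin_width, 2 * max(above, na.rm = TRUE) / 2.355)
  obj <- function(par) {
    d <- circ_diff_deg(x, par[2])
    f <- par[4] + par[1] * exp(-d^2 / (2 * par[3]^2))
    sum((y - f)^2)
  }
  obj_safe <- function(par) {
    if (par[1] < 0 || par[3] <= 1e-2 || par[3] >= 180) return(Inf)
    obj(par)
  }
  opt <- tryCatch({
    o1 <- optim(c(A0, mu0, sigma0, c0), obj, method = "L-BFGS-B",
                lower = c(0, mu0 - 360, 1e-2, -Inf),
                upper = c(Inf, mu0 + 360, 180, Inf),
                control = list(factr = 1e4, maxit = 1000))
    ## derivative-free polish; also rescues abnormal L-BFGS-B terminations
    o2 <- optim(o1$par, obj_safe, method = "Nelder-Mead",
                control = list(reltol = 1e-12, maxit = 10000))
    best <- if (o2$value <= o1$value) o2 else o1
    best$convergence <- min(o1$convergence, o2$convergence)
    best
  }, error = function(e) NULL)
  if (is.null(opt))
    return(structure(list(A = NA_real_, mu = NA_real_, sigma = NA_real_,
                          c = NA_real_, converged = FALSE, rss = NA_real_,
                          message = "optimizer error"),
                     class = "GaussianFit"))
  par <- opt$par
  conv <- opt$convergence == 0 && par[1] > 1e-9 * max(abs(y)) &&
    par[3] > 2e-2 && par[3] < 180 - 1e-6
  structure(list(A = par[1], mu = wrap_deg(par[2]), sigma = par[3], c = par[4],
                 converged = conv, rss = opt$value,
                 message = if (conv) "ok" else "did not converge"),
            class = "GaussianFit")
}

#' @export
print.GaussianFit <- function(x, ...) {
  if (isTRUE(x$converged))
    cat(sprintf("<GaussianFit> A = %.4g, mu = %.2f deg, sigma = %.2f deg, c = %.4g\n",
                x$A, x$mu, x$sigma, x$c))
  else cat(sprintf("<GaussianFit> not converged (%s)\n", x$message))
  invisible(x)
}

#' Normalize a profile by its fitted peak and center the peak on 180 degrees
#'
#' Intensities are divided by the fitted peak height (`A + c`) and the bins
#' are circularly rotated by the integer bin shift closest to `180 - mu`, so
#' the fitted peak sits at 180 degrees (within one bin; the sub-bin remainder
#' is recorded in the `sub_bin_shift_deg` attribute).
#'
#' @param profile an `AngularProfile`.
#' @param fit a converged `GaussianFit` for that profile.
#' @return the normalized, rotated `AngularProfile`.
#' @export
normalize_center <- function(profile, fit) {
  if (!isTRUE(fit$converged)) abort_input("fit did not converge")
  peak <- fit$A + fit$c
  if (peak <= 0) abort_input("fitted peak height is not positive")
  n <- length(profile$bin_means)
  shift <- round(circ_diff_deg(180, fit$mu) / profile$bin_width)
  rot <- function(v) v[((seq_len(n) - 1L - shift) %% n) + 1L]
  out <- profile
  out$bin_means <- rot(profile$bin_means) / peak
  out$n_pixels <- rot(profile$n_pixels)
  out$bin_mean_angle <- wrap_deg(rot(profile$bin_mean_angle) + shift * profile$bin_width)
  attr(out, "bin_shift") <- shift
  attr(out, "sub_bin_shift_deg") <- circ_diff_deg(180, fit$mu) - shift * profile$bin_width
  out
}

#' Normalize a profile to its own peak bin
#'
#' Divides all bin means by the maximum bin mean, the per-cell display
#' normalization of profile plots ("intensity normalized to the peak intensity
#' in the cell").
#'
#' @param profile an `AngularProfile` with at least one positive finite bin.
#' @return the normalized `AngularProfile` (max bin = 1).
#' @export
per_cell_peak_normalize <- function(profile) {
  m <- suppressWarnings(max(profile$bin_means, na.rm = TRUE))
  if (!is.finite(m) || m <= 0)
    abort_input("profile has no positive finite bin; cannot peak-normalize")
  out <- profile
  out$bin_means <- profile$bin_means / m
  out
}

#' Compare two groups of profile values with a two-sample KS test
#'
#' Accepts either numeric vectors (samples of per-cell values) or matrices
#' (cells in rows, bins in columns). For matrices, `mode = "per_cell"` pools
#' every cell's bin values into one sample per group (the per-cell default),
#' while `mode = "pooled"` first averages cells into one group-mean profile
#' and compares the two 120-value profiles.
#'
#' @param group_a,group_b numeric vectors or cell x bin matrices.
#' @param mode `"per_cell"` or `"pooled"` (matrices only).
#' @return list with `D` (KS statistic) and `p_value`.
#' @export
compare_profiles <- function(group_a, group_b, mode = c("per_cell", "pooled")) {
  mode <- match.arg(mode)
  flatten <- function(g) {
    if (is.matrix(g)) {
      if (mode == "pooled") colMeans(g, na.rm = TRUE) else as.numeric(g)
    } else as.numeric(g)
  }
  a <- flatten(group_a); b <- flatten(group_b)
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2L || length(b) < 2L)
    abort_input("each group needs at least 2 finite values")
  ks_two_sample(a, b)
}

#' Ezrin-style cortical profile pipeline for one movie
#'
#' Convenience wrapper: segment every frame, build the cortex ring, slice
#' angularly, average the per-frame profiles bin-wise (one profile per cell)
#' and fit the circular Gaussian.
#'
#' @param stack an [image_stack()] (signal used both for masking and
#'   profiling).
#' @param frames frames to use (default: all).
#' @param threshold,erosions,elem passed to [segment_movie()].
#' @param bin_width degrees per bin (default 3).
#' @return list with `profile` (averaged `AngularProfile`), `fit`
#'   (`GaussianFit`), and `masks` (`CellMaskSeries`).
#' @export
profile_movie <- function(stack, frames = NULL, threshold = "otsu",
                          erosions = 4L, elem = "cross", bin_width = 3) {
  if (is.null(frames)) frames <- seq_len(n_frames(stack))
  sub <- image_stack(stack$data[frames, , , drop = FALSE],
                     stack$pixel_size_um, stack$frame_interval_s)
  masks <- segment_movie(sub, threshold, erosions, elem)
  profs <- list()
  for (i in seq_along(masks$masks)) {
    if (masks$empty[i]) next
    profs[[length(profs) + 1L]] <-
      slice_angular(get_frame(sub, i), masks$cortex_masks[[i]],
                    masks$centers[i, ], bin_width)
  }
  if (length(profs) == 0L) abort_input("no non-empty frames to profile")
  prof <- average_profiles(profs)
  list(profile = prof, fit = fit_gaussian(prof), masks = masks)
}
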