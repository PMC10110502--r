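## Track-based migration kinetics and kymograph flow estimation.
##
## Tracks are data.frames with columns (track_id, t_s, x_um, y_um[, z_um],
## class); timestamps must be strictly increasing within a track.

track_coords <- function(track) {
  cols <- intersect(c("x_um", "y_um", "z_um"), names(track))
  if (length(cols) < 2L) abort_input("track needs x_um and y_um columns")
  as.matrix(track[, cols, drop = FALSE])
}

check_track <- function(track) {
  if (!is.data.frame(track) || nrow(track) < 2L)
    abort_input("a track needs at least 2 positions")
  if (is.unsorted(track$t_s, strictly = TRUE))
    abort_input("track timestamps must be strictly increasing")
  invisible(track)
}

#' Track speed (path length over duration)
#'
#' Total path length divided by total duration, in um/min.
#'
#' @param track track data.frame (`t_s`, `x_um`, `y_um`[, `z_um`]).
#' @param mode `"path"` (default: path length / duration) or `"instantaneous"`
#'   (mean of per-step speeds).
#' @return speed in um/min.
#' @export
track_speed <- function(track, mode = c("path", "instantaneous")) {
  mode <- match.arg(mode)
  check_track(track)
  xy <- track_coords(track)
  seg <- sqrt(rowSums(diff(xy)^2))
  dt <- diff(track$t_s) / 60
  if (sum(dt) <= 0) abort_input("track has zero duration")
  if (mode == "path") sum(seg) / sum(dt) else mean(seg / dt)
}

#' Track straightness (net displacement over path length)
#'
#' `|end - start| / path length`, in `[0, 1]`: 1 for straight monotone motion,
#' 0 for a closed loop.
#'
#' @param track track data.frame.
#' @return straightness in `[0, 1]`.
#' @export
track_straightness <- function(track) {
  check_track(track)
  xy <- track_coords(track)
  path <- sum(sqrt(rowSums(diff(xy)^2)))
  if (path == 0) abort_input("track has zero path length")
  net <- sqrt(sum((xy[nrow(xy), ] - xy[1, ])^2))
  net / path
}

#' Correct a track for tissue drift using somatic reference tracks
#'
#' For each interval of the motile track, the mean displacement vector of the
#' `k` somatic tracks nearest (at the interval start) is subtracted from the
#' cell's displacement; corrected positions are re-integrated from the
#' starting point. This is the "movement relative to somatic nuclei"
#' correction.
#'
#' @param track motile-cell track data.frame.
#' @param somatic_tracks data.frame of somatic tracks (same columns plus
#'   `track_id`).
#' @param k number of nearest somatic tracks to average (default 5).
#' @return the drift-corrected track (same shape as `track`).
#' @export
drift_correct <- function(track, somatic_tracks, k = 5L) {
  check_track(track)
  if (nrow(somatic_tracks) == 0L) abort_input("no somatic tracks supplied")
  xy <- track_coords(track)
  cols <- colnames(xy)
  som <- split(somatic_tracks, somatic_tracks$track_id)
  out <- xy
  for (i in seq_len(nrow(xy) - 1L)) {
    t0 <- track$t_s[i]; t1 <- track$t_s[i + 1L]
    disp <- list(); d0 <- numeric(0)
    for (s in som) {
      i0 <- match(t0, s$t_s); i1 <- match(t1, s$t_s)
      if (is.na(i0) || is.na(i1)) next
      sxy <- track_coords(s)
      disp[[length(disp) + 1L]] <- sxy[i1, ] - sxy[i0, ]
      d0 <- c(d0, sqrt(sum((sxy[i0, ] - xy[i, ])^2)))
    }
    if (length(disp) == 0L)
      abort_input(sprintf("no somatic track overlaps interval starting t = %g s", t0))
    use <- order(d0)[seq_len(min(k, length(d0)))]
    drift <- colMeans(do.call(rbind, disp[use]))
    out[i + 1L, ] <- out[i, ] + (xy[i + 1L, ] - xy[i, ]) - drift
  }
  res <- track
  res[, cols] <- out
  res
}

#' Normalize per-cell metrics to each repeat's control mean
#'
#' Divides every value by the mean of the control (reference) group measured
#' in the same experimental repeat — the per-day normalization used for
#' speed, straightness, stain and FRET values.
#'
#' @param df data.frame with columns `value`, `group`, `repeat_id`.
#' @param reference_group group label serving as control.
#' @return `df` with an added `normalized` column.
#' @export
per_repeat_normalize <- function(df, reference_group) {
  need <- c("value", "group", "repeat_id")
  if (!all(need %in% names(df)))
    abort_input("`df` needs columns value, group, repeat_id")
  out <- df
  out$normalized <- NA_real_
  for (r in unique(df$repeat_id)) {
    in_r <- df$repeat_id == r
    ref <- df$value[in_r & df$group == reference_group]
    if (length(ref) == 0L)
      abort_input(sprintf("repeat '%s' has no '%s' (control) cells", r, reference_group))
    mref <- mean(ref)
    if (!is.finite(mref) || mref <= 0)
      abort_input(sprintf("repeat '%s': control mean is not positive", r))
    out$normalized[in_r] <- df$value[in_r] / mref
  }
  out
}

#' Build a kymograph by sampling a movie along a line
#'
#' Row `t` holds bilinear interpolations of frame `t` at 1-px steps along the
#' segment from `(x0, y0)` to `(x1, y1)` (0-based pixel-center coordinates),
#' plus the segment endpoint, giving `ceiling(length) + 1` columns.
#'
#' @param stack an [image_stack()].
#' @param line numeric `c(x0, y0, x1, y1)`.
#' @return a `Kymograph`: list with `image` (time x position), `pixel_size_um`,
#'   `frame_interval_s`, `line`.
#' @export
build_kymograph <- function(stack, line) {
  if (length(line) != 4L) abort_input("`line` must be c(x0, y0, x1, y1)")
  d <- dim(stack$data)
  x0 <- line[1]; y0 <- line[2]; x1 <- line[3]; y1 <- line[4]
  len <- sqrt((x1 - x0)^2 + (y1 - y0)^2)
  if (len == 0) abort_input("line has zero length")
  ts <- c(seq(0, floor(len)), if (len > floor(len)) len)
  px <- x0 + (x1 - x0) * ts / len
  py <- y0 + (y1 - y0) * ts / len
  if (any(px < 0 | px > d[3] - 1 | py < 0 | py > d[2] - 1))
    abort_input("line leaves the image bounds")
  img <- matrix(0, d[1], length(ts))
  xf <- pmin(floor(px), d[3] - 2); yf <- pmin(floor(py), d[2] - 2)
  wx <- px - xf; wy <- py - yf
  for (t in seq_len(d[1])) {
    fr <- matrix(stack$data[t, , ], d[2], d[3])
    v00 <- fr[cbind(yf + 1, xf + 1)]; v01 <- fr[cbind(yf + 1, xf + 2)]
    v10 <- fr[cbind(yf + 2, xf + 1)]; v11 <- fr[cbind(yf + 2, xf + 2)]
    img[t, ] <- (1 - wy) * ((1 - wx) * v00 + wx * v01) +
      wy * ((1 - wx) * v10 + wx * v11)
  }
  structure(list(image = img, pixel_size_um = stack$pixel_size_um,
                 frame_interval_s = stack$frame_interval_s, line = line),
            class = "Kymograph")
}

#' Flow speed from a kymograph
#'
#' For each pair of consecutive kymograph rows, the displacement is the argmax
#' of their 1D cross-correlation (rows are mean-subtracted and Hann-windowed;
#' the correlation is evaluated through the FFT, so sub-pixel lags come from a
#' continuous search on the sinc-interpolated correlation — three-point
#' parabolic refinement biases half-pixel displacements by more than 2% and is
#' not used); the reported speed is the median per-frame displacement
#' converted to um/min. Positive values mean motion toward increasing position
#' along the sampling line, so a line oriented front-to-back reports
#' retrograde flow as positive.
#'
#' @param kymo a `Kymograph` (>= 2 rows).
#' @param max_lag largest displacement searched, px (default: an eighth of the
#'   row length; keep below half the pattern period for periodic scenes).
#' @return a `FlowEstimate`: list with `V_um_per_min`, `displacements_px`
#'   (per frame pair), `low_confidence` flag.
#' @export
flow_speed <- function(kymo, max_lag = NULL) {
  img <- kymo$image
  if (nrow(img) < 2L) abort_input("kymograph needs at least 2 rows")
  nc <- ncol(img)
  if (is.null(max_lag)) max_lag <- max(1L, floor(nc / 8))
  disp <- rep(NA_real_, nrow(img) - 1L)
  flat <- TRUE
  kk <- 0:(nc - 1)
  kfreq <- ifelse(kk <= nc / 2, kk, kk - nc)
  hann <- 0.5 - 0.5 * cos(2 * pi * kk / (nc - 1))
  for (t in seq_len(nrow(img) - 1L)) {
    a <- img[t, ]; b <- img[t + 1L, ]
    a <- a - mean(a); b <- b - mean(b)
    if (sd(a) == 0 || sd(b) == 0) { disp[t] <- 0; next }
    flat <- FALSE
    cross <- Conj(stats::fft(a * hann)) * stats::fft(b * hann)
    ccl <- function(l) Re(sum(cross * exp(2i * pi * kfreq * l / nc))) / nc
    lags <- -max_lag:max_lag
    cc <- vapply(lags, ccl, numeric(1))
    ## near-ties (periodic patterns alias at d +/- period) resolve toward the
    ## smallest displacement
    mx <- max(cc)
    cand <- which(cc >= mx - 1e-3 * abs(mx))
    k <- cand[which.min(abs(lags[cand]))]
    lo <- max(lags[k] - 1, -max_lag); hi <- min(lags[k] + 1, max_lag)
    opt <- stats::optimize(ccl, c(lo, hi), maximum = TRUE, tol = 1e-5)
    disp[t] <- if (opt$objective >= cc[k]) opt$maximum else lags[k]
  }
  v <- median(disp) * kymo$pixel_size_um / kymo$frame_interval_s * 60
  structure(list(V_um_per_min = v, displacements_px = disp,
                 low_confidence = flat,
                 method = "xcorr-argmax + parabolic refinement, median over row pairs"),
            class = "FlowEstimate")
}

#' @export
print.FlowEstimate <- function(x, ...) {
  cat(sprintf("<FlowEstimate> V = %.3g um/min%s\n", x$V_um_per_min,
              if (x$low_confidence) " (low confidence: constant rows)" else ""))
  invisible(x)
}
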