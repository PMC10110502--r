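## Synthetic motile-cell movies with ground truth.
##
## The shape model is a star-convex radial function r(theta, t) around a moving
## center: a base disk plus transient Gaussian bumps in r(theta) representing
## blebs. The cortical ring carries a circular-Gaussian angular intensity
## profile c + A * exp(-d(theta, mu)^2 / (2 sigma^2)); during the early phase
## of a bleb the ring signal is suppressed over the bleb cap (blebs start
## cortex-free). Everything the movie encodes is also written to a truth
## record so downstream metrics can be checked exactly.

THETA_GRID_N <- 720L  # radial-profile sampling resolution (0.5 degree)

default_cell_params <- function() {
  list(
    frames = 24L,
    size = c(96L, 96L),            # (Y, X) px
    radius_px = 20,
    center_start = NULL,           # default: image center
    speed_px_per_frame = 0,
    polarity_deg = 0,
    profile = list(A = 150, mu_deg = NA, sigma_deg = 40, c = 30),  # mu NA -> polarity
    ring_width_px = 4,
    interior_level = 60,
    bleb_rate_per_min = 1,
    bleb_duration_s = 20,
    bleb_rise_s = 5,
    bleb_sigma_deg = 18,
    bleb_height_px = 6,
    bleb_signal_lag_s = 10,
    bleb_min_separation_s = 0,     # > 0 forbids temporally overlapping events
    noise_sd = 0,
    pixel_size_um = 0.33,
    frame_interval_s = 5
  )
}

## radial profile r(theta) for one frame, on the dense theta grid
radial_profile <- function(radius_px, blebs, frame, rise_f, dur_f, theta_grid) {
  r <- rep(radius_px, length(theta_grid))
  if (length(blebs$start_frame) == 0L) return(r)
  for (e in seq_along(blebs$start_frame)) {
    s <- blebs$start_frame[e]
    if (frame < s || frame > blebs$end_frame[e]) next
    peak <- blebs$max_expansion_frame[e]
    h <- if (frame <= peak) {
      blebs$height_px[e] * (frame - s + 1) / (peak - s + 1)
    } else {
      blebs$height_px[e] * (blebs$end_frame[e] - frame) / max(1, blebs$end_frame[e] - peak)
    }
    if (h <= 0) next
    d <- circ_diff_deg(theta_grid, blebs$apex_angle_deg[e])
    r <- r + h * exp(-d^2 / (2 * blebs$sigma_deg[e]^2))
  }
  r
}

## rasterize a star-convex shape: mask of pixels with dist <= interp(r(theta)).
## Shared by the generator and by rasterize_truth so the conservation between
## movie masks and truth contours is exact by construction.
radial_mask <- function(center_yx, theta_grid, r_grid, dim_yx, grid = NULL) {
  g <- if (is.null(grid)) pixel_grid(dim_yx) else grid
  dy <- g$y - center_yx[1]; dx <- g$x - center_yx[2]
  th <- wrap_deg(atan2(dy, dx) * 180 / pi)
  d <- sqrt(dy^2 + dx^2)
  rr <- approx(x = c(theta_grid, 360), y = c(r_grid, r_grid[1]),
               xout = th, rule = 2)$y
  list(mask = d <= rr, theta = th, dist = d)
}

#' Generate a synthetic motile-cell movie with ground truth
#'
#' Produces a single-channel time-lapse of a roughly circular cell with a
#' bright cortical ring whose angular intensity follows a circular Gaussian,
#' plus discrete bleb events (transient local contour expansions lacking
#' cortical signal during their rise). Bleb starts are a Poisson process at
#' `bleb_rate_per_min`. The returned truth records the full contour per frame,
#' every bleb event, per-frame polarity angle and front-type label, and the
#' cortical profile parameters.
#'
#' @param params named list overriding the defaults (see
#'   `pgcprot:::default_cell_params()`): movie geometry, cortical profile
#'   `(A, mu_deg, sigma_deg, c)`, bleb kinetics, noise s.d., calibration.
#' @param seed integer; the generator is a pure function of `(params, seed)`.
#' @param truth_only if `TRUE`, skip pixel rendering and return truth only
#'   (bleb areas then use an analytic cap-area estimate; used for fast
#'   event-statistics studies).
#' @return a `SyntheticScene`: list with `stacks` (list of [image_stack()];
#'   empty when `truth_only`), `truth` (`CellMovieTruth`) and `params`.
#' @export
generate_cell_movie <- function(params = list(), seed = 1L, truth_only = FALSE) {
  p <- utils::modifyList(default_cell_params(), params)
  if (p$frames < 2L) abort_param("movie needs at least 2 frames")
  if (p$bleb_rate_per_min < 0) abort_param("bleb rate must be >= 0")
  if (p$radius_px <= 0) abort_param("cell radius must be > 0")
  if (!is.null(p$profile$A) && p$profile$A < 0) abort_param("profile amplitude A must be >= 0")
  if (!(p$profile$sigma_deg > 0 && p$profile$sigma_deg < 180))
    abort_param("profile sigma must be in (0, 180) degrees")
  if (is.na(p$profile$mu_deg)) p$profile$mu_deg <- p$polarity_deg

  with_seed(seed, {
    dt_min <- p$frame_interval_s / 60
    duration_min <- p$frames * dt_min

    ## --- bleb event schedule (Poisson process) ---
    n_ev <- rpois(1L, p$bleb_rate_per_min * duration_min)
    dur_f <- max(2L, round(p$bleb_duration_s / p$frame_interval_s))
    rise_f <- max(1L, min(dur_f - 1L, round(p$bleb_rise_s / p$frame_interval_s)))
    ## events run their full course inside the movie: starts leave one
    ## pre-bleb frame and the whole duration (boundary-truncated events are
    ## ambiguous for any scorer); the count stays Poisson at rate x duration
    s_hi <- max(2L, p$frames - dur_f)
    starts <- sort(sample(seq(2L, s_hi), n_ev, replace = TRUE))
    if (p$bleb_min_separation_s > 0 && n_ev > 1L) {
      gap_f <- ceiling(p$bleb_min_separation_s / p$frame_interval_s)
      keep <- rep(TRUE, n_ev)
      last <- -Inf
      for (i in seq_len(n_ev)) {
        if (starts[i] - last < gap_f) keep[i] <- FALSE else last <- starts[i]
      }
      starts <- starts[keep]
      n_ev <- length(starts)
    }
    blebs <- list(
      start_frame = starts,
      max_expansion_frame = pmin(p$frames, starts + rise_f),
      end_frame = pmin(p$frames, starts + dur_f),
      apex_angle_deg = runif(n_ev, 0, 360),
      sigma_deg = rep(p$bleb_sigma_deg, n_ev),
      ## per-event size variation (30%) so bleb-size metrics carry spread
      height_px = p$bleb_height_px * runif(n_ev, 0.7, 1.3)
    )

    ## --- center path ---
    pol <- rep(wrap_deg(p$polarity_deg), p$frames)
    dirv <- c(sin(p$polarity_deg * pi / 180), cos(p$polarity_deg * pi / 180))  # (dy, dx)
    c0 <- if (is.null(p$center_start)) (p$size - 1) / 2 else p$center_start
    centers <- cbind(c0[1] + dirv[1] * p$speed_px_per_frame * (seq_len(p$frames) - 1L),
                     c0[2] + dirv[2] * p$speed_px_per_frame * (seq_len(p$frames) - 1L))
    margin <- p$radius_px + p$bleb_height_px + 1
    if (any(centers[, 1] < margin) || any(centers[, 1] > p$size[1] - 1 - margin) ||
        any(centers[, 2] < margin) || any(centers[, 2] > p$size[2] - 1 - margin))
      abort_param("cell leaves the field of view; reduce speed/frames or enlarge `size`")

    theta_grid <- seq(0, 360, length.out = THETA_GRID_N + 1L)[-(THETA_GRID_N + 1L)]

    ## per-frame front type: bleb while any event is active, else actin_rich
    front <- rep("actin_rich", p$frames)
    for (e in seq_len(n_ev))
      front[blebs$start_frame[e]:blebs$end_frame[e]] <- "bleb"

    contours <- vector("list", p$frames)
    r_grids <- vector("list", p$frames)
    for (t in seq_len(p$frames)) {
      r <- radial_profile(p$radius_px, blebs, t, rise_f, dur_f, theta_grid)
      r_grids[[t]] <- r
      contours[[t]] <- cbind(
        x = centers[t, 2] + r * cos(theta_grid * pi / 180),
        y = centers[t, 1] + r * sin(theta_grid * pi / 180))
    }

    ## --- bleb area bookkeeping ---
    grid <- if (!truth_only) pixel_grid(p$size) else NULL
    max_area <- cell_area_at_max <- numeric(n_ev)
    if (n_ev > 0L) {
      for (e in seq_len(n_ev)) {
        tmax <- blebs$max_expansion_frame[e]
        if (truth_only) {
          ## analytic cap-area estimate: line integral of the radial bump
          max_area[e] <- sqrt(2 * pi) * blebs$sigma_deg[e] * pi / 180 *
            p$radius_px * blebs$height_px[e]
          cell_area_at_max[e] <- pi * p$radius_px^2 + max_area[e]
        } else {
          r_with <- r_grids[[tmax]]
          m_with <- radial_mask(centers[tmax, ], theta_grid, r_with, p$size, grid)$mask
          base <- radial_profile(p$radius_px,
                                 lapply(blebs, function(v) v[-e]),
                                 tmax, rise_f, dur_f, theta_grid)
          m_without <- radial_mask(centers[tmax, ], theta_grid, base, p$size, grid)$mask
          max_area[e] <- sum(m_with & !m_without)
          cell_area_at_max[e] <- sum(m_with)
        }
      }
    }

    truth <- structure(list(
      contour_per_frame = contours,
      centers = centers,
      bleb_events = data.frame(
        start_frame = blebs$start_frame,
        max_expansion_frame = blebs$max_expansion_frame,
        end_frame = blebs$end_frame,
        apex_angle_deg = blebs$apex_angle_deg,
        max_area_px2 = max_area,
        cell_area_px2 = cell_area_at_max),
      polarity_angle_per_frame = pol,
      front_type_per_frame = front,
      cortical_profile_params = p$profile,
      pixel_size_um = p$pixel_size_um,
      frame_interval_s = p$frame_interval_s,
      noise_sd = p$noise_sd,
      seed = seed), class = "CellMovieTruth")

    if (truth_only)
      return(structure(list(stacks = list(), truth = truth, params = p),
                       class = "SyntheticScene"))

    ## --- render ---
    arr <- array(0, c(p$frames, p$size[1], p$size[2]))
    lag_f <- ceiling(p$bleb_signal_lag_s / p$frame_interval_s)
    for (t in seq_len(p$frames)) {
      rm_ <- radial_mask(centers[t, ], theta_grid, r_grids[[t]], p$size, grid)
      mask <- rm_$mask
      rr <- approx(x = c(theta_grid, 360),
                   y = c(r_grids[[t]], r_grids[[t]][1]),
                   xout = rm_$theta, rule = 2)$y
      ring <- mask & (rm_$dist >= rr - p$ring_width_px)
      img <- matrix(0, p$size[1], p$size[2])
      img[mask] <- p$interior_level
      dmu <- circ_diff_deg(rm_$theta, p$profile$mu_deg)
      ## cortical enrichment rides on the cytoplasmic baseline, as with a
      ## membrane/cortex marker over a cytoplasmic background
      ringval <- p$interior_level + p$profile$c +
        p$profile$A * exp(-dmu^2 / (2 * p$profile$sigma_deg^2))
      ## suppress cortical signal over young bleb caps
      supp <- matrix(FALSE, p$size[1], p$size[2])
      for (e in seq_len(n_ev)) {
        if (t >= blebs$start_frame[e] && t - blebs$start_frame[e] < lag_f) {
          dca <- circ_diff_deg(rm_$theta, blebs$apex_angle_deg[e])
          supp <- supp | (abs(dca) < 2 * blebs$sigma_deg[e])
        }
      }
      vals <- ifelse(supp, p$interior_level + p$profile$c, ringval)
      img[ring] <- vals[ring]
      if (p$noise_sd > 0)
        img <- img + matrix(rnorm(length(img), 0, p$noise_sd), p$size[1], p$size[2])
      arr[t, , ] <- img
    }
    stack <- image_stack(arr, p$pixel_size_um, p$frame_interval_s)
    structure(list(stacks = list(stack), truth = truth, params = p),
              class = "SyntheticScene")
  })
}

#' Rasterize a truth contour back into a binary mask
#'
#' Reconstructs the cell mask of a given frame from the stored contour polygon
#' alone (pixel-exact at zero noise, by the shared star-convex rasterization
#' rule).
#'
#' @param truth a `CellMovieTruth`.
#' @param frame frame index.
#' @param dim_yx image dimensions `(Y, X)`.
#' @return logical mask.
#' @export
rasterize_truth <- function(truth, frame, dim_yx) {
  poly <- truth$contour_per_frame[[frame]]
  ctr <- truth$centers[frame, ]
  dx <- poly[, "x"] - ctr[2]; dy <- poly[, "y"] - ctr[1]
  th <- wrap_deg(atan2(dy, dx) * 180 / pi)
  r <- sqrt(dx^2 + dy^2)
  o <- order(th)
  radial_mask(ctr, th[o], r[o], dim_yx)$mask
}

#' @export
print.SyntheticScene <- function(x, ...) {
  cat(sprintf("<SyntheticScene> %d channel(s); truth: %s\n",
              length(x$stacks), class(x$truth)[1]))
  invisible(x)
}

#' @export
print.CellMovieTruth <- function(x, ...) {
  cat(sprintf("<CellMovieTruth> %d frame(s), %d bleb event(s), profile sigma = %.3g deg\n",
              length(x$contour_per_frame), nrow(x$bleb_events),
              x$cortical_profile_params$sigma_deg))
  invisible(x)
}
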