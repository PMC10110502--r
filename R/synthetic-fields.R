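## Synthetic inputs for the non-movie pipeline stages: 3D nuclei point fields,
## two-channel ratio stacks, moving-stripe movies for kymographs, biased random
## walk tracks in a drifting tissue, and gel-encounter movies.

#' Generate a 3D nuclei centroid field
#'
#' @param mode `"cubic_lattice"` (regular grid, spacing is the ground truth) or
#'   `"uniform_random"` (uniform points in the box).
#' @param n number of points (`uniform_random`; must be >= 6 so that 5
#'   neighbours exist).
#' @param spacing lattice spacing in micrometers (`cubic_lattice`).
#' @param box box dimensions in micrometers, length 3.
#' @param seed RNG seed.
#' @return `SyntheticScene` with `truth$centroids_um` (n x 3 matrix) and, for
#'   lattices, `truth$spacing_um`.
#' @export
generate_nuclei_field <- function(mode = c("cubic_lattice", "uniform_random"),
                                  n = 100L, spacing = 10, box = c(100, 100, 100),
                                  seed = 1L) {
  mode <- match.arg(mode)
  with_seed(seed, {
    if (mode == "cubic_lattice") {
      ax <- lapply(box, function(b) seq(0, b, by = spacing))
      pts <- as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]]))
      if (nrow(pts) < 6L) abort_param("lattice has fewer than 6 points; enlarge `box`")
      truth <- list(centroids_um = pts, spacing_um = spacing, mode = mode, seed = seed)
    } else {
      if (n < 6L) abort_param("need n >= 6 nuclei (5 neighbours must exist)")
      pts <- cbind(x = runif(n, 0, box[1]), y = runif(n, 0, box[2]),
                   z = runif(n, 0, box[3]))
      truth <- list(centroids_um = pts, mode = mode, seed = seed)
    }
    structure(list(stacks = list(), truth = truth,
                   params = list(mode = mode, n = n, spacing = spacing, box = box)),
              class = "SyntheticScene")
  })
}

#' Generate a two-channel stack with a known ratio field
#'
#' Channel 1 is the donor at `donor_level`; channel 2 is donor times the
#' requested ratio field inside an elliptical cell mask, so channel2/channel1
#' equals the field exactly before noise.
#'
#' @param ratio either a single constant or `c(from, to)` for a linear gradient
#'   along the long (x) axis of the mask.
#' @param donor_level donor intensity (> 0).
#' @param size image size `(Y, X)`.
#' @param semiaxes ellipse semi-axes `(ry, rx)` in px; the mask is centered.
#' @param noise_sd additive Gaussian noise s.d. applied to both channels.
#' @param frames number of frames.
#' @param pixel_size_um,frame_interval_s calibration.
#' @param seed RNG seed.
#' @return `SyntheticScene` with `stacks = list(donor, acceptor)` and truth
#'   holding the per-pixel ratio field and the mask.
#' @export
generate_ratio_stack <- function(ratio = 2, donor_level = 100,
                                 size = c(64L, 96L), semiaxes = c(20, 40),
                                 noise_sd = 0, frames = 1L,
                                 pixel_size_um = 0.3, frame_interval_s = 8,
                                 seed = 1L) {
  if (donor_level <= 0) abort_param("`donor_level` must be > 0")
  g <- pixel_grid(size)
  cy <- (size[1] - 1) / 2; cx <- (size[2] - 1) / 2
  mask <- ((g$y - cy) / semiaxes[1])^2 + ((g$x - cx) / semiaxes[2])^2 <= 1
  if (!any(mask)) abort_param("mask is empty; enlarge `semiaxes`")
  field <- matrix(ratio[1], size[1], size[2])
  if (length(ratio) == 2L) {
    xmin <- min(g$x[mask]); xmax <- max(g$x[mask])
    field <- ratio[1] + (ratio[2] - ratio[1]) * (g$x - xmin) / (xmax - xmin)
  }
  with_seed(seed, {
    don <- array(0, c(frames, size[1], size[2]))
    acc <- array(0, c(frames, size[1], size[2]))
    for (t in seq_len(frames)) {
      d <- matrix(0, size[1], size[2]); d[mask] <- donor_level
      a <- matrix(0, size[1], size[2]); a[mask] <- donor_level * field[mask]
      if (noise_sd > 0) {
        d <- d + matrix(rnorm(length(d), 0, noise_sd), size[1], size[2])
        a <- a + matrix(rnorm(length(a), 0, noise_sd), size[1], size[2])
      }
      don[t, , ] <- d; acc[t, , ] <- a
    }
    truth <- list(ratio_field = field, mask = mask, noise_sd = noise_sd, seed = seed)
    structure(list(stacks = list(donor = image_stack(don, pixel_size_um, frame_interval_s),
                                 acceptor = image_stack(acc, pixel_size_um, frame_interval_s)),
                   truth = truth,
                   params = list(ratio = ratio, donor_level = donor_level,
                                 size = size, semiaxes = semiaxes)),
              class = "SyntheticScene")
  })
}

#' Generate a moving-stripe movie for kymograph benchmarking
#'
#' A periodic pattern of Gaussian-profile stripes translating along the x axis
#' at exactly `speed` px/frame (every row identical).
#'
#' @param speed stripe speed in px/frame (may be fractional or negative).
#' @param size image size `(Y, X)`.
#' @param frames number of frames (>= 2).
#' @param period stripe period in px.
#' @param stripe_sigma Gaussian stripe width in px.
#' @param amplitude stripe peak intensity.
#' @param noise_sd additive Gaussian noise s.d.
#' @param pixel_size_um,frame_interval_s calibration.
#' @param seed RNG seed.
#' @return `SyntheticScene`; truth stores `speed_px_per_frame`.
#' @export
generate_stripe_movie <- function(speed = 1, size = c(16L, 128L), frames = 12L,
                                  period = 24, stripe_sigma = 3, amplitude = 100,
                                  noise_sd = 0, pixel_size_um = 0.2,
                                  frame_interval_s = 2, seed = 1L) {
  if (frames < 2L) abort_param("need at least 2 frames")
  x <- seq_len(size[2]) - 1
  with_seed(seed, {
    arr <- array(0, c(frames, size[1], size[2]))
    for (t in seq_len(frames)) {
      phase <- (x - speed * (t - 1)) %% period
      d <- pmin(phase, period - phase)       # distance to nearest stripe center
      row <- amplitude * exp(-d^2 / (2 * stripe_sigma^2))
      img <- matrix(rep(row, each = size[1]), size[1], size[2])
      if (noise_sd > 0)
        img <- img + matrix(rnorm(length(img), 0, noise_sd), size[1], size[2])
      arr[t, , ] <- img
    }
    truth <- list(speed_px_per_frame = speed, period_px = period,
                  noise_sd = noise_sd, seed = seed)
    structure(list(stacks = list(image_stack(arr, pixel_size_um, frame_interval_s)),
                   truth = truth,
                   params = list(speed = speed, size = size, frames = frames,
                                 period = period, stripe_sigma = stripe_sigma)),
              class = "SyntheticScene")
  })
}

#' Generate migrating-cell tracks inside a drifting tissue
#'
#' Motile ("pgc") tracks follow a constant-step biased random walk (step length
#' `mean_speed * interval`, heading persistence in `[0, 1]`; persistence 1 is a
#' straight line) with a uniform tissue drift added. Companion "somatic" tracks
#' carry the drift only, which is what drift correction subtracts.
#'
#' @param n_tracks number of motile tracks.
#' @param mean_speed cell speed in um/min.
#' @param persistence heading persistence in `[0, 1]`; the per-step turn angle
#'   is Gaussian with s.d. `(1 - persistence) * 180` degrees.
#' @param drift tissue drift vector `c(x, y)` in um/min.
#' @param speed_cv coefficient of variation of the per-step length (default 0:
#'   constant steps, so path length = speed x duration exactly).
#' @param duration_min,interval_min track duration and sampling interval.
#' @param n_somatic number of somatic (drift-only) tracks.
#' @param field_um side of the square seeding region, um.
#' @param seed RNG seed.
#' @return `SyntheticScene`; `truth$tracks` is a data.frame
#'   `(track_id, t_s, x_um, y_um, class)` and truth stores all parameters.
#' @export
generate_tracks <- function(n_tracks = 10L, mean_speed = 6, persistence = 0.8,
                            drift = c(0, 0), speed_cv = 0,
                            duration_min = 60, interval_min = 2,
                            n_somatic = 20L, field_um = 200, seed = 1L) {
  if (interval_min <= 0) abort_param("`interval_min` must be > 0")
  if (duration_min < 2 * interval_min) abort_param("duration must cover >= 2 intervals")
  if (persistence < 0 || persistence > 1) abort_param("persistence must be in [0, 1]")
  with_seed(seed, {
    nt <- floor(duration_min / interval_min) + 1L
    tt <- (seq_len(nt) - 1L) * interval_min * 60   # seconds
    step <- mean_speed * interval_min              # um per step
    turn_sd <- (1 - persistence) * pi
    rows <- list()
    for (i in seq_len(n_tracks)) {
      pos <- matrix(0, nt, 2)
      pos[1, ] <- runif(2, 0, field_um)
      heading <- runif(1, 0, 2 * pi)
      for (k in 2:nt) {
        if (turn_sd > 0) heading <- heading + rnorm(1, 0, turn_sd)
        stp <- if (speed_cv > 0) step * max(0, 1 + speed_cv * rnorm(1)) else step
        pos[k, ] <- pos[k - 1, ] + stp * c(cos(heading), sin(heading)) +
          drift * interval_min
      }
      rows[[length(rows) + 1L]] <- data.frame(
        track_id = sprintf("pgc_%03d", i), t_s = tt,
        x_um = pos[, 1], y_um = pos[, 2], class = "pgc")
    }
    for (i in seq_len(n_somatic)) {
      start <- runif(2, 0, field_um)
      rows[[length(rows) + 1L]] <- data.frame(
        track_id = sprintf("som_%03d", i), t_s = tt,
        x_um = start[1] + drift[1] * interval_min * (seq_len(nt) - 1L),
        y_um = start[2] + drift[2] * interval_min * (seq_len(nt) - 1L),
        class = "somatic")
    }
    truth <- list(tracks = do.call(rbind, rows), mean_speed = mean_speed,
                  persistence = persistence, drift = drift, seed = seed)
    structure(list(stacks = list(), truth = truth,
                   params = list(n_tracks = n_tracks, mean_speed = mean_speed,
                                 persistence = persistence, drift = drift,
                                 duration_min = duration_min,
                                 interval_min = interval_min)),
              class = "SyntheticScene")
  })
}

#' Generate a gel-encounter movie with a scripted polarity response
#'
#' A polarized cell (actin-rich front, constant polarity angle) approaches a
#' static bright circular gel; contact happens at `encounter_frame`. After a
#' scripted lag the polarity trajectory follows `behavior`: `turn` rotates the
#' polarity by `turn_angle_deg`, `loss_of_polarity` switches the front type to
#' `unpolarized`, `no_change` leaves everything constant. Truth stores the
#' category, the encounter frame and the scripted response lag.
#'
#' @param behavior one of `"turn"`, `"loss_of_polarity"`, `"no_change"`.
#' @param turn_angle_deg scripted turn magnitude.
#' @param encounter_frame frame of first gel contact; must leave >= 1 min
#'   before and >= 5 min after within the movie.
#' @param response_lag_s delay between encounter and the scripted response.
#' @param frames movie length; `frame_interval_s` calibration (default 30 s,
#'   the acquisition interval of gel-encounter experiments).
#' @param render if `TRUE`, also render a small movie (cell + bright gel disk).
#' @param noise_sd additive Gaussian noise for rendered movies.
#' @param seed RNG seed.
#' @return `SyntheticScene`; truth holds `polarity_angle_per_frame`,
#'   `front_type_per_frame`, `category`, `encounter_frame`, `response_lag_s`,
#'   and gel geometry.
#' @export
generate_gel_encounter_movie <- function(behavior = c("turn", "loss_of_polarity", "no_change"),
                                         turn_angle_deg = 90,
                                         encounter_frame = 5L,
                                         response_lag_s = 60,
                                         frames = 16L, frame_interval_s = 30,
                                         render = FALSE, noise_sd = 0, seed = 1L) {
  behavior <- match.arg(behavior)
  pre_f <- 60 / frame_interval_s          # 1 min before
  post_f <- 300 / frame_interval_s        # 5 min after
  if (encounter_frame - pre_f < 1 || encounter_frame + post_f > frames)
    abort_param("the 6-min window (-1/+5 min) around `encounter_frame` does not fit the movie")
  with_seed(seed, {
    lag_f <- round(response_lag_s / frame_interval_s)
    resp_frame <- encounter_frame + lag_f
    if (resp_frame > frames) abort_param("response lag exceeds the movie")
    pol <- rep(0, frames)
    type <- rep("actin_rich", frames)
    if (behavior == "turn") {
      pol[resp_frame:frames] <- wrap_deg(turn_angle_deg)
    } else if (behavior == "loss_of_polarity") {
      type[resp_frame:frames] <- "unpolarized"
    }
    truth <- list(polarity_angle_per_frame = pol,
                  front_type_per_frame = type,
                  category = behavior,
                  encounter_frame = encounter_frame,
                  response_lag_s = lag_f * frame_interval_s,
                  turn_angle_deg = if (behavior == "turn") turn_angle_deg else NA_real_,
                  frame_interval_s = frame_interval_s,
                  seed = seed)
    stacks <- list()
    if (render) {
      size <- c(96L, 160L)
      radius <- 12; gel_r <- 18
      gel_c <- c((size[1] - 1) / 2, size[2] - 1 - gel_r - 4)  # (y, x)
      ## cell moves +x, touching the gel exactly at encounter_frame
      contact_x <- gel_c[2] - gel_r - radius
      speed <- 2.5
      x0 <- contact_x - speed * (encounter_frame - 1)
      g <- pixel_grid(size)
      arr <- array(0, c(frames, size[1], size[2]))
      gel_mask <- (g$y - gel_c[1])^2 + (g$x - gel_c[2])^2 <= gel_r^2
      for (t in seq_len(frames)) {
        cx <- min(x0 + speed * (t - 1), contact_x)
        cell <- (g$y - gel_c[1])^2 + (g$x - cx)^2 <= radius^2
        img <- matrix(0, size[1], size[2])
        img[gel_mask] <- 80
        img[cell] <- 150
        if (noise_sd > 0)
          img <- img + matrix(rnorm(length(img), 0, noise_sd), size[1], size[2])
        arr[t, , ] <- img
      }
      truth$gel_center <- gel_c; truth$gel_radius <- gel_r
      stacks <- list(image_stack(arr, 0.5, frame_interval_s))
    }
    structure(list(stacks = stacks, truth = truth,
                   params = list(behavior = behavior, turn_angle_deg = turn_angle_deg,
                                 encounter_frame = encounter_frame,
                                 response_lag_s = response_lag_s, frames = frames,
                                 frame_interval_s = frame_interval_s)),
              class = "SyntheticScene")
  })
}

#' Write scene tables (tracks, centroids) to CSV
#'
#' @param scene a `SyntheticScene` holding tabular truth.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_scene_csv <- function(scene, path) {
  tab <- if (!is.null(scene$truth$tracks)) scene$truth$tracks
  else if (!is.null(scene$truth$centroids_um)) as.data.frame(scene$truth$centroids_um)
  else abort_input("scene holds no tabular truth")
  write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
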