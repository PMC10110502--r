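test_that("cell movie generator honours the rate-zero and determinism contracts", {
  p0 <- list(frames = 5L, bleb_rate_per_min = 0, noise_sd = 0,
             speed_px_per_frame = 1)
  sc <- generate_cell_movie(p0, seed = 3)
  expect_equal(nrow(sc$truth$bleb_events), 0L)
  ## contour constant up to translation
  c1 <- sweep(sc$truth$contour_per_frame[[1]], 2,
              c(sc$truth$centers[1, 2], sc$truth$centers[1, 1]))
  c5 <- sweep(sc$truth$contour_per_frame[[5]], 2,
              c(sc$truth$centers[5, 2], sc$truth$centers[5, 1]))
  expect_equal(c1, c5)

  a <- generate_cell_movie(list(frames = 4L, bleb_rate_per_min = 2, noise_sd = 3), seed = 7)
  b <- generate_cell_movie(list(frames = 4L, bleb_rate_per_min = 2, noise_sd = 3), seed = 7)
  expect_identical(a$stacks[[1]]$data, b$stacks[[1]]$data)
  expect_identical(a$truth$bleb_events, b$truth$bleb_events)
})

test_that("cell movie generator rejects non-physical parameters", {
  expect_error(generate_cell_movie(list(frames = 1L)), class = "pgcprot_parameter_error")
  expect_error(generate_cell_movie(list(bleb_rate_per_min = -1)),
               class = "pgcprot_parameter_error")
  expect_error(generate_cell_movie(list(radius_px = 0)), class = "pgcprot_parameter_error")
  expect_error(generate_cell_movie(list(profile = list(A = 1, mu_deg = 0, sigma_deg = 200, c = 0))),
               class = "pgcprot_parameter_error")
})

test_that("bleb event counts follow the configured Poisson rate", {
  ## 2 events/min over a 10-min movie, truth-only for speed
  counts <- vapply(1:200, function(s) {
    sc <- generate_cell_movie(list(frames = 120L, frame_interval_s = 5,
                                   bleb_rate_per_min = 2), seed = s,
                              truth_only = TRUE)
    nrow(sc$truth$bleb_events)
  }, numeric(1))
  expect_lt(abs(mean(counts) - 20), 3 * sqrt(20))
})

test_that("truth contours rasterize back to the movie's cell mask", {
  sc <- generate_cell_movie(list(frames = 4L, bleb_rate_per_min = 3,
                                 noise_sd = 0), seed = 11)
  for (t in seq_len(4L)) {
    fr <- get_frame(sc$stacks[[1]], t)
    mask <- fr > 0            # zero-noise movie: any signal is cell
    expect_identical(rasterize_truth(sc$truth, t, dim(fr)), mask)
  }
})

test_that("nuclei field generator builds lattices and reproducible random fields", {
  sc <- generate_nuclei_field("cubic_lattice", spacing = 10, box = c(40, 40, 40))
  expect_equal(nrow(sc$truth$centroids_um), 125L)
  expect_true(all(sc$truth$centroids_um %% 10 == 0))

  r1 <- generate_nuclei_field("uniform_random", n = 100, seed = 5)
  r2 <- generate_nuclei_field("uniform_random", n = 100, seed = 5)
  expect_identical(r1$truth$centroids_um, r2$truth$centroids_um)
  d <- dist(generate_nuclei_field("uniform_random", n = 500, seed = 1)$truth$centroids_um)
  expect_gt(min(d), 0)
  expect_error(generate_nuclei_field("uniform_random", n = 5),
               class = "pgcprot_parameter_error")
})

test_that("ratio stack encodes the requested field exactly at zero noise", {
  sc <- generate_ratio_stack(ratio = 2, noise_sd = 0)
  don <- get_frame(sc$stacks$donor, 1); acc <- get_frame(sc$stacks$acceptor, 1)
  m <- sc$truth$mask
  expect_equal(acc[m] / don[m], rep(2, sum(m)))

  grad <- generate_ratio_stack(ratio = c(1, 3), noise_sd = 0)
  don <- get_frame(grad$stacks$donor, 1); acc <- get_frame(grad$stacks$acceptor, 1)
  m <- grad$truth$mask
  expect_equal(acc[m] / don[m], grad$truth$ratio_field[m], tolerance = 1e-12)

  expect_error(generate_ratio_stack(donor_level = 0), class = "pgcprot_parameter_error")
  expect_error(generate_ratio_stack(semiaxes = c(0.1, 0.1)),
               class = "pgcprot_parameter_error")
})

test_that("stripe movies translate at exactly the configured speed", {
  still <- generate_stripe_movie(speed = 0, frames = 4)
  expect_equal(still$stacks[[1]]$data[1, , ], still$stacks[[1]]$data[4, , ])

  mv <- generate_stripe_movie(speed = 2, frames = 6)
  ## brute-force correlation oracle between consecutive frames
  r1 <- mv$stacks[[1]]$data[1, 1, ]; r2 <- mv$stacks[[1]]$data[2, 1, ]
  lags <- -6:6
  cc <- vapply(lags, function(l) {
    if (l >= 0) sum(r1[seq_len(128 - l)] * r2[seq_len(128 - l) + l])
    else sum(r2[seq_len(128 + l)] * r1[seq_len(128 + l) - l])
  }, numeric(1))
  expect_equal(lags[which.max(cc)], 2)

  ## non-integer speed: cumulative shift over 10 intervals = 15 px
  fr <- generate_stripe_movie(speed = 1.5, frames = 11)
  f1 <- fr$stacks[[1]]$data[1, 1, ]; f11 <- fr$stacks[[1]]$data[11, 1, ]
  ## frame 11 equals frame 1 shifted by 15 px (period 24 makes this exact)
  expect_equal(f11[16:128], f1[1:113], tolerance = 1e-12)
  expect_error(generate_stripe_movie(frames = 1), class = "pgcprot_parameter_error")
})

test_that("track generator honours persistence and drift contracts", {
  straight <- generate_tracks(n_tracks = 3, mean_speed = 6, persistence = 1,
                              drift = c(0, 0), duration_min = 20,
                              interval_min = 2, seed = 2)
  tab <- straight$truth$tracks
  for (id in unique(tab$track_id[tab$class == "pgc"])) {
    tr <- tab[tab$track_id == id, ]
    expect_equal(track_straightness(tr), 1, tolerance = 1e-12)
    expect_equal(track_speed(tr), 6, tolerance = 1e-12)
  }
  expect_error(generate_tracks(interval_min = 0), class = "pgcprot_parameter_error")
  expect_error(generate_tracks(duration_min = 1, interval_min = 2),
               class = "pgcprot_parameter_error")
})

test_that("gel encounter movies script the requested behavior", {
  nc <- generate_gel_encounter_movie("no_change", encounter_frame = 5, seed = 1)
  expect_true(all(nc$truth$polarity_angle_per_frame == nc$truth$polarity_angle_per_frame[1]))
  expect_true(all(nc$truth$front_type_per_frame == "actin_rich"))

  tu <- generate_gel_encounter_movie("turn", turn_angle_deg = 90,
                                     encounter_frame = 5, seed = 1)
  pol <- tu$truth$polarity_angle_per_frame
  expect_equal(abs(circ_diff_deg(pol[length(pol)], pol[1])), 90)

  lp <- generate_gel_encounter_movie("loss_of_polarity", encounter_frame = 5, seed = 1)
  expect_equal(lp$truth$front_type_per_frame[16], "unpolarized")

  ## window must fit: 1 min before and 5 min after at 30-s frames
  expect_error(generate_gel_encounter_movie("turn", encounter_frame = 1),
               class = "pgcprot_parameter_error")
  expect_error(generate_gel_encounter_movie("turn", encounter_frame = 10, frames = 16),
               class = "pgcprot_parameter_error")
})

test_that("stack text serialization round-trips", {
  sc <- generate_stripe_movie(speed = 1, frames = 3, size = c(8L, 16L), seed = 9)
  dir <- tempfile("stack_")
  write_image_stack(sc$stacks[[1]], dir, extra = list(seed = 9))
  back <- read_image_stack(dir)
  expect_equal(back$data, sc$stacks[[1]]$data, tolerance = 1e-12)
  expect_equal(back$pixel_size_um, sc$stacks[[1]]$pixel_size_um)
  unlink(dir, recursive = TRUE)
})
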