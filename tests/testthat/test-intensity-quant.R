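test_that("ratio_map computes per-pixel ratios with a donor floor", {
  don <- matrix(10, 8, 8); acc <- 2 * don
  mask <- matrix(TRUE, 8, 8)
  rm_ <- ratio_map(don, acc, mask)
  expect_true(all(rm_$ratio[rm_$valid] == 2))
  expect_equal(whole_cell_value(rm_), 2)

  ## donor below floor everywhere: flagged, whole_cell_value errors
  low <- ratio_map(matrix(0.1, 4, 4), matrix(1, 4, 4), matrix(TRUE, 4, 4),
                   donor_floor = 5)
  expect_true(low$no_valid)
  expect_error(whole_cell_value(low), class = "pgcprot_input_error")

  expect_error(ratio_map(matrix(1, 2, 2), matrix(1, 3, 3), matrix(TRUE, 2, 2)),
               class = "pgcprot_input_error")
})

test_that("ratio metrics agree with generator truth and a brute-force mean", {
  sc <- generate_ratio_stack(ratio = c(1, 3), noise_sd = 0)
  don <- get_frame(sc$stacks$donor, 1); acc <- get_frame(sc$stacks$acceptor, 1)
  rm_ <- ratio_map(don, acc, sc$truth$mask)
  expect_equal(rm_$ratio[rm_$valid], sc$truth$ratio_field[rm_$valid],
               tolerance = 1e-6)
  expect_equal(whole_cell_value(rm_), mean(sc$truth$ratio_field[rm_$valid]),
               tolerance = 1e-9)

  ## half-mask at 1, half at 3 with equal areas -> mean 2
  don2 <- matrix(10, 6, 8); acc2 <- matrix(10, 6, 8)
  acc2[, 5:8] <- 30
  rm2 <- ratio_map(don2, acc2, matrix(TRUE, 6, 8))
  expect_equal(whole_cell_value(rm2), 2)
})

test_that("ratio metrics are invariant to common-channel scaling", {
  sc <- generate_ratio_stack(ratio = c(1, 3), noise_sd = 0)
  don <- get_frame(sc$stacks$donor, 1); acc <- get_frame(sc$stacks$acceptor, 1)
  r1 <- ratio_map(don, acc, sc$truth$mask, donor_floor = 1)
  r2 <- ratio_map(don * 7, acc * 7, sc$truth$mask, donor_floor = 7)
  expect_equal(whole_cell_value(r1), whole_cell_value(r2), tolerance = 1e-12)
  fb1 <- front_back_ratio(r1, movement_axis = 0)
  fb2 <- front_back_ratio(r2, movement_axis = 0)
  expect_equal(fb1$ratio, fb2$ratio, tolerance = 1e-12)
})

test_that("front_back_ratio quarters along the long axis", {
  ## uniform ratio -> 1
  sc <- generate_ratio_stack(ratio = 2, noise_sd = 0)
  rm_ <- ratio_map(get_frame(sc$stacks$donor, 1),
                   get_frame(sc$stacks$acceptor, 1), sc$truth$mask)
  expect_equal(front_back_ratio(rm_, movement_axis = 0)$ratio, 1, tolerance = 1e-9)

  ## linear gradient 1 -> 3 across a 40-px rectangle, sampled at pixel
  ## centers so the quarter means are exactly 1.25 and 2.75
  don <- matrix(10, 16, 40)
  grad <- matrix(rep(1 + 2 * ((0:39) + 0.5) / 40, each = 16), 16, 40)
  acc <- don * grad
  mask <- matrix(TRUE, 16, 40)
  fb <- front_back_ratio(ratio_map(don, acc, mask), movement_axis = 0)
  expect_equal(fb$ratio, 2.75 / 1.25, tolerance = 1e-9)
  expect_equal(sum(fb$section_counts), sum(mask))

  ## flipped map gives the reciprocal
  fb_flip <- front_back_ratio(ratio_map(don, acc[, 40:1], mask), movement_axis = 0)
  expect_equal(fb_flip$ratio, 1 / fb$ratio, tolerance = 1e-9)

  ## movement_axis flips the front assignment
  fb_rev <- front_back_ratio(ratio_map(don, acc, mask), movement_axis = 180)
  expect_equal(fb_rev$ratio, 1 / fb$ratio, tolerance = 1e-9)

  expect_error(front_back_ratio(ratio_map(don[1:3, 1:3], acc[1:3, 1:3],
                                          matrix(TRUE, 3, 3))),
               class = "pgcprot_input_error")
})

test_that("front/back quarter means match the generator's analytic truth", {
  sc <- generate_ratio_stack(ratio = c(1, 3), noise_sd = 0)
  rm_ <- ratio_map(get_frame(sc$stacks$donor, 1),
                   get_frame(sc$stacks$acceptor, 1), sc$truth$mask)
  fb <- front_back_ratio(rm_, movement_axis = 0)
  ## brute-force quarter means over the generator's own field
  mask <- sc$truth$mask
  xs <- which(mask, arr.ind = TRUE)[, 2] - 1
  rng <- range(xs); brk <- rng[1] + diff(rng) * (1:3) / 4
  sect <- findInterval(xs, brk) + 1
  vals <- sc$truth$ratio_field[mask]
  oracle <- mean(vals[sect == 4]) / mean(vals[sect == 1])
  expect_equal(fb$ratio, oracle, tolerance = 0.01)
})

test_that("normalize_per_day normalizes within each repeat", {
  df <- data.frame(value = c(1, 3, 4, 2, 6, 9),
                   group = c("meso", "meso", "ecto", "meso", "meso", "ecto"),
                   repeat_id = c("d1", "d1", "d1", "d2", "d2", "d2"))
  out <- normalize_per_day(df, "meso")
  expect_equal(mean(out$normalized[out$group == "meso" & out$repeat_id == "d1"]), 1)
  expect_equal(mean(out$normalized[out$group == "meso" & out$repeat_id == "d2"]), 1)
  expect_equal(out$normalized[3], 2)   # 4 / mean(1, 3)
  expect_equal(out$normalized[6], 9 / 4)
  expect_error(normalize_per_day(df[df$group == "ecto", ], "meso"),
               class = "pgcprot_input_error")
})

test_that("quantify_stain projects, subtracts background and flags overlap", {
  ## uniform signal S over cell, B elsewhere
  z <- array(0, c(12, 20, 20))
  cell <- matrix(FALSE, 20, 20); cell[8:12, 8:12] <- TRUE
  bg1 <- matrix(FALSE, 20, 20); bg1[1:4, 1:4] <- TRUE
  bg2 <- matrix(FALSE, 20, 20); bg2[16:19, 16:19] <- TRUE
  for (k in 1:12) { fr <- matrix(3, 20, 20); fr[cell] <- 10; z[k, , ] <- fr }

  avg <- quantify_stain(z, "average", cell_region = cell,
                        background_regions = list(bg1, bg2))
  expect_equal(avg$projection_mode, "average")
  expect_equal(avg$n_slices, 10L)              # default: first 10 slices
  expect_equal(avg$corrected_mean, 10 - 3)

  sm <- quantify_stain(z, "sum", cell_region = cell,
                       background_regions = list(bg1, bg2))
  expect_equal(sm$n_slices, 12L)               # sum mode: all slices
  expect_equal(sm$corrected_mean, 12 * (10 - 3))

  ## 10-slice uniform stack: sum / average = 10
  z10 <- z[1:10, , , drop = FALSE]
  a10 <- quantify_stain(z10, "average", cell_region = cell,
                        background_regions = list(bg1, bg2))
  s10 <- quantify_stain(z10, "sum", cell_region = cell,
                        background_regions = list(bg1, bg2))
  expect_equal(s10$cell_mean / a10$cell_mean, 10)

  ## per-slice varying stack equals brute-force projection
  set.seed(5)
  zr <- array(runif(6 * 10 * 10), c(6, 10, 10))
  cr <- matrix(FALSE, 10, 10); cr[4:6, 4:6] <- TRUE
  b1 <- matrix(FALSE, 10, 10); b1[1:2, 1:2] <- TRUE
  b2 <- matrix(FALSE, 10, 10); b2[9:10, 9:10] <- TRUE
  got <- quantify_stain(zr, "sum", cell_region = cr, background_regions = list(b1, b2))
  proj <- apply(zr, c(2, 3), sum)
  expect_equal(got$cell_mean, mean(proj[cr]), tolerance = 1e-12)
  expect_equal(got$background_mean, mean(c(mean(proj[b1]), mean(proj[b2]))),
               tolerance = 1e-12)

  expect_error(quantify_stain(z, "average", cell_region = cell,
                              background_regions = list(cell)),
               class = "pgcprot_input_error")
  expect_error(quantify_stain(z, "average", slices = 1:20, cell_region = cell,
                              background_regions = list(bg1)),
               class = "pgcprot_input_error")
})
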