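test_that("eligibility_filter requires a forward run strictly longer than 3 min", {
  dt <- 5  # seconds per frame
  ok <- eligibility_filter(rep(TRUE, 48), dt)           # 4 min
  expect_true(ok$eligible)
  expect_equal(ok$duration_min, 4)

  ## 2 min + 2 min separated by tumbling: no single qualifying run
  ann <- c(rep(TRUE, 24), rep(FALSE, 6), rep(TRUE, 24))
  expect_false(eligibility_filter(ann, dt)$eligible)

  ## exactly 3.0 min: strict inequality -> ineligible
  expect_false(eligibility_filter(rep(TRUE, 36), dt)$eligible)
  expect_error(eligibility_filter(c(TRUE, NA), dt), class = "pgcprot_input_error")
})

test_that("bleb_metrics computes frequency and relative size from events", {
  ev <- data.frame(max_area_px2 = c(30, 60, 45, 30, 30),
                   cell_area_px2 = c(300, 300, 300, 300, 300))
  m <- bleb_metrics(ev, analyzed_time_min = 10)
  expect_equal(m$blebbing_frequency, 0.5)
  expect_equal(m$mean_relative_bleb_size, mean(c(0.1, 0.2, 0.15, 0.1, 0.1)))

  m1 <- bleb_metrics(data.frame(max_area_px2 = 30, cell_area_px2 = 300), 5)
  expect_equal(m1$mean_relative_bleb_size, 0.1)

  ## generator truth bookkeeping: frequency = count / duration exactly
  sc <- generate_cell_movie(list(frames = 60L, frame_interval_s = 5,
                                 bleb_rate_per_min = 2), seed = 21,
                            truth_only = TRUE)
  dur <- 60 * 5 / 60
  mt <- bleb_metrics(sc$truth$bleb_events, dur)
  expect_equal(mt$blebbing_frequency, nrow(sc$truth$bleb_events) / dur)

  expect_error(bleb_metrics(ev, 0), class = "pgcprot_input_error")
})

test_that("normalize_to_reference scales by the reference mean", {
  out <- normalize_to_reference(3, c(2, 4))
  expect_equal(out$values, 1)
  expect_equal(out$reference_values, c(2, 4) / 3)
  expect_equal(mean(out$reference_values), 1, tolerance = 1e-12)

  same <- normalize_to_reference(c(2, 4), c(2, 4))
  expect_equal(mean(same$values), 1, tolerance = 1e-12)
  expect_error(normalize_to_reference(1, c(0, 0)), class = "pgcprot_input_error")
})

test_that("frequency is additive over movie halves", {
  sc <- generate_cell_movie(list(frames = 120L, frame_interval_s = 5,
                                 bleb_rate_per_min = 1.5), seed = 31,
                            truth_only = TRUE)
  ev <- sc$truth$bleb_events
  n1 <- sum(ev$start_frame <= 60); n2 <- sum(ev$start_frame > 60)
  whole <- bleb_metrics(ev, 10)$blebbing_frequency
  f1 <- bleb_metrics(ev[ev$start_frame <= 60, ], 5)$blebbing_frequency
  f2 <- bleb_metrics(ev[ev$start_frame > 60, ], 5)$blebbing_frequency
  expect_equal((f1 * 5 + f2 * 5) / 10, whole)
})

test_that("actin_rich_fraction follows its definition", {
  expect_equal(actin_rich_fraction(c(rep("actin_rich", 30), rep("bleb", 30))), 0.5)
  expect_equal(actin_rich_fraction(rep("actin_rich", 10)), 1)
  ## unpolarized frames drop out of the denominator
  expect_equal(actin_rich_fraction(c(rep("actin_rich", 7), rep("bleb", 3),
                                     rep("unpolarized", 20))), 0.7)
  expect_error(actin_rich_fraction(rep("unpolarized", 5)),
               class = "pgcprot_input_error")
  expect_error(actin_rich_fraction(c("actin_rich", "typo")),
               class = "pgcprot_input_error")
})

test_that("detect_blebs finds generator blebs on favorable noise-free movies", {
  ## favorable parameters: bright near-uniform cortex, temporally separated
  ## events, fixed low threshold
  sc <- generate_cell_movie(list(frames = 40L, frame_interval_s = 5,
                                 bleb_rate_per_min = 1.5, noise_sd = 0,
                                 bleb_min_separation_s = 40,
                                 profile = list(A = 150, mu_deg = 0,
                                                sigma_deg = 150, c = 30),
                                 size = c(96L, 96L)), seed = 12)
  masks <- segment_movie(sc$stacks[[1]], threshold = 30)
  det <- detect_blebs(sc$stacks[[1]], masks, min_area_fraction = 0.005)
  truth <- sc$truth$bleb_events
  ## every truth event matched by apex angle and time overlap
  matched <- vapply(seq_len(nrow(truth)), function(i) {
    any(abs(circ_diff_deg(det$apex_angle_deg, truth$apex_angle_deg[i])) < 30 &
          det$start_frame <= truth$end_frame[i] &
          det$end_frame >= truth$start_frame[i])
  }, logical(1))
  expect_true(all(matched))
  expect_equal(nrow(det), nrow(truth))   # no false positives

  ## static cell: no events
  quiet <- generate_cell_movie(list(frames = 10L, bleb_rate_per_min = 0,
                                    noise_sd = 0), seed = 13)
  qm <- segment_movie(quiet$stacks[[1]])
  expect_equal(nrow(detect_blebs(quiet$stacks[[1]], qm)), 0L)

  ## area threshold suppresses reporting
  det2 <- detect_blebs(sc$stacks[[1]], masks, min_area_fraction = 0.5)
  expect_equal(nrow(det2), 0L)

  expect_error(detect_blebs(sc$stacks[[1]],
                            structure(list(masks = qm$masks), class = "CellMaskSeries")),
               class = "pgcprot_input_error")
})

test_that("score_gel_response reproduces scripted categories and times", {
  dt <- 30
  mk_pol <- function(truth) data.frame(angle_deg = truth$polarity_angle_per_frame,
                                       front_type = truth$front_type_per_frame)
  nc <- generate_gel_encounter_movie("no_change", encounter_frame = 5, seed = 2)
  r <- score_gel_response(mk_pol(nc$truth), 5, dt)
  expect_equal(r$category, "no_change")
  expect_true(is.na(r$response_time_s))
  expect_equal(r$window_s, c(-60, 300))

  tu <- generate_gel_encounter_movie("turn", turn_angle_deg = 90,
                                     encounter_frame = 5, response_lag_s = 60, seed = 2)
  rt <- score_gel_response(mk_pol(tu$truth), 5, dt, turn_threshold_deg = 45)
  expect_equal(rt$category, "turn")
  expect_equal(rt$response_time_s, 60)

  lp <- generate_gel_encounter_movie("loss_of_polarity", encounter_frame = 5,
                                     response_lag_s = 90, seed = 2)
  rl <- score_gel_response(mk_pol(lp$truth), 5, dt)
  expect_equal(rl$category, "loss_of_polarity")
  expect_equal(rl$response_time_s, 90)

  expect_error(score_gel_response(mk_pol(nc$truth), 40, dt),
               class = "pgcprot_input_error")
})

test_that("response_contingency_test builds the right tables and adjusts p", {
  counts <- rbind(stiff = c(turn = 10, loss_of_polarity = 0, no_change = 0),
                  soft = c(turn = 0, loss_of_polarity = 0, no_change = 10))
  out <- response_contingency_test(counts)
  ## the collapsed 2x2 is [[10, 0], [0, 10]]
  expect_equal(out$p_value, fisher_enum_oracle(rbind(c(10, 0), c(0, 10))),
               tolerance = 1e-12)

  same <- rbind(a = c(turn = 3, loss_of_polarity = 2, no_change = 5),
                b = c(turn = 3, loss_of_polarity = 2, no_change = 5))
  expect_equal(response_contingency_test(same)$p_value, 1)

  three <- rbind(a = c(turn = 5, loss_of_polarity = 1, no_change = 4),
                 b = c(turn = 2, loss_of_polarity = 1, no_change = 7),
                 c = c(turn = 8, loss_of_polarity = 0, no_change = 2))
  o3 <- response_contingency_test(three)
  expect_equal(nrow(o3), 3L)
  expect_equal(o3$p_adjusted, pmin(1, o3$p_value * 3))

  expect_error(response_contingency_test(
    rbind(a = c(turn = 0, loss_of_polarity = 0, no_change = 0),
          b = c(turn = 1, loss_of_polarity = 1, no_change = 1))),
    class = "pgcprot_input_error")
})
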