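## Bleb and protrusion metrics, eligibility filtering, gel-response scoring.
##
## The protocol-faithful metrics consume event/frame annotations (human scoring
## or generator truth); detect_blebs() is an optional automated helper for
## synthetic benchmarking and is never substituted silently.

#' Eligibility filter: sustained forward movement
#'
#' A cell enters the blebbing analysis only if it moves forward continuously
#' for longer than 3 minutes (strict inequality). Returns the longest forward
#' run and its duration.
#'
#' @param moving_forward logical vector, one entry per frame.
#' @param frame_interval_s seconds per frame.
#' @param min_duration_min required run length in minutes (default 3).
#' @return list with `eligible`, `span` (first/last frame of the longest run,
#'   or `NULL`), `duration_min`.
#' @export
eligibility_filter <- function(moving_forward, frame_interval_s,
                               min_duration_min = 3) {
  if (length(moving_forward) == 0L || anyNA(moving_forward))
    abort_input("`moving_forward` must be a complete logical vector")
  r <- rle(moving_forward)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  fwd <- which(r$values)
  if (length(fwd) == 0L)
    return(list(eligible = FALSE, span = NULL, duration_min = 0))
  best <- fwd[which.max(r$lengths[fwd])]
  dur <- r$lengths[best] * frame_interval_s / 60
  list(eligible = dur > min_duration_min,
       span = c(start = starts[best], end = ends[best]),
       duration_min = dur)
}

#' Bleb frequency and relative size metrics
#'
#' Frequency = event count / analyzed time (events per minute). Relative bleb
#' size per event = bleb area at maximum expansion / cell area at the same
#' time point; the reported size is the mean over events (absent when no
#' events occurred).
#'
#' @param events data.frame of bleb events with columns `max_area_px2` and
#'   `cell_area_px2` (zero-row data.frame allowed).
#' @param analyzed_time_min analyzed time period in minutes (> 0).
#' @return a `ProtrusionMetrics`: list with `blebbing_frequency` (events/min),
#'   `mean_relative_bleb_size` (`NA` when no events), `n_events`.
#' @export
bleb_metrics <- function(events, analyzed_time_min) {
  if (!is.numeric(analyzed_time_min) || analyzed_time_min <= 0)
    abort_input("`analyzed_time_min` must be > 0")
  n <- if (is.null(events)) 0L else nrow(events)
  rel <- NA_real_
  if (n > 0L) {
    if (any(events$max_area_px2 <= 0) || any(events$cell_area_px2 <= 0))
      abort_input("bleb and cell areas must be positive")
    rel <- mean(events$max_area_px2 / events$cell_area_px2)
  }
  structure(list(blebbing_frequency = n / analyzed_time_min,
                 mean_relative_bleb_size = rel,
                 n_events = n,
                 analyzed_time_min = analyzed_time_min),
            class = "ProtrusionMetrics")
}

#' @export
print.ProtrusionMetrics <- function(x, ...) {
  cat(sprintf("<ProtrusionMetrics> %.3g events/min over %.3g min; mean relative size %.3g\n",
              x$blebbing_frequency, x$analyzed_time_min, x$mean_relative_bleb_size))
  invisible(x)
}

#' Normalize per-cell metric values to a reference group's mean
#'
#' Every value (test and reference alike) is divided by the reference group's
#' mean, so the normalized reference mean is 1 — the "normalized to the
#' average value measured in the control condition" convention.
#'
#' @param values numeric per-cell metric values.
#' @param reference_values per-cell values of the reference group.
#' @return list with `values` and `reference_values`, both normalized.
#' @export
normalize_to_reference <- function(values, reference_values) {
  mref <- mean(reference_values)
  if (!is.finite(mref) || mref <= 0)
    abort_input("reference mean must be positive")
  list(values = values / mref, reference_values = reference_values / mref)
}

#' Fraction of forward-moving time with an actin-rich front
#'
#' Counts frames labeled `actin_rich` (front present, no bleb) and divides by
#' the number of polarized forward-moving frames (`actin_rich` plus `bleb`);
#' `unpolarized` frames are excluded from the denominator.
#'
#' @param labels character vector of per-frame labels in
#'   `{"actin_rich", "bleb", "unpolarized"}`.
#' @return proportion in `[0, 1]`.
#' @export
actin_rich_fraction <- function(labels) {
  bad <- setdiff(unique(labels), c("actin_rich", "bleb", "unpolarized"))
  if (length(bad) > 0L)
    abort_input(sprintf("unknown front labels: %s", paste(bad, collapse = ", ")))
  denom <- sum(labels %in% c("actin_rich", "bleb"))
  if (denom == 0L)
    abort_input("no polarized forward-moving frames: fraction undefined")
  sum(labels == "actin_rich") / denom
}

#' Detect bleb events in a synthetic movie
#'
#' Automated helper for benchmarking against generator truth (blebs in the
#' source experiments were scored manually). A connected region of newly
#' gained cell area between consecutive frames becomes a candidate when its
#' area reaches `min_area_fraction` of the cell area within `max_rise_time_s`,
#' and the mean cortical-channel intensity over the new region stays at or
#' below `actin_deficit_ratio` times the mean ring intensity (young blebs are
#' cortex-free). Candidates overlapping by at least half across consecutive
#' frames are merged into one event; maximum expansion is the frame with the
#' largest gain (earliest on ties).
#'
#' @param stack an [image_stack()] (cortical channel).
#' @param masks a `CellMaskSeries` aligned with `stack`.
#' @param min_area_fraction minimum new area as a fraction of cell area
#'   (default 0.02).
#' @param max_rise_time_s maximum time for the region to reach that size
#'   (default 20).
#' @param actin_deficit_ratio cortical-signal deficit threshold: the new
#'   region's mean intensity must not exceed this fraction of the ring mean
#'   (default 0.8; young blebs sit at the cytoplasmic baseline with no
#'   cortical enrichment).
#' @return data.frame of events: `start_frame`, `max_expansion_frame`,
#'   `end_frame`, `max_area_px2`, `cell_area_px2`, `apex_angle_deg`.
#' @export
detect_blebs <- function(stack, masks, min_area_fraction = 0.02,
                         max_rise_time_s = 20, actin_deficit_ratio = 0.8) {
  nt <- n_frames(stack)
  if (length(masks$masks) != nt) abort_input("masks are not aligned with the movie")
  max_rise_f <- max(1L, round(max_rise_time_s / stack$frame_interval_s))
  ## per-frame candidate regions
  regions <- vector("list", nt)
  for (t in 2:nt) {
    gained <- masks$masks[[t]] & !masks$masks[[t - 1L]]
    if (!any(gained)) next
    lab <- label_components(gained, 4L)
    cell_area <- sum(masks$masks[[t]])
    ring <- masks$cortex_masks[[t]]
    fr <- get_frame(stack, t)
    ctr <- masks$centers[t, ]
    keep <- list()
    for (l in seq_len(max(lab))) {
      reg <- lab == l
      area <- sum(reg)
      if (area < min_area_fraction * cell_area) next
      ## reference cortical level: the same angular sector of the previous
      ## frame's ring, i.e. the cortex as it looked before the bleb detached
      ## it (a young bleb suppresses the ring over its own cap, and with a
      ## polarized cortex only the local comparison is meaningful)
      reg_idx <- which(reg, arr.ind = TRUE)
      reg_ang <- wrap_deg(atan2(reg_idx[, 1] - 1 - ctr[1],
                                reg_idx[, 2] - 1 - ctr[2]) * 180 / pi)
      apex <- wrap_deg(atan2(mean(sin(reg_ang * pi / 180)),
                             mean(cos(reg_ang * pi / 180))) * 180 / pi)
      halfw <- min(120, max(abs(circ_diff_deg(reg_ang, apex))) + 5)
      prev_ring <- masks$cortex_masks[[t - 1L]]
      prev_ctr <- masks$centers[t - 1L, ]
      pr_idx <- which(prev_ring, arr.ind = TRUE)
      pr_ang <- wrap_deg(atan2(pr_idx[, 1] - 1 - prev_ctr[1],
                               pr_idx[, 2] - 1 - prev_ctr[2]) * 180 / pi)
      pr_fr <- get_frame(stack, t - 1L)
      sector <- abs(circ_diff_deg(pr_ang, apex)) <= halfw
      ring_mean <- if (any(sector)) mean(pr_fr[prev_ring][sector])
                   else mean(fr[ring])
      if (mean(fr[reg]) > actin_deficit_ratio * ring_mean) next
      keep[[length(keep) + 1L]] <- list(mask = reg, area = area,
                                        cell_area = cell_area)
    }
    if (length(keep) > 0L) regions[[t]] <- keep
  }
  ## link candidate regions across frames by >= 50% overlap
  events <- list()
  open <- list()   # each: list(start, frames, areas, cell_areas, last_mask)
  for (t in seq_len(nt)) {
    cur <- regions[[t]]
    matched_open <- rep(FALSE, length(open))
    next_open <- list()
    if (!is.null(cur)) {
      for (cand in cur) {
        linked <- FALSE
        for (j in seq_along(open)) {
          if (matched_open[j]) next
          ## the gain rim advances outward as the bleb grows, so compare
          ## against a dilated copy of the event's last region
          prev <- dilate_mask(open[[j]]$last_mask, n = 3L)
          ov <- sum(cand$mask & prev)
          if (ov >= 0.5 * min(cand$area, sum(open[[j]]$last_mask))) {
            e <- open[[j]]
            e$frames <- c(e$frames, t); e$areas <- c(e$areas, cand$area)
            e$cell_areas <- c(e$cell_areas, cand$cell_area)
            e$last_mask <- cand$mask
            next_open[[length(next_open) + 1L]] <- e
            matched_open[j] <- TRUE
            linked <- TRUE
            break
          }
        }
        if (!linked)
          next_open[[length(next_open) + 1L]] <-
            list(start = t, frames = t, areas = cand$area,
                 cell_areas = cand$cell_area, last_mask = cand$mask)
      }
    }
    ## close unmatched open events
    for (j in seq_along(open)) if (!matched_open[j])
      events[[length(events) + 1L]] <- open[[j]]
    open <- next_open
  }
  for (e in open) events[[length(events) + 1L]] <- e
  if (length(events) == 0L)
    return(data.frame(start_frame = integer(0), max_expansion_frame = integer(0),
                      end_frame = integer(0), max_area_px2 = numeric(0),
                      cell_area_px2 = numeric(0), apex_angle_deg = numeric(0)))
  rows <- lapply(events, function(e) {
    ## rise-time gate: must reach threshold size within max_rise_f frames
    if ((e$frames[1] - e$start) > max_rise_f) return(NULL)
    imax <- which.max(e$areas)        # earliest frame on ties (which.max rule)
    tmax <- e$frames[imax]
    ctr <- masks$centers[tmax, ]
    reg_idx <- which(e$last_mask, arr.ind = TRUE)
    ang <- wrap_deg(atan2(mean(reg_idx[, 1]) - 1 - ctr[1],
                          mean(reg_idx[, 2]) - 1 - ctr[2]) * 180 / pi)
    data.frame(start_frame = e$start,   # first frame showing the expansion
               max_expansion_frame = tmax,
               end_frame = e$frames[length(e$frames)],
               max_area_px2 = e$areas[imax],
               cell_area_px2 = e$cell_areas[imax],
               apex_angle_deg = ang)
  })
  do.call(rbind, Filter(Negate(is.null), rows))
}

#' Score a cell's response to a gel encounter
#'
#' Scoring uses the 6-minute window from 1 minute before to 5 minutes after
#' the encounter: the category is `loss_of_polarity` if the front type becomes
#' `unpolarized` for at least `depolarization_dwell_s`; otherwise `turn` if
#' the circular change of polarity angle between the window start and any
#' post-encounter frame reaches `turn_threshold_deg`; otherwise `no_change`.
#' The response time, however, is measured over the whole movie ("followed
#' until turning or polarity loss occurred, regardless of the 6-min
#' interval").
#'
#' @param polarity data.frame with per-frame `angle_deg` and `front_type`.
#' @param encounter_frame frame of gel contact.
#' @param frame_interval_s seconds per frame.
#' @param turn_threshold_deg angular change counting as a turn (default 45).
#' @param depolarization_dwell_s minimum unpolarized dwell (default 30).
#' @return a `GelResponse`: list with `category`, `encounter_frame`,
#'   `response_time_s` (`NA` for `no_change`), `window_s = c(-60, 300)`.
#' @export
score_gel_response <- function(polarity, encounter_frame, frame_interval_s,
                               turn_threshold_deg = 45,
                               depolarization_dwell_s = 30) {
  nf <- nrow(polarity)
  pre_f <- 60 / frame_interval_s; post_f <- 300 / frame_interval_s
  if (encounter_frame < 1L || encounter_frame > nf)
    abort_input("`encounter_frame` outside the movie")
  if (encounter_frame - pre_f < 1 || encounter_frame + post_f > nf)
    abort_input("the 6-min window (-1/+5 min) does not fit the movie")
  w0 <- as.integer(encounter_frame - pre_f)
  w1 <- as.integer(encounter_frame + post_f)
  baseline <- polarity$angle_deg[w0]
  dwell_f <- max(1L, ceiling(depolarization_dwell_s / frame_interval_s))

  first_qualifying <- function(last_frame) {
    ## returns list(category, frame) or NULL, scanning post-encounter frames
    post <- (encounter_frame + 1L):last_frame
    unpol <- polarity$front_type[post] == "unpolarized"
    r <- rle(unpol)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    loss_i <- which(r$values & r$lengths >= dwell_f)
    loss_frame <- if (length(loss_i) > 0L) post[starts[loss_i[1]]] else NA_integer_
    turned <- abs(circ_diff_deg(polarity$angle_deg[post], baseline)) >= turn_threshold_deg
    turn_frame <- if (any(turned)) post[which(turned)[1]] else NA_integer_
    if (!is.na(loss_frame) && (is.na(turn_frame) || loss_frame <= turn_frame))
      list(category = "loss_of_polarity", frame = loss_frame)
    else if (!is.na(turn_frame))
      list(category = "turn", frame = turn_frame)
    else NULL
  }

  in_window <- first_qualifying(w1)
  category <- if (is.null(in_window)) "no_change" else in_window$category
  response_time <- NA_real_
  if (category != "no_change") {
    whole <- first_qualifying(nf)
    response_time <- (whole$frame - encounter_frame) * frame_interval_s
  }
  structure(list(category = category,
                 encounter_frame = encounter_frame,
                 response_time_s = response_time,
                 window_s = c(-60, 300),
                 turn_threshold_deg = turn_threshold_deg,
                 depolarization_dwell_s = depolarization_dwell_s),
            class = "GelResponse")
}

#' @export
print.GelResponse <- function(x, ...) {
  cat(sprintf("<GelResponse> %s%s\n", x$category,
              if (is.finite(x$response_time_s))
                sprintf(" (response time %g s)", x$response_time_s) else ""))
  invisible(x)
}

#' Fisher tests on gel-response contingency counts
#'
#' For each pair of conditions, builds the 2x2 table
#' `[(turn + loss_of_polarity), no_change] x condition`, runs the exact
#' two-sided Fisher test, and applies a Bonferroni correction over
#' `n_comparisons`.
#'
#' @param counts matrix or data.frame: rows = conditions, columns must include
#'   `turn`, `loss_of_polarity`, `no_change`.
#' @param n_comparisons number of comparisons for Bonferroni (default: number
#'   of condition pairs).
#' @return data.frame with one row per pair: `condition_a`, `condition_b`,
#'   `odds_ratio`, `p_value`, `p_adjusted`.
#' @export
response_contingency_test <- function(counts, n_comparisons = NULL) {
  cm <- as.matrix(counts[, c("turn", "loss_of_polarity", "no_change")])
  if (any(cm < 0)) abort_input("counts must be non-negative")
  if (any(rowSums(cm) == 0)) abort_input("every condition needs at least one cell")
  conds <- rownames(cm)
  if (is.null(conds)) conds <- sprintf("condition_%d", seq_len(nrow(cm)))
  pairs <- utils::combn(seq_len(nrow(cm)), 2)
  if (is.null(n_comparisons)) n_comparisons <- ncol(pairs)
  rows <- apply(pairs, 2, function(ij) {
    tb <- rbind(c(cm[ij[1], "turn"] + cm[ij[1], "loss_of_polarity"],
                  cm[ij[1], "no_change"]),
                c(cm[ij[2], "turn"] + cm[ij[2], "loss_of_polarity"],
                  cm[ij[2], "no_change"]))
    fe <- if (any(colSums(tb) == 0)) list(odds_ratio = NA_real_, p_value = 1)
          else fisher_exact(tb)   # a zero column margin is degenerate: p = 1
    data.frame(condition_a = conds[ij[1]], condition_b = conds[ij[2]],
               odds_ratio = fe$odds_ratio, p_value = fe$p_value)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- bonferroni(out$p_value, m = max(n_comparisons, nrow(out)))
  out
}
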