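## Shared fixture builders. Everything is generated in code; no binary data.

# solid disk mask on an n x n grid, 0-based center (cy, cx)
disk_mask <- function(n, cy, cx, r) {
  g <- expand.grid(y = seq_len(n) - 1, x = seq_len(n) - 1)
  matrix((g$y - cy)^2 + (g$x - cx)^2 <= r^2, n, n)
}

# random blob: union of a few disks, guaranteed non-empty
random_blob <- function(n = 48, seed = 1) {
  set.seed(seed)
  m <- matrix(FALSE, n, n)
  for (i in seq_len(3)) {
    m <- m | disk_mask(n, runif(1, n * 0.3, n * 0.7), runif(1, n * 0.3, n * 0.7),
                       runif(1, 4, n * 0.2))
  }
  m
}

# brute-force erosion with a 3x3 cross, by explicit pixel loops (oracle)
erode_bruteforce <- function(mask, n = 1) {
  for (k in seq_len(n)) {
    out <- mask
    nr <- nrow(mask); nc <- ncol(mask)
    for (i in seq_len(nr)) for (j in seq_len(nc)) {
      if (!mask[i, j]) next
      nb <- c(if (i > 1) mask[i - 1, j] else FALSE,
              if (i < nr) mask[i + 1, j] else FALSE,
              if (j > 1) mask[i, j - 1] else FALSE,
              if (j < nc) mask[i, j + 1] else FALSE)
      out[i, j] <- all(nb)
    }
    mask <- out
  }
  mask
}

# toy AngularProfile from explicit bin means (bin_width chosen to fit length)
toy_profile <- function(bin_means, bin_width = 360 / length(bin_means)) {
  n <- length(bin_means)
  structure(list(bin_width = bin_width, bin_means = bin_means,
                 n_pixels = rep(4L, n),
                 bin_mean_angle = (seq_len(n) - 0.5) * bin_width,
                 bin_centers = (seq_len(n) - 0.5) * bin_width,
                 n_frames_averaged = 1L),
            class = "AngularProfile")
}

# noiseless circular-Gaussian profile sampled at 120 bin centers
gaussian_profile <- function(A = 1, mu = 90, sigma = 30, c = 0.1, bin_width = 3) {
  centers <- seq(bin_width / 2, 360 - bin_width / 2, by = bin_width)
  d <- pgcprot::circ_diff_deg(centers, mu)
  toy_profile(c + A * exp(-d^2 / (2 * sigma^2)), bin_width)
}

# simple straight-line track data.frame
line_track <- function(n = 5, dt_s = 60, dx = 1, dy = 0, x0 = 0, y0 = 0) {
  data.frame(track_id = "t1", t_s = (seq_len(n) - 1) * dt_s,
             x_um = x0 + (seq_len(n) - 1) * dx,
             y_um = y0 + (seq_len(n) - 1) * dy, class = "pgc")
}

# exhaustive two-sample KS enumeration oracle: p = P(D >= d_obs) over all
# C(n+m, n) assignments of the pooled sample (distinct values assumed)
ks_enum_oracle <- function(a, b) {
  pool <- c(a, b)
  n <- length(a); m <- length(b)
  ks_D <- function(x, y) {
    pts <- sort(unique(c(x, y)))
    max(abs(ecdf(x)(pts) - ecdf(y)(pts)))
  }
  d_obs <- ks_D(a, b)
  idx <- utils::combn(n + m, n)
  ds <- apply(idx, 2, function(ii) ks_D(pool[ii], pool[-ii]))
  list(D = d_obs, p = mean(ds >= d_obs - 1e-12))
}

# exhaustive Fisher oracle from factorial hypergeometric probabilities
fisher_enum_oracle <- function(tb) {
  m <- sum(tb[1, ]); n <- sum(tb[2, ]); k <- sum(tb[, 1])
  lp <- function(a) {
    b <- m - a; c_ <- k - a; d <- n - c_
    lchoose(m, a) + lchoose(n, c_) - lchoose(m + n, k)
  }
  support <- max(0, k - n):min(k, m)
  probs <- exp(vapply(support, lp, numeric(1)))
  p_obs <- exp(lp(tb[1, 1]))
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
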