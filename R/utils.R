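## Shared helpers: error classes, circular arithmetic, seeded evaluation.

abort_input <- function(msg) {
  stop(structure(list(message = msg, call = sys.call(-1)),
                 class = c("pgcprot_input_error", "error", "condition")))
}

abort_param <- function(msg) {
  stop(structure(list(message = msg, call = sys.call(-1)),
                 class = c("pgcprot_parameter_error", "error", "condition")))
}

#' Wrap angles into [0, 360)
#' @param a numeric vector of angles in degrees.
#' @return angles in `[0, 360)`.
#' @export
wrap_deg <- function(a) a %% 360

#' Signed minimal circular difference between angles
#'
#' @param a,b angles in degrees.
#' @return `a - b` wrapped into `(-180, 180]`.
#' @export
circ_diff_deg <- function(a, b) {
  d <- (a - b) %% 360
  ifelse(d > 180, d - 360, d)
}

## Evaluate `expr` under a fixed RNG state, restoring the caller's state.
## All generators funnel through this so they are pure in (params, seed).
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    abort_param("`seed` must be a single finite number")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister", normal.kind = "Inversion")
  expr
}

## Polynomial rolling hash (mod 2^31 - 1, exact in doubles) of a serialized
## object; used to stamp outputs with a provenance hash of the configuration
## they came from.
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Otsu threshold of an intensity image
#'
#' Maximizes between-class variance on a 256-bin histogram spanning the data
#' range. Returns a threshold value; pixels strictly above it are foreground.
#'
#' @param x numeric vector or matrix of intensities.
#' @param n_bins histogram resolution.
#' @return a single threshold on the intensity scale.
#' @export
otsu_threshold <- function(x, n_bins = 256L) {
  x <- as.numeric(x[is.finite(x)])
  if (length(x) == 0L) abort_input("no finite intensities for Otsu threshold")
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  counts <- tabulate(findInterval(x, edges, rightmost.closed = TRUE), n_bins)
  p <- counts / sum(counts)
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  w1 <- 1 - w0
  between <- (mu_t * w0 - mu)^2 / (w0 * w1)
  between[!is.finite(between)] <- -Inf
  mids[which.max(between)]
}

## row/col index grids matching a matrix, in 0-based pixel coordinates
pixel_grid <- function(dim_yx) {
  list(y = matrix(rep(seq_len(dim_yx[1]) - 1L, dim_yx[2]), dim_yx[1], dim_yx[2]),
       x = matrix(rep(seq_len(dim_yx[2]) - 1L, each = dim_yx[1]), dim_yx[1], dim_yx[2]))
}
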