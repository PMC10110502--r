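#' Time-lapse image stack container
#'
#' A thin container for a single-channel grayscale movie: a numeric array of
#' dimension `T x Y x X` plus the physical calibration that every downstream
#' metric needs (`pixel_size_um`, `frame_interval_s`).
#'
#' @param data numeric array `T x Y x X` (a single matrix is promoted to one
#'   frame) .
#' @param pixel_size_um micrometers per pixel (isotropic).
#' @param frame_interval_s seconds between consecutive frames.
#' @return an object of class `ImageStack`.
#' @export
image_stack <- function(data, pixel_size_um = 1, frame_interval_s = 1) {
  if (is.matrix(data)) data <- array(data, c(1L, dim(data)))
  if (!is.array(data) || length(dim(data)) != 3L)
    abort_input("`data` must be a T x Y x X array or a single matrix")
  if (!is.numeric(pixel_size_um) || pixel_size_um <= 0)
    abort_param("`pixel_size_um` must be > 0")
  if (!is.numeric(frame_interval_s) || frame_interval_s <= 0)
    abort_param("`frame_interval_s` must be > 0")
  structure(list(data = data,
                 pixel_size_um = pixel_size_um,
                 frame_interval_s = frame_interval_s),
            class = "ImageStack")
}

#' @export
print.ImageStack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<ImageStack> %d frame(s), %d x %d px, %.4g um/px, %.4g s/frame\n",
              d[1], d[2], d[3], x$pixel_size_um, x$frame_interval_s))
  invisible(x)
}

#' Number of frames in a stack
#' @param stack an `ImageStack`.
#' @return integer frame count.
#' @export
n_frames <- function(stack) dim(stack$data)[1]

#' Extract one frame as a matrix
#' @param stack an `ImageStack`.
#' @param i frame index (1-based).
#' @return a `Y x X` numeric matrix.
#' @export
get_frame <- function(stack, i) {
  d <- dim(stack$data)
  if (i < 1L || i > d[1]) abort_input("frame index out of range")
  matrix(stack$data[i, , ], d[2], d[3])
}

#' Write / read an image stack as plain text
#'
#' Stacks are persisted as one whitespace-delimited numeric matrix per frame
#' (`frame_0001.txt`, ...) plus a `meta.json` sidecar holding the calibration
#' and any extra metadata. A plain-text encoding is used deliberately so that
#' serialized fixtures stay human-readable and diff-able.
#'
#' @param stack an `ImageStack`.
#' @param dir output directory (created if missing).
#' @param extra named list merged into the JSON sidecar (e.g. seed, truth).
#' @return `dir`, invisibly.
#' @export
write_image_stack <- function(stack, dir, extra = list()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- c(list(n_frames = n_frames(stack),
                 height = dim(stack$data)[2], width = dim(stack$data)[3],
                 pixel_size_um = stack$pixel_size_um,
                 frame_interval_s = stack$frame_interval_s),
            extra)
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (i in seq_len(n_frames(stack))) {
    write.table(get_frame(stack, i),
                file.path(dir, sprintf("frame_%04d.txt", i)),
                row.names = FALSE, col.names = FALSE)
  }
  invisible(dir)
}

#' @rdname write_image_stack
#' @export
read_image_stack <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  files <- sort(list.files(dir, pattern = "^frame_\\d+\\.txt$", full.names = TRUE))
  if (length(files) == 0L) abort_input(sprintf("no frames found in %s", dir))
  frames <- lapply(files, function(f) as.matrix(read.table(f)))
  arr <- array(0, c(length(frames), nrow(frames[[1]]), ncol(frames[[1]])))
  for (i in seq_along(frames)) arr[i, , ] <- frames[[i]]
  image_stack(arr, meta$pixel_size_um, meta$frame_interval_s)
}
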