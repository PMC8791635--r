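#' Calibrated single-channel movie
#'
#' Container for a 2-D fluorescence time series together with its
#' physical calibration.  The stack is stored as a numeric array of
#' dimension `rows x cols x frames` (photon counts or arbitrary
#' intensity units, non-negative).  All positions elsewhere in the
#' package are expressed in micrometres with a 0-based pixel-center
#' convention: the pixel in column `i` (0-based) spans
#' `[i, i + 1) * pixel_size` along x and its center sits at
#' `(i + 0.5) * pixel_size`; rows map to y the same way.
#'
#' @param stack numeric array `rows x cols x frames` (a matrix is
#'   promoted to a single-frame stack); intensities must be finite and
#'   non-negative.
#' @param pixel_size pixel size in micrometres per pixel.
#' @param frame_interval time between consecutive frames in seconds.
#' @return an object of class `spt_movie`: a list with elements
#'   `stack`, `pixel_size`, `frame_interval`.
#' @examples
#' m <- spt_movie(array(0, c(16, 16, 3)), pixel_size = 0.1,
#'                frame_interval = 0.05)
#' n_frames(m)
#' @export
spt_movie <- function(stack, pixel_size, frame_interval) {
  if (is.matrix(stack)) stack <- array(stack, c(dim(stack), 1L))
  if (!is.array(stack) || length(dim(stack)) != 3L)
    stop("'stack' must be a rows x cols x frames array", call. = FALSE)
  if (dim(stack)[3] < 1L) stop("movie needs at least one frame", call. = FALSE)
  if (anyNA(stack) || any(!is.finite(stack)))
    stop("movie intensities must be finite", call. = FALSE)
  if (any(stack < 0)) stop("movie intensities must be non-negative", call. = FALSE)
  stop_if_not_positive(pixel_size, "pixel_size")
  stop_if_not_positive(frame_interval, "frame_interval")
  structure(list(stack = stack, pixel_size = pixel_size,
                 frame_interval = frame_interval),
            class = "spt_movie")
}

#' @rdname spt_movie
#' @param x an `spt_movie`.
#' @export
n_frames <- function(x) dim(x$stack)[3]

#' @export
print.spt_movie <- function(x, ...) {
  d <- dim(x$stack)
  cat(sprintf("<spt_movie> %d x %d px, %d frames, %.3g um/px, %.3g s/frame\n",
              d[1], d[2], d[3], x$pixel_size, x$frame_interval))
  invisible(x)
}

#' Read and write movies as multi-page TIFF
#'
#' Movies are exchanged as 16-bit multi-page TIFF files.  On write,
#' intensities are rounded to integer counts and clipped to the 16-bit
#' range; the physical calibration is stored in a plain-text sidecar
#' file (`<path>.cal`) and recovered on read (explicit calibration
#' arguments take precedence).
#'
#' @param movie an [spt_movie()].
#' @param path file path.
#' @return `write_movie_tiff()` returns `path` invisibly;
#'   `read_movie_tiff()` returns an [spt_movie()].
#' @export
write_movie_tiff <- function(movie, path) {
  stopifnot(inherits(movie, "spt_movie"))
  nt <- n_frames(movie)
  frames <- lapply(seq_len(nt), function(t) {
    f <- round(movie$stack[, , t])
    f[f < 0] <- 0; f[f > 65535] <- 65535
    f / 65535
  })
  tiff::writeTIFF(frames, path, bits.per.sample = 16L, compression = "none")
  writeLines(c(sprintf("pixel_size_um = %.17g", movie$pixel_size),
               sprintf("frame_interval_s = %.17g", movie$frame_interval)),
             paste0(path, ".cal"))
  invisible(path)
}

#' @rdname write_movie_tiff
#' @param pixel_size,frame_interval calibration overrides; if `NULL`,
#'   read from the sidecar written by [write_movie_tiff()].
#' @export
read_movie_tiff <- function(path, pixel_size = NULL, frame_interval = NULL) {
  frames <- tiff::readTIFF(path, all = TRUE)
  if (is.matrix(frames)) frames <- list(frames)
  cal_path <- paste0(path, ".cal")
  cal <- if (file.exists(cal_path)) {
    lines <- readLines(cal_path)
    kv <- strsplit(lines, "\\s*=\\s*")
    stats::setNames(vapply(kv, function(x) as.numeric(x[2]), numeric(1)),
                    vapply(kv, `[`, character(1), 1))
  } else c()
  pixel_size <- pixel_size %||% unname(cal["pixel_size_um"])
  frame_interval <- frame_interval %||% unname(cal["frame_interval_s"])
  if (is.null(pixel_size) || is.na(pixel_size))
    stop("pixel_size not found; supply it explicitly", call. = FALSE)
  if (is.null(frame_interval) || is.na(frame_interval))
    stop("frame_interval not found; supply it explicitly", call. = FALSE)
  stack <- array(0, c(dim(frames[[1]])[1:2], length(frames)))
  for (t in seq_along(frames)) {
    f <- frames[[t]]
    if (length(dim(f)) == 3L) f <- f[, , 1]  # grayscale written, be lenient
    stack[, , t] <- f * 65535
  }
  spt_movie(stack, pixel_size, frame_interval)
}
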