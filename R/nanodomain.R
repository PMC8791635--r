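#' Intensity profile along a line
#'
#' One line profile sampled at one-pixel spacing, the unit of
#' measurement for the spatial clustering index.
#'
#' @param samples non-negative intensity values.
#' @param line optional numeric length-4 `c(x0, y0, x1, y1)` endpoints
#'   in um.
#' @param length_um optional physical length in um.
#' @return an `intensity_profile` list with elements `samples`, `line`,
#'   `length_um`, `mean_intensity`.
#' @export
intensity_profile <- function(samples, line = NULL, length_um = NA_real_) {
  samples <- as.numeric(samples)
  if (any(!is.finite(samples)) || any(samples < 0))
    stop("profile samples must be finite and non-negative", call. = FALSE)
  structure(list(samples = samples, line = line, length_um = length_um,
                 mean_intensity = mean(samples)),
            class = "intensity_profile")
}

#' Maximum projection of the first frames
#'
#' Per-pixel maximum over the first `n_frames` frames, the temporal
#' averaging used to reveal laterally stable structures before SCI
#' quantification.
#'
#' @param movie an [spt_movie()].
#' @param n_frames number of frames to project (default: all).
#' @return numeric matrix.
#' @export
max_project <- function(movie, n_frames = NULL) {
  stopifnot(inherits(movie, "spt_movie"))
  n_frames <- n_frames %||% n_frames(movie)
  if (n_frames > n_frames(movie))
    stop("'n_frames' exceeds the stack length", call. = FALSE)
  apply(movie$stack[, , seq_len(n_frames), drop = FALSE], c(1, 2), max)
}

#' Rolling-ball background subtraction and smoothing
#'
#' Estimates the background as the grayscale morphological opening of
#' the image with a disc structuring element of the given radius (the
#' classical rolling-ball estimate), subtracts it, clips negative
#' residuals to zero, and finally applies a 3x3 mean smoothing.
#'
#' @param image numeric matrix.
#' @param radius_px disc radius in pixels (default 30).
#' @param smooth apply the 3x3 mean filter (default `TRUE`).
#' @return numeric matrix of the same size.
#' @export
subtract_background <- function(image, radius_px = 30L, smooth = TRUE) {
  if (radius_px < 1L) stop("'radius_px' must be >= 1", call. = FALSE)
  if (2 * radius_px + 1 > min(dim(image)))
    stop("'radius_px' is larger than the image", call. = FALSE)
  kern <- EBImage::makeBrush(2 * radius_px + 1, shape = "disc")
  # EBImage grayscale morphology assumes intensities in [0, 1]; opening
  # commutes with positive scaling, so normalize, open, and scale back
  top <- max(image)
  bg <- if (top > 0) EBImage::opening(image / top, kern) * top else image

  out <- image - bg
  out[out < 0] <- 0
  if (smooth) {
    k3 <- matrix(1 / 9, 3, 3)
    out <- EBImage::filter2(out, k3, boundary = "replicate")
    out[out < 0] <- 0   # guard against FFT round-off
  }
  out
}

#' Background-corrected maximum projection for SCI quantification
#'
#' Applies [subtract_background()] to each of the first `n_frames`
#' frames and takes the per-pixel maximum of the corrected frames.
#' Correcting before projecting keeps the shot-noise residual as a
#' stable, strictly positive floor in the projection, so the bottom
#' tail of a line profile measures the inter-domain level rather than
#' an exact zero.
#'
#' @inheritParams max_project
#' @param radius_px rolling-ball radius, see [subtract_background()].
#' @return numeric matrix.
#' @export
sci_projection <- function(movie, n_frames = NULL, radius_px = 30L) {
  stopifnot(inherits(movie, "spt_movie"))
  n_frames <- n_frames %||% n_frames(movie)
  if (n_frames > n_frames(movie))
    stop("'n_frames' exceeds the stack length", call. = FALSE)
  corrected <- vapply(seq_len(n_frames), function(t)
    subtract_background(movie$stack[, , t], radius_px),
    matrix(0, dim(movie$stack)[1], dim(movie$stack)[2]))
  apply(corrected, c(1, 2), max)
}

#' Randomly placed line profiles
#'
#' Places `n_lines` straight lines of physical length `length_um` at
#' seeded random positions and orientations, rejection-sampled so both
#' endpoints (and therefore the whole line) lie inside the analysis
#' region: the supplied logical `mask`, or the image minus a
#' `margin_px` border when no mask is given.  Intensities are read at
#' one-pixel spacing by bilinear interpolation, giving
#' `round(length_um / pixel_size) + 1` samples per profile.
#'
#' @param image numeric matrix (typically a background-subtracted
#'   maximum projection).
#' @param pixel_size um per pixel.
#' @param n_lines number of lines (default 3, the per-cell convention).
#' @param length_um line length in um (default 8).
#' @param seed integer seed for the placement.
#' @param mask optional logical matrix marking the cell region.
#' @param margin_px border margin used when `mask` is `NULL`.
#' @param max_attempts rejection-sampling budget per line.
#' @return list of [intensity_profile()] objects.
#' @export
sample_lines <- function(image, pixel_size, n_lines = 3L, length_um = 8,
                         seed = 1L, mask = NULL, margin_px = 10L,
                         max_attempts = 2000L) {
  stop_if_not_positive(pixel_size, "pixel_size")
  nr <- nrow(image); nc <- ncol(image)
  len_px <- length_um / pixel_size
  inside <- function(x, y) {
    if (!is.null(mask)) {
      r <- floor(y) + 1L; c0 <- floor(x) + 1L
      r >= 1 && r <= nr && c0 >= 1 && c0 <= nc && isTRUE(mask[r, c0])
    } else {
      x >= margin_px && x <= nc - margin_px &&
        y >= margin_px && y <= nr - margin_px
    }
  }
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(substream_seed(seed, 404L))
  profiles <- vector("list", n_lines)
  for (li in seq_len(n_lines)) {
    placed <- FALSE
    for (att in seq_len(max_attempts)) {
      cx <- stats::runif(1, 0, nc); cy <- stats::runif(1, 0, nr)
      th <- stats::runif(1, 0, pi)
      x0 <- cx - len_px / 2 * cos(th); x1 <- cx + len_px / 2 * cos(th)
      y0 <- cy - len_px / 2 * sin(th); y1 <- cy + len_px / 2 * sin(th)
      mid_ok <- inside(cx, cy)
      if (mid_ok && inside(x0, y0) && inside(x1, y1)) {
        n_samp <- round(len_px) + 1L
        tt <- seq(0, 1, length.out = n_samp)
        vals <- bilinear_sample(image, x0 + tt * (x1 - x0),
                                y0 + tt * (y1 - y0))
        vals[vals < 0] <- 0
        profiles[[li]] <- intensity_profile(
          vals,
          line = c(x0, y0, x1, y1) * pixel_size,
          length_um = length_um)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
      stop("could not place a line inside the analysis region", call. = FALSE)
    }
  }
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  profiles
}

#' Spatial clustering index of a line profile
#'
#' `SCI = mean(top k samples) / mean(bottom k samples)` with
#' `k = max(1, round(fraction * n))` (default fraction 5%).  The index
#' is exactly invariant under multiplicative intensity rescaling, which
#' is what makes it usable across acquisitions of different brightness.
#' If the bottom-tail mean is zero (possible after background
#' subtraction), the measurement is not left infinite: the bottom mean
#' is floored at one intensity quantum (the smallest positive sample,
#' or 1 when all samples in the tail are zero) and the result is
#' flagged `"bottom_floor"` so it can be excluded or inspected.
#'
#' @param profile an [intensity_profile()] (or a bare numeric vector).
#' @param fraction tail fraction (default 0.05).
#' @param cell_id,line_id optional identifiers carried into the result.
#' @return a one-row data frame of class `sci_measurement`: `cell_id`,
#'   `line_id`, `sci`, `fraction`, `mean_intensity`, `flag`.
#' @export
compute_sci <- function(profile, fraction = 0.05, cell_id = NA,
                        line_id = NA) {
  if (is.numeric(profile)) profile <- intensity_profile(profile)
  v <- sort(profile$samples)
  n <- length(v)
  if (n < 2L) stop("profile needs at least 2 samples", call. = FALSE)
  k <- max(1L, round(fraction * n))
  top <- mean(v[(n - k + 1L):n])
  bot <- mean(v[seq_len(k)])
  flag <- ""
  if (bot == 0) {
    quantum <- if (any(v > 0)) min(v[v > 0]) else 1
    bot <- quantum
    flag <- "bottom_floor"
  }
  structure(data.frame(cell_id = cell_id, line_id = line_id,
                       sci = top / bot, fraction = fraction,
                       mean_intensity = profile$mean_intensity,
                       flag = flag, stringsAsFactors = FALSE),
            class = c("sci_measurement", "data.frame"))
}

#' SCI table for one projected image
#'
#' Applies [sample_lines()] and [compute_sci()] to one cell image and
#' returns the per-line measurements.
#'
#' @inheritParams sample_lines
#' @param fraction tail fraction for [compute_sci()].
#' @param cell_id identifier recorded in every row.
#' @return data frame with one row per line.
#' @export
sci_table <- function(image, pixel_size, cell_id = 1L, n_lines = 3L,
                      length_um = 8, fraction = 0.05, seed = 1L,
                      mask = NULL, margin_px = 10L) {
  profs <- sample_lines(image, pixel_size, n_lines = n_lines,
                        length_um = length_um, seed = seed, mask = mask,
                        margin_px = margin_px)
  out <- do.call(rbind, lapply(seq_along(profs), function(i)
    compute_sci(profs[[i]], fraction, cell_id = cell_id, line_id = i)))
  rownames(out) <- NULL
  out
}

#' Correlation between mean intensity and SCI
#'
#' Spearman rank correlation between the mean line intensity and the
#' SCI of the same lines -- the audit showing that SCI differences are
#' not an artefact of brightness differences.  A constant input (all
#' SCI or all intensities identical) has no defined rank correlation
#' and is flagged instead of raising.
#'
#' @param measurements data frame with columns `mean_intensity` and
#'   `sci` (rows flagged `"bottom_floor"` are excluded).
#' @return list: `rho`, `p`, `n`, `flag` (`""` or `"constant_input"`).
#' @export
intensity_sci_correlation <- function(measurements) {
  m <- measurements
  if ("flag" %in% names(m)) m <- m[m$flag == "", , drop = FALSE]
  if (nrow(m) < 5L) stop("need at least 5 measurements", call. = FALSE)
  if (length(unique(m$sci)) < 2L || length(unique(m$mean_intensity)) < 2L)
    return(list(rho = NA_real_, p = NA_real_, n = nrow(m),
                flag = "constant_input"))
  ct <- suppressWarnings(
    stats::cor.test(m$mean_intensity, m$sci, method = "spearman",
                    alternative = "two.sided"))
  list(rho = unname(ct$estimate), p = ct$p.value, n = nrow(m), flag = "")
}

#' Kymograph along a line
#'
#' Space-time image: row `t` holds the intensity profile along the line
#' in frame `t`, sampled at one-pixel spacing by bilinear
#' interpolation.  Static particles on the line appear as vertical
#' stripes; a particle moving along the line at speed `v` draws a
#' stripe of slope `v * frame_interval / pixel_size` pixels per frame.
#'
#' @param movie an [spt_movie()].
#' @param line numeric length-4 `c(x0, y0, x1, y1)` endpoints in um.
#' @return numeric matrix, `n_frames` rows x `n_samples` columns.
#' @export
kymograph <- function(movie, line) {
  stopifnot(inherits(movie, "spt_movie"), length(line) == 4L)
  px <- movie$pixel_size
  p_px <- line / px
  len_px <- sqrt((p_px[3] - p_px[1])^2 + (p_px[4] - p_px[2])^2)
  n_samp <- round(len_px) + 1L
  tt <- seq(0, 1, length.out = n_samp)
  xs <- p_px[1] + tt * (p_px[3] - p_px[1])
  ys <- p_px[2] + tt * (p_px[4] - p_px[2])
  nt <- n_frames(movie)
  out <- matrix(0, nt, n_samp)
  for (t in seq_len(nt)) out[t, ] <- bilinear_sample(movie$stack[, , t], xs, ys)
  out
}

#' Write a kymograph or projection as an image file
#'
#' Writes a matrix as 16-bit grayscale TIFF or 8-bit PNG, scaled to the
#' data range.
#'
#' @param img numeric matrix.
#' @param path output path ending in `.tif`, `.tiff` or `.png`.
#' @export
write_image <- function(img, path) {
  rng <- range(img)
  scaled <- if (diff(rng) > 0) (img - rng[1]) / diff(rng) else img * 0
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::writePNG(scaled, path)
  } else {
    tiff::writeTIFF(scaled, path, bits.per.sample = 16L, compression = "none")
  }
  invisible(path)
}
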