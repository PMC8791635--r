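#' Scale-normalized Laplacian-of-Gaussian blob response
#'
#' Convolves one frame with a negated, scale-normalized
#' Laplacian-of-Gaussian kernel at the blob-optimal scale
#' `sigma = diameter / (2 * sqrt(2))` for a bright disc of the given
#' diameter, so that spots of matched size produce positive local
#' maxima.  The kernel is zero-mean, hence a constant image gives a
#' (numerically) zero response; boundaries are handled by replication.
#'
#' @param frame numeric matrix (one movie frame).
#' @param diameter expected particle diameter in um.
#' @param pixel_size um per pixel.
#' @return matrix of the same dimension as `frame`.
#' @export
log_response <- function(frame, diameter, pixel_size) {
  if (anyNA(frame) || any(!is.finite(frame)))
    stop("frame contains non-finite pixels", call. = FALSE)
  stop_if_not_positive(pixel_size, "pixel_size")
  if (diameter < 2 * pixel_size)
    stop("'diameter' must be at least two pixels", call. = FALSE)
  sigma <- diameter / (2 * sqrt(2)) / pixel_size
  h <- max(3L, ceiling(4 * sigma))
  g <- seq(-h, h)
  r2 <- outer(g^2, g^2, "+")
  # negated scale-normalized LoG: sigma^2 * (2 - r^2/sigma^2)/sigma^2 ... folded
  k <- (2 - r2 / sigma^2) / sigma^2 * exp(-r2 / (2 * sigma^2)) * sigma^2
  k <- k - mean(k)                      # exact zero response on constants
  EBImage::filter2(frame, k, boundary = "replicate")
}

# 3x3 quadratic refinement: least-squares fit of
# f = a + b x + c y + d x^2 + e x y + f y^2 on the 9-point stencil,
# returning the stationary-point offset (dx, dy) in pixels
quadratic_refine <- function(nb) {
  # closed-form LS on the 3x3 grid (x = col offset, y = row offset)
  xs <- rep(c(-1, 0, 1), each = 3)   # column-major: rows vary fastest
  ys <- rep(c(-1, 0, 1), times = 3)
  f <- as.numeric(nb)                 # column-major matches xs/ys above
  b <- sum(xs * f) / 6
  c_ <- sum(ys * f) / 6
  d <- (sum(xs^2 * f) - 2 / 3 * sum(f)) / 2
  e <- sum(xs * ys * f) / 4
  f2 <- (sum(ys^2 * f) - 2 / 3 * sum(f)) / 2
  # stationary point of the fitted quadratic: solve H %*% off = -grad
  H <- matrix(c(2 * d, e, e, 2 * f2), 2)
  det_h <- H[1, 1] * H[2, 2] - H[1, 2] * H[2, 1]
  if (!is.finite(det_h) || abs(det_h) < .Machine$double.eps) return(c(0, 0))
  off <- solve(H, -c(b, c_))
  c(dx = off[1], dy = off[2])
}

#' Detect sub-pixel spots in every frame
#'
#' Finds local maxima of the [log_response()] above `quality_threshold`,
#' applies non-maximum suppression within one spot radius, and refines
#' each surviving maximum to sub-pixel precision by fitting a 2-D
#' quadratic to the 3x3 response neighbourhood and taking its stationary
#' point (refinements displacing by more than one pixel fall back to the
#' integer maximum).  The intensity reported per spot is the raw frame
#' signal summed over a diameter-sized square window.
#'
#' The detection threshold is a required input: suitable values depend
#' on signal-to-noise and must be chosen per data set (see
#' [auto_quality_threshold()] for a labelled heuristic).
#'
#' @param movie an [spt_movie()].
#' @param diameter expected particle diameter in um (default 0.4).
#' @param quality_threshold minimum LoG response at the maximum (>= 0).
#' @param frames optional integer vector of 0-based frame indices to
#'   process (default: all).
#' @return data frame with columns `frame` (0-based), `x_um`, `y_um`,
#'   `quality`, `intensity`.
#' @export
detect_spots <- function(movie, diameter = 0.4, quality_threshold,
                         frames = NULL) {
  stopifnot(inherits(movie, "spt_movie"))
  if (missing(quality_threshold) || !is.numeric(quality_threshold) ||
      quality_threshold < 0)
    stop("'quality_threshold' is required and must be >= 0", call. = FALSE)
  px <- movie$pixel_size
  frames <- frames %||% (seq_len(n_frames(movie)) - 1L)
  rad_px <- max(1L, round(diameter / 2 / px))
  out <- vector("list", length(frames))
  for (fi in seq_along(frames)) {
    t <- frames[fi]
    img <- movie$stack[, , t + 1L]
    resp <- log_response(img, diameter, px)
    pk <- find_peaks(resp, quality_threshold, rad_px)
    if (!nrow(pk)) {
      out[[fi]] <- empty_spots()
      next
    }
    nr <- nrow(resp); nc <- ncol(resp)
    x <- numeric(nrow(pk)); y <- numeric(nrow(pk)); inten <- numeric(nrow(pk))
    for (s in seq_len(nrow(pk))) {
      r <- pk$row[s]; c0 <- pk$col[s]
      off <- c(0, 0)
      if (r > 1 && r < nr && c0 > 1 && c0 < nc) {
        off <- quadratic_refine(resp[(r - 1):(r + 1), (c0 - 1):(c0 + 1)])
        if (any(abs(off) > 1)) off <- c(0, 0)
      }
      # 0-based pixel indices with centers at +0.5
      x[s] <- (c0 - 1 + 0.5 + off[1]) * px
      y[s] <- (r - 1 + 0.5 + off[2]) * px
      rr <- max(1, r - rad_px):min(nr, r + rad_px)
      cc <- max(1, c0 - rad_px):min(nc, c0 + rad_px)
      inten[s] <- sum(img[rr, cc])
    }
    out[[fi]] <- data.frame(frame = t, x_um = x, y_um = y,
                            quality = pk$quality, intensity = inten)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

empty_spots <- function() {
  data.frame(frame = integer(), x_um = numeric(), y_um = numeric(),
             quality = numeric(), intensity = numeric())
}

# local maxima (>= all 8 neighbours, > threshold), optionally followed by
# greedy non-maximum suppression within radius `rad_px` (strongest first,
# deterministic tie order: quality desc, then row, then col)
find_peaks <- function(resp, threshold, rad_px, nms = TRUE) {
  nr <- nrow(resp); nc <- ncol(resp)
  if (nr < 3 || nc < 3)
    return(data.frame(row = integer(), col = integer(), quality = numeric()))
  ctr <- resp[2:(nr - 1), 2:(nc - 1)]
  is_max <- ctr > threshold
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    is_max <- is_max & (ctr >= resp[2:(nr - 1) + dr, 2:(nc - 1) + dc])
  }
  idx <- which(is_max, arr.ind = TRUE)
  if (!nrow(idx))
    return(data.frame(row = integer(), col = integer(), quality = numeric()))
  pk <- data.frame(row = idx[, 1] + 1L, col = idx[, 2] + 1L,
                   quality = ctr[idx])
  pk <- pk[order(-pk$quality, pk$row, pk$col), , drop = FALSE]
  if (!nms) return(pk)
  k <- nrow(pk)
  alive <- rep(TRUE, k)
  keep <- logical(k)
  rows <- pk$row; cols <- pk$col
  for (i in seq_len(k)) {
    if (!alive[i]) next
    keep[i] <- TRUE
    alive <- alive & ((rows - rows[i])^2 + (cols - cols[i])^2 > rad_px^2)
  }
  pk[keep, , drop = FALSE]
}

#' Heuristic automatic detection threshold
#'
#' Otsu split of the LoG local-maxima responses (no suppression, up to
#' `max_frames` frames) into a background and a signal class; the
#' returned value is the split point.  This is a convenience heuristic,
#' not a calibrated threshold: inspect detections before trusting it on
#' real data.
#'
#' @inheritParams detect_spots
#' @param max_frames number of frames sampled (default 10).
#' @return a single threshold value.
#' @export
auto_quality_threshold <- function(movie, diameter = 0.4, max_frames = 10L) {
  stopifnot(inherits(movie, "spt_movie"))
  px <- movie$pixel_size
  rad_px <- max(1L, round(diameter / 2 / px))
  use <- seq_len(min(max_frames, n_frames(movie)))
  vals <- unlist(lapply(use, function(t) {
    resp <- log_response(movie$stack[, , t], diameter, px)
    find_peaks(resp, -Inf, rad_px, nms = FALSE)$quality
  }))
  if (!length(vals)) return(0)
  otsu_threshold(vals)
}

#' Write detected spots to CSV
#' @param spots data frame from [detect_spots()].
#' @param path CSV path.
#' @export
write_spots_csv <- function(spots, path) {
  utils::write.csv(spots, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spots_csv
#' @export
read_spots_csv <- function(path) utils::read.csv(path)
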