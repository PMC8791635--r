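# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop(sprintf("'%s' must be a single positive finite number", name),
         call. = FALSE)
  invisible(x)
}

#' Derive a reproducible sub-stream seed
#'
#' Mixes a base seed with one or more integer keys so that independent
#' random sub-streams (per particle, per cell, per stage) can be drawn
#' from a single run seed without any stream depending on the order in
#' which the others are consumed.  A small multiplicative hash keeps the
#' result inside the 32-bit integer range R accepts for `set.seed()`.
#'
#' @param seed base integer seed.
#' @param ... integer keys identifying the sub-stream.
#' @return a single integer seed.
#' @keywords internal
substream_seed <- function(seed, ...) {
  keys <- c(seed, unlist(list(...)))
  m <- 2147483647
  h <- 0
  # every intermediate stays below 2^53, so the arithmetic is exact
  for (k in keys) {
    h <- (h + as.numeric(k) %% m) %% m
    h <- (h * 69069 + 12345) %% m
    h <- (h * 69069 + 12345) %% m
  }
  as.integer(h)
}

#' Bilinear interpolation at continuous pixel coordinates
#'
#' Pixel-center convention: the intensity of the pixel in (0-based) row
#' `r`, column `c` is located at pixel coordinates `(c + 0.5, r + 0.5)`.
#' Coordinates are clamped to the image so edge queries extrapolate with
#' the border value.
#'
#' @param img numeric matrix (rows = y, cols = x).
#' @param x_px,y_px continuous pixel coordinates (0-based, units of px).
#' @return numeric vector of interpolated intensities.
#' @keywords internal
bilinear_sample <- function(img, x_px, y_px) {
  nr <- nrow(img); nc <- ncol(img)
  # shift to center-based grid and clamp into [0, n-1]
  gx <- pmin(pmax(x_px - 0.5, 0), nc - 1)
  gy <- pmin(pmax(y_px - 0.5, 0), nr - 1)
  x0 <- pmin(floor(gx), nc - 2); x1 <- x0 + 1
  y0 <- pmin(floor(gy), nr - 2); y1 <- y0 + 1
  if (nc == 1) { x0 <- x1 <- 0 }
  if (nr == 1) { y0 <- y1 <- 0 }
  fx <- gx - x0; fy <- gy - y0
  i00 <- img[cbind(y0 + 1, x0 + 1)]
  i01 <- img[cbind(y0 + 1, x1 + 1)]
  i10 <- img[cbind(y1 + 1, x0 + 1)]
  i11 <- img[cbind(y1 + 1, x1 + 1)]
  (1 - fy) * ((1 - fx) * i00 + fx * i01) + fy * ((1 - fx) * i10 + fx * i11)
}

#' One-dimensional Otsu threshold
#'
#' Splits a numeric sample into two classes by maximizing the
#' between-class variance, the classical Otsu criterion applied directly
#' to the (continuous) values rather than to a fixed histogram.
#'
#' @param x numeric vector.
#' @return the threshold value (midpoint between the two classes at the
#'   optimal split).
#' @keywords internal
otsu_threshold <- function(x) {
  x <- sort(x[is.finite(x)])
  n <- length(x)
  if (n < 2L || x[1] == x[n]) return(x[1] %||% NA_real_)
  csum  <- cumsum(x)
  k     <- seq_len(n - 1)
  w0    <- k / n
  w1    <- 1 - w0
  mu0   <- csum[k] / k
  mu1   <- (csum[n] - csum[k]) / (n - k)
  bcv   <- w0 * w1 * (mu0 - mu1)^2
  # ignore splits between tied values (threshold would not separate them)
  valid <- x[k] < x[k + 1]
  bcv[!valid] <- -Inf
  i <- which.max(bcv)
  (x[i] + x[i + 1]) / 2
}
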