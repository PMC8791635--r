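#' Per-track mean square displacement
#'
#' Computes the MSD of a single trajectory as a function of time lag.
#' The default is the time-averaged estimator standard in
#' single-particle tracking, averaging over all overlapping pairs:
#' `msd(k) = mean_i [ (x_{i+k} - x_i)^2 + (y_{i+k} - y_i)^2 ]`.
#' The origin-displacement form `msd(k) = (x_k - x_0)^2 + (y_k - y_0)^2`
#' (one displacement per lag, measured from the first point) is
#' available as `method = "origin"`.
#'
#' @param track data frame with `x_um`, `y_um` ordered by frame, for a
#'   single track with strictly consecutive frames.
#' @param frame_interval seconds per frame.
#' @param max_lag largest lag in frames; must be < number of points.
#'   Default: `n_points - 1`.
#' @param method `"time_averaged"` (default) or `"origin"`.
#' @return data frame of class `msd_curve` with columns `lag` (frames),
#'   `lag_s` (seconds), `msd` (um^2), `n_pairs`.
#' @export
compute_msd <- function(track, frame_interval, max_lag = NULL,
                        method = c("time_averaged", "origin")) {
  method <- match.arg(method)
  stop_if_not_positive(frame_interval, "frame_interval")
  x <- track$x_um; y <- track$y_um
  n <- length(x)
  if (n < 2L) stop("track needs at least 2 points", call. = FALSE)
  max_lag <- max_lag %||% (n - 1L)
  if (max_lag >= n) stop("'max_lag' must be smaller than the number of points",
                         call. = FALSE)
  lags <- seq_len(max_lag)
  if (method == "time_averaged") {
    msd <- vapply(lags, function(k) {
      i <- seq_len(n - k)
      mean((x[i + k] - x[i])^2 + (y[i + k] - y[i])^2)
    }, numeric(1))
    n_pairs <- n - lags
  } else {
    msd <- (x[lags + 1L] - x[1])^2 + (y[lags + 1L] - y[1])^2
    n_pairs <- rep(1L, length(lags))
  }
  structure(data.frame(lag = lags, lag_s = lags * frame_interval,
                       msd = msd, n_pairs = n_pairs),
            class = c("msd_curve", "data.frame"))
}

#' Diffusion coefficient from the first MSD lags
#'
#' Ordinary least squares of MSD against time lag over the first
#' `n_lags` points of the curve, with a free intercept (the intercept
#' absorbs static localization error, which otherwise biases the
#' slope).  The diffusion coefficient is a quarter of the fitted slope
#' (2-D); it can come out negative on noisy short tracks and is then
#' reported as-is with a flag rather than clamped, because silent
#' clamping biases group medians.  An anomalous exponent `alpha` is
#' estimated as the slope of `log(msd)` vs `log(lag)` over the same
#' lags (`NA`, flagged, if any MSD value is non-positive): `alpha ~ 1`
#' for free diffusion, `< 1` for confined motion.
#'
#' @param msd an `msd_curve` from [compute_msd()].
#' @param n_lags number of initial lags to fit (default 4).
#' @return list of class `diffusion_estimate`: `D` (um^2/s),
#'   `intercept` (um^2), `alpha`, `n_lags_used`, `flags` (character).
#' @export
fit_diffusion <- function(msd, n_lags = 4L) {
  if (nrow(msd) < n_lags)
    stop(sprintf("MSD curve has %d points; %d lags requested", nrow(msd),
                 n_lags), call. = FALSE)
  d <- msd[seq_len(n_lags), ]
  if (length(unique(d$lag_s)) < 2L)
    stop("degenerate lags: cannot fit a slope", call. = FALSE)
  fit <- stats::lm.fit(cbind(1, d$lag_s), d$msd)
  slope <- fit$coefficients[2]
  intercept <- fit$coefficients[1]
  flags <- character()
  if (slope < 0) flags <- c(flags, "negative_slope")
  alpha <- NA_real_
  if (all(d$msd > 0)) {
    lf <- stats::lm.fit(cbind(1, log(d$lag_s)), log(d$msd))
    alpha <- unname(lf$coefficients[2])
  } else flags <- c(flags, "alpha_skipped_nonpositive_msd")
  structure(list(D = unname(slope) / 4, intercept = unname(intercept),
                 alpha = alpha, n_lags_used = as.integer(n_lags),
                 flags = flags),
            class = "diffusion_estimate")
}

#' @export
print.diffusion_estimate <- function(x, ...) {
  cat(sprintf("<diffusion_estimate> D = %.4g um^2/s, intercept = %.3g um^2, alpha = %.3g (%d lags)%s\n",
              x$D, x$intercept, x$alpha, x$n_lags_used,
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]")
              else ""))
  invisible(x)
}

#' Per-track diffusion table
#'
#' Convenience wrapper applying [compute_msd()] and [fit_diffusion()]
#' to every track of a linked, filtered track table.
#'
#' @param tracks an `spt_tracks` data frame (filtered so every track has
#'   more than `n_lags` points).
#' @param frame_interval seconds per frame.
#' @param n_lags lags used in the diffusion fit (default 4).
#' @param method MSD estimator, see [compute_msd()].
#' @return data frame with one row per track: `track_id`, `n_points`,
#'   `D_um2_s`, `intercept_um2`, `alpha`, `flags` (`;`-separated).
#' @export
track_diffusion <- function(tracks, frame_interval, n_lags = 4L,
                            method = "time_averaged") {
  ids <- unique(tracks$track_id)
  rows <- lapply(ids, function(id) {
    tr <- tracks[tracks$track_id == id, , drop = FALSE]
    tr <- tr[order(tr$frame), , drop = FALSE]
    m <- compute_msd(tr, frame_interval,
                     max_lag = min(nrow(tr) - 1L, max(n_lags, 10L)),
                     method = method)
    est <- fit_diffusion(m, n_lags)
    data.frame(track_id = id, n_points = nrow(tr), D_um2_s = est$D,
               intercept_um2 = est$intercept, alpha = est$alpha,
               flags = paste(est$flags, collapse = ";"))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write the per-track diffusion table
#' @param diff_table data frame from [track_diffusion()].
#' @param path CSV path.
#' @export
write_diffusion_csv <- function(diff_table, path) {
  utils::write.csv(diff_table, path, row.names = FALSE)
  invisible(path)
}
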