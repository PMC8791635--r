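#' Particle specification for the movie simulator
#'
#' Describes one particle of a synthetic VA-TIRFM movie.  Three motion
#' regimes cover the behaviours contrasted in membrane receptor imaging:
#' free Brownian diffusion (mobile, weakly organized proteins), motion
#' confined to a square domain by reflecting boundaries (particles held
#' in a nanodomain), and strictly static particles (laterally stable
#' foci).
#'
#' @param regime one of `"brownian"`, `"confined"`, `"static"`.
#' @param D_true diffusion coefficient in um^2/s (ignored for
#'   `"static"`); must be >= 0.
#' @param start_position numeric length-2, starting `(x, y)` in um.
#' @param domain_side side of the square confinement domain in um
#'   (required for `"confined"`).
#' @param on_fraction probability that the particle emits in a given
#'   frame (simple blinking model); in `(0, 1]`.
#' @return a `particle_spec` list.
#' @export
particle_spec <- function(regime = c("brownian", "confined", "static"),
                          D_true = 0.05, start_position = c(0, 0),
                          domain_side = NULL, on_fraction = 1) {
  regime <- match.arg(regime)
  if (!is.numeric(D_true) || length(D_true) != 1L || !is.finite(D_true) ||
      D_true < 0)
    stop("'D_true' must be a finite number >= 0", call. = FALSE)
  if (length(start_position) != 2L || any(!is.finite(start_position)))
    stop("'start_position' must be two finite coordinates (um)", call. = FALSE)
  if (regime == "confined") {
    if (is.null(domain_side)) stop("confined regime needs 'domain_side'",
                                   call. = FALSE)
    stop_if_not_positive(domain_side, "domain_side")
  }
  if (!is.numeric(on_fraction) || on_fraction <= 0 || on_fraction > 1)
    stop("'on_fraction' must be in (0, 1]", call. = FALSE)
  structure(list(regime = regime, D_true = D_true,
                 start_position = as.numeric(start_position),
                 domain_side = domain_side, on_fraction = on_fraction),
            class = "particle_spec")
}

#' Simulation configuration
#'
#' Collects the acquisition geometry, optics and particle content of one
#' synthetic movie.  Identical configuration and seed always produce
#' bit-identical tracks and movies.
#'
#' Defaults mirror a typical VA-TIRFM acquisition of plasma-membrane
#' receptors: 20 frames per second (50 ms per frame), 0.1 um pixels
#' (160x objective on a 16-um-pixel EMCCD) and a PSF matching a 0.4 um
#' apparent particle size (sigma = 0.4 / 2.355 um under the FWHM
#' convention).
#'
#' @param field_of_view numeric length-2, width x height in um.
#' @param pixel_size um per pixel.
#' @param frame_interval seconds between frames.
#' @param n_frames number of frames (>= 2).
#' @param particles list of [particle_spec()] objects.
#' @param background_level expected background photons per pixel per
#'   frame.
#' @param psf_sigma Gaussian PSF standard deviation in um.
#' @param photons_per_particle expected photons emitted per particle per
#'   frame.
#' @param rng_seed integer seed controlling all randomness of this
#'   simulation.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(field_of_view = c(12.8, 12.8),
                              pixel_size = 0.1,
                              frame_interval = 0.05,
                              n_frames = 50L,
                              particles = list(),
                              background_level = 10,
                              psf_sigma = 0.4 / 2.355,
                              photons_per_particle = 2000,
                              rng_seed = 1L) {
  if (length(field_of_view) != 2L || any(!is.finite(field_of_view)) ||
      any(field_of_view <= 0))
    stop("'field_of_view' must be two positive extents (um)", call. = FALSE)
  stop_if_not_positive(pixel_size, "pixel_size")
  stop_if_not_positive(frame_interval, "frame_interval")
  if (!is.numeric(n_frames) || n_frames < 2)
    stop("'n_frames' must be >= 2", call. = FALSE)
  stop_if_not_positive(psf_sigma, "psf_sigma")
  if (!is.numeric(background_level) || background_level < 0 ||
      !is.finite(background_level))
    stop("'background_level' must be finite and >= 0", call. = FALSE)
  stop_if_not_positive(photons_per_particle, "photons_per_particle")
  if (!all(vapply(particles, inherits, logical(1), "particle_spec")))
    stop("'particles' must be a list of particle_spec objects", call. = FALSE)
  structure(list(field_of_view = as.numeric(field_of_view),
                 pixel_size = pixel_size, frame_interval = frame_interval,
                 n_frames = as.integer(n_frames), particles = particles,
                 background_level = background_level, psf_sigma = psf_sigma,
                 photons_per_particle = photons_per_particle,
                 rng_seed = as.integer(rng_seed)),
            class = "simulation_config")
}

# fold a coordinate into [lo, hi] by reflection (triangle-wave map);
# exact for arbitrarily large excursions, not just single crossings
reflect_into <- function(x, lo, hi) {
  w <- hi - lo
  y <- (x - lo) %% (2 * w)
  lo + ifelse(y > w, 2 * w - y, y)
}

#' Simulate ground-truth particle trajectories
#'
#' Draws one trajectory per particle in the configuration.  Brownian
#' particles take independent Gaussian per-axis increments of variance
#' `2 * D_true * frame_interval`; confined particles take the same
#' increments but are reflected at the walls of a square domain of side
#' `domain_side` centered on their start position; static particles do
#' not move.  Each particle consumes its own random sub-stream derived
#' from `rng_seed` and the particle index, so trajectories do not depend
#' on how many other particles are simulated.
#'
#' @param config a [simulation_config()].
#' @return a data frame of class `spt_ground_truth` with columns
#'   `particle_id`, `frame` (0-based), `x_um`, `y_um`, `regime`, `on`
#'   (logical, whether the particle emits in that frame), carrying the
#'   configuration in attribute `"config"`.
#' @export
simulate_tracks <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  nt <- config$n_frames
  dt <- config$frame_interval
  out <- vector("list", length(config$particles))
  for (i in seq_along(config$particles)) {
    p <- config$particles[[i]]
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
    set.seed(substream_seed(config$rng_seed, 101L, i))
    sd_step <- sqrt(2 * p$D_true * dt)
    if (p$regime == "static" || sd_step == 0) {
      x <- rep(p$start_position[1], nt)
      y <- rep(p$start_position[2], nt)
    } else {
      x <- p$start_position[1] + cumsum(c(0, stats::rnorm(nt - 1, 0, sd_step)))
      y <- p$start_position[2] + cumsum(c(0, stats::rnorm(nt - 1, 0, sd_step)))
      if (p$regime == "confined") {
        half <- p$domain_side / 2
        x <- reflect_into(x, p$start_position[1] - half, p$start_position[1] + half)
        y <- reflect_into(y, p$start_position[2] - half, p$start_position[2] + half)
      }
    }
    on <- if (p$on_fraction >= 1) rep(TRUE, nt) else
      stats::runif(nt) < p$on_fraction
    if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
    out[[i]] <- data.frame(particle_id = i, frame = seq_len(nt) - 1L,
                           x_um = x, y_um = y, regime = p$regime, on = on)
  }
  truth <- if (length(out)) do.call(rbind, out) else
    data.frame(particle_id = integer(), frame = integer(), x_um = numeric(),
               y_um = numeric(), regime = character(), on = logical())
  attr(truth, "config") <- config
  class(truth) <- c("spt_ground_truth", "data.frame")
  truth
}

#' Render a ground truth into a noisy movie
#'
#' Each emitting particle deposits an integrated 2-D Gaussian PSF of
#' width `psf_sigma` centered at its true position (the expected photon
#' count in a pixel is the exact integral of the Gaussian over that
#' pixel, so total signal is conserved for particles away from the
#' border).  Pixel values are drawn `Poisson(background + signal)`;
#' `noise = "none"` returns the expectation instead, which is useful for
#' localization oracles.
#'
#' @param truth an `spt_ground_truth` from [simulate_tracks()].
#' @param config the matching [simulation_config()]; defaults to the one
#'   stored in `truth`.
#' @param noise `"poisson"` (default) or `"none"`.
#' @return an [spt_movie()].
#' @export
render_movie <- function(truth, config = attr(truth, "config"),
                         noise = c("poisson", "none")) {
  noise <- match.arg(noise)
  stopifnot(inherits(config, "simulation_config"))
  px <- config$pixel_size
  if (config$psf_sigma < 0.25 * px)
    stop("psf_sigma below 0.25 px cannot be rendered faithfully", call. = FALSE)
  nx <- max(1L, round(config$field_of_view[1] / px))
  ny <- max(1L, round(config$field_of_view[2] / px))
  nt <- config$n_frames
  sig_px <- config$psf_sigma / px
  halfw <- ceiling(5 * sig_px)
  stack <- array(config$background_level, c(ny, nx, nt))
  if (nrow(truth)) {
    tr <- truth[truth$on, , drop = FALSE]
    for (r in seq_len(nrow(tr))) {
      cx <- tr$x_um[r] / px            # continuous px; pixel i spans [i, i+1)
      cy <- tr$y_um[r] / px
      jx <- max(0L, floor(cx) - halfw):min(nx - 1L, floor(cx) + halfw)
      jy <- max(0L, floor(cy) - halfw):min(ny - 1L, floor(cy) + halfw)
      if (!length(jx) || !length(jy)) next
      wx <- stats::pnorm(jx + 1, cx, sig_px) - stats::pnorm(jx, cx, sig_px)
      wy <- stats::pnorm(jy + 1, cy, sig_px) - stats::pnorm(jy, cy, sig_px)
      t <- tr$frame[r] + 1L
      stack[jy + 1L, jx + 1L, t] <- stack[jy + 1L, jx + 1L, t] +
        config$photons_per_particle * outer(wy, wx)
    }
  }
  if (noise == "poisson") {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
    set.seed(substream_seed(config$rng_seed, 202L))
    stack[] <- stats::rpois(length(stack), stack)
    if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  }
  spt_movie(stack, px, config$frame_interval)
}

#' Synthetic 1-D intensity profiles
#'
#' Fixture generator for the spatial clustering index: `"uniform"`
#' profiles are a constant mean plus Gaussian noise; `"clustered"`
#' profiles are a baseline with a minority (5% of samples, at least one)
#' of peaks at `contrast` times the baseline, mimicking bright
#' nanodomain foci crossed by a line profile.  Values are clipped at a
#' small positive floor so downstream ratios stay defined.
#'
#' @param kind `"uniform"` or `"clustered"`.
#' @param n_samples number of samples (>= 20).
#' @param contrast peak-to-baseline ratio (>= 1) for `"clustered"`.
#' @param noise_sd Gaussian noise standard deviation (a.u.).
#' @param seed integer seed.
#' @param baseline baseline intensity (a.u.).
#' @return an `intensity_profile` (see [compute_sci()]).
#' @export
make_profile <- function(kind = c("uniform", "clustered"), n_samples = 81L,
                         contrast = 10, noise_sd = 0, seed = 1L,
                         baseline = 100) {
  kind <- match.arg(kind)
  if (n_samples < 20L) stop("'n_samples' must be >= 20", call. = FALSE)
  if (contrast < 1) stop("'contrast' must be >= 1", call. = FALSE)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(substream_seed(seed, 303L))
  v <- rep(baseline, n_samples)
  if (kind == "clustered") {
    n_peak <- max(1L, round(0.05 * n_samples))
    at <- sample.int(n_samples, n_peak)
    v[at] <- baseline * contrast
  }
  v <- v + stats::rnorm(n_samples, 0, noise_sd)
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  v[v < 1e-6] <- 1e-6
  intensity_profile(v)
}

#' Write and read ground-truth track tables
#'
#' Plain CSV with columns `particle_id, frame, x_um, y_um, regime, on`;
#' the configuration is echoed alongside as a key-value text file by
#' [write_config_txt()].
#'
#' @param truth an `spt_ground_truth`.
#' @param path CSV path.
#' @export
write_ground_truth_csv <- function(truth, path) {
  utils::write.csv(as.data.frame(truth)[
    c("particle_id", "frame", "x_um", "y_um", "regime", "on")],
    path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ground_truth_csv
#' @export
read_ground_truth_csv <- function(path) {
  df <- utils::read.csv(path)
  class(df) <- c("spt_ground_truth", "data.frame")
  df
}

#' @rdname write_ground_truth_csv
#' @param config a [simulation_config()].
#' @export
write_config_txt <- function(config, path) {
  flat <- c(field_of_view = paste(config$field_of_view, collapse = " "),
            pixel_size = config$pixel_size,
            frame_interval = config$frame_interval,
            n_frames = config$n_frames,
            n_particles = length(config$particles),
            background_level = config$background_level,
            psf_sigma = config$psf_sigma,
            photons_per_particle = config$photons_per_particle,
            rng_seed = config$rng_seed)
  writeLines(paste(names(flat), flat, sep = " = "), path)
  invisible(path)
}
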