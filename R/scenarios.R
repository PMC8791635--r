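#' Preset simulation scenarios
#'
#' Builds a [simulation_config()] for one synthetic "cell" in one of
#' three regimes contrasted throughout the package:
#'
#' * `"static_clustered"` -- immobile particles grouped into tight
#'   clusters (laterally stable nanodomain foci; high SCI, low D).
#' * `"mobile_dispersed"` -- freely diffusing particles placed
#'   uniformly (mobile, weakly organized protein; low SCI, higher D).
#' * `"confined"` -- diffusing particles confined to 0.4-um square
#'   domains (intermediate regime: mobile at short lags, organized at
#'   long lags).
#'
#' Placement randomness is derived from `seed`, so a scenario + seed
#' pair defines the cell completely.
#'
#' Per-scenario particle defaults reflect the two imaging situations
#' the regimes emulate: nanodomain-forming proteins are dense (about
#' 0.6 foci per um^2, each focus holding several molecules), whereas
#' single-particle tracking of mobile proteins uses sparse expression
#' (about 0.3 particles per um^2) so that trajectories stay
#' unambiguous.
#'
#' @param scenario one of the three regime names.
#' @param seed integer seed for placement, motion and noise.
#' @param n_particles particles per cell; `NULL` (default) picks the
#'   per-scenario default: 400 for `"static_clustered"` (100 foci of
#'   4), 50 for the mobile regimes.
#' @param fov field of view side in um (default 12.8, i.e. 128 px at
#'   0.1 um/px).
#' @param pixel_size um per pixel (default 0.1).
#' @param frame_interval seconds per frame (default 0.05, 20 fps).
#' @param n_frames frames per movie (default 50).
#' @param D diffusion coefficient for mobile regimes in um^2/s
#'   (default 0.05).
#' @param domain_side confinement side in um for `"confined"`
#'   (default 0.4).
#' @param cluster_sd within-cluster spread (um) for
#'   `"static_clustered"` (default 0.05, well below the PSF so a focus
#'   renders as one bright spot).
#' @param particles_per_cluster cluster occupancy for
#'   `"static_clustered"` (default 4).
#' @param photons_per_particle,background_level,psf_sigma optics, see
#'   [simulation_config()].
#' @return a [simulation_config()].
#' @export
scenario_config <- function(scenario = c("static_clustered",
                                         "mobile_dispersed", "confined"),
                            seed = 1L, n_particles = NULL, fov = 12.8,
                            pixel_size = 0.1, frame_interval = 0.05,
                            n_frames = 50L, D = 0.05, domain_side = 0.4,
                            cluster_sd = 0.05, particles_per_cluster = 4,
                            photons_per_particle = 2000,
                            background_level = 10,
                            psf_sigma = 0.4 / 2.355) {
  scenario <- match.arg(scenario)
  n_particles <- n_particles %||%
    if (scenario == "static_clustered") 400L else 50L
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(substream_seed(seed, 505L))
  margin <- 1.2   # um; keeps PSF tails and short excursions inside the FOV
  pos <- if (scenario == "static_clustered") {
    n_cl <- max(1L, round(n_particles / particles_per_cluster))
    centers <- cbind(stats::runif(n_cl, margin, fov - margin),
                     stats::runif(n_cl, margin, fov - margin))
    idx <- sample.int(n_cl, n_particles, replace = TRUE)
    p <- centers[idx, , drop = FALSE] +
      matrix(stats::rnorm(2 * n_particles, 0, cluster_sd), ncol = 2)
    p[, 1] <- pmin(pmax(p[, 1], margin), fov - margin)
    p[, 2] <- pmin(pmax(p[, 2], margin), fov - margin)
    p
  } else {
    cbind(stats::runif(n_particles, margin, fov - margin),
          stats::runif(n_particles, margin, fov - margin))
  }
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  particles <- lapply(seq_len(n_particles), function(i) {
    switch(scenario,
      static_clustered = particle_spec("static", D_true = 0,
                                       start_position = pos[i, ]),
      mobile_dispersed = particle_spec("brownian", D_true = D,
                                       start_position = pos[i, ]),
      confined = particle_spec("confined", D_true = D,
                               start_position = pos[i, ],
                               domain_side = domain_side))
  })
  simulation_config(field_of_view = c(fov, fov), pixel_size = pixel_size,
                    frame_interval = frame_interval, n_frames = n_frames,
                    particles = particles,
                    background_level = background_level,
                    psf_sigma = psf_sigma,
                    photons_per_particle = photons_per_particle,
                    rng_seed = substream_seed(seed, 606L))
}

#' Simulate one synthetic cell
#'
#' Convenience wrapper: builds the scenario configuration, simulates
#' the ground truth and renders the movie.
#'
#' @inheritParams scenario_config
#' @param ... passed to [scenario_config()].
#' @return list with elements `config`, `truth`, `movie`.
#' @export
simulate_cell <- function(scenario, seed = 1L, ...) {
  cfg <- scenario_config(scenario, seed = seed, ...)
  truth <- simulate_tracks(cfg)
  movie <- render_movie(truth, cfg)
  list(config = cfg, truth = truth, movie = movie)
}
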