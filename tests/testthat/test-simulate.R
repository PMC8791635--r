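test_that("zero diffusion leaves every regime at its start position", {
  for (spec in list(particle_spec("brownian", 0, c(2, 3)),
                    particle_spec("confined", 0, c(2, 3), domain_side = 0.4),
                    particle_spec("static", 0, c(2, 3)))) {
    cfg <- simulation_config(particles = list(spec), n_frames = 20,
                             rng_seed = 5)
    tr <- simulate_tracks(cfg)
    expect_true(all(tr$x_um == 2) && all(tr$y_um == 3))
  }
})

test_that("brownian single-step displacement matches 4*D*dt", {
  cfg <- simulation_config(n_frames = 10001,
                           particles = list(particle_spec("brownian", 0.05,
                                                          c(0, 0))),
                           rng_seed = 7)
  tr <- simulate_tracks(cfg)
  step2 <- diff(tr$x_um)^2 + diff(tr$y_um)^2
  expected <- 4 * 0.05 * 0.05
  se <- stats::sd(step2) / sqrt(length(step2))
  expect_lt(abs(mean(step2) - expected), 3 * se)
})

test_that("confined tracks stay inside the domain and plateau near L^2/3", {
  L <- 0.4
  cfg <- simulation_config(n_frames = 20000,
                           particles = list(particle_spec("confined", 0.05,
                                                          c(5, 5),
                                                          domain_side = L)),
                           rng_seed = 8)
  tr <- simulate_tracks(cfg)
  expect_true(all(tr$x_um >= 5 - L / 2 - 1e-12 & tr$x_um <= 5 + L / 2 + 1e-12))
  expect_true(all(tr$y_um >= 5 - L / 2 - 1e-12 & tr$y_um <= 5 + L / 2 + 1e-12))
  k <- 500
  i <- seq_len(nrow(tr) - k)
  msd_long <- mean((tr$x_um[i + k] - tr$x_um[i])^2 +
                     (tr$y_um[i + k] - tr$y_um[i])^2)
  expect_lt(abs(msd_long - L^2 / 3) / (L^2 / 3), 0.1)
  expect_lt(max((tr$x_um - 5)^2 + (tr$y_um - 5)^2) * 2, 2 * L^2)  # bounded
})

test_that("simulation and rendering are deterministic given the seed", {
  cfg <- simulation_config(n_frames = 10,
                           particles = list(particle_spec("brownian", 0.05,
                                                          c(3, 3))),
                           rng_seed = 42)
  t1 <- simulate_tracks(cfg); t2 <- simulate_tracks(cfg)
  expect_identical(t1$x_um, t2$x_um)
  m1 <- render_movie(t1, cfg); m2 <- render_movie(t2, cfg)
  expect_identical(m1$stack, m2$stack)
})

test_that("trajectories are invariant to the other particles simulated", {
  p1 <- particle_spec("brownian", 0.05, c(2, 2))
  p2 <- particle_spec("brownian", 0.05, c(8, 8))
  cfg_solo <- simulation_config(particles = list(p1), rng_seed = 3)
  cfg_both <- simulation_config(particles = list(p1, p2), rng_seed = 3)
  solo <- simulate_tracks(cfg_solo)
  both <- simulate_tracks(cfg_both)
  expect_identical(solo$x_um, both$x_um[both$particle_id == 1])
})

test_that("rendering a particle-free config gives pure background", {
  cfg <- simulation_config(particles = list(), n_frames = 4,
                           background_level = 25, rng_seed = 2)
  mv <- render_movie(simulate_tracks(cfg), cfg)
  expect_lt(abs(mean(mv$stack) - 25), 3 * sqrt(25 / length(mv$stack)))
})

test_that("rendering conserves photons and centers the PSF correctly", {
  fx <- one_emitter_movie(pos = c(1.234, 1.767), photons = 1e6, bg = 0,
                          noise = "none")
  f <- fx$movie$stack[, , 1]
  expect_lt(abs(sum(f) - 1e6) / 1e6, 1e-3)
  px <- fx$movie$pixel_size
  xs <- (seq_len(ncol(f)) - 0.5) * px
  ys <- (seq_len(nrow(f)) - 0.5) * px
  cx <- sum(t(f) * xs) / sum(f)
  cy <- sum(f * ys) / sum(f)
  expect_lt(abs(cx - 1.234) / px, 0.02)
  expect_lt(abs(cy - 1.767) / px, 0.02)
})

test_that("expected photon count scales with the number of emitters", {
  cfg <- simulation_config(field_of_view = c(6.4, 6.4), n_frames = 2,
                           particles = list(
                             particle_spec("static", 0, c(2, 2)),
                             particle_spec("static", 0, c(4, 4))),
                           background_level = 5, photons_per_particle = 1000,
                           rng_seed = 9)
  mv <- render_movie(simulate_tracks(cfg), cfg, noise = "none")
  f <- mv$stack[, , 1]
  expect_lt(abs(sum(f) - prod(dim(f)) * 5 - 2000) / 2000, 0.01)
})

test_that("unresolvable PSF and invalid physics are rejected", {
  expect_error(simulation_config(pixel_size = -1), "pixel_size")
  expect_error(simulation_config(n_frames = 1), "n_frames")
  expect_error(particle_spec("brownian", D_true = -0.1), "D_true")
  expect_error(particle_spec("confined", 0.05, c(0, 0)), "domain_side")
  cfg <- simulation_config(psf_sigma = 0.01,
                           particles = list(particle_spec("static", 0,
                                                          c(1, 1))))
  expect_error(render_movie(simulate_tracks(cfg), cfg), "psf_sigma")
})

test_that("profile generator honours its contract", {
  u <- make_profile("uniform", 40, noise_sd = 0, seed = 1)
  expect_true(all(u$samples == u$samples[1]))
  cl <- make_profile("clustered", 80, contrast = 20, noise_sd = 0, seed = 1)
  expect_setequal(unique(cl$samples), c(100, 2000))
  expect_identical(make_profile("clustered", 80, 20, 1, seed = 9)$samples,
                   make_profile("clustered", 80, 20, 1, seed = 9)$samples)
  expect_error(make_profile("clustered", 80, contrast = 0.5), "contrast")
  expect_error(make_profile("uniform", 10), "n_samples")
})

test_that("blinking suppresses emission at the configured rate", {
  cfg <- simulation_config(n_frames = 2000,
                           particles = list(particle_spec("static", 0,
                                                          c(5, 5),
                                                          on_fraction = 0.3)),
                           rng_seed = 11)
  tr <- simulate_tracks(cfg)
  expect_lt(abs(mean(tr$on) - 0.3), 3 * sqrt(0.3 * 0.7 / 2000))
})

test_that("ground truth and movies survive a disk round trip", {
  fx <- one_emitter_movie(n_frames = 3, seed = 21)
  tmp_csv <- tempfile(fileext = ".csv")
  write_ground_truth_csv(fx$truth, tmp_csv)
  back <- read_ground_truth_csv(tmp_csv)
  expect_equal(back$x_um, fx$truth$x_um, tolerance = 1e-12)
  tmp_tif <- tempfile(fileext = ".tif")
  write_movie_tiff(fx$movie, tmp_tif)
  mv2 <- read_movie_tiff(tmp_tif)
  expect_equal(mv2$stack, round(fx$movie$stack), tolerance = 1e-9)
  expect_equal(mv2$pixel_size, fx$movie$pixel_size)
  expect_equal(mv2$frame_interval, fx$movie$frame_interval)
  unlink(c(tmp_csv, tmp_tif))
})
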