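test_that("a static track has zero MSD and zero diffusion", {
  tr <- data.frame(frame = 0:19, x_um = 2, y_um = 3)
  m <- compute_msd(tr, frame_interval = 0.05)
  expect_true(all(m$msd == 0))
  est <- fit_diffusion(m)
  expect_equal(est$D, 0)
  expect_equal(est$intercept, 0)
})

test_that("ballistic MSD follows (v k dt)^2 and D-hat = 1.25 v^2 dt", {
  v <- 0.4; dt <- 0.05
  tr <- data.frame(frame = 0:49, x_um = v * (0:49) * dt, y_um = 0)
  m <- compute_msd(tr, dt, max_lag = 10)
  expect_equal(m$msd, (v * m$lag * dt)^2, tolerance = 1e-12)
  est <- fit_diffusion(m, 4)
  expect_equal(est$D, 1.25 * v^2 * dt, tolerance = 1e-10)   # 0.010 um^2/s
  expect_equal(est$alpha, 2, tolerance = 0.1)               # ballistic
})

test_that("an exactly linear MSD recovers D, zero intercept, alpha 1", {
  D <- 0.05; dt <- 0.05
  m <- structure(data.frame(lag = 1:6, lag_s = (1:6) * dt,
                            msd = 4 * D * (1:6) * dt, n_pairs = 50),
                 class = c("msd_curve", "data.frame"))
  est <- fit_diffusion(m, 4)
  expect_equal(est$D, D, tolerance = 1e-12)
  expect_equal(est$intercept, 0, tolerance = 1e-12)
  expect_equal(est$alpha, 1, tolerance = 1e-10)
})

test_that("time-averaged MSD equals the naive double loop", {
  set.seed(12)
  for (trial in 1:10) {
    n <- sample(12:40, 1)
    tr <- data.frame(frame = seq_len(n) - 1,
                     x_um = cumsum(stats::rnorm(n, 0, 0.1)),
                     y_um = cumsum(stats::rnorm(n, 0, 0.1)))
    m <- compute_msd(tr, 0.05, max_lag = n - 1)
    expect_equal(m$msd, naive_msd(tr$x_um, tr$y_um, n - 1),
                 tolerance = 1e-13)
    expect_equal(m$n_pairs, n - seq_len(n - 1))
  }
})

test_that("origin-displacement MSD matches the direct formula", {
  tr <- data.frame(frame = 0:9, x_um = (0:9) * 0.1, y_um = (0:9) * 0.2)
  m <- compute_msd(tr, 0.05, method = "origin")
  expect_equal(m$msd, (tr$x_um[-1] - tr$x_um[1])^2 +
                 (tr$y_um[-1] - tr$y_um[1])^2, tolerance = 1e-13)
  expect_true(all(m$n_pairs == 1))
})

test_that("brownian ensembles recover D_true from ground truth", {
  D <- numeric(120)
  for (i in seq_along(D)) {
    cfg <- simulation_config(field_of_view = c(4, 4), n_frames = 50,
                             particles = list(particle_spec("brownian", 0.05,
                                                            c(2, 2))),
                             rng_seed = 3000 + i)
    tr <- simulate_tracks(cfg)
    est <- fit_diffusion(compute_msd(tr, 0.05, max_lag = 10), 4)
    D[i] <- est$D
  }
  expect_lt(abs(stats::median(D) - 0.05) / 0.05, 0.1)
})

test_that("increasing the true mobility increases the recovered median D", {
  med <- vapply(c(0.02, 0.05, 0.1), function(Dt) {
    Ds <- vapply(1:60, function(i) {
      cfg <- simulation_config(field_of_view = c(6, 6), n_frames = 50,
                               particles = list(particle_spec("brownian", Dt,
                                                              c(3, 3))),
                               rng_seed = 4000 + i)
      fit_diffusion(compute_msd(simulate_tracks(cfg), 0.05, max_lag = 10),
                    4)$D
    }, numeric(1))
    stats::median(Ds)
  }, numeric(1))
  expect_true(all(diff(med) > 0))
})

test_that("confined motion is flagged by depressed alpha", {
  al_conf <- vapply(1:60, function(i) {
    cfg <- simulation_config(field_of_view = c(4, 4), n_frames = 50,
                             particles = list(particle_spec("confined", 0.05,
                                                            c(2, 2),
                                                            domain_side = 0.4)),
                             rng_seed = 5000 + i)
    fit_diffusion(compute_msd(simulate_tracks(cfg), 0.05, max_lag = 10), 4)$alpha
  }, numeric(1))
  al_free <- vapply(1:60, function(i) {
    cfg <- simulation_config(field_of_view = c(4, 4), n_frames = 50,
                             particles = list(particle_spec("brownian", 0.05,
                                                            c(2, 2))),
                             rng_seed = 6000 + i)
    fit_diffusion(compute_msd(simulate_tracks(cfg), 0.05, max_lag = 10), 4)$alpha
  }, numeric(1))
  expect_lt(stats::median(al_conf), 0.8)
  expect_gt(stats::median(al_free), 0.9)
  expect_lt(stats::median(al_free), 1.1)
})

test_that("degenerate inputs are rejected and negative slopes flagged", {
  tr <- data.frame(frame = 0:4, x_um = 1:5, y_um = 0)
  expect_error(compute_msd(tr, 0.05, max_lag = 5), "max_lag")
  expect_error(compute_msd(tr[1, , drop = FALSE], 0.05), "2 points")
  m <- structure(data.frame(lag = 1:4, lag_s = (1:4) * 0.05,
                            msd = c(4, 3, 2, 1), n_pairs = 10),
                 class = c("msd_curve", "data.frame"))
  est <- fit_diffusion(m, 4)
  expect_lt(est$D, 0)
  expect_true("negative_slope" %in% est$flags)
})

test_that("track_diffusion produces one row per track", {
  spots <- do.call(rbind, lapply(0:14, function(f)
    data.frame(frame = f, x_um = c(1, 5) + f * 0.01, y_um = c(1, 5))))
  tr <- filter_tracks(link_spots(spots, 0.4), 10, 0.05)
  dt <- track_diffusion(tr, 0.05)
  expect_equal(nrow(dt), 2)
  expect_true(all(dt$n_points == 15))
})
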