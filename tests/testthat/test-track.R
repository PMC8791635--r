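test_that("the assignment solver matches exhaustive enumeration", {
  set.seed(101)
  for (trial in 1:30) {
    n <- sample(2:5, 1)
    cost <- matrix(stats::runif(n * n), n)
    cost[stats::runif(n * n) < 0.25] <- Inf
    diag(cost) <- stats::runif(n)          # keep a feasible assignment
    sol <- solve_lap(cost)
    expect_equal(sum(cost[cbind(seq_len(n), sol)]),
                 brute_force_assignment_cost(cost), tolerance = 1e-10)
  }
})

test_that("gated linking cost is optimal on enumerable frame pairs", {
  set.seed(202)
  for (trial in 1:20) {
    n <- sample(1:5, 1); m <- sample(1:5, 1)
    xy1 <- cbind(stats::runif(n, 0, 2), stats::runif(n, 0, 2))
    xy2 <- cbind(stats::runif(m, 0, 2), stats::runif(m, 0, 2))
    gate <- 0.6
    d2 <- outer(xy1[, 1], xy2[, 1], "-")^2 + outer(xy1[, 2], xy2[, 2], "-")^2
    links <- sptnano:::link_frame_pair(xy1, xy2, gate)
    got <- pairing_cost(links, d2, gate^2, n, m)
    expect_equal(got, brute_force_link_cost(xy1, xy2, gate),
                 tolerance = 1e-10)
  }
})

test_that("optimal assignment beats greedy nearest-neighbour pairing", {
  # frame 1: A=(0,0), B=(0.30,0); frame 2: C=(0.28,0), D=(0.58,0).
  # Greedy would give A->C (0.28) and strand B/D; optimal is A->C? No:
  # costs: A-C=0.28^2, A-D gated out, B-C=0.02^2, B-D=0.28^2 -> optimal
  # pairs B->C and A unlinked is worse than A->C,B->D; enumeration decides.
  spots <- data.frame(frame = c(0L, 0L, 1L, 1L),
                      x_um = c(0, 0.30, 0.28, 0.58),
                      y_um = 0)
  tracks <- link_spots(spots, max_link_distance = 0.4)
  # optimal total cost pairs A->C, B->D (0.28^2 + 0.28^2 = 0.1568) versus
  # B->C + two no-links (0.0004 + 2*0.16); verify against enumeration
  xy1 <- cbind(c(0, 0.30), c(0, 0))
  xy2 <- cbind(c(0.28, 0.58), c(0, 0))
  best <- brute_force_link_cost(xy1, xy2, 0.4)
  expect_equal(best, 2 * 0.28^2, tolerance = 1e-10)
  expect_equal(length(unique(tracks$track_id)), 2)
  for (id in unique(tracks$track_id))
    expect_equal(nrow(tracks[tracks$track_id == id, ]), 2)
})

test_that("a static particle yields one track; a gated jump yields two", {
  spots <- data.frame(frame = 0:9, x_um = 1, y_um = 1)
  tr <- link_spots(spots, 0.4)
  expect_equal(length(unique(tr$track_id)), 1)
  expect_equal(nrow(tr), 10)

  jump <- data.frame(frame = c(0L, 1L), x_um = c(0, 0.5), y_um = 0)
  tr2 <- link_spots(jump, 0.4)
  expect_equal(length(unique(tr2$track_id)), 2)
})

test_that("every spot lands in exactly one track", {
  set.seed(77)
  spots <- do.call(rbind, lapply(0:5, function(f)
    data.frame(frame = f, x_um = stats::runif(8, 0, 5),
               y_um = stats::runif(8, 0, 5))))
  tr <- link_spots(spots, 0.4)
  expect_equal(nrow(tr), nrow(spots))
  key <- paste(tr$frame, tr$x_um, tr$y_um)
  expect_false(any(duplicated(key)))
  # within a track, frames strictly consecutive
  for (id in unique(tr$track_id)) {
    f <- sort(tr$frame[tr$track_id == id])
    if (length(f) > 1) expect_true(all(diff(f) == 1))
  }
})

test_that("linking result does not depend on the input row order", {
  set.seed(88)
  spots <- do.call(rbind, lapply(0:4, function(f)
    data.frame(frame = f, x_um = stats::runif(6, 0, 3),
               y_um = stats::runif(6, 0, 3))))
  t1 <- link_spots(spots, 0.4)
  t2 <- link_spots(spots[sample(nrow(spots)), ], 0.4)
  expect_identical(t1, t2)
})

test_that("well-separated particles are tracked without identity errors", {
  parts <- list()
  for (i in 1:3) for (j in 1:3)
    parts[[length(parts) + 1L]] <- particle_spec("brownian", 0.01,
                                                 c(i * 2, j * 2))
  cfg <- simulation_config(field_of_view = c(8, 8), n_frames = 20,
                           particles = parts, rng_seed = 55)
  truth <- simulate_tracks(cfg)
  spots <- data.frame(frame = truth$frame, x_um = truth$x_um,
                      y_um = truth$y_um)
  tr <- link_spots(spots, 0.4)
  expect_equal(length(unique(tr$track_id)), 9)
  # every reconstructed track must coincide with one true particle
  for (id in unique(tr$track_id)) {
    sub <- tr[tr$track_id == id, ]
    sub <- sub[order(sub$frame), ]
    pid <- truth$particle_id[truth$frame == 0 &
                               truth$x_um == sub$x_um[1] &
                               truth$y_um == sub$y_um[1]][1]
    want <- truth[truth$particle_id == pid, ]
    expect_equal(sub$x_um, want$x_um)
    expect_equal(sub$y_um, want$y_um)
  }
})

test_that("track filter keeps >= min_points and sets the duration", {
  mk <- function(id, n) data.frame(track_id = id, frame = seq_len(n) - 1L,
                                   x_um = 0, y_um = 0)
  tracks <- rbind(mk(1, 9), mk(2, 10), mk(3, 11))
  class(tracks) <- c("spt_tracks", "data.frame")
  out <- filter_tracks(tracks, min_points = 10, frame_interval = 0.05)
  expect_setequal(unique(out$n_points), c(10, 11))
  expect_equal(unique(out$duration_s[out$n_points == 10]), 0.5)
  # min_points = 2 is the identity on multi-point tracks
  all2 <- filter_tracks(tracks, 2, 0.05)
  expect_equal(nrow(all2), nrow(tracks))
  expect_error(filter_tracks(tracks, 1, 0.05), "min_points")
})

test_that("track tables round-trip through CSV", {
  spots <- data.frame(frame = 0:3, x_um = c(1, 1.1, 1.2, 1.3), y_um = 2)
  tr <- link_spots(spots, 0.4)
  p <- tempfile(fileext = ".csv")
  write_tracks_csv(tr, p)
  back <- read_tracks_csv(p)
  expect_equal(back$x_um, tr$x_um, tolerance = 1e-12)
  expect_equal(back$track_id, tr$track_id)
  unlink(p)
})
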