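# Independent oracles used to cross-check the implementation.  These are
# deliberately naive (enumeration, double loops) and must stay separate
# from the code paths they verify.

# minimum assignment cost by exhaustive enumeration of all permutations
brute_force_assignment_cost <- function(cost) {
  n <- nrow(cost)
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    out
  }
  best <- Inf
  for (p in perms(seq_len(n))) {
    s <- sum(cost[cbind(seq_len(n), p)])
    if (s < best) best <- s
  }
  best
}

# total linking cost of a track solution on one frame pair
pairing_cost <- function(links, d2, gate2, n, m) {
  linked_from <- links[, "from"]; linked_to <- links[, "to"]
  sum(d2[cbind(linked_from, linked_to)]) +
    gate2 * (n - length(linked_from)) + gate2 * (m - length(linked_to))
}

# minimum gated-linking cost by enumerating every feasible partial
# matching between two small frames
brute_force_link_cost <- function(xy1, xy2, gate) {
  n <- nrow(xy1); m <- nrow(xy2)
  d2 <- outer(xy1[, 1], xy2[, 1], "-")^2 + outer(xy1[, 2], xy2[, 2], "-")^2
  gate2 <- gate^2
  best <- Inf
  # enumerate assignments of each source spot to a target or to "none"
  choices <- rep(list(0:m), n)
  grid <- do.call(expand.grid, choices)
  for (r in seq_len(nrow(grid))) {
    a <- as.integer(grid[r, ])
    tgt <- a[a > 0]
    if (anyDuplicated(tgt)) next
    if (any(a > 0 & d2[cbind(seq_len(n), pmax(a, 1))] > gate2)) next
    cost <- sum(d2[cbind(which(a > 0), a[a > 0])]) +
      gate2 * sum(a == 0) + gate2 * (m - length(tgt))
    if (cost < best) best <- cost
  }
  best
}

# naive double-loop time-averaged MSD
naive_msd <- function(x, y, max_lag) {
  vapply(seq_len(max_lag), function(k) {
    acc <- 0; cnt <- 0
    for (i in seq_len(length(x) - k)) {
      acc <- acc + (x[i + k] - x[i])^2 + (y[i + k] - y[i])^2
      cnt <- cnt + 1
    }
    acc / cnt
  }, numeric(1))
}

# exact two-sided Mann-Whitney p by enumeration of all group labelings
permutation_mw_p <- function(a, b) {
  pool <- c(a, b)
  n <- length(a)
  obs_u <- sum(rank(pool)[seq_len(n)]) - n * (n + 1) / 2
  m_u <- length(a) * length(b)
  # two-sided: distance of U from its mean
  obs_dev <- abs(obs_u - m_u / 2)
  combs <- utils::combn(length(pool), n)
  devs <- apply(combs, 2, function(idx) {
    u <- sum(rank(pool)[idx]) - n * (n + 1) / 2
    abs(u - m_u / 2)
  })
  mean(devs >= obs_dev - 1e-12)
}

# Kruskal-Wallis H from the textbook rank formula (tie-corrected)
hand_kruskal_h <- function(values, groups) {
  groups <- factor(groups)
  r <- rank(values)
  N <- length(values)
  h <- 12 / (N * (N + 1)) *
    sum(tapply(r, groups, function(ri) length(ri) * mean(ri)^2)) -
    3 * (N + 1)
  ties <- table(values)
  corr <- 1 - sum(ties^3 - ties) / (N^3 - N)
  h / corr
}

# deterministic small movie with one bright static emitter
one_emitter_movie <- function(pos = c(1.6, 1.6), photons = 2000, bg = 10,
                              n_frames = 2, seed = 1, noise = "poisson",
                              fov = 3.2) {
  cfg <- simulation_config(field_of_view = c(fov, fov), n_frames = n_frames,
                           particles = list(particle_spec("static", 0,
                                                          start_position = pos)),
                           background_level = bg,
                           photons_per_particle = photons, rng_seed = seed)
  truth <- simulate_tracks(cfg)
  list(config = cfg, truth = truth,
       movie = render_movie(truth, cfg, noise = noise))
}
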