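#' Exact linear assignment (square cost matrix)
#'
#' Jonker-Volgenant style shortest-augmenting-path solver for the square
#' linear assignment problem, O(n^3).  Forbidden assignments are given
#' as `Inf` and are internally replaced by a large finite cost; the
#' caller must guarantee that a fully finite assignment exists (the
#' augmented linking matrix below always has one).  The algorithm is
#' fully deterministic: rows are processed and columns scanned in index
#' order, so ties between equal-cost optima are resolved reproducibly.
#'
#' @param cost square numeric matrix.
#' @return integer vector `a` with `a[i]` the column assigned to row `i`.
#' @keywords internal
#' @export
solve_lap <- function(cost) {
  if (!is.matrix(cost) || nrow(cost) != ncol(cost))
    stop("'cost' must be a square matrix", call. = FALSE)
  n <- nrow(cost)
  if (n == 0L) return(integer())
  finite <- cost[is.finite(cost)]
  big <- if (length(finite)) (sum(abs(finite)) + 1) * 2 else 1
  a <- cost
  a[!is.finite(a)] <- big * n
  u <- numeric(n); v <- numeric(n + 1)       # v[1] is the virtual column 0
  p <- integer(n + 1)                        # p[j+1]: row matched to column j
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0L
    minv <- rep(Inf, n)
    used <- logical(n + 1)
    way <- integer(n)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      delta <- Inf; j1 <- 0L
      for (j in seq_len(n)) {
        if (!used[j + 1L]) {
          cur <- a[i0, j] - u[i0] - v[j + 1L]
          if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
          if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
        }
      }
      for (j in 0:n) {
        if (used[j + 1L]) {
          if (j == 0L || p[j + 1L] > 0L) u[p[j + 1L]] <- u[p[j + 1L]] + delta
          v[j + 1L] <- v[j + 1L] - delta
        } else minv[j] <- minv[j] - delta
      }
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  assign_col <- integer(n)
  for (j in seq_len(n)) if (p[j + 1L] > 0L) assign_col[p[j + 1L]] <- j
  assign_col
}

# gated assignment for one connected component of the gate graph,
# following the standard augmented-LAP construction: real links cost d^2
# (forbidden beyond the gate), and each spot owns a "no-link" alternative
# at cost gate^2, so a link is made exactly when it is cheaper than
# letting both spots go unlinked.
link_component <- function(d2, gate2) {
  n <- nrow(d2); m <- ncol(d2)
  size <- n + m
  cost <- matrix(Inf, size, size)
  cost[seq_len(n), seq_len(m)] <- d2
  cost[cbind(seq_len(n), m + seq_len(n))] <- gate2        # source no-link
  cost[cbind(n + seq_len(m), seq_len(m))] <- gate2        # target no-link
  cost[n + seq_len(m), m + seq_len(n)] <- 0               # slack block
  sol <- solve_lap(cost)
  from <- which(sol[seq_len(n)] <= m)
  to <- sol[from]
  ok <- is.finite(d2[cbind(from, to)])
  cbind(from = from[ok], to = to[ok])
}

# frame-to-frame gated assignment; because assignments across distinct
# connected components of the within-gate candidate graph cannot
# interact, the problem decomposes exactly and each component is solved
# by the O(k^3) solver on its own small augmented matrix
link_frame_pair <- function(xy1, xy2, max_link_distance) {
  n <- nrow(xy1); m <- nrow(xy2)
  if (n == 0L || m == 0L) return(cbind(from = integer(), to = integer()))
  d2 <- outer(xy1[, 1], xy2[, 1], "-")^2 + outer(xy1[, 2], xy2[, 2], "-")^2
  gate2 <- max_link_distance^2
  d2[d2 > gate2] <- Inf
  # union-find over the bipartite candidate graph
  parent <- seq_len(n + m)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  cand <- which(is.finite(d2), arr.ind = TRUE)
  for (r in seq_len(nrow(cand))) {
    a <- find(cand[r, 1]); b <- find(n + cand[r, 2])
    if (a != b) parent[b] <- a
  }
  comp_of_row <- vapply(seq_len(n), find, integer(1))
  comp_of_col <- vapply(n + seq_len(m), find, integer(1))
  links <- list()
  for (cp in unique(comp_of_row)) {
    rows <- which(comp_of_row == cp)
    cols <- which(comp_of_col == cp)
    if (!length(cols)) next
    lk <- link_component(d2[rows, cols, drop = FALSE], gate2)
    if (nrow(lk))
      links[[length(links) + 1L]] <- cbind(from = rows[lk[, "from"]],
                                           to = cols[lk[, "to"]])
  }
  if (!length(links)) return(cbind(from = integer(), to = integer()))
  do.call(rbind, links)
}

#' Link spots into trajectories
#'
#' For every pair of consecutive frames, solves the rectangular
#' assignment problem with squared-Euclidean link costs under a hard
#' distance gate (`max_link_distance`); no gap closing, so a particle
#' missing in one frame terminates its track and any later detection
#' starts a new one.  Spots left unlinked seed new tracks.  The result
#' is independent of the input row order.
#'
#' @param spots data frame with columns `frame` (0-based, integer),
#'   `x_um`, `y_um` (additional columns are carried through).
#' @param max_link_distance gate in um (default 0.4).
#' @return data frame of class `spt_tracks`: the spot columns plus
#'   `track_id`, ordered by track and frame.
#' @export
link_spots <- function(spots, max_link_distance = 0.4) {
  stop_if_not_positive(max_link_distance, "max_link_distance")
  stopifnot(all(c("frame", "x_um", "y_um") %in% names(spots)))
  spots <- spots[order(spots$frame, spots$x_um, spots$y_um), , drop = FALSE]
  rownames(spots) <- NULL
  ns <- nrow(spots)
  track_of <- integer(ns)
  if (ns) {
    by_frame <- split(seq_len(ns), spots$frame)
    frames <- as.integer(names(by_frame))
    next_id <- 0L
    # seed tracks for the first populated frame
    first <- by_frame[[1]]
    track_of[first] <- next_id + seq_along(first)
    next_id <- next_id + length(first)
    if (length(frames) > 1L) for (k in seq_len(length(frames) - 1L)) {
      i1 <- by_frame[[k]]; i2 <- by_frame[[k + 1L]]
      links <- if (frames[k + 1L] == frames[k] + 1L) {
        link_frame_pair(cbind(spots$x_um[i1], spots$y_um[i1]),
                        cbind(spots$x_um[i2], spots$y_um[i2]),
                        max_link_distance)
      } else cbind(from = integer(), to = integer())   # gap: no links
      linked_to <- integer(length(i2))
      linked_to[links[, "to"]] <- i1[links[, "from"]]
      for (s in seq_along(i2)) {
        if (linked_to[s] > 0L) {
          track_of[i2[s]] <- track_of[linked_to[s]]
        } else {
          next_id <- next_id + 1L
          track_of[i2[s]] <- next_id
        }
      }
    }
  }
  spots$track_id <- track_of
  # renumber tracks by order of first appearance for stable output
  spots$track_id <- match(spots$track_id, unique(spots$track_id))
  out <- spots[order(spots$track_id, spots$frame),
               c("track_id", setdiff(names(spots), "track_id")),
               drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("spt_tracks", "data.frame")
  out
}

#' Keep tracks with a minimum number of points
#'
#' Retains tracks with at least `min_points` consecutive detections and
#' annotates each with its point count and duration.  The duration
#' convention is `n_points * frame_interval` (a 10-point track at 20
#' frames per second lasts 500 ms).
#'
#' @param tracks an `spt_tracks` data frame.
#' @param min_points minimum number of points (default 10, >= 2).
#' @param frame_interval seconds per frame, used for the duration.
#' @return filtered `spt_tracks` with added `n_points` and `duration_s`
#'   columns.
#' @export
filter_tracks <- function(tracks, min_points = 10L, frame_interval) {
  if (min_points < 2L) stop("'min_points' must be >= 2", call. = FALSE)
  stop_if_not_positive(frame_interval, "frame_interval")
  cnt <- table(tracks$track_id)
  keep <- names(cnt)[cnt >= min_points]
  out <- tracks[as.character(tracks$track_id) %in% keep, , drop = FALSE]
  n_pt <- as.integer(cnt[as.character(out$track_id)])
  out$n_points <- n_pt
  out$duration_s <- n_pt * frame_interval
  rownames(out) <- NULL
  class(out) <- c("spt_tracks", "data.frame")
  out
}

#' Write and read track tables
#'
#' CSV with columns `track_id, frame, x_um, y_um` (plus any extras),
#' round-trippable back into the pipeline.
#'
#' @param tracks an `spt_tracks` data frame.
#' @param path CSV path.
#' @export
write_tracks_csv <- function(tracks, path) {
  utils::write.csv(as.data.frame(tracks), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tracks_csv
#' @export
read_tracks_csv <- function(path) {
  df <- utils::read.csv(path)
  class(df) <- c("spt_tracks", "data.frame")
  df
}
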