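#' Sample a trial configuration
#'
#' Draws the per-trial factors uniformly at random: which door of each pair is
#' open, the order in which the four fixed rewards must be collected, the site
#' of the fifth (bonus) reward on the outer corridor, and the start pose.
#'
#' @param maze A [maze_map][load_maze].
#' @param seed Integer seed; the draw is fully reproducible given the seed.
#' @return A `trial_spec`: list with `door_state` (length-7 integer vector in
#'   {1,2}, the open alternative per pair), `reward_order` (permutation of
#'   1:4), `bonus_site` (row, col), `start_pose` (row, col, heading) and
#'   `rng_seed`.
#' @export
#' @examples
#' trial <- sample_trial(default_maze(), seed = 1)
#' trial$reward_order
sample_trial <- function(maze, seed) {
  stopifnot(inherits(maze, "maze_map"), is.numeric(seed))
  withr::with_seed(as.integer(seed), {
    spec <- structure(
      list(
        door_state = sample.int(2, 7, replace = TRUE),
        reward_order = sample.int(4),
        bonus_site = as.integer(maze$bonus_sites[sample.int(nrow(maze$bonus_sites), 1), ]),
        start_pose = as.list(maze$start_poses[sample.int(nrow(maze$start_poses), 1), ]),
        rng_seed = as.integer(seed)
      ),
      class = "trial_spec"
    )
    spec
  })
}

#' @export
print.trial_spec <- function(x, ...) {
  cat(sprintf(
    "<trial_spec> seed %d | doors %s | rewards %s | bonus (%d,%d)\n",
    x$rng_seed, paste(x$door_state, collapse = ""),
    paste(x$reward_order, collapse = ">"), x$bonus_site[1], x$bonus_site[2]
  ))
  invisible(x)
}

# Breadth-first search over corridor tiles with blocked tiles removed.
# Returns integer distance matrix and predecessor matrix (cell ids).
bfs_from <- function(open, from_r, from_c) {
  nr <- nrow(open)
  nc <- ncol(open)
  dist <- matrix(NA_integer_, nr, nc)
  pred <- matrix(NA_integer_, nr, nc)
  if (!open[from_r, from_c]) {
    return(list(dist = dist, pred = pred))
  }
  start <- (from_c - 1L) * nr + from_r
  dist[start] <- 0L
  queue <- integer(sum(open))
  queue[1] <- start
  head <- 1L
  tail <- 1L
  nbr_off <- c(-1L, 1L, -nr, nr)
  while (head <= tail) {
    id <- queue[head]
    head <- head + 1L
    r <- ((id - 1L) %% nr) + 1L
    for (k in 1:4) {
      id2 <- id + nbr_off[k]
      # guard row wrap at grid edges
      if (k == 1L && r == 1L) next
      if (k == 2L && r == nr) next
      if (id2 < 1L || id2 > nr * nc) next
      if (!open[id2] || !is.na(dist[id2])) next
      dist[id2] <- dist[id] + 1L
      pred[id2] <- id
      tail <- tail + 1L
      queue[tail] <- id2
    }
  }
  list(dist = dist, pred = pred)
}

# reconstruct tile path (matrix of row, col) from a bfs result
bfs_path <- function(bfs, nr, to_r, to_c) {
  id <- (to_c - 1L) * nr + to_r
  if (is.na(bfs$dist[id])) {
    return(NULL)
  }
  ids <- id
  while (!is.na(bfs$pred[id])) {
    id <- bfs$pred[id]
    ids <- c(id, ids)
  }
  cbind(row = ((ids - 1L) %% nr) + 1L, col = ((ids - 1L) %/% nr) + 1L)
}

#' Plan the route for a trial
#'
#' Stands in for the human navigator: computes a shortest corridor path (by
#' breadth-first search, closed doors impassable) from the start pose through
#' the four fixed rewards in the trial's prescribed order, inserting the bonus
#' reward at the point that minimizes the added path length. An optional
#' suboptimality probability inserts small random detours at junction tiles so
#' that simulated track pools are not degenerate.
#'
#' @param maze A [maze_map][load_maze].
#' @param trial A [trial_spec][sample_trial].
#' @param detour_prob Probability, per junction tile on the route, of a
#'   two-tile sidestep detour (default 0: strictly shortest path).
#' @param seed Seed for the detour draws (defaults to the trial's seed).
#' @return Tibble with columns `row`, `col` (pairwise-adjacent corridor
#'   tiles) and `event` (`""`, `"reward<k>"` or `"bonus"` at collection
#'   tiles), with attribute `reward_steps` (path indices of the 5 pickups in
#'   collection order).
#' @export
plan_route <- function(maze, trial, detour_prob = 0, seed = trial$rng_seed) {
  stopifnot(inherits(maze, "maze_map"), inherits(trial, "trial_spec"))
  open <- maze$grid
  blocked <- closed_door_cells(maze, trial$door_state)
  open[cbind(blocked$row, blocked$col)] <- FALSE

  rew <- maze$fixed_rewards[match(trial$reward_order, maze$fixed_rewards$id), ]
  stops <- rbind(
    c(trial$start_pose$row, trial$start_pose$col),
    as.matrix(rew[, c("row", "col")])
  )
  nr <- nrow(open)
  dist_between <- function(a, b) {
    bfs <- bfs_from(open, a[1], a[2])
    d <- bfs$dist[b[1], b[2]]
    if (is.na(d)) {
      rlang::abort(sprintf(
        "reward at (%d,%d) unreachable from (%d,%d) under door state %s",
        b[1], b[2], a[1], a[2], paste(trial$door_state, collapse = "")
      ))
    }
    d
  }
  # choose where along the reward sequence to insert the bonus pickup
  bonus <- trial$bonus_site
  leg_d <- vapply(1:4, function(i) dist_between(stops[i, ], stops[i + 1, ]), numeric(1))
  added <- vapply(1:5, function(i) {
    if (i <= 4) {
      dist_between(stops[i, ], bonus) + dist_between(bonus, stops[i + 1, ]) - leg_d[i]
    } else {
      dist_between(stops[5, ], bonus)
    }
  }, numeric(1))
  ins <- which.min(added)
  labels <- c("", paste0("reward", trial$reward_order))
  if (ins <= 4) {
    stops <- rbind(stops[1:ins, , drop = FALSE], bonus, stops[(ins + 1):5, , drop = FALSE])
    labels <- c(labels[1:ins], "bonus", labels[(ins + 1):5])
  } else {
    stops <- rbind(stops, bonus)
    labels <- c(labels, "bonus")
  }

  path <- stops[1, , drop = FALSE]
  events <- ""
  withr::with_seed(as.integer(seed) + 1203L, {
    for (i in seq_len(nrow(stops) - 1)) {
      leg <- leg_path(open, stops[i, ], stops[i + 1, ], detour_prob)
      path <- rbind(path, leg[-1, , drop = FALSE])
      events <- c(events, c(rep("", nrow(leg) - 2), labels[i + 1]))
    }
  })
  out <- tibble::tibble(
    row = as.integer(path[, 1]), col = as.integer(path[, 2]), event = events
  )
  attr(out, "reward_steps") <- which(out$event != "")
  out
}

# shortest path for one leg, with optional sidestep detours at junctions
leg_path <- function(open, from, to, detour_prob) {
  bfs <- bfs_from(open, from[1], from[2])
  p <- bfs_path(bfs, nrow(open), to[1], to[2])
  if (is.null(p)) rlang::abort("leg target unreachable")
  if (detour_prob <= 0 || nrow(p) < 3) {
    return(p)
  }
  dr <- c(-1L, 1L, 0L, 0L)
  dc <- c(0L, 0L, -1L, 1L)
  out <- p[1, , drop = FALSE]
  for (i in 2:(nrow(p) - 1)) {
    out <- rbind(out, p[i, ])
    nbr_r <- p[i, 1] + dr
    nbr_c <- p[i, 2] + dc
    ok <- nbr_r >= 1 & nbr_r <= nrow(open) & nbr_c >= 1 & nbr_c <= ncol(open)
    ok[ok] <- open[cbind(nbr_r[ok], nbr_c[ok])]
    # junction = 3+ open neighbours; sidestep to one off the route and back
    off <- which(ok &
      !(nbr_r == p[i - 1, 1] & nbr_c == p[i - 1, 2]) &
      !(nbr_r == p[i + 1, 1] & nbr_c == p[i + 1, 2]))
    if (sum(ok) >= 3 && length(off) > 0 && stats::runif(1) < detour_prob) {
      j <- off[sample.int(length(off), 1)]
      out <- rbind(out, c(nbr_r[j], nbr_c[j]), p[i, ])
    }
  }
  rbind(out, p[nrow(p), ])
}
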