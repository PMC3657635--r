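#' Maze map objects
#'
#' A `maze_map` describes the virtual environment: a 22 x 22 occupancy grid of
#' wall and corridor tiles, seven pairs of doors (on each trial exactly one
#' door of each pair is open, the other blocks its corridor tile), nine wall
#' pictures at fixed positions, four fixed reward tiles that must be collected
#' in a per-trial order, and four candidate sites on the outer corridor for a
#' fifth, freely-collectable reward.
#'
#' Coordinates are 1-based `(row, col)` tile indices. Continuous positions use
#' tile units with tile centers at `(row - 0.5, col - 0.5)`; headings are in
#' degrees, counter-clockwise positive, with 0 = east (increasing column),
#' 90 = north (decreasing row).
#'
#' @param path Path to a plain-text maze layout (see Details).
#'
#' @details The text format is 22 lines of 22 characters (`#` wall, `.`
#' corridor) followed by annotation lines: `door <pair> <row> <col>` (two
#' lines per pair), `picture <id> <row> <col> <face> <texture>` (face is the
#' outward normal of the wall face carrying the picture, one of N/E/S/W),
#' `reward <id> <row> <col>`, `bonus <row> <col>`, and
#' `start <row> <col> <heading>`. Lines starting with `#` after the grid are
#' comments.
#'
#' @return A `maze_map`: a list with elements `grid` (22 x 22 logical matrix,
#'   `TRUE` = corridor), `door_pairs` (tibble: pair, alt, row, col),
#'   `pictures` (tibble: id, row, col, face, texture), `fixed_rewards`
#'   (tibble: id, row, col), `bonus_sites` (tibble: row, col), and
#'   `start_poses` (tibble: row, col, heading).
#' @export
#' @examples
#' maze <- default_maze()
#' maze
load_maze <- function(path) {
  stopifnot(is.character(path), length(path) == 1)
  raw <- readLines(path)
  raw <- raw[nzchar(trimws(raw))]
  grid_lines <- raw[seq_len(min(22, length(raw)))]
  if (length(grid_lines) < 22 || any(nchar(grid_lines) != 22)) {
    rlang::abort("maze layout must start with a 22 x 22 character grid")
  }
  chars <- do.call(rbind, strsplit(grid_lines, ""))
  if (!all(chars %in% c("#", "."))) {
    rlang::abort("grid characters must be '#' (wall) or '.' (corridor)")
  }
  grid <- chars == "."

  ann <- raw[-seq_len(22)]
  ann <- ann[!startsWith(trimws(ann), "#")]
  tok <- strsplit(trimws(ann), "\\s+")
  field <- function(kind, n) {
    rows <- tok[vapply(tok, function(t) t[1] == kind, logical(1))]
    if (length(rows) == 0) {
      return(matrix(character(), 0, n))
    }
    if (any(vapply(rows, length, integer(1)) != n + 1)) {
      rlang::abort(sprintf("malformed '%s' annotation line", kind))
    }
    do.call(rbind, lapply(rows, function(t) t[-1]))
  }
  doors <- field("door", 3)
  door_pairs <- tibble::tibble(
    pair = as.integer(doors[, 1]),
    row = as.integer(doors[, 2]), col = as.integer(doors[, 3])
  )
  door_pairs <- dplyr::mutate(
    dplyr::group_by(door_pairs, .data$pair),
    alt = dplyr::row_number(), .after = "pair"
  )
  door_pairs <- dplyr::ungroup(door_pairs)
  pics <- field("picture", 5)
  pictures <- tibble::tibble(
    id = as.integer(pics[, 1]), row = as.integer(pics[, 2]),
    col = as.integer(pics[, 3]), face = pics[, 4],
    texture = as.integer(pics[, 5])
  )
  rew <- field("reward", 3)
  fixed_rewards <- tibble::tibble(
    id = as.integer(rew[, 1]), row = as.integer(rew[, 2]),
    col = as.integer(rew[, 3])
  )
  bon <- field("bonus", 2)
  bonus_sites <- tibble::tibble(row = as.integer(bon[, 1]), col = as.integer(bon[, 2]))
  sta <- field("start", 3)
  start_poses <- tibble::tibble(
    row = as.integer(sta[, 1]), col = as.integer(sta[, 2]),
    heading = as.numeric(sta[, 3])
  )
  new_maze_map(grid, door_pairs, pictures, fixed_rewards, bonus_sites, start_poses)
}

#' @rdname load_maze
#' @export
default_maze <- function() {
  load_maze(system.file("extdata", "default_maze.txt", package = "navdecode"))
}

new_maze_map <- function(grid, door_pairs, pictures, fixed_rewards, bonus_sites,
                         start_poses) {
  maze <- structure(
    list(
      grid = grid, door_pairs = door_pairs, pictures = pictures,
      fixed_rewards = fixed_rewards, bonus_sites = bonus_sites,
      start_poses = start_poses
    ),
    class = "maze_map"
  )
  validate_maze_map(maze)
}

validate_maze_map <- function(maze) {
  grid <- maze$grid
  if (!is.matrix(grid) || !all(dim(grid) == c(22, 22))) {
    rlang::abort("maze grid must be a 22 x 22 matrix")
  }
  if (!any(grid)) rlang::abort("maze has no corridor tiles")
  n_pairs <- length(unique(maze$door_pairs$pair))
  if (n_pairs != 7 || nrow(maze$door_pairs) != 14) {
    rlang::abort(sprintf("maze must have exactly 7 door pairs (found %d)", n_pairs))
  }
  if (any(table(maze$door_pairs$pair) != 2)) {
    rlang::abort("every door pair must hold exactly 2 alternative door tiles")
  }
  if (nrow(maze$pictures) != 9 || !setequal(maze$pictures$id, 1:9)) {
    rlang::abort("maze must have exactly 9 pictures with ids 1..9")
  }
  if (nrow(maze$fixed_rewards) != 4 || !setequal(maze$fixed_rewards$id, 1:4)) {
    rlang::abort("maze must have exactly 4 fixed rewards with ids 1..4")
  }
  if (nrow(maze$bonus_sites) != 4) {
    rlang::abort("maze must have exactly 4 bonus reward sites")
  }
  if (nrow(maze$start_poses) < 1) rlang::abort("maze needs at least one start pose")

  in_grid <- function(r, c) r >= 1 & r <= 22 & c >= 1 & c <= 22
  corridor <- function(r, c) in_grid(r, c) & grid[cbind(r, c)]
  # doors sit in corridor tiles (a closed door blocks its tile)
  with(maze$door_pairs, if (!all(corridor(row, col))) {
    rlang::abort("dangling door: every door tile must be a corridor tile")
  })
  with(maze$fixed_rewards, if (!all(corridor(row, col))) {
    rlang::abort("every fixed-reward tile must be a corridor tile")
  })
  with(maze$bonus_sites, if (!all(corridor(row, col))) {
    rlang::abort("every bonus site must be a corridor tile")
  })
  with(maze$start_poses, if (!all(corridor(row, col))) {
    rlang::abort("every start pose must be on a corridor tile")
  })
  # pictures hang on wall tiles and face an adjacent corridor tile
  step <- face_step()
  p <- maze$pictures
  if (any(grid[cbind(p$row, p$col)])) {
    rlang::abort("pictures must hang on wall tiles")
  }
  fr <- p$row + step[p$face, "dr"]
  fc <- p$col + step[p$face, "dc"]
  if (!all(corridor(fr, fc))) {
    rlang::abort("dangling picture: faced tile must be a corridor tile")
  }
  if (!all(p$face %in% c("N", "E", "S", "W"))) {
    rlang::abort("picture face must be one of N, E, S, W")
  }
  maze
}

# outward-normal unit steps in (row, col) for each wall face
face_step <- function() {
  m <- rbind(
    N = c(dr = -1L, dc = 0L), S = c(dr = 1L, dc = 0L),
    E = c(dr = 0L, dc = 1L), W = c(dr = 0L, dc = -1L)
  )
  m
}

#' @export
print.maze_map <- function(x, ...) {
  cat(sprintf(
    "<maze_map> %d x %d grid, %d corridor tiles, %d door pairs, %d pictures, %d+%d rewards\n",
    nrow(x$grid), ncol(x$grid), sum(x$grid),
    length(unique(x$door_pairs$pair)), nrow(x$pictures),
    nrow(x$fixed_rewards), 1L
  ))
  invisible(x)
}

is_corridor <- function(maze, row, col) {
  row >= 1 & row <= nrow(maze$grid) & col >= 1 & col <= ncol(maze$grid) &
    maze$grid[cbind(row, col)]
}

# tiles blocked by the closed door of each pair under a trial's door state
closed_door_cells <- function(maze, door_state) {
  dp <- maze$door_pairs
  closed <- dp[dp$alt != door_state[dp$pair], , drop = FALSE]
  closed[, c("row", "col")]
}
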