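#' Average a frame-resolution series into TR bins
#'
#' Behavioral and stimulus variables are computed at the maze frame rate
#' (20 frames/s) and then averaged within each fMRI acquisition interval:
#' with a TR of 3 s, all 60 frame values falling into one TR are averaged. A
#' final partial bin is averaged over its available frames, so the binned
#' length is always `ceiling(length(x) / frames_per_tr)`.
#'
#' @param x Numeric per-frame series.
#' @param frames_per_tr Frames per TR bin (default 60 = 20 fps x 3 s).
#' @return Numeric per-TR series.
#' @export
#' @examples
#' bin_to_tr(1:120) # c(30.5, 90.5)
bin_to_tr <- function(x, frames_per_tr = 60) {
  if (length(x) == 0) rlang::abort("cannot bin an empty series")
  stopifnot(frames_per_tr >= 1)
  bin <- (seq_along(x) - 1) %/% frames_per_tr
  as.numeric(tapply(x, bin, mean))
}

#' Quadrant geometry and per-TR quadrant location
#'
#' The maze floor is divided into four rectangles with a central band (two
#' tiles wide by default) that belongs to no quadrant; time points whose
#' TR-mean position falls in the band (or outside every rectangle) are not
#' assigned and are excluded from classifier training.
#'
#' @param rects A 4-row data frame with columns `quadrant`, `row_min`,
#'   `row_max`, `col_min`, `col_max` (tile bounds, inclusive), or `NULL` for
#'   the default geometry: four 9 x 9 rectangles separated by a 2-tile cross.
#' @export
quadrant_geometry <- function(rects = NULL) {
  if (is.null(rects)) {
    rects <- tibble::tibble(
      quadrant = 1:4,
      row_min = c(2, 2, 13, 13), row_max = c(10, 10, 21, 21),
      col_min = c(2, 13, 2, 13), col_max = c(10, 21, 10, 21)
    )
  }
  rects <- tibble::as_tibble(rects)
  stopifnot(nrow(rects) == 4)
  rects
}

#' @rdname quadrant_geometry
#' @param track A [track][simulate_track].
#' @param frames_per_tr Frames per TR bin.
#' @return For `quadrant_location()`: integer per-TR labels in 1..4, `NA`
#'   where the TR-mean position is unassigned.
#' @export
quadrant_location <- function(track, rects = NULL, frames_per_tr = 60) {
  rects <- quadrant_geometry(rects)
  mx <- bin_to_tr(track$x, frames_per_tr)
  my <- bin_to_tr(track$y, frames_per_tr)
  # continuous (x, y) in tile units: tile (r, c) spans y in [r-1, r)
  lab <- rep(NA_integer_, length(mx))
  for (q in seq_len(4)) {
    inside <- my >= rects$row_min[q] - 1 & my < rects$row_max[q] &
      mx >= rects$col_min[q] - 1 & mx < rects$col_max[q]
    lab[inside] <- rects$quadrant[q]
  }
  lab
}

#' Per-frame picture visibility from rendered scenes
#'
#' The visibility of picture k in a frame is the fraction of scene pixels
#' showing it: 0 when not visible, 1 when the picture fills the whole scene.
#'
#' @param scenes A list of [scene][render_frame] objects.
#' @return A 9 x n_frames matrix of visibilities in \[0, 1\].
#' @export
picture_visibility <- function(scenes) {
  vapply(scenes, function(sc) {
    tabulate(sc$picture_mask[sc$picture_mask > 0], nbins = 9) /
      length(sc$picture_mask)
  }, numeric(9))
}

#' Per-frame rotational motion
#'
#' Signed heading change from one frame to the next, in degrees, positive
#' when turning left and zero while stationary or moving straight ahead. The
#' first frame's value is zero.
#'
#' @param track A [track][simulate_track].
#' @return Numeric per-frame series (degrees/frame).
#' @export
motion_path <- function(track) {
  if (nrow(track) < 2) rlang::abort("motion needs at least 2 frames")
  c(0, diff(track$heading))
}

#' Per-TR reward-planning onsets
#'
#' Value 1 exactly at TRs in which the navigator first learns which reward to
#' collect next: at the trial start and at each pickup that reveals the next
#' target (the final pickup reveals nothing).
#'
#' @param track A [track][simulate_track].
#' @param frames_per_tr Frames per TR bin.
#' @return Binary per-TR series.
#' @export
reward_timing <- function(track, frames_per_tr = 60) {
  ev <- attr(track, "reward_events")
  cue_frames <- unique(c(1L, utils::head(ev, -1)))
  n_tr <- ceiling(nrow(track) / frames_per_tr)
  out <- numeric(n_tr)
  out[unique((cue_frames - 1) %/% frames_per_tr + 1)] <- 1
  out
}

#' The 28-region scene grid
#'
#' Scenes are summarized on a 5 x 5 grid of squares whose middle square is
#' further divided into four smaller squares, yielding 28 disjoint regions
#' covering every pixel. Remainder pixels of an uneven division are assigned
#' to the last row/column of cells.
#'
#' @param height,width Scene resolution in pixels (each >= 10).
#' @return Integer `height x width` matrix of region ids 1..28. Regions 1-24
#'   are the outer cells in raster order; 25-28 are the four center subcells
#'   (top-left, top-right, bottom-left, bottom-right).
#' @export
#' @examples
#' table(scene_grid(100, 100))
scene_grid <- function(height, width) {
  if (height < 10 || width < 10) rlang::abort("resolution must be at least 10 x 10")
  cell_idx <- function(n) pmin((seq_len(n) - 1) %/% (n %/% 5), 4) # 0..4
  ri <- cell_idx(height)
  ci <- cell_idx(width)
  cell <- outer(ri, ci, function(a, b) a * 5 + b + 1) # 1..25 raster order
  out <- matrix(0L, height, width)
  outer_ids <- setdiff(1:25, 13)
  out[] <- match(cell, outer_ids) # NA at the center cell
  center <- which(cell == 13)
  rr <- ((center - 1) %% height) + 1
  cc <- ((center - 1) %/% height) + 1
  rmid <- stats::median(range(rr))
  cmid <- stats::median(range(cc))
  sub <- 24L + ifelse(rr <= rmid, ifelse(cc <= cmid, 1L, 2L), ifelse(cc <= cmid, 3L, 4L))
  out[center] <- sub
  out
}

#' Stationary and temporal scene content
#'
#' `scene_rms()` summarizes each of the 28 grid regions of each frame by the
#' population standard deviation of pixel luminance (local spatial contrast).
#' `scene_temp()` sums, per region and frame pair, the positive
#' frame-to-frame luminance increments over pixels (onset-weighted temporal
#' contrast); the first frame's value is 0.
#'
#' @param scenes A list of [scene][render_frame] objects with equal
#'   resolution.
#' @param grid Optional precomputed [scene_grid()] matrix.
#' @return A 28 x n_frames matrix.
#' @export
scene_rms <- function(scenes, grid = NULL) {
  g <- grid %||% scene_grid(nrow(scenes[[1]]$luminance), ncol(scenes[[1]]$luminance))
  gi <- as.integer(g)
  n <- tabulate(gi, 28)
  vapply(scenes, function(sc) {
    v <- as.numeric(sc$luminance)
    s1 <- rowsum_by(v, gi)
    s2 <- rowsum_by(v * v, gi)
    sqrt(pmax(s2 / n - (s1 / n)^2, 0))
  }, numeric(28))
}

#' @rdname scene_rms
#' @export
scene_temp <- function(scenes, grid = NULL) {
  if (length(scenes) < 2) rlang::abort("temporal contrast needs at least 2 frames")
  g <- grid %||% scene_grid(nrow(scenes[[1]]$luminance), ncol(scenes[[1]]$luminance))
  gi <- as.integer(g)
  prev <- as.numeric(scenes[[1]]$luminance)
  out <- matrix(0, 28, length(scenes))
  for (f in 2:length(scenes)) {
    cur <- as.numeric(scenes[[f]]$luminance)
    out[, f] <- rowsum_by(pmax(cur - prev, 0), gi)
    prev <- cur
  }
  out
}

rowsum_by <- function(v, gi) {
  out <- numeric(28)
  s <- rowsum(v, gi)
  out[as.integer(rownames(s))] <- s
  out
}

#' Assemble the 73 decoding variables for one trial
#'
#' Runs the full extraction pipeline for a trial: renders the first-person
#' scene of every frame, computes the six information sources at frame
#' resolution, bins them to TR resolution, and packages the 73 decoding
#' variables: 6 quadrant pairs, 9 picture visibilities, 1 rotational motion,
#' 1 reward timing, 28 scene-RMS and 28 scene-Temp regions.
#'
#' Quadrant-pair variables take value 1 when the TR-mean position is in the
#' pair's first quadrant, 0 in its second, and 0.5 when unassigned (the 0.5
#' time points are masked from classifier training).
#'
#' @param maze A [maze_map][load_maze].
#' @param track A [track][simulate_track].
#' @param trial The trial's [trial_spec][sample_trial] (for door state during
#'   rendering); defaults to the track's trial attribute.
#' @param width,height,fov Renderer parameters (see [render_frame()]).
#' @param frames_per_tr Frames per TR bin (default 60).
#' @param rects Quadrant geometry (see [quadrant_geometry()]).
#' @return A `variable_set` tibble with columns `source`, `variable`, `tr`,
#'   `value`; 73 variables x `ceiling(frames / frames_per_tr)` TRs.
#' @export
build_variable_set <- function(maze, track, trial = attr(track, "trial"),
                               width = 200, height = 150, fov = 60,
                               frames_per_tr = 60, rects = NULL) {
  door_state <- if (!is.null(trial)) trial$door_state else NULL
  g <- scene_grid(height, width)
  gi <- as.integer(g)
  n_reg <- tabulate(gi, 28)
  n_frames <- nrow(track)
  vis <- matrix(0, 9, n_frames)
  rms <- matrix(0, 28, n_frames)
  tmp <- matrix(0, 28, n_frames)
  prev <- NULL
  for (f in seq_len(n_frames)) {
    sc <- render_frame(
      maze, list(x = track$x[f], y = track$y[f], heading = track$heading[f]),
      door_state = door_state, width = width, height = height, fov = fov
    )
    v <- as.numeric(sc$luminance)
    vis[, f] <- tabulate(sc$picture_mask[sc$picture_mask > 0], 9) / length(v)
    s1 <- rowsum_by(v, gi)
    s2 <- rowsum_by(v * v, gi)
    rms[, f] <- sqrt(pmax(s2 / n_reg - (s1 / n_reg)^2, 0))
    if (!is.null(prev)) tmp[, f] <- rowsum_by(pmax(v - prev, 0), gi)
    prev <- v
  }
  motion <- motion_path(track)
  reward <- reward_timing(track, frames_per_tr)
  quad <- quadrant_location(track, rects, frames_per_tr)
  n_tr <- length(reward)

  pairs <- utils::combn(4, 2)
  quad_vals <- lapply(seq_len(6), function(j) {
    a <- pairs[1, j]
    b <- pairs[2, j]
    ifelse(is.na(quad), 0.5, ifelse(quad == a, 1, ifelse(quad == b, 0, 0.5)))
  })
  bin_rows <- function(m) lapply(seq_len(nrow(m)), function(i) bin_to_tr(m[i, ], frames_per_tr))

  vars <- c(
    stats::setNames(quad_vals, sprintf("q%d%d", pairs[1, ], pairs[2, ])),
    stats::setNames(bin_rows(vis), sprintf("vis%d", 1:9)),
    list(motion = bin_to_tr(motion, frames_per_tr)),
    list(reward = reward),
    stats::setNames(bin_rows(rms), sprintf("rms%02d", 1:28)),
    stats::setNames(bin_rows(tmp), sprintf("temp%02d", 1:28))
  )
  src <- rep(
    c("quadrant", "visibility", "motion", "reward", "scene_rms", "scene_temp"),
    c(6, 9, 1, 1, 28, 28)
  )
  out <- tibble::tibble(
    source = rep(src, each = n_tr),
    variable = rep(names(vars), each = n_tr),
    tr = rep(seq_len(n_tr), length(vars)),
    value = unlist(vars, use.names = FALSE)
  )
  stopifnot(length(vars) == 73, all(lengths(vars) == n_tr))
  class(out) <- c("variable_set", class(out))
  out
}

#' @export
print.variable_set <- function(x, ...) {
  if (all(c("variable", "tr", "source") %in% names(x))) {
    cat(sprintf(
      "<variable_set> %d variables x %d TRs (%s)\n",
      dplyr::n_distinct(x$variable), max(x$tr),
      paste(unique(x$source), collapse = ", ")
    ))
  }
  NextMethod()
}
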