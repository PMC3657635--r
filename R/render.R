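#' Render a first-person scene by ray casting
#'
#' Casts one ray per screen column through the tile grid (closed doors are
#' rendered as walls, open doors as passable gaps) and paints textured wall
#' columns over a darker sky region and a mid-gray floor. Wall faces carrying
#' a picture show a procedural picture texture on the central area of the
#' face; those pixels are flagged in an integer mask so that visible picture
#' area can be measured exactly.
#'
#' @param maze A [maze_map][load_maze].
#' @param pose Numeric vector or list with `x`, `y` (continuous tile units)
#'   and `heading` (degrees, 0 = east, counter-clockwise positive). Must lie
#'   inside a corridor tile.
#' @param door_state Length-7 integer vector (the open alternative per pair),
#'   or `NULL` for all pairs open.
#' @param width,height Scene resolution in pixels (default 200 x 150).
#' @param fov Horizontal field of view in degrees (default 60).
#' @return A `scene`: list with `luminance` (height x width matrix in
#'   \[0, 1\]) and `picture_mask` (height x width integer matrix, 0 =
#'   background, k = pixel shows picture k).
#' @export
#' @examples
#' maze <- default_maze()
#' sc <- render_frame(maze, c(x = 1.5, y = 1.5, heading = 0),
#'   width = 64, height = 48
#' )
#' range(sc$luminance)
render_frame <- function(maze, pose, door_state = NULL, width = 200,
                         height = 150, fov = 60) {
  pose <- as.list(pose)
  x <- pose$x
  y <- pose$y
  heading <- pose$heading
  walls <- !maze$grid
  if (!is.null(door_state)) {
    blocked <- closed_door_cells(maze, door_state)
    walls[cbind(blocked$row, blocked$col)] <- TRUE
  }
  r0 <- floor(y) + 1L
  c0 <- floor(x) + 1L
  if (r0 < 1 || r0 > nrow(walls) || c0 < 1 || c0 > ncol(walls) || walls[r0, c0]) {
    rlang::abort("pose must lie inside a corridor tile")
  }
  hit <- cast_rays(walls, x, y, heading, width, fov)
  paint_scene(maze, hit, width, height)
}

# Digital differential analyzer over the tile grid, vectorized across rays.
# Screen y is row-down, so a heading of +h degrees has direction
# (cos h, -sin h) in (x, y).
cast_rays <- function(walls, x, y, heading, width, fov) {
  nr <- nrow(walls)
  nc <- ncol(walls)
  ang <- (heading + seq(fov / 2, -fov / 2, length.out = width)) * pi / 180
  dx <- cos(ang)
  dy <- -sin(ang)
  # current tile indices (0-based during the march)
  cx <- rep(floor(x), width)
  cy <- rep(floor(y), width)
  step_x <- ifelse(dx >= 0, 1, -1)
  step_y <- ifelse(dy >= 0, 1, -1)
  inv_dx <- ifelse(abs(dx) < 1e-12, Inf, 1 / abs(dx))
  inv_dy <- ifelse(abs(dy) < 1e-12, Inf, 1 / abs(dy))
  tmax_x <- ifelse(dx >= 0, (cx + 1 - x), (x - cx)) * inv_dx
  tmax_y <- ifelse(dy >= 0, (cy + 1 - y), (y - cy)) * inv_dy
  t_hit <- rep(NA_real_, width)
  side <- integer(width) # 1 = crossed a column boundary, 2 = a row boundary
  active <- rep(TRUE, width)
  for (i in seq_len(2 * (nr + nc))) {
    if (!any(active)) break
    sx <- active & (tmax_x <= tmax_y)
    sy <- active & !sx
    cx[sx] <- cx[sx] + step_x[sx]
    cy[sy] <- cy[sy] + step_y[sy]
    t_now <- ifelse(sx, tmax_x, tmax_y)
    tmax_x[sx] <- tmax_x[sx] + inv_dx[sx]
    tmax_y[sy] <- tmax_y[sy] + inv_dy[sy]
    oob <- active & (cx < 0 | cx >= nc | cy < 0 | cy >= nr)
    idx <- active & !oob
    hit_wall <- idx
    hit_wall[idx] <- walls[cbind(cy[idx] + 1, cx[idx] + 1)]
    newly <- hit_wall | oob
    t_hit[newly] <- t_now[newly]
    side[newly & sx] <- 1L
    side[newly & sy] <- 2L
    active <- active & !newly
  }
  t_hit[is.na(t_hit)] <- 2 * (nr + nc)
  # face of the hit cell seen by the ray (outward normal toward the viewer)
  face <- ifelse(side == 1L,
    ifelse(step_x > 0, "W", "E"), # moving +x enters through the west face
    ifelse(step_y > 0, "N", "S")
  )
  hx <- x + dx * t_hit
  hy <- y + dy * t_hit
  # texture coordinate along the wall face in [0, 1)
  u <- ifelse(side == 1L, hy - floor(hy + 1e-9), hx - floor(hx + 1e-9))
  list(
    dist = t_hit * cos(ang - heading * pi / 180), # fisheye-corrected
    row = cy + 1L, col = cx + 1L, face = face, u = pmin(pmax(u, 0), 1 - 1e-9)
  )
}

# procedural textures ------------------------------------------------------

brick_tex <- function(u, v) {
  # staggered brick courses with darker mortar lines
  course <- floor(v * 5)
  uu <- (u * 3 + 0.5 * (course %% 2)) %% 1
  vv <- (v * 5) %% 1
  mortar <- (vv < 0.12) | (uu < 0.08)
  ifelse(mortar, 0.38, 0.72 + 0.06 * sin(37 * u + 17 * v))
}

picture_tex <- function(id, u, v) {
  # a distinct oriented grating per picture id
  f1 <- 2 + (id %% 3) * 2
  f2 <- 1 + (id %% 4)
  ph <- id * 0.7
  0.5 + 0.45 * sin(2 * pi * (f1 * u + f2 * v) + ph)
}

paint_scene <- function(maze, hit, width, height) {
  sky <- 0.15
  floor_lum <- 0.45
  wall_scale <- 0.9
  lum <- matrix(0, height, width)
  mask <- matrix(0L, height, width)
  # picture lookup keyed by wall cell + face
  pk <- paste(maze$pictures$row, maze$pictures$col, maze$pictures$face)
  hit_key <- paste(hit$row, hit$col, hit$face)
  pic_id <- maze$pictures$id[match(hit_key, pk)]
  pic_tex <- maze$pictures$texture[match(hit_key, pk)]

  half <- height / 2
  wall_h <- pmin(height * wall_scale / pmax(hit$dist, 1e-6), 1e6)
  top <- half - wall_h / 2
  bot <- half + wall_h / 2
  rowi <- matrix(seq_len(height) - 0.5, height, width)
  topm <- matrix(top, height, width, byrow = TRUE)
  botm <- matrix(bot, height, width, byrow = TRUE)
  on_wall <- rowi >= topm & rowi < botm
  lum[rowi < topm] <- sky
  lum[rowi >= botm] <- floor_lum
  # vertical texture coordinate on the wall face
  v <- (rowi - topm) / pmax(botm - topm, 1e-9)
  um <- matrix(hit$u, height, width, byrow = TRUE)
  shade <- matrix(
    ifelse(hit$face %in% c("N", "S"), 1, 0.85) / (1 + 0.05 * hit$dist),
    height, width,
    byrow = TRUE
  )
  wl <- brick_tex(um[on_wall], v[on_wall]) * shade[on_wall]
  lum[on_wall] <- wl
  # picture quad on the central area of the face
  picm <- matrix(pic_id, height, width, byrow = TRUE)
  pictex <- matrix(pic_tex, height, width, byrow = TRUE)
  in_pic <- on_wall & !is.na(picm) &
    um >= 0.15 & um < 0.85 & v >= 0.15 & v < 0.85
  if (any(in_pic)) {
    uu <- (um[in_pic] - 0.15) / 0.7
    vv <- (v[in_pic] - 0.15) / 0.7
    lum[in_pic] <- picture_tex(pictex[in_pic], uu, vv) * shade[in_pic]
    mask[in_pic] <- picm[in_pic]
  }
  structure(
    list(luminance = pmin(pmax(lum, 0), 1), picture_mask = mask),
    class = "scene"
  )
}

#' @export
print.scene <- function(x, ...) {
  cat(sprintf(
    "<scene> %d x %d, luminance [%.2f, %.2f], %d picture pixels\n",
    nrow(x$luminance), ncol(x$luminance),
    min(x$luminance), max(x$luminance), sum(x$picture_mask > 0)
  ))
  invisible(x)
}
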