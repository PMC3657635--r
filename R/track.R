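#' Simulate navigation kinematics along a tile path
#'
#' Converts a planned tile path into a per-frame pose sequence with the
#' navigator's kinematics: forward travel at 1 tile per 0.78 s sampled at
#' 20 frames/s (1/(0.78*20) tiles per frame), and turns executed in place at
#' `turn_rate` degrees per frame (turning and advancing are separate button
#' presses, so forward speed is zero while turning). Within each straight
#' segment the position advances a fixed step per frame and clamps at the
#' corner, so a segment of length L tiles costs `ceiling(L / step)` frames
#' and a turn of angle A costs `ceiling(A / turn_rate)` frames.
#'
#' @param path Tibble of pairwise-adjacent corridor tiles from [plan_route()]
#'   (columns `row`, `col`, optionally `event`).
#' @param trial The [trial_spec][sample_trial] the path realizes (kept as an
#'   attribute; may be `NULL` for constructed paths).
#' @param turn_rate Turn speed in degrees per frame (> 0; default 6, i.e.
#'   0.75 s per 90 degree turn).
#' @param fps Frame rate (default 20 frames/s).
#' @param tile_s Seconds to traverse one tile when moving forward
#'   (default 0.78).
#' @return A `track`: tibble with columns `frame`, `x` (continuous column
#'   units), `y` (continuous row units), `heading` (degrees, unwrapped,
#'   counter-clockwise positive, 0 = east) and `event`; attributes
#'   `reward_events` (frame index of each pickup, in collection order),
#'   `fps`, and `trial`.
#' @export
#' @examples
#' path <- tibble::tibble(row = 2, col = 2:9)
#' tr <- simulate_track(path)
#' track_duration(tr)
simulate_track <- function(path, trial = NULL, turn_rate = 6, fps = 20,
                           tile_s = 0.78) {
  if (turn_rate <= 0) rlang::abort("turn_rate must be positive")
  path <- tibble::as_tibble(path)
  if (nrow(path) < 1) rlang::abort("path must contain at least one tile")
  if (!"event" %in% names(path)) path$event <- ""
  if (nrow(path) > 1) {
    stepdist <- abs(diff(path$row)) + abs(diff(path$col))
    if (any(stepdist != 1)) rlang::abort("path tiles must be pairwise adjacent")
  }
  step <- 1 / (tile_s * fps)
  # tile centers in continuous units: x along columns, y along rows
  cx <- path$col - 0.5
  cy <- path$row - 0.5
  # heading of each path step: 0 = east, 90 = north (decreasing row), CCW+
  seg_head <- function(i) {
    dxy <- c(cx[i + 1] - cx[i], cy[i + 1] - cy[i])
    atan2(-dxy[2], dxy[1]) * 180 / pi
  }
  n <- nrow(path)
  if (n == 1) {
    out <- tibble::tibble(
      frame = 1L, x = cx, y = cy,
      heading = if (!is.null(trial)) trial$start_pose$heading else 0,
      event = path$event
    )
    return(new_track(out, integer(0), fps, trial))
  }
  heading0 <- if (!is.null(trial)) trial$start_pose$heading else seg_head(1)

  # group consecutive path steps into straight segments
  heads <- vapply(seq_len(n - 1), seg_head, numeric(1))
  seg_end <- c(which(diff(heads) != 0), n - 1) # index of last step per segment
  seg_start <- c(1, utils::head(seg_end, -1) + 1)

  xs <- cx[1]
  ys <- cy[1]
  hs <- heading0
  evs <- path$event[1]
  ev_at <- function(i) path$event[i] # event fires at the frame its tile is reached
  cur_h <- heading0
  for (s in seq_along(seg_start)) {
    i0 <- seg_start[s]
    i1 <- seg_end[s]
    target_h <- heads[i0]
    # turn in place toward the segment heading by the shortest signed angle
    dh <- ((target_h - cur_h + 180) %% 360) - 180
    if (abs(dh) > 1e-9) {
      nturn <- ceiling(abs(dh) / turn_rate - 1e-9)
      inc <- dh / abs(dh) * turn_rate
      turns <- cur_h + inc * seq_len(nturn)
      turns[nturn] <- cur_h + dh # final partial turn step lands exactly
      xs <- c(xs, rep(cx[i0], nturn))
      ys <- c(ys, rep(cy[i0], nturn))
      hs <- c(hs, turns)
      evs <- c(evs, rep("", nturn))
      cur_h <- cur_h + dh
    }
    # advance along the segment, clamping at the corner tile
    len <- (i1 - i0 + 1) # tiles in this segment
    nfwd <- ceiling(len / step - 1e-9)
    d <- pmin(step * seq_len(nfwd), len)
    ux <- cos(cur_h * pi / 180)
    uy <- -sin(cur_h * pi / 180)
    xs <- c(xs, cx[i0] + ux * d)
    ys <- c(ys, cy[i0] + uy * d)
    hs <- c(hs, rep(cur_h, nfwd))
    # an event fires on the first frame at or past its tile center
    seg_ev <- rep("", nfwd)
    for (i in (i0 + 1):(i1 + 1)) {
      if (ev_at(i) != "") {
        k <- which(d >= (i - i0) - 1e-9)[1]
        seg_ev[k] <- paste0(seg_ev[k], ev_at(i))
      }
    }
    evs <- c(evs, seg_ev)
  }
  out <- tibble::tibble(
    frame = seq_along(xs), x = xs, y = ys, heading = hs, event = evs
  )
  new_track(out, which(out$event != ""), fps, trial)
}

new_track <- function(poses, reward_events, fps, trial) {
  structure(poses,
    class = c("track", class(poses)),
    reward_events = reward_events, fps = fps, trial = trial
  )
}

#' @rdname simulate_track
#' @param track A `track`.
#' @export
track_duration <- function(track) {
  nrow(track) / attr(track, "fps")
}

#' @export
print.track <- function(x, ...) {
  cat(sprintf(
    "<track> %d frames (%.1f s at %g fps), %d pickups\n",
    nrow(x), track_duration(x), attr(x, "fps"), length(attr(x, "reward_events"))
  ))
  NextMethod()
}
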