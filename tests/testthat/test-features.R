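test_that("TR binning averages 60-frame windows and keeps partial bins", {
  expect_equal(bin_to_tr(1:120), c(30.5, 90.5))
  expect_equal(bin_to_tr(rep(3.7, 200)), rep(3.7, 4))
  expect_equal(length(bin_to_tr(1:130)), 3) # ceiling(130/60)
  expect_equal(bin_to_tr(1:130)[3], mean(121:130))
  expect_error(bin_to_tr(numeric(0)), "empty")
  # linearity: bin(a x + b y) = a bin(x) + b bin(y)
  withr::with_seed(5, {
    for (i in 1:20) {
      x <- rnorm(150)
      y <- rnorm(150)
      a <- rnorm(1)
      b <- rnorm(1)
      expect_equal(bin_to_tr(a * x + b * y), a * bin_to_tr(x) + b * bin_to_tr(y))
    }
  })
})

test_that("quadrant labels follow the TR-mean position with a masked band", {
  # stationary at the center of quadrant 1 (rows 2-10, cols 2-10)
  still <- tibble::tibble(
    frame = 1:120, x = 5.5, y = 5.5, heading = 0, event = ""
  )
  expect_equal(quadrant_location(still), c(1L, 1L))
  # stationary in the central band -> unassigned
  band <- tibble::tibble(frame = 1:60, x = 10.5, y = 10.5, heading = 0, event = "")
  expect_true(is.na(quadrant_location(band)))
  # a crossing track: label follows the TR-mean, verified per TR by brute force
  withr::with_seed(11, {
    for (rep in 1:5) {
      x <- cumsum(rnorm(240, 0, 0.3)) + 9
      y <- rep(5.5, 240)
      tr <- tibble::tibble(frame = 1:240, x = x, y = y, heading = 0, event = "")
      got <- quadrant_location(tr)
      rects <- quadrant_geometry()
      expected <- vapply(seq_along(got), function(t) {
        mx <- mean(x[((t - 1) * 60 + 1):min(t * 60, 240)])
        my <- mean(y[((t - 1) * 60 + 1):min(t * 60, 240)])
        hit <- which(my >= rects$row_min - 1 & my < rects$row_max &
          mx >= rects$col_min - 1 & mx < rects$col_max)
        if (length(hit)) hit else NA_integer_
      }, integer(1))
      expect_equal(got, expected)
    }
  })
})

test_that("picture visibility counts mask pixels exactly", {
  blank <- make_scene(matrix(0.5, 20, 20))
  expect_equal(picture_visibility(list(blank, blank)), matrix(0, 9, 2))
  full <- make_scene(matrix(0.5, 20, 20), matrix(3L, 20, 20))
  expect_equal(picture_visibility(list(full))[3, 1], 1)
  half_mask <- matrix(0L, 20, 20)
  half_mask[, 1:10] <- 7L
  expect_equal(picture_visibility(list(make_scene(matrix(0.1, 20, 20), half_mask)))[7, 1], 0.5)
})

test_that("rotational motion telescopes to the net heading change", {
  straight <- tibble::tibble(frame = 1:50, x = 1:50, y = 0, heading = 0, event = "")
  expect_equal(motion_path(straight), rep(0, 50))
  turn <- tibble::tibble(frame = 1:16, x = 0, y = 0, heading = c(0, seq(6, 90, by = 6)), event = "")
  expect_equal(motion_path(turn), c(0, rep(6, 15)))
  withr::with_seed(3, {
    for (i in 1:10) {
      h <- cumsum(rnorm(100, 0, 4))
      tr <- tibble::tibble(frame = 1:100, x = 0, y = 0, heading = h, event = "")
      expect_equal(sum(motion_path(tr)), h[100] - h[1])
    }
  })
  expect_error(motion_path(straight[1, ]), "2 frames")
})

test_that("reward timing marks the TRs of next-reward cues", {
  mk <- function(n_frames, events) {
    tr <- tibble::tibble(frame = 1:n_frames, x = 0, y = 0, heading = 0, event = "")
    attr(tr, "reward_events") <- events
    class(tr) <- c("track", class(tr))
    attr(tr, "fps") <- 20
    tr
  }
  # 5 pickups in distinct TRs: trial start + 4 reveal cues = 5 ones
  t1 <- mk(600, c(70, 190, 310, 430, 550))
  expect_equal(sum(reward_timing(t1)), 5)
  expect_equal(which(reward_timing(t1) == 1), c(1, 2, 4, 6, 8))
  # two cues inside one TR collapse to a single 1 there
  t2 <- mk(240, c(65, 80, 130, 190, 230))
  rt <- reward_timing(t2)
  expect_equal(rt, c(1, 1, 1, 1))
  # no pickups: only the trial-start cue
  t3 <- mk(120, integer(0))
  expect_equal(reward_timing(t3), c(1, 0))
})

test_that("the scene grid partitions any resolution into 28 regions", {
  for (res in list(c(100, 100), c(30, 40), c(150, 200), c(13, 17))) {
    g <- scene_grid(res[1], res[2])
    expect_equal(sort(unique(as.integer(g))), 1:28)
    expect_equal(length(g), res[1] * res[2]) # disjoint cover by construction
  }
  g <- scene_grid(100, 100)
  expect_equal(sum(g == 1), 400) # outer cells 20 x 20
  expect_equal(sum(g == 25), 100) # center subcells 10 x 10
  expect_error(scene_grid(5, 100), "at least 10 x 10")
})

test_that("scene RMS is the per-region population SD of luminance", {
  uni <- make_scene(matrix(0.42, 30, 40))
  expect_equal(scene_rms(list(uni)), matrix(0, 28, 1))
  # half-black / half-white region -> SD exactly 0.5
  g <- scene_grid(30, 40)
  lum <- matrix(0, 30, 40)
  reg1 <- which(g == 1)
  lum[reg1[seq_len(length(reg1) / 2)]] <- 1
  expect_equal(scene_rms(list(make_scene(lum)))[1, 1], 0.5)
  # random scenes match a brute-force oracle
  withr::with_seed(21, {
    for (i in 1:30) {
      sc <- make_scene(matrix(runif(30 * 40), 30, 40))
      got <- scene_rms(list(sc))[, 1]
      oracle <- vapply(1:28, function(r) {
        v <- sc$luminance[g == r]
        sqrt(mean((v - mean(v))^2))
      }, numeric(1))
      expect_equal(got, oracle)
    }
  })
})

test_that("scene Temp sums only positive luminance increments", {
  a <- make_scene(matrix(0.5, 30, 40))
  expect_equal(scene_temp(list(a, a)), matrix(0, 28, 2))
  darker <- make_scene(matrix(0.2, 30, 40))
  expect_equal(scene_temp(list(a, darker))[, 2], rep(0, 28)) # negatives discarded
  # single-pixel +0.2 step contributes 0.2 to its region
  g <- scene_grid(30, 40)
  lum2 <- matrix(0.5, 30, 40)
  px <- which(g == 9)[1]
  lum2[px] <- 0.7
  expect_equal(scene_temp(list(a, make_scene(lum2)))[9, 2], 0.2)
  # brute-force oracle on random frame pairs
  withr::with_seed(22, {
    for (i in 1:20) {
      s1 <- make_scene(matrix(runif(30 * 40), 30, 40))
      s2 <- make_scene(matrix(runif(30 * 40), 30, 40))
      got <- scene_temp(list(s1, s2))[, 2]
      oracle <- vapply(1:28, function(r) {
        sum(pmax(s2$luminance[g == r] - s1$luminance[g == r], 0))
      }, numeric(1))
      expect_equal(got, oracle)
    }
  })
})

test_that("the assembled variable set always holds 73 aligned variables", {
  behavior <- fx_behavior()
  vs <- behavior$variable_sets[[1]]
  counts <- table(vs$source[vs$tr == 1])
  expect_equal(
    as.integer(counts[c(
      "quadrant", "visibility", "motion", "reward",
      "scene_rms", "scene_temp"
    )]),
    c(6, 9, 1, 1, 28, 28)
  )
  expect_equal(sum(counts), 73)
  # all variables share the TR axis
  lens <- tapply(vs$tr, vs$variable, max)
  expect_true(all(lens == lens[1]))
  # quadrant pairs enumerate the 6 unordered pairs
  expect_setequal(
    unique(vs$variable[vs$source == "quadrant"]),
    c("q12", "q13", "q14", "q23", "q24", "q34")
  )
  # visibility bounded, scene statistics non-negative
  expect_true(all(vs$value[vs$source == "visibility"] >= 0 &
    vs$value[vs$source == "visibility"] <= 1))
  expect_true(all(vs$value[vs$source %in% c("scene_rms", "scene_temp")] >= 0))
})
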