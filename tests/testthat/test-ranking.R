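test_that("linear resampling preserves endpoints and order", {
  expect_equal(resample_linear(c(0, 1), 3), c(0, 0.5, 1))
  x <- c(2, 5, 1, 7)
  expect_equal(resample_linear(x, 4), x) # identity at source length
  withr::with_seed(15, {
    for (i in 1:20) {
      mono <- cumsum(runif(10))
      out <- resample_linear(mono, sample(2:30, 1))
      expect_true(all(diff(out) >= -1e-12))
      expect_equal(out[1], mono[1])
      expect_equal(out[length(out)], mono[10])
    }
  })
  expect_error(resample_linear(1, 5), "at least 2")
})

test_that("standardization yields exact zero mean and unit variance", {
  z <- standardize(c(1, 2, 3))
  expect_equal(mean(z), 0)
  expect_equal(stats::var(z), 1)
  expect_equal(standardize(rep(4, 6)), rep(0, 6))
  withr::with_seed(16, {
    for (i in 1:20) {
      x <- rnorm(sample(3:50, 1), sd = runif(1, 0.1, 10))
      expect_equal(standardize(standardize(x)), standardize(x))
    }
  })
})

test_that("the sum-of-squares mismatch matches hand computation", {
  expect_equal(ss_diff(c(1, 2, 3, 4), c(1, 2, 3, 4)), 0)
  expect_equal(ss_diff(c(1, 0, 2, -1), c(0, 1, 0, 1)), 1 + 1 + 4 + 4)
  expect_error(ss_diff(1:3, 1:4), "equal length")
  # uncorrelated standardized vectors have expected mismatch ~ 2n
  withr::with_seed(17, {
    n <- 40
    ssv <- replicate(400, ss_diff(standardize(rnorm(n)), standardize(rnorm(n))))
    expect_equal(mean(ssv), 2 * n, tolerance = 0.05)
  })
})

test_that("track ranking recovers the correct track and is null-calibrated", {
  lib <- toy_library(n_tracks = 20)
  # a library of one: the correct track must get rank 1
  lib1 <- toy_library(n_tracks = 1)
  p1 <- toy_predictions(lib1, 1, "motion", noise_sd = 0)
  rk1 <- rank_tracks(p1, lib1, correct_track = 1)
  expect_equal(attr(rk1, "correct_track_rank"), 1)
  # exact predictions give rank 1 with zero mismatch
  p <- toy_predictions(lib, 7, "motion", noise_sd = 0)
  rk <- rank_tracks(p, lib, correct_track = 7)
  expect_equal(attr(rk, "correct_track_rank"), 1)
  expect_equal(rk$ss_diff[rk$track == "7"], 0, tolerance = 1e-9)
  # random predictions: mean normalized rank within the Monte-Carlo CI of 0.5
  withr::with_seed(18, {
    nr <- vapply(1:100, function(i) {
      correct <- sample(20, 1)
      pr <- tibble::tibble(
        variable = "motion", tr = 1:20, predicted = rnorm(20)
      )
      attr(rank_tracks(pr, lib, correct_track = correct), "normalized_rank")
    }, numeric(1))
    se <- stats::sd(nr) / sqrt(length(nr))
    expect_lt(abs(mean(nr) - 0.5), 1.96 * se + 0.02)
  })
})

test_that("chance and normalized ranks follow the pool-size formulas", {
  expect_equal(chance_rank(18), 9.5)
  expect_equal(chance_rank(1), 1)
  expect_equal(chance_rank(390), 195.5)
  expect_equal(normalized_rank(chance_rank(18), 18), 0.5)
  for (n in c(2, 7, 106, 390)) {
    expect_equal(normalized_rank(chance_rank(n), n), 0.5)
  }
  expect_equal(normalized_rank(1, 390), 1 / 391)
  expect_lt(normalized_rank(390, 390), 1)
  expect_error(normalized_rank(0.5, 10), "rank")
})

test_that("combination weights interpolate between perfect and chance", {
  expect_equal(combination_weight(1, 20), 1)
  expect_equal(combination_weight(chance_rank(20), 20), 0)
  expect_equal(combination_weight(chance_rank(20) + 3, 20), 0) # floored
  expect_equal(combination_weight(5.75, 20), 0.5)
})

test_that("weighted rank combination is consistent and exploits complementarity", {
  rk <- tibble::tibble(
    combination = "a", track = as.character(1:5), rank = c(2, 1, 4, 3, 5)
  )
  # a single combination reproduces itself
  out <- combine_rankings(rk, c(a = 1))
  expect_equal(out$rank[match(rk$track, out$track)], rk$rank)
  # identical rankings are invariant under any weights
  rk2 <- dplyr::bind_rows(rk, dplyr::mutate(rk, combination = "b"))
  out2 <- combine_rankings(rk2, c(a = 0.2, b = 0.9))
  expect_equal(out2$rank[match(rk$track, out2$track)], rk$rank)
  expect_error(combine_rankings(rk2, c(a = 0, b = 0)), "zero")

  # complementary information: source A confuses half the foils, source B
  # the other half; the weighted combination beats both
  withr::with_seed(19, {
    n_pool <- 21
    ranks_a <- ranks_b <- ranks_c <- numeric(40)
    for (i in 1:40) {
      a_conf <- 2:11 # foils identical to the correct track in source A
      b_conf <- 12:21
      ss_a <- c(0, rep(0, 10), runif(10, 2, 6)) + stats::rnorm(n_pool, 0, 0.2)^2
      ss_b <- c(0, runif(10, 2, 6), rep(0, 10)) + stats::rnorm(n_pool, 0, 0.2)^2
      rka <- rank(ss_a, ties.method = "average")
      rkb <- rank(ss_b, ties.method = "average")
      comb <- combine_rankings(
        tibble::tibble(
          combination = rep(c("A", "B"), each = n_pool),
          track = as.character(rep(1:n_pool, 2)),
          rank = c(rka, rkb)
        ),
        c(A = 0.5, B = 0.5)
      )
      ranks_a[i] <- rka[1]
      ranks_b[i] <- rkb[1]
      ranks_c[i] <- comb$rank[comb$track == "1"]
    }
    expect_lt(mean(ranks_c), min(mean(ranks_a), mean(ranks_b)))
    expect_lt(mean(ranks_c), 2.5)
  })
})

test_that("weights from an independent split barely change combined ranks", {
  # same-split vs split-half weighting on a constructed two-source problem
  withr::with_seed(20, {
    lib <- toy_library(n_tracks = 20, seed = 31)
    trials <- 1:16
    per_combo <- lapply(c(motion = "motion", visibility = "visibility"), function(src) {
      lapply(trials, function(tri) {
        p <- toy_predictions(lib, tri, src, noise_sd = 1, seed = tri + 57 * nchar(src))
        rank_tracks(p, lib, correct_track = tri)
      })
    })
    cr <- function(src, tris) {
      mean(vapply(
        tris,
        function(tri) attr(per_combo[[src]][[tri]], "correct_track_rank"),
        numeric(1)
      ))
    }
    combine_with <- function(weights, tris) {
      vapply(tris, function(tri) {
        rk <- dplyr::bind_rows(
          dplyr::mutate(tibble::as_tibble(per_combo$motion[[tri]]), combination = "m"),
          dplyr::mutate(tibble::as_tibble(per_combo$visibility[[tri]]), combination = "v")
        )
        out <- combine_rankings(rk[, c("combination", "track", "rank")], weights)
        out$rank[out$track == as.character(tri)]
      }, numeric(1))
    }
    w_same <- c(
      m = combination_weight(cr("motion", trials), 20),
      v = combination_weight(cr("visibility", trials), 20)
    )
    half1 <- trials[1:8]
    half2 <- trials[9:16]
    w_half1 <- c(
      m = combination_weight(cr("motion", half2), 20),
      v = combination_weight(cr("visibility", half2), 20)
    )
    w_half2 <- c(
      m = combination_weight(cr("motion", half1), 20),
      v = combination_weight(cr("visibility", half1), 20)
    )
    same <- mean(combine_with(w_same, trials))
    split <- mean(c(combine_with(w_half1, half1), combine_with(w_half2, half2)))
    expect_lt(abs(same - split), 2)
  })
})
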