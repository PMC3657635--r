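#' Empirical null distribution of normalized correct-track ranks
#'
#' Builds the chance distribution from decodings that carry no information —
#' in practice, classifiers trained and tested on white-matter voxel
#' signals. Under the null the normalized correct-track rank is centered on
#' 0.5.
#'
#' @param values Normalized correct-track ranks from non-informative
#'   decodings (at least 10).
#' @return A `null_distribution`: list with `values`, `mean`, `sd` (sample
#'   SD), and fitted normal parameters.
#' @export
build_null <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 10) rlang::abort("null distribution needs at least 10 values")
  structure(
    list(
      values = values, mean = mean(values), sd = stats::sd(values),
      normal = c(mean = mean(values), sd = stats::sd(values))
    ),
    class = "null_distribution"
  )
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf(
    "<null_distribution> n = %d, mean = %.3f, sd = %.3f\n",
    length(x$values), x$mean, x$sd
  ))
  invisible(x)
}

#' Significance threshold from the empirical null
#'
#' A normalized correct-track rank is called significant when it falls more
#' than `k_sd` standard deviations below the null mean; with k = 2.4 and a
#' normal null this corresponds to a one-sided level of about 0.01.
#'
#' @param null A [build_null()] result.
#' @param k_sd Number of null SDs below the mean (default 2.4).
#' @return The threshold `mean - k_sd * sd` (significant = rank at or below
#'   it).
#' @export
#' @examples
#' nd <- build_null(c(rep(0.482, 20))) # degenerate example
#' significance_threshold(nd)
significance_threshold <- function(null, k_sd = 2.4) {
  stopifnot(inherits(null, "null_distribution"))
  null$mean - k_sd * null$sd
}

#' Resampled distribution of k-value means under the null
#'
#' Draws `k` values without replacement from the null values, averages them,
#' and repeats; returns the mean and SD of the resulting mean-of-k
#' distribution. Used to judge whether a combination's mean rank across
#' several sessions could arise by chance.
#'
#' @param null_values Numeric null values.
#' @param k Values per draw (default 6).
#' @param reps Number of resamples (default 5000).
#' @param seed Integer seed.
#' @return List with `mean`, `sd`, and the resampled `means`.
#' @export
mean_of_k_null <- function(null_values, k = 6, reps = 5000, seed = 1L) {
  if (k > length(null_values)) rlang::abort("k exceeds the number of null values")
  means <- withr::with_seed(as.integer(seed), {
    vapply(
      seq_len(reps),
      function(i) mean(sample(null_values, k)), numeric(1)
    )
  })
  list(mean = mean(means), sd = stats::sd(means), means = means)
}

#' Correct-track rank as a function of time points used
#'
#' Re-ranks the candidate pool using only the first `t` TRs of the predicted
#' traces (re-sampling and standardization are redone on the truncated
#' window), for t = 2..`max_t`. With informative decoding the correct-track
#' rank improves as time points accumulate.
#'
#' @param predictions Per-trial predicted traces: tibble with `trial`,
#'   `variable`, `tr`, `predicted`.
#' @param library A [track_library()]; track names must match `trial` ids.
#' @param max_t Largest number of leading TRs to use (defaults to the
#'   longest predicted trace).
#' @param t_grid Optional explicit vector of time-point counts (>= 2).
#' @return Tibble with `t`, `mean_rank`, `mean_normalized_rank`.
#' @export
timepoint_curve <- function(predictions, library, max_t = NULL, t_grid = NULL) {
  lens <- tapply(predictions$tr, predictions$trial, max)
  max_t <- max_t %||% max(lens)
  if (max_t > max(lens)) rlang::abort("max_t exceeds the longest predicted trace")
  t_grid <- t_grid %||% seq(2, max_t)
  n <- attr(library, "n_tracks")
  rows <- lapply(t_grid, function(tt) {
    ranks <- vapply(unique(predictions$trial), function(tri) {
      pred <- predictions[predictions$trial == tri & predictions$tr <= tt, ]
      # truncate the library to the same leading window (proportionally)
      rk <- rank_tracks_window(pred, library, tt, max(lens[[as.character(tri)]]))
      rk$rank[rk$track == as.character(tri)]
    }, numeric(1))
    tibble::tibble(
      t = tt, mean_rank = mean(ranks),
      mean_normalized_rank = mean(normalized_rank(ranks, n))
    )
  })
  dplyr::bind_rows(rows)
}

# rank using only the leading fraction t/full of every trace
rank_tracks_window <- function(predictions, library, t, full_len) {
  L <- attr(library, "common_length")
  Lw <- max(2L, round(L * t / full_len))
  tracks <- attr(library, "tracks")
  frac <- t / full_len
  ss <- stats::setNames(numeric(length(tracks)), tracks)
  for (v in unique(predictions$variable)) {
    pv <- predictions[predictions$variable == v, ]
    pv <- pv[order(pv$tr), ]
    if (nrow(pv) < 2) next
    zp <- standardize(resample_linear(pv$predicted, Lw))
    lv <- library[library$variable == v, ]
    for (tk in tracks) {
      av <- lv$value[lv$track == tk][order(lv$tr[lv$track == tk])]
      keep <- seq_len(max(2L, round(length(av) * frac)))
      av <- av[pmin(keep, length(av))]
      if (length(av) < 2) next
      za <- standardize(resample_linear(av, Lw))
      ss[tk] <- ss[tk] + sum((zp - za)^2)
    }
  }
  tibble::tibble(track = tracks, ss_diff = as.numeric(ss), rank = rank(ss, ties.method = "average"))
}

#' Foil-similarity analysis
#'
#' Tests whether candidate tracks that resemble the correct track in one
#' information source confuse decoding based on that source: per trial, the
#' foils are scored by their similarity to the correct track (sum-of-squares
#' distance between their standardized actual traces for the named source),
#' and the mean assigned rank of the `n_group` most similar foils is
#' compared with that of the `n_group` least similar foils by a paired
#' t-test plus a sign-flip permutation test across trials.
#'
#' @param library A [track_library()].
#' @param rankings Tibble with `trial`, `track`, `rank` (e.g. combined
#'   rankings; track names must match library tracks, trial ids name the
#'   correct track).
#' @param similarity_source Information source used to score similarity.
#' @param n_group Foils per group (default 5).
#' @param n_perm Sign flips for the permutation test (default 10000).
#' @param seed Integer seed for the permutation draws.
#' @return List with `per_trial` tibble (trial, mean_rank_similar,
#'   mean_rank_dissimilar), group means, `t_test` and `perm_p`.
#' @export
similarity_analysis <- function(library, rankings, similarity_source,
                                n_group = 5, n_perm = 10000, seed = 1L) {
  if (attr(library, "n_tracks") < 2 * n_group + 1) {
    rlang::abort("candidate pool too small for the similarity grouping")
  }
  vars <- unique(library$variable[library$source == similarity_source])
  if (length(vars) == 0) rlang::abort("unknown similarity source")
  z_act <- attr(library, "z_actual")
  tracks <- attr(library, "tracks")
  sim_to <- function(correct) {
    d <- numeric(length(tracks))
    for (v in vars) {
      m <- z_act[[v]]
      d <- d + rowSums((m - matrix(m[correct, ],
        length(tracks), ncol(m),
        byrow = TRUE
      ))^2, na.rm = TRUE)
    }
    stats::setNames(d, tracks)
  }
  rows <- lapply(unique(rankings$trial), function(tri) {
    correct <- as.character(tri)
    d <- sim_to(correct)
    foils <- setdiff(tracks, correct)
    ord <- foils[order(d[foils])]
    most <- utils::head(ord, n_group)
    least <- utils::tail(ord, n_group)
    rk <- rankings[rankings$trial == tri, ]
    tibble::tibble(
      trial = tri,
      mean_rank_similar = mean(rk$rank[match(most, rk$track)]),
      mean_rank_dissimilar = mean(rk$rank[match(least, rk$track)])
    )
  })
  per_trial <- dplyr::bind_rows(rows)
  diffs <- per_trial$mean_rank_similar - per_trial$mean_rank_dissimilar
  tt <- stats::t.test(diffs)
  perm_p <- withr::with_seed(as.integer(seed), {
    obs <- mean(diffs)
    flips <- vapply(seq_len(n_perm), function(i) {
      mean(diffs * sample(c(-1, 1), length(diffs), replace = TRUE))
    }, numeric(1))
    mean(abs(flips) >= abs(obs))
  })
  list(
    per_trial = per_trial,
    mean_similar = mean(per_trial$mean_rank_similar),
    mean_dissimilar = mean(per_trial$mean_rank_dissimilar),
    t_test = tt, perm_p = perm_p
  )
}

#' Percent of trials identified exactly
#'
#' The percentage of trials whose correct track obtained rank 1.
#'
#' @param correct_ranks Numeric vector of per-trial correct-track ranks.
#' @return Percentage in \[0, 100\].
#' @export
#' @examples
#' identification_accuracy(c(1, 1, 2, 1)) # 75
identification_accuracy <- function(correct_ranks) {
  if (length(correct_ranks) < 1) rlang::abort("needs at least one trial")
  100 * mean(correct_ranks <= 1 + 1e-9)
}
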