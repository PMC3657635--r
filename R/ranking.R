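#' Linear resampling of a per-TR series
#'
#' Re-samples a series by linear interpolation onto a uniform grid of
#' `target_length` points so that traces from tracks of different durations
#' become comparable; endpoints are preserved.
#'
#' @param x Numeric series (length >= 2).
#' @param target_length Target number of samples (>= 2).
#' @return Numeric series of length `target_length`.
#' @export
#' @examples
#' resample_linear(c(0, 1), 3) # c(0, 0.5, 1)
resample_linear <- function(x, target_length) {
  if (length(x) < 2 || target_length < 2) {
    rlang::abort("resampling needs source and target lengths of at least 2")
  }
  stats::approx(seq_along(x), x, n = target_length)$y
}

#' Standardize a vector to mean 0, variance 1
#'
#' Zero-variance input is returned as all zeros so that degenerate constant
#' variables contribute nothing to the mismatch rather than aborting a trial.
#'
#' @param x Numeric vector.
#' @return Standardized vector.
#' @export
standardize <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) {
    return(rep(0, length(x)))
  }
  (x - mean(x)) / s
}

#' Sum-of-squares mismatch between predicted and actual traces
#'
#' @param predicted,actual Equal-length numeric vectors (concatenated
#'   standardized variable traces).
#' @return `sum((predicted - actual)^2)`.
#' @export
ss_diff <- function(predicted, actual) {
  if (length(predicted) != length(actual)) {
    rlang::abort("predicted and actual traces must have equal length")
  }
  sum((predicted - actual)^2)
}

#' Build a candidate-track library
#'
#' Collects the actual per-TR variable traces of every candidate track. The
#' common comparison length is the TR count of the longest track in the
#' pool.
#'
#' @param variable_sets Named list of [variable_set][build_variable_set]
#'   tibbles (or any tibble with `variable`, `tr`, `value`), one per
#'   candidate track.
#' @return A `track_library` tibble with columns `track`, `variable`, `tr`,
#'   `value` and attributes `common_length` and `n_tracks`.
#' @export
track_library <- function(variable_sets) {
  stopifnot(length(variable_sets) >= 1)
  if (is.null(names(variable_sets))) {
    names(variable_sets) <- seq_along(variable_sets)
  }
  out <- dplyr::bind_rows(
    lapply(variable_sets, function(v) v[, c("source", "variable", "tr", "value")]),
    .id = "track"
  )
  lens <- dplyr::summarise(dplyr::group_by(out, .data$track),
    len = max(.data$tr), .groups = "drop"
  )
  L <- max(lens$len)
  tracks <- unique(out$track)
  # cache the standardized, resampled actual trace of every variable x track
  z_actual <- lapply(split(out, out$variable), function(lv) {
    m <- t(vapply(tracks, function(tk) {
      av <- lv$value[lv$track == tk][order(lv$tr[lv$track == tk])]
      if (length(av) < 2) return(rep(NA_real_, L))
      standardize(resample_linear(av, L))
    }, numeric(L)))
    rownames(m) <- tracks
    m
  })
  structure(out,
    class = c("track_library", class(out)),
    common_length = L, n_tracks = length(tracks), tracks = tracks,
    z_actual = z_actual
  )
}

#' Rank candidate tracks by predicted-trace mismatch
#'
#' For one trial and one set of predicted variable traces: per variable, the
#' predicted trace and every candidate track's actual trace are re-sampled
#' to the pool's common length and standardized separately; the per-variable
#' traces are concatenated and the sum-of-squares difference to each
#' candidate computed. Candidates are ranked by this mismatch, smallest
#' first, with midranks on ties.
#'
#' @param predictions Tibble with columns `variable`, `tr`, `predicted` —
#'   the calibrated predicted traces of the variables to use.
#' @param library A [track_library()].
#' @param correct_track Name of the true track in the library (optional; adds
#'   correct-track rank summaries).
#' @return A `rank_stats` tibble (track, ss_diff, rank) with attributes
#'   `correct_track_rank`, `normalized_rank`, `n_tracks`.
#' @export
rank_tracks <- function(predictions, library, correct_track = NULL) {
  stopifnot(inherits(library, "track_library"))
  L <- attr(library, "common_length")
  z_act <- attr(library, "z_actual")
  vars <- unique(predictions$variable)
  if (length(vars) == 0) rlang::abort("no predicted variables supplied")
  tracks <- attr(library, "tracks")
  ss <- stats::setNames(numeric(length(tracks)), tracks)
  for (v in vars) {
    pv <- predictions[predictions$variable == v, ]
    pv <- pv[order(pv$tr), ]
    if (nrow(pv) < 2 || is.null(z_act[[v]])) next
    zp <- standardize(resample_linear(pv$predicted, L))
    d <- z_act[[v]] - matrix(zp, length(tracks), L, byrow = TRUE)
    ss <- ss + rowSums(d * d, na.rm = TRUE)
  }
  out <- tibble::tibble(
    track = tracks, ss_diff = unname(as.numeric(ss)),
    rank = unname(rank(ss, ties.method = "average"))
  )
  class(out) <- c("rank_stats", class(out))
  attr(out, "n_tracks") <- length(tracks)
  if (!is.null(correct_track)) {
    cr <- unname(out$rank[out$track == as.character(correct_track)])
    attr(out, "correct_track_rank") <- cr
    attr(out, "normalized_rank") <- normalized_rank(cr, length(tracks))
  }
  out
}

#' Chance level of the correct-track rank
#'
#' With `n` alternative tracks and no decodable information, the expected
#' rank of the correct track is `(n + 1) / 2`.
#'
#' @param n_tracks Number of alternative tracks (>= 1).
#' @export
#' @examples
#' chance_rank(18) # 9.5
chance_rank <- function(n_tracks) {
  stopifnot(n_tracks >= 1)
  (n_tracks + 1) / 2
}

#' @rdname chance_rank
#' @param rank Correct-track rank in \[1, n_tracks\].
#' @return `normalized_rank()`: `rank / (n_tracks + 1)`; 0.5 at chance.
#' @export
normalized_rank <- function(rank, n_tracks) {
  if (any(rank < 1 - 1e-9) || any(rank > n_tracks + 1e-9)) {
    rlang::abort("rank must lie in [1, n_tracks]")
  }
  rank / (n_tracks + 1)
}

#' Combination weights from calibration performance
#'
#' The weight of a source x ROI combination is an inverse linear function of
#' its mean correct-track rank: rank 1 gives weight 1, chance rank
#' `(n + 1) / 2` gives weight 0, and worse-than-chance combinations are
#' floored at 0.
#'
#' @param mean_rank Mean correct-track rank of the combination.
#' @param n_tracks Candidate-pool size.
#' @export
combination_weight <- function(mean_rank, n_tracks) {
  rc <- chance_rank(n_tracks)
  if (rc <= 1) {
    return(ifelse(mean_rank <= 1, 1, 0))
  }
  pmax(0, (rc - mean_rank) / (rc - 1))
}

#' Combine rankings across source x ROI combinations
#'
#' Computes, per candidate track, the weighted average of its ranks across
#' combinations, and re-ranks candidates by this combined score (midranks on
#' ties).
#'
#' @param rankings Tibble with columns `combination`, `track`, `rank` (one
#'   trial's rankings from several combinations over the same pool).
#' @param weights Named numeric vector of weights per combination (values in
#'   \[0, 1\], at least one positive).
#' @return A `rank_stats` tibble with columns `track`, `score` (weighted
#'   mean rank) and `rank`.
#' @export
combine_rankings <- function(rankings, weights) {
  w <- weights[as.character(rankings$combination)]
  if (any(is.na(w))) rlang::abort("every combination needs a weight")
  if (sum(weights) <= 0) rlang::abort("all-zero combination weights")
  comb <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(track = rankings$track, rank = rankings$rank, w = w),
      .data$track,
      .drop = TRUE
    ),
    score = sum(.data$rank * .data$w) / sum(.data$w), .groups = "drop"
  )
  comb$rank <- rank(comb$score, ties.method = "average")
  class(comb) <- c("rank_stats", class(comb))
  comb
}
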