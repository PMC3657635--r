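#' Tidy and glance methods for experiment results
#'
#' `tidy()` returns the per-combination summary (one row per source x ROI:
#' mean correct-track rank, normalized rank, combination weight,
#' significance flag). `glance()` returns a one-row experiment summary.
#'
#' @param x A `navdecode_experiment` from [run_experiment()].
#' @param ... Unused.
#' @return A tibble.
#' @exportS3Method generics::tidy
tidy.navdecode_experiment <- function(x, ...) {
  w <- dplyr::summarise(
    dplyr::group_by(x$weights, .data$combination),
    weight = mean(.data$weight), .groups = "drop"
  )
  dplyr::left_join(x$report, w, by = "combination")
}

#' @rdname tidy.navdecode_experiment
#' @exportS3Method generics::glance
glance.navdecode_experiment <- function(x, ...) {
  tibble::tibble(
    n_trials = nrow(x$trials),
    n_sessions = x$config$n_sessions,
    n_tracks = x$combined$n_tracks[1],
    n_combinations = nrow(x$report),
    n_significant = sum(x$report$significant),
    combined_mean_rank = mean(x$combined$rank),
    combined_mean_normalized_rank = mean(x$combined$normalized),
    identification_pct = x$identification,
    chance_rank = chance_rank(x$combined$n_tracks[1]),
    threshold = x$threshold
  )
}

#' @rdname tidy.navdecode_experiment
#' @exportS3Method generics::tidy
tidy.decoder_cv <- function(x, ...) {
  out <- x$stats %||% tibble::tibble(
    H = NA_real_, F = NA_real_, dprime = NA_real_, P = NA_real_
  )
  dplyr::mutate(tibble::as_tibble(out),
    variable = x$variable, source = x$source,
    n_skipped = length(x$skipped), .before = 1
  )
}
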