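#' Experiment configuration
#'
#' Collects every tunable of the synthetic end-to-end experiment in one
#' object. All randomness flows from `seed`; re-running a config reproduces
#' the experiment exactly.
#'
#' @param maze A [maze_map][load_maze] (default: the bundled layout).
#' @param n_sessions Number of scan sessions (runs).
#' @param trials_per_session Trials per session.
#' @param rois Named integer vector of ROI voxel counts (names from
#'   V1, Ve, Pa, M1, PM, Hi, WM).
#' @param snr Encoding signal-to-noise ratio (see [default_roi_profiles()]).
#' @param sources Information sources to decode (default all six).
#' @param width,height,fov Renderer resolution and field of view.
#' @param fps Frame rate (frames/s).
#' @param tr_s TR in seconds; `frames_per_tr = fps * tr_s`.
#' @param lag_trs Hemodynamic lag in TRs.
#' @param turn_rate Turn speed (degrees/frame).
#' @param detour_prob Route suboptimality (see [plan_route()]).
#' @param duration_range Plausible trial-duration range in seconds; routes
#'   shorter than the minimum are re-planned with extra detours.
#' @param cost SVM regularization parameter.
#' @param pool Candidate pool: `"all"` tracks of the experiment or
#'   per-`"session"` tracks.
#' @param weight_source `"other-session"` (weights for a trial's combination
#'   come from the other sessions' correct-track ranks; falls back to same
#'   when there is a single session) or `"same"`.
#' @param seed Integer master seed.
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(maze = default_maze(), n_sessions = 2,
                              trials_per_session = 12,
                              rois = c(
                                V1 = 120, Ve = 100, Pa = 80, M1 = 40,
                                PM = 60, Hi = 50, WM = 100
                              ),
                              snr = 1,
                              sources = c(
                                "quadrant", "visibility", "motion",
                                "reward", "scene_rms", "scene_temp"
                              ),
                              width = 40, height = 30, fov = 60, fps = 20,
                              tr_s = 3, lag_trs = 2, turn_rate = 6,
                              detour_prob = 0.15,
                              duration_range = c(57, 195), cost = 1,
                              pool = c("all", "session"),
                              weight_source = c("other-session", "same"),
                              seed = 1L) {
  structure(
    list(
      maze = maze, n_sessions = n_sessions,
      trials_per_session = trials_per_session, rois = rois, snr = snr,
      sources = sources, width = width, height = height, fov = fov,
      fps = fps, tr_s = tr_s, frames_per_tr = as.integer(round(fps * tr_s)),
      lag_trs = lag_trs, turn_rate = turn_rate, detour_prob = detour_prob,
      duration_range = duration_range, cost = cost,
      pool = match.arg(pool), weight_source = match.arg(weight_source),
      seed = as.integer(seed)
    ),
    class = "experiment_config"
  )
}

#' Simulate the behavioral side of an experiment
#'
#' Samples every trial's doors/reward-order/start, plans and simulates the
#' routes (re-planning with a higher detour probability until the trial
#' duration reaches the plausible minimum), renders the scenes, and extracts
#' the 73 decoding variables per trial.
#'
#' @param config An [experiment_config()].
#' @return List with `trials` (tibble: trial, session, seed, n_tr,
#'   duration_s), `variable_sets` (named list of per-trial
#'   [variable_set][build_variable_set]s; names are trial ids), `tracks`
#'   (named list of [track][simulate_track]s) and `library`
#'   (a [track_library()] over all trials).
#' @export
simulate_behavior <- function(config) {
  n_tot <- config$n_sessions * config$trials_per_session
  ids <- as.character(seq_len(n_tot))
  sessions <- rep(seq_len(config$n_sessions), each = config$trials_per_session)
  tracks <- vector("list", n_tot)
  varsets <- vector("list", n_tot)
  seeds <- config$seed + 101L * seq_len(n_tot)
  for (i in seq_len(n_tot)) {
    trial <- sample_trial(config$maze, seeds[i])
    tr <- NULL
    for (dp in config$detour_prob + seq(0, 0.6, by = 0.1)) {
      route <- plan_route(config$maze, trial, detour_prob = dp, seed = seeds[i])
      cand <- simulate_track(route, trial,
        turn_rate = config$turn_rate, fps = config$fps
      )
      tr <- cand
      if (track_duration(cand) >= config$duration_range[1]) break
    }
    tracks[[i]] <- tr
    varsets[[i]] <- build_variable_set(
      config$maze, tr, trial,
      width = config$width, height = config$height, fov = config$fov,
      frames_per_tr = config$frames_per_tr
    )
  }
  names(tracks) <- ids
  names(varsets) <- ids
  trials <- tibble::tibble(
    trial = ids, session = sessions, seed = seeds,
    n_tr = vapply(varsets, function(v) max(v$tr), numeric(1)),
    duration_s = vapply(tracks, track_duration, numeric(1))
  )
  list(
    trials = trials, variable_sets = varsets, tracks = tracks,
    library = track_library(varsets)
  )
}

#' Synthesize, prepare and align ROI signals for an experiment
#'
#' Generates one voxel run per ROI and session from the behavioral
#' variables, normalizes each run (grand-mean removal + quadratic detrend),
#' and aligns signal to variables under the hemodynamic lag. Sessions are
#' concatenated per ROI with globally unique trial ids.
#'
#' @param behavior A [simulate_behavior()] result.
#' @param config The [experiment_config()].
#' @return Named list (per ROI) of aligned sets as returned by
#'   [align_to_variables()].
#' @export
synthesize_signals <- function(behavior, config) {
  profiles <- default_roi_profiles(
    snr = config$snr, n_voxels = config$rois, seed = config$seed + 7L
  )
  out <- list()
  for (roi in names(config$rois)) {
    parts <- list()
    for (s in seq_len(config$n_sessions)) {
      ids <- behavior$trials$trial[behavior$trials$session == s]
      mats <- lapply(behavior$variable_sets[ids], as_variable_matrix)
      X <- do.call(rbind, mats)
      lens <- vapply(mats, nrow, integer(1))
      ends <- cumsum(lens)
      bounds <- tibble::tibble(
        trial = ids, start = c(1L, utils::head(ends, -1) + 1L), end = ends
      )
      spec <- profiles[[roi]]
      spec$lag_trs <- as.integer(config$lag_trs)
      run <- synthesize_run(
        spec, X,
        trial_bounds = bounds, run_id = s,
        seed = config$seed + 7919L * s + 13L * match(roi, names(config$rois))
      )
      parts[[s]] <- align_to_variables(normalize_run(run), X, config$lag_trs)
    }
    out[[roi]] <- list(
      X = do.call(rbind, lapply(parts, `[[`, "X")),
      V = do.call(rbind, lapply(parts, `[[`, "V")),
      trial = unlist(lapply(parts, `[[`, "trial")),
      tr = unlist(lapply(parts, `[[`, "tr"))
    )
  }
  out
}

#' Decode every variable in every ROI
#'
#' Runs [leave_one_trial_out()] for each variable of the configured sources
#' in each ROI.
#'
#' @param aligned_rois A [synthesize_signals()] result.
#' @param config The [experiment_config()].
#' @return List with `accuracy` (tibble: roi, source, variable, H, F,
#'   dprime, P, n_skipped) and `predictions` (tibble: roi, source, variable,
#'   trial, tr, dv, predicted, label).
#' @export
decode_experiment <- function(aligned_rois, config) {
  roster <- variable_roster()
  roster <- roster[roster$source %in% config$sources, ]
  acc <- list()
  preds <- list()
  for (roi in names(aligned_rois)) {
    for (i in seq_len(nrow(roster))) {
      cv <- leave_one_trial_out(
        aligned_rois[[roi]], roster$variable[i],
        source = roster$source[i], cost = config$cost,
        seed = config$seed + 31L * i
      )
      if (!is.null(cv$stats)) {
        acc[[length(acc) + 1]] <- tibble::tibble(
          roi = roi, source = cv$source, variable = cv$variable,
          H = cv$stats$H, F = cv$stats$F, dprime = cv$stats$dprime,
          P = cv$stats$P, n_skipped = length(cv$skipped)
        )
      }
      if (nrow(cv$predictions) > 0) {
        preds[[length(preds) + 1]] <- dplyr::mutate(cv$predictions,
          roi = roi, source = cv$source, variable = cv$variable,
          .before = 1
        )
      }
    }
  }
  list(accuracy = dplyr::bind_rows(acc), predictions = dplyr::bind_rows(preds))
}

#' Rank candidate tracks for every trial and combination
#'
#' For each source x ROI combination and each trial, ranks the candidate
#' pool by the sum-of-squares mismatch between the trial's predicted traces
#' and each candidate's actual traces.
#'
#' @param predictions The `predictions` tibble from [decode_experiment()].
#' @param behavior The [simulate_behavior()] result.
#' @param config The [experiment_config()].
#' @return List with `rankings` (tibble: roi, source, trial, track, ss_diff,
#'   rank) and `correct_ranks` (tibble: roi, source, trial, session,
#'   n_tracks, rank, normalized).
#' @export
rank_experiment <- function(predictions, behavior, config) {
  trials <- behavior$trials
  libs <- if (config$pool == "all") {
    list(all = behavior$library)
  } else {
    lapply(
      split(trials$trial, trials$session),
      function(ids) track_library(behavior$variable_sets[ids])
    )
  }
  ranks <- list()
  for (roi in unique(predictions$roi)) {
    for (src in unique(predictions$source)) {
      pr <- predictions[predictions$roi == roi & predictions$source == src, ]
      if (nrow(pr) == 0) next
      for (tri in unique(pr$trial)) {
        lib <- if (config$pool == "all") {
          libs$all
        } else {
          libs[[as.character(trials$session[trials$trial == as.character(tri)])]]
        }
        pvt <- pr[pr$trial == tri, ]
        rk <- rank_tracks(
          pvt[, c("variable", "tr", "predicted")], lib,
          correct_track = as.character(tri)
        )
        ranks[[length(ranks) + 1]] <- dplyr::mutate(
          tibble::as_tibble(rk),
          roi = roi, source = src, trial = as.character(tri), .before = 1
        )
      }
    }
  }
  rankings <- dplyr::bind_rows(ranks)
  correct <- dplyr::filter(rankings, .data$track == .data$trial)
  correct <- dplyr::mutate(correct,
    session = trials$session[match(.data$trial, trials$trial)]
  )
  correct$n_tracks <- if (config$pool == "all") {
    attr(behavior$library, "n_tracks")
  } else {
    config$trials_per_session
  }
  correct$normalized <- normalized_rank(correct$rank, correct$n_tracks)
  list(
    rankings = rankings[, c("roi", "source", "trial", "track", "ss_diff", "rank")],
    correct_ranks = correct[, c(
      "roi", "source", "trial", "session",
      "n_tracks", "rank", "normalized"
    )]
  )
}

#' Run the full synthetic decoding experiment
#'
#' Sequences behavior simulation, signal synthesis and preparation,
#' per-variable decoding, track ranking, rank combination, and evaluation.
#'
#' @param config An [experiment_config()].
#' @return A `navdecode_experiment`: list with `config`, `trials`,
#'   `accuracy`, `predictions`, `correct_ranks`, `rankings`, `weights`,
#'   `combined` (per-trial combined correct-track rank), `null` (white-matter
#'   [build_null()] when available), `threshold`, and `report` (per-combo
#'   summary with significance flags). Has [tidy()][generics::tidy],
#'   [glance()][generics::glance] and [autoplot()][ggplot2::autoplot]
#'   methods.
#' @export
run_experiment <- function(config = experiment_config()) {
  behavior <- simulate_behavior(config)
  aligned <- synthesize_signals(behavior, config)
  decoded <- decode_experiment(aligned, config)
  ranked <- rank_experiment(decoded$predictions, behavior, config)
  evaluate_experiment(behavior, decoded, ranked, config)
}

#' @rdname run_experiment
#' @param behavior,decoded,ranked Intermediate stage results (see
#'   [simulate_behavior()], [decode_experiment()], [rank_experiment()]).
#' @export
evaluate_experiment <- function(behavior, decoded, ranked, config) {
  cr <- ranked$correct_ranks
  cr$combination <- paste(cr$source, cr$roi, sep = " x ")
  rankings <- ranked$rankings
  rankings$combination <- paste(rankings$source, rankings$roi, sep = " x ")

  # combination weights from mean correct-track rank on calibration trials
  weight_for <- function(combo, session) {
    use <- cr$combination == combo
    if (config$weight_source == "other-session" && config$n_sessions > 1) {
      use <- use & cr$session != session
    }
    if (!any(use)) {
      return(0)
    }
    combination_weight(mean(cr$rank[use]), cr$n_tracks[use][1])
  }
  combos <- unique(cr$combination)
  weights <- tidyr::expand_grid(
    combination = combos, session = seq_len(config$n_sessions)
  )
  weights$weight <- mapply(weight_for, weights$combination, weights$session)

  # combined ranking per trial
  combined <- lapply(unique(cr$trial), function(tri) {
    ses <- behavior$trials$session[behavior$trials$trial == tri]
    w <- weights$weight[weights$session == ses]
    names(w) <- weights$combination[weights$session == ses]
    rk_t <- rankings[rankings$trial == tri, ]
    w <- w[names(w) %in% rk_t$combination]
    if (sum(w) <= 0) w[] <- 1 # no informative combination: unweighted
    comb <- combine_rankings(rk_t[, c("combination", "track", "rank")], w)
    n <- nrow(comb)
    tibble::tibble(
      trial = tri, session = ses, n_tracks = n,
      rank = comb$rank[comb$track == tri],
      normalized = normalized_rank(comb$rank[comb$track == tri], n)
    )
  })
  combined <- dplyr::bind_rows(combined)

  # white-matter empirical null and significance threshold
  wm <- cr[cr$roi == "WM", ]
  null <- if (nrow(wm) >= 10) build_null(wm$normalized) else NULL
  threshold <- if (!is.null(null)) significance_threshold(null) else NA_real_

  report <- dplyr::summarise(
    dplyr::group_by(cr, .data$roi, .data$source, .data$combination),
    mean_rank = mean(.data$rank),
    mean_normalized_rank = mean(.data$normalized),
    n_trials = dplyr::n(), .groups = "drop"
  )
  report$significant <- !is.na(threshold) &
    report$mean_normalized_rank <= threshold
  structure(
    list(
      config = config, trials = behavior$trials,
      accuracy = decoded$accuracy, predictions = decoded$predictions,
      correct_ranks = cr, rankings = rankings, weights = weights,
      combined = combined, null = null, threshold = threshold,
      report = report,
      identification = identification_accuracy(combined$rank)
    ),
    class = "navdecode_experiment"
  )
}

#' @export
print.navdecode_experiment <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<navdecode_experiment> %d trials, %d ROIs x %d sources\n",
      "  combined mean correct-track rank: %.2f (pool %d, chance %.1f)\n",
      "  identification accuracy: %.0f%%\n"
    ),
    nrow(x$trials), dplyr::n_distinct(x$correct_ranks$roi),
    dplyr::n_distinct(x$correct_ranks$source),
    mean(x$combined$rank), x$combined$n_tracks[1],
    chance_rank(x$combined$n_tracks[1]), x$identification
  ))
  if (!is.na(x$threshold)) {
    cat(sprintf(
      "  %d/%d combinations significant (normalized rank <= %.2f)\n",
      sum(x$report$significant), nrow(x$report), x$threshold
    ))
  }
  invisible(x)
}
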