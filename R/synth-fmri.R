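#' Default ROI encoding profiles
#'
#' Builds one encoding specification per region of interest, with tunings
#' chosen so that, qualitatively, the visual regions (V1, ventral visual Ve,
#' parietal Pa) carry scene-content, picture-visibility and motion
#' information, the motor regions (M1, dorsal premotor PM) carry motion and
#' reward-timing information, the hippocampus (Hi) carries only weak quadrant
#' signal, and the white-matter control (WM) carries no signal at all.
#'
#' Each tuned voxel loads on a small random subset (1-3) of its ROI's tuned
#' variables with weight magnitude `snr / sqrt(k)` for `k` loaded variables,
#' so the per-voxel signal standard deviation is about `snr` times the unit
#' noise SD; the first tuned voxels cover each tuned variable once, so every
#' tuned variable has at least one tuned voxel whenever the ROI is large
#' enough.
#'
#' @param snr Signal-to-noise ratio (>= 0): per-voxel signal SD in noise-SD
#'   units.
#' @param n_voxels Named integer vector of ROI sizes; defaults loosely follow
#'   typical ROI magnitudes (V1 and WM large, M1 small).
#' @param seed Integer seed for the tuning draws.
#' @return Named list of `encoding_spec` objects with fields `roi`,
#'   `n_voxels`, `tuning` (voxel x 73 weight matrix), `noise_sd`, `drift_sd`,
#'   `lag_trs`, `seed`.
#' @export
default_roi_profiles <- function(snr = 1,
                                 n_voxels = c(
                                   V1 = 1000, Ve = 800, Pa = 500, M1 = 120,
                                   PM = 250, Hi = 300, WM = 800
                                 ),
                                 seed = 1L) {
  stopifnot(snr >= 0)
  sources <- list(
    V1 = c("scene_rms", "scene_temp", "visibility", "motion"),
    Ve = c("visibility", "scene_rms", "scene_temp"),
    Pa = c("quadrant", "visibility", "scene_temp", "motion"),
    M1 = c("motion", "reward"),
    PM = c("motion", "reward"),
    Hi = c("quadrant"),
    WM = character(0)
  )
  gain <- c(V1 = 1, Ve = 1, Pa = 1, M1 = 1, PM = 1, Hi = 0.3, WM = 0)
  vars <- variable_roster()
  out <- lapply(names(n_voxels), function(roi) {
    idx <- which(vars$source %in% sources[[roi]])
    encoding_spec(
      roi = roi, n_voxels = n_voxels[[roi]], tuned_vars = idx,
      snr = snr * gain[[roi]],
      seed = as.integer(seed) + match(roi, names(n_voxels))
    )
  })
  stats::setNames(out, names(n_voxels))
}

# the fixed 73-variable roster shared by features and the encoding model
variable_roster <- function() {
  pairs <- utils::combn(4, 2)
  tibble::tibble(
    source = rep(
      c("quadrant", "visibility", "motion", "reward", "scene_rms", "scene_temp"),
      c(6, 9, 1, 1, 28, 28)
    ),
    variable = c(
      sprintf("q%d%d", pairs[1, ], pairs[2, ]), sprintf("vis%d", 1:9),
      "motion", "reward", sprintf("rms%02d", 1:28), sprintf("temp%02d", 1:28)
    )
  )
}

#' @rdname default_roi_profiles
#' @param roi ROI name.
#' @param tuned_vars Integer indices (into the 73-variable roster) of the
#'   variables this ROI encodes.
#' @param noise_sd Gaussian noise SD per voxel-TR.
#' @param drift_sd SD of the per-voxel linear/quadratic drift coefficients,
#'   in noise-SD units over a run.
#' @param lag_trs Hemodynamic lag in TRs (default 2).
#' @param prop_tuned Fraction of voxels carrying signal.
#' @export
encoding_spec <- function(roi, n_voxels, tuned_vars, snr, noise_sd = 1,
                          drift_sd = 1, lag_trs = 2L, prop_tuned = 0.7,
                          seed = 1L) {
  stopifnot(n_voxels > 0, noise_sd >= 0, snr >= 0)
  tuning <- matrix(0, n_voxels, 73)
  if (length(tuned_vars) > 0 && snr > 0) {
    withr::with_seed(as.integer(seed), {
      n_tuned <- max(1L, round(prop_tuned * n_voxels))
      for (v in seq_len(n_tuned)) {
        k <- sample.int(3, 1)
        if (v <= length(tuned_vars)) {
          # deterministic coverage: first voxels take each tuned variable once
          pick <- unique(c(tuned_vars[v], sample(tuned_vars, min(k - 1, length(tuned_vars)))))
        } else {
          pick <- sample(tuned_vars, min(k, length(tuned_vars)))
        }
        tuning[v, pick] <- sample(c(-1, 1), length(pick), replace = TRUE) *
          snr / sqrt(length(pick))
      }
    })
  }
  structure(
    list(
      roi = roi, n_voxels = as.integer(n_voxels), tuning = tuning,
      noise_sd = noise_sd, drift_sd = drift_sd, lag_trs = as.integer(lag_trs),
      seed = as.integer(seed)
    ),
    class = "encoding_spec"
  )
}

#' Synthesize a voxel x TR run from behavioral variables
#'
#' Generates one run of ROI signal as a lagged, drifting, noisy linear
#' mixture of the behavioral variables: each voxel's trace is the weighted
#' sum of its tuned variables shifted `lag_trs` TRs later (the hemodynamic
#' delay modeled as a pure lag), plus a smooth per-voxel linear + quadratic
#' drift, plus i.i.d. Gaussian noise. Variables are standardized across the
#' run before mixing (sources have incommensurate units); values before the
#' run start are taken at the run mean (0 after standardization).
#'
#' @param spec An [encoding_spec()].
#' @param variables A variable matrix (TR x 73, columns in roster order, see
#'   [build_variable_set()]) or a tibble with `variable`, `tr`, `value`
#'   columns covering one run.
#' @param trial_bounds Tibble with `trial`, `start`, `end` (TR indices) when
#'   `variables` spans several concatenated trials; defaults to one trial.
#' @param run_id Run identifier.
#' @param seed Integer seed for noise and drift.
#' @return A `voxel_run`: list with `roi`, `data` (voxel x TR matrix),
#'   `run_id`, `trial_bounds`, `normalized = FALSE`.
#' @export
synthesize_run <- function(spec, variables, trial_bounds = NULL, run_id = 1L,
                           seed = spec$seed) {
  X <- as_variable_matrix(variables)
  n_tr <- nrow(X)
  lag <- spec$lag_trs
  if (lag >= n_tr) rlang::abort("hemodynamic lag must be shorter than the run")
  if (is.null(trial_bounds)) {
    trial_bounds <- tibble::tibble(trial = 1L, start = 1L, end = n_tr)
  }
  Z <- scale(X)
  Z[, attr(Z, "scaled:scale") == 0 | !is.finite(attr(Z, "scaled:scale"))] <- 0
  Z[!is.finite(Z)] <- 0
  lagged <- rbind(matrix(0, lag, 73), Z[seq_len(n_tr - lag), , drop = FALSE])
  signal <- tcrossprod(spec$tuning, lagged) # voxel x TR
  withr::with_seed(as.integer(seed), {
    t_norm <- seq_len(n_tr) / n_tr
    c1 <- stats::rnorm(spec$n_voxels, 0, spec$drift_sd * spec$noise_sd)
    c2 <- stats::rnorm(spec$n_voxels, 0, spec$drift_sd * spec$noise_sd)
    drift <- outer(c1, t_norm) + outer(c2, t_norm^2)
    noise <- matrix(
      stats::rnorm(spec$n_voxels * n_tr, 0, spec$noise_sd),
      spec$n_voxels, n_tr
    )
  })
  structure(
    list(
      roi = spec$roi, data = signal + drift + noise, run_id = run_id,
      trial_bounds = tibble::as_tibble(trial_bounds), normalized = FALSE
    ),
    class = "voxel_run"
  )
}

as_variable_matrix <- function(variables) {
  if (is.matrix(variables)) {
    stopifnot(ncol(variables) == 73)
    return(variables)
  }
  roster <- variable_roster()
  wide <- tidyr::pivot_wider(
    variables[, c("variable", "tr", "value")],
    names_from = "variable", values_from = "value"
  )
  wide <- wide[order(wide$tr), ]
  missing <- setdiff(roster$variable, names(wide))
  if (length(missing)) {
    rlang::abort(sprintf("variables missing from set: %s", paste(missing, collapse = ", ")))
  }
  as.matrix(wide[, roster$variable])
}

#' @export
print.voxel_run <- function(x, ...) {
  cat(sprintf(
    "<voxel_run> %s run %s: %d voxels x %d TRs, %d trials%s\n",
    x$roi, format(x$run_id), nrow(x$data), ncol(x$data),
    nrow(x$trial_bounds), if (x$normalized) ", normalized" else ""
  ))
  invisible(x)
}
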