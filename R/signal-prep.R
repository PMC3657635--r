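#' Normalize a voxel run
#'
#' Reproduces the run normalization applied before decoding: (1) subtract the
#' scalar mean of the signal over all ROI voxels and all time points of the
#' run, then (2) remove, per voxel, the least-squares fit of an intercept +
#' linear + quadratic time trend. Matrix shape is unchanged.
#'
#' @param run A [voxel_run][synthesize_run] that has not been normalized yet.
#' @return The run with drift-free, grand-mean-zero data and
#'   `normalized = TRUE`.
#' @export
normalize_run <- function(run) {
  stopifnot(inherits(run, "voxel_run"))
  if (isTRUE(run$normalized)) rlang::abort("run is already normalized")
  n_tr <- ncol(run$data)
  if (n_tr < 3) rlang::abort("run too short for a quadratic detrend (< 3 TRs)")
  d <- run$data - mean(run$data)
  t <- seq_len(n_tr)
  Q <- qr.Q(qr(cbind(1, t, t^2)))
  run$data <- d - (d %*% Q) %*% t(Q)
  run$normalized <- TRUE
  run
}

#' Pair variables with lagged fMRI signal
#'
#' Aligns the behavioral variables to the fMRI signal under the hemodynamic
#' offset: the variable at TR `t` is paired with the signal at TR
#' `t + lag_trs`. The lag is applied within each trial, so each trial loses
#' its trailing `lag_trs` variable time points (which have no within-trial
#' signal partner), and no pairing crosses a trial boundary.
#'
#' @param run A normalized [voxel_run][synthesize_run].
#' @param variables Variable matrix (TR x 73) or long tibble for the run (see
#'   [synthesize_run()]).
#' @param lag_trs Hemodynamic lag in TRs (>= 0; default 2 = 6 s at TR 3 s).
#' @return List with `X` (time point x voxel signal matrix), `V` (time point
#'   x 73 variable matrix), `trial` (integer trial id per time point) and
#'   `tr` (variable-TR index within trial).
#' @export
align_to_variables <- function(run, variables, lag_trs = 2) {
  stopifnot(inherits(run, "voxel_run"), lag_trs >= 0)
  V <- as_variable_matrix(variables)
  stopifnot(nrow(V) == ncol(run$data))
  tb <- run$trial_bounds
  keep_var <- integer(0)
  keep_sig <- integer(0)
  trial <- integer(0)
  tr <- integer(0)
  for (i in seq_len(nrow(tb))) {
    len <- tb$end[i] - tb$start[i] + 1
    if (lag_trs >= len) {
      rlang::abort(sprintf("lag (%d TRs) is not shorter than trial %s", lag_trs, tb$trial[i]))
    }
    t_var <- tb$start[i]:(tb$end[i] - lag_trs)
    keep_var <- c(keep_var, t_var)
    keep_sig <- c(keep_sig, t_var + lag_trs)
    trial <- c(trial, rep(tb$trial[i], length(t_var)))
    tr <- c(tr, seq_along(t_var))
  }
  list(
    X = t(run$data[, keep_sig, drop = FALSE]),
    V = V[keep_var, , drop = FALSE],
    trial = trial, tr = tr
  )
}
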