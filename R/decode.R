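#' Binarize a variable series for classifier training
#'
#' Each information source is turned into a binary labeling with a
#' source-specific rule, computed from training data only:
#' \describe{
#'   \item{quadrant}{pair values 1/0 map to +1/-1; unassigned (0.5) time
#'     points are masked.}
#'   \item{motion}{only the lower third (negative, turning right, -1) and
#'     upper third (positive, turning left, +1) of training values are used;
#'     the middle tertile is masked.}
#'   \item{visibility / reward}{positive values are +1, zeros -1; the "no"
#'     class is subsampled (seeded, uniform) so its frequency is at most 3x
#'     the "yes" class.}
#'   \item{scene_rms / scene_temp}{below/above the median of all training
#'     values; the training median is reused for held-out data.}
#' }
#'
#' @param values Numeric training values (concatenated over training trials).
#' @param rule One of `"quadrant"`, `"motion"`, `"yes_no"` (visibility /
#'   reward), `"median"` (scene content).
#' @param seed Seed for the 3:1 cap subsampling.
#' @param max_ratio Majority:minority cap for `"yes_no"` (default 3).
#' @return A `binary_labeling`: list with `labels` (+1/-1/NA per time
#'   point), `include` (logical training mask), `rule`, and `params`
#'   (thresholds needed to label held-out data via [apply_binarize()]).
#'   `NULL` if the rule degenerates to a single class (variable skipped).
#' @export
binarize <- function(values, rule = c("quadrant", "motion", "yes_no", "median"),
                     seed = 1L, max_ratio = 3) {
  rule <- match.arg(rule)
  if (length(values) == 0) rlang::abort("cannot binarize an empty series")
  params <- list()
  if (rule == "quadrant") {
    labels <- ifelse(values > 0.75, 1, ifelse(values < 0.25, -1, NA))
  } else if (rule == "motion") {
    qs <- stats::quantile(values, c(1 / 3, 2 / 3), names = FALSE)
    if (qs[1] >= qs[2]) return(NULL) # degenerate tertiles
    labels <- ifelse(values <= qs[1], -1, ifelse(values >= qs[2], 1, NA))
    params <- list(lo = qs[1], hi = qs[2])
  } else if (rule == "yes_no") {
    labels <- ifelse(values > 1e-12, 1, -1)
  } else {
    med <- stats::median(values)
    labels <- ifelse(values > med, 1, -1)
    if (length(unique(labels[!is.na(labels)])) < 2) return(NULL)
    params <- list(median = med)
  }
  include <- !is.na(labels)
  n_yes <- sum(labels == 1, na.rm = TRUE)
  n_no <- sum(labels == -1, na.rm = TRUE)
  if (n_yes == 0 || n_no == 0) return(NULL)
  if (rule == "yes_no" && n_no > max_ratio * n_yes) {
    keep_no <- withr::with_seed(
      as.integer(seed),
      sample(which(labels == -1), max_ratio * n_yes)
    )
    include <- include & (labels == 1 | seq_along(labels) %in% keep_no)
  }
  structure(
    list(labels = labels, include = include, rule = rule, params = params),
    class = "binary_labeling"
  )
}

#' @rdname binarize
#' @param labeling A `binary_labeling` fitted on training data.
#' @export
apply_binarize <- function(labeling, values) {
  switch(labeling$rule,
    quadrant = ifelse(values > 0.75, 1, ifelse(values < 0.25, -1, NA)),
    motion = ifelse(values <= labeling$params$lo, -1,
      ifelse(values >= labeling$params$hi, 1, NA)
    ),
    yes_no = ifelse(values > 1e-12, 1, -1),
    median = ifelse(values > labeling$params$median, 1, -1)
  )
}

# rule used to binarize each information source
source_rule <- function(source) {
  c(
    quadrant = "quadrant", visibility = "yes_no", motion = "motion",
    reward = "yes_no", scene_rms = "median", scene_temp = "median"
  )[[source]]
}

#' Train a linear max-margin classifier
#'
#' Fits a linear support vector machine (regularization parameter `C = 1`,
#' no kernel, no rescaling) on the included training time points and extracts
#' the separating hyperplane. Decision values are oriented so that positive
#' values vote for the +1 class.
#'
#' @param signals Time point x voxel matrix.
#' @param labeling A [binary_labeling][binarize] for the same time points.
#' @param cost Regularization parameter C (default 1).
#' @return A `variable_decoder`: list with `w` (voxel weight vector), `b`
#'   (bias), and `calibration` (`NULL` until [calibrate()]d). Decision value
#'   of a pattern `x` is `sum(w * x) + b`.
#' @export
train_decoder <- function(signals, labeling, cost = 1) {
  keep <- which(labeling$include)
  y <- labeling$labels[keep]
  if (length(unique(y)) < 2 || min(table(y)) < 2) {
    rlang::abort("training needs at least 2 time points in each class")
  }
  X <- signals[keep, , drop = FALSE]
  fit <- e1071::svm(
    x = X, y = factor(y, levels = c(-1, 1)),
    kernel = "linear", cost = cost, scale = FALSE
  )
  w <- as.numeric(crossprod(fit$SV, fit$coefs))
  b <- -fit$rho
  dv <- as.numeric(X %*% w + b)
  # orient so positive decision values vote for the +1 class
  if (mean(dv[y == 1]) < mean(dv[y == -1])) {
    w <- -w
    b <- -b
  }
  structure(
    list(w = w, b = b, cost = cost, calibration = NULL),
    class = "variable_decoder"
  )
}

decision_values <- function(decoder, signals) {
  as.numeric(signals %*% decoder$w + decoder$b)
}

#' Calibrate decision values into predicted probabilities
#'
#' Relates the classifier's decision value (signed distance from the
#' hyperplane) to the probability of the positive class: training time
#' points are sorted by decision value, partitioned into consecutive bins of
#' `bin_size` (a final partial bin is kept if it holds at least
#' `min_partial` points), and the per-bin (mean decision value, positive
#' fraction) pairs are fitted by least squares with the four-parameter
#' sigmoid `y = c + (1 - c - d) / (1 + exp((x - a) / b))`. If the fit fails
#' to converge, a clipped linear map through the two extreme bins is used
#' instead.
#'
#' @param dv Training decision values.
#' @param labels Training labels (+1/-1).
#' @param bin_size Points per bin (default 20).
#' @param min_partial Minimum size for keeping the final partial bin
#'   (default 10).
#' @return A `calibration_sigmoid`: list with parameters `a`, `b`, `c`, `d`
#'   (or the linear fallback) and the bin table. Evaluate with
#'   [predict_calibrated()]; outputs are clipped to \[0, 1\].
#' @export
calibrate <- function(dv, labels, bin_size = 20, min_partial = 10) {
  stopifnot(length(dv) == length(labels))
  ord <- order(dv)
  dv <- dv[ord]
  y <- as.numeric(labels[ord] == 1)
  n <- length(dv)
  n_full <- n %/% bin_size
  sizes <- rep(bin_size, n_full)
  rest <- n - n_full * bin_size
  if (rest >= min_partial) sizes <- c(sizes, rest)
  if (length(sizes) < 2) rlang::abort("calibration needs at least 2 bins")
  idx <- rep(seq_along(sizes), sizes)
  used <- seq_len(sum(sizes))
  bins <- tibble::tibble(
    dv = as.numeric(tapply(dv[used], idx, mean)),
    p = as.numeric(tapply(y[used], idx, mean))
  )
  rng <- diff(range(bins$dv))
  slope_up <- stats::coef(stats::lm(p ~ dv, data = bins))[2] >= 0
  start <- list(
    a = stats::median(dv), b = (if (slope_up) -1 else 1) * max(rng / 10, 1e-6),
    c = 0.05, d = 0.05
  )
  fit <- tryCatch(
    suppressWarnings(minpack.lm::nlsLM(
      p ~ c + (1 - c - d) / (1 + exp((dv - a) / b)),
      data = bins, start = start,
      lower = c(a = -Inf, b = -Inf, c = 0, d = 0),
      upper = c(a = Inf, b = Inf, c = 0.5, d = 0.5),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    )),
    error = function(e) NULL
  )
  if (!is.null(fit) && abs(stats::coef(fit)[["b"]]) > 1e-12) {
    pars <- as.list(stats::coef(fit))
    out <- list(type = "sigmoid", a = pars$a, b = pars$b, c = pars$c, d = pars$d)
  } else {
    # clipped linear map through the two extreme bins
    x1 <- bins$dv[1]
    x2 <- bins$dv[nrow(bins)]
    y1 <- bins$p[1]
    y2 <- bins$p[nrow(bins)]
    slope <- if (x2 > x1) (y2 - y1) / (x2 - x1) else 0
    out <- list(type = "linear", x0 = x1, y0 = y1, slope = slope)
  }
  structure(c(out, list(bins = bins)), class = "calibration_sigmoid")
}

#' @rdname calibrate
#' @param calibration A `calibration_sigmoid`.
#' @export
predict_calibrated <- function(calibration, dv) {
  p <- if (calibration$type == "sigmoid") {
    calibration$c + (1 - calibration$c - calibration$d) /
      (1 + exp((dv - calibration$a) / calibration$b))
  } else {
    calibration$y0 + calibration$slope * (dv - calibration$x0)
  }
  pmin(pmax(p, 0), 1)
}

#' Predicted-probability trace for held-out data
#'
#' Applies a calibrated decoder to the held-out trial's signal: per time
#' point, the decision value and the calibrated predicted value in \[0, 1\].
#'
#' @param decoder A calibrated [variable_decoder][train_decoder].
#' @param signals Held-out time point x voxel matrix.
#' @return Tibble with columns `tr`, `dv`, `predicted`.
#' @export
predict_series <- function(decoder, signals) {
  if (is.null(decoder$calibration)) rlang::abort("decoder is not calibrated")
  if (ncol(signals) != length(decoder$w)) {
    rlang::abort("voxel dimension of signals does not match the decoder")
  }
  dv <- decision_values(decoder, signals)
  tibble::tibble(
    tr = seq_along(dv), dv = dv,
    predicted = predict_calibrated(decoder$calibration, dv)
  )
}

#' Signal-detection corrected accuracy
#'
#' With unequal class frequencies, raw proportion correct overstates
#' performance: a classifier that always answers the 90%-prevalent class is
#' 90% "correct" while extracting no information. The corrected accuracy
#' neutralizes this by the sensitivity index `d' = z(H) - z(F)` (H = hit
#' proportion, F = false-alarm proportion, z = inverse normal CDF) and
#' reports `P = normcdf(d' / 2)`, the proportion correct an unbiased
#' observer with that d' would reach with equally frequent alternatives.
#' Proportions of exactly 0 or 1 are clipped to `1/(2n)` and `1 - 1/(2n)`
#' before the z transform.
#'
#' @param H Hit proportion in \[0, 1\].
#' @param F False-alarm proportion in \[0, 1\].
#' @param n Number of test time points behind the proportions (used only for
#'   the clipping of 0/1 proportions).
#' @return An `accuracy_stats` tibble with columns `H`, `F`, `dprime`, `P`.
#' @export
#' @examples
#' corrected_accuracy(1, 1, n = 100)$P # always-majority classifier: 0.5
corrected_accuracy <- function(H, F, n = 100) {
  stopifnot(H >= 0, H <= 1, F >= 0, F <= 1, n >= 1)
  clip <- function(p) pmin(pmax(p, 1 / (2 * n)), 1 - 1 / (2 * n))
  dprime <- stats::qnorm(clip(H)) - stats::qnorm(clip(F))
  out <- tibble::tibble(H = H, F = F, dprime = dprime, P = stats::pnorm(dprime / 2))
  class(out) <- c("accuracy_stats", class(out))
  out
}

#' Leave-one-trial-out decoding of one variable in one ROI
#'
#' Trains a classifier on all time points from all trials minus one and
#' tests it on the individual time points of the remaining trial, repeating
#' so that every trial is tested once. Within each fold the binarization
#' thresholds (medians, tertiles, subsampling) and the calibration sigmoid
#' are refit from the training trials only. Folds whose training set
#' degenerates to a single class are skipped and reported.
#'
#' @param aligned Output of [align_to_variables()].
#' @param variable Column index (1..73) or name of the variable to decode.
#' @param source Information source of the variable (sets the binarization
#'   rule); inferred from the roster when a name is given.
#' @param cost SVM regularization parameter (default 1).
#' @param seed Seed for the subsampling draws.
#' @param min_calibration_bins Minimum bins for the sigmoid fit; folds with
#'   fewer points fall back to the linear map.
#' @return A `decoder_cv`: list with `predictions` (tibble: trial, tr, dv,
#'   predicted, label), `stats` (pooled [corrected_accuracy()] row),
#'   `skipped` (trial ids of skipped folds), `variable`.
#' @export
leave_one_trial_out <- function(aligned, variable, source = NULL, cost = 1,
                                seed = 1L, min_calibration_bins = 2) {
  roster <- variable_roster()
  if (is.character(variable)) {
    vi <- match(variable, roster$variable)
  } else {
    vi <- as.integer(variable)
  }
  if (is.na(vi) || vi < 1 || vi > 73) rlang::abort("unknown variable")
  source <- source %||% roster$source[vi]
  rule <- source_rule(source)
  trials <- unique(aligned$trial)
  if (length(trials) < 2) rlang::abort("leave-one-trial-out needs >= 2 trials")
  vals <- aligned$V[, vi]
  preds <- list()
  skipped <- c()
  hits <- fas <- n_pos <- n_neg <- 0
  for (ti in trials) {
    test <- aligned$trial == ti
    lab <- binarize(vals[!test], rule, seed = as.integer(seed) + match(ti, trials))
    dec <- NULL
    if (!is.null(lab)) {
      dec <- tryCatch(
        train_decoder(aligned$X[!test, , drop = FALSE], lab, cost = cost),
        error = function(e) NULL
      )
    }
    if (is.null(dec)) {
      skipped <- c(skipped, ti)
      next
    }
    keep <- which(lab$include)
    dv_train <- decision_values(dec, aligned$X[!test, , drop = FALSE][keep, , drop = FALSE])
    dec$calibration <- tryCatch(
      calibrate(dv_train, lab$labels[keep]),
      error = function(e) NULL
    )
    if (is.null(dec$calibration)) {
      skipped <- c(skipped, ti)
      next
    }
    ps <- predict_series(dec, aligned$X[test, , drop = FALSE])
    test_lab <- apply_binarize(lab, vals[test])
    preds[[length(preds) + 1]] <- tibble::tibble(
      trial = ti, tr = aligned$tr[test], dv = ps$dv,
      predicted = ps$predicted, label = test_lab
    )
    pred_cls <- ifelse(ps$dv > 0, 1, -1)
    hits <- hits + sum(pred_cls == 1 & test_lab == 1, na.rm = TRUE)
    fas <- fas + sum(pred_cls == 1 & test_lab == -1, na.rm = TRUE)
    n_pos <- n_pos + sum(test_lab == 1, na.rm = TRUE)
    n_neg <- n_neg + sum(test_lab == -1, na.rm = TRUE)
  }
  stats <- if (n_pos > 0 && n_neg > 0) {
    corrected_accuracy(hits / n_pos, fas / n_neg, n = n_pos + n_neg)
  } else {
    NULL
  }
  structure(
    list(
      predictions = dplyr::bind_rows(preds), stats = stats,
      skipped = skipped, variable = roster$variable[vi], source = source
    ),
    class = "decoder_cv"
  )
}

#' @export
print.decoder_cv <- function(x, ...) {
  p <- if (!is.null(x$stats)) sprintf("%.1f%%", 100 * x$stats$P) else "NA"
  cat(sprintf(
    "<decoder_cv> %s (%s): %d folds, corrected accuracy %s%s\n",
    x$variable, x$source, dplyr::n_distinct(x$predictions$trial), p,
    if (length(x$skipped)) sprintf(", %d skipped", length(x$skipped)) else ""
  ))
  invisible(x)
}
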