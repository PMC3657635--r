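test_that("binarization rules label and mask as specified", {
  withr::with_seed(2, {
    # motion: tertile rule masks the middle third
    vals <- rnorm(300)
    lab <- binarize(vals, "motion")
    expect_equal(sum(is.na(lab$labels)), sum(!lab$include))
    expect_equal(mean(lab$labels == 1, na.rm = TRUE), 0.5, tolerance = 0.05)
    expect_true(all(vals[which(lab$labels == 1)] > vals[which(lab$labels == -1)[1]]))
    expect_equal(sum(lab$include), 2 * sum(vals <= quantile(vals, 1 / 3)))

    # yes/no with 100 no / 10 yes keeps at most 30 no
    v <- c(rep(0, 100), rep(1, 10))
    lab2 <- binarize(v, "yes_no", seed = 3)
    expect_equal(sum(lab2$include & lab2$labels == -1), 30)
    expect_equal(sum(lab2$include & lab2$labels == 1), 10)

    # degenerate median split is skipped
    expect_null(binarize(rep(0.2, 50), "median"))
    expect_null(binarize(rep(1, 50), "motion"))

    # the training median transfers to held-out data
    lab3 <- binarize(c(1, 2, 3, 4, 5), "median")
    expect_equal(apply_binarize(lab3, c(0, 10)), c(-1, 1))

    # quadrant-pair values 1 / 0 / 0.5 map to +1 / -1 / masked
    lab4 <- binarize(c(1, 0, 0.5, 1, 0), "quadrant")
    expect_equal(lab4$labels, c(1, -1, NA, 1, -1))
  })
})

test_that("the max-margin classifier separates a separable toy exactly", {
  withr::with_seed(4, {
    n <- 60
    y <- rep(c(1, -1), each = n / 2)
    X <- cbind(y * 2 + rnorm(n, 0, 0.3), rnorm(n))
    lab <- structure(
      list(
        labels = y, include = rep(TRUE, n),
        rule = "median", params = list(median = 0)
      ),
      class = "binary_labeling"
    )
    dec <- train_decoder(X, lab)
    dv <- X %*% dec$w + dec$b
    expect_true(all(sign(dv) == y)) # 100% training classification
    # positive decision values vote for the +1 class
    expect_gt(mean(dv[y == 1]), mean(dv[y == -1]))
    # duplicating a voxel leaves the decision signs unchanged
    dec2 <- train_decoder(cbind(X, X[, 1]), lab)
    dv2 <- cbind(X, X[, 1]) %*% dec2$w + dec2$b
    expect_equal(sign(dv2), sign(dv))
    expect_error(
      train_decoder(X, structure(
        list(labels = rep(1, n), include = rep(TRUE, n), rule = "median", params = list()),
        class = "binary_labeling"
      )),
      "class"
    )
  })
})

test_that("calibration recovers the decision-value/probability relationship", {
  withr::with_seed(6, {
    # well-separated decision values: monotone fit hitting both asymptotes
    dv <- c(rnorm(120, -2, 0.5), rnorm(120, 2, 0.5))
    y <- rep(c(-1, 1), each = 120)
    cal <- calibrate(dv, y)
    grid <- seq(min(dv), max(dv), length.out = 50)
    p <- predict_calibrated(cal, grid)
    expect_true(all(diff(p) >= -1e-9)) # monotone over the observed range
    expect_lt(p[1], 0.15)
    expect_gt(p[50], 0.85)
    # at dv = a the sigmoid passes its midpoint c + (1 - c - d)/2
    if (cal$type == "sigmoid") {
      expect_equal(
        predict_calibrated(cal, cal$a),
        cal$c + (1 - cal$c - cal$d) / 2,
        tolerance = 1e-9
      )
    }
    # labels independent of the decision value: near-constant curve
    dv_big <- rnorm(1200)
    y_ind <- sample(c(-1, 1), 1200, replace = TRUE, prob = c(0.3, 0.7))
    cal2 <- calibrate(dv_big, y_ind)
    p2 <- predict_calibrated(cal2, seq(min(dv_big), max(dv_big), length.out = 50))
    # near-constant at the base rate, far flatter than the separated case
    expect_lt(diff(range(p2)), 0.2)
    expect_lt(diff(range(p2)), 0.3 * diff(range(p)))
    expect_equal(mean(p2), 0.7, tolerance = 0.12)
    expect_error(calibrate(dv[1:15], y[1:15]), "2 bins")
  })
})

test_that("corrected accuracy implements d-prime with the 1/(2n) clipping", {
  # always-majority classifier at 90% prevalence: H = F = 1 -> P = 50%
  maj <- corrected_accuracy(1, 1, n = 100)
  expect_equal(maj$dprime, 0)
  expect_equal(maj$P, 0.5)
  # H = F at any value gives chance
  expect_equal(corrected_accuracy(0.7, 0.7, n = 50)$P, 0.5)
  # standard-normal oracle: H = 0.8413, F = 0.5 -> d' ~ 1, P ~ 0.691
  st <- corrected_accuracy(0.8413, 0.5, n = 1000)
  expect_equal(st$dprime, 1, tolerance = 1e-3)
  expect_equal(st$P, pnorm(0.5), tolerance = 1e-3)
  # antisymmetry: swapping H and F maps P -> 1 - P
  withr::with_seed(12, {
    for (i in 1:50) {
      H <- runif(1)
      F <- runif(1)
      expect_equal(
        corrected_accuracy(H, F, 40)$P + corrected_accuracy(F, H, 40)$P, 1
      )
    }
  })
})

test_that("predicted series are calibrated probabilities of the signal", {
  withr::with_seed(13, {
    n <- 200
    y <- sample(c(-1, 1), n, replace = TRUE)
    X <- cbind(y + rnorm(n, 0, 0.8), rnorm(n, 0, 0.5))
    lab <- structure(
      list(labels = y, include = rep(TRUE, n), rule = "median", params = list(median = 0)),
      class = "binary_labeling"
    )
    dec <- train_decoder(X, lab)
    dec$calibration <- calibrate(as.numeric(X %*% dec$w + dec$b), y)
    ps <- predict_series(dec, X)
    expect_true(all(ps$predicted >= 0 & ps$predicted <= 1))
    # mean prediction on the training data approximates the base rate
    expect_equal(mean(ps$predicted), mean(y == 1), tolerance = 0.1)
    # an all-zero pattern maps to the calibrated bias response
    expect_equal(
      predict_series(dec, matrix(0, 2, 2))$predicted,
      rep(predict_calibrated(dec$calibration, dec$b), 2)
    )
    expect_error(predict_series(dec, matrix(0, 2, 5)), "dimension")
  })
})

test_that("leave-one-trial-out predicts each trial once without leakage", {
  withr::with_seed(14, {
    n_trials <- 8
    tr_per <- 22
    n <- n_trials * tr_per
    v <- rnorm(n)
    X <- cbind(v + rnorm(n, 0, 0.5), matrix(rnorm(n * 5), n, 5))
    V <- matrix(0, n, 73)
    V[, 17] <- v # a scene_rms variable (median rule)
    aligned <- list(
      X = X, V = V,
      trial = rep(seq_len(n_trials), each = tr_per),
      tr = rep(seq_len(tr_per), n_trials)
    )
    cv <- leave_one_trial_out(aligned, 17)
    expect_equal(sort(unique(cv$predictions$trial)), seq_len(n_trials))
    expect_equal(nrow(cv$predictions), n) # every time point predicted once
    expect_gt(cv$stats$P, 0.75) # informative signal decodes well

    # no leakage: permuting the held-out trial's variable values changes
    # nothing in the predictions (labels are evaluation-only)
    V2 <- V
    idx <- which(aligned$trial == 3)
    V2[idx, 17] <- sample(V2[idx, 17])
    cv2 <- leave_one_trial_out(list(X = X, V = V2, trial = aligned$trial, tr = aligned$tr), 17)
    expect_equal(
      cv2$predictions$predicted[cv2$predictions$trial == 3],
      cv$predictions$predicted[cv$predictions$trial == 3]
    )

    # random labels cross-validate at chance
    Vr <- V
    Vr[, 17] <- rnorm(n)
    Xr <- matrix(rnorm(n * 6), n, 6)
    cvr <- leave_one_trial_out(list(X = Xr, V = Vr, trial = aligned$trial, tr = aligned$tr), 17)
    ci <- 0.5 + c(-1, 1) * 1.96 * sqrt(0.25 / n)
    raw_acc <- with(
      cvr$predictions,
      mean(ifelse(dv > 0, 1, -1) == label, na.rm = TRUE)
    )
    expect_gt(raw_acc, ci[1] - 0.02)
    expect_lt(raw_acc, ci[2] + 0.02)
  })
})
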