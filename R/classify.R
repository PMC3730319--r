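## Per-time-point linear SVM evaluation: stratified 2/3 split, LOOCV cost
## tuning maximized on balanced accuracy, Table-style metric reporting.
## Hypoxia is the positive class throughout.

#' Stratified 2/3 train/test split for one time point
#'
#' From the 9 hypoxia + 9 normoxia samples at a time point, draws 6 + 6
#' training samples at random (the remaining 3 + 3 form the test set).
#'
#' @param tab A `concentration_table`.
#' @param time_point Time point to split.
#' @param seed Integer seed; the plan is deterministic given it.
#' @return A `split_plan`: list with `time_point`, `train_ids`, `test_ids`,
#'   `seed`.
#' @export
make_split <- function(tab, time_point, seed = 1L) {
  sub <- tab[tab$time_point == time_point, ]
  n_h <- sum(sub$condition == "hypoxia")
  n_n <- sum(sub$condition == "normoxia")
  if (n_h != 9 || n_n != 9) {
    abort("WRONG_DESIGN",
          sprintf("expected 9 + 9 samples at '%s', found %d + %d", time_point, n_h, n_n))
  }
  with_seed(seed, {
    train <- c(sample(sub$sample_id[sub$condition == "hypoxia"], 6),
               sample(sub$sample_id[sub$condition == "normoxia"], 6))
    structure(list(time_point = time_point,
                   train_ids = train,
                   test_ids = setdiff(sub$sample_id, train),
                   seed = as.integer(seed)),
              class = "split_plan")
  })
}

#' Default cost grid for linear-SVM tuning
#' @return Powers of 4 from 2^-5 to 2^15.
#' @export
default_cost_grid <- function() 2^seq(-5, 15, by = 2)

#' LOOCV predictions of a linear SVM at one cost
#' @noRd
loocv_predict <- function(x, y, cost) {
  n <- nrow(x)
  pred <- character(n)
  for (i in seq_len(n)) {
    fit <- e1071::svm(x[-i, , drop = FALSE], y[-i], kernel = "linear",
                      cost = cost, scale = FALSE)
    pred[i] <- as.character(stats::predict(fit, x[i, , drop = FALSE]))
  }
  factor(pred, levels = levels(y))
}

#' Tune and train a linear SVM by leave-one-out balanced accuracy
#'
#' Features are standardized on training statistics only (leakage-free);
#' the linear-kernel cost is chosen from a fixed grid by maximizing the
#' LOOCV balanced accuracy (mean of specificity and sensitivity), with ties
#' broken toward the smallest cost. The returned rule is refit on all
#' training rows.
#'
#' @param x Training feature matrix (rows = samples).
#' @param y Labels (`"hypoxia"`/`"normoxia"`); hypoxia is positive.
#' @param cost_grid Candidate costs (default [default_cost_grid()]).
#' @param standardize Standardize features on training statistics.
#' @return An `svm_rule`: list with the fitted model, chosen `cost`, the
#'   per-cost LOOCV table (`tuning`), LOOCV metrics at the chosen cost
#'   (`loocv_metrics`), and the standardization parameters.
#' @export
tune_and_train <- function(x, y, cost_grid = default_cost_grid(),
                           standardize = TRUE) {
  x <- as.matrix(x)
  y <- factor(as.character(y), levels = CONDITIONS)
  if (any(table(y) < 2)) abort("DEGENERATE", "need at least 2 training samples per class")
  if (standardize) {
    ctr <- colMeans(x)
    scl <- apply(x, 2, stats::sd)
    scl[scl == 0 | !is.finite(scl)] <- 1
  } else {
    ctr <- rep(0, ncol(x)); scl <- rep(1, ncol(x))
  }
  xs <- scale(x, center = ctr, scale = scl)

  tuning <- data.frame(cost = cost_grid, bac = NA_real_)
  loocv_by_cost <- vector("list", length(cost_grid))
  for (k in seq_along(cost_grid)) {
    pred <- loocv_predict(xs, y, cost_grid[k])
    m <- confusion_metrics(pred, y)
    tuning$bac[k] <- m$bac
    loocv_by_cost[[k]] <- m
  }
  best <- which(tuning$bac == max(tuning$bac))[1]   # ties -> smallest cost
  fit <- e1071::svm(xs, y, kernel = "linear", cost = cost_grid[best], scale = FALSE)
  structure(list(fit = fit, cost = cost_grid[best], tuning = tuning,
                 loocv_metrics = loocv_by_cost[[best]],
                 center = ctr, scale = scl, levels = levels(y)),
            class = "svm_rule")
}

#' Confusion counts and derived metrics (hypoxia positive)
#'
#' @param pred Predicted labels.
#' @param truth True labels.
#' @return A `class_metrics` list: TP, TN, FP, FN, accuracy, specificity,
#'   sensitivity, bac (all fractions in \[0, 1\]).
#' @export
confusion_metrics <- function(pred, truth) {
  pred <- as.character(pred); truth <- as.character(truth)
  TP <- sum(pred == "hypoxia" & truth == "hypoxia")
  TN <- sum(pred == "normoxia" & truth == "normoxia")
  FP <- sum(pred == "hypoxia" & truth == "normoxia")
  FN <- sum(pred == "normoxia" & truth == "hypoxia")
  metrics_from_counts(TP, TN, FP, FN)
}

#' Metrics from raw confusion counts
#' @param TP,TN,FP,FN Confusion counts.
#' @return A `class_metrics` list.
#' @export
metrics_from_counts <- function(TP, TN, FP, FN) {
  sens <- if (TP + FN > 0) TP / (TP + FN) else NA_real_
  spec <- if (TN + FP > 0) TN / (TN + FP) else NA_real_
  structure(list(TP = TP, TN = TN, FP = FP, FN = FN,
                 accuracy = (TN + TP) / (TP + FP + FN + TN),
                 specificity = spec, sensitivity = sens,
                 bac = mean(c(spec, sens))),
            class = "class_metrics")
}

#' @export
print.class_metrics <- function(x, ...) {
  cat(sprintf("BAC %.1f%%  accuracy %.1f%%  specificity %.1f%%  sensitivity %.1f%%  (TP %d TN %d FP %d FN %d)\n",
              100 * x$bac, 100 * x$accuracy, 100 * x$specificity,
              100 * x$sensitivity, x$TP, x$TN, x$FP, x$FN))
  invisible(x)
}

#' Evaluate a trained rule on labeled rows
#'
#' @param rule An `svm_rule` from [tune_and_train()].
#' @param x Feature matrix.
#' @param y True labels.
#' @return A `class_metrics` list (hypoxia positive).
#' @export
evaluate <- function(rule, x, y) {
  xs <- scale(as.matrix(x), center = rule$center, scale = rule$scale)
  pred <- stats::predict(rule$fit, xs)
  confusion_metrics(pred, factor(as.character(y), levels = rule$levels))
}

#' Full per-time-point classification report
#'
#' For each time point: stratified split, LOOCV-tuned linear SVM on the 12
#' training samples, evaluation on the 6 held-out samples. Mirrors the
#' training-LOOCV / testing metric table layout.
#'
#' @param tab A (normalized) `concentration_table` with the 17 panel
#'   metabolites as features.
#' @param seed Split seed (one per run; splits differ by time point index).
#' @param cost_grid Candidate costs.
#' @return data.frame with columns `time_point`, `set`
#'   (`training_loocv`/`testing`), `bac`, `accuracy`, `specificity`,
#'   `sensitivity` (percentages), `cost`.
#' @export
classification_report <- function(tab, seed = 1L, cost_grid = default_cost_grid()) {
  tps <- unique(tab$time_point)
  out <- list()
  for (i in seq_along(tps)) {
    tp <- tps[i]
    plan <- make_split(tab, tp, seed = seed + (i - 1L))
    vals <- conc_values(tab)
    tr <- match(plan$train_ids, tab$sample_id)
    te <- match(plan$test_ids, tab$sample_id)
    rule <- tune_and_train(vals[tr, , drop = FALSE], tab$condition[tr], cost_grid = cost_grid)
    mtest <- evaluate(rule, vals[te, , drop = FALSE], tab$condition[te])
    mloo <- rule$loocv_metrics
    row <- function(set, m) data.frame(time_point = tp, set = set,
                                       bac = 100 * m$bac, accuracy = 100 * m$accuracy,
                                       specificity = 100 * m$specificity,
                                       sensitivity = 100 * m$sensitivity,
                                       cost = rule$cost)
    out[[length(out) + 1]] <- row("training_loocv", mloo)
    out[[length(out) + 1]] <- row("testing", mtest)
  }
  do.call(rbind, out)
}
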