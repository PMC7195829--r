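#' Stratified fold assignment
#'
#' Assigns each record to one of `k` folds so that within every class the
#' per-fold counts differ by at most one. The assignment depends only on
#' `(labels, k, seed)`.
#'
#' @param labels Class label vector.
#' @param k Number of folds.
#' @param seed Seed.
#' @return Integer fold id (1..k) per record.
#' @export
stratified_folds <- function(labels, k = 10L, seed = 1L) {
  labels <- as.factor(labels)
  counts <- table(labels)
  if (any(counts < k)) {
    stop(sprintf("class '%s' has %d members, fewer than k = %d folds",
                 names(counts)[which.min(counts)], min(counts), k))
  }
  fold <- integer(length(labels))
  withr::with_seed(seed, {
    for (cl in levels(labels)) {
      idx <- which(labels == cl)
      fold[idx] <- sample(rep(seq_len(k), length.out = length(idx)))
    }
  })
  fold
}

#' Confusion counts with ECM as the positive class
#'
#' @param truth Factor/character of true labels (`nonECM`/`ECM`).
#' @param predicted Factor/character of predicted labels.
#' @return List with integer fields `TP`, `FN`, `TN`, `FP`.
#' @export
confusion_counts <- function(truth, predicted) {
  truth <- factor(truth, levels = c("nonECM", "ECM"))
  predicted <- factor(predicted, levels = c("nonECM", "ECM"))
  if (length(truth) != length(predicted)) stop("length mismatch")
  list(TP = sum(truth == "ECM" & predicted == "ECM"),
       FN = sum(truth == "ECM" & predicted == "nonECM"),
       TN = sum(truth == "nonECM" & predicted == "nonECM"),
       FP = sum(truth == "nonECM" & predicted == "ECM"))
}

#' Performance metrics from confusion counts
#'
#' Sensitivity `Sn = TP/(TP+FN)`, specificity `Sp = TN/(TN+FP)`, accuracy
#' `Acc = (TP+TN)/n` and balanced accuracy `BAcc = (Sn+Sp)/2`. Values are
#' kept at full precision; presentation rounding (4 decimals) is left to
#' report writers.
#'
#' @param counts List with `TP`, `FN`, `TN`, `FP` (see [confusion_counts()]).
#' @return List with `Sn`, `Sp`, `Acc`, `BAcc` and the four counts.
#' @export
compute_metrics <- function(counts) {
  with(counts, {
    if (TP + FN == 0L) stop("no positive examples; sensitivity undefined")
    if (TN + FP == 0L) stop("no negative examples; specificity undefined")
    Sn <- TP / (TP + FN)
    Sp <- TN / (TN + FP)
    list(Sn = Sn, Sp = Sp,
         Acc = (TP + TN) / (TP + FN + TN + FP),
         BAcc = (Sn + Sp) / 2,
         TP = TP, FN = FN, TN = TN, FP = FP)
  })
}

## CV given a precomputed fold assignment; the negative partition of each
## ensemble is computed inside the training split only, so held-out folds
## never influence training.
cross_validate_folds <- function(x, y, config, folds, seed = 1L) {
  x <- as.matrix(x)
  y <- factor(y, levels = c("nonECM", "ECM"))
  prob <- rep(NA_real_, length(y))
  for (f in sort(unique(folds))) {
    train <- folds != f
    cfg <- config
    cfg$seed <- derive_seed(seed, 1000L + f)
    fit <- train_ensemble(x[train, , drop = FALSE], y[train], cfg)
    prob[!train] <- predict_proba(fit, x[!train, , drop = FALSE])
  }
  predicted <- ifelse(prob >= config$decision_threshold, "ECM", "nonECM")
  m <- compute_metrics(confusion_counts(y, predicted))
  m$probabilities <- prob
  m$folds <- folds
  m
}

#' Cross-validated performance of the under-sampling ensemble
#'
#' Stratified k-fold cross-validation: for each fold a fresh under-sampling
#' ensemble is trained on the remaining folds (its negative partition drawn
#' within that training split only) and applied to the held-out fold.
#' Held-out predictions are pooled and a single metrics report is computed,
#' which is stable even when a fold holds only a few dozen positives.
#'
#' @param x Feature matrix.
#' @param y Factor with levels `nonECM`, `ECM`.
#' @param config An [ensemble_config()].
#' @param k Number of folds.
#' @param seed Seed controlling folds and model randomness.
#' @param folds Optional precomputed fold assignment (overrides `k`/the
#'   seed-derived partition); useful for paired comparisons.
#' @return Metrics list as in [compute_metrics()], plus pooled per-record
#'   `probabilities` and the `folds` assignment.
#' @export
cross_validate <- function(x, y, config = ensemble_config(), k = 10L,
                           seed = 1L, folds = NULL) {
  if (is.null(folds)) folds <- stratified_folds(y, k = k, seed = seed)
  cross_validate_folds(x, y, config, folds, seed = seed)
}

#' Imbalance-ratio experiment
#'
#' Rebuilds the training set at positive:negative ratios `1:r` for each `r`
#' in `ratios` (all positives plus `r * n_pos` negatives sampled without
#' replacement), runs k-fold cross-validation with a single random forest
#' (K = 1: no under-sampling ensemble, so the raw effect of imbalance on the
#' learner is visible) and averages the four metrics over `repeats`
#' resamplings.
#'
#' @param x Feature matrix.
#' @param y Factor with levels `nonECM`, `ECM`.
#' @param ratios Integer vector of negative:positive ratios.
#' @param repeats Resampling repeats per ratio.
#' @param seed Master seed.
#' @param config Base configuration (its `K` is forced to 1).
#' @param k Number of CV folds.
#' @return Data.frame with columns `ratio`, `Sn`, `Sp`, `Acc`, `BAcc`
#'   (means over repeats).
#' @export
imbalance_experiment <- function(x, y, ratios = 1:21, repeats = 10L,
                                 seed = 1L, config = ensemble_config(),
                                 k = 10L) {
  x <- as.matrix(x)
  y <- factor(y, levels = c("nonECM", "ECM"))
  pos <- which(y == "ECM")
  neg <- which(y == "nonECM")
  n_pos <- length(pos)
  if (length(neg) < max(ratios) * n_pos) {
    stop(sprintf("need %d negatives for ratio 1:%d but only %d available",
                 max(ratios) * n_pos, max(ratios), length(neg)))
  }
  config$K <- 1L
  rows <- lapply(ratios, function(r) {
    reps <- vapply(seq_len(repeats), function(i) {
      s <- derive_seed(seed, r * 1000L + i)
      take <- withr::with_seed(s, sample(neg, r * n_pos))
      idx <- c(pos, take)
      cv <- cross_validate(x[idx, , drop = FALSE], droplevels(y[idx]),
                           config, k = k, seed = s)
      c(cv$Sn, cv$Sp, cv$Acc, cv$BAcc)
    }, numeric(4))
    data.frame(ratio = r, Sn = mean(reps[1, ]), Sp = mean(reps[2, ]),
               Acc = mean(reps[3, ]), BAcc = mean(reps[4, ]))
  })
  do.call(rbind, rows)
}
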