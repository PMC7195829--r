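#' Under-sampling ensemble configuration
#'
#' @param n_trees Trees per random-forest base learner.
#' @param mtry Variables tried at each split; `"sqrt"` means
#'   `floor(sqrt(p))` for p features.
#' @param K Number of base learners; `"auto"` derives
#'   `floor(n_neg / n_pos)` from the training data.
#' @param seed Master seed; per-learner seeds are fanned out
#'   deterministically from it.
#' @param feature_subset Optional ordered character vector restricting
#'   training to these features.
#' @param decision_threshold Probability at or above which a protein is
#'   labeled ECM.
#' @param confidence_threshold Probability strictly above which a prediction
#'   is flagged high-confidence.
#' @return A list of class `ensemble_config`.
#' @export
ensemble_config <- function(n_trees = 500L, mtry = "sqrt", K = "auto",
                            seed = 1L, feature_subset = NULL,
                            decision_threshold = 0.5,
                            confidence_threshold = 0.7) {
  stopifnot(n_trees >= 1L,
            decision_threshold > 0, decision_threshold < 1,
            identical(K, "auto") || (is.numeric(K) && K >= 1))
  structure(list(n_trees = as.integer(n_trees), mtry = mtry, K = K,
                 seed = as.integer(seed), feature_subset = feature_subset,
                 decision_threshold = decision_threshold,
                 confidence_threshold = confidence_threshold),
            class = "ensemble_config")
}

#' Partition the negative class into balanced under-samples
#'
#' Negatives are shuffled with the seed and split into `K` disjoint
#' near-equal subsets (sizes differ by at most one; leftovers are appended
#' round-robin), whose union covers every negative. With `K = "auto"`,
#' `K = floor(n_neg / n_pos)`, so each subset is approximately
#' class-balanced against the full positive set.
#'
#' @param n_neg,n_pos Class counts (`n_neg >= n_pos` for a true
#'   under-sampling split; otherwise K collapses to 1 with a warning).
#' @param seed Shuffle seed.
#' @param K Number of subsets or `"auto"`.
#' @return List of K integer index vectors into `1..n_neg`.
#' @export
partition_negatives <- function(n_neg, n_pos, seed = 1L, K = "auto") {
  stopifnot(n_neg >= 1L, n_pos >= 1L)
  if (n_neg < n_pos) {
    warning("fewer negatives than positives; using a single (degenerate) subset")
    K <- 1L
  } else if (identical(K, "auto")) {
    K <- max(1L, n_neg %/% n_pos)
  }
  K <- as.integer(K)
  perm <- withr::with_seed(seed, sample.int(n_neg))
  sizes <- rep(n_neg %/% K, K)
  r <- n_neg %% K
  if (r > 0) sizes[seq_len(r)] <- sizes[seq_len(r)] + 1L
  split(perm, rep(seq_len(K), times = sizes))
}

#' Train an under-sampling ensemble of random forests
#'
#' Base learner j is a random forest trained on all positives plus the j-th
#' disjoint negative subset, restricted to `config$feature_subset` when one
#' is given. Each learner gets its own seed derived from `config$seed`, so
#' training is bit-reproducible.
#'
#' @param x Feature matrix (proteins x features, named columns).
#' @param y Factor with levels `nonECM`, `ECM` (ECM = positive class).
#' @param config An [ensemble_config()].
#' @return An object of class `ecm_ensemble`.
#' @export
train_ensemble <- function(x, y, config = ensemble_config()) {
  x <- as.matrix(x)
  y <- factor(y, levels = c("nonECM", "ECM"))
  if (nlevels(droplevels(y)) < 2L) stop("training data must contain both classes")
  if (!all(is.finite(x))) stop("non-finite feature values")
  feats <- config$feature_subset
  if (is.null(feats)) feats <- colnames(x)
  if (!all(feats %in% colnames(x))) {
    stop("feature subset not found in training matrix: ",
         paste(utils::head(setdiff(feats, colnames(x)), 3), collapse = ", "))
  }
  x <- x[, feats, drop = FALSE]
  pos <- which(y == "ECM")
  neg <- which(y == "nonECM")
  parts <- partition_negatives(length(neg), length(pos),
                               seed = config$seed, K = config$K)
  mtry <- if (identical(config$mtry, "sqrt")) {
    max(1L, floor(sqrt(ncol(x))))
  } else {
    as.integer(config$mtry)
  }
  learners <- lapply(seq_along(parts), function(j) {
    rows <- c(pos, neg[parts[[j]]])
    withr::with_seed(derive_seed(config$seed, j), {
      randomForest::randomForest(x = x[rows, , drop = FALSE],
                                 y = droplevels(y[rows]),
                                 ntree = config$n_trees, mtry = mtry)
    })
  })
  structure(list(learners = learners,
                 features = feats,
                 partition = parts,
                 config = config,
                 n_pos = length(pos), n_neg = length(neg),
                 trained_at = format(Sys.time(), tz = "UTC")),
            class = "ecm_ensemble")
}

#' Ensemble ECM probabilities
#'
#' The unweighted mean over the K base learners of each learner's ECM-class
#' probability (the fraction of its trees voting ECM).
#'
#' @param model An `ecm_ensemble`.
#' @param x Feature matrix carrying (at least) the model's feature subset.
#' @return Named numeric vector of probabilities in `[0, 1]`.
#' @export
predict_proba <- function(model, x) {
  stopifnot(inherits(model, "ecm_ensemble"))
  x <- as.matrix(x)
  miss <- setdiff(model$features, colnames(x))
  if (length(miss)) {
    stop("input lacks model feature(s): ",
         paste(utils::head(miss, 3), collapse = ", "))
  }
  if (ncol(x) != length(model$features) &&
      !all(colnames(x) %in% model$features)) {
    stop("input carries features unknown to the model; expected exactly the ",
         length(model$features), " training features")
  }
  newx <- x[, model$features, drop = FALSE]
  probs <- vapply(model$learners, function(rf) {
    stats::predict(rf, newx, type = "prob")[, "ECM"]
  }, numeric(nrow(newx)))
  probs <- matrix(probs, nrow = nrow(newx))
  p <- rowMeans(probs)
  names(p) <- rownames(x)
  p
}

#' Threshold probabilities into prediction results
#'
#' A protein is labeled ECM when its probability is at least
#' `decision_threshold`; it is flagged high-confidence when the probability
#' is strictly above `confidence_threshold` (the "higher than 0.7" rule used
#' to admit proteins into a reference catalogue of putative ECM proteins).
#'
#' @param probabilities Named numeric vector from [predict_proba()].
#' @param decision_threshold Label cut-off in (0, 1).
#' @param confidence_threshold Strict high-confidence cut-off in (0, 1).
#' @return Data.frame with columns `protein_id`, `probability`, `label`
#'   (factor `nonECM`/`ECM`) and `high_confidence` (logical).
#' @export
classify <- function(probabilities, decision_threshold = 0.5,
                     confidence_threshold = 0.7) {
  stopifnot(decision_threshold > 0, decision_threshold < 1,
            confidence_threshold > 0, confidence_threshold < 1)
  ids <- names(probabilities)
  if (is.null(ids)) ids <- as.character(seq_along(probabilities))
  data.frame(
    protein_id = ids,
    probability = as.numeric(probabilities),
    label = factor(ifelse(probabilities >= decision_threshold, "ECM", "nonECM"),
                   levels = c("nonECM", "ECM")),
    high_confidence = as.numeric(probabilities) > confidence_threshold,
    stringsAsFactors = FALSE)
}
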