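#' Discretize one feature for mutual-information scoring
#'
#' Binary 0/1 features pass through unchanged. Continuous features are
#' three-binned at mean +/- one standard deviation: code -1 below
#' `mu - sigma`, +1 above `mu + sigma`, 0 between. A zero-variance feature
#' collapses to a single constant code (its mutual information with anything
#' is then 0).
#'
#' @param values Numeric vector of finite values.
#' @return Integer code vector over \{-1, 0, +1\}.
#' @export
discretize_feature <- function(values) {
  if (!all(is.finite(values))) stop("non-finite feature values")
  u <- unique(values)
  if (all(u %in% c(0, 1))) return(as.integer(values))
  mu <- mean(values)
  sigma <- stats::sd(values)
  if (!is.finite(sigma) || sigma == 0) return(integer(length(values)))
  as.integer((values > mu + sigma) - (values < mu - sigma))
}

#' Discretize every column of a feature matrix
#'
#' @param x Numeric matrix (proteins x features).
#' @return Integer matrix of codes with the same dimnames.
#' @export
discretize_matrix <- function(x) {
  codes <- apply(x, 2L, discretize_feature)
  dimnames(codes) <- dimnames(x)
  codes
}

#' Empirical mutual information in bits
#'
#' Plug-in estimate over the empirical joint distribution of two discrete
#' vectors, log base 2. Non-negative; zero iff the empirical joint factorizes.
#'
#' @param x,y Equal-length vectors of discrete codes/labels.
#' @return Mutual information in bits.
#' @export
mutual_information <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch between x and y")
  if (length(x) < 1L) stop("empty input")
  joint <- table(x, y) / length(x)
  px <- rowSums(joint)
  py <- colSums(joint)
  nz <- joint > 0
  sum(joint[nz] * log2(joint[nz] / outer(px, py)[nz]))
}

#' mRMR feature ranking (MID scheme)
#'
#' Greedy maximum-relevance minimum-redundancy ranking in the difference
#' form: the first feature maximizes relevance `I(f; class)`; each subsequent
#' pick maximizes `I(f; class) - mean over selected s of I(f; s)`. Ties are
#' broken by input column order. All features are ranked.
#'
#' @param codes Integer code matrix from [discretize_matrix()]
#'   (proteins x features, named columns).
#' @param labels Class label vector (one per row of `codes`).
#' @return A data.frame with columns `feature`, `score` (bits) and `rank`.
#' @export
mrmr_rank <- function(codes, labels) {
  codes <- as.matrix(codes)
  p <- ncol(codes)
  if (p < 1L) stop("need at least one feature")
  if (nrow(codes) != length(labels)) stop("labels do not match feature rows")
  if (is.null(colnames(codes))) colnames(codes) <- sprintf("f%d", seq_len(p))
  relevance <- vapply(seq_len(p), function(j) {
    mutual_information(codes[, j], labels)
  }, numeric(1))
  selected <- integer(0)
  remaining <- seq_len(p)
  red_sum <- numeric(p)  # cumulative redundancy with the selected set
  scores <- numeric(p)
  for (step in seq_len(p)) {
    sc <- if (step == 1L) {
      relevance[remaining]
    } else {
      relevance[remaining] - red_sum[remaining] / length(selected)
    }
    pick <- which.max(sc)  # first maximum = input column order tie-break
    best <- remaining[pick]
    scores[best] <- sc[pick]
    selected <- c(selected, best)
    remaining <- remaining[-pick]
    if (length(remaining)) {
      red_sum[remaining] <- red_sum[remaining] +
        vapply(remaining, function(j) {
          mutual_information(codes[, j], codes[, best])
        }, numeric(1))
    }
  }
  data.frame(feature = colnames(codes)[selected],
             score = scores[selected],
             rank = seq_len(p),
             stringsAsFactors = FALSE)
}

#' Incremental feature selection curve
#'
#' Evaluates the nested top-k subsets of a feature ranking with the full
#' cross-validation protocol, reusing one fold partition (and one seed) for
#' every k so the curve isolates the effect of the subset size.
#'
#' @param x Feature matrix (proteins x features).
#' @param y Class labels (factor with positive level `ECM`).
#' @param ranking Ranking data.frame from [mrmr_rank()].
#' @param config Ensemble configuration, see [ensemble_config()].
#' @param k_folds Number of CV folds.
#' @param seed Seed controlling folds and all model randomness.
#' @param max_k Optional truncation: evaluate only the top `max_k` subset
#'   sizes (default: all).
#' @return A data.frame with one row per subset size k and columns
#'   `k`, `Sn`, `Sp`, `Acc`, `BAcc`.
#' @export
ifs_evaluate <- function(x, y, ranking, config = ensemble_config(),
                         k_folds = 10L, seed = 1L, max_k = NULL) {
  feats <- ranking$feature
  if (!all(feats %in% colnames(x))) {
    stop("ranking names features absent from the feature matrix")
  }
  kk <- if (is.null(max_k)) length(feats) else min(max_k, length(feats))
  folds <- stratified_folds(y, k = k_folds, seed = seed)
  rows <- lapply(seq_len(kk), function(k) {
    sub <- x[, feats[seq_len(k)], drop = FALSE]
    cv <- cross_validate_folds(sub, y, config, folds, seed = seed)
    data.frame(k = k, Sn = cv$Sn, Sp = cv$Sp, Acc = cv$Acc, BAcc = cv$BAcc)
  })
  do.call(rbind, rows)
}

#' Pick the optimal subset size from an IFS curve
#'
#' The smallest k attaining the maximum balanced accuracy (better
#' performance with fewer features).
#'
#' @param curve Data.frame from [ifs_evaluate()] with columns `k` and `BAcc`.
#' @return Integer k*.
#' @export
select_optimal <- function(curve) {
  if (nrow(curve) == 0L) stop("empty IFS curve")
  best <- max(curve$BAcc)
  min(curve$k[curve$BAcc == best])
}
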