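test_that("negative partitioning is balanced, disjoint and covering", {
  # corpus-scale arithmetic: 11336 negatives vs 521 positives
  parts <- partition_negatives(11336, 521, seed = 1)
  expect_length(parts, 21L)
  expect_setequal(unlist(parts), 1:11336)
  expect_true(all(lengths(parts) %in% c(539L, 540L)))

  p3 <- partition_negatives(30, 10, seed = 2)
  expect_length(p3, 3L)
  expect_equal(unname(lengths(p3)), rep(10L, 3))

  p1 <- partition_negatives(15, 15, seed = 3)
  expect_length(p1, 1L)
  expect_equal(sort(p1[[1]]), 1:15)

  expect_warning(partition_negatives(5, 10, seed = 4), "fewer negatives")

  # property: true partition over random (n_pos, n_neg) pairs
  withr::with_seed(99, {
    for (i in 1:60) {
      n_pos <- sample(1:50, 1)
      n_neg <- n_pos + sample(0:500, 1)
      pp <- partition_negatives(n_neg, n_pos, seed = i)
      expect_equal(sort(unlist(pp, use.names = FALSE)), 1:n_neg)
      expect_equal(length(pp), max(1, n_neg %/% n_pos))
      expect_lte(diff(range(lengths(pp))), 1L)
    }
  })
})

test_that("ensemble training is deterministic and separates separable data", {
  toy <- toy_informative_data(n_per_class = 50)
  model <- train_ensemble(toy$x, toy$y, fast_config(seed = 11))
  prob <- predict_proba(model, toy$x)
  res <- classify(prob)
  m <- compute_metrics(confusion_counts(toy$y, res$label))
  expect_equal(m$BAcc, 1.0)

  # same seed twice: identical predictions
  model2 <- train_ensemble(toy$x, toy$y, fast_config(seed = 11))
  expect_identical(predict_proba(model2, toy$x), prob)

  expect_error(train_ensemble(toy$x, factor(rep("ECM", nrow(toy$x)),
                                            levels = c("nonECM", "ECM")),
                              fast_config()), "both classes")
  expect_error(train_ensemble(toy$x, toy$y,
                              fast_config(feature_subset = "absent_feature")),
               "not found")
})

test_that("a K=1 ensemble on balanced data equals a directly trained forest", {
  toy <- toy_informative_data(n_per_class = 40)
  cfg <- fast_config(seed = 17, K = 1)
  model <- train_ensemble(toy$x, toy$y, cfg)
  expect_length(model$learners, 1L)
  direct <- withr::with_seed(ecmscout:::derive_seed(17L, 1L), {
    randomForest::randomForest(x = toy$x[c(which(toy$y == "ECM"),
                                           which(toy$y == "nonECM")[
                                             model$partition[[1]]]), ],
                               y = toy$y[c(which(toy$y == "ECM"),
                                           which(toy$y == "nonECM")[
                                             model$partition[[1]]])],
                               ntree = 100, mtry = floor(sqrt(ncol(toy$x))))
  })
  expect_equal(unname(predict_proba(model, toy$x)),
               unname(predict(direct, toy$x, type = "prob")[, "ECM"]))
})

test_that("ensemble probabilities are learner means inside the learner range", {
  toy <- toy_informative_data(n_per_class = 30, seed = 8)
  model <- train_ensemble(toy$x, toy$y, fast_config(seed = 3))
  newx <- toy$x[1:10, ]
  per_learner <- vapply(model$learners, function(rf) {
    predict(rf, newx, type = "prob")[, "ECM"]
  }, numeric(10))
  p <- predict_proba(model, newx)
  expect_equal(unname(p), unname(rowMeans(per_learner)))
  expect_true(all(p >= apply(per_learner, 1, min) - 1e-12))
  expect_true(all(p <= apply(per_learner, 1, max) + 1e-12))
})

test_that("classification thresholds follow the strict high-confidence rule", {
  p <- c(a = 0.70, b = 0.49, c = 0.71, d = 1.0, e = 0.5)
  res <- classify(p, decision_threshold = 0.5, confidence_threshold = 0.7)
  expect_equal(as.character(res$label), c("ECM", "nonECM", "ECM", "ECM", "ECM"))
  # probability of exactly 0.7 is NOT high-confidence ("higher than 0.7")
  expect_equal(res$high_confidence, c(FALSE, FALSE, TRUE, TRUE, FALSE))
  # high confidence implies the ECM label at default thresholds
  expect_true(all(res$label[res$high_confidence] == "ECM"))
  expect_error(classify(p, decision_threshold = 0), "decision_threshold")
})

test_that("on pure-noise features the balanced resamples remove the prior skew", {
  withr::with_seed(31, {
    n_pos <- 30; n_neg <- 630
    x <- matrix(rnorm((n_pos + n_neg) * 12), ncol = 12,
                dimnames = list(NULL, sprintf("f%d", 1:12)))
    y <- factor(rep(c("ECM", "nonECM"), c(n_pos, n_neg)),
                levels = c("nonECM", "ECM"))
    x_new <- matrix(rnorm(200 * 12), ncol = 12,
                    dimnames = list(NULL, sprintf("f%d", 1:12)))
  })
  model <- train_ensemble(x, y, fast_config(seed = 31))
  expect_length(model$learners, 21L)
  p <- predict_proba(model, x_new)
  expect_lt(abs(mean(p) - 0.5), 0.05)
})
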