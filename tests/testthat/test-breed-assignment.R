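# Shared-covariance discriminant fitting, posterior prediction, the
# minimum-posterior threshold, and confusion summaries.

gauss_train <- function(n_per, means, sd = 1, seed = 1) {
  set.seed(seed)
  cls <- rownames(means)
  X <- do.call(rbind, lapply(seq_along(cls), function(k) {
    matrix(rnorm(n_per * ncol(means), mean = rep(means[k, ], each = n_per),
                 sd = sd), n_per)
  }))
  colnames(X) <- colnames(means) %||% sprintf("v%d", seq_len(ncol(means)))
  list(X = X, labels = rep(cls, each = n_per))
}

test_that("two univariate classes split at the midpoint", {
  # exact two-point-mass construction: means 0 and 4, equal spread
  X <- matrix(c(-1, 1, 3, 5), ncol = 1, dimnames = list(NULL, "v1"))
  fit <- fit_cda(X, labels = c("a", "a", "b", "b"), priors = "equal")
  at2 <- predict(fit, matrix(2, 1, 1, dimnames = list(NULL, "v1")))
  expect_equal(unname(at2$posterior[1, ]), c(0.5, 0.5))
  expect_equal(at2$predicted, "a")           # tie -> lexicographically first
  expect_equal(predict(fit, matrix(2.2, 1, 1))$predicted, "b")
  expect_equal(predict(fit, matrix(1.8, 1, 1))$predicted, "a")
})

test_that("canonical axes span c-1 dimensions ordered by eigenvalue", {
  means <- rbind(a = c(0, 0), b = c(8, 0), c = c(0, 5))
  tr <- gauss_train(30, means, seed = 2)
  fit <- fit_cda(tr$X, tr$labels)
  expect_equal(ncol(fit$axes), 2L)
  expect_true(all(diff(fit$axis_eigenvalues) <= 1e-10))
  expect_gt(fit$axis_eigenvalues[1], fit$axis_eigenvalues[2])
  # whitened between-scatter eigenvalues from a direct dense oracle
  W <- fit$cov
  cls <- fit$classes
  nk <- table(tr$labels)[cls]
  gm <- colMeans(tr$X)
  B <- Reduce(`+`, lapply(seq_along(cls), function(k) {
    d <- fit$means[k, ] - gm
    as.numeric(nk[k]) * tcrossprod(d)
  })) / (length(cls) - 1)
  oracle <- sort(Re(eigen(solve(W) %*% B)$values), decreasing = TRUE)[1:2]
  expect_equal(fit$axis_eigenvalues, oracle, tolerance = 1e-8)
})

test_that("a constant marker makes the fit singular unless ridged", {
  X <- cbind(v1 = c(rnorm(10), rnorm(10, 4)), v2 = rep(1, 20))
  labels <- rep(c("a", "b"), each = 10)
  expect_error(fit_cda(X, labels), "ridge")
  fit <- fit_cda(X, labels, ridge = 1e-3)
  expect_s3_class(fit, "cda_model")
  expect_equal(predict(fit, X[1, , drop = FALSE])$predicted, "a")
})

test_that("class-size and label preconditions are enforced", {
  X <- matrix(rnorm(6), 3, 2, dimnames = list(NULL, c("v1", "v2")))
  expect_error(fit_cda(X, labels = c("a", "a", "b")), ">= 2 individuals")
  expect_error(fit_cda(X, labels = rep("a", 3)), "two classes")
  expect_error(fit_cda(X, labels = c("a", "a")), "one class label per row")
})

test_that("an individual at a class mean gets that class's top posterior", {
  means <- rbind(a = c(0, 0, 0), b = c(3, 1, 0), c = c(0, 4, 2))
  tr <- gauss_train(40, means, seed = 3)
  fit <- fit_cda(tr$X, tr$labels, priors = "equal")
  at_b <- predict(fit, fit$means["b", , drop = FALSE])
  expect_equal(at_b$predicted, "b")
  expect_equal(max(at_b$posterior), at_b$posterior[1, "b"])
})

test_that("posteriors match the dense Bayes oracle and sum to one", {
  set.seed(17)
  for (rep_i in 1:5) {
    means <- matrix(rnorm(5 * 20, sd = 2), 5,
                    dimnames = list(paste0("c", 1:5), sprintf("v%d", 1:20)))
    tr <- gauss_train(50, means, seed = 100 + rep_i)
    fit <- fit_cda(tr$X, tr$labels)
    Xnew <- matrix(rnorm(8 * 20), 8, dimnames = list(NULL, colnames(tr$X)))
    res <- predict(fit, Xnew)
    oracle <- bayes_posterior_oracle(Xnew, fit$means, fit$cov, fit$priors)
    expect_equal(unname(res$posterior), unname(oracle), tolerance = 1e-10)
    expect_equal(unname(rowSums(res$posterior)), rep(1, 8),
                 tolerance = 1e-12)
  }
})

test_that("the fitted model is invariant to training-sample order", {
  means <- rbind(a = c(0, 0), b = c(4, 2))
  tr <- gauss_train(25, means, seed = 5)
  fit1 <- fit_cda(tr$X, tr$labels)
  perm <- sample(nrow(tr$X))
  fit2 <- fit_cda(tr$X[perm, ], tr$labels[perm])
  expect_equal(fit1$means, fit2$means)
  expect_equal(fit1$cov, fit2$cov, tolerance = 1e-12)
  expect_equal(abs(fit1$axes), abs(fit2$axes), tolerance = 1e-8)
})

test_that("posteriors agree with an independent reference implementation", {
  skip_if_not_installed("MASS")
  means <- rbind(a = c(0, 0, 0), b = c(2, 1, 0), c = c(0, 2, 2))
  tr <- gauss_train(40, means, seed = 8)
  fit <- fit_cda(tr$X, tr$labels, priors = "proportional")
  Xnew <- matrix(rnorm(12 * 3), 12, dimnames = list(NULL, colnames(tr$X)))
  ref <- MASS::lda(tr$X, grouping = tr$labels)
  expect_equal(unname(predict(fit, Xnew)$posterior),
               unname(predict(ref, Xnew)$posterior), tolerance = 1e-8)
})

test_that("the threshold keeps confident calls and reassigns the rest", {
  res <- structure(list(
    sample_id = c("i1", "i2", "i3"),
    posterior = rbind(c(0.70, 0.30), c(0.5493, 0.4507), c(0.66, 0.34)),
    predicted = c("NS", "NS", "HY"),
    max_posterior = c(0.70, 0.5493, 0.66),
    thresholded = rep(NA_character_, 3), threshold = NULL),
    class = "assignment_result")
  colnames(res$posterior) <- c("NS", "HY")
  out <- apply_threshold(res, threshold_rule(0.65, "HY"))
  expect_equal(out$thresholded, c("NS", "HY", "HY"))
  # tau near 0: everything keeps its predicted class
  lo <- apply_threshold(res, threshold_rule(1e-6, "HY"))
  expect_equal(lo$thresholded, res$predicted)
  expect_error(threshold_rule(0), "between 0 and 1")
  expect_error(threshold_rule(1), "between 0 and 1")
})

test_that("raising tau never increases the number keeping a breed label", {
  set.seed(23)
  means <- rbind(a = c(0, 0), b = c(1.5, 0.5), HY = c(0.7, 0.2))
  tr <- gauss_train(30, means, seed = 23)
  fit <- fit_cda(tr$X, tr$labels)
  res <- predict(fit, tr$X)
  kept <- vapply(c(0.4, 0.5, 0.65, 0.8, 0.95), function(tau) {
    sum(apply_threshold(res, threshold_rule(tau))$thresholded != "HY")
  }, numeric(1))
  expect_true(all(diff(kept) <= 0))
})

test_that("assignment rates approach 100% as separation grows", {
  rates <- vapply(c(0.5, 2, 8), function(sep) {
    means <- rbind(a = c(0, 0), b = c(sep, 0), c = c(0, sep))
    tr <- gauss_train(40, means, seed = 11)
    fit <- fit_cda(tr$X, tr$labels)
    mean(predict(fit, tr$X)$predicted == tr$labels)
  }, numeric(1))
  expect_true(all(diff(rates) >= 0))
  expect_equal(rates[3], 1)
})

test_that("confusion summaries report counts, rates and error destinations", {
  res <- structure(list(
    sample_id = sprintf("i%d", 1:6),
    posterior = matrix(rep(c(0.9, 0.05, 0.05), 6), 6, byrow = TRUE,
                       dimnames = list(NULL, c("A", "B", "HY"))),
    predicted = c("A", "A", "B", "A", "B", "B"),
    max_posterior = c(0.9, 0.9, 0.9, 0.6, 0.9, 0.5),
    thresholded = rep(NA_character_, 6), threshold = NULL),
    class = "assignment_result")
  truth <- c("A", "A", "B", "B", "B", "B")
  sm <- assignment_summary(res, truth)
  expect_equal(sm$overall[["rate_cda"]], 5 / 6)
  expect_equal(sm$per_class$wrong_destinations[sm$per_class$true_class == "B"],
               "A")
  all_ok <- assignment_summary(
    structure(list(sample_id = "i1",
                   posterior = matrix(c(0.99, 0.01), 1,
                                      dimnames = list(NULL, c("A", "B"))),
                   predicted = "A", max_posterior = 0.99,
                   thresholded = NA_character_, threshold = NULL),
              class = "assignment_result"), "A")
  expect_equal(all_ok$overall[["rate_cda"]], 1)
  expect_equal(all_ok$per_class$wrong_destinations, "")
  # a rate recomputed from counts: 284 of 300 correct is 94.7%
  expect_equal(round(100 * 284 / 300, 1), 94.7)
  expect_error(assignment_summary(res, truth[1:3]), "one truth label")
})

test_that("summarizing an empty cohort is an explicit error", {
  empty <- structure(list(sample_id = character(0),
                          posterior = matrix(numeric(0), 0, 2,
                                             dimnames = list(NULL, c("A", "B"))),
                          predicted = character(0),
                          max_posterior = numeric(0),
                          thresholded = character(0), threshold = NULL),
                     class = "assignment_result")
  expect_error(assignment_summary(empty, character(0)), "empty")
})
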