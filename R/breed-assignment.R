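# Canonical discriminant breed assignment: shared-covariance Gaussian
# classifier over panel dosages, canonical axes for visualization, a
# minimum-posterior threshold that reassigns low-confidence calls to the
# hybrid class, and confusion summaries.

as_dosage_matrix <- function(x) {
  if (inherits(x, "genotype_dataset")) x$dosage else as.matrix(x)
}

#' Fit the canonical discriminant assignment model
#'
#' Computes per-class mean dosage vectors, the pooled within-class
#' covariance, class priors and the canonical axes (eigenvectors of the
#' within^-1 x between scatter problem, at most `n_classes - 1`). Genotypes
#' enter as numeric dosages 0/1/2 without scaling. Classification uses the
#' full shared-covariance Gaussian rule; the canonical axes are retained for
#' projection and plotting.
#'
#' @param x a [genotype_dataset()] restricted to the panel SNPs (no missing
#'   calls), or a numeric matrix with named columns.
#' @param labels class label per row; defaults to the dataset's population
#'   column. At least two classes, each with at least two members.
#' @param priors `"proportional"` (training class frequencies, default) or
#'   `"equal"`, or a named numeric vector summing to 1.
#' @param ridge non-negative ridge coefficient: `ridge * mean(diag(W))` is
#'   added to the diagonal of the pooled covariance `W`, allowing fits in
#'   the presence of monomorphic (constant) panel columns. Default 0.
#' @return An object of class `cda_model`: `classes` (sorted labels),
#'   `means`, `cov` (pooled within-class covariance after any ridge),
#'   `priors`, `axes` (p x k canonical axes), `axis_eigenvalues`,
#'   `snp_ids`, `ridge`.
#' @export
fit_cda <- function(x, labels = NULL, priors = c("proportional", "equal"),
                    ridge = 0) {
  X <- as_dosage_matrix(x)
  if (is.null(labels) && inherits(x, "genotype_dataset")) {
    labels <- x$samples$population
  }
  if (is.null(labels) || length(labels) != nrow(X)) {
    stop_("need one class label per row")
  }
  if (anyNA(X)) stop_("training genotypes must have no missing calls")
  classes <- sort(unique(as.character(labels)))
  c_n <- length(classes)
  if (c_n < 2L) stop_("need at least two classes")
  nk <- table(factor(labels, levels = classes))
  if (any(nk < 2L)) {
    stop_("every class needs >= 2 individuals; too small: ",
          paste(classes[nk < 2], collapse = ", "))
  }
  p <- ncol(X)
  n <- nrow(X)

  means <- matrix(0, c_n, p, dimnames = list(classes, colnames(X)))
  W <- matrix(0, p, p)
  for (k in seq_len(c_n)) {
    Xk <- X[labels == classes[k], , drop = FALSE]
    means[k, ] <- colMeans(Xk)
    W <- W + crossprod(sweep(Xk, 2, means[k, ]))
  }
  W <- W / (n - c_n)
  if (ridge > 0) {
    md <- mean(diag(W))
    if (md == 0) md <- 1
    W <- W + diag(ridge * md, p)
  }

  if (is.character(priors)) {
    priors <- match.arg(priors)
    pri <- if (priors == "equal") rep(1 / c_n, c_n) else as.numeric(nk) / n
    names(pri) <- classes
  } else {
    pri <- priors[classes]
    if (anyNA(pri) || abs(sum(pri) - 1) > 1e-8 || any(pri < 0)) {
      stop_("priors must be named, non-negative and sum to 1 over the classes")
    }
  }

  U <- tryCatch(chol(W), error = function(e) {
    stop_("pooled within-class covariance is singular (constant or ",
          "collinear panel columns); refit with ridge > 0")
  })

  # canonical axes: generalized eigenproblem of between vs within scatter,
  # solved in the whitened space L^-1 B L^-T with W = L L'
  gmean <- colMeans(X)
  B <- matrix(0, p, p)
  for (k in seq_len(c_n)) {
    d <- means[k, ] - gmean
    B <- B + nk[[k]] * tcrossprod(d)
  }
  B <- B / max(c_n - 1, 1)
  L <- t(U)
  C <- forwardsolve(L, t(forwardsolve(L, B)))
  C <- (C + t(C)) / 2
  ed <- eigen(C, symmetric = TRUE)
  keep <- seq_len(min(p, c_n - 1L))
  axes <- backsolve(U, ed$vectors[, keep, drop = FALSE])
  # fix sign: largest-magnitude loading positive, for reproducibility
  for (j in seq_len(ncol(axes))) {
    i <- which.max(abs(axes[, j]))
    if (axes[i, j] < 0) axes[, j] <- -axes[, j]
  }
  rownames(axes) <- colnames(X)

  structure(list(classes = classes, means = means, cov = W, chol = U,
                 priors = pri, axes = axes,
                 axis_eigenvalues = ed$values[keep],
                 snp_ids = colnames(X), n_train = n, ridge = ridge),
            class = "cda_model")
}

#' @export
print.cda_model <- function(x, ...) {
  cat("<cda_model> ", length(x$classes), " classes, ", length(x$snp_ids),
      " markers, ", x$n_train, " training samples\n", sep = "")
  cat("  classes:", paste(x$classes, collapse = ", "), "\n")
  cat("  priors: ", paste(sprintf("%.3f", x$priors), collapse = ", "), "\n")
  invisible(x)
}

#' Project samples onto the canonical axes
#'
#' @param model a [fit_cda()] model.
#' @param x dataset or matrix with the model's markers.
#' @return Matrix of canonical scores (centered at the grand mean of the
#'   class means).
#' @export
canonical_scores <- function(model, x) {
  X <- as_dosage_matrix(x)
  X <- check_model_columns(model, X)
  sweep(X, 2, colMeans(model$means)) %*% model$axes
}

check_model_columns <- function(model, X) {
  if (ncol(X) != length(model$snp_ids)) {
    stop_("marker dimension mismatch: model has ", length(model$snp_ids),
          ", data has ", ncol(X))
  }
  if (!is.null(colnames(X)) && !identical(colnames(X), model$snp_ids)) {
    j <- match(model$snp_ids, colnames(X))
    if (anyNA(j)) stop_("data lack model markers: ",
                        paste(model$snp_ids[is.na(j)], collapse = ", "))
    X <- X[, j, drop = FALSE]
  }
  X
}

#' Predict class posteriors for new individuals
#'
#' Posterior of class k is proportional to
#' `prior_k * exp(-0.5 * (x - mu_k)' W^-1 (x - mu_k))`, normalized over
#' classes (the shared-covariance Gaussian rule, computed with a stable
#' log-sum-exp). The predicted class is the posterior argmax; exact ties go
#' to the lexicographically smallest class label.
#'
#' @param object a [fit_cda()] model.
#' @param newdata a [genotype_dataset()] or matrix on the model's markers,
#'   with no missing calls.
#' @param ... unused.
#' @return An object of class `assignment_result`: `sample_id`, `posterior`
#'   (n x classes matrix), `predicted`, `max_posterior`, and `thresholded`
#'   (`NA` until [apply_threshold()] is used).
#' @export
predict.cda_model <- function(object, newdata, ...) {
  X <- as_dosage_matrix(newdata)
  if (anyNA(X)) stop_("individuals to classify must have no missing calls")
  X <- check_model_columns(object, X)
  n <- nrow(X)
  cls <- object$classes
  logd <- matrix(0, n, length(cls), dimnames = list(rownames(X), cls))
  for (k in seq_along(cls)) {
    d <- sweep(X, 2, object$means[k, ])
    z <- backsolve(object$chol, t(d), transpose = TRUE)   # solves U' z = d
    logd[, k] <- -0.5 * colSums(z^2) + log(object$priors[k])
  }
  mx <- apply(logd, 1, max)
  post <- exp(logd - mx)
  post <- post / rowSums(post)
  pred_i <- apply(post, 1, which.max)   # first maximum = smallest label
  sample_id <- if (inherits(newdata, "genotype_dataset")) {
    newdata$samples$sample_id
  } else {
    rownames(X) %||% sprintf("sample_%d", seq_len(n))
  }
  structure(list(sample_id = sample_id, posterior = post,
                 predicted = cls[pred_i],
                 max_posterior = post[cbind(seq_len(n), pred_i)],
                 thresholded = rep(NA_character_, n),
                 threshold = NULL),
            class = "assignment_result")
}

#' @export
print.assignment_result <- function(x, ...) {
  cat("<assignment_result> ", length(x$sample_id), " individuals, ",
      ncol(x$posterior), " classes\n", sep = "")
  tab <- table(x$predicted)
  cat("  predicted:",
      paste(sprintf("%s (%d)", names(tab), as.integer(tab)), collapse = ", "),
      "\n")
  if (!anyNA(x$thresholded)) {
    cat("  after threshold", x$threshold$tau, "->",
        sum(x$thresholded == x$threshold$fallback_class), "reassigned to",
        x$threshold$fallback_class, "\n")
  }
  invisible(x)
}

#' Minimum-posterior threshold rule
#'
#' @param tau minimum assignation probability an individual must reach to
#'   keep its predicted breed (default 0.65).
#' @param fallback_class label given to individuals below the threshold
#'   (default `"HY"`, i.e. presumed hybrids).
#' @return An object of class `threshold_rule`.
#' @export
threshold_rule <- function(tau = 0.65, fallback_class = "HY") {
  if (!is.numeric(tau) || length(tau) != 1L || tau <= 0 || tau >= 1) {
    stop_("tau must lie strictly between 0 and 1")
  }
  structure(list(tau = tau, fallback_class = fallback_class),
            class = "threshold_rule")
}

#' Apply the minimum-posterior threshold
#'
#' Individuals whose maximum posterior reaches `tau` keep their predicted
#' class; the rest are reassigned to the fallback (hybrid) class.
#' Individuals already predicted as the fallback class are unchanged.
#'
#' @param result an [predict.cda_model()] `assignment_result`.
#' @param rule a [threshold_rule()].
#' @return The `assignment_result` with `thresholded` filled in.
#' @export
apply_threshold <- function(result, rule = threshold_rule()) {
  stopifnot(inherits(result, "assignment_result"),
            inherits(rule, "threshold_rule"))
  result$thresholded <- ifelse(result$max_posterior >= rule$tau,
                               result$predicted, rule$fallback_class)
  result$threshold <- rule
  result
}

#' Assignment confusion summary
#'
#' Per true class: individuals correctly assigned by the discriminant rule
#' alone and (when a threshold was applied) after thresholding, the mean and
#' lowest posterior given to the true class, the mean posterior of the
#' assigned class, and where the errors went. Plus the overall correct rate.
#'
#' @param result an `assignment_result`.
#' @param truth true class label per individual (same order as `result`).
#' @return A list of class `confusion_summary`: `per_class` data.frame and
#'   `overall` (named vector of counts and rates; thresholded entries `NA`
#'   when no threshold was applied).
#' @export
assignment_summary <- function(result, truth) {
  stopifnot(inherits(result, "assignment_result"))
  n <- length(result$sample_id)
  if (n == 0L) stop_("cannot summarize an empty cohort")
  truth <- as.character(truth)
  if (length(truth) != n) {
    stop_("need one truth label per individual (", n, " individuals, ",
          length(truth), " labels)")
  }
  has_thr <- !anyNA(result$thresholded)
  classes_true <- sort(unique(truth))
  post_cols <- colnames(result$posterior)

  rows <- lapply(classes_true, function(cl) {
    idx <- which(truth == cl)
    correct <- result$predicted[idx] == cl
    p_true <- if (cl %in% post_cols) result$posterior[idx, cl] else rep(NA_real_, length(idx))
    wrong <- result$predicted[idx][!correct]
    ct <- if (has_thr) sum(result$thresholded[idx] == cl) else NA_integer_
    wrong_t <- if (has_thr) result$thresholded[idx][result$thresholded[idx] != cl] else character(0)
    data.frame(
      true_class = cl, n_total = length(idx),
      n_correct_cda = sum(correct),
      n_correct_thresholded = ct,
      mean_posterior_true = mean(p_true),
      lowest_posterior_true = suppressWarnings(min(p_true)),
      mean_posterior_assigned = mean(result$max_posterior[idx]),
      wrong_destinations = paste(sort(unique(wrong)), collapse = ","),
      wrong_destinations_thresholded =
        paste(sort(unique(wrong_t)), collapse = ","),
      stringsAsFactors = FALSE)
  })
  per_class <- do.call(rbind, rows)
  overall <- c(n_total = n,
               n_correct_cda = sum(result$predicted == truth),
               rate_cda = sum(result$predicted == truth) / n,
               n_correct_thresholded =
                 if (has_thr) sum(result$thresholded == truth) else NA_real_,
               rate_thresholded =
                 if (has_thr) sum(result$thresholded == truth) / n else NA_real_)
  structure(list(per_class = per_class, overall = overall),
            class = "confusion_summary")
}

#' @export
print.confusion_summary <- function(x, ...) {
  cat("<confusion_summary>\n")
  print.data.frame(x$per_class, row.names = FALSE, digits = 4)
  cat(sprintf("overall: %d/%d correct (%.1f%%)",
              x$overall[["n_correct_cda"]], x$overall[["n_total"]],
              100 * x$overall[["rate_cda"]]))
  if (!is.na(x$overall[["rate_thresholded"]])) {
    cat(sprintf("; with threshold %d/%d (%.1f%%)",
                as.integer(x$overall[["n_correct_thresholded"]]),
                x$overall[["n_total"]], 100 * x$overall[["rate_thresholded"]]))
  }
  cat("\n")
  invisible(x)
}

#' Write an assignment report as TSV
#'
#' One row per individual: sample_id, truth (if given), predicted class,
#' max posterior, thresholded class.
#'
#' @param result an `assignment_result`.
#' @param path output file path.
#' @param truth optional truth labels.
#' @return `path`, invisibly.
#' @export
write_assignment_report <- function(result, path, truth = NULL) {
  stopifnot(inherits(result, "assignment_result"))
  out <- data.frame(sample_id = result$sample_id,
                    truth = if (is.null(truth)) NA_character_ else as.character(truth),
                    predicted = result$predicted,
                    max_posterior = result$max_posterior,
                    thresholded = result$thresholded,
                    stringsAsFactors = FALSE)
  write_tsv(out, path)
}
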