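#' Fit a Fisher linear discriminant with covariance shrinkage
#'
#' Trains the classifier used to identify odors from color patterns: class
#' means plus a pooled within-class covariance shrunk toward the scaled
#' identity `(tr(S)/p) I`. Shrinkage is essential here because the 72
#' features typically outnumber the training patterns, making the raw
#' pooled covariance singular.
#'
#' The pooled covariance uses the maximum-likelihood denominator `n` (not
#' `n - K`), so duplicating every training pattern leaves the fitted model
#' unchanged. With `shrinkage = "auto"` the coefficient is the analytic
#' variance-minimising (Ledoit-Wolf-type) estimate; `shrinkage = 1` yields
#' a covariance proportional to the identity, i.e. nearest-class-mean
#' classification.
#'
#' @param x Numeric matrix, one training pattern per row.
#' @param labels Class label per row (at least 2 classes, each non-empty).
#' @param shrinkage `"auto"` or a coefficient in `[0, 1]`.
#' @return An `fld_model`: class means, shrunk covariance (and its
#'   inverse), the shrinkage used, and `class_labels` in first-appearance
#'   order (the tie-breaking order).
#' @export
fld_fit <- function(x, labels, shrinkage = "auto") {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  labels <- as.character(labels)
  if (nrow(x) != length(labels)) stop("one label per row of x is required")
  class_labels <- unique(labels)
  if (length(class_labels) < 2L) stop("need at least 2 classes")
  n <- nrow(x)
  p <- ncol(x)
  means <- matrix(0, length(class_labels), p,
                  dimnames = list(class_labels, colnames(x)))
  xc <- x
  for (cl in class_labels) {
    idx <- which(labels == cl)
    means[cl, ] <- colMeans(x[idx, , drop = FALSE])
    xc[idx, ] <- sweep(x[idx, , drop = FALSE], 2, means[cl, ])
  }
  s <- crossprod(xc) / n
  mu <- sum(diag(s)) / p
  if (identical(shrinkage, "auto")) {
    d2 <- sum((s - diag(mu, p))^2)
    if (d2 <= .Machine$double.eps) {
      lambda <- 1
    } else {
      s_norm2 <- sum(s^2)
      b2bar <- sum(rowSums(xc^2)^2) / n^2 - s_norm2 / n
      lambda <- max(0, min(1, min(b2bar, d2) / d2))
    }
  } else {
    lambda <- as.numeric(shrinkage)
    if (is.na(lambda) || lambda < 0 || lambda > 1) {
      stop("shrinkage must be 'auto' or a coefficient in [0, 1]")
    }
  }
  if (mu <= 0) {
    # zero within-class variance (e.g. identical replicates): any isotropic
    # metric gives nearest-class-mean, use the identity
    sigma <- diag(1, p)
    lambda <- 1
  } else {
    sigma <- (1 - lambda) * s + diag(lambda * mu, p)
  }
  ch <- tryCatch(chol(sigma), error = function(e) NULL)
  if (is.null(ch)) {
    stop("shrunk covariance is not positive definite; ",
         "increase the shrinkage coefficient")
  }
  structure(
    list(class_means = means, pooled_covariance = sigma,
         covariance_inverse = chol2inv(ch), shrinkage = lambda,
         class_labels = class_labels),
    class = "fld_model"
  )
}

#' Classify patterns with a fitted linear discriminant
#'
#' Assigns each pattern the class with the highest linear discriminant
#' score under the shared-covariance Gaussian model with equal priors,
#' `x' S^{-1} m_k - m_k' S^{-1} m_k / 2`. Ties are broken deterministically
#' in favour of the earlier class in `model$class_labels`.
#'
#' @param model An `fld_model`.
#' @param x A pattern vector or a matrix with one pattern per row.
#' @return Character vector of predicted class labels.
#' @export
fld_predict <- function(model, x) {
  stopifnot(inherits(model, "fld_model"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  x <- as.matrix(x)
  p <- ncol(model$class_means)
  if (ncol(x) != p) {
    stop("pattern dimension ", ncol(x), " does not match model dimension ", p)
  }
  w <- model$covariance_inverse %*% t(model$class_means)  # p x K
  const <- 0.5 * colSums(t(model$class_means) * w)
  scores <- x %*% w - rep(const, each = nrow(x))
  model$class_labels[apply(scores, 1L, which.max)]
}

#' @export
print.fld_model <- function(x, ...) {
  cat("<fld_model> ", length(x$class_labels), " classes, ",
      ncol(x$class_means), " features, shrinkage = ",
      format(x$shrinkage, digits = 3), "\n", sep = "")
  invisible(x)
}

# Fold x feature x odor array of (optionally per-participant-normalised)
# pattern vectors for one fold assignment. `m` is the flattened
# participant-feature matrix (n_part x (72 * n_odors)).
.fold_odor_array <- function(m, assignment, n_odors, n_folds, normalize) {
  fm <- rowsum(m, assignment)  # n_folds x (72 * n_odors), fold order 1..k
  if (normalize) {
    fm <- fm / as.vector(table(assignment))
  }
  array(fm, dim = c(n_folds, 72L, n_odors))
}

# One full cross-validation pass: rotate each fold as test set once.
# Returns total correct / (n_folds * n_odors).
.one_cv_pass <- function(fm, odors, n_folds, shrinkage) {
  n_odors <- length(odors)
  correct <- 0L
  for (f in seq_len(n_folds)) {
    tr <- setdiff(seq_len(n_folds), f)
    xtr <- do.call(rbind, lapply(tr, function(ff) t(fm[ff, , ])))
    fit <- fld_fit(xtr, rep(odors, times = length(tr)), shrinkage = shrinkage)
    pred <- fld_predict(fit, t(fm[f, , ]))
    correct <- correct + sum(pred == odors)
  }
  correct / (n_folds * n_odors)
}

#' Cross-validated odor classification accuracy
#'
#' For each of `n_shuffles` random refoldings, partitions the group's
#' participants into `n_folds` folds, compiles one color pattern per fold
#' and odor, trains the discriminant on all but one fold and classifies
#' the held-out fold's odor patterns, rotating every fold through the test
#' role. Each refolding yields one accuracy (correct / number of odors,
#' averaged over rotations); the vector of refolding accuracies is the
#' stable accuracy sample.
#'
#' @param dataset An `odor_dataset`.
#' @param group Group label.
#' @param n_folds Number of cross-validation folds (default 3).
#' @param n_shuffles Number of random refoldings (default 1000).
#' @param seed Master RNG seed.
#' @param shrinkage Passed to [fld_fit()].
#' @param normalize Divide each fold pattern by its participant count
#'   before classification (default `TRUE`), removing fold-size scale
#'   differences.
#' @return Numeric vector of `n_shuffles` accuracies in `[0, 1]`.
#' @export
cv_accuracy <- function(dataset, group, n_folds = 3L, n_shuffles = 1000L,
                        seed = 1L, shrinkage = "auto", normalize = TRUE) {
  parts <- .group_participants(dataset, group)
  n_folds <- as.integer(n_folds)
  if (n_folds < 2L || n_folds > length(parts)) {
    stop("n_folds must be between 2 and the number of participants (",
         length(parts), ")")
  }
  arr <- .participant_feature_array(dataset, group)
  m <- matrix(arr, nrow = length(parts))
  odors <- dataset$odors
  vapply(seq_len(n_shuffles), function(s) {
    assignment <- .with_stream(seed, 21L, s,
                               expr = .random_fold_assignment(parts, n_folds))
    fm <- .fold_odor_array(m, assignment, length(odors), n_folds, normalize)
    .one_cv_pass(fm, odors, n_folds, shrinkage)
  }, numeric(1))
}

# Chosen color ids per trial, used to rebuild permuted feature matrices.
.trial_choices <- function(arr) {
  n_part <- dim(arr)[1]
  n_odors <- dim(arr)[3]
  cong <- vector("list", n_part * n_odors)
  incong <- vector("list", n_part * n_odors)
  for (o in seq_len(n_odors)) {
    for (pp in seq_len(n_part)) {
      k <- (o - 1L) * n_part + pp
      cong[[k]] <- which(arr[pp, 1:36, o] == 1L)
      incong[[k]] <- which(arr[pp, 37:72, o] == 1L)
    }
  }
  list(cong = cong, incong = incong, n_part = n_part, n_odors = n_odors)
}

# Feature matrix after permuting color identity. scheme "per_trial" draws an
# independent permutation of the 36 colors for every participant x odor
# trial (destroys cross-participant agreement); "global" applies one shared
# permutation to all trials (preserves within-group agreement).
.permuted_matrix <- function(choices, scheme) {
  n_part <- choices$n_part
  n_odors <- choices$n_odors
  pm <- matrix(0L, n_part, 72L * n_odors)
  if (scheme == "global") {
    perm <- sample.int(36L)
  }
  for (o in seq_len(n_odors)) {
    base <- (o - 1L) * 72L
    for (pp in seq_len(n_part)) {
      k <- (o - 1L) * n_part + pp
      if (scheme == "per_trial") perm <- sample.int(36L)
      pm[pp, base + perm[choices$cong[[k]]]] <- 1L
      pm[pp, base + 36L + perm[choices$incong[[k]]]] <- 1L
    }
  }
  pm
}

#' Permutation test of classification accuracy
#'
#' Compares the observed cross-validated accuracy sample against a null
#' distribution obtained by permuting color identities, which destroys any
#' stable color-odor association while preserving each trial's 3+3
#' structure and each pattern's total counts. Each of the `n_permutations`
#' repetitions draws fresh permutations, recompiles the patterns and runs
#' one cross-validation pass (one refolding per repetition). The p-value is
#' the add-one-smoothed fraction of null accuracies at or above the mean
#' observed accuracy, `(1 + #(null >= observed)) / (1 + n_permutations)`.
#'
#' @inheritParams cv_accuracy
#' @param n_permutations Number of color-permutation repetitions
#'   (default 10000).
#' @param scheme `"per_trial"` (default): an independent color permutation
#'   per participant x odor trial; `"global"`: one shared permutation per
#'   repetition (preserves within-group consistency -- not a stability
#'   null; provided for comparison only).
#' @return An `accuracy_result`: `accuracy_sample`, `mean_accuracy`,
#'   `null_distribution`, `p`, and the call parameters.
#' @export
permutation_test <- function(dataset, group, n_folds = 3L,
                             n_shuffles = 1000L, n_permutations = 10000L,
                             seed = 1L, shrinkage = "auto", normalize = TRUE,
                             scheme = c("per_trial", "global")) {
  scheme <- match.arg(scheme)
  observed <- cv_accuracy(dataset, group, n_folds = n_folds,
                          n_shuffles = n_shuffles,
                          seed = .stream_seed(seed, 22L),
                          shrinkage = shrinkage, normalize = normalize)
  parts <- .group_participants(dataset, group)
  arr <- .participant_feature_array(dataset, group)
  choices <- .trial_choices(arr)
  odors <- dataset$odors
  n_folds <- as.integer(n_folds)
  null_acc <- vapply(seq_len(n_permutations), function(r) {
    .with_stream(seed, 23L, r, expr = {
      pm <- .permuted_matrix(choices, scheme)
      assignment <- .random_fold_assignment(parts, n_folds)
      fm <- .fold_odor_array(pm, assignment, length(odors), n_folds,
                             normalize)
      .one_cv_pass(fm, odors, n_folds, shrinkage)
    })
  }, numeric(1))
  mean_obs <- mean(observed)
  structure(
    list(accuracy_sample = observed, mean_accuracy = mean_obs,
         null_distribution = null_acc,
         p = (1 + sum(null_acc >= mean_obs)) / (1 + n_permutations),
         group = group, n_folds = n_folds, n_shuffles = n_shuffles,
         n_permutations = n_permutations, scheme = scheme, seed = seed),
    class = "accuracy_result"
  )
}

#' @export
print.accuracy_result <- function(x, ...) {
  cat("Odor classification from color patterns -- group '", x$group,
      "'\n", sep = "")
  cat(sprintf("  mean accuracy: %.1f%% (SD = %.3f, %d refoldings)\n",
              100 * x$mean_accuracy, stats::sd(x$accuracy_sample),
              length(x$accuracy_sample)))
  cat(sprintf("  permutation null: mean %.1f%% (%d repetitions, %s scheme)\n",
              100 * mean(x$null_distribution), x$n_permutations, x$scheme))
  cat(sprintf("  p = %.4g\n", x$p))
  invisible(x)
}
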