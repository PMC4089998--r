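test_that("class means average their patterns; covariance is replication-invariant", {
  x <- matrix(c(-1.1, -0.9, 0.9, 1.1), ncol = 1)
  labels <- c("a", "a", "b", "b")
  fit <- fld_fit(x, labels, shrinkage = 0)
  expect_equal(unname(fit$class_means[, 1]), c(-1, 1))
  expect_equal(fit$class_labels, c("a", "b"))

  dup <- fld_fit(rbind(x, x), c(labels, labels), shrinkage = 0)
  expect_equal(dup$class_means, fit$class_means)
  expect_equal(dup$pooled_covariance, fit$pooled_covariance)

  expect_error(fld_fit(x, c("a", "a", "a", "a")), "2 classes")
  expect_error(fld_fit(x, c("a", "b")), "one label per row")
})

test_that("prediction picks the nearer mean and breaks ties by label order", {
  x <- matrix(c(-1.1, -0.9, 0.9, 1.1), ncol = 1)
  fit <- fld_fit(x, c("a", "a", "b", "b"))
  expect_equal(fld_predict(fit, -1.05), "a")
  expect_equal(fld_predict(fit, 2), "b")
  # exactly equidistant: first class in label order wins
  expect_equal(fld_predict(fit, 0), "a")
  # the tie rule follows class-label order, not alphabetical order
  fit2 <- fld_fit(x, c("z", "z", "b", "b"))
  expect_equal(fld_predict(fit2, 0), "z")
  expect_error(fld_predict(fit, matrix(1:4, 2)), "dimension")
})

test_that("full shrinkage reduces the discriminant to nearest class mean", {
  set.seed(42)
  for (i in 1:50) {
    k <- sample(2:4, 1)
    p <- sample(2:6, 1)
    n_per <- sample(2:5, 1)
    x <- matrix(rnorm(k * n_per * p, mean = rep(1:k, each = n_per)),
                k * n_per, p)
    labels <- rep(sprintf("c%d", 1:k), each = n_per)
    fit <- fld_fit(x, labels, shrinkage = 1)
    test_x <- matrix(rnorm(3 * p), 3, p)
    got <- fld_predict(fit, test_x)
    # brute-force oracle: smallest Euclidean distance to a class mean
    oracle <- apply(test_x, 1, function(v) {
      d <- apply(fit$class_means, 1, function(m) sum((v - m)^2))
      names(d)[which.min(d)]
    })
    expect_identical(got, unname(oracle))
  }
})

test_that("auto shrinkage keeps the 72-feature covariance positive definite", {
  ds <- generate_dataset(small_config(n_parts = 9L, n_odors = 4L, seed = 3L))
  fp <- compile_fold_patterns(ds, "g1", 3L, seed = 1L)
  x <- do.call(rbind, lapply(1:2, function(f)
    t(vapply(fp$patterns[[f]], function(p) p$counts / p$n_participants,
             numeric(72)))))
  fit <- fld_fit(x, rep(ds$odors, 2))
  expect_gt(fit$shrinkage, 0)
  expect_lte(fit$shrinkage, 1)
  ev <- eigen(fit$pooled_covariance, symmetric = TRUE, only.values = TRUE)
  expect_gt(min(ev$values), 0)
  expect_equal(fit$pooled_covariance, t(fit$pooled_covariance))
})

test_that("separable data classifies perfectly; accuracies are rational multiples", {
  ds <- separable_dataset(n_parts = 9L, n_odors = 4L)
  acc <- cv_accuracy(ds, "g1", n_folds = 3L, n_shuffles = 10L, seed = 5L)
  expect_equal(acc, rep(1, 10L))

  ds2 <- generate_dataset(small_config(n_parts = 9L, n_odors = 4L,
                                       kappa = 1, seed = 8L))
  acc2 <- cv_accuracy(ds2, "g1", n_folds = 3L, n_shuffles = 25L, seed = 5L)
  expect_true(all(acc2 >= 0 & acc2 <= 1))
  # aggregation granularity: multiples of 1 / (odors x folds)
  expect_true(all(abs(acc2 * 12 - round(acc2 * 12)) < 1e-9))
  # seeded determinism
  expect_identical(acc2, cv_accuracy(ds2, "g1", 3L, 25L, seed = 5L))
})

test_that("spiky profiles give high accuracy; chance data does not", {
  cfg <- small_config(n_groups = 1L, n_parts = 12L, n_odors = 6L,
                      kappa = 0.05, seed = 10L)
  acc <- cv_accuracy(generate_dataset(cfg), "g1", n_shuffles = 20L, seed = 2L)
  expect_gt(mean(acc), 0.5)

  nd <- null_dataset(small_config(n_groups = 1L, n_parts = 12L,
                                  n_odors = 6L, seed = 11L))
  acc0 <- cv_accuracy(nd, "g1", n_shuffles = 40L, seed = 2L)
  expect_lt(abs(mean(acc0) - 1 / 6), 3 * sd(acc0) / sqrt(40) + 0.05)
})

test_that("monotonicity: smaller kappa raises mean accuracy over seeds", {
  mean_acc <- function(kappa) {
    mean(vapply(1:5, function(s) {
      cfg <- generator_config(groups = c(g = 9L),
                              odors = default_odors()[1:5],
                              kappa = kappa, rho = 0, seed = 500L + s)
      mean(cv_accuracy(generate_dataset(cfg), "g",
                       n_shuffles = 10L, seed = s))
    }, 0))
  }
  accs <- vapply(c(5, 0.5, 0.05), mean_acc, 0)
  expect_true(accs[1] < accs[3])
  expect_true(accs[2] < accs[3])
})

test_that("permutation test recovers structure and respects its floor", {
  ds <- separable_dataset(n_parts = 9L, n_odors = 4L)
  res <- permutation_test(ds, "g1", n_shuffles = 10L, n_permutations = 99L,
                          seed = 4L)
  expect_s3_class(res, "accuracy_result")
  expect_equal(res$mean_accuracy, 1)
  # add-one smoothed minimum when the null never reaches the observed level
  expect_equal(res$p, 1 / 100)
  expect_length(res$null_distribution, 99L)
  expect_true(all(res$null_distribution >= 0 & res$null_distribution <= 1))
  # the global scheme preserves within-group consistency, so its null
  # reaches the observed accuracy and the test loses its power
  resg <- permutation_test(ds, "g1", n_shuffles = 5L, n_permutations = 20L,
                           seed = 4L, scheme = "global")
  expect_gt(resg$p, 0.5)
})

test_that("type-I control: the permutation test rarely rejects null data", {
  rejections <- vapply(1:20, function(s) {
    nd <- null_dataset(generator_config(groups = c(g = 9L),
                                        odors = default_odors()[1:5],
                                        seed = 3000L + s))
    permutation_test(nd, "g", n_shuffles = 5L, n_permutations = 60L,
                     seed = s)$p <= 0.05
  }, logical(1))
  expect_lte(sum(rejections), 3L)
})

test_that("a global color relabeling leaves all accuracies unchanged", {
  ds <- generate_dataset(small_config(n_parts = 9L, n_odors = 4L,
                                      kappa = 0.3, seed = 14L))
  set.seed(1)
  perm <- sample.int(36L)
  ds2 <- relabel_colors(ds, perm)
  expect_identical(cv_accuracy(ds, "g1", n_shuffles = 15L, seed = 7L),
                   cv_accuracy(ds2, "g1", n_shuffles = 15L, seed = 7L))
})
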