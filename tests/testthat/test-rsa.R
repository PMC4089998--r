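test_that("correlation distance has the right fixed points and range", {
  expect_equal(pattern_dissimilarity(1:4, 1:4), 0)
  expect_equal(pattern_dissimilarity(1:4, 5 * (1:4) + 2), 0)
  expect_equal(pattern_dissimilarity(1:4, 4:1), 2)
  expect_error(pattern_dissimilarity(c(1, 1, 1), 1:3), "constant")
  expect_error(pattern_dissimilarity(1:3, 1:4), "equal length")
  expect_error(pattern_dissimilarity(1:2, 2:1), "length >= 3")
})

test_that("first-order RDMs are symmetric, zero-diagonal, and label-ordered", {
  ds <- generate_dataset(small_config(seed = 4L))
  rdm <- compute_rdm(ds, "g1")
  expect_valid_rdm(rdm)
  expect_equal(rdm$labels, ds$odors)
  expect_true(all(rdm$matrix >= 0 & rdm$matrix <= 2))
})

test_that("odors given identical choice data are zero-dissimilar", {
  rec <- rbind(minimal_records(odor = "fruity"),
               minimal_records(odor = "candy"),
               minimal_records(odor = "woody",
                               cong = c(10L, 11L, 12L),
                               incong = c(20L, 21L, 22L)))
  rec2 <- rec
  rec2$participant <- "p02"
  rec2$color_id[rec2$odor == "woody" & rec2$choice_type == "congruent"] <-
    c(13L, 14L, 15L)
  ds <- odor_dataset(rbind(rec, rec2))
  rdm <- compute_rdm(ds, "us")
  expect_equal(rdm$matrix["fruity", "candy"], 0)
  expect_gt(rdm$matrix["fruity", "woody"], 0)
})

test_that("planted shared-profile odor pairs come out most similar", {
  hits <- vapply(1:20, function(s) {
    cfg <- generator_config(groups = c(g = 20L),
                            odors = c("pair1", "pair2", "lone"),
                            kappa = 0.1, rho = 0, seed = 7000L + s)
    prof <- draw_profiles(cfg)
    prof[["g"]][["pair2"]] <- prof[["g"]][["pair1"]]
    m <- compute_rdm(generate_dataset(cfg, prof), "g")$matrix
    m["pair1", "pair2"] < min(m["pair1", "lone"], m["pair2", "lone"])
  }, logical(1))
  expect_gte(sum(hits), 17L)
})

test_that("the color-shuffle null centres at dissimilarity 1", {
  nd <- null_dataset(generator_config(groups = c(g = 20L), seed = 31L))
  null <- bootstrap_rdm_null(nd, "g", n_reps = 300L, seed = 9L)
  expect_length(null, 300L * choose(14, 2))
  expect_true(all(null >= 0 & null <= 2))
  expect_lt(abs(mean(null) - 1), 0.05)
  # determinism
  null2 <- bootstrap_rdm_null(nd, "g", n_reps = 10L, seed = 9L)
  expect_identical(null[seq_along(null2)], null2)
})

test_that("planted structure falls below the null's 5th percentile", {
  cfg <- generator_config(groups = c(g = 20L),
                          odors = c("pair1", "pair2", "lone"),
                          kappa = 0.1, rho = 0, seed = 77L)
  prof <- draw_profiles(cfg)
  prof[["g"]][["pair2"]] <- prof[["g"]][["pair1"]]
  ds <- generate_dataset(cfg, prof)
  obs <- compute_rdm(ds, "g")$matrix["pair1", "pair2"]
  null <- bootstrap_rdm_null(ds, "g", n_reps = 200L, seed = 5L)
  expect_lt(obs, quantile(null, 0.05))
})

test_that("participant-bootstrap resampling spreads around the observed RDM", {
  ds <- generate_dataset(small_config(n_parts = 10L, n_odors = 3L,
                                      kappa = 0.2, seed = 6L))
  boot <- bootstrap_rdm_null(ds, "g1", n_reps = 100L, seed = 2L,
                             method = "participant_bootstrap")
  obs <- compute_rdm(ds, "g1")$matrix
  expect_lt(abs(mean(boot) - mean(obs[upper.tri(obs)])), 0.25)
})

test_that("second-order RDM compares group RDMs and hits its fixed points", {
  ds <- generate_dataset(small_config(n_groups = 3L, seed = 12L))
  rdms <- lapply(ds$groups, function(g) compute_rdm(ds, g))
  names(rdms) <- ds$groups
  so <- second_order_rdm(rdms)
  expect_valid_rdm(so)
  expect_equal(so$labels, ds$groups)
  # a group against a copy of itself is zero-dissimilar
  twin <- second_order_rdm(list(a = rdms[[1]], b = rdms[[1]], c = rdms[[2]]))
  expect_equal(twin$matrix["a", "b"], 0)
  # spearman variant stays a valid RDM
  expect_valid_rdm(second_order_rdm(rdms, method = "spearman"))
  # mismatched odor sets are refused
  bad <- rdms
  bad[[2]]$labels <- rev(bad[[2]]$labels)
  dimnames(bad[[2]]$matrix) <- list(bad[[2]]$labels, bad[[2]]$labels)
  expect_error(second_order_rdm(bad), "identical odor labels")
  expect_error(second_order_rdm(rdms[1]), "at least 2")
})

test_that("odor order permutes first-order RDMs and leaves second order alone", {
  cfg <- small_config(n_groups = 2L, n_parts = 10L, n_odors = 4L,
                      kappa = 0.3, seed = 19L)
  ds <- generate_dataset(cfg)
  new_order <- c(3L, 1L, 4L, 2L)
  cfg2 <- cfg
  cfg2$odors <- cfg$odors[new_order]
  ds2 <- generate_dataset(cfg2)  # same trials, reordered odor declaration
  r1 <- compute_rdm(ds, "g1")
  r2 <- compute_rdm(ds2, "g1")
  expect_equal(r2$matrix, r1$matrix[new_order, new_order],
               tolerance = 1e-12)
  so1 <- second_order_rdm(list(a = compute_rdm(ds, "g1"),
                               b = compute_rdm(ds, "g2")))
  so2 <- second_order_rdm(list(a = compute_rdm(ds2, "g1"),
                               b = compute_rdm(ds2, "g2")))
  expect_equal(so1$matrix, so2$matrix, tolerance = 1e-12)
})

test_that("a global color relabeling leaves all dissimilarities unchanged", {
  ds <- generate_dataset(small_config(n_parts = 10L, kappa = 0.3, seed = 23L))
  set.seed(2)
  ds2 <- relabel_colors(ds, sample.int(36L))
  expect_equal(compute_rdm(ds2, "g1")$matrix, compute_rdm(ds, "g1")$matrix,
               tolerance = 1e-12)
  r <- lapply(list(ds, ds2), function(d) {
    rl <- lapply(d$groups, function(g) compute_rdm(d, g))
    names(rl) <- d$groups
    second_order_rdm(rl)$matrix
  })
  expect_equal(r[[1]], r[[2]], tolerance = 1e-12)
})

test_that("congruent-only and incongruent-only feature masks work", {
  ds <- generate_dataset(small_config(n_parts = 10L, kappa = 0.2, seed = 9L))
  expect_valid_rdm(compute_rdm(ds, "g1", features = "congruent"))
  expect_valid_rdm(compute_rdm(ds, "g1", features = "incongruent"))
})

test_that("RDMs round-trip through their delimited form", {
  ds <- generate_dataset(small_config(seed = 15L))
  rdm <- compute_rdm(ds, "g1")
  f <- tempfile(fileext = ".csv")
  write_rdm(rdm, f)
  back <- as.matrix(read.csv(f, row.names = 1, check.names = FALSE))
  expect_equal(unname(back), unname(rdm$matrix), tolerance = 1e-12)
})
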