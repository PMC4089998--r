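# Shared fixtures: all datasets are built in code, at test time.

# One participant, one odor: the minimal valid dataset.
minimal_records <- function(cong = c(2L, 5L, 7L), incong = c(30L, 31L, 36L),
                            group = "us", participant = "p01",
                            odor = "fruity") {
  data.frame(
    group = group, participant = participant, odor = odor,
    choice_type = rep(c("congruent", "incongruent"), each = 3L),
    color_id = c(cong, incong),
    stringsAsFactors = FALSE
  )
}

# A small generator configuration for fast tests.
small_config <- function(n_groups = 2L, n_parts = 8L, n_odors = 4L,
                         kappa = 0.2, rho = 0, seed = 1L, ...) {
  groups <- stats::setNames(rep(n_parts, n_groups),
                            paste0("g", seq_len(n_groups)))
  generator_config(groups = groups, odors = default_odors()[seq_len(n_odors)],
                   kappa = kappa, rho = rho, seed = seed, ...)
}

# Profiles in which every participant of every group deterministically
# chooses colors `cong` (congruent) and `incong` (incongruent) per odor.
# With one odor-specific support each odor is perfectly identifiable.
degenerate_profiles <- function(config, cong_sets, incong_sets) {
  prof <- lapply(seq_along(config$groups), function(gi) {
    pr <- lapply(seq_along(config$odors), function(oi) {
      p_cong <- rep(0, 36)
      p_cong[cong_sets[[oi]]] <- 1 / 3
      p_incong <- rep(0, 36)
      p_incong[incong_sets[[oi]]] <- 1 / 3
      list(p_cong = p_cong, p_incong = p_incong)
    })
    names(pr) <- config$odors
    pr
  })
  names(prof) <- names(config$groups)
  structure(prof, class = "generative_profiles", config = config)
}

# Deterministic, perfectly separable dataset: every participant in every
# group picks colors {3o-2, 3o-1, 3o} congruent and {3o+18, ...} incongruent
# for odor o.
separable_dataset <- function(n_groups = 1L, n_parts = 9L, n_odors = 4L,
                              seed = 1L) {
  cfg <- small_config(n_groups, n_parts, n_odors, seed = seed)
  cong <- lapply(seq_len(n_odors), function(o) (3 * o - 2):(3 * o))
  incong <- lapply(seq_len(n_odors), function(o) (3 * o + 16):(3 * o + 18))
  generate_dataset(cfg, degenerate_profiles(cfg, cong, incong))
}

expect_valid_rdm <- function(rdm) {
  expect_s3_class(rdm, "rdm")
  expect_silent(validate_rdm(rdm))
  expect_identical(unname(diag(rdm$matrix)), rep(0, length(rdm$labels)))
}
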