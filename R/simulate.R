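#' Configuration for the synthetic response generator
#'
#' The generator emulates the study design: six populations (five of 20
#' participants, one of 22, 122 in total) each smelling 14 odors and picking
#' 3 congruent plus 3 incongruent colors out of 36. Group-level association
#' structure is controlled by two knobs:
#'
#' * `kappa` -- concentration of the symmetric Dirichlet from which each
#'   group's per-odor color-propensity profiles are drawn. Small `kappa`
#'   gives spiky profiles, i.e. strong within-group agreement on which
#'   colors suit an odor; large `kappa` approaches uniform, association-free
#'   choice.
#' * `rho` -- weight in `[0, 1]` mixing a shared global profile into every
#'   group's profile. `rho = 1` makes all groups identical; `rho = 0` makes
#'   them independent.
#'
#' @param groups Named integer vector: participant count per group label.
#' @param odors Character vector of odor labels.
#' @param kappa Dirichlet concentration, `> 0`.
#' @param rho Cross-group sharing weight in `[0, 1]`.
#' @param group_pairs_shared Optional list of length-2 character vectors;
#'   the second group of each pair is forced to use the first group's
#'   profiles exactly (planted second-order structure).
#' @param seed Master RNG seed (integer).
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(groups = c(dutch = 20L, german = 20L,
                                        malay = 20L, malaysian_chinese = 20L,
                                        netherlands_chinese = 20L, us = 22L),
                             odors = default_odors(),
                             kappa = 0.5, rho = 0.3,
                             group_pairs_shared = NULL,
                             seed = 1L) {
  if (is.null(names(groups)) || any(!nzchar(names(groups)))) {
    stop("groups must be a named vector of participant counts")
  }
  groups <- vapply(groups, as.integer, integer(1))
  if (any(groups < 1L)) stop("participant counts must be >= 1")
  if (anyDuplicated(names(groups))) stop("duplicate group labels")
  if (!is.numeric(kappa) || kappa <= 0) stop("kappa must be > 0")
  if (!is.numeric(rho) || rho < 0 || rho > 1) stop("rho must be in [0, 1]")
  if (!is.null(group_pairs_shared)) {
    for (pr in group_pairs_shared) {
      if (length(pr) != 2 || !all(pr %in% names(groups))) {
        stop("group_pairs_shared entries must be pairs of known group labels")
      }
    }
  }
  odors <- tolower(trimws(odors))
  if (anyDuplicated(odors)) stop("duplicate odor labels")
  structure(
    list(groups = groups, odors = odors, kappa = kappa, rho = rho,
         group_pairs_shared = group_pairs_shared, seed = as.integer(seed)),
    class = "generator_config"
  )
}

#' Draw group-by-odor color-propensity profiles
#'
#' For every odor a global pair of propensity vectors over the 36 colors
#' (congruent and incongruent) is drawn from a symmetric Dirichlet with
#' concentration `kappa`; each group's profile is the `rho`-weighted mixture
#' of that global pair with its own independent Dirichlet draw. Groups
#' listed in `group_pairs_shared` receive identical profiles. Fully
#' determined by `config$seed`, independently of evaluation order.
#'
#' @param config A `generator_config`.
#' @return A list of class `generative_profiles`: `profiles[[group]][[odor]]`
#'   is a list with unit-sum vectors `p_cong` and `p_incong` of length 36.
#' @export
draw_profiles <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  gl <- names(config$groups)
  rdirichlet1 <- function() {
    g <- stats::rgamma(36, shape = config$kappa, rate = 1)
    if (all(g == 0)) g[] <- 1  # numeric underflow guard at tiny kappa
    g / sum(g)
  }
  prof <- vector("list", length(gl))
  names(prof) <- gl
  for (gi in seq_along(gl)) {
    prof[[gi]] <- vector("list", length(config$odors))
    names(prof[[gi]]) <- config$odors
  }
  for (oi in seq_along(config$odors)) {
    oh <- .label_hash(config$odors[oi])
    glob <- .with_stream(config$seed, 1L, oh, 0L, expr = {
      list(p_cong = rdirichlet1(), p_incong = rdirichlet1())
    })
    for (gi in seq_along(gl)) {
      own <- .with_stream(config$seed, 1L, oh, .label_hash(gl[gi]), expr = {
        list(p_cong = rdirichlet1(), p_incong = rdirichlet1())
      })
      prof[[gi]][[oi]] <- list(
        p_cong = config$rho * glob$p_cong + (1 - config$rho) * own$p_cong,
        p_incong = config$rho * glob$p_incong + (1 - config$rho) * own$p_incong
      )
    }
  }
  if (!is.null(config$group_pairs_shared)) {
    for (pr in config$group_pairs_shared) {
      prof[[pr[2]]] <- prof[[pr[1]]]
    }
  }
  structure(prof, class = "generative_profiles", config = config)
}

# One trial: 3 distinct congruent colors by sequential weighted sampling
# without replacement from p_cong, then 3 distinct incongruent colors from
# p_incong restricted to the 33 colors not chosen congruent.
.sample_trial <- function(p_cong, p_incong) {
  if (sum(p_cong > 0) < 3) {
    stop("congruent profile has fewer than 3 colors of positive mass")
  }
  cong <- sample.int(36L, 3L, replace = FALSE, prob = p_cong)
  rest <- setdiff(1:36, cong)
  w <- p_incong[rest]
  if (sum(w > 0) < 3) {
    stop("incongruent profile has fewer than 3 available colors of positive mass")
  }
  incong <- rest[sample.int(length(rest), 3L, replace = FALSE, prob = w)]
  c(cong, incong)
}

.assemble_dataset <- function(config, draw_fun) {
  gl <- names(config$groups)
  n_trials <- sum(config$groups) * length(config$odors)
  g_col <- p_col <- o_col <- character(6L * n_trials)
  t_col <- character(6L * n_trials)
  c_col <- integer(6L * n_trials)
  row <- 0L
  for (gi in seq_along(gl)) {
    for (pk in seq_len(config$groups[[gi]])) {
      pid <- sprintf("p%02d", pk)
      for (oi in seq_along(config$odors)) {
        six <- draw_fun(gi, pk, oi)
        idx <- row + 1:6
        g_col[idx] <- gl[gi]
        p_col[idx] <- pid
        o_col[idx] <- config$odors[oi]
        t_col[idx] <- rep(c("congruent", "incongruent"), each = 3L)
        c_col[idx] <- six
        row <- row + 6L
      }
    }
  }
  odor_dataset(
    data.frame(group = g_col, participant = p_col, odor = o_col,
               choice_type = t_col, color_id = c_col,
               stringsAsFactors = FALSE),
    odors = config$odors, groups = sort(gl)
  )
}

#' Generate a synthetic response dataset
#'
#' Samples every trial from the group's per-odor propensity profiles:
#' 3 congruent colors by sequential weighted sampling without replacement,
#' then 3 incongruent colors from the remaining 33 (renormalised), honoring
#' the disjointness invariant. Each (group, participant, odor) trial uses
#' its own counter-derived RNG substream, so the dataset is fully
#' determined by `config$seed`.
#'
#' @param config A `generator_config`.
#' @param profiles Optional `generative_profiles`; drawn from `config` when
#'   absent.
#' @return A validated `odor_dataset`.
#' @export
generate_dataset <- function(config, profiles = NULL) {
  stopifnot(inherits(config, "generator_config"))
  if (is.null(profiles)) profiles <- draw_profiles(config)
  gl <- names(config$groups)
  .assemble_dataset(config, function(gi, pk, oi) {
    pr <- profiles[[gl[gi]]][[config$odors[oi]]]
    .with_stream(config$seed, 2L, .label_hash(gl[gi]), pk,
                 .label_hash(config$odors[oi]),
                 expr = .sample_trial(pr$p_cong, pr$p_incong))
  })
}

#' Generate an association-free (null) dataset
#'
#' Every trial's six colors are a uniform random draw of 6 distinct color
#' ids, split 3 congruent / 3 incongruent -- the no-association null under
#' which color choices carry no information about the odor.
#'
#' @param config A `generator_config` (only `groups`, `odors`, `seed` are
#'   used).
#' @return A validated `odor_dataset`.
#' @export
null_dataset <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  gl <- names(config$groups)
  .assemble_dataset(config, function(gi, pk, oi) {
    .with_stream(config$seed, 3L, .label_hash(gl[gi]), pk,
                 .label_hash(config$odors[oi]),
                 expr = sample.int(36L, 6L, replace = FALSE))
  })
}
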