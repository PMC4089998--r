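#' Compile a 72-feature color pattern
#'
#' A color pattern summarises one group's choices for one odor as a count
#' vector of 72 features: positions 1..36 count how often each color was
#' chosen as congruent, positions 37..72 how often as incongruent. With
#' `n` contributing participants each half sums to `3 n`.
#'
#' @param dataset An `odor_dataset`.
#' @param group Group label.
#' @param odor Odor label.
#' @param participants Optional participant subset (within the group) to
#'   pool; defaults to all participants of the group.
#' @return A `color_pattern`: list with `odor`, `group`, `fold` (`NA` for a
#'   whole-group pattern), integer `counts` of length 72 and
#'   `n_participants`.
#' @export
compile_pattern <- function(dataset, group, odor, participants = NULL) {
  if (!(odor %in% dataset$odors)) stop("unknown odor: ", odor)
  all_parts <- .group_participants(dataset, group)
  if (is.null(participants)) {
    participants <- all_parts
  } else {
    participants <- tolower(trimws(participants))
    if (length(participants) == 0) stop("empty participant subset")
    bad <- setdiff(participants, all_parts)
    if (length(bad) > 0) {
      stop("participant(s) not in group ", group, ": ",
           paste(bad, collapse = ", "))
    }
  }
  rec <- dataset$records
  sel <- rec$group == group & rec$odor == odor &
    rec$participant %in% participants
  feat <- rec$color_id[sel] + 36L * (rec$choice_type[sel] == "incongruent")
  .new_pattern(tabulate(feat, nbins = 72L), odor, group,
               n_participants = length(participants))
}

.new_pattern <- function(counts, odor, group, n_participants, fold = NA_integer_) {
  structure(
    list(odor = odor, group = group, fold = fold,
         counts = as.integer(counts), n_participants = n_participants),
    class = "color_pattern"
  )
}

#' @export
print.color_pattern <- function(x, ...) {
  cat("<color_pattern> odor=", x$odor, " group=", x$group,
      if (!is.na(x$fold)) paste0(" fold=", x$fold),
      " n=", x$n_participants,
      " (congruent sum ", sum(x$counts[1:36]),
      ", incongruent sum ", sum(x$counts[37:72]), ")\n", sep = "")
  invisible(x)
}

# Per-participant 0/1 feature array for one group:
# dims (participant, 72 features, odor). Fold and whole-group patterns are
# column sums over participant subsets; cross-validation loops reuse it.
.participant_feature_array <- function(dataset, group) {
  parts <- .group_participants(dataset, group)
  rec <- dataset$records[dataset$records$group == group, , drop = FALSE]
  arr <- array(0L, dim = c(length(parts), 72L, length(dataset$odors)),
               dimnames = list(parts, NULL, dataset$odors))
  pi <- match(rec$participant, parts)
  oi <- match(rec$odor, dataset$odors)
  fi <- rec$color_id + 36L * (rec$choice_type == "incongruent")
  arr[cbind(pi, fi, oi)] <- 1L
  arr
}

# Near-equal random fold sizes: the first (n %% k) folds get the extra
# participant, e.g. 20 participants in 3 folds -> 7/7/6.
.random_fold_assignment <- function(participants, n_folds) {
  n <- length(participants)
  fold <- rep(seq_len(n_folds), length.out = n)
  assignment <- fold[order(sample.int(n))]
  names(assignment) <- participants
  assignment
}

#' Compile per-fold color patterns for cross-validation
#'
#' Partitions a group's participants into `n_folds` near-equal folds at
#' random (seeded) and compiles one pattern per fold and odor. The
#' elementwise sum of the per-fold patterns equals the whole-group pattern.
#'
#' @param dataset An `odor_dataset`.
#' @param group Group label.
#' @param n_folds Number of folds (default 3: train on two-thirds, test on
#'   the remaining third).
#' @param seed RNG seed for the partition.
#' @return A `fold_patterns`: list with `assignment` (named fold index per
#'   participant) and `patterns[[fold]][[odor]]`, each a `color_pattern`.
#' @export
compile_fold_patterns <- function(dataset, group, n_folds = 3L, seed = 1L) {
  parts <- .group_participants(dataset, group)
  n_folds <- as.integer(n_folds)
  if (n_folds < 2L || n_folds > length(parts)) {
    stop("n_folds must be between 2 and the number of participants (",
         length(parts), ")")
  }
  assignment <- .with_stream(seed, 11L,
                             expr = .random_fold_assignment(parts, n_folds))
  arr <- .participant_feature_array(dataset, group)
  patterns <- vector("list", n_folds)
  for (f in seq_len(n_folds)) {
    members <- names(assignment)[assignment == f]
    patterns[[f]] <- lapply(seq_along(dataset$odors), function(oi) {
      cnt <- colSums(arr[members, , oi, drop = FALSE])
      .new_pattern(cnt, dataset$odors[oi], group,
                   n_participants = length(members), fold = f)
    })
    names(patterns[[f]]) <- dataset$odors
  }
  structure(list(assignment = assignment, patterns = patterns,
                 group = group, n_folds = n_folds),
            class = "fold_patterns")
}

#' Export patterns as a delimited-ready matrix
#'
#' Flattens a list of `color_pattern`s into a `data.frame` with metadata
#' columns (`group`, `odor`, `fold`, `n_participants`) followed by the 72
#' feature columns `cong_1..cong_36, incong_1..incong_36`.
#'
#' @param patterns A list of `color_pattern` objects.
#' @return A `data.frame` with one row per pattern.
#' @export
patterns_table <- function(patterns) {
  stopifnot(length(patterns) > 0)
  meta <- data.frame(
    group = vapply(patterns, `[[`, "", "group"),
    odor = vapply(patterns, `[[`, "", "odor"),
    fold = vapply(patterns, `[[`, NA_integer_, "fold"),
    n_participants = vapply(patterns, `[[`, 0L, "n_participants"),
    stringsAsFactors = FALSE
  )
  counts <- t(vapply(patterns, `[[`, integer(72), "counts"))
  colnames(counts) <- c(paste0("cong_", 1:36), paste0("incong_", 1:36))
  cbind(meta, as.data.frame(counts))
}
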