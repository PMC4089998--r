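#' Correlation-distance between two color patterns
#'
#' The dissimilarity between two patterns is `1 - r`, with `r` the Pearson
#' correlation of the two feature vectors: 0 for perfectly similar
#' patterns, 1 for unrelated ones, 2 for perfectly anti-correlated ones.
#'
#' @param a,b Numeric vectors of equal length (>= 3), neither constant.
#' @return Dissimilarity in `[0, 2]`.
#' @examples
#' pattern_dissimilarity(1:4, 1:4)        # 0
#' pattern_dissimilarity(1:4, 4:1)        # 2
#' @export
pattern_dissimilarity <- function(a, b) {
  a <- as.numeric(a)
  b <- as.numeric(b)
  if (length(a) != length(b)) stop("patterns must have equal length")
  if (length(a) < 3L) stop("patterns must have length >= 3")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("correlation undefined for a constant pattern")
  }
  min(2, max(0, 1 - stats::cor(a, b)))
}

.new_rdm <- function(mat, labels, null_distribution = NULL) {
  dimnames(mat) <- list(labels, labels)
  diag(mat) <- 0
  mat <- pmin(pmax((mat + t(mat)) / 2, 0), 2)  # enforce exact symmetry
  diag(mat) <- 0
  structure(list(labels = labels, matrix = mat,
                 null_distribution = null_distribution),
            class = "rdm")
}

#' Validate a representational dissimilarity matrix
#'
#' Checks the `rdm` invariants: square with matching labels, symmetric to
#' 1e-12, diagonal exactly zero, all entries in `[0, 2]`.
#'
#' @param rdm An `rdm` object.
#' @return The object, after passing all checks.
#' @export
validate_rdm <- function(rdm) {
  stopifnot(inherits(rdm, "rdm"))
  m <- rdm$matrix
  if (nrow(m) != ncol(m) || nrow(m) != length(rdm$labels)) {
    stop("rdm matrix must be square with one row per label")
  }
  if (max(abs(m - t(m))) > 1e-12) stop("rdm matrix must be symmetric")
  if (any(diag(m) != 0)) stop("rdm diagonal must be exactly 0")
  if (any(m < 0) || any(m > 2)) stop("rdm entries must lie in [0, 2]")
  rdm
}

# 1 - Pearson correlation between all pairs of rows of x.
.cor_distance_matrix <- function(x) {
  1 - stats::cor(t(x))
}

#' First-order RDM: odor dissimilarity within a group
#'
#' Compiles the whole-group pooled 72-feature pattern of every odor and
#' assembles the matrix of pairwise `1 - Pearson r` dissimilarities. The
#' diagonal is set to exactly zero by construction.
#'
#' @param dataset An `odor_dataset`.
#' @param group Group label.
#' @param features `"both"` (default, all 72 features), `"congruent"` or
#'   `"incongruent"` (the corresponding 36-feature half only).
#' @param null_reps If `> 0`, attach a color-shuffle null distribution of
#'   dissimilarities computed with [bootstrap_rdm_null()].
#' @param seed RNG seed, required when `null_reps > 0`.
#' @return A validated `rdm` over the dataset's odors.
#' @export
compute_rdm <- function(dataset, group,
                        features = c("both", "congruent", "incongruent"),
                        null_reps = 0L, seed = NULL) {
  features <- match.arg(features)
  pats <- t(vapply(dataset$odors, function(od) {
    as.numeric(compile_pattern(dataset, group, od)$counts)
  }, numeric(72)))
  pats <- .mask_features(pats, features)
  if (any(apply(pats, 1, stats::sd) == 0)) {
    stop("constant pooled pattern: correlation distance undefined")
  }
  null_distribution <- NULL
  if (null_reps > 0L) {
    if (is.null(seed)) stop("seed is required when null_reps > 0")
    null_distribution <- bootstrap_rdm_null(dataset, group,
                                            n_reps = null_reps, seed = seed,
                                            features = features)
  }
  validate_rdm(.new_rdm(.cor_distance_matrix(pats), dataset$odors,
                        null_distribution))
}

.mask_features <- function(pats, features) {
  switch(features,
         both = pats,
         congruent = pats[, 1:36, drop = FALSE],
         incongruent = pats[, 37:72, drop = FALSE])
}

#' Null / uncertainty distribution of RDM dissimilarities
#'
#' `method = "color_shuffle"` (default) repeatedly permutes color
#' identities per trial (the same scheme as the classification null),
#' recomputes the RDM and collects all strict-upper-triangle values: the
#' distribution of dissimilarities expected when color-odor associations
#' carry no shared structure. `method = "participant_bootstrap"` instead
#' resamples participants with replacement, giving an uncertainty (not
#' null) distribution for the observed dissimilarities.
#'
#' @inheritParams compute_rdm
#' @param n_reps Number of repetitions.
#' @param seed RNG seed.
#' @param method `"color_shuffle"` or `"participant_bootstrap"`.
#' @return Numeric vector of `n_reps * choose(n_odors, 2)` dissimilarities.
#' @export
bootstrap_rdm_null <- function(dataset, group, n_reps = 1000L, seed = 1L,
                               features = c("both", "congruent",
                                            "incongruent"),
                               method = c("color_shuffle",
                                          "participant_bootstrap")) {
  features <- match.arg(features)
  method <- match.arg(method)
  arr <- .participant_feature_array(dataset, group)
  n_part <- dim(arr)[1]
  n_odors <- dim(arr)[3]
  m <- matrix(arr, nrow = n_part)
  choices <- .trial_choices(arr)
  ut <- upper.tri(matrix(0, n_odors, n_odors))
  out <- lapply(seq_len(n_reps), function(r) {
    .with_stream(seed, 31L, r, expr = {
      mm <- if (method == "color_shuffle") {
        .permuted_matrix(choices, "per_trial")
      } else {
        m[sample.int(n_part, n_part, replace = TRUE), , drop = FALSE]
      }
      pooled <- matrix(colSums(mm), nrow = n_odors, byrow = TRUE)
      d <- .cor_distance_matrix(.mask_features(pooled, features))
      pmin(2, pmax(0, d[ut]))
    })
  })
  unlist(out)
}

#' Second-order RDM: dissimilarity between group RDMs
#'
#' Quantifies the second-order isomorphism across groups: for every pair
#' of groups the dissimilarity is `1 - r` between the vectorised strict
#' upper triangles of their odor RDMs (Pearson by default, Spearman
#' optionally).
#'
#' @param rdms Named list of `rdm` objects (one per group) with identical
#'   odor labels in identical order.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return A validated `rdm` over the groups.
#' @export
second_order_rdm <- function(rdms, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(rdms) < 2L) stop("need at least 2 group RDMs")
  if (is.null(names(rdms)) || any(!nzchar(names(rdms)))) {
    stop("rdms must be a named list (one name per group)")
  }
  lab0 <- rdms[[1]]$labels
  for (r in rdms) {
    validate_rdm(r)
    if (!identical(r$labels, lab0)) {
      stop("all RDMs must share identical odor labels in identical order")
    }
  }
  ut <- upper.tri(rdms[[1]]$matrix)
  vecs <- t(vapply(rdms, function(r) r$matrix[ut],
                   numeric(sum(ut))))
  d <- 1 - stats::cor(t(vecs), method = method)
  validate_rdm(.new_rdm(pmin(pmax(d, 0), 2), names(rdms)))
}

#' @export
print.rdm <- function(x, ...) {
  cat("<rdm> ", length(x$labels), " x ", length(x$labels), " (",
      paste(utils::head(x$labels, 4), collapse = ", "),
      if (length(x$labels) > 4) ", ...", ")",
      if (!is.null(x$null_distribution))
        paste0("; null distribution of ", length(x$null_distribution),
               " values"),
      "\n", sep = "")
  print(round(x$matrix, 3))
  invisible(x)
}

#' @export
as.matrix.rdm <- function(x, ...) x$matrix

#' Write an RDM as a labeled delimited matrix
#'
#' @param rdm An `rdm`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_rdm <- function(rdm, path) {
  utils::write.csv(as.data.frame(rdm$matrix), path, row.names = TRUE,
                   quote = FALSE)
  invisible(path)
}
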