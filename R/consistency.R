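#' Pearson chi-square test against a fixed expectation
#'
#' Computes the Pearson goodness-of-fit statistic
#' \eqn{\sum_i (O_i - E_i)^2 / E_i} for an observed count vector against a
#' fixed expectation (uniform over cells when not supplied), with
#' `df = length(counts) - 1` and the upper-tail chi-square p-value.
#'
#' @param counts Non-negative count vector with positive total.
#' @param expected Optional strictly positive expectation vector of the same
#'   length and total.
#' @return A list with `chi2`, `df` and `p`.
#' @examples
#' chi_square_uniform(c(6, 0, 0))  # chi2 = 12, df = 2
#' @export
chi_square_uniform <- function(counts, expected = NULL) {
  counts <- as.numeric(counts)
  if (length(counts) < 2L) stop("counts must have length >= 2")
  if (any(is.na(counts)) || any(counts < 0)) {
    stop("counts must be non-negative")
  }
  total <- sum(counts)
  if (total <= 0) stop("counts must have a positive total")
  if (is.null(expected)) {
    expected <- rep(total / length(counts), length(counts))
  } else {
    expected <- as.numeric(expected)
    if (length(expected) != length(counts)) {
      stop("expected must match the length of counts")
    }
    if (any(is.na(expected)) || any(expected <= 0)) {
      stop("expected cells must be strictly positive")
    }
    if (abs(sum(expected) - total) > 1e-8 * max(1, total)) {
      stop("expected must have the same total as counts")
    }
  }
  chi2 <- sum((counts - expected)^2 / expected)
  df <- length(counts) - 1L
  list(chi2 = chi2, df = df,
       p = stats::pchisq(chi2, df = df, lower.tail = FALSE))
}

#' Per-odor chi-square consistency tests within a group
#'
#' For every odor, tests whether the group's pooled color choices deviate
#' from uniform random choice. The congruent and incongruent 36-count
#' vectors are tested separately (df = 35 each) and combined as the sum of
#' the two statistics (df = 70); the combined p-value is the one flagged
#' against the Bonferroni-corrected threshold `alpha / m`.
#'
#' Because each participant contributes 3 *distinct* colors per choice
#' type (sampling without replacement from the 36-color palette), the raw
#' Pearson statistic is underdispersed relative to the chi-square reference.
#' With `correct = TRUE` (default) each statistic is rescaled by the
#' standard finite-population factor \eqn{(K-1)/(K-m) = 35/33}
#' (K = 36 colors, m = 3 choices), which restores nominal type-I error;
#' `correct = FALSE` gives the plain statistic.
#'
#' @param dataset An `odor_dataset`.
#' @param group Group label.
#' @param alpha Family-wise error rate for the Bonferroni flag.
#' @param m Number of comparisons in the family; defaults to
#'   `length(groups) * length(odors)` of the dataset (84 in the reference
#'   design), so the default per-test threshold is `0.05 / 84 = 0.0006`
#'   (rounded).
#' @param correct Apply the finite-population calibration factor
#'   (default `TRUE`).
#' @return A `data.frame` of class `consistency_result` with one row per
#'   odor: `group`, `odor`, `chi2_congruent`, `p_congruent`,
#'   `chi2_incongruent`, `p_incongruent`, combined `chi2`, `df`, `p` and
#'   `significant_bonferroni`; the per-test threshold is in
#'   `attr(, "threshold")`.
#' @export
test_group_consistency <- function(dataset, group, alpha = 0.05, m = NULL,
                                   correct = TRUE) {
  if (is.null(m)) m <- length(dataset$groups) * length(dataset$odors)
  if (!is.numeric(m) || m < 1) stop("m must be >= 1")
  threshold <- alpha / m
  parts <- .group_participants(dataset, group)
  n <- length(parts)
  expected_cell <- 3 * n / 36
  if (expected_cell < 5) {
    warning("expected count per color (", format(expected_cell, digits = 3),
            ") is below 5 for group '", group,
            "'; the chi-square approximation may be coarse", call. = FALSE)
  }
  fpc <- if (correct) 35 / 33 else 1
  rows <- lapply(dataset$odors, function(od) {
    pat <- compile_pattern(dataset, group, od)
    cg <- chi_square_uniform(pat$counts[1:36])
    ig <- chi_square_uniform(pat$counts[37:72])
    chi2_c <- fpc * cg$chi2
    chi2_i <- fpc * ig$chi2
    chi2 <- chi2_c + chi2_i
    data.frame(
      group = group, odor = od,
      chi2_congruent = chi2_c,
      p_congruent = stats::pchisq(chi2_c, 35, lower.tail = FALSE),
      chi2_incongruent = chi2_i,
      p_incongruent = stats::pchisq(chi2_i, 35, lower.tail = FALSE),
      chi2 = chi2, df = 70L,
      p = stats::pchisq(chi2, 70, lower.tail = FALSE),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out$significant_bonferroni <- out$p < threshold
  rownames(out) <- NULL
  attr(out, "threshold") <- threshold
  attr(out, "alpha") <- alpha
  attr(out, "m") <- m
  class(out) <- c("consistency_result", "data.frame")
  out
}

#' @export
print.consistency_result <- function(x, ...) {
  cat("Within-group color-choice consistency (chi-square vs uniform)\n")
  cat("Bonferroni: alpha=", attr(x, "alpha"), ", m=", attr(x, "m"),
      " -> per-test threshold ", format(attr(x, "threshold"), digits = 2),
      "\n\n", sep = "")
  print.data.frame(x, digits = 4)
  invisible(x)
}
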