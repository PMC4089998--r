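#' @title Response datasets
#' @description An `odor_dataset` holds one row per single color choice:
#'   a participant, for one odor, tagged a color as congruent or incongruent.
#'   Every participant contributes exactly three congruent and three
#'   incongruent choices per odor, with all six colors distinct.
#' @name odor_dataset
NULL

#' The 14 default odor labels
#' @return Character vector of odor labels in canonical (alphabetical) order.
#' @export
default_odors <- function() {
  c("burnt", "candy", "fish", "flower", "fruity", "hazelnut", "meat",
    "musty", "plastic", "rice", "soap", "vegetable", "vinegar", "woody")
}

#' Construct and validate a response dataset
#'
#' @param records `data.frame` with columns `group`, `participant`, `odor`,
#'   `choice_type` (`"congruent"` or `"incongruent"`) and `color_id`
#'   (integer 1..36).
#' @param palette A `color_palette` (default [load_palette()]).
#' @param odors,groups Optional ordered label vectors; inferred (sorted,
#'   stable) from the records when absent. Matrix-valued outputs downstream
#'   follow these orders.
#' @return An object of class `odor_dataset`.
#' @export
odor_dataset <- function(records, palette = load_palette(),
                         odors = NULL, groups = NULL) {
  needed <- c("group", "participant", "odor", "choice_type", "color_id")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols) > 0) {
    stop("records are missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  records <- records[needed]
  for (ch in c("group", "participant", "odor", "choice_type")) {
    records[[ch]] <- tolower(trimws(as.character(records[[ch]])))
  }
  records$color_id <- as.integer(records$color_id)
  if (is.null(odors)) odors <- sort(unique(records$odor))
  else odors <- tolower(trimws(odors))
  if (is.null(groups)) groups <- sort(unique(records$group))
  else groups <- tolower(trimws(groups))
  ds <- structure(
    list(records = records, palette = palette,
         odors = odors, groups = groups),
    class = "odor_dataset"
  )
  validate_dataset(ds)
}

#' Validate an `odor_dataset`
#'
#' Enforces the structural invariants: every record's odor, group and
#' color_id belong to the declared sets; each (group, participant, odor)
#' trial has exactly 3 congruent and 3 incongruent choices; the colors
#' within a choice type are distinct; and a participant's congruent and
#' incongruent sets for one odor are disjoint.
#'
#' @param dataset An `odor_dataset`.
#' @return The dataset, invisibly usable, after passing all checks.
#' @export
validate_dataset <- function(dataset) {
  rec <- dataset$records
  if (nrow(rec) == 0) {
    return(dataset)
  }
  bad <- which(!(rec$choice_type %in% c("congruent", "incongruent")))
  if (length(bad) > 0) {
    stop("invalid choice_type in record(s) ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  bad <- which(is.na(rec$color_id) |
                 !(rec$color_id %in% dataset$palette$color_id))
  if (length(bad) > 0) {
    stop("unknown color_id in record(s) ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  bad <- which(!(rec$odor %in% dataset$odors))
  if (length(bad) > 0) {
    stop("odor not in declared odor set in record(s) ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  bad <- which(!(rec$group %in% dataset$groups))
  if (length(bad) > 0) {
    stop("group not in declared group set in record(s) ",
         paste(utils::head(bad, 5), collapse = ", "))
  }

  key <- paste(rec$group, rec$participant, rec$odor, sep = "\r")
  .trial_fail <- function(keys, what) {
    k <- strsplit(keys[1], "\r", fixed = TRUE)[[1]]
    stop(what, " for (group=", k[1], ", participant=", k[2],
         ", odor=", k[3], ")",
         if (length(keys) > 1) paste0(" and ", length(keys) - 1, " other trial(s)"))
  }
  cnt <- table(key, factor(rec$choice_type,
                           levels = c("congruent", "incongruent")))
  off <- rownames(cnt)[cnt[, "congruent"] != 3 | cnt[, "incongruent"] != 3]
  if (length(off) > 0) {
    .trial_fail(off, "expected exactly 3 congruent and 3 incongruent choices")
  }
  dup <- tapply(rec$color_id, key, anyDuplicated)
  off <- names(dup)[dup > 0]
  if (length(off) > 0) {
    .trial_fail(off, "congruent and incongruent colors must be 6 distinct colors")
  }
  dataset
}

# Column-name synonyms accepted by the tolerant reader.
.COLUMN_SYNONYMS <- list(
  group = c("group", "culture", "population", "country", "cohort"),
  participant = c("participant", "subject", "participant_id", "subject_id", "id"),
  odor = c("odor", "odour", "odorant", "smell", "pen"),
  choice_type = c("choice_type", "type", "congruency", "choice", "condition"),
  color_id = c("color_id", "colour_id", "color", "colour")
)

#' Read a response table
#'
#' Reads the canonical comma-delimited response format (header
#' `group,participant,odor,choice_type,color_id`, one row per single color
#' choice). Obvious column-name synonyms (e.g. `culture`, `subject`,
#' `odour`, `colour_id`) are mapped; anything else errors loudly.
#' Identifiers are trimmed and lower-cased.
#'
#' @param path Path to the delimited file.
#' @param palette A `color_palette` used to validate color ids.
#' @param odors,groups Optional explicit orderings (see [odor_dataset()]).
#' @return A validated `odor_dataset`.
#' @export
read_responses <- function(path, palette = load_palette(),
                           odors = NULL, groups = NULL) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  names(tab) <- tolower(trimws(names(tab)))
  out <- list()
  for (canon in names(.COLUMN_SYNONYMS)) {
    hit <- intersect(.COLUMN_SYNONYMS[[canon]], names(tab))
    if (length(hit) == 0) {
      stop("no column recognisable as '", canon, "' in ", path)
    }
    out[[canon]] <- tab[[hit[1]]]
  }
  rec <- as.data.frame(out, stringsAsFactors = FALSE)
  rec$color_id <- suppressWarnings(as.integer(rec$color_id))
  odor_dataset(rec, palette = palette, odors = odors, groups = groups)
}

#' Write a response table
#'
#' Writes the canonical comma-delimited format with a deterministic row
#' order (group, participant, odor, choice_type, color_id ascending), so a
#' dataset always serialises to the same bytes and round-trips losslessly
#' through [read_responses()].
#'
#' @param dataset An `odor_dataset`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_responses <- function(dataset, path) {
  rec <- dataset$records
  if (nrow(rec) > 0) {
    rec <- rec[order(rec$group, rec$participant, rec$odor,
                     rec$choice_type, rec$color_id), , drop = FALSE]
  }
  utils::write.csv(rec, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @export
print.odor_dataset <- function(x, ...) {
  n_part <- length(unique(paste(x$records$group, x$records$participant)))
  cat("<odor_dataset> ", nrow(x$records), " choice records; ",
      length(x$groups), " group(s), ", n_part, " participant(s), ",
      length(x$odors), " odor(s), ", nrow(x$palette), " colors\n", sep = "")
  invisible(x)
}

# Participants of one group, in sorted (stable) order.
.group_participants <- function(dataset, group) {
  if (!(group %in% dataset$groups)) {
    stop("unknown group: ", group)
  }
  sort(unique(dataset$records$participant[dataset$records$group == group]))
}

#' Apply a color relabeling to a whole dataset
#'
#' Replaces every `color_id` `c` by `perm[c]` for one fixed permutation of
#' the palette. All correlation-based dissimilarities and all classifier
#' accuracies are invariant under such a global relabeling; the helper
#' exists chiefly to make that property testable.
#'
#' @param dataset An `odor_dataset`.
#' @param perm Integer vector: a permutation of `1:36`.
#' @return The relabeled, revalidated `odor_dataset`.
#' @export
relabel_colors <- function(dataset, perm) {
  if (length(perm) != 36L || !setequal(perm, 1:36)) {
    stop("perm must be a permutation of 1:36")
  }
  dataset$records$color_id <- as.integer(perm[dataset$records$color_id])
  validate_dataset(dataset)
}
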