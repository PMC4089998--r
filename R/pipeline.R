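#' Configure an end-to-end analysis run
#'
#' Bundles every switch of the full pipeline: the input (a response-table
#' path, or a [generator_config()] for synthetic data), the
#' cross-validation and null-distribution sizes, the shrinkage and feature
#' selection, the output directory and the master seed. Every stochastic
#' stage derives its own substream from `seed`, so a pipeline run is a pure
#' function of its configuration.
#'
#' @param input Optional path to a response table; when `NULL`, `generator`
#'   is used to simulate one.
#' @param generator A `generator_config` (used when `input` is `NULL`).
#' @param n_folds,n_shuffles,n_permutations Cross-validation folds, number
#'   of refoldings, and color-permutation repetitions
#'   (see [cv_accuracy()], [permutation_test()]).
#' @param rdm_null_reps Repetitions for the RDM color-shuffle null.
#' @param shrinkage Passed to [fld_fit()].
#' @param null_scheme `"per_trial"` or `"global"` (see [permutation_test()]).
#' @param features Feature mask for RDMs (see [compute_rdm()]).
#' @param second_order_method `"pearson"` or `"spearman"`.
#' @param alpha Family-wise error rate for the consistency tests.
#' @param out_dir Output directory (created if missing).
#' @param seed Master seed for all stochastic stages.
#' @param figures Render figures (`FALSE` for headless runs).
#' @param figure_format `"png"` or `"svg"`.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, generator = generator_config(),
                            n_folds = 3L, n_shuffles = 1000L,
                            n_permutations = 10000L, rdm_null_reps = 1000L,
                            shrinkage = "auto",
                            null_scheme = c("per_trial", "global"),
                            features = c("both", "congruent", "incongruent"),
                            second_order_method = c("pearson", "spearman"),
                            alpha = 0.05, out_dir = tempfile("odorcolor_run_"),
                            seed = 1L, figures = TRUE,
                            figure_format = c("png", "svg")) {
  structure(
    list(input = input, generator = generator,
         n_folds = as.integer(n_folds),
         n_shuffles = as.integer(n_shuffles),
         n_permutations = as.integer(n_permutations),
         rdm_null_reps = as.integer(rdm_null_reps),
         shrinkage = shrinkage,
         null_scheme = match.arg(null_scheme),
         features = match.arg(features),
         second_order_method = match.arg(second_order_method),
         alpha = alpha, out_dir = out_dir, seed = as.integer(seed),
         figures = isTRUE(figures),
         figure_format = match.arg(figure_format)),
    class = "pipeline_config"
  )
}

#' Run the full analysis pipeline
#'
#' Executes every stage in order on one dataset: load or simulate the
#' responses, validate them, run the per-group chi-square consistency
#' tests, the cross-validated classification with its color-permutation
#' null, the first-order odor RDMs with their shuffle nulls, and the
#' second-order inter-group RDM; then writes delimited result tables,
#' optional figures and a provenance manifest to `config$out_dir`.
#'
#' @param config A `pipeline_config`.
#' @return Invisibly, the result bundle: `dataset`, `consistency`
#'   (stacked table over groups), `accuracy` (one `accuracy_result` per
#'   group, plus a summary table), `rdms` (named list), `second_order`,
#'   and `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(force(expr), error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    message(sprintf("[odorcolor] %-12s %6.1fs", name,
                    proc.time()[["elapsed"]] - t0))
    res
  }

  dataset <- stage("load", {
    if (!is.null(config$input)) read_responses(config$input)
    else generate_dataset(config$generator)
  })
  write_responses(dataset, file.path(config$out_dir, "responses.csv"))

  consistency <- stage("consistency", {
    do.call(rbind, lapply(dataset$groups, function(g) {
      as.data.frame(test_group_consistency(dataset, g, alpha = config$alpha))
    }))
  })
  utils::write.csv(consistency,
                   file.path(config$out_dir, "consistency.csv"),
                   row.names = FALSE, quote = FALSE)

  accuracy <- stage("classify", {
    res <- lapply(dataset$groups, function(g) {
      permutation_test(dataset, g, n_folds = config$n_folds,
                       n_shuffles = config$n_shuffles,
                       n_permutations = config$n_permutations,
                       seed = .stream_seed(config$seed, 41L,
                                           match(g, dataset$groups)),
                       shrinkage = config$shrinkage,
                       scheme = config$null_scheme)
    })
    names(res) <- dataset$groups
    res
  })
  acc_table <- data.frame(
    group = dataset$groups,
    mean_accuracy = vapply(accuracy, `[[`, 0, "mean_accuracy"),
    sd_accuracy = vapply(accuracy, function(a) stats::sd(a$accuracy_sample), 0),
    null_mean = vapply(accuracy, function(a) mean(a$null_distribution), 0),
    p = vapply(accuracy, `[[`, 0, "p"),
    stringsAsFactors = FALSE
  )
  utils::write.csv(acc_table, file.path(config$out_dir, "accuracy.csv"),
                   row.names = FALSE, quote = FALSE)

  rdms <- stage("rsa", {
    res <- lapply(dataset$groups, function(g) {
      compute_rdm(dataset, g, features = config$features,
                  null_reps = config$rdm_null_reps,
                  seed = .stream_seed(config$seed, 42L,
                                      match(g, dataset$groups)))
    })
    names(res) <- dataset$groups
    res
  })
  for (g in dataset$groups) {
    write_rdm(rdms[[g]], file.path(config$out_dir,
                                   paste0("rdm_", g, ".csv")))
    utils::write.csv(
      data.frame(dissimilarity = rdms[[g]]$null_distribution),
      file.path(config$out_dir, paste0("rdm_null_", g, ".csv")),
      row.names = FALSE, quote = FALSE)
  }
  second_order <- stage("second_order", {
    second_order_rdm(rdms, method = config$second_order_method)
  })
  write_rdm(second_order, file.path(config$out_dir, "rdm_second_order.csv"))

  if (config$figures) {
    stage("figures", {
      ext <- config$figure_format
      plot_congruency(dataset,
                      file.path(config$out_dir, paste0("congruency.", ext)))
      for (g in dataset$groups) {
        plot_rdm(rdms[[g]],
                 file.path(config$out_dir, paste0("rdm_", g, ".", ext)))
      }
      plot_rdm(second_order,
               file.path(config$out_dir, paste0("rdm_second_order.", ext)))
      invisible(NULL)
    })
  }

  manifest <- .write_manifest(config, config$out_dir)
  invisible(list(dataset = dataset, consistency = consistency,
                 accuracy = accuracy, accuracy_table = acc_table,
                 rdms = rdms, second_order = second_order,
                 manifest = manifest))
}

# Provenance manifest: configuration (with its hash), seed and versions --
# enough to re-run the bundle identically. Deliberately timestamp-free so
# identical configurations produce byte-identical output directories.
.write_manifest <- function(config, out_dir) {
  cfg <- config
  cfg$generator <- unclass(cfg$generator)
  cfg_json <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA,
                               null = "null")
  tmp <- tempfile()
  writeLines(as.character(cfg_json), tmp)
  manifest <- list(
    package = "odorcolor",
    package_version = as.character(utils::packageVersion("odorcolor")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    config_md5 = unname(tools::md5sum(tmp)),
    config = jsonlite::fromJSON(cfg_json, simplifyVector = TRUE)
  )
  unlink(tmp)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest
}
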