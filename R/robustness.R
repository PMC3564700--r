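# Perturbation-robustness pipeline: perturb -> distance -> NJ ->
# consensus -> RF against the unperturbed tree, across mutation levels.

#' Consensus robustness curve from pre-built replicate trees
#'
#' For each mutation rate: the extended-majority-rule consensus of the
#' replicate trees is computed and its Robinson-Foulds symmetric distance
#' to the original (unperturbed) tree is recorded, together with the
#' per-replicate RF distribution. Rates are reported in input order.
#'
#' @param original The unperturbed tree (`phylo`).
#' @param replicate_trees_by_rate Named list: rate (as character or
#'   numeric names) to list of replicate `phylo` trees.
#' @return An object of class `rcm_robustness`; its `curve` element is a
#'   tibble with `rate`, `n_replicates`, `rf_consensus`,
#'   `rf_consensus_normalized`, `consensus` (list column of trees) and
#'   `replicate_rf` (list column of per-replicate RF vectors).
#' @export
robustness_curve <- function(original, replicate_trees_by_rate) {
  rates <- as.numeric(names(replicate_trees_by_rate))
  if (anyNA(rates)) stop("replicate_trees_by_rate must be named by rate",
                         call. = FALSE)
  rows <- purrr::imap(replicate_trees_by_rate, function(trees, nm) {
    cons <- consensus_mre(trees)
    tibble(rate = as.numeric(nm),
           n_replicates = length(trees),
           rf_consensus = rf_distance(cons, original),
           rf_consensus_normalized = rf_distance(cons, original,
                                                 normalized = TRUE),
           consensus = list(cons),
           replicate_rf = list(vapply(trees, rf_distance, numeric(1),
                                      t2 = original)))
  })
  structure(list(curve = dplyr::bind_rows(rows), original = original),
            class = "rcm_robustness")
}

#' Run the full perturbation-robustness experiment
#'
#' The end-to-end pipeline on a set of unaligned sequences: build the
#' original RCM + neighbor-joining tree, then for every mutation rate
#' generate `n_replicates` perturbed datasets (pool-based, composition
#' conserving), rebuild a tree from each, take the extended-majority-rule
#' consensus, and measure how far it drifts from the original topology.
#' The classic design uses the seven mutation levels 1, 2, 5, 10, 15, 20
#' and 25\% with 1000 replicates each; a tree whose topology survives up
#' to some level unchanged is considered robust at that level.
#'
#' @param x Sequences accepted by [as_seq_tbl()] (>= 4 recommended so
#'   the topology is informative).
#' @param rates Mutation fractions, e.g. `c(0.01, 0.02, 0.05, 0.10,
#'   0.15, 0.20, 0.25)`.
#' @param n_replicates Replicates per rate.
#' @param seed Master seed; every replicate has its own derived
#'   substream.
#' @param out_dir Optional directory: writes `robustness.tsv` (one row
#'   per rate), `consensus_rate_<k>.nwk` per rate, `original.nwk`, and a
#'   JSON `manifest.json` (config, seed, file list). Refuses to
#'   overwrite an existing directory unless `force = TRUE`.
#' @param force Overwrite `out_dir` if it exists?
#' @return An `rcm_robustness` object (see [robustness_curve()]).
#' @export
run_robustness_experiment <- function(x,
                                      rates = c(0.01, 0.02, 0.05, 0.10,
                                                0.15, 0.20, 0.25),
                                      n_replicates = 1000, seed = 42,
                                      out_dir = NULL, force = FALSE) {
  x <- as_seq_tbl(x)
  if (nrow(x) < 3) stop("need >= 3 sequences", call. = FALSE)
  original <- nj_tree(rcm_distance_matrix(x))
  by_rate <- lapply(rates, function(r) {
    perturb_dataset(x, r, n_replicates, seed,
                    .f = function(rep_x) nj_tree(rcm_distance_matrix(rep_x)))
  })
  names(by_rate) <- rates
  res <- robustness_curve(original, by_rate)
  if (!is.null(out_dir))
    write_robustness(res, out_dir, rates = rates,
                     n_replicates = n_replicates, seed = seed, force = force)
  res
}

write_robustness <- function(res, out_dir, rates, n_replicates, seed,
                             force = FALSE) {
  if (dir.exists(out_dir) && length(list.files(out_dir)) && !force)
    stop("output directory exists; use force = TRUE to overwrite",
         call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ape::write.tree(res$original, file.path(out_dir, "original.nwk"))
  files <- "original.nwk"
  for (i in seq_len(nrow(res$curve))) {
    f <- sprintf("consensus_rate_%g.nwk", res$curve$rate[i])
    ape::write.tree(res$curve$consensus[[i]], file.path(out_dir, f))
    files <- c(files, f)
  }
  tab <- glance(res)
  utils::write.table(tab, file.path(out_dir, "robustness.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  files <- c(files, "robustness.tsv")
  manifest <- list(tool = "lzphylo",
                   version = as.character(utils::packageVersion("lzphylo")),
                   rates = rates, n_replicates = n_replicates, seed = seed,
                   files = files)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}

#' @export
tidy.rcm_robustness <- function(x, ...) {
  x$curve |>
    dplyr::select("rate", "replicate_rf") |>
    tidyr::unnest_longer("replicate_rf", values_to = "rf") |>
    dplyr::group_by(.data$rate) |>
    dplyr::mutate(replicate = dplyr::row_number(), .after = "rate") |>
    dplyr::ungroup()
}

#' @export
glance.rcm_robustness <- function(x, ...) {
  x$curve |>
    dplyr::mutate(mean_replicate_rf =
                    vapply(.data$replicate_rf, mean, numeric(1))) |>
    dplyr::select("rate", "n_replicates", "rf_consensus",
                  "rf_consensus_normalized", "mean_replicate_rf")
}

#' @export
print.rcm_robustness <- function(x, ...) {
  cat("Perturbation robustness of the RCM tree\n")
  print(glance(x))
  invisible(x)
}

#' Run the simulation accuracy benchmark and write its report
#'
#' Drives [benchmark_rcm()] for one or both substitution models and
#' writes a summary table (method x model: mean and standard deviation of
#' the raw and normalized symmetric distances) plus a JSON manifest.
#'
#' @param models Character vector among `"K2P"`, `"F84"`.
#' @param n_families Families per model.
#' @param tstv,base_freq Model parameters (see [subst_model()]).
#' @param seed Master seed; each model gets a split substream.
#' @param out_dir Optional output directory (`benchmark.tsv`,
#'   `manifest.json`).
#' @param force Overwrite `out_dir` if non-empty?
#' @param ... Passed on to [benchmark_rcm()] (tree, root_length,
#'   indel_rate, extra_methods, ...).
#' @return Named list of `rcm_benchmark` objects, one per model,
#'   invisibly with the combined summary attached as attribute
#'   `"summary"`.
#' @export
run_benchmark_experiment <- function(models = c("K2P", "F84"),
                                     n_families = 200, tstv = 2,
                                     base_freq = c(0.3, 0.2, 0.2, 0.3),
                                     seed = 7, out_dir = NULL,
                                     force = FALSE, ...) {
  models <- match.arg(models, several.ok = TRUE)
  res <- lapply(seq_along(models), function(i) {
    benchmark_rcm(n_families,
                  subst_model(models[i], tstv = tstv, base_freq = base_freq),
                  seed = derive_seed(seed, 7L, i), ...)
  })
  names(res) <- models
  summary <- dplyr::bind_rows(lapply(res, glance))
  if (!is.null(out_dir)) {
    if (dir.exists(out_dir) && length(list.files(out_dir)) && !force)
      stop("output directory exists; use force = TRUE to overwrite",
           call. = FALSE)
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(summary, file.path(out_dir, "benchmark.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(tool = "lzphylo",
           version = as.character(utils::packageVersion("lzphylo")),
           models = models, n_families = n_families, tstv = tstv,
           base_freq = base_freq, seed = seed,
           files = c("benchmark.tsv")),
      file.path(out_dir, "manifest.json"), auto_unbox = TRUE, pretty = TRUE)
  }
  attr(res, "summary") <- summary
  invisible(res)
}
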