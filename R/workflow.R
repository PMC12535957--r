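# Configuration-driven orchestration: one call reproduces the full synthetic
# benchmark (generate -> preprocess -> featurize -> evaluate -> summarize).
# Persistence diagrams, the slow stage, are computed once per subject and
# representation at the highest requested dimension and reused across the
# nested dimension sets.

#' Full-run configuration
#'
#' @param synthetic A [synthetic_config()].
#' @param abs_fmri,residualize Preprocessing toggles.
#' @param grid_size Betti-curve grid length.
#' @param dims_sets List of homology dimension sets; restricted to
#'   `{0}`, `{0, 1}`, `{0, 1, 2}`.
#' @param supra_dim_cap Cap on supra-complex homology dimension.
#' @param metrics Metric tags for the second pipeline (plus `ALL`,
#'   PCA-reduced and importance-selected variants on the single layers).
#' @param representations Which network representations to evaluate.
#' @param n_folds,n_repeats,eval_seed Cross-validation settings.
#' @param pca_components,top_k PCA / feature-selection sizes.
#' @param out_dir Output directory for tables and the run manifest.
#' @return An object of class `run_config`.
#' @export
run_config <- function(synthetic = synthetic_config(),
                       abs_fmri = TRUE, residualize = TRUE,
                       grid_size = 100,
                       dims_sets = list(0, c(0, 1), c(0, 1, 2)),
                       supra_dim_cap = 2,
                       metrics = c("degree", "strength", "local_efficiency",
                                   "betweenness", "closeness"),
                       representations = REPRESENTATIONS,
                       n_folds = 4, n_repeats = 10, eval_seed = 13,
                       pca_components = 20, top_k = 100,
                       out_dir = tempfile("topoconnectome_run_")) {
  allowed <- list(0, c(0, 1), c(0, 1, 2))
  for (d in dims_sets) {
    if (!any(vapply(allowed, identical, TRUE, y = as.numeric(sort(d)))))
      stop("dims_sets entries must be one of {0}, {0,1}, {0,1,2}",
           call. = FALSE)
  }
  structure(list(synthetic = synthetic, abs_fmri = abs_fmri,
                 residualize = residualize, grid_size = grid_size,
                 dims_sets = dims_sets, supra_dim_cap = supra_dim_cap,
                 metrics = metrics, representations = representations,
                 n_folds = n_folds, n_repeats = n_repeats,
                 eval_seed = eval_seed, pca_components = pca_components,
                 top_k = top_k, out_dir = out_dir),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Top-level YAML keys mirror [run_config()] arguments; the `synthetic` block
#' mirrors [synthetic_config()].
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(y$synthetic))
    args$synthetic <- do.call(synthetic_config, y$synthetic)
  for (nm in setdiff(names(formals(run_config)), "synthetic"))
    if (!is.null(y[[nm]])) args[[nm]] <- y[[nm]]
  do.call(run_config, args)
}

#' Run the complete synthetic benchmark
#'
#' Generates the synthetic cohort, preprocesses it, assembles the
#' Betti-curve feature tables for every (representation, dimension-set)
#' combination and the node-metric tables for every (representation, metric)
#' combination (plus all-metric, PCA-reduced and importance-selected
#' variants on the single layers), runs the repeated cross-validation
#' benchmark on each, and writes two summary tables plus a JSON manifest of
#' every seed used.
#'
#' @param config A [run_config()].
#' @return List with `betti_summary`, `metric_summary`, the raw `records`
#'   and the output directory, invisibly.
#' @export
run_all <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  stage <- function(name, expr) {
    tic <- Sys.time()
    out <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    message(sprintf("[%s] done in %.1fs", name,
                    as.numeric(difftime(Sys.time(), tic, units = "secs"))))
    out
  }

  ch <- stage("generate", generate_cohort(config$synthetic))
  ch <- stage("preprocess",
              preprocess_cohort(ch, config$abs_fmri, config$residualize))

  max_dims <- max(unlist(config$dims_sets))
  # homology cache: diagrams at the highest requested dimension, one entry
  # per (subject, complex); nested dimension sets reuse them
  diagrams <- stage("homology", {
    lapply(ch$subjects, function(s) {
      nets <- list()
      for (rep_ in config$representations) {
        cx <- subject_complexes(s, rep_)
        for (nm in names(cx)) {
          if (!nm %in% names(nets)) {
            hd <- if (nm == "ML") min(max_dims, config$supra_dim_cap) else max_dims
            nets[[nm]] <- compute_persistence(cx[[nm]], max_hom_dim = hd)
          }
        }
      }
      nets
    })
  })

  curve_features <- function(representation, dims) {
    mods <- switch(representation,
                   "multilayer" = "ML",
                   "concat-SL" = c("GM", "DTI", "FMRI"),
                   sub("SL-", "", representation))
    rows <- lapply(diagrams, function(dgs) {
      unlist(lapply(mods, function(nm) {
        avail <- dims[dims <= attr(dgs[[nm]], "max_hom_dim")]
        bc <- betti_curve(dgs[[nm]], grid_size = config$grid_size,
                          dims = avail)
        out <- matrix(0, length(dims), config$grid_size,
                      dimnames = list(paste0("dim", dims), NULL))
        out[rownames(bc), ] <- bc
        stats::setNames(as.vector(t(out)),
                        as.vector(t(outer(paste0(nm, "|betti|dim", dims),
                                          sprintf("t%03d",
                                                  seq_len(config$grid_size)),
                                          paste, sep = "|"))))
      }))
    })
    feature_matrix(do.call(rbind, rows),
                   vapply(ch$subjects, function(s) s$subject_id, ""),
                   cohort_groups(ch),
                   sprintf("%s/betti-dims%s", representation,
                           paste(dims, collapse = "")))
  }

  records <- list()
  stage("betti-benchmark", {
    for (dims in config$dims_sets) {
      for (rep_ in config$representations) {
        fm <- curve_features(rep_, as.numeric(dims))
        records[[length(records) + 1]] <-
          repeated_cv(fm, n_folds = config$n_folds,
                      n_repeats = config$n_repeats, seed = config$eval_seed)
      }
    }
  })
  betti_records <- do.call(rbind, records)
  betti_summary <- summarize_cv(betti_records)
  write_results_table(betti_summary,
                      file.path(config$out_dir, "betti_benchmark.csv"))

  records <- list()
  stage("metric-benchmark", {
    for (m in config$metrics) {
      for (rep_ in config$representations) {
        fm <- metric_features(ch, rep_, m)
        records[[length(records) + 1]] <-
          repeated_cv(fm, n_folds = config$n_folds,
                      n_repeats = config$n_repeats, seed = config$eval_seed)
      }
    }
    # all-metric configuration plus reduction/selection, single layers only
    for (rep_ in intersect(c("SL-DTI", "SL-GM", "SL-FMRI"),
                           config$representations)) {
      fm <- metric_features(ch, rep_, "ALL")
      records[[length(records) + 1]] <-
        repeated_cv(fm, n_folds = config$n_folds,
                    n_repeats = config$n_repeats, seed = config$eval_seed)
      pca_tf <- function(tr, te, seed) {
        k <- min(config$pca_components, nrow(tr$X) - 1L, ncol(tr$X))
        pca_reduce(tr, te, n_components = k)
      }
      fm_pca <- fm; fm_pca$config_tag <- paste0(fm$config_tag, "-pca")
      records[[length(records) + 1]] <-
        repeated_cv(fm_pca, n_folds = config$n_folds,
                    n_repeats = config$n_repeats, seed = config$eval_seed,
                    transform = pca_tf)
      sel_tf <- function(tr, te, seed) {
        k <- min(config$top_k, ncol(tr$X))
        rf_importance_select(tr, te, top_k = k, seed = seed)
      }
      fm_sel <- fm; fm_sel$config_tag <- paste0(fm$config_tag, "-sel")
      records[[length(records) + 1]] <-
        repeated_cv(fm_sel, n_folds = config$n_folds,
                    n_repeats = config$n_repeats, seed = config$eval_seed,
                    transform = sel_tf)
    }
  })
  metric_records <- do.call(rbind, records)
  metric_summary <- summarize_cv(metric_records)
  write_results_table(metric_summary,
                      file.path(config$out_dir, "metric_benchmark.csv"))

  all_records <- rbind(betti_records, metric_records)
  write.csv(all_records, file.path(config$out_dir, "fold_records.csv"),
            row.names = FALSE)
  manifest <- list(
    generator_seed = config$synthetic$seed,
    eval_seed = config$eval_seed,
    n_subjects = length(ch$subjects),
    parcellation_size = config$synthetic$parcellation_size,
    grid_size = config$grid_size,
    dims_sets = lapply(config$dims_sets, as.numeric),
    representations = config$representations,
    n_folds = config$n_folds, n_repeats = config$n_repeats,
    wall_time_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    package_version = as.character(utils::packageVersion("topoconnectome")))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(betti_summary = betti_summary,
                 metric_summary = metric_summary,
                 records = all_records, out_dir = config$out_dir))
}
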