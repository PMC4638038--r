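# End-to-end orchestration: simulate (or load) a cohort, quantify,
# condition the matrix, run the unsupervised and enrichment analyses, and
# select the SVM panel -- with every stage artifact serialized between
# stages and a machine-readable run report at the end. Stage seeds are
# derived from one global seed, so a single integer reproduces the run.

PIPELINE_STAGES <- c("simulate", "quantify", "preprocess", "pca", "enrich",
                     "classify")

#' Pipeline configuration
#'
#' @param out_dir Directory for stage artifacts and the run report.
#' @param seed Global seed; stage seeds are derived from it.
#' @param stages Which stages to run (always executed in the fixed order
#'   simulate, quantify, preprocess, pca, enrich, classify).
#' @param simulate Arguments for [sim_config()].
#' @param annotations Arguments for [generate_annotations()] (simulated
#'   runs only).
#' @param quantify Arguments for [quant_config()].
#' @param preprocess List: `min_valid_fraction`, `width`, `downshift`, and
#'   the stage toggles `filter`, `impute`, `normalize`.
#' @param enrichment List: `loading_quantile`, `fdr`.
#' @param classify Arguments for [cv_feature_selection()] (minus
#'   profile/labels/seed).
#' @param inputs Paths (`peptides`, `labels`, `catalog`) when `simulate` is
#'   not among the stages.
#' @return A validated `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1L, stages = PIPELINE_STAGES,
                            simulate = list(), annotations = list(),
                            quantify = list(), preprocess = list(),
                            enrichment = list(), classify = list(),
                            inputs = list()) {
  stages <- match.arg(stages, PIPELINE_STAGES, several.ok = TRUE)
  pp <- utils::modifyList(list(min_valid_fraction = 0.75, width = 0.3,
                               downshift = 1, filter = TRUE, impute = TRUE,
                               normalize = TRUE), preprocess)
  enr <- utils::modifyList(list(loading_quantile = 0.9, fdr = 0.05), enrichment)
  cfg <- structure(list(
    out_dir = out_dir, seed = as.integer(seed), stages = stages,
    simulate = simulate, annotations = annotations, quantify = quantify,
    preprocess = pp, enrichment = enr, classify = classify, inputs = inputs
  ), class = "pipeline_config")
  validate_pipeline_config(cfg)
  cfg
}

validate_pipeline_config <- function(cfg) {
  pp <- cfg$preprocess
  if ("preprocess" %in% cfg$stages && !pp$impute && pp$normalize) {
    abort(paste("invalid configuration: width normalization requires a",
                "complete matrix; enable imputation or disable normalization"))
  }
  if (!"simulate" %in% cfg$stages) {
    need <- c("peptides", "labels")
    miss <- need[!vapply(cfg$inputs[need], function(p)
      !is.null(p) && file.exists(p), logical(1))]
    if (length(miss)) {
      abort(paste0("without the simulate stage, input path(s) must exist: ",
                   paste(miss, collapse = ", ")))
    }
  }
  invisible(cfg)
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file whose keys mirror the [pipeline_config()]
#'   arguments.
#' @return A validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Run the analysis pipeline
#'
#' Executes the enabled stages in fixed order, serializing every stage's
#' artifact under `out_dir` and collecting counts, seeds and timings in a
#' run report (also written as `run_report.json`). A stage failure halts
#' the run with the failing stage named; artifacts of completed stages are
#' retained.
#'
#' @param config A [pipeline_config()].
#' @return The run report (list), invisibly; stage results are in
#'   `$results`.
#' @export
run_pipeline <- function(config) {
  validate_pipeline_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(seed = config$seed, stages = list(),
                 package_version = as.character(utils::packageVersion("proteopanel")))
  results <- list()
  tsv <- function(x, file) {
    utils::write.table(x, file.path(config$out_dir, file), sep = "\t",
                       quote = FALSE, row.names = FALSE, na = "")
  }
  run_stage <- function(name, fn) {
    t0 <- Sys.time()
    out <- tryCatch(fn(), error = function(e) {
      abort(sprintf("stage `%s` failed: %s", name, conditionMessage(e)))
    })
    report$stages[[name]] <<- c(out$info,
                                list(elapsed_s = as.numeric(Sys.time() - t0,
                                                            units = "secs")))
    out$value
  }

  ## -- simulate / load -------------------------------------------------------
  if ("simulate" %in% config$stages) {
    sim <- run_stage("simulate", function() {
      cfg <- do.call(sim_config, utils::modifyList(
        config$simulate, list(seed = derive_seed(config$seed, "simulate"))))
      cohort <- generate_cohort(cfg)
      write_cohort(cohort, config$out_dir)
      catalog <- do.call(generate_annotations, c(
        list(truth = cohort$truth,
             seed = derive_seed(config$seed, "annotate")),
        config$annotations))
      tsv(catalog, "catalog.tsv")
      list(value = list(peptides = cohort$peptides, truth = cohort$truth,
                        labels = cohort$truth$samples, catalog = catalog),
           info = list(seed = cfg$seed, n_proteins = cfg$n_proteins,
                       n_peptide_rows = nrow(cohort$peptides)))
    })
  } else {
    sim <- run_stage("load", function() {
      peptides <- read_peptide_table(config$inputs$peptides)
      labels <- tibble::as_tibble(utils::read.delim(config$inputs$labels,
                                                    stringsAsFactors = FALSE))
      catalog <- if (!is.null(config$inputs$catalog)) {
        read_catalog(config$inputs$catalog)
      }
      list(value = list(peptides = peptides, truth = NULL, labels = labels,
                        catalog = catalog),
           info = list(n_peptide_rows = nrow(peptides)))
    })
  }
  results$labels <- sim$labels

  ## -- quantify --------------------------------------------------------------
  profile <- NULL
  if ("quantify" %in% config$stages) {
    profile <- run_stage("quantify", function() {
      qc <- do.call(quant_config, config$quantify)
      prof <- quantify_matrix(sim$peptides, qc)
      tsv(prof, "profile_raw.tsv")
      rep <- quant_report(prof)
      jsonlite::write_json(as.list(rep),
                           file.path(config$out_dir, "quant_report.json"),
                           auto_unbox = TRUE, digits = NA)
      list(value = prof, info = as.list(rep))
    })
    results$profile_raw <- profile
  }

  ## -- preprocess ------------------------------------------------------------
  if ("preprocess" %in% config$stages) {
    profile <- run_stage("preprocess", function() {
      pp <- config$preprocess
      x <- profile
      if (pp$filter) x <- filter_valid_values(x, pp$min_valid_fraction)
      thr <- attr(x, "filter_report")
      if (pp$impute) x <- impute_downshift(x, pp$width, pp$downshift,
                                           seed = derive_seed(config$seed, "impute"))
      if (pp$normalize) x <- width_normalize(x)
      tsv(x, "profile_processed.tsv")
      list(value = x,
           info = list(threshold = if (!is.null(thr)) thr$threshold,
                       n_proteins = nrow(x)))
    })
    results$profile <- profile
  }

  ## -- pca -------------------------------------------------------------------
  pca <- NULL
  if ("pca" %in% config$stages) {
    pca <- run_stage("pca", function() {
      res <- profile_pca(profile)
      pair <- select_component_pair(res, sim$labels)
      tsv(tidy(res, "scores"), "pca_scores.tsv")
      tsv(tidy(res, "loadings"), "pca_loadings.tsv")
      tsv(tidy(res, "eigenvalues"), "pca_eigenvalues.tsv")
      list(value = list(pca = res, pair = pair),
           info = list(component_pair = as.integer(pair),
                       explained = res$explained_variance[pair]))
    })
    results$pca <- pca$pca
    results$component_pair <- pca$pair
  }

  ## -- enrich ----------------------------------------------------------------
  if ("enrich" %in% config$stages && !is.null(sim$catalog)) {
    results$enrichment <- run_stage("enrich", function() {
      m <- as_profile_matrix(profile)
      lab <- align_subtypes(sim$labels, colnames(m))
      dim_x <- apply(m[, lab == levels(lab)[1], drop = FALSE], 1, median)
      dim_y <- apply(m[, lab == levels(lab)[2], drop = FALSE], 1, median)
      e2 <- enrichment_2d(dim_x, dim_y, sim$catalog, fdr = config$enrichment$fdr)
      tsv(e2, "enrichment_2d.tsv")
      drv <- if (!is.null(pca)) {
        d <- component_driver_enrichment(
          pca$pca, pca$pair[1], sim$catalog,
          loading_quantile = config$enrichment$loading_quantile)
        tsv(d, "enrichment_component_drivers.tsv")
        d
      }
      list(value = list(enrichment_2d = e2, driver_enrichment = drv),
           info = list(n_categories = nrow(e2),
                       n_significant = sum(e2$significant)))
    })
  }

  ## -- classify --------------------------------------------------------------
  if ("classify" %in% config$stages) {
    results$cv <- run_stage("classify", function() {
      cv <- do.call(cv_feature_selection, c(
        list(profile = profile, labels = sim$labels,
             seed = derive_seed(config$seed, "cv")),
        config$classify))
      tsv(cv$error_curve, "cv_error_curve.tsv")
      tsv(cv$panel, "panel.tsv")
      ranked <- rank_features(profile, sim$labels,
                              s0 = config$classify$s0 %||% 0.1)
      cutoff <- clustering_loss_cutoff(profile, sim$labels, ranked$protein_id)
      jsonlite::write_json(
        list(optimal_k = cv$optimal_k, error_at_optimal_k =
               cv$error_curve$mean_error[cv$error_curve$k == cv$optimal_k],
             clustering_loss_cutoff = as.integer(cutoff),
             seed = cv$config$seed),
        file.path(config$out_dir, "cv_report.json"), auto_unbox = TRUE,
        digits = NA)
      list(value = list(cv = cv, clustering_loss_cutoff = as.integer(cutoff)),
           info = list(optimal_k = cv$optimal_k,
                       clustering_loss_cutoff = as.integer(cutoff)))
    })
  }

  report$results <- results
  json_report <- report[c("seed", "package_version", "stages")]
  jsonlite::write_json(json_report, file.path(config$out_dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(report)
}

#' Validate pipeline input files
#'
#' Checks the peptide TSV header and intensity positivity, that every
#' labeled sample exists in the peptide table (and vice versa), and the
#' overlap of catalog protein IDs with the peptide table. Problems are
#' returned as a tibble with `severity` (`"error"` or `"warning"`) and a
#' message naming offending lines where applicable.
#'
#' @param peptides_path Peptide-feature TSV.
#' @param labels_path Optional label TSV (`sample_id`, `subtype`).
#' @param catalog_path Optional catalog TSV/GMT.
#' @return Tibble of issues (zero rows if everything is well-formed).
#' @export
validate_inputs <- function(peptides_path, labels_path = NULL,
                            catalog_path = NULL) {
  issues <- tibble::tibble(severity = character(), message = character())
  add <- function(sev, msg) {
    issues <<- dplyr::bind_rows(issues, tibble::tibble(severity = sev,
                                                       message = msg))
  }
  pep <- tryCatch(read_peptide_table(peptides_path), error = function(e) {
    add("error", conditionMessage(e)); NULL
  })
  if (is.null(pep)) return(issues)

  if (!is.null(labels_path)) {
    lab <- utils::read.delim(labels_path, stringsAsFactors = FALSE)
    if (!all(c("sample_id", "subtype") %in% names(lab))) {
      add("error", "label file needs `sample_id` and `subtype` columns")
    } else {
      unknown <- setdiff(lab$sample_id, pep$sample_id)
      if (length(unknown)) {
        add("error", paste0("label file names unknown sample(s): ",
                            paste(unknown, collapse = ", ")))
      }
      unlabeled <- setdiff(pep$sample_id, lab$sample_id)
      if (length(unlabeled)) {
        add("warning", paste0("sample(s) without label: ",
                              paste(unlabeled, collapse = ", ")))
      }
    }
  }
  if (!is.null(catalog_path)) {
    cat_tbl <- tryCatch(read_catalog(catalog_path), error = function(e) {
      add("error", conditionMessage(e)); NULL
    })
    if (!is.null(cat_tbl)) {
      overlap <- mean(unique(cat_tbl$protein_id) %in% pep$protein_group_id)
      if (overlap == 0) {
        add("warning", "catalog shares no protein ID with the peptide table")
      }
    }
  }
  issues
}
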