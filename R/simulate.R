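# Cohort simulator: peptide-level light/heavy intensities with the
# statistical structure the downstream quantification assumes -- log-normal
# protein abundance, peptide-specific response factors, a heavy spike-in
# standard covering only part of the proteome, multiplicative noise and
# abundance-dependent (missing-not-at-random) detection.

# Internal scale constants (log10): grand mean protein abundance and the
# spread of peptide response factors. Intensities land in the 1e5-1e9 range
# typical of Orbitrap feature intensities.
MEAN_LOG10_ABUNDANCE <- 7
RESPONSE_SD_LOG10 <- 0.5

#' Simulation configuration for a two-subtype proteome cohort
#'
#' Defaults emulate a 13 vs 7 two-subtype cohort at a reduced proteome size
#' so that a full pipeline run stays fast; raise `n_proteins` toward several
#' thousand for realism. A fraction of proteins is "planted" as truly
#' differential between subtypes, and a fraction is covered by the heavy
#' spike-in standard; proteins absent from the standard can only be
#' quantified through the label-free fallback.
#'
#' @param n_samples_A,n_samples_B Samples per subtype (defaults 13 and 7).
#' @param n_proteins Number of protein groups to simulate.
#' @param frac_differential Fraction of proteins with a true subtype effect.
#' @param log2fc_range Magnitude range (low, high) of planted log2 fold
#'   changes; signs are random.
#' @param frac_in_standard Fraction of proteins present in the heavy
#'   spike-in standard. The complement is drawn disjointly from the
#'   differential set (when possible) so standard coverage does not
#'   confound the subtype signal.
#' @param peptides_per_protein_mean Mean peptide count per protein
#'   (`1 + Poisson(mean - 1)`, so every protein has at least one peptide).
#' @param abundance_sd_log10 SD (log10) of protein base abundance across the
#'   proteome; 1.0 spans the several orders of magnitude seen in deep
#'   proteomes.
#' @param noise_cv Coefficient of variation of multiplicative (log-normal)
#'   measurement noise per observation.
#' @param detection_midpoint log2 intensity at which detection probability
#'   is 50%.
#' @param detection_slope Logistic slope of detection vs log2 intensity.
#'   A slope of 0 is interpreted as "always detected".
#' @param seed Integer seed; the generator is fully deterministic given the
#'   configuration.
#' @return A `sim_config` list, validated.
#' @export
sim_config <- function(n_samples_A = 13, n_samples_B = 7, n_proteins = 500,
                       frac_differential = 0.025, log2fc_range = c(1, 2),
                       frac_in_standard = 0.9, peptides_per_protein_mean = 3,
                       abundance_sd_log10 = 1, noise_cv = 0.2,
                       detection_midpoint = 20, detection_slope = 0.5,
                       seed = 1L) {
  cfg <- list(
    n_samples_A = check_count(n_samples_A, "n_samples_A"),
    n_samples_B = check_count(n_samples_B, "n_samples_B"),
    n_proteins = check_count(n_proteins, "n_proteins"),
    frac_differential = check_fraction(frac_differential, "frac_differential"),
    log2fc_range = log2fc_range,
    frac_in_standard = check_fraction(frac_in_standard, "frac_in_standard"),
    peptides_per_protein_mean = peptides_per_protein_mean,
    abundance_sd_log10 = abundance_sd_log10,
    noise_cv = noise_cv,
    detection_midpoint = detection_midpoint,
    detection_slope = detection_slope,
    seed = as.integer(seed)
  )
  if (length(cfg$log2fc_range) != 2 || any(cfg$log2fc_range <= 0) ||
      cfg$log2fc_range[1] > cfg$log2fc_range[2]) {
    abort("`log2fc_range` must be an increasing pair of positive reals")
  }
  if (cfg$peptides_per_protein_mean < 1) {
    abort("`peptides_per_protein_mean` must be >= 1")
  }
  if (cfg$abundance_sd_log10 <= 0) abort("`abundance_sd_log10` must be > 0")
  if (cfg$noise_cv < 0) abort("`noise_cv` must be >= 0")
  if (cfg$detection_slope < 0) abort("`detection_slope` must be >= 0")
  structure(cfg, class = "sim_config")
}

#' Generate a synthetic peptide-feature cohort with ground truth
#'
#' Draws, in a documented fixed order (proteins, then peptides, then
#' samples), a two-subtype cohort at the peptide-feature level. The light
#' channel carries the biology (subtype fold changes); the heavy channel is
#' the spike-in standard, constant across samples in expectation (a 1:1
#' spike) and entirely absent for proteins not covered by the standard.
#' Each observation survives detection with probability
#' `plogis((log2(intensity) - detection_midpoint) * detection_slope)`,
#' which makes missingness abundance-dependent (MNAR).
#'
#' @param config A [sim_config()].
#' @return A list with `peptides` (a tibble: `protein_group_id`,
#'   `peptide_id`, `sample_id`, `intensity_l`, `intensity_h`; `NA` =
#'   not detected; rows where both channels are missing are dropped) and
#'   `truth` (a `cohort_truth`: per-protein tibble, per-sample label tibble,
#'   and the true proteins x samples log2 abundance matrix).
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  n_prot <- config$n_proteins
  n_samp <- config$n_samples_A + config$n_samples_B
  prot_ids <- sprintf("P%05d", seq_len(n_prot))
  samp_ids <- sprintf("S%02d", seq_len(n_samp))
  subtype <- factor(rep(c("A", "B"), c(config$n_samples_A, config$n_samples_B)))

  withr::with_seed(config$seed, {
    ## -- protein-level draws ------------------------------------------------
    base_log10 <- rnorm(n_prot, MEAN_LOG10_ABUNDANCE, config$abundance_sd_log10)
    n_diff <- round(config$frac_differential * n_prot)
    diff_idx <- sample.int(n_prot, n_diff)
    log2fc <- numeric(n_prot)
    log2fc[diff_idx] <- sample(c(-1, 1), n_diff, replace = TRUE) *
      runif(n_diff, config$log2fc_range[1], config$log2fc_range[2])
    n_absent <- round((1 - config$frac_in_standard) * n_prot)
    pool <- setdiff(seq_len(n_prot), diff_idx)
    absent_idx <- if (n_absent <= length(pool)) {
      sample(pool, n_absent)
    } else {
      c(pool, sample(diff_idx, n_absent - length(pool)))
    }
    in_standard <- !(seq_len(n_prot) %in% absent_idx)
    n_pep <- 1L + rpois(n_prot, config$peptides_per_protein_mean - 1)

    ## -- peptide-level draws ------------------------------------------------
    total_pep <- sum(n_pep)
    pep_prot <- rep.int(seq_len(n_prot), n_pep)
    pep_ids <- paste0(prot_ids[pep_prot], "_pep",
                      unlist(lapply(n_pep, seq_len), use.names = FALSE))
    response_log2 <- rnorm(total_pep, 0, RESPONSE_SD_LOG10) * log2(10)

    ## -- sample-level draws -------------------------------------------------
    base_log2 <- base_log10 * log2(10)
    true_log2 <- matrix(base_log2, n_prot, n_samp) +
      outer(log2fc, as.integer(subtype == "B"))
    dimnames(true_log2) <- list(prot_ids, samp_ids)

    sd_log2_noise <- if (config$noise_cv > 0) {
      sqrt(log(1 + config$noise_cv^2)) / log(2)
    } else 0
    noise <- function() {
      if (sd_log2_noise == 0) 0 else
        matrix(rnorm(total_pep * n_samp, 0, sd_log2_noise), total_pep, n_samp)
    }
    light_log2 <- true_log2[pep_prot, , drop = FALSE] + response_log2 + noise()
    heavy_log2 <- matrix(base_log2[pep_prot], total_pep, n_samp) +
      response_log2 + noise()
    heavy_log2[!in_standard[pep_prot], ] <- NA_real_

    detect <- function(log2_int) {
      p <- if (config$detection_slope == 0) 1 else
        stats::plogis((log2_int - config$detection_midpoint) * config$detection_slope)
      keep <- matrix(runif(length(log2_int)), nrow(log2_int)) < p
      keep & !is.na(log2_int)
    }
    keep_l <- detect(light_log2)
    keep_h <- detect(ifelse(is.na(heavy_log2), -Inf, heavy_log2))
  })

  intensity_l <- ifelse(keep_l, 2^light_log2, NA_real_)
  intensity_h <- ifelse(keep_h, 2^heavy_log2, NA_real_)
  peptides <- tibble::tibble(
    protein_group_id = rep(prot_ids[pep_prot], n_samp),
    peptide_id = rep(pep_ids, n_samp),
    sample_id = rep(samp_ids, each = total_pep),
    intensity_l = as.vector(intensity_l),
    intensity_h = as.vector(intensity_h)
  )
  peptides <- peptides[!(is.na(peptides$intensity_l) & is.na(peptides$intensity_h)), ]
  peptides <- dplyr::arrange(peptides, .data$protein_group_id,
                             .data$peptide_id, .data$sample_id)

  truth <- structure(list(
    proteins = tibble::tibble(
      protein_id = prot_ids,
      base_log2 = base_log2,
      differential = seq_len(n_prot) %in% diff_idx,
      log2fc = log2fc,
      in_standard = in_standard
    ),
    samples = tibble::tibble(sample_id = samp_ids, subtype = as.character(subtype)),
    true_log2_abundance = true_log2,
    config = config
  ), class = "cohort_truth")

  list(peptides = peptides, truth = truth)
}

#' @export
print.cohort_truth <- function(x, ...) {
  cat(sprintf(
    "<cohort_truth> %d proteins x %d samples (%s), %d differential, %d in standard\n",
    nrow(x$proteins), nrow(x$samples),
    paste(table(x$samples$subtype), collapse = " vs "),
    sum(x$proteins$differential), sum(x$proteins$in_standard)
  ))
  invisible(x)
}

#' Generate an annotation catalog matched to a simulated cohort
#'
#' Produces `n_categories` uniformly random categories plus one "planted"
#' category drawn preferentially from the truly differential proteins, so
#' enrichment analyses have a known positive control. With
#' `frac_differential_category = 0` the planted category is a plain uniform
#' draw (a null category); with 1 it is a subset of the differential set.
#' When the cohort has proteins absent from the spike-in standard, an extra
#' `standard_absent_like` category collecting them is appended by default,
#' mimicking the extracellular/secreted character of proteins only
#' quantifiable label-free.
#'
#' @param truth A `cohort_truth`.
#' @param n_categories Number of random categories.
#' @param category_size Proteins per category.
#' @param frac_differential_category Expected fraction of the planted
#'   category drawn from the differential set.
#' @param seed Integer seed.
#' @param tag_standard_absent Append the standard-absent category?
#' @return A two-column tibble (`category`, `protein_id`).
#' @export
generate_annotations <- function(truth, n_categories = 20, category_size = 25,
                                 frac_differential_category = 0.8, seed = 1L,
                                 tag_standard_absent = TRUE) {
  ids <- truth$proteins$protein_id
  n_categories <- check_count(n_categories, "n_categories", min = 0)
  category_size <- check_count(category_size, "category_size")
  check_fraction(frac_differential_category, "frac_differential_category")
  if (category_size > length(ids)) {
    abort("`category_size` exceeds the number of proteins in the cohort")
  }
  diff_ids <- ids[truth$proteins$differential]

  withr::with_seed(as.integer(seed), {
    k_diff <- min(rbinom(1, category_size, frac_differential_category),
                  length(diff_ids))
    planted <- sample(diff_ids, k_diff)
    planted <- c(planted, sample(setdiff(ids, planted), category_size - k_diff))
    rand <- lapply(seq_len(n_categories), function(i) sample(ids, category_size))
  })

  cats <- c(list(planted_differential = planted),
            setNames(rand, sprintf("random_%02d", seq_len(n_categories))))
  absent <- ids[!truth$proteins$in_standard]
  if (tag_standard_absent && length(absent)) {
    cats$standard_absent_like <- absent
  }
  tibble::tibble(
    category = rep(names(cats), lengths(cats)),
    protein_id = unlist(cats, use.names = FALSE)
  )
}

#' Write a simulated cohort as tab-separated text
#'
#' Writes `peptides.tsv` (empty field = missing), `labels.tsv`,
#' `truth_proteins.tsv` and `true_log2_abundance.tsv` into `dir`.
#'
#' @param cohort Result of [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(x, file) {
    utils::write.table(x, file.path(dir, file), sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
  }
  tsv(cohort$peptides, "peptides.tsv")
  tsv(cohort$truth$samples, "labels.tsv")
  tsv(cohort$truth$proteins, "truth_proteins.tsv")
  tsv(profile_tbl(cohort$truth$true_log2_abundance), "true_log2_abundance.tsv")
  invisible(dir)
}

#' Read a peptide-feature table from tab-separated text
#'
#' Expects the dialect written by [write_cohort()]: columns
#' `protein_group_id`, `peptide_id`, `sample_id`, `intensity_l`,
#' `intensity_h`, empty fields meaning "not detected". A `col_map` named
#' character vector (`c(protein_group_id = "Proteins", ...)`) adapts
#' evidence-style exports with other column names.
#'
#' @param path File path.
#' @param col_map Optional named character vector mapping the canonical
#'   column names to the names used in the file.
#' @return A validated peptide tibble.
#' @export
read_peptide_table <- function(path, col_map = NULL) {
  x <- tibble::as_tibble(utils::read.delim(path, na.strings = "",
                                           stringsAsFactors = FALSE))
  if (!is.null(col_map)) {
    for (canon in names(col_map)) {
      if (!col_map[[canon]] %in% names(x)) {
        abort(sprintf("column `%s` (mapped to `%s`) not found in %s",
                      col_map[[canon]], canon, path))
      }
      names(x)[names(x) == col_map[[canon]]] <- canon
    }
  }
  validate_peptide_table(x)
}

#' Validate a peptide-feature table
#'
#' Checks required columns, strictly positive intensities, no duplicated
#' (peptide, sample) rows, and that each peptide belongs to exactly one
#' protein group. Offending rows are reported by row number.
#'
#' @param x A peptide tibble.
#' @return The table, invisibly checked (character IDs enforced).
#' @export
validate_peptide_table <- function(x) {
  need <- c("protein_group_id", "peptide_id", "sample_id",
            "intensity_l", "intensity_h")
  miss <- setdiff(need, names(x))
  if (length(miss)) abort(paste0("missing column(s): ", paste(miss, collapse = ", ")))
  bad <- which((!is.na(x$intensity_l) & x$intensity_l <= 0) |
                 (!is.na(x$intensity_h) & x$intensity_h <= 0))
  if (length(bad)) {
    abort(paste0("non-positive intensities at row(s): ",
                 paste(head(bad, 10), collapse = ", ")))
  }
  key <- paste(x$peptide_id, x$sample_id, sep = "\r")
  if (anyDuplicated(key)) {
    abort(paste0("duplicated (peptide_id, sample_id) at row(s): ",
                 paste(head(which(duplicated(key)), 10), collapse = ", ")))
  }
  multi <- tapply(x$protein_group_id, x$peptide_id,
                  function(p) length(unique(p)))
  if (any(multi > 1)) {
    abort(paste0("peptide(s) mapped to multiple protein groups: ",
                 paste(head(names(multi)[multi > 1], 5), collapse = ", ")))
  }
  x$protein_group_id <- as.character(x$protein_group_id)
  x$peptide_id <- as.character(x$peptide_id)
  x$sample_id <- as.character(x$sample_id)
  x
}
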