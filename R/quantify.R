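# Hybrid SILAC/label-free quantification. For every protein group and every
# sample pair, each peptide feature contributes one log2 ratio: the
# ratio-of-ratios (light/heavy in sample a over light/heavy in sample b)
# when the SILAC ratio exists in both samples, otherwise the ratio of the
# two light intensities when both are present, otherwise nothing. The
# median peptide ratio per pair feeds an unweighted least-squares
# reconstruction of a relative log2 intensity profile over the samples.

#' Quantification configuration
#'
#' @param min_ratio_count Minimum number of peptide-level ratios required to
#'   keep a sample-pair entry (default 1).
#' @param mode `"hybrid"` (ratio-of-ratios with light-intensity fallback) or
#'   `"silac"` (ratio-of-ratios only).
#' @param anchor_rule How the free additive constant of each profile is
#'   fixed: `"sum_of_light"` (total linear intensity of the profile equals
#'   the protein's total observed light intensity) or
#'   `"geometric_mean_one"` (profile mean 0 in log2 space). The anchor is
#'   presentation only; all relative information is in the differences.
#' @return A `quant_config` list.
#' @export
quant_config <- function(min_ratio_count = 1,
                         mode = c("hybrid", "silac"),
                         anchor_rule = c("sum_of_light", "geometric_mean_one")) {
  structure(list(
    min_ratio_count = check_count(min_ratio_count, "min_ratio_count"),
    mode = match.arg(mode),
    anchor_rule = match.arg(anchor_rule)
  ), class = "quant_config")
}

#' Log2 ratio contributed by one peptide feature between two samples
#'
#' Implements the hybrid pairing rule: if the light/heavy SILAC ratio is
#' computable in both samples, return the log2 ratio of ratios; otherwise,
#' if both light intensities are present, return the log2 light ratio;
#' otherwise `NA` (the feature does not take part for this pair).
#'
#' @param light_a,heavy_a,light_b,heavy_b Positive intensities or `NA`.
#' @param use_fallback Allow the light-intensity fallback (FALSE for
#'   SILAC-only quantification).
#' @return Log2 ratio (sample a over sample b) or `NA`. Vectorized.
#' @export
peptide_pair_log_ratio <- function(light_a, heavy_a, light_b, heavy_b,
                                   use_fallback = TRUE) {
  rr <- log2((light_a / heavy_a) / (light_b / heavy_b))
  if (!use_fallback) return(rr)
  ifelse(is.na(rr), log2(light_a / light_b), rr)
}

# Sample-pair log-ratio entries for a single protein group, from peptide x
# sample intensity matrices (log2; NA = missing). Returns a tibble of upper
# pairs (a < b) with the median peptide ratio, its support count, and
# whether any contributing peptide used the light fallback.
pairwise_entries <- function(light_log2, heavy_log2, samples,
                             min_ratio_count = 1, use_fallback = TRUE) {
  n <- length(samples)
  if (n < 2) {
    return(tibble::tibble(a = character(), b = character(), log_ratio = numeric(),
                          support = integer(), fallback = logical()))
  }
  pr <- combn(n, 2)
  rr <- light_log2 - heavy_log2                       # SILAC ratio, log2
  d_rr <- rr[, pr[1, ], drop = FALSE] - rr[, pr[2, ], drop = FALSE]
  d <- d_rr
  fb <- matrix(FALSE, nrow(d), ncol(d))
  if (use_fallback) {
    d_l <- light_log2[, pr[1, ], drop = FALSE] - light_log2[, pr[2, ], drop = FALSE]
    fb <- is.na(d_rr) & !is.na(d_l)
    d[fb] <- d_l[fb]
  }
  support <- colSums(!is.na(d))
  keep <- which(support >= min_ratio_count & support > 0)
  if (!length(keep)) {
    return(tibble::tibble(a = character(), b = character(), log_ratio = numeric(),
                          support = integer(), fallback = logical()))
  }
  tibble::tibble(
    a = samples[pr[1, keep]],
    b = samples[pr[2, keep]],
    log_ratio = unname(apply(d[, keep, drop = FALSE], 2, median, na.rm = TRUE)),
    support = as.integer(support[keep]),
    fallback = apply(fb[, keep, drop = FALSE], 2, any)
  )
}

#' Pairwise sample log-ratio matrix for one protein group
#'
#' @param features Peptide table rows of a single protein group.
#' @param config A [quant_config()].
#' @param samples Character vector of all sample IDs (defaults to those in
#'   `features`).
#' @return Tibble of defined pairs `(a, b, log_ratio, support, fallback)`
#'   with `a < b`; antisymmetric completion is implicit
#'   (`r(b, a) = -r(a, b)`).
#' @export
protein_pairwise_ratios <- function(features, config = quant_config(),
                                    samples = NULL) {
  samples <- samples %||% sort(unique(features$sample_id))
  peps <- sort(unique(features$peptide_id))
  L <- H <- matrix(NA_real_, length(peps), length(samples),
                   dimnames = list(peps, samples))
  i <- cbind(match(features$peptide_id, peps), match(features$sample_id, samples))
  L[i] <- log2(features$intensity_l)
  H[i] <- log2(features$intensity_h)
  pairwise_entries(L, H, samples, config$min_ratio_count,
                   use_fallback = config$mode == "hybrid")
}

#' Least-squares reconstruction of a relative log2 profile
#'
#' Minimizes `sum over defined pairs of (x_a - x_b - r(a, b))^2` within
#' each connected component of the sample graph (nodes = samples, edges =
#' defined pairs). The minimizer is unique up to one additive constant per
#' component, fixed by the anchor rule. Samples in no component are `NA`.
#'
#' @param ratios Pair tibble as returned by [protein_pairwise_ratios()].
#' @param samples All sample IDs the profile should cover.
#' @param anchor_rule See [quant_config()].
#' @param light_sums Named vector of total observed linear light intensity
#'   per sample for this protein (required for the `sum_of_light` anchor).
#' @return Named numeric vector of log2 relative intensities (`NA` where
#'   unquantified).
#' @export
reconstruct_profile <- function(ratios, samples,
                                anchor_rule = c("sum_of_light", "geometric_mean_one"),
                                light_sums = NULL) {
  anchor_rule <- match.arg(anchor_rule)
  x <- setNames(rep(NA_real_, length(samples)), samples)
  if (nrow(ratios) == 0) return(x)
  nodes <- sort(unique(c(ratios$a, ratios$b)))
  comp <- graph_components(nodes, ratios$a, ratios$b)
  for (cc in split(nodes, comp)) {
    sub <- ratios[ratios$a %in% cc & ratios$b %in% cc, , drop = FALSE]
    idx <- match(c(sub$a, sub$b), cc)
    k <- length(cc)
    if (k == 1) {
      xs <- 0
    } else {
      # normal equations of the pair system, made non-singular by pinning
      # the component mean to zero (one row of ones)
      A <- matrix(0, nrow(sub), k)
      A[cbind(seq_len(nrow(sub)), match(sub$a, cc))] <- 1
      A[cbind(seq_len(nrow(sub)), match(sub$b, cc))] <- -1
      A <- rbind(A, rep(1, k))
      b <- c(sub$log_ratio, 0)
      xs <- qr.coef(qr(A), b)
    }
    if (anchor_rule == "sum_of_light" && !is.null(light_sums)) {
      tot <- sum(light_sums[cc], na.rm = TRUE)
      if (is.finite(tot) && tot > 0) xs <- xs + log2(tot / sum(2^xs))
    }
    x[cc] <- xs
  }
  x
}

# Connected components by label propagation on a small sample graph.
graph_components <- function(nodes, a, b) {
  comp <- seq_along(nodes)
  names(comp) <- nodes
  repeat {
    new <- comp
    m <- pmin(new[a], new[b])
    # propagate the smaller label across each edge until a fixed point
    for (i in seq_along(a)) {
      new[a[i]] <- min(new[a[i]], m[i])
      new[b[i]] <- min(new[b[i]], m[i])
      m[i] <- min(new[a[i]], new[b[i]])
    }
    if (identical(new, comp)) break
    comp <- new
  }
  comp
}

#' Quantify a protein profile matrix from a peptide-feature table
#'
#' Runs the hybrid (or SILAC-only) pairwise-ratio and least-squares steps
#' for every protein group and assembles the proteins x samples log2
#' relative intensity profile. Per-protein provenance (whether any
#' light-intensity fallback pair contributed, number of quantified samples)
#' is attached as the `"provenance"` attribute; a summary is available via
#' [quant_report()].
#'
#' @param peptides A validated peptide tibble (see
#'   [validate_peptide_table()]).
#' @param config A [quant_config()].
#' @return Wide profile tibble (`protein_id` + one log2 column per sample;
#'   `NA` = unquantified), with attributes `provenance` and `mode`.
#' @export
quantify_matrix <- function(peptides, config = quant_config()) {
  peptides <- validate_peptide_table(peptides)
  samples <- sort(unique(peptides$sample_id))
  groups <- split(peptides, peptides$protein_group_id)
  use_fb <- config$mode == "hybrid"

  rows <- lapply(groups, function(g) {
    peps <- unique(g$peptide_id)
    L <- H <- matrix(NA_real_, length(peps), length(samples),
                     dimnames = list(peps, samples))
    i <- cbind(match(g$peptide_id, peps), match(g$sample_id, samples))
    L[i] <- log2(g$intensity_l)
    H[i] <- log2(g$intensity_h)
    entries <- pairwise_entries(L, H, samples, config$min_ratio_count, use_fb)
    light_sums <- colSums(2^L, na.rm = TRUE)
    prof <- reconstruct_profile(entries, samples, config$anchor_rule, light_sums)
    list(profile = prof, fallback = any(entries$fallback),
         n_quantified = sum(!is.na(prof)))
  })

  mat <- do.call(rbind, lapply(rows, `[[`, "profile"))
  rownames(mat) <- names(groups)
  out <- profile_tbl(mat)
  attr(out, "provenance") <- tibble::tibble(
    protein_id = names(groups),
    fallback_used = vapply(rows, `[[`, logical(1), "fallback"),
    n_quantified = vapply(rows, `[[`, integer(1), "n_quantified")
  )
  attr(out, "mode") <- config$mode
  out
}

#' Summarize a quantification run
#'
#' @param profile Output of [quantify_matrix()].
#' @return One-row tibble: proteins quantified (in at least one sample),
#'   proteins using the light fallback, mean quantifications per sample.
#' @export
quant_report <- function(profile) {
  prov <- attr(profile, "provenance")
  if (is.null(prov)) abort("no provenance attribute; was this made by quantify_matrix()?")
  m <- as_profile_matrix(profile)
  tibble::tibble(
    mode = attr(profile, "mode") %||% NA_character_,
    n_proteins = nrow(m),
    n_quantified = sum(rowSums(!is.na(m)) > 0),
    n_fallback = sum(prov$fallback_used),
    mean_per_sample = mean(colSums(!is.na(m)))
  )
}
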