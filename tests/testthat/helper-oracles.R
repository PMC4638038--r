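# Shared fixtures and independent oracles. Everything here is built in
# code at test time; oracles deliberately take a different route than the
# implementation they check.

# Wide profile tibble from a plain matrix (naming rows/cols if absent).
make_profile <- function(m, proteins = NULL, samples = NULL) {
  rownames(m) <- proteins %||% rownames(m) %||% sprintf("P%03d", seq_len(nrow(m)))
  colnames(m) <- samples %||% colnames(m) %||% sprintf("S%02d", seq_len(ncol(m)))
  proteopanel::profile_tbl(m)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

label_tbl <- function(sample_ids, subtypes) {
  tibble::tibble(sample_id = sample_ids, subtype = subtypes)
}

# Brute-force least-squares oracle for profile reconstruction: stacks one
# row per defined pair into a dense design matrix and takes the
# minimum-norm solution via the Moore-Penrose pseudoinverse. The min-norm
# solution has zero mean within every connected component, i.e. it equals
# the geometric_mean_one anchoring.
ls_oracle <- function(ratios, samples) {
  x <- setNames(rep(NA_real_, length(samples)), samples)
  if (nrow(ratios) == 0) return(x)
  nodes <- sort(unique(c(ratios$a, ratios$b)))
  A <- matrix(0, nrow(ratios), length(nodes), dimnames = list(NULL, nodes))
  A[cbind(seq_len(nrow(ratios)), match(ratios$a, nodes))] <- 1
  A[cbind(seq_len(nrow(ratios)), match(ratios$b, nodes))] <- -1
  x[nodes] <- as.vector(MASS::ginv(A) %*% ratios$log_ratio)
  x
}

# Random small quantification instance: n_samples <= 5, n_peptides <= 6,
# mixed SILAC/light availability. Returns a peptide table for one protein.
random_quant_instance <- function(n_samples = sample(2:5, 1),
                                  n_peptides = sample(1:6, 1)) {
  rows <- expand.grid(pep = seq_len(n_peptides), s = seq_len(n_samples))
  light <- 2^runif(nrow(rows), 10, 20)
  heavy <- 2^runif(nrow(rows), 10, 20)
  light[runif(nrow(rows)) < 0.3] <- NA
  heavy[runif(nrow(rows)) < 0.4] <- NA
  tab <- tibble::tibble(
    protein_group_id = "P001",
    peptide_id = sprintf("pep%d", rows$pep),
    sample_id = sprintf("S%02d", rows$s),
    intensity_l = light,
    intensity_h = heavy
  )
  tab[!(is.na(tab$intensity_l) & is.na(tab$intensity_h)), ]
}

# First-principles pairwise ratio recomputation: loops over every peptide
# and every ordered sample pair, applying the hybrid rule scalar-wise.
brute_pairwise <- function(features, samples, min_ratio_count = 1,
                           use_fallback = TRUE) {
  get <- function(pep, s, col) {
    v <- features[features$peptide_id == pep & features$sample_id == s, ][[col]]
    if (length(v)) v else NA_real_
  }
  out <- list()
  peps <- unique(features$peptide_id)
  for (i in seq_along(samples)) for (j in seq_along(samples)) {
    if (i >= j) next
    vals <- c()
    for (pep in peps) {
      la <- get(pep, samples[i], "intensity_l"); ha <- get(pep, samples[i], "intensity_h")
      lb <- get(pep, samples[j], "intensity_l"); hb <- get(pep, samples[j], "intensity_h")
      r <- if (!is.na(la) && !is.na(ha) && !is.na(lb) && !is.na(hb)) {
        log2((la / ha) / (lb / hb))
      } else if (use_fallback && !is.na(la) && !is.na(lb)) {
        log2(la / lb)
      } else NA_real_
      vals <- c(vals, r)
    }
    vals <- vals[!is.na(vals)]
    if (length(vals) >= min_ratio_count && length(vals) > 0) {
      out[[length(out) + 1]] <- tibble::tibble(
        a = samples[i], b = samples[j],
        log_ratio = median(vals), support = length(vals))
    }
  }
  if (length(out)) dplyr::bind_rows(out) else
    tibble::tibble(a = character(), b = character(), log_ratio = numeric(),
                   support = integer())
}

# Exact-enumeration Fisher oracle via log-binomial coefficients (a route
# independent of dhyper), with the same relative tie guard.
fisher_oracle <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  supp <- max(0, k - n):min(k, m)
  logp <- lchoose(m, supp) + lchoose(n, k - supp) - lchoose(m + n, k)
  probs <- exp(logp)
  min(1, sum(probs[probs <= probs[supp == a] * (1 + 1e-7)]))
}

# Naive average-linkage agglomeration oracle: returns merge heights in
# order and the two-cluster partition, recomputing all pairwise average
# distances from scratch at every step.
average_linkage_oracle <- function(d_mat) {
  clusters <- as.list(seq_len(nrow(d_mat)))
  heights <- c()
  while (length(clusters) > 1) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i >= j) next
      h <- mean(d_mat[clusters[[i]], clusters[[j]]])
      if (h < best[1]) best <- c(h, i, j)
    }
    heights <- c(heights, best[1])
    merged <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters <- c(clusters[-c(best[2], best[3])], list(merged))
    if (length(clusters) == 2) two_clusters <- clusters
  }
  list(heights = heights, two_clusters = two_clusters)
}
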