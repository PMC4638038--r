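# Category enrichment machinery: exact Fisher tests with Benjamini-
# Hochberg correction for PCA-component driver sets, and rank-based
# (Wilcoxon-Mann-Whitney) 1D/2D annotation enrichment scores in [-1, 1].

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Computes the exact two-sided p value by hypergeometric enumeration: the
#' sum of the probabilities of all tables with the same margins whose
#' probability does not exceed that of the observed table (with a 1e-7
#' relative guard so exact ties in probability are included despite
#' floating-point rounding). A table with any zero margin has a single
#' possible configuration and p = 1.
#'
#' @param tab A 2x2 matrix of non-negative integer counts, or a length-4
#'   vector `(a, b, c, d)` filling the table by row.
#' @return The two-sided p value.
#' @export
fisher_exact <- function(tab) {
  x <- as.vector(t(as.matrix(tab)))
  if (length(x) != 4 || any(x < 0) || any(x != floor(x))) {
    abort("`tab` must be 4 non-negative integer counts")
  }
  a <- x[1]; b <- x[2]; c <- x[3]; d <- x[4]
  m <- a + b; n <- c + d; k <- a + c
  supp <- max(0, k - n):min(k, m)
  probs <- dhyper(supp, m, n, k)
  p_obs <- probs[supp == a]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p Vector of p values in [0, 1].
#' @return Vector of q values (monotone step-up adjustment), same order as
#'   the input.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) abort("p values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Fisher enrichment of annotation categories among component drivers
#'
#' Defines the proteins "associated" with a component as those whose
#' absolute loading exceeds the `loading_quantile` quantile of all absolute
#' loadings on that component, then tests each catalog category for
#' overrepresentation among the associated proteins with a two-sided Fisher
#' exact test, BH-corrected across categories. The enrichment factor is the
#' in-category fraction among associated proteins divided by the
#' in-category fraction overall.
#'
#' @param pca A `profile_pca`.
#' @param component Component index.
#' @param catalog Two-column tibble (`category`, `protein_id`).
#' @param loading_quantile Quantile of `|loading|` defining association
#'   (default 0.9).
#' @param alpha Significance cutoff on q values (default 0.05).
#' @return Tibble per tested category: counts, `enrichment_factor`,
#'   `p_value`, `q_value`, `significant`; categories with no protein in the
#'   matrix are skipped (their number is attribute `n_skipped`).
#' @export
component_driver_enrichment <- function(pca, component, catalog,
                                        loading_quantile = 0.9, alpha = 0.05) {
  if (component < 1 || component > ncol(pca$loadings)) abort("no such component")
  check_fraction(loading_quantile, "loading_quantile")
  v <- abs(pca$loadings[, component])
  thr <- quantile(v, loading_quantile)
  if (max(v) <= min(v)) abort("all loadings equal; driver set is degenerate")
  assoc <- names(v)[v > thr]
  ids <- names(v)

  sets <- split(catalog$protein_id, catalog$category)
  present <- lapply(sets, intersect, ids)
  skipped <- sum(lengths(present) == 0)
  present <- present[lengths(present) > 0]
  if (!length(present)) {
    warn("no catalog category overlaps the profile")
    out <- tibble::tibble(category = character(), n_category = integer(),
                          n_associated = integer(), n_overlap = integer(),
                          enrichment_factor = numeric(), p_value = numeric(),
                          q_value = numeric(), significant = logical())
    attr(out, "n_skipped") <- skipped
    return(out)
  }

  rows <- purrr::map(present, function(cat_ids) {
    a <- length(intersect(assoc, cat_ids))
    tab <- c(a, length(assoc) - a,
             length(cat_ids) - a,
             length(ids) - length(assoc) - length(cat_ids) + a)
    expected <- length(cat_ids) / length(ids)
    observed <- if (length(assoc)) a / length(assoc) else 0
    tibble::tibble(n_category = length(cat_ids), n_associated = length(assoc),
                   n_overlap = a,
                   enrichment_factor = observed / expected,
                   p_value = fisher_exact(tab))
  })
  out <- dplyr::bind_rows(rows, .id = "category")
  out$q_value <- bh_adjust(out$p_value)
  out$significant <- out$q_value <= alpha
  out <- dplyr::arrange(out, .data$p_value)
  attr(out, "n_skipped") <- skipped
  if (skipped) inform(sprintf("%d categor%s had no protein in the profile",
                              skipped, if (skipped == 1) "y" else "ies"))
  out
}

#' Rank-based annotation enrichment score (1D)
#'
#' With `U` the Mann-Whitney rank-sum statistic of category members versus
#' non-members (mid-ranks for ties), returns
#' `s = 2 U / (m (n - m)) - 1`, so `s = 1` when the members occupy all top
#' ranks, `-1` when they occupy all bottom ranks, and `E[s] = 0` under
#' exchangeability. The two-sided Mann-Whitney p value is exact when both
#' groups have at most 25 members and the values are tie-free, and uses
#' the normal approximation with tie correction otherwise.
#'
#' @param values Named numeric vector (per-protein values, e.g. a median
#'   subtype profile or a loading column).
#' @param members Character vector of category member IDs.
#' @return One-row tibble: `score`, `p_value`, `n_members`, `n_total`.
#' @export
enrichment_score_1d <- function(values, members) {
  if (is.null(names(values))) abort("`values` must be named by protein ID")
  mem <- names(values) %in% members
  m <- sum(mem); n <- length(values)
  if (m == 0 || m == n) abort("member set must be non-empty and proper")
  r <- rank(values)
  U <- sum(r[mem]) - m * (m + 1) / 2
  s <- 2 * U / (m * (n - m)) - 1
  ties <- anyDuplicated(values) > 0
  exact <- !ties && m <= 25 && (n - m) <= 25
  p <- suppressWarnings(
    wilcox.test(values[mem], values[!mem], exact = exact, correct = TRUE)$p.value
  )
  tibble::tibble(score = s, p_value = p, n_members = m, n_total = n)
}

#' Two-dimensional annotation enrichment
#'
#' Scores every catalog category on two per-protein value dimensions
#' (e.g. the median profiles of two subtypes) with
#' [enrichment_score_1d()], placing each category at `(score_x, score_y)`
#' in the [-1, 1] square. Joint significance is assessed conservatively by
#' doubling the smaller of the two per-dimension Mann-Whitney p values
#' (a Bonferroni factor for the two dimensions) and BH-adjusting across
#' categories.
#'
#' @param dim_x,dim_y Named numeric vectors on a shared protein ID set.
#' @param catalog Two-column tibble (`category`, `protein_id`).
#' @param fdr Significance cutoff on q values (default 0.05).
#' @return An `enrichment_2d` tibble: per category `score_x`, `score_y`,
#'   `p_x`, `p_y`, `p_joint`, `q_value`, `significant`, member counts.
#' @export
enrichment_2d <- function(dim_x, dim_y, catalog, fdr = 0.05) {
  ids <- intersect(names(dim_x), names(dim_y))
  if (!length(ids)) abort("`dim_x` and `dim_y` share no protein IDs")
  dim_x <- dim_x[ids]; dim_y <- dim_y[ids]
  sets <- split(catalog$protein_id, catalog$category)
  sets <- lapply(sets, intersect, ids)
  sets <- sets[lengths(sets) > 0 & lengths(sets) < length(ids)]
  if (!length(sets)) abort("no catalog category has a proper overlap with the IDs")
  rows <- purrr::map(sets, function(mem) {
    ex <- enrichment_score_1d(dim_x, mem)
    ey <- enrichment_score_1d(dim_y, mem)
    tibble::tibble(n_members = ex$n_members, score_x = ex$score,
                   score_y = ey$score, p_x = ex$p_value, p_y = ey$p_value,
                   p_joint = min(1, 2 * min(ex$p_value, ey$p_value)))
  })
  out <- dplyr::bind_rows(rows, .id = "category")
  out$q_value <- bh_adjust(out$p_joint)
  out$significant <- out$q_value <= fdr
  out <- dplyr::arrange(out, .data$q_value)
  class(out) <- c("enrichment_2d", class(out))
  out
}

#' Scatter of 2D enrichment scores
#'
#' @param object An `enrichment_2d` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot enrichment_2d
#' @export
autoplot.enrichment_2d <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$score_x, .data$score_y,
                                       color = .data$significant)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, color = "grey60") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, color = "grey60") +
    ggplot2::geom_abline(slope = 1, intercept = 0, color = "grey85") +
    ggplot2::geom_point() +
    ggplot2::coord_fixed(xlim = c(-1, 1), ylim = c(-1, 1)) +
    ggplot2::labs(x = "enrichment score (dimension x)",
                  y = "enrichment score (dimension y)") +
    ggplot2::theme_minimal()
}

#' Read an annotation catalog from TSV or GMT
#'
#' Accepts a two-column tab-separated file (`category`, `protein_id`) or a
#' `.gmt` file (one category per line: name, description, member IDs).
#'
#' @param path File path; format inferred from the `.gmt` extension.
#' @return Two-column tibble (`category`, `protein_id`).
#' @export
read_catalog <- function(path) {
  if (grepl("\\.gmt$", path, ignore.case = TRUE)) {
    if (requireNamespace("fgsea", quietly = TRUE)) {
      sets <- fgsea::gmtPathways(path)
    } else {
      lines <- strsplit(readLines(path), "\t", fixed = TRUE)
      sets <- setNames(lapply(lines, function(l) l[-(1:2)]),
                       vapply(lines, `[[`, character(1), 1))
    }
    return(tibble::tibble(category = rep(names(sets), lengths(sets)),
                          protein_id = unlist(sets, use.names = FALSE)))
  }
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("category", "protein_id") %in% names(x))) {
    abort("catalog TSV needs `category` and `protein_id` columns")
  }
  tibble::as_tibble(x[c("category", "protein_id")])
}
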