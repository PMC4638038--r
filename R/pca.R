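# PCA by singular value decomposition on the conditioned profile matrix:
# samples are observations, proteins are variables, each protein centered
# across samples. Loadings reveal the proteins driving a component
# ("drivers"); a component pair separating the subtypes is selected
# automatically by a two-sample statistic on the scores.

#' Principal component analysis of a protein profile
#'
#' SVD-based PCA with samples as observations and proteins as (centered)
#' variables. Signs are fixed so that each loading column's
#' largest-magnitude entry is positive, making results deterministic.
#'
#' @param profile Complete wide profile tibble (or proteins x samples
#'   matrix).
#' @return A `profile_pca` object: `scores` (samples x components),
#'   `loadings` (proteins x components, orthonormal columns),
#'   `explained_variance` (fraction per component, non-increasing).
#' @export
profile_pca <- function(profile) {
  m <- as_profile_matrix(profile)
  if (ncol(m) < 2) abort("PCA needs at least 2 samples")
  if (anyNA(m)) abort("PCA requires a complete matrix; impute first")
  x <- t(m)                                  # samples x proteins
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  # centering makes the last singular value exactly zero in exact
  # arithmetic; drop components that are pure rounding noise
  if (max(pc$sdev) > 0) {
    keep <- pc$sdev > max(pc$sdev) * 1e-10
    pc$sdev <- pc$sdev[keep]
    pc$rotation <- pc$rotation[, keep, drop = FALSE]
    pc$x <- pc$x[, keep, drop = FALSE]
  }
  flip <- vapply(seq_len(ncol(pc$rotation)), function(j) {
    v <- pc$rotation[, j]
    sign(v[which.max(abs(v))]) < 0
  }, logical(1))
  pc$rotation[, flip] <- -pc$rotation[, flip]
  pc$x[, flip] <- -pc$x[, flip]
  ev <- pc$sdev^2
  structure(list(
    scores = pc$x,
    loadings = pc$rotation,
    explained_variance = if (sum(ev) > 0) ev / sum(ev) else ev,
    sdev = pc$sdev,
    center = pc$center,
    n_matched = nrow(m)
  ), class = "profile_pca")
}

#' @export
print.profile_pca <- function(x, ...) {
  k <- min(5, length(x$explained_variance))
  cat(sprintf("<profile_pca> %d samples x %d proteins; top variance fractions: %s\n",
              nrow(x$scores), nrow(x$loadings),
              paste(sprintf("%.1f%%", 100 * x$explained_variance[seq_len(k)]),
                    collapse = ", ")))
  invisible(x)
}

#' Select the component pair that best separates two groups
#'
#' For each component, computes the absolute two-sample t statistic of the
#' scores between the label groups and returns the two components with the
#' largest values — an automated stand-in for visually picking the
#' separating pair in a scores plot.
#'
#' @param pca A `profile_pca`.
#' @param labels Sample labels (tibble `sample_id`/`subtype` or named
#'   vector) with exactly two classes.
#' @return Integer vector of length 2 (component indices, ascending), with
#'   the per-component statistics as attribute `"statistic"`.
#' @export
select_component_pair <- function(pca, labels) {
  lab <- align_subtypes(labels, rownames(pca$scores))
  if (nlevels(lab) != 2) abort("labels must have exactly two classes")
  stat <- vapply(seq_len(ncol(pca$scores)), function(j) {
    s <- pca$scores[, j]
    ok <- tryCatch(abs(t.test(s[lab == levels(lab)[1]],
                              s[lab == levels(lab)[2]])$statistic),
                   error = function(e) 0)
    as.numeric(ok)
  }, numeric(1))
  pair <- sort(order(stat, decreasing = TRUE)[1:2])
  attr(pair, "statistic") <- stat
  pair
}

#' Top loading drivers of a component
#'
#' @param pca A `profile_pca`.
#' @param component Component index.
#' @param k Number of proteins to return.
#' @return Tibble (`protein_id`, `loading`, `direction`) of the `k`
#'   proteins with largest absolute loading, ordered by `|loading|`
#'   descending; ties broken by protein ID. `direction` is the loading
#'   sign: proteins with positive loading are relatively up in samples with
#'   positive scores on the component.
#' @export
top_loadings <- function(pca, component, k) {
  if (component < 1 || component > ncol(pca$loadings)) abort("no such component")
  v <- pca$loadings[, component]
  if (k < 1 || k > length(v)) abort("`k` must be between 1 and the protein count")
  ord <- order(-abs(v), names(v))
  sel <- ord[seq_len(k)]
  tibble::tibble(
    protein_id = names(v)[sel],
    loading = unname(v[sel]),
    direction = ifelse(v[sel] >= 0, "up_with_positive_scores",
                       "down_with_positive_scores")
  )
}

#' PCA restricted to a signature protein set
#'
#' Subsets the profile to the signature IDs actually present (reporting the
#' match count, since filtering typically loses part of a signature) and
#' runs [profile_pca()] on the subset.
#'
#' @param profile Complete wide profile tibble (or matrix).
#' @param signature_ids Character vector of protein IDs.
#' @return A `profile_pca` with `n_matched` set to the number of signature
#'   proteins found in the profile.
#' @export
signature_pca <- function(profile, signature_ids) {
  m <- as_profile_matrix(profile)
  found <- intersect(signature_ids, rownames(m))
  if (length(found) < 3) {
    abort(sprintf("only %d signature protein(s) present in the profile (need >= 3)",
                  length(found)))
  }
  res <- profile_pca(m[found, , drop = FALSE])
  res$n_matched <- length(found)
  res
}

#' @rdname profile_pca
#' @method tidy profile_pca
#' @param x A `profile_pca`.
#' @param matrix Which part to tidy: `"scores"`, `"loadings"` or
#'   `"eigenvalues"`.
#' @param ... Unused.
#' @export
tidy.profile_pca <- function(x, matrix = c("scores", "loadings", "eigenvalues"),
                             ...) {
  matrix <- match.arg(matrix)
  switch(matrix,
    scores = tibble::as_tibble(x$scores, rownames = "sample_id") |>
      tidyr::pivot_longer(-"sample_id", names_to = "component",
                          values_to = "score") |>
      dplyr::mutate(component = as.integer(sub("^PC", "", .data$component))),
    loadings = tibble::as_tibble(x$loadings, rownames = "protein_id") |>
      tidyr::pivot_longer(-"protein_id", names_to = "component",
                          values_to = "loading") |>
      dplyr::mutate(component = as.integer(sub("^PC", "", .data$component))),
    eigenvalues = tibble::tibble(
      component = seq_along(x$explained_variance),
      variance = x$sdev^2,
      explained_fraction = x$explained_variance
    )
  )
}

#' @rdname profile_pca
#' @method glance profile_pca
#' @export
glance.profile_pca <- function(x, ...) {
  tibble::tibble(
    n_samples = nrow(x$scores),
    n_proteins = nrow(x$loadings),
    n_matched = x$n_matched,
    pc1_explained = x$explained_variance[1],
    pc2_explained = x$explained_variance[2]
  )
}

#' Scores plot of a PCA result
#'
#' @param object A `profile_pca`.
#' @param components Pair of component indices to plot.
#' @param labels Optional sample labels for coloring.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot profile_pca
#' @export
autoplot.profile_pca <- function(object, components = c(1, 2), labels = NULL,
                                 ...) {
  df <- tibble::tibble(
    sample_id = rownames(object$scores),
    x = object$scores[, components[1]],
    y = object$scores[, components[2]]
  )
  lab_axis <- function(i) sprintf("PC%d (%.1f%%)", components[i],
                                  100 * object$explained_variance[components[i]])
  p <- if (is.null(labels)) {
    ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y))
  } else {
    df$subtype <- align_subtypes(labels, df$sample_id)
    ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, color = .data$subtype))
  }
  p + ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = lab_axis(1), y = lab_axis(2)) +
    ggplot2::theme_minimal()
}
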