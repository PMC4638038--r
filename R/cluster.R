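# Agglomerative hierarchical clustering of samples or proteins with
# Pearson-correlation distance (1 - r) and average linkage -- the standard
# choice for expression heatmaps. A two-cluster cut of the sample tree is
# compared with the subtype labels to decide whether the unsupervised
# clustering still recovers the subtypes.

#' Hierarchical clustering of a profile
#'
#' @param profile Complete wide profile tibble (or matrix).
#' @param axis Cluster `"samples"` (columns) or `"proteins"` (rows).
#' @param distance `"correlation"` (1 - Pearson r, the default) or
#'   `"euclidean"`.
#' @param linkage Linkage method passed to [stats::hclust()] (default
#'   `"average"`).
#' @return An `hclust` tree over the chosen axis.
#' @export
hierarchical_cluster <- function(profile, axis = c("samples", "proteins"),
                                 distance = c("correlation", "euclidean"),
                                 linkage = "average") {
  axis <- match.arg(axis)
  distance <- match.arg(distance)
  m <- as_profile_matrix(profile)
  if (anyNA(m)) abort("clustering requires a complete matrix")
  x <- if (axis == "samples") t(m) else m     # rows = items to cluster
  if (nrow(x) < 2) abort("need at least 2 items to cluster")
  if (distance == "correlation") {
    sds <- apply(x, 1, sd)
    if (any(sds == 0)) {
      abort(paste0("constant ", axis, " make correlation undefined: ",
                   paste(head(rownames(x)[sds == 0], 5), collapse = ", ")))
    }
    d <- as.dist(1 - cor(t(x)))
  } else {
    d <- stats::dist(x)
  }
  hclust(d, method = linkage)
}

#' Does a two-cluster cut of the sample tree reproduce the subtypes?
#'
#' Cuts the dendrogram into exactly two clusters and returns `TRUE` iff the
#' resulting bipartition of samples is identical to the label bipartition
#' (cluster naming is immaterial).
#'
#' @param dendrogram Sample-axis `hclust` tree.
#' @param labels Two-class sample labels.
#' @return Logical.
#' @export
subtype_split_correct <- function(dendrogram, labels) {
  cut2 <- cutree(dendrogram, k = 2)
  lab <- align_subtypes(labels, names(cut2))
  if (nlevels(lab) != 2) abort("labels must have exactly two classes")
  a <- cut2 == 1
  b <- lab == levels(lab)[1]
  all(a == b) || all(a == !b)
}

#' Serialize a dendrogram in Newick format
#'
#' @param dendrogram An `hclust` tree.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dendrogram_newick <- function(dendrogram, path) {
  if (!requireNamespace("ape", quietly = TRUE)) {
    abort("the `ape` package is required to write Newick trees")
  }
  ape::write.tree(ape::as.phylo(dendrogram), file = path)
  invisible(path)
}
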