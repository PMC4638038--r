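# Shared helpers: the protein profile travels through the pipeline as a wide
# tibble (one `protein_id` column, one numeric column per sample). Internally
# most stages work on the equivalent numeric matrix with protein row names.

#' Convert a protein profile tibble to a numeric matrix
#'
#' @param x A wide profile tibble with a `protein_id` column and one numeric
#'   column per sample, or an already-converted numeric matrix with row names.
#' @return A numeric matrix (proteins x samples) with protein IDs as row names.
#' @export
as_profile_matrix <- function(x) {
  if (is.matrix(x)) {
    if (is.null(rownames(x))) abort("profile matrix must have protein row names")
    return(x)
  }
  if (!is.data.frame(x) || !"protein_id" %in% names(x)) {
    abort("expected a profile tibble with a `protein_id` column")
  }
  ids <- as.character(x$protein_id)
  if (anyDuplicated(ids)) abort("duplicated protein_id in profile")
  m <- as.matrix(x[setdiff(names(x), "protein_id")])
  if (!is.numeric(m)) abort("sample columns of a profile must be numeric")
  rownames(m) <- ids
  m
}

#' Convert a protein matrix to a wide profile tibble
#'
#' @param m Numeric matrix (proteins x samples) with row and column names.
#' @return A tibble with `protein_id` and one column per sample.
#' @export
profile_tbl <- function(m) {
  dplyr::bind_cols(
    tibble::tibble(protein_id = rownames(m)),
    tibble::as_tibble(m, .name_repair = "minimal")
  )
}

profile_samples <- function(x) {
  if (is.matrix(x)) colnames(x) else setdiff(names(x), "protein_id")
}

# Accepts labels as a tibble (sample_id, subtype) or a named vector and
# returns a factor aligned to `sample_ids`, erroring on unknown samples.
align_subtypes <- function(labels, sample_ids) {
  if (is.data.frame(labels)) {
    if (!all(c("sample_id", "subtype") %in% names(labels))) {
      abort("label table needs `sample_id` and `subtype` columns")
    }
    lab <- setNames(as.character(labels$subtype), labels$sample_id)
  } else {
    if (is.null(names(labels))) abort("label vector must be named by sample_id")
    lab <- setNames(as.character(labels), names(labels))
  }
  missing <- setdiff(sample_ids, names(lab))
  if (length(missing)) {
    abort(paste0("no subtype label for sample(s): ", paste(missing, collapse = ", ")))
  }
  factor(lab[sample_ids])
}

check_fraction <- function(x, name, lo = 0, hi = 1) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < lo || x > hi) {
    abort(sprintf("`%s` must be a single number in [%g, %g]", name, lo, hi))
  }
  x
}

check_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min || x != floor(x)) {
    abort(sprintf("`%s` must be an integer >= %d", name, min))
  }
  as.integer(x)
}

# Stage seeds are derived from one global seed so that a single integer
# reproduces the full pipeline while stages stay independently replayable.
derive_seed <- function(seed, tag) {
  offs <- c(simulate = 101L, annotate = 211L, impute = 307L, cv = 401L,
            permute = 503L, misc = 601L)
  off <- offs[[tag]] %||% abort(paste0("unknown seed tag: ", tag))
  (as.integer(seed) + off) %% .Machine$integer.max
}
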