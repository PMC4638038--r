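# Matrix conditioning, applied in a fixed order: valid-value filtering,
# then imputation of missing values from a downshifted narrowed normal per
# sample, then width normalization (median 0, interquartile range 1 in
# every sample). All three operate on log2 profiles.

#' Filter proteins by valid-value count
#'
#' Keeps proteins quantified in at least `ceil(min_valid_fraction *
#' n_samples)` samples. With 20 samples and the default 0.75 the integer
#' threshold is 15 valid values.
#'
#' @param profile Wide profile tibble (or matrix).
#' @param min_valid_fraction Required fraction of valid (non-missing)
#'   values per protein, in (0, 1].
#' @return Filtered profile tibble with attribute `filter_report`
#'   (threshold used, proteins before/after).
#' @export
filter_valid_values <- function(profile, min_valid_fraction = 0.75) {
  check_fraction(min_valid_fraction, "min_valid_fraction")
  if (min_valid_fraction <= 0) abort("`min_valid_fraction` must be > 0")
  m <- as_profile_matrix(profile)
  if (ncol(m) < 1 || nrow(m) < 1) abort("empty profile matrix")
  threshold <- as.integer(ceiling(min_valid_fraction * ncol(m)))
  keep <- rowSums(!is.na(m)) >= threshold
  out <- profile_tbl(m[keep, , drop = FALSE])
  attr(out, "filter_report") <- tibble::tibble(
    n_samples = ncol(m), min_valid_fraction = min_valid_fraction,
    threshold = threshold, n_before = nrow(m), n_after = sum(keep)
  )
  out
}

#' Impute missing values from a downshifted, narrowed normal
#'
#' Models values missing because they fall near the detection limit: for
#' each sample with observed mean `m` and standard deviation `s`, every
#' missing cell is replaced by an independent draw from
#' `Normal(m - downshift * s, (width * s)^2)`. Observed cells are never
#' touched. Imputation is per sample because the detection limit is a
#' property of the individual run.
#'
#' @param profile Wide log2 profile tibble (or matrix).
#' @param width Width of the imputation distribution as a fraction of the
#'   sample SD (default 0.3).
#' @param downshift Downshift of its mean in sample SDs (default 1).
#' @param seed Integer seed; the same seed reproduces the imputed matrix.
#' @return Complete profile tibble with attribute `impute_report`
#'   (per-sample mean, sd and number of imputed cells).
#' @export
impute_downshift <- function(profile, width = 0.3, downshift = 1, seed = 1L) {
  if (width <= 0) abort("`width` must be > 0")
  if (downshift < 0) abort("`downshift` must be >= 0")
  m <- as_profile_matrix(profile)
  n_obs <- colSums(!is.na(m))
  if (any(n_obs < 2)) {
    abort(paste0("cannot impute sample(s) with fewer than 2 observed values: ",
                 paste(colnames(m)[n_obs < 2], collapse = ", ")))
  }
  mu <- colMeans(m, na.rm = TRUE)
  s <- apply(m, 2, sd, na.rm = TRUE)
  n_missing <- colSums(is.na(m))
  withr::with_seed(as.integer(seed), {
    for (j in seq_len(ncol(m))) {
      miss <- is.na(m[, j])
      if (any(miss)) {
        m[miss, j] <- rnorm(sum(miss), mu[j] - downshift * s[j], width * s[j])
      }
    }
  })
  out <- profile_tbl(m)
  attr(out, "impute_report") <- tibble::tibble(
    sample_id = colnames(m), observed_mean = mu, observed_sd = s,
    n_imputed = n_missing
  )
  out
}

#' Width normalization: per-sample median 0, interquartile range 1
#'
#' Subtracts each sample's median and divides by its interquartile range
#' (Q3 - Q1, linear-interpolation quantiles), so all samples share the same
#' location and spread. Requires a complete matrix (run after imputation).
#'
#' @param profile Complete wide profile tibble (or matrix).
#' @return Normalized profile tibble with attribute `normalize_report`
#'   (per-sample median and IQR removed).
#' @export
width_normalize <- function(profile) {
  m <- as_profile_matrix(profile)
  if (anyNA(m)) abort("width_normalize requires a complete matrix; impute first")
  med <- apply(m, 2, median)
  iqr <- apply(m, 2, function(x) unname(diff(quantile(x, c(0.25, 0.75)))))
  if (any(iqr == 0)) {
    abort(paste0("zero interquartile range in sample(s): ",
                 paste(colnames(m)[iqr == 0], collapse = ", ")))
  }
  m <- sweep(sweep(m, 2, med), 2, iqr, "/")
  out <- profile_tbl(m)
  attr(out, "normalize_report") <- tibble::tibble(
    sample_id = colnames(m), median = med, iqr = iqr
  )
  out
}

#' Run the full conditioning chain: filter, impute, normalize
#'
#' @inheritParams filter_valid_values
#' @inheritParams impute_downshift
#' @return Normalized complete profile tibble; the three stage reports are
#'   attached as attributes.
#' @export
preprocess_profile <- function(profile, min_valid_fraction = 0.75,
                               width = 0.3, downshift = 1, seed = 1L) {
  f <- filter_valid_values(profile, min_valid_fraction)
  i <- impute_downshift(f, width = width, downshift = downshift, seed = seed)
  n <- width_normalize(i)
  attr(n, "filter_report") <- attr(f, "filter_report")
  attr(n, "impute_report") <- attr(i, "impute_report")
  n
}
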