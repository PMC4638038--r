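# Supervised core: S0-moderated two-sample statistic for feature ranking,
# linear soft-margin SVM training, random-sampling cross-validation with
# per-k error curves and panel extraction, and the clustering-loss feature
# cutoff. Feature ranking inside cross-validation uses training samples
# only -- the held-out samples never influence which features are used.

#' Default feature-count grid for cross-validation
#'
#' @return Ascending integer vector: every count up to 20, then a sparser
#'   grid to 500.
#' @export
default_k_grid <- function() {
  c(1:20, 25, 30, 40, 50, 75, 100, 150, 200, 300, 400, 500)
}

# Fast internal moderated statistic on a proteins x samples matrix.
# d = (mean_A - mean_B) / (pooled SE + s0); the additive S0 keeps
# small-variance, small-fold-change proteins from dominating the ranking.
moderated_stat <- function(m, lab, s0) {
  ia <- lab == levels(lab)[1]
  na <- sum(ia); nb <- sum(!ia)
  ma <- rowMeans(m[, ia, drop = FALSE])
  mb <- rowMeans(m[, !ia, drop = FALSE])
  ssa <- rowSums((m[, ia, drop = FALSE] - ma)^2)
  ssb <- rowSums((m[, !ia, drop = FALSE] - mb)^2)
  pooled_var <- (ssa + ssb) / (na + nb - 2)
  se <- sqrt(pooled_var * (1 / na + 1 / nb))
  if (s0 == 0 && any(se == 0)) {
    abort(paste0("zero-variance protein(s) with s0 = 0: ",
                 paste(head(rownames(m)[se == 0], 5), collapse = ", ")))
  }
  list(d = (ma - mb) / (se + s0), fc = ma - mb, mean_A = ma, mean_B = mb,
       df = na + nb - 2)
}

#' S0-moderated two-sample statistic per protein
#'
#' Computes, for each protein, `d = (mean_A - mean_B) / (se + s0)` with
#' `se` the pooled two-sample standard error. `s0 = 0` recovers the
#' classical pooled t statistic; `s0 > 0` acts as a background correction
#' that favors proteins with larger mean fold changes at comparable
#' significance. P values come from the Student reference with
#' `n_A + n_B - 2` degrees of freedom (`p_mode = "parametric"`) or from
#' label permutations (`p_mode = "permutation"`, per-protein null).
#'
#' @param profile Complete wide profile tibble (or matrix).
#' @param labels Two-class sample labels.
#' @param s0 Background correction constant (default 0.1 on log2 data).
#' @param p_mode `"parametric"` or `"permutation"`.
#' @param n_permutations Number of label permutations (permutation mode).
#' @param seed Seed for the permutation null.
#' @return Tibble per protein: `mean_A`, `mean_B`, `log2fc` (A minus B),
#'   `statistic`, `p_value`.
#' @export
moderated_t <- function(profile, labels, s0 = 0.1,
                        p_mode = c("parametric", "permutation"),
                        n_permutations = 250, seed = 1L) {
  p_mode <- match.arg(p_mode)
  if (s0 < 0) abort("`s0` must be >= 0")
  m <- as_profile_matrix(profile)
  if (anyNA(m)) abort("moderated_t requires a complete matrix")
  lab <- align_subtypes(labels, colnames(m))
  if (nlevels(lab) != 2 || any(table(lab) < 2)) {
    abort("labels must have two classes with at least 2 samples each")
  }
  st <- moderated_stat(m, lab, s0)
  p <- if (p_mode == "parametric") {
    2 * pt(-abs(st$d), df = st$df)
  } else {
    withr::with_seed(as.integer(seed), {
      hits <- integer(nrow(m))
      for (b in seq_len(n_permutations)) {
        perm <- sample(lab)
        dstar <- moderated_stat(m, perm, s0)$d
        hits <- hits + (abs(dstar) >= abs(st$d))
      }
      (1 + hits) / (1 + n_permutations)
    })
  }
  tibble::tibble(protein_id = rownames(m), mean_A = unname(st$mean_A),
                 mean_B = unname(st$mean_B), log2fc = unname(st$fc),
                 statistic = unname(st$d), p_value = unname(p))
}

#' Rank proteins by discriminative power
#'
#' Orders proteins by ascending moderated-statistic p value (equivalently
#' descending `|d|` in parametric mode), breaking ties by larger absolute
#' fold change and then by protein ID for full determinism.
#'
#' @inheritParams moderated_t
#' @return The [moderated_t()] tibble with a `rank` column, sorted.
#' @export
rank_features <- function(profile, labels, s0 = 0.1,
                          p_mode = c("parametric", "permutation"),
                          n_permutations = 250, seed = 1L) {
  tt <- moderated_t(profile, labels, s0, p_mode, n_permutations, seed)
  ord <- order(tt$p_value, -abs(tt$log2fc), tt$protein_id)
  out <- tt[ord, ]
  out$rank <- seq_len(nrow(out))
  out
}

#' Train a linear soft-margin SVM on sample profiles
#'
#' @param x Samples x features numeric matrix (rows named by sample).
#' @param labels Two-class labels for the rows of `x`.
#' @param cost Soft-margin cost parameter (default 1).
#' @return A `panel_svm` predictor.
#' @export
train_svm <- function(x, labels, cost = 1) {
  lab <- align_subtypes(labels, rownames(x))
  if (nlevels(lab) != 2) abort("training labels must have exactly two classes")
  fit <- e1071::svm(x, lab, kernel = "linear", cost = cost, scale = FALSE)
  structure(list(fit = fit, features = colnames(x), levels = levels(lab)),
            class = "panel_svm")
}

#' Predict subtypes with a trained panel SVM
#'
#' @param object A `panel_svm`.
#' @param newdata Samples x features matrix covering the training features.
#' @param ... Unused.
#' @return Tibble (`sample_id`, `predicted`, `margin`); `margin` is the
#'   signed distance-like decision value (positive for the first level).
#' @export
predict.panel_svm <- function(object, newdata, ...) {
  nd <- newdata[, object$features, drop = FALSE]
  pred <- stats::predict(object$fit, nd, decision.values = TRUE)
  dv <- attr(pred, "decision.values")
  tibble::tibble(sample_id = rownames(nd) %||% as.character(seq_len(nrow(nd))),
                 predicted = as.character(pred),
                 margin = as.numeric(dv))
}

#' SVM feature-selection cross-validation
#'
#' Repeats, `repetitions` times: draw a stratified random sample of
#' `train_fraction` of each class for training; rank the proteins on the
#' training samples only; for each `k` in `k_grid`, train a linear SVM on
#' the top-`k` features and record the held-out error. The per-k mean error
#' curve identifies `optimal_k`, the smallest feature count attaining the
#' minimum mean error (parsimony tie-break); the final panel is the top
#' `optimal_k` of the full-data ranking, reported together with how often
#' each protein entered the per-repetition top `optimal_k`.
#'
#' @param profile Complete wide profile tibble (or matrix).
#' @param labels Two-class sample labels.
#' @param train_fraction Fraction of each class used for training
#'   (default 0.9).
#' @param repetitions Number of random splits (default 1000).
#' @param k_grid Ascending feature counts to evaluate (entries beyond the
#'   protein count are dropped).
#' @param seed Integer seed making the whole procedure deterministic.
#' @param s0 Moderated-statistic background constant.
#' @param cost SVM cost parameter.
#' @return An `svm_cv` report: `error_curve` (per-k mean/sd error and
#'   per-repetition spread), `optimal_k`, `panel`,
#'   `selection_frequency`, `n_redraws`, and the configuration.
#' @export
cv_feature_selection <- function(profile, labels, train_fraction = 0.9,
                                 repetitions = 1000, k_grid = default_k_grid(),
                                 seed = 1L, s0 = 0.1, cost = 1) {
  check_fraction(train_fraction, "train_fraction")
  if (train_fraction <= 0 || train_fraction >= 1) {
    abort("`train_fraction` must be strictly between 0 and 1")
  }
  repetitions <- check_count(repetitions, "repetitions")
  m <- as_profile_matrix(profile)
  if (anyNA(m)) abort("cross-validation requires a complete matrix")
  lab <- align_subtypes(labels, colnames(m))
  if (nlevels(lab) != 2 || any(table(lab) < 2)) {
    abort("labels must have two classes with at least 2 samples each")
  }
  k_grid <- sort(unique(as.integer(k_grid)))
  k_grid <- k_grid[k_grid >= 1 & k_grid <= nrow(m)]
  if (!length(k_grid)) abort("`k_grid` has no usable entry")
  max_k <- max(k_grid)
  X <- t(m)
  idx_by_class <- split(seq_along(lab), lab)
  n_train_class <- vapply(idx_by_class, function(i) {
    as.integer(min(max(round(train_fraction * length(i)), 1), length(i) - 1))
  }, integer(1))

  err <- matrix(NA_real_, repetitions, length(k_grid),
                dimnames = list(NULL, k_grid))
  top_ids <- matrix(NA_character_, repetitions, max_k)
  withr::with_seed(as.integer(seed), {
    for (r in seq_len(repetitions)) {
      train <- unlist(purrr::map2(idx_by_class, n_train_class, sample),
                      use.names = FALSE)
      test <- setdiff(seq_along(lab), train)
      st <- moderated_stat(m[, train, drop = FALSE], droplevels(lab[train]), s0)
      p <- 2 * pt(-abs(st$d), df = st$df)
      ord <- order(p, -abs(st$fc), rownames(m))
      top_ids[r, ] <- rownames(m)[ord[seq_len(max_k)]]
      for (ki in seq_along(k_grid)) {
        feats <- ord[seq_len(k_grid[ki])]
        fit <- e1071::svm(X[train, feats, drop = FALSE], lab[train],
                          kernel = "linear", cost = cost, scale = FALSE)
        pred <- stats::predict(fit, X[test, feats, drop = FALSE])
        err[r, ki] <- mean(pred != lab[test])
      }
    }
  })

  error_curve <- tibble::tibble(
    k = k_grid,
    mean_error = colMeans(err),
    sd_error = apply(err, 2, sd),
    n_repetitions = repetitions
  )
  optimal_k <- k_grid[which(error_curve$mean_error ==
                              min(error_curve$mean_error))[1]]
  sel <- table(as.vector(top_ids[, seq_len(optimal_k), drop = FALSE]))
  selection_frequency <- tibble::tibble(
    protein_id = names(sel),
    frequency = as.numeric(sel) / repetitions
  ) |> dplyr::arrange(dplyr::desc(.data$frequency), .data$protein_id)

  full_rank <- rank_features(m, lab, s0 = s0)
  panel <- dplyr::left_join(
    full_rank[seq_len(optimal_k), c("protein_id", "rank", "log2fc",
                                    "statistic", "p_value")],
    selection_frequency, by = "protein_id"
  )
  panel$frequency[is.na(panel$frequency)] <- 0

  structure(list(
    error_curve = error_curve,
    optimal_k = optimal_k,
    panel = panel,
    selection_frequency = selection_frequency,
    n_redraws = 0L,
    config = list(train_fraction = train_fraction, repetitions = repetitions,
                  k_grid = k_grid, seed = as.integer(seed), s0 = s0,
                  cost = cost)
  ), class = "svm_cv")
}

#' @export
print.svm_cv <- function(x, ...) {
  best <- x$error_curve[x$error_curve$k == x$optimal_k, ]
  cat(sprintf(
    "<svm_cv> %d repetitions; optimal panel size %d with %.1f%% held-out error\n",
    x$config$repetitions, x$optimal_k, 100 * best$mean_error))
  cat("panel:", paste(x$panel$protein_id, collapse = ", "), "\n")
  invisible(x)
}

#' @rdname cv_feature_selection
#' @param x,object An `svm_cv` report.
#' @param ... Unused.
#' @method tidy svm_cv
#' @export
tidy.svm_cv <- function(x, ...) x$error_curve

#' @rdname cv_feature_selection
#' @method glance svm_cv
#' @export
glance.svm_cv <- function(x, ...) {
  best <- x$error_curve[x$error_curve$k == x$optimal_k, ]
  tibble::tibble(optimal_k = x$optimal_k, mean_error = best$mean_error,
                 sd_error = best$sd_error,
                 repetitions = x$config$repetitions,
                 n_redraws = x$n_redraws)
}

#' @rdname cv_feature_selection
#' @method autoplot svm_cv
#' @export
autoplot.svm_cv <- function(object, ...) {
  se <- object$error_curve$sd_error / sqrt(object$error_curve$n_repetitions)
  df <- dplyr::mutate(object$error_curve, se = se)
  ggplot2::ggplot(df, ggplot2::aes(.data$k, .data$mean_error)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_error - .data$se,
                                      ymax = .data$mean_error + .data$se),
                         alpha = 0.2) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::geom_vline(xintercept = object$optimal_k, linetype = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "panel size k (log scale)",
                  y = "mean held-out error rate") +
    ggplot2::theme_minimal()
}

#' Final discriminating panel from the full data
#'
#' Top-`k` proteins of the full-data ranking; if a cross-validation report
#' is supplied, per-feature selection frequencies are attached so the
#' stability of each panel member across repetitions is visible.
#'
#' @inheritParams moderated_t
#' @param k Panel size.
#' @param cv An optional `svm_cv` report.
#' @return Ranked panel tibble.
#' @export
final_panel <- function(profile, labels, k, s0 = 0.1, cv = NULL) {
  m <- as_profile_matrix(profile)
  k <- check_count(k, "k")
  if (k > nrow(m)) abort("`k` exceeds the number of proteins")
  out <- rank_features(m, labels, s0 = s0)[seq_len(k), ]
  if (!is.null(cv)) {
    out <- dplyr::left_join(out, cv$selection_frequency, by = "protein_id")
    out$frequency[is.na(out$frequency)] <- 0
  }
  out
}

#' Feature cutoff where unsupervised subtype clustering is lost
#'
#' Scans panel sizes upward along a ranked feature list and returns the
#' largest scanned `k` such that a two-cluster cut of the sample dendrogram
#' (on the top-`k` features) reproduces the subtype bipartition at every
#' scanned size up to `k`. The scan stops at the first loss. Returns 0
#' (with a warning) if even the smallest scanned size fails. The default
#' grid is every size from 3 to 50, then steps of 10; sizes 1 and 2 are not
#' scanned because the Pearson correlation between samples is undefined
#' over one feature and identically +/-1 over two, so the correlation
#' distance only becomes informative from three features on.
#'
#' @param profile Complete wide profile tibble (or matrix).
#' @param labels Two-class sample labels.
#' @param ranked_ids Protein IDs in ranked order (e.g. from
#'   [rank_features()]).
#' @param scan_grid Optional ascending integer sizes to scan.
#' @param distance,linkage Passed to [hierarchical_cluster()].
#' @return The cutoff size (integer), with the scanned sizes and their
#'   outcomes as attribute `"scan"`.
#' @export
clustering_loss_cutoff <- function(profile, labels, ranked_ids,
                                   scan_grid = NULL,
                                   distance = "correlation",
                                   linkage = "average") {
  m <- as_profile_matrix(profile)
  ranked_ids <- ranked_ids[ranked_ids %in% rownames(m)]
  n <- length(ranked_ids)
  if (n < 2) abort("need at least 2 ranked features")
  if (is.null(scan_grid)) {
    scan_grid <- c(3:min(50, n), if (n > 50) seq(60, n, 10))
  }
  scan_grid <- sort(unique(as.integer(scan_grid)))
  scan_grid <- scan_grid[scan_grid >= 2 & scan_grid <= n]
  cutoff <- 0L
  scanned <- integer(0); ok <- logical(0)
  for (k in scan_grid) {
    correct <- tryCatch({
      hc <- hierarchical_cluster(m[ranked_ids[seq_len(k)], , drop = FALSE],
                                 axis = "samples", distance = distance,
                                 linkage = linkage)
      subtype_split_correct(hc, labels)
    }, error = function(e) FALSE)
    scanned <- c(scanned, k); ok <- c(ok, correct)
    if (!correct) break
    cutoff <- k
  }
  if (cutoff == 0L) warn("subtype clustering incorrect at the smallest scanned size")
  attr(cutoff, "scan") <- tibble::tibble(k = scanned, split_correct = ok)
  cutoff
}
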