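test_that("a matrix constant across samples has no explained variance", {
  m <- matrix(rep(rnorm(30), 6), 30, 6)
  prof <- make_profile(m)
  res <- profile_pca(prof)
  expect_true(all(res$explained_variance < 1e-20))
})

test_that("all components reconstruct the centered input exactly", {
  withr::with_seed(61, m <- matrix(rnorm(50 * 10), 50, 10))
  prof <- make_profile(m)
  res <- profile_pca(prof)
  centered <- scale(t(as_profile_matrix(prof)), center = TRUE, scale = FALSE)
  recon <- res$scores %*% t(res$loadings)
  expect_equal(unname(recon), unname(centered[, rownames(res$loadings)]),
               tolerance = 1e-10)
  expect_equal(sum(res$explained_variance), 1, tolerance = 1e-10)
  # loadings columns are orthonormal, explained fractions non-increasing
  expect_equal(crossprod(res$loadings), diag(ncol(res$loadings)),
               ignore_attr = TRUE, tolerance = 1e-10)
  expect_true(all(diff(res$explained_variance) <= 1e-12))
})

test_that("PCA is invariant to sample order and per-protein shifts", {
  withr::with_seed(67, m <- matrix(rnorm(40 * 8), 40, 8))
  prof <- make_profile(m)
  res <- profile_pca(prof)
  perm <- sample(ncol(m))
  m_perm <- as_profile_matrix(prof)[, perm]
  res_perm <- profile_pca(m_perm)
  expect_equal(res_perm$scores[rownames(res$scores), ], res$scores,
               tolerance = 1e-8)
  shifted <- as_profile_matrix(prof) + rnorm(40)  # adds a constant per row
  res_shift <- profile_pca(shifted)
  expect_equal(res_shift$scores, res$scores, tolerance = 1e-8)
  expect_equal(res_shift$loadings, res$loadings, tolerance = 1e-8)
})

test_that("a component separates planted subtypes with positive silhouette", {
  co <- generate_cohort(sim_config(n_proteins = 400, frac_differential = 0.15,
                                   log2fc_range = c(1.5, 2.5), seed = 71))
  prof <- preprocess_profile(quantify_matrix(co$peptides), seed = 1)
  res <- profile_pca(prof)
  lab <- co$truth$samples
  pair <- select_component_pair(res, lab)
  sc <- res$scores[, pair, drop = FALSE]
  sil <- cluster::silhouette(as.integer(align_subtypes(lab, rownames(sc))),
                             dist(sc))
  expect_gt(mean(sil[, "sil_width"]), 0)
})

test_that("the selected pair matches an exhaustive scan of t statistics", {
  withr::with_seed(73, {
    scores <- matrix(rnorm(20 * 6), 20,
                     dimnames = list(sprintf("S%02d", 1:20), paste0("PC", 1:6)))
    # plant separation along components 3 and 5
    grp <- rep(c(0, 1), c(13, 7))
    scores[, 3] <- scores[, 3] + 6 * grp
    scores[, 5] <- scores[, 5] - 4 * grp
  })
  fake <- structure(list(scores = scores), class = "profile_pca")
  lab <- label_tbl(rownames(scores), ifelse(grp == 1, "B", "A"))
  pair <- select_component_pair(fake, lab)
  expect_identical(as.integer(pair), c(3L, 5L))
  # brute force: the attribute holds the full scan
  stat <- attr(pair, "statistic")
  brute <- apply(scores, 2, function(s)
    abs(t.test(s[grp == 0], s[grp == 1])$statistic))
  expect_equal(stat, unname(brute), tolerance = 1e-12)
})

test_that("top_loadings ranks by absolute loading with a stable tie rule", {
  loadings <- matrix(c(0.9, -0.1, 0.05), 3, 1,
                     dimnames = list(c("Pa", "Pb", "Pc"), "PC1"))
  fake <- structure(list(loadings = loadings), class = "profile_pca")
  expect_identical(top_loadings(fake, 1, 1)$protein_id, "Pa")
  # ties broken by protein ID order
  tie <- matrix(c(0.5, -0.5, 0.1), 3, 1,
                dimnames = list(c("Pz", "Pa", "Pm"), "PC1"))
  fake2 <- structure(list(loadings = tie), class = "profile_pca")
  expect_identical(top_loadings(fake2, 1, 2)$protein_id, c("Pa", "Pz"))
  expect_error(top_loadings(fake, 1, 4), "k")
  expect_error(top_loadings(fake, 3, 1), "component")
})

test_that("planted drivers are recovered among the top loadings", {
  co <- generate_cohort(sim_config(n_proteins = 400, frac_differential = 0.1,
                                   log2fc_range = c(2, 3), seed = 79))
  prof <- preprocess_profile(quantify_matrix(co$peptides), seed = 1)
  res <- profile_pca(prof)
  lab <- co$truth$samples
  comp <- select_component_pair(res, lab)[1]
  k <- 20
  top <- top_loadings(res, comp, k)
  planted <- co$truth$proteins$protein_id[co$truth$proteins$differential]
  recall <- mean(top$protein_id %in% planted)
  chance <- length(intersect(planted, rownames(res$loadings))) /
    nrow(res$loadings)
  expect_gt(recall, chance)
})

test_that("signature PCA reports matches and reduces to full PCA when trivial", {
  withr::with_seed(83, m <- matrix(rnorm(30 * 8), 30, 8))
  prof <- make_profile(m)
  all_ids <- prof$protein_id
  full <- profile_pca(prof)
  sig <- signature_pca(prof, all_ids)
  expect_equal(sig$explained_variance, full$explained_variance)
  expect_equal(sig$scores, full$scores)
  sub <- signature_pca(prof, c(all_ids[1:6], "absent_1", "absent_2",
                               "absent_3", "absent_4"))
  expect_identical(sub$n_matched, 6L)
  expect_error(signature_pca(prof, c(all_ids[1], "x", "y")), "3")
})

test_that("identical samples merge first at height zero", {
  withr::with_seed(89, base <- rnorm(20))
  m <- cbind(s1 = base, s2 = base, s3 = base + rnorm(20, 0, 2),
             s4 = rnorm(20))
  rownames(m) <- sprintf("P%03d", 1:20)
  hc <- hierarchical_cluster(make_profile(m), axis = "samples")
  first <- sort(hc$labels[-hc$merge[1, ]])
  expect_identical(first, c("s1", "s2"))
  expect_equal(hc$height[1], 0, tolerance = 1e-12)
  expect_true(all(diff(hc$height) >= -1e-12))
})

test_that("well-separated sample pairs form the top split", {
  withr::with_seed(97, {
    sig1 <- rnorm(30); sig2 <- rnorm(30)
    m <- cbind(a1 = sig1 + rnorm(30, 0, 0.1), a2 = sig1 + rnorm(30, 0, 0.1),
               b1 = sig2 + rnorm(30, 0, 0.1), b2 = sig2 + rnorm(30, 0, 0.1))
  })
  rownames(m) <- sprintf("P%03d", 1:30)
  hc <- hierarchical_cluster(make_profile(m), axis = "samples")
  cut2 <- cutree(hc, 2)
  expect_identical(unname(cut2["a1"]), unname(cut2["a2"]))
  expect_identical(unname(cut2["b1"]), unname(cut2["b2"]))
  expect_false(cut2[["a1"]] == cut2[["b1"]])
  lab <- label_tbl(colnames(m), c("A", "A", "B", "B"))
  expect_true(subtype_split_correct(hc, lab))
  expect_false(subtype_split_correct(hc, label_tbl(colnames(m),
                                                   c("A", "B", "A", "B"))))
})

test_that("merge heights match a naive average-linkage oracle", {
  withr::with_seed(101, m <- matrix(rnorm(15 * 7), 15, 7))
  prof <- make_profile(m)
  hc <- hierarchical_cluster(prof, axis = "samples")
  d <- 1 - cor(as_profile_matrix(prof))
  oracle <- average_linkage_oracle(d)
  expect_equal(hc$height, oracle$heights, tolerance = 1e-12)
  got2 <- cutree(hc, 2)
  want <- oracle$two_clusters[[1]]
  expect_true(all(got2[want] == got2[want][1]) &&
                all(got2[-want] == got2[-want][1]) &&
                got2[want][1] != got2[-want][1])
})

test_that("constant items are rejected by name; protein axis works", {
  m <- matrix(rnorm(40), 10, 4,
              dimnames = list(sprintf("P%03d", 1:10), paste0("s", 1:4)))
  m[4, ] <- 2
  expect_error(hierarchical_cluster(make_profile(m), axis = "proteins"),
               "P004")
  m[4, ] <- rnorm(4)
  hc <- hierarchical_cluster(make_profile(m), axis = "proteins")
  expect_identical(hc$labels, rownames(m))
})

test_that("random labels rarely pass the subtype split check", {
  withr::with_seed(103, {
    sig <- rnorm(40)
    m <- sapply(1:10, function(i) sig * rep(c(1, -1), c(5, 5))[i] +
                  rnorm(40, 0, 0.3))
    colnames(m) <- sprintf("S%02d", 1:10)
    rownames(m) <- sprintf("P%03d", 1:40)
    hc <- hierarchical_cluster(make_profile(m), axis = "samples")
    hits <- vapply(1:20, function(i) {
      subtype_split_correct(hc, label_tbl(colnames(m),
                                          sample(rep(c("A", "B"), 5))))
    }, logical(1))
  })
  expect_lt(mean(hits), 0.25)
})

test_that("tidy, glance and autoplot expose PCA results", {
  withr::with_seed(107, prof <- make_profile(matrix(rnorm(200), 40, 5)))
  res <- profile_pca(prof)
  sc <- tidy(res, "scores")
  expect_setequal(names(sc), c("sample_id", "component", "score"))
  ev <- tidy(res, "eigenvalues")
  expect_equal(sum(ev$explained_fraction), 1, tolerance = 1e-10)
  expect_s3_class(glance(res), "tbl_df")
  p <- autoplot(res, labels = label_tbl(sprintf("S%02d", 1:5),
                                        c("A", "A", "A", "B", "B")))
  expect_s3_class(p, "ggplot")
})
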