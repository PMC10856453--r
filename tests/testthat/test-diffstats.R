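sim_matrix <- function(n_comp, n_per_group, fold = rep(1, n_comp),
                       cv = 0.3, loading_sd = 0, seed = 1) {
  set.seed(seed)
  sdlog <- sqrt(log(1 + cv^2))
  base <- exp(stats::runif(n_comp, log(1e6), log(1e8)))
  load <- stats::rlnorm(2 * n_per_group, 0, loading_sd)
  m <- outer(base, load) *
    matrix(stats::rlnorm(n_comp * 2 * n_per_group, -sdlog^2 / 2, sdlog),
           n_comp)
  m[, seq_len(n_per_group)] <- m[, seq_len(n_per_group)] * fold
  rownames(m) <- sprintf("cmp%03d", seq_len(n_comp))
  colnames(m) <- c(sprintf("liver_%02d", seq_len(n_per_group)),
                   sprintf("muscle_%02d", seq_len(n_per_group)))
  list(m = m, groups = rep(c("liver", "muscle"), each = n_per_group))
}

test_that("median normalization removes sample loading factors", {
  s <- sim_matrix(100, 10, loading_sd = 0.2, seed = 2)
  norm <- normalize_abundance(s$m)
  med <- apply(norm, 2, function(x) stats::median(x[x > 0]))
  expect_lt((max(med) - min(med)) / stats::median(med), 1e-9)
  # a global x2 scale on one sample is exactly undone: the normalized
  # matrices agree up to one common scalar (the retargeted global median)
  m2 <- s$m; m2[, 3] <- m2[, 3] * 2
  r <- normalize_abundance(m2) / norm
  expect_lt(max(r) - min(r), 1e-9 * stats::median(r))
  # already median-equal input is unchanged
  expect_equal(normalize_abundance(norm), norm, tolerance = 1e-12)
  # zeros stay zero
  mz <- s$m; mz[1, 1] <- 0
  expect_equal(normalize_abundance(mz)[1, 1], 0)
  bad <- s$m; bad[, 1] <- 0
  expect_error(normalize_abundance(bad), "no detected compounds")
})

test_that("volcano classifies planted effects and exclusive compounds", {
  n <- 18L
  fold <- c(rep(4, 5), rep(1 / 4, 5), rep(1, 20))
  s <- sim_matrix(30, n, fold = fold, cv = 0.2, seed = 3)
  m <- rbind(s$m,
             excl_liver = c(stats::rlnorm(n, log(1e6), 0.2), rep(0, n)))
  d <- volcano(m, s$groups)
  expect_equal(nrow(d), 31L)
  expect_equal(d$volcano_class[1:5], rep("up_liver", 5))
  expect_equal(d$volcano_class[6:10], rep("up_muscle", 5))
  expect_true(all(d$p_value[1:10] < 1e-4))
  expect_equal(d$exclusive_to[31], "liver")
  expect_equal(d$volcano_class[31], "up_liver")
  expect_true(is.na(d$p_value[31]))
  # class partition covers all compounds
  expect_equal(sum(d$volcano_class %in% c("up_liver", "up_muscle", "ns")),
               nrow(d))
  # identical group means come out ns with log2fc near 0
  expect_true(all(d$volcano_class[11:30] == "ns" |
                    abs(d$log2fc[11:30]) < 1))
})

test_that("swapping group labels negates fold changes and swaps classes", {
  s <- sim_matrix(40, 10, fold = c(rep(5, 8), rep(1, 32)), seed = 4)
  d1 <- volcano(s$m, s$groups)
  flipped <- ifelse(s$groups == "liver", "muscle", "liver")
  d2 <- volcano(s$m, flipped)
  expect_equal(d2$log2fc, -d1$log2fc, tolerance = 1e-12)
  expect_equal(d2$p_value, d1$p_value, tolerance = 1e-9)
  map <- c(up_liver = "up_muscle", up_muscle = "up_liver", ns = "ns")
  expect_equal(d2$volcano_class, unname(map[d1$volcano_class]))
})

test_that("Welch test is calibrated under the null", {
  s <- sim_matrix(1000, 18, seed = 5)
  d <- volcano(s$m, s$groups)
  typeI <- mean(d$p_value < 0.05)
  expect_gte(typeI, 0.03)
  expect_lte(typeI, 0.07)
})

test_that("PCA separates planted tissue groups and is orthogonal", {
  fold <- c(rep(6, 20), rep(1, 40))
  s <- sim_matrix(60, 18, fold = fold, cv = 0.3, seed = 6)
  p <- pca_samples(normalize_abundance(s$m))
  expect_equal(sum(crossprod(p$scores)[1, 2]), 0, tolerance = 1e-8)
  expect_true(all(diff(p$explained_variance) <= 1e-12))
  expect_true(all(p$explained_variance >= 0 & p$explained_variance <= 1))
  # silhouette of the tissue labels on the first two PCs
  d2 <- as.matrix(dist(p$scores[, 1:2]))
  sil <- vapply(seq_len(nrow(d2)), function(i) {
    own <- s$groups == s$groups[i]; own[i] <- FALSE
    a <- mean(d2[i, own]); b <- mean(d2[i, !own & seq_along(own) != i])
    (b - a) / max(a, b)
  }, 0)
  expect_gt(mean(sil), 0.5)
  # identical columns: no variance to explain
  flat <- matrix(rep(c(1e6, 2e6, 3e6), 6), nrow = 3)
  rownames(flat) <- c("a", "b", "c")
  expect_warning(p0 <- pca_samples(flat), "zero-variance")
  expect_error(pca_samples(s$m[, 1, drop = FALSE]), "at least 2 samples")
})

test_that("clustering recovers planted compound blocks deterministically", {
  fold <- c(rep(6, 10), rep(1 / 6, 10))
  s <- sim_matrix(20, 12, fold = fold, cv = 0.2, seed = 7)
  hm <- hclust_heatmap(normalize_abundance(s$m))
  split2 <- stats::cutree(hm$compound_hclust, k = 2)
  expect_equal(length(unique(split2[1:10])), 1L)
  expect_equal(length(unique(split2[11:20])), 1L)
  expect_false(split2[1] == split2[11])
  # permuting input rows leaves the tree topology unchanged
  perm <- sample(20)
  hm2 <- hclust_heatmap(normalize_abundance(s$m[perm, ]))
  split2b <- stats::cutree(hm2$compound_hclust, k = 2)[rownames(s$m)]
  expect_true(all(table(split2, split2b) %in% c(0, 10)))
  # duplicate rows merge at distance zero
  dup <- s$m[c(1, 1, 5), ]
  rownames(dup) <- c("r1", "r1b", "r5")
  hd <- hclust_heatmap(dup)
  expect_equal(min(hd$compound_hclust$height), 0)
  expect_error(hclust_heatmap(s$m[1, , drop = FALSE]), "relax")
})

test_that("cluster trees export as newick", {
  s <- sim_matrix(8, 4, seed = 8)
  hm <- hclust_heatmap(s$m)
  f <- withr::local_tempfile(fileext = ".nwk")
  write_tree_newick(hm$compound_hclust, f)
  tr <- ape::read.tree(f)
  expect_equal(sort(tr$tip.label), sort(rownames(s$m)))
})
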