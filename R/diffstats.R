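#' Median normalization of a compound-by-sample abundance matrix
#'
#' Scales each sample (column) so that its median over detected compounds
#' (area > 0) equals the global target (the median of the per-sample
#' medians). Zeros stay zero, so detection patterns are preserved.
#'
#' @param mat Numeric matrix, compounds x samples, raw areas (>= 0).
#' @return Normalized matrix of the same shape.
#' @export
normalize_abundance <- function(mat) {
  if (any(mat < 0)) stop("raw abundance matrix must be non-negative")
  med <- apply(mat, 2L, function(x) stats::median(x[x > 0]))
  if (any(is.na(med)))
    stop("sample(s) with no detected compounds: ",
         paste(colnames(mat)[is.na(med)], collapse = ", "))
  target <- stats::median(med)
  sweep(mat, 2L, target / med, `*`)
}

#' Log2 transform with per-compound half-minimum imputation
#'
#' Zeros are replaced, per compound, by half the smallest positive value in
#' that row before taking log2; all-zero rows stay at NA and are handled by
#' the exclusivity rule downstream.
#'
#' @param mat Normalized abundance matrix.
#' @return List with `log2` (matrix) and `imputed` (matrix with zeros
#'   replaced, linear scale).
#' @export
log2_impute <- function(mat) {
  imp <- mat
  for (i in seq_len(nrow(imp))) {
    pos <- imp[i, ] > 0
    if (any(pos) && !all(pos))
      imp[i, !pos] <- min(imp[i, pos]) / 2
  }
  lg <- suppressWarnings(log2(imp))
  lg[!is.finite(lg)] <- NA_real_
  list(log2 = lg, imputed = imp)
}

#' Volcano analysis: per-compound two-group differential test
#'
#' For each compound, computes log2(mean liver / mean muscle) on the
#' normalized (imputed) scale and a two-sided Welch t-test p-value on log2
#' data, then classifies: `up_liver` when p < `p_thr` and log2 FC >=
#' `lfc_thr`; `up_muscle` when p < `p_thr` and log2 FC <= -`lfc_thr`;
#' otherwise `ns`. Compounds detected in no sample of one tissue bypass the
#' test and are reported as exclusive to the other tissue (classified by
#' exclusivity, p-value NA).
#'
#' @param mat Normalized abundance matrix (compounds x samples, raw scale).
#' @param groups Character vector per column, `"liver"` or `"muscle"`.
#' @param p_thr P-value threshold (default 0.05, unadjusted, as in the
#'   source workflow).
#' @param lfc_thr Absolute log2 fold-change threshold (default 1).
#' @param p_adjust Multiple-testing adjustment passed to [stats::p.adjust()]
#'   (default `"none"`).
#' @return Data frame: `compound`, `log2fc`, `p_value`, `volcano_class`,
#'   `exclusive_to`.
#' @export
volcano <- function(mat, groups, p_thr = 0.05, lfc_thr = 1,
                    p_adjust = "none") {
  stopifnot(ncol(mat) == length(groups),
            all(groups %in% c("liver", "muscle")))
  if (sum(groups == "liver") < 2L || sum(groups == "muscle") < 2L)
    stop("need >= 2 samples per group")
  li <- groups == "liver"
  mu <- groups == "muscle"
  tr <- log2_impute(mat)
  res <- lapply(seq_len(nrow(mat)), function(i) {
    x <- mat[i, ]
    excl <- if (all(x[mu] == 0) && any(x[li] > 0)) "liver"
      else if (all(x[li] == 0) && any(x[mu] > 0)) "muscle"
      else NA_character_
    if (!is.na(excl) || all(x == 0)) {
      cls <- if (is.na(excl)) "ns"
        else if (excl == "liver") "up_liver" else "up_muscle"
      return(data.frame(compound = rownames(mat)[i], log2fc = NA_real_,
                        p_value = NA_real_, volcano_class = cls,
                        exclusive_to = excl))
    }
    lfc <- log2(mean(tr$imputed[i, li]) / mean(tr$imputed[i, mu]))
    p <- tryCatch(
      stats::t.test(tr$log2[i, li], tr$log2[i, mu])$p.value,
      error = function(e) NA_real_)
    data.frame(compound = rownames(mat)[i], log2fc = lfc, p_value = p,
               volcano_class = NA_character_, exclusive_to = NA_character_)
  })
  out <- do.call(rbind, res)
  tested <- is.na(out$volcano_class)
  padj <- out$p_value
  padj[tested] <- stats::p.adjust(out$p_value[tested], method = p_adjust)
  out$volcano_class[tested] <- ifelse(
    !is.na(padj[tested]) & padj[tested] < p_thr & out$log2fc[tested] >= lfc_thr,
    "up_liver",
    ifelse(!is.na(padj[tested]) & padj[tested] < p_thr &
             out$log2fc[tested] <= -lfc_thr,
           "up_muscle", "ns"))
  out
}

#' PCA of a log2-normalized abundance matrix
#'
#' Column-centered principal component analysis over samples (samples are
#' observations, compounds variables). Compounds with zero variance are
#' dropped with a warning.
#'
#' @param mat Normalized abundance matrix (raw scale; log2 with imputation
#'   is applied internally).
#' @param n_components Number of components to return.
#' @return List with `scores` (samples x components), `loadings`
#'   (compounds x components) and `explained_variance` (fractions).
#' @export
pca_samples <- function(mat, n_components = 2L) {
  if (ncol(mat) < 2L) stop("need at least 2 samples for PCA")
  lg <- log2_impute(mat)$log2
  lg[is.na(lg)] <- 0
  v <- apply(lg, 1L, stats::var)
  if (any(v == 0)) {
    warning(sprintf("%d zero-variance compound(s)", sum(v == 0)))
    if (any(v > 0)) lg <- lg[v > 0, , drop = FALSE]
  }
  pr <- stats::prcomp(t(lg), center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pr$x))
  ev <- pr$sdev^2
  evf <- if (sum(ev) == 0) rep(0, length(ev)) else ev / sum(ev)
  list(scores = pr$x[, seq_len(k), drop = FALSE],
       loadings = pr$rotation[, seq_len(k), drop = FALSE],
       explained_variance = evf[seq_len(k)])
}

#' Hierarchical clustering of volcano-significant compounds
#'
#' Ward-linkage agglomerative clustering (on squared Euclidean distances,
#' `ward.D2`) of row-standardized log2 abundances, clustering both the
#' significant compounds and the samples. Exports the reordered matrix and
#' both dendrograms; trees can be written as newick via [ape::as.phylo()].
#'
#' @param mat Normalized abundance matrix restricted to the compounds to
#'   cluster (>= 2 rows).
#' @return List with `compound_hclust`, `sample_hclust` (hclust objects),
#'   `scaled` (row-standardized log2 matrix) and `ordered` (matrix reordered
#'   by both trees).
#' @export
hclust_heatmap <- function(mat) {
  if (nrow(mat) < 2L)
    stop("need >= 2 significant compounds to cluster; relax the volcano ",
         "thresholds")
  lg <- log2_impute(mat)$log2
  lg[is.na(lg)] <- 0
  z <- t(scale(t(lg)))
  z[is.na(z)] <- 0
  ch <- stats::hclust(stats::dist(z), method = "ward.D2")
  sh <- stats::hclust(stats::dist(t(z)), method = "ward.D2")
  list(compound_hclust = ch, sample_hclust = sh, scaled = z,
       ordered = z[ch$order, sh$order, drop = FALSE])
}

#' Write an hclust tree as newick
#'
#' @param hc An `hclust` object.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_tree_newick <- function(hc, path) {
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}

#' Build a compound-by-sample abundance matrix from annotated candidates
#'
#' @param candidates Feature table (with area columns).
#' @param samples Sample table; only liver and muscle samples are used.
#' @param ids Optional row labels (defaults to `feature_id`).
#' @return List with `matrix` (compounds x samples) and `groups`.
#' @export
abundance_matrix <- function(candidates, samples, ids = NULL) {
  keep <- samples$group %in% c("liver", "muscle")
  m <- area_matrix(candidates, samples[keep, , drop = FALSE])
  if (!is.null(ids)) rownames(m) <- ids
  list(matrix = m, groups = samples$group[keep])
}
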