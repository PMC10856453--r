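#!/usr/bin/env Rscript
# Step 5 -- liver-versus-muscle differential analysis of the candidates.
#
# Median normalization, volcano classification (Welch test on log2 areas,
# p < 0.05, |log2 FC| >= 1), tissue-exclusivity calls, PCA of samples, and
# Ward hierarchical clustering of the significant compounds. Tables,
# PCA scores and newick trees go to results/.

suppressPackageStartupMessages(library(pfasnta))

samples <- read_sample_table("results/collapsed_samples.tsv")
cand <- read_feature_table("results/candidates.tsv", samples)

ab <- abundance_matrix(cand, samples)
norm <- normalize_abundance(ab$matrix)

d <- volcano(norm, ab$groups)
write.table(d, "results/differential.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("volcano (p < 0.05, |log2FC| >= 1): %d up-liver, %d up-muscle, %d ns\n",
            sum(d$volcano_class == "up_liver"),
            sum(d$volcano_class == "up_muscle"),
            sum(d$volcano_class == "ns")))
cat(sprintf("tissue-exclusive compounds: %d liver-only, %d muscle-only\n",
            sum(d$exclusive_to == "liver", na.rm = TRUE),
            sum(d$exclusive_to == "muscle", na.rm = TRUE)))

p <- pca_samples(norm)
cat(sprintf("PCA: PC1 %.0f%%, PC2 %.0f%% of variance\n",
            100 * p$explained_variance[1], 100 * p$explained_variance[2]))
write.table(data.frame(sample_id = rownames(p$scores), group = ab$groups,
                       p$scores),
            "results/pca_scores.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

sig <- d$compound[d$volcano_class != "ns"]
cat(sprintf("clustering %d significant compounds\n", length(sig)))
hm <- hclust_heatmap(norm[sig, , drop = FALSE])
write.table(data.frame(compound = rownames(hm$ordered), hm$ordered,
                       check.names = FALSE),
            "results/heatmap_matrix.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write_tree_newick(hm$compound_hclust, "results/compound_tree.nwk")
write_tree_newick(hm$sample_hclust, "results/sample_tree.nwk")
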