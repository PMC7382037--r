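#!/usr/bin/env Rscript
# Community statistics over the reconstructed capability matrix: Pearson
# screens between niche features, hydrolytic-vs-syntroph group tests and
# the PCA ordination.

suppressPackageStartupMessages(library(ecothermo))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[1]) else 1L

com <- generate_community(community_spec(seed = seed, noise_sigma = 0.5))
caps <- capacity_matrix(com$genomes, localizations = com$localizations)
feat <- caps$cluster

pear <- pearson_screen(feat[, c("n_aa_hs", "n_aa_ht", "n_gh", "n_protease",
                                "n_fa", "formate_gen")])
utils::write.table(pear, "results/stats_pearson.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat("Pearson screen over capability features:\n")
print(pear, row.names = FALSE, digits = 3)

# hydrolytic niches vs the rest on HS amino-acid pathway counts
guild <- ifelse(feat$cluster_id %in% c("hyd1", "hyd2", "ht", "residual"),
                "hydrolytic", "syntroph_methanogen")
tt <- group_t_test(feat, "n_aa_hs", guild, "hydrolytic")
cat(sprintf("\nhydrolytic guild vs rest, HS AA pathways: t = %.2f, p = %.3g\n",
            tt$t, tt$p))

num_cols <- c("n_protease", "n_gh", "n_lipase", "n_sugar", "n_aa_hs",
              "n_aa_ht", "n_fa", "h2_gen", "formate_gen", "o2_resp",
              "pili", "cytochromes", "rnf", "nfn", "fix")
pca <- suppressMessages(pca_ordinate(feat[, num_cols], phylum_col = guild))
scores <- data.frame(cluster_id = feat$cluster_id, guild = guild,
                     round(pca$scores, 4))
utils::write.table(scores, "results/stats_pca_scores.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat(sprintf("\nPCA: PC1 %.0f%%, PC2 %.0f%% of variance; scores in %s\n",
            100 * pca$var_explained[1], 100 * pca$var_explained[2],
            "results/stats_pca_scores.tsv"))
for (g in names(pca$ellipses)) {
  e <- pca$ellipses[[g]]
  cat(sprintf("  95%% ellipse %s: center (%.2f, %.2f), radii (%.2f, %.2f)\n",
              g, e$center[1], e$center[2], e$radii[1], e$radii[2]))
}
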