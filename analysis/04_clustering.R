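#!/usr/bin/env Rscript
# Stage 4: multivariate structure of the collection.
#
# PCA on mean-imputed dosages and a UPGMA dendrogram on pairwise-complete
# Euclidean genotype distances; PC scores as CSV and the tree as Newick.

library(corepanel)

m <- read_vcf("results/data/genotypes.vcf")
pops <- read_population_csv("results/data/populations.csv")
filt <- filter_loci(m)

pca <- pca_genotypes(filt$matrix)
cat(sprintf("PC1 %.1f%%, PC2 %.1f%% of total variance\n",
            100 * pca$explained[1], 100 * pca$explained[2]))
scores <- data.frame(accession_id = rownames(pca$scores),
                     population = as.character(pops[rownames(pca$scores)]),
                     pca$scores[, 1:5])
write.csv(scores, "results/pc_scores.csv", row.names = FALSE)

tree <- upgma(euclidean_distances(filt$matrix))
write_newick(tree, "results/upgma_all_loci.nwk")
cat("UPGMA tree over", length(tree$phylo$tip.label), "accessions ->",
    "results/upgma_all_loci.nwk\n")
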