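#!/usr/bin/env Rscript

# Build the synthetic study panel: three populations (BCY, BJY, BRs) at
# the observed pairwise divergence profile, with two sweeps private to
# the BJY lineage (one detectable against both other populations) plus a
# synthetic gene annotation along the chromosome. Writes a phased VCF,
# population map, truth BED and GFF3 under results/sim/.

suppressPackageStartupMessages(library(sweepscan))
out <- "results/sim"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
seed <- 20260925L

fmat <- matrix(0, 3, 3, dimnames = rep(list(c("BCY", "BJY", "BRs")), 2))
fmat["BJY", "BRs"] <- fmat["BRs", "BJY"] <- 0.1681
fmat["BCY", "BJY"] <- fmat["BJY", "BCY"] <- 0.1231
fmat["BCY", "BRs"] <- fmat["BRs", "BCY"] <- 0.0946

cfg <- sim_config(
  n_pops = 3, samples_per_pop = c(31L, 32L, 40L), n_snps = 8000L,
  chrom_lengths = c(chr1 = 1.2e7, chr2 = 0.8e7), fst_matrix = fmat,
  maf_floor = 0.05, pop_labels = c("BCY", "BJY", "BRs"),
  merge_sublines = list(BRs = c("BRA", "BRB")),
  sweeps = list(
    sweep_spec("BJY", "chr1", 6e6, 5e4, final_freq = 0.98,
               carrier_fraction = 0.9),
    sweep_spec("BJY", "chr2", 3e6, 5e4, final_freq = 0.96,
               carrier_fraction = 0.85)),
  seed = seed)

panel <- simulate_populations(cfg)
print(panel)

write_vcf(panel, file.path(out, "panel.vcf"),
          popmap_path = file.path(out, "popmap.tsv"))
write_truth_bed(panel$truth, file.path(out, "truth_sweeps.bed"))

# synthetic annotation: 20 kb gene bodies every 100 kb on both chromosomes
gff <- c("##gff-version 3",
         "# synthetic gene models (evenly tiled; not a real annotation)")
gid <- 0
for (chr in names(cfg$chrom_lengths)) {
  starts <- seq(50000, cfg$chrom_lengths[[chr]] - 70000, by = 100000)
  for (s in starts) {
    gid <- gid + 1
    gff <- c(gff, sprintf(
      "%s\tsim\tgene\t%d\t%d\t.\t%s\t.\tID=SYNG%04d;Name=SYNG%04d",
      chr, s, s + 19999, if (gid %% 2) "+" else "-", gid, gid))
  }
}
writeLines(gff, file.path(out, "genes_synthetic.gff3"))

cat("panel written:", nrow(panel$variants), "SNPs,",
    length(unlist(panel$samples)), "samples;",
    nrow(panel$truth), "true sweeps;", gid, "synthetic genes\n")
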