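#!/usr/bin/env Rscript

# Selection-signature scans for the two study comparisons (BJY vs BRs and
# BJY vs BCY): per-SNP FST + Fisher/Bonferroni, normalized XP-EHH, the
# 25 kb composite-likelihood window scan with the top-1% rule, the
# two-tier classification and the seed-and-extend region caller, plus
# gene annotation against the synthetic GFF3. Outputs under
# results/scans/.

suppressPackageStartupMessages(library(sweepscan))
sim <- "results/sim"
out <- "results/scans"

panel <- read_vcf(file.path(sim, "panel.vcf"), file.path(sim, "popmap.tsv"),
                  merge_groups = list(BRs = c("BRA", "BRB")))
genes <- read_gff3(file.path(sim, "genes_synthetic.gff3"))

config <- run_config(
  comparisons = list(list(object = "BJY", reference = "BRs"),
                     list(object = "BJY", reference = "BCY")),
  seed = 20260925L)
run <- run_pipeline(panel, config, genes = genes, out_dir = out)
print(run)

# how well do the called regions line up with the injected sweeps?
truth <- read.table(file.path(sim, "truth_sweeps.bed"), sep = "\t",
                    col.names = c("chrom", "start0", "end"))
truth$start <- truth$start0 + 1L
cat("\nsweep recovery against the truth intervals:\n")
for (cp in run$comparisons) {
  for (k in seq_len(nrow(truth))) {
    ov <- cp$regions$chrom == truth$chrom[k] &
      cp$regions$start <= truth$end[k] & cp$regions$end >= truth$start[k]
    cat(sprintf("  %s / %s:%d-%d: methods {%s}\n", cp$label,
                truth$chrom[k], truth$start[k], truth$end[k],
                paste(sort(unique(cp$regions$method[ov])),
                      collapse = ", ")))
  }
}
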