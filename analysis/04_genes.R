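#!/usr/bin/env Rscript

# Final candidate genes: per-method unique gene sets, the >=2-of-3
# intersection for each comparison, and the genes shared by both
# comparisons (the BJY-specific signature in the study design). Reads
# the per-comparison gene JSONs written by 03_scans.R.

suppressPackageStartupMessages(library(sweepscan))
scans <- "results/scans"
out <- "results/genes"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

labels <- c("BJY-vs-BRs", "BJY-vs-BCY")
finals <- list()
for (lab in labels) {
  gs <- jsonlite::read_json(file.path(scans, paste0(lab, "_genes.json")),
                            simplifyVector = TRUE)
  finals[[lab]] <- gs$final
  cat(sprintf("%s: %s; final (>=2 methods): %d genes\n", lab,
              paste(sprintf("%s %d", names(gs$per_method),
                            lengths(gs$per_method)), collapse = ", "),
              length(gs$final)))
}

shared <- cross_comparison_overlap(finals[[1]], finals[[2]])
cat(sprintf("\n%d final genes shared by both comparisons:\n",
            length(shared)))
if (length(shared)) cat(" ", paste(shared, collapse = ", "), "\n")

writeLines(c("# final candidate genes shared by both comparisons",
             shared), file.path(out, "shared_final_genes.txt"))
jsonlite::write_json(
  list(per_comparison = finals, shared = shared),
  file.path(out, "final_gene_sets.json"), auto_unbox = TRUE, pretty = TRUE)
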