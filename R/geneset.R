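#' Annotate selected regions with overlapping genes
#'
#' A gene is assigned to a region iff its gene body `[start, end]` overlaps
#' the region interval by at least one bp (both 1-based inclusive); no
#' promoter/flank extension unless `flank > 0`. Strand is ignored.
#'
#' @param regions data.frame with `chrom`, `start`, `end`.
#' @param genes data.frame from [read_gff3()].
#' @param flank Bp added to each side of every region (default 0).
#' @return `regions` with list-columns `gene_ids` and `gene_names`.
#' @export
annotate_regions <- function(regions, genes, flank = 0) {
  if (nrow(regions) == 0) {
    regions$gene_ids <- list(); regions$gene_names <- list()
    return(regions)
  }
  if (length(intersect(unique(regions$chrom), unique(genes$chrom))) == 0 &&
      nrow(genes) > 0)
    stop("no shared chromosome names between regions (e.g. ",
         paste(utils::head(unique(regions$chrom), 3), collapse = ","),
         ") and annotation (e.g. ",
         paste(utils::head(unique(genes$chrom), 3), collapse = ","), ")")
  gene_ids <- vector("list", nrow(regions))
  gene_names <- vector("list", nrow(regions))
  for (chr in unique(regions$chrom)) {
    ri <- which(regions$chrom == chr)
    gi <- which(genes$chrom == chr)
    if (length(gi) == 0) {
      gene_ids[ri] <- list(character(0))
      gene_names[ri] <- list(character(0))
      next
    }
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(regions$start[ri] - flank, regions$end[ri] + flank),
      IRanges::IRanges(genes$start[gi], genes$end[gi]))
    for (k in seq_along(ri)) {
      g <- gi[S4Vectors::subjectHits(hits)[S4Vectors::queryHits(hits) == k]]
      gene_ids[[ri[k]]] <- genes$gene_id[g]
      gene_names[[ri[k]]] <- genes$name[g]
    }
  }
  regions$gene_ids <- gene_ids
  regions$gene_names <- gene_names
  regions
}

#' Per-method gene sets and the >=2-of-3 final candidates
#'
#' @param region_sets Named list (by method label, e.g. `fst`, `xpehh`,
#'   `xpclr`) of annotated region data.frames from [annotate_regions()].
#' @param comparison Comparison label stored on the result.
#' @return List of class `method_gene_sets`: `comparison`, `per_method`
#'   (named list of unique gene-id character vectors), `final` (genes in
#'   at least two method sets).
#' @export
method_gene_sets <- function(region_sets, comparison = "comparison") {
  per_method <- lapply(region_sets, function(r)
    sort(unique(unlist(r$gene_ids, use.names = FALSE))))
  all_genes <- unique(unlist(per_method, use.names = FALSE))
  support <- vapply(all_genes, function(g)
    sum(vapply(per_method, function(s) g %in% s, TRUE)), integer(1))
  structure(list(comparison = comparison, per_method = per_method,
                 final = sort(all_genes[support >= 2L])),
            class = "method_gene_sets")
}

#' @export
print.method_gene_sets <- function(x, ...) {
  cat("method_gene_sets [", x$comparison, "]\n", sep = "")
  for (m in names(x$per_method))
    cat(sprintf("  %-6s %d unique gene(s)\n", m, length(x$per_method[[m]])))
  cat("  final (>= 2 methods):", length(x$final), "gene(s)\n")
  invisible(x)
}

#' Genes shared by the final candidate sets of two comparisons
#'
#' @param a,b `method_gene_sets` objects or plain character vectors.
#' @return Sorted character vector of shared gene ids.
#' @export
cross_comparison_overlap <- function(a, b) {
  ga <- if (inherits(a, "method_gene_sets")) a$final else a
  gb <- if (inherits(b, "method_gene_sets")) b$final else b
  sort(intersect(ga, gb))
}
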