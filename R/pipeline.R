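#' Pipeline configuration
#'
#' Collects every tunable of the scan with its default: extreme tier = top
#' 0.01% FST with corrected p < 0.01, or top 0.1% |XP-EHH|; significant
#' tier = FST >= 0.4 with corrected p < 0.01, or |XP-EHH| >= 1; XP-CLR
#' window 25,000 bp, 500-SNP cap, LD cutoff 0.95, top 1% of windows; EHH
#' cutoff 0.05 and maximum gap 200 kb. All thresholds are echoed into
#' output file headers.
#'
#' @param comparisons List of lists with `object`, `reference` and
#'   optionally `label`; the object population is the XP-EHH/XP-CLR
#'   numerator.
#' @param merge_groups Passed to [read_vcf()] (e.g.
#'   `list(BRs = c("BRA", "BRB"))`).
#' @param fst_extreme_q,xpehh_extreme_q,fst_sig,p_sig,xpehh_sig Tier
#'   thresholds.
#' @param window,max_snps,ld_cutoff,top_fraction XP-CLR parameters.
#' @param ehh_cutoff,max_gap EHH parameters.
#' @param maf_min,hwe_alpha,missing_max QC filters applied before scanning
#'   (defaults keep every complete polymorphic site).
#' @param seed RNG seed recorded in the manifest (scanning itself is
#'   deterministic).
#' @return List of class `run_config`.
#' @export
run_config <- function(comparisons,
                       merge_groups = NULL,
                       fst_extreme_q = 1e-4, xpehh_extreme_q = 1e-3,
                       fst_sig = 0.4, p_sig = 0.01, xpehh_sig = 1,
                       window = 25000L, max_snps = 500L, ld_cutoff = 0.95,
                       top_fraction = 0.01,
                       ehh_cutoff = 0.05, max_gap = 2e5,
                       maf_min = 0, hwe_alpha = 0, missing_max = 1,
                       seed = 1L) {
  stopifnot(length(comparisons) >= 1)
  comparisons <- lapply(comparisons, function(cp) {
    stopifnot(!is.null(cp$object), !is.null(cp$reference))
    if (is.null(cp$label))
      cp$label <- paste0(cp$object, "-vs-", cp$reference)
    cp
  })
  structure(as.list(environment()), class = "run_config")
}

config_meta <- function(config) {
  keep <- c("fst_extreme_q", "xpehh_extreme_q", "fst_sig", "p_sig",
            "xpehh_sig", "window", "max_snps", "ld_cutoff", "top_fraction",
            "ehh_cutoff", "max_gap", "maf_min", "hwe_alpha", "missing_max",
            "seed")
  unlist(lapply(config[keep], format, scientific = FALSE))
}

#' Run the full selection-signature pipeline on a panel
#'
#' For each configured comparison: QC filters, per-SNP Weir-Cockerham FST
#' with Fisher/Bonferroni p-values, XP-EHH scan with genome-wide
#' normalization, windowed composite likelihood scan with the top-fraction
#' rule, tier classification, region growing, and (when an annotation is
#' given) gene assignment and the >=2-of-3-methods candidate set. All
#' outputs are written as TSV/BED under `out_dir` with thresholds echoed
#' into their headers; the result is also returned.
#'
#' @param panel A phased `hap_panel` (from [simulate_populations()] or
#'   [read_vcf()]).
#' @param config A [run_config()].
#' @param genes Optional gene table from [read_gff3()].
#' @param out_dir Optional output directory.
#' @return List of class `sweepscan_run`: `config`, `qc_report`,
#'   `pairwise_fst`, `diversity`, and per-comparison entries with
#'   `snp_scores`, `windows`, `regions` (combined data.frame), and
#'   `gene_sets` (when annotated).
#' @export
run_pipeline <- function(panel, config, genes = NULL, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  meta <- config_meta(config)

  filt <- apply_filters(panel, maf_min = config$maf_min,
                        hwe_alpha = config$hwe_alpha,
                        missing_max = config$missing_max)
  panel <- filt$panel
  pops <- names(panel$haplotypes)
  genotypes <- lapply(pops, function(p) panel_genotypes(panel, p))
  names(genotypes) <- pops

  # genome-wide pairwise FST + per-population diversity
  pairs <- if (length(pops) >= 2) utils::combn(pops, 2, simplify = FALSE)
           else list()
  pairwise_fst <- data.frame(
    pop_a = vapply(pairs, `[`, "", 1), pop_b = vapply(pairs, `[`, "", 2),
    fst = vapply(pairs, function(pr)
      genomewide_fst(site_counts(genotypes[pr])), numeric(1)),
    stringsAsFactors = FALSE)
  diversity <- data.frame(
    population = pops,
    n = vapply(genotypes, nrow, integer(1)),
    het_obs = vapply(genotypes, function(G)
      observed_heterozygosity(G)$mean, numeric(1)),
    gene_diversity = vapply(genotypes, function(G)
      gene_diversity(G)$corrected, numeric(1)),
    stringsAsFactors = FALSE)

  result <- list(config = config, qc_report = filt$report,
                 pairwise_fst = pairwise_fst, diversity = diversity,
                 comparisons = list())

  for (cp in config$comparisons) {
    cnt <- site_counts(genotypes[c(cp$object, cp$reference)])
    fst <- wc_fst_site(cnt)
    ref_alt <- function(pop) {
      n2 <- 2 * cnt$n[pop, ]
      alt <- 2 * cnt$hom_alt[pop, ] + cnt$het[pop, ]
      list(ref = n2 - alt, alt = alt)
    }
    a <- ref_alt(cp$object); b <- ref_alt(cp$reference)
    p_raw <- fisher_allele_test(a$ref, a$alt, b$ref, b$alt)
    p_adj <- bonferroni(p_raw, m = sum(!is.na(p_raw)))

    xe <- xpehh_scan(panel, cp$object, cp$reference,
                     cutoff = config$ehh_cutoff, max_gap = config$max_gap)

    snp_scores <- data.frame(
      chrom = panel$variants$chrom, pos = panel$variants$pos,
      fst = fst$theta, fisher_p = p_raw, p_adj = p_adj,
      ihh_a = xe$ihh_a, ihh_b = xe$ihh_b,
      xpehh_raw = xe$xpehh_raw, xpehh_norm = xe$xpehh_norm,
      stringsAsFactors = FALSE)
    snp_scores$tier_fst <- classify_snps(
      snp_scores, "fst", extreme_quantile = config$fst_extreme_q,
      fst_sig = config$fst_sig, p_sig = config$p_sig)
    snp_scores$tier_xpehh <- classify_snps(
      snp_scores, "xpehh", extreme_quantile = config$xpehh_extreme_q,
      xpehh_sig = config$xpehh_sig)

    windows <- xpclr_scan(panel, cp$object, cp$reference,
                          window = config$window,
                          max_snps = config$max_snps,
                          ld_cutoff = config$ld_cutoff)
    called <- call_top_windows(windows, config$top_fraction)

    regions <- rbind(
      grow_regions(snp_scores$chrom, snp_scores$pos, snp_scores$tier_fst,
                   method = "fst")[, c("chrom", "start", "end", "method")],
      grow_regions(snp_scores$chrom, snp_scores$pos,
                   snp_scores$tier_xpehh,
                   method = "xpehh")[, c("chrom", "start", "end", "method")],
      regions_from_windows(called)[, c("chrom", "start", "end", "method")])
    rownames(regions) <- NULL

    entry <- list(label = cp$label, object = cp$object,
                  reference = cp$reference, snp_scores = snp_scores,
                  windows = windows, called_windows = called,
                  regions = regions)

    if (!is.null(genes)) {
      ann <- lapply(split(regions, regions$method), annotate_regions,
                    genes = genes)
      entry$gene_sets <- method_gene_sets(ann, comparison = cp$label)
      entry$annotated_regions <- ann
    }

    if (!is.null(out_dir)) {
      base <- file.path(out_dir, cp$label)
      write_score_table(snp_scores, paste0(base, "_snp_scores.tsv"),
                        meta = c(comparison = cp$label, meta))
      write_score_table(
        data.frame(chrom = windows$chrom, pos = windows$start, windows[
          , c("end", "n_snps", "xpclr_raw", "xpclr_norm")]),
        paste0(base, "_windows.tsv"), meta = c(comparison = cp$label, meta))
      write_regions_bed(regions, paste0(base, "_regions.bed"))
      if (!is.null(genes))
        jsonlite::write_json(
          list(comparison = cp$label,
               per_method = entry$gene_sets$per_method,
               final = entry$gene_sets$final),
          paste0(base, "_genes.json"), auto_unbox = TRUE, pretty = TRUE)
    }
    result$comparisons[[cp$label]] <- entry
  }
  class(result) <- "sweepscan_run"
  if (!is.null(out_dir)) {
    writeLines(pipeline_report(result), file.path(out_dir, "report.md"))
  }
  result
}

#' Human-readable run summary
#'
#' Counts per tier, method and comparison, the pairwise FST table and the
#' per-population diversity table; every number is re-derivable from the
#' TSV outputs.
#'
#' @param run A `sweepscan_run` from [run_pipeline()].
#' @return Character vector of markdown lines.
#' @export
pipeline_report <- function(run) {
  lines <- c("# sweepscan run report", "",
             "## Pairwise genome-wide FST")
  if (nrow(run$pairwise_fst) == 0) lines <- c(lines, "0 population pairs")
  lines <- c(lines, sprintf("- %s vs %s: %.4f", run$pairwise_fst$pop_a,
                            run$pairwise_fst$pop_b, run$pairwise_fst$fst),
             "", "## Diversity",
             sprintf("- %s (n=%d): observed het %.4f, gene diversity %.4f",
                     run$diversity$population, run$diversity$n,
                     run$diversity$het_obs, run$diversity$gene_diversity))
  for (cp in run$comparisons) {
    lines <- c(lines, "", paste0("## Comparison ", cp$label))
    for (m in c("fst", "xpehh")) {
      tier <- cp$snp_scores[[paste0("tier_", m)]]
      lines <- c(lines, sprintf(
        "- %s tiers: %d extreme, %d significant, %d nonsignificant",
        m, sum(tier == "E"), sum(tier == "S"), sum(tier == "N")))
    }
    for (m in c("fst", "xpehh", "xpclr")) {
      n <- sum(cp$regions$method == m)
      lines <- c(lines, sprintf("- %s: %d region(s)", m, n))
    }
    if (!is.null(cp$gene_sets)) {
      gs <- cp$gene_sets
      lines <- c(lines, sprintf(
        "- genes: %s; final (>=2 methods): %d",
        paste(sprintf("%s %d", names(gs$per_method),
                      lengths(gs$per_method)), collapse = ", "),
        length(gs$final)))
    }
  }
  lines
}

#' @export
print.sweepscan_run <- function(x, ...) {
  cat(pipeline_report(x), sep = "\n")
  invisible(x)
}
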