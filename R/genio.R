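#' Write a phased panel as VCF v4.2 plus a population map
#'
#' @param panel A `hap_panel` from [simulate_populations()] or [read_vcf()].
#' @param path Output VCF path (plain text).
#' @param popmap_path Optional path for a two-column TSV population map
#'   (`sample_id`, `population`). When the panel's config carries
#'   `merge_sublines`, samples of a merged population are split
#'   alternately across its sub-line labels.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(panel, path, popmap_path = NULL) {
  v <- panel$variants
  sample_ids <- unlist(panel$samples, use.names = FALSE)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=sweepscan",
    sprintf("##contig=<ID=%s>", unique(v$chrom)),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_ids), collapse = "\t"))

  sep <- if (isTRUE(panel$phased)) "|" else "/"
  gt_cols <- lapply(panel$haplotypes, function(H) {
    n <- nrow(H) / 2L
    a1 <- H[2L * seq_len(n) - 1L, , drop = FALSE]
    a2 <- H[2L * seq_len(n), , drop = FALSE]
    g <- matrix(paste0(ifelse(is.na(a1), ".", a1), sep,
                       ifelse(is.na(a2), ".", a2)),
                nrow = n)
    g
  })
  gt <- do.call(rbind, gt_cols)  # samples x sites
  body <- paste(v$chrom, v$pos, ".", v$ref, v$alt, ".", "PASS", ".", "GT",
                apply(gt, 2, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)

  if (!is.null(popmap_path)) {
    pop_of <- rep(names(panel$samples),
                  vapply(panel$samples, length, 1L))
    merges <- panel$config$merge_sublines
    if (!is.null(merges)) {
      for (merged in names(merges)) {
        idx <- which(pop_of == merged)
        subs <- merges[[merged]]
        pop_of[idx] <- subs[((seq_along(idx) - 1L) %% length(subs)) + 1L]
      }
    }
    write.table(data.frame(sample_id = sample_ids, population = pop_of),
                popmap_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a sample-to-population map
#'
#' @param path TSV with columns `sample_id` and `population`.
#' @return Named character vector: population label per sample id.
#' @export
read_popmap <- function(path) {
  pm <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE, comment.char = "#")
  if (!all(c("sample_id", "population") %in% names(pm)))
    stop("population map must have columns sample_id and population")
  if (anyDuplicated(pm$sample_id))
    stop("duplicate sample ids in population map")
  setNames(as.character(pm$population), as.character(pm$sample_id))
}

#' Read a multi-sample VCF into per-population haplotypes
#'
#' Keeps biallelic SNP records only (multiallelic and non-SNP records are
#' dropped with a logged count). Positions are 1-based as in the VCF; sites
#' are sorted by chromosome (natural-numeric where chromosome names permit,
#' else lexicographic) then position.
#'
#' @param path VCF path (vcfR handles plain or gzipped text).
#' @param popmap Named character vector from [read_popmap()], or a path to
#'   the TSV. Every VCF sample must be mapped.
#' @param merge_groups Optional named list, e.g.
#'   `list(BRs = c("BRA", "BRB"))`, relabelling sub-lines into one
#'   population before splitting.
#' @param allow_unphased Accept unphased ("/") genotypes; the returned
#'   panel is then flagged `phased = FALSE` and haplotype-based statistics
#'   refuse to run on it.
#' @param chrom_include Optional character vector restricting to these
#'   chromosomes.
#' @return A `hap_panel` (see [simulate_populations()]); `truth` is `NULL`.
#' @export
read_vcf <- function(path, popmap, merge_groups = NULL,
                     allow_unphased = FALSE, chrom_include = NULL) {
  if (is.character(popmap) && length(popmap) == 1L && file.exists(popmap))
    popmap <- read_popmap(popmap)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  chrom <- fix[, "CHROM"]; pos <- as.integer(fix[, "POS"])
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]

  keep <- !is.na(alt) & !grepl(",", alt) &
    nchar(ref) == 1L & nchar(alt) == 1L &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  if (!is.null(chrom_include)) keep <- keep & chrom %in% chrom_include
  n_drop <- sum(!keep)
  if (n_drop > 0)
    message("read_vcf: dropped ", n_drop,
            " non-biallelic-SNP (or excluded-chromosome) record(s)")
  if (!any(keep)) stop("no biallelic SNP records retained from ", path)

  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1,
                                     dimnames = list(NULL, names(gt)))
  gt <- gt[keep, , drop = FALSE]
  chrom <- chrom[keep]; pos <- pos[keep]; ref <- ref[keep]; alt <- alt[keep]

  samples <- colnames(gt)
  unknown <- setdiff(samples, names(popmap))
  if (length(unknown) > 0)
    stop("sample(s) missing from population map: ",
         paste(unknown, collapse = ", "))

  pop_of <- popmap[samples]
  if (!is.null(merge_groups)) {
    for (merged in names(merge_groups))
      pop_of[pop_of %in% merge_groups[[merged]]] <- merged
  }
  if (length(unique(pop_of)) < 1L) stop("no populations after mapping")

  unphased <- any(grepl("/", gt[!is.na(gt)], fixed = TRUE))
  if (unphased && !allow_unphased)
    stop("VCF contains unphased genotypes; pass allow_unphased = TRUE ",
         "to read them (haplotype statistics will refuse to run)")

  # sort: natural-numeric chromosome order where names allow, then position
  o <- order(chrom_rank(chrom), pos)
  gt <- gt[o, , drop = FALSE]
  variants <- data.frame(chrom = chrom[o], pos = pos[o],
                         ref = ref[o], alt = alt[o],
                         stringsAsFactors = FALSE)
  if (anyDuplicated(variants[, c("chrom", "pos")]))
    stop("duplicate chrom/pos records in ", path)

  a1 <- suppressWarnings(
    matrix(as.integer(substr(gt, 1L, 1L)), nrow = nrow(gt)))
  a2 <- suppressWarnings(
    matrix(as.integer(substr(gt, 3L, 3L)), nrow = nrow(gt)))
  if (any(stats::na.omit(c(a1, a2)) > 1L))
    stop("genotype alleles other than 0/1 found despite biallelic filter")

  haplotypes <- list(); sample_sets <- list()
  for (pop in unique(pop_of)) {
    cols <- which(pop_of == pop)
    H <- matrix(NA_integer_, 2L * length(cols), nrow(variants))
    H[2L * seq_along(cols) - 1L, ] <- t(a1[, cols, drop = FALSE])
    H[2L * seq_along(cols), ] <- t(a2[, cols, drop = FALSE])
    rownames(H) <- paste0(rep(samples[cols], each = 2), "_", c(1L, 2L))
    haplotypes[[pop]] <- H
    sample_sets[[pop]] <- samples[cols]
  }

  structure(list(variants = variants, haplotypes = haplotypes,
                 samples = sample_sets, phased = !unphased, truth = NULL,
                 pop_freq = NULL, config = NULL),
            class = "hap_panel")
}

# ordering key: numeric part of chr names when all have one, else the name
chrom_rank <- function(chrom) {
  num <- suppressWarnings(as.numeric(sub("^[Cc]hr", "", chrom)))
  if (!anyNA(num)) num else chrom
}

#' Read gene models from GFF3
#'
#' Keeps `gene`-type features only. The display name comes from the `Name`
#' attribute, then `gene_id`, then `ID`; the stable id from `ID` (falling
#' back to `gene_id`). Coordinates stay 1-based inclusive as in GFF3.
#'
#' @param path GFF3 path.
#' @return data.frame with `gene_id`, `name`, `chrom`, `start`, `end`,
#'   `strand`.
#' @export
read_gff3 <- function(path) {
  g <- ape::read.gff(path, na.strings = c(".", "?"), GFF3 = TRUE)
  g <- g[g$type == "gene", , drop = FALSE]
  attr_get <- function(attrs, key) {
    m <- regmatches(attrs, regexec(paste0("(?:^|;)", key, "=([^;]+)"), attrs))
    vapply(m, function(x) if (length(x) == 2) x[2] else NA_character_,
           character(1))
  }
  ids <- attr_get(g$attributes, "ID")
  gene_ids <- attr_get(g$attributes, "gene_id")
  names_ <- attr_get(g$attributes, "Name")
  bad <- is.na(ids) & is.na(gene_ids)
  if (any(bad)) {
    message("read_gff3: skipped ", sum(bad),
            " gene record(s) with malformed attributes")
    g <- g[!bad, , drop = FALSE]
    ids <- ids[!bad]; gene_ids <- gene_ids[!bad]; names_ <- names_[!bad]
  }
  id <- ifelse(is.na(ids), gene_ids, ids)
  name <- ifelse(!is.na(names_), names_,
                 ifelse(!is.na(gene_ids), gene_ids, ids))
  strand <- as.character(g$strand)
  strand[is.na(strand)] <- "."
  data.frame(gene_id = id, name = name, chrom = as.character(g$seqid),
             start = as.integer(g$start), end = as.integer(g$end),
             strand = strand, stringsAsFactors = FALSE)
}

#' Write / read a per-SNP score table (TSV with "#" metadata header)
#'
#' Columns `chrom` and `pos` are required; any per-statistic columns follow
#' (missing values encoded `NA`). Numeric values round-trip at 10
#' significant digits. Metadata lines ("#key=value") record the parameters
#' used; chromosome ordering in the file is natural-numeric where names
#' permit, else lexicographic, and is recorded in the header.
#'
#' @param scores data.frame with at least `chrom` and `pos`.
#' @param path Output path.
#' @param meta Named character/numeric vector written as "#name=value".
#' @return `path`, invisibly.
#' @export
write_score_table <- function(scores, path, meta = NULL) {
  stopifnot(all(c("chrom", "pos") %in% names(scores)))
  o <- order(chrom_rank(scores$chrom), scores$pos)
  scores <- scores[o, , drop = FALSE]
  num <- vapply(scores, is.numeric, TRUE) & names(scores) != "pos"
  scores[num] <- lapply(scores[num], signif, digits = 10)
  hdr <- c(sprintf("#sweepscan_score_table=%s",
                   as.character(utils::packageVersion("sweepscan"))),
           "#chrom_order=natural-numeric_else_lexicographic",
           if (!is.null(meta)) sprintf("#%s=%s", names(meta),
                                       as.character(meta)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  write.table(scores, con, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' @rdname write_score_table
#' @param required Column names that must be present when reading.
#' @export
read_score_table <- function(path, required = c("chrom", "pos")) {
  x <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                  stringsAsFactors = FALSE, na.strings = "NA",
                  check.names = FALSE)
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0)
    stop("score table ", path, " lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  x
}

#' Write selected regions as BED (0-based half-open)
#'
#' @param regions data.frame with `chrom`, `start`, `end` (1-based
#'   inclusive) and optionally `method`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_regions_bed <- function(regions, path) {
  lines <- "# selected regions (BED, 0-based half-open)"
  if (nrow(regions) > 0) {
    o <- order(chrom_rank(regions$chrom), regions$start)
    regions <- regions[o, , drop = FALSE]
    name <- if ("method" %in% names(regions)) regions$method else "."
    lines <- c(lines, sprintf("%s\t%d\t%d\t%s", regions$chrom,
                              as.integer(regions$start) - 1L,
                              as.integer(regions$end), name))
  }
  writeLines(lines, path)
  invisible(path)
}
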