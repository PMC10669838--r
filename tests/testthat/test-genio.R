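test_that("VCF round-trip preserves genotypes and sites exactly", {
  cfg <- sim_config(n_pops = 2, samples_per_pop = 5, n_snps = 300,
                    chrom_lengths = c(chr1 = 5e5, chr2 = 5e5), seed = 9)
  pan <- simulate_populations(cfg)
  vcf <- tempfile(fileext = ".vcf"); pm <- tempfile(fileext = ".tsv")
  write_vcf(pan, vcf, popmap_path = pm)
  back <- read_vcf(vcf, pm)
  expect_identical(back$variants$pos, pan$variants$pos)
  expect_identical(back$variants$chrom, pan$variants$chrom)
  for (p in names(pan$haplotypes))
    expect_equal(unname(back$haplotypes[[p]]),
                 unname(pan$haplotypes[[p]]))
  # byte-identical GT after a second write
  vcf2 <- tempfile(fileext = ".vcf")
  write_vcf(back, vcf2)
  expect_identical(readLines(vcf), readLines(vcf2))
})

test_that("multiallelic and non-SNP records are dropped with a count", {
  f <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2\ts3",
    "chr1\t100\t.\tA\tT\t.\tPASS\t.\tGT\t0|1\t0|0\t1|1",
    "chr1\t200\t.\tA\tT,G\t.\tPASS\t.\tGT\t0|1\t0|2\t1|1",
    "chr1\t300\t.\tAT\tA\t.\tPASS\t.\tGT\t0|1\t0|0\t1|1",
    "chr1\t400\t.\tC\tG\t.\tPASS\t.\tGT\t0|0\t0|1\t1|1",
    "chr1\t500\t.\tG\tA\t.\tPASS\t.\tGT\t1|1\t0|0\t0|1"), f)
  popmap <- c(s1 = "A", s2 = "A", s3 = "B")
  expect_message(pan <- read_vcf(f, popmap), "dropped 2")
  expect_equal(nrow(pan$variants), 3)
  expect_equal(pan$variants$pos, c(100L, 400L, 500L))
  expect_equal(ncol(pan$haplotypes$A), 3)
})

test_that("merge_groups relabels sub-lines into one population", {
  cfg <- sim_config(n_pops = 3, samples_per_pop = 4, n_snps = 100,
                    pop_labels = c("BCY", "BRA", "BRB"), seed = 2)
  pan <- simulate_populations(cfg)
  vcf <- tempfile(fileext = ".vcf"); pm <- tempfile(fileext = ".tsv")
  write_vcf(pan, vcf, popmap_path = pm)
  merged <- read_vcf(vcf, pm, merge_groups = list(BRs = c("BRA", "BRB")))
  expect_setequal(names(merged$haplotypes), c("BCY", "BRs"))
  expect_equal(length(merged$samples$BRs), 8)
  expect_equal(length(merged$haplotypes), length(pan$haplotypes) - 1)
})

test_that("unknown samples and unphased input are typed failures", {
  cfg <- sim_config(n_pops = 1, samples_per_pop = 3, n_snps = 50, seed = 4)
  pan <- simulate_populations(cfg)
  vcf <- tempfile(fileext = ".vcf")
  write_vcf(pan, vcf)
  expect_error(read_vcf(vcf, c(pop1_01 = "A")), "missing from population map")

  unph <- sub("0\\|1", "0/1", readLines(vcf))
  f2 <- tempfile(fileext = ".vcf")
  writeLines(unph, f2)
  pm <- setNames(rep("A", 3), pan$samples$pop1)
  expect_error(read_vcf(f2, pm), "unphased")
  pan2 <- read_vcf(f2, pm, allow_unphased = TRUE)
  expect_false(pan2$phased)
  expect_error(xpehh_scan(pan2, "A", "A"), "unphased")
})

test_that("GFF3 reader keeps gene rows and applies the name fallback", {
  genes <- data.frame(
    gene_id = c("G1", "G2"), name = c("ALPHA", NA),
    chrom = "chr1", start = c(100L, 1000L), end = c(200L, 2000L),
    strand = c("+", "-"), stringsAsFactors = FALSE)
  path <- write_toy_gff3(genes)
  got <- read_gff3(path)
  expect_equal(nrow(got), 2)  # mRNA rows skipped
  expect_equal(got$name, c("ALPHA", "G2"))  # fallback to ID
  expect_equal(got$start, c(100L, 1000L))
  expect_equal(got$end, c(200L, 2000L))
  expect_equal(got$strand, c("+", "-"))
})

test_that("1-based inclusive boundary overlap is honoured end-to-end", {
  genes <- read_gff3(write_toy_gff3(data.frame(
    gene_id = "G1", name = "A", chrom = "chr1", start = 100L, end = 200L,
    strand = "+", stringsAsFactors = FALSE)))
  touching <- data.frame(chrom = "chr1", start = 200L, end = 300L)
  missed <- data.frame(chrom = "chr1", start = 201L, end = 300L)
  expect_equal(annotate_regions(touching, genes)$gene_ids[[1]], "G1")
  expect_length(annotate_regions(missed, genes)$gene_ids[[1]], 0)
})

test_that("score tables round-trip with NA preservation and stable sort", {
  x <- data.frame(chrom = c("chr10", "chr2", "chr1"),
                  pos = c(5L, 10L, 7L),
                  fst = c(0.123456789012, NA, 1 / 3),
                  tier = c("E", "N", "S"), stringsAsFactors = FALSE)
  f <- tempfile(fileext = ".tsv")
  write_score_table(x, f, meta = c(object = "popA"))
  back <- read_score_table(f)
  # natural-numeric chromosome order: chr1, chr2, chr10
  expect_equal(back$chrom, c("chr1", "chr2", "chr10"))
  expect_equal(back$pos, c(7L, 10L, 5L))
  expect_true(is.na(back$fst[2]))
  expect_equal(back$fst[c(1, 3)], signif(c(1 / 3, 0.123456789012), 10))
  expect_error(read_score_table(f, required = c("chrom", "pos", "zzz")),
               "zzz")
  # shuffled input sorts identically (sort oracle)
  perm <- x[sample(nrow(x)), ]
  f2 <- tempfile(fileext = ".tsv")
  write_score_table(perm, f2)
  expect_equal(read_score_table(f2), back)
})
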