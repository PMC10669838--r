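geno_from_counts <- function(hom_ref, het, hom_alt) {
  c(rep(0L, hom_ref), rep(1L, het), rep(2L, hom_alt))
}

test_that("site counts match a brute-force tally under missingness", {
  set.seed(31)
  g1 <- matrix(sample(c(0:2, NA), 50 * 20, TRUE, prob = c(.3, .3, .3, .1)),
               50, 20)
  g2 <- matrix(sample(c(0:2, NA), 40 * 20, TRUE, prob = c(.25, .5, .2, .05)),
               40, 20)
  cnt <- site_counts(list(p1 = g1, p2 = g2))
  for (j in c(1, 7, 20)) {
    expect_equal(unname(cnt$n[1, j]), sum(!is.na(g1[, j])))
    expect_equal(unname(cnt$het[2, j]), sum(g2[, j] == 1, na.rm = TRUE))
    expect_equal(unname(cnt$hom_ref[1, j] + cnt$het[1, j] +
                          cnt$hom_alt[1, j]), unname(cnt$n[1, j]))
    expect_equal(unname(cnt$p[2, j]),
                 sum(g2[, j], na.rm = TRUE) / (2 * sum(!is.na(g2[, j]))))
  }
  # population with all calls missing at a site -> unusable
  g2[, 3] <- NA
  cnt <- site_counts(list(p1 = g1, p2 = g2))
  expect_false(cnt$usable[3])
})

test_that("per-site Weir-Cockerham theta matches the independent
           transcription on 100 random sites", {
  set.seed(17)
  for (rep_i in 1:100) {
    n1 <- sample(5:40, 1); n2 <- sample(5:40, 1)
    g1 <- sample(0:2, n1, TRUE, prob = runif(3))
    g2 <- sample(0:2, n2, TRUE, prob = runif(3))
    cnt <- site_counts(list(a = matrix(g1, ncol = 1),
                            b = matrix(g2, ncol = 1)))
    got <- wc_fst_site(cnt)$theta
    want <- wc_oracle_site(list(g1, g2))
    if (is.na(want)) expect_true(is.na(got)) else
      expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("theta is 1 on fixed differences and NA when monomorphic", {
  fixed <- site_counts(list(a = matrix(rep(0L, 30), ncol = 1),
                            b = matrix(rep(2L, 30), ncol = 1)))
  expect_equal(wc_fst_site(fixed)$theta, 1)
  mono <- site_counts(list(a = matrix(rep(0L, 30), ncol = 1),
                           b = matrix(rep(0L, 30), ncol = 1)))
  expect_true(is.na(wc_fst_site(mono)$theta))
  single <- site_counts(list(a = matrix(c(0L, 1L, 2L), ncol = 1),
                             b = matrix(NA_integer_, 3, 1)))
  expect_true(is.na(wc_fst_site(single)$theta))
})

test_that("three-population theta matches the oracle too", {
  set.seed(23)
  for (rep_i in 1:20) {
    gs <- lapply(1:3, function(i)
      sample(0:2, sample(8:25, 1), TRUE, prob = runif(3)))
    cnt <- site_counts(lapply(setNames(gs, c("a", "b", "c")),
                              matrix, ncol = 1))
    got <- wc_fst_site(cnt)$theta
    want <- wc_oracle_site(gs)
    if (is.na(want)) expect_true(is.na(got)) else
      expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("genome-wide FST is the ratio of summed components", {
  set.seed(41)
  g1 <- matrix(sample(0:2, 30 * 1000, TRUE), 30, 1000)
  g2 <- matrix(sample(0:2, 30 * 1000, TRUE, prob = c(.5, .3, .2)),
               30, 1000)
  cnt <- site_counts(list(a = g1, b = g2))
  got <- genomewide_fst(cnt)
  abc <- sapply(seq_len(1000), function(j)
    wc_oracle_abc(list(g1[, j], g2[, j])))
  denom <- colSums(abc)
  ok <- denom != 0
  expect_equal(got, sum(abc["a", ok]) / sum(denom[ok]), tolerance = 1e-12)
  # single usable site equals the per-site value
  one <- site_counts(list(a = g1[, 1, drop = FALSE],
                          b = g2[, 1, drop = FALSE]))
  expect_equal(genomewide_fst(one), wc_fst_site(one)$theta)
})

test_that("samples drawn from one distribution give near-zero genome-wide
           FST, and literal copies show the expected negative bias", {
  cfg <- sim_config(n_pops = 2, samples_per_pop = 30, n_snps = 20000,
                    fst_matrix = 0, seed = 6)
  pan <- simulate_populations(cfg)
  g <- lapply(names(pan$haplotypes), function(p) panel_genotypes(pan, p))
  names(g) <- names(pan$haplotypes)
  expect_lt(abs(genomewide_fst(site_counts(g))), 0.01)
  # duplicating one sample set zeroes the between-population variance, so
  # the estimate sits below zero by about p(1-p)/(2(n-1)) per site
  dup <- site_counts(list(a = g[[1]], b = g[[1]]))
  fst_dup <- genomewide_fst(dup)
  expect_lt(fst_dup, 0)
  expect_gt(fst_dup, -0.03)
})

test_that("Fisher exact allele test matches enumeration and fisher.test", {
  expect_equal(fisher_allele_test(10, 10, 10, 10), 1)
  expect_equal(fisher_allele_test(10, 0, 0, 10), 2 / choose(20, 10),
               tolerance = 1e-10)
  expect_equal(fisher_allele_test(10, 0, 0, 10), 1.0824e-5,
               tolerance = 1e-3)
  expect_equal(fisher_allele_test(0, 0, 0, 0), 1)  # zero margins

  set.seed(53)
  for (rep_i in 1:60) {
    tb <- as.vector(stats::rmultinom(1, sample(4:60, 1), runif(4, .05, 1)))
    got <- fisher_allele_test(tb[1], tb[2], tb[3], tb[4])
    expect_equal(got, fisher_oracle(tb[1], tb[2], tb[3], tb[4]),
                 tolerance = 1e-10)
    ft <- stats::fisher.test(matrix(tb, 2, byrow = TRUE))$p.value
    expect_equal(got, ft, tolerance = 1e-9)
    # transposition invariance
    expect_equal(got, fisher_allele_test(tb[3], tb[4], tb[1], tb[2]),
                 tolerance = 1e-12)
    expect_equal(got, fisher_allele_test(tb[2], tb[1], tb[4], tb[3]),
                 tolerance = 1e-12)
  }
})

test_that("Bonferroni correction caps at 1 and scales linearly", {
  expect_equal(bonferroni(0.3, 4), 1)
  expect_equal(bonferroni(1e-9, 8207242), 8.207242e-3)
  expect_equal(bonferroni(0, 12), 0)
  expect_error(bonferroni(0.1, 0), "positive")
})

test_that("HWE exact test equals enumeration for all tables, total <= 60", {
  expect_equal(hwe_exact_test(0, 0, 0), 1)
  expect_equal(hwe_exact_test(30, 0, 0), 1)
  expect_equal(hwe_exact_test(3, 5, 1), hwe_oracle(3, 5, 1),
               tolerance = 1e-10)
  set.seed(59)
  for (rep_i in 1:80) {
    tb <- as.vector(stats::rmultinom(1, sample(3:60, 1), runif(3, .05, 1)))
    expect_equal(hwe_exact_test(tb[1], tb[2], tb[3]),
                 hwe_oracle(tb[1], tb[2], tb[3]), tolerance = 1e-10)
  }
  expect_error(hwe_exact_test(-1, 2, 3), "negative")
})

test_that("observed heterozygosity matches a direct tally", {
  all_het <- matrix(1L, 4, 10)
  expect_equal(observed_heterozygosity(all_het)$mean, 1)
  all_hom <- matrix(rep(c(0L, 2L), 20), 4, 10)
  expect_equal(observed_heterozygosity(all_hom)$mean, 0)
  set.seed(61)
  G <- matrix(sample(c(0:2, NA), 200, TRUE), 10, 20)
  got <- observed_heterozygosity(G)
  for (i in 1:10)
    expect_equal(unname(got$per_individual[i]),
                 sum(G[i, ] == 1, na.rm = TRUE) / sum(!is.na(G[i, ])))
})

test_that("gene diversity follows the per-locus Nei formula", {
  # p = 0.5 at large n: per-locus value tends to 0.5
  G <- matrix(rep(c(0L, 2L), 500), ncol = 1)
  expect_equal(gene_diversity(G)$uncorrected, 0.5)
  expect_equal(gene_diversity(G)$corrected, 0.5 * 2000 / 1999)
  # monomorphic locus contributes 0
  G2 <- cbind(G, 0L)
  expect_equal(gene_diversity(G2)$uncorrected, 0.25)
  set.seed(67)
  G3 <- matrix(sample(0:2, 25 * 40, TRUE), 25, 40)
  p <- colMeans(G3) / 2
  expect_equal(gene_diversity(G3)$uncorrected,
               mean(1 - p^2 - (1 - p)^2), tolerance = 1e-12)
})

test_that("IBS distances match the brute-force pair loop", {
  ident <- rbind(a = c(0, 1, 2, 1), b = c(0, 1, 2, 1))
  expect_equal(ibs_distance_matrix(ident)["a", "b"], 0)
  opp <- rbind(a = rep(0, 5), b = rep(2, 5))
  expect_equal(ibs_distance_matrix(opp)["a", "b"], 1)
  set.seed(71)
  G <- matrix(sample(c(0:2, NA), 8 * 50, TRUE, prob = c(.3, .3, .3, .1)),
              8, 50)
  D <- ibs_distance_matrix(G)
  expect_true(isSymmetric(D))
  expect_true(all(diag(D) == 0))
  for (i in 1:7) for (j in (i + 1):8) {
    shared <- 2 - abs(G[i, ] - G[j, ])
    expect_equal(D[i, j], 1 - mean(shared, na.rm = TRUE) / 2)
  }
})

test_that("QC filters keep exactly the sites passing MAF, HWE and
           missingness, attributed in order", {
  cfg <- sim_config(n_pops = 2, samples_per_pop = 15, n_snps = 400,
                    maf_floor = 0.02, missing_rate = 0.05, seed = 73)
  pan <- simulate_populations(cfg)
  filt <- apply_filters(pan, maf_min = 0.2, hwe_alpha = 1e-6,
                        missing_max = 0.05)
  qc <- filt$qc
  fail_maf <- is.na(qc$maf) | qc$maf < 0.2
  fail_hwe <- !fail_maf & qc$hwe_p < 1e-6
  fail_miss <- !fail_maf & !fail_hwe & qc$missingness > 0.05
  expect_equal(unname(filt$report["removed_maf"]), sum(fail_maf))
  expect_equal(unname(filt$report["removed_hwe"]), sum(fail_hwe))
  expect_equal(unname(filt$report["removed_missing"]), sum(fail_miss))
  expect_equal(nrow(filt$panel$variants),
               400 - sum(fail_maf | fail_hwe | fail_miss))
  expect_gt(sum(fail_maf), 0)  # floor below threshold guarantees removals
  # permissive thresholds are the identity
  all_kept <- apply_filters(pan, maf_min = 0, hwe_alpha = 0,
                            missing_max = 1)
  expect_equal(nrow(all_kept$panel$variants), 400)
})
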