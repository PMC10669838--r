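test_that("EHH equals the pair-counting formula on forced examples", {
  # all haplotypes identical over the span -> EHH = 1 everywhere
  hap <- matrix(rep(c(0L, 1L, 0L, 1L, 1L), each = 6), 6, 5)
  pos <- c(100, 200, 300, 400, 500)
  cv <- ehh(hap, pos, core = 1, direction = "right")
  expect_equal(cv$ehh, rep(1, 4))
  expect_equal(cv$distance, c(100, 200, 300, 400))

  # two identity classes of 2 at the next site: (1+1)/C(4,2)
  hap2 <- cbind(c(0L, 0L, 1L, 1L), c(0L, 1L, 0L, 1L))
  cv2 <- ehh(hap2, c(10, 50), core = 1)
  expect_equal(cv2$ehh[1], 1 / 3)
  # 4 pairwise distinct haplotypes at distance d -> EHH(d) = 0
  hap3 <- cbind(rep(0L, 4), c(0L, 1L, 0L, 1L), c(0L, 0L, 1L, 1L))
  cv3 <- ehh(hap3, c(10, 50, 90), core = 1, cutoff = 0)
  expect_equal(cv3$ehh[2], 0)

  # identity classes {3,2,1} -> (3+1)/15 = 4/15
  hap4 <- cbind(rep(0L, 6), c(0L, 0L, 0L, 1L, 1L, 1L),
                c(0L, 0L, 0L, 0L, 0L, 1L))
  cv4 <- ehh(hap4, c(10, 20, 30), core = 1, cutoff = 0)
  expect_equal(cv4$ehh[2], 4 / 15)

  expect_error(ehh(hap4[1, , drop = FALSE], c(10, 20, 30), 1),
               "at least 2")
})

test_that("EHH is non-increasing away from the core on random panels", {
  for (seed in 1:10) {
    hap <- random_hap_matrix(12, 30, seed)
    pos <- sort(sample.int(1e5, 30))
    core <- sample(2:29, 1)
    for (dir in c("left", "right")) {
      cv <- ehh(hap, pos, core, dir, cutoff = 0)
      expect_true(all(diff(c(1, cv$ehh)) <= 1e-12))
      expect_true(all(cv$ehh >= 0 & cv$ehh <= 1))
    }
  }
})

test_that("EHH and iHH match the exhaustive oracle on small panels", {
  for (seed in 1:15) {
    n_hap <- sample(4:8, 1)
    m <- sample(6:10, 1)
    hap <- random_hap_matrix(n_hap, m, seed + 100)
    pos <- sort(sample.int(5e5, m))
    for (core in c(1, sample(2:(m - 1), 2), m)) {
      cv_r <- ehh(hap, pos, core, "right", cutoff = 0.05)
      for (k in seq_along(cv_r$distance)) {
        x <- core + k
        expect_equal(cv_r$ehh[k], ehh_oracle_at(hap, core, x),
                     tolerance = 1e-9)
      }
      got <- ihh(ehh(hap, pos, core, "left"),
                 ehh(hap, pos, core, "right"))
      want <- ihh_oracle(hap, pos, core)
      if (is.na(want)) expect_true(is.na(got)) else
        expect_equal(got, want, tolerance = 1e-9)
    }
  }
})

test_that("constant EHH over L bp with a hard stop integrates to 2L", {
  hap <- matrix(0L, 6, 3)
  pos <- c(1000, 2000, 3000)
  expect_equal(ihh(ehh(hap, pos, 2, "left"), ehh(hap, pos, 2, "right")),
               2000)
  # single side available at the chromosome edge
  expect_equal(ihh(NULL, ehh(hap, pos, 1, "right")), 2000)
  one_site <- matrix(0L, 6, 1)
  expect_true(is.na(ihh(NULL, NULL)))
})

test_that("gaps larger than max_gap truncate the curve", {
  hap <- matrix(0L, 4, 3)
  pos <- c(1000, 2000, 300000)
  cv <- ehh(hap, pos, 1, "right", max_gap = 2e5)
  expect_equal(cv$distance, 1000)  # third site unreachable
  expect_equal(ihh(NULL, cv), 1000)
})

test_that("cutoff crossing is linearly interpolated in iHH", {
  # EHH drops 1 -> 12/28 -> 6/28 over 8 haplotypes; a 0.3 cutoff is
  # crossed between the two informative sites
  hap <- cbind(rep(0L, 8), rep(c(0L, 1L), 4),
               c(0L, 0L, 1L, 1L, 0L, 1L, 0L, 1L))
  pos <- c(0, 1000, 2000)
  cutoff <- 0.3
  cv <- ehh(hap, pos, 1, "right", cutoff = cutoff)
  e1 <- ehh_oracle_at(hap, 1, 2)
  e2 <- ehh_oracle_at(hap, 1, 3)
  expect_equal(c(e1, e2), c(12 / 28, 6 / 28))
  expect_lt(e2, cutoff)
  dcross <- 1000 + 1000 * (e1 - cutoff) / (e1 - e2)
  want <- 1000 * (1 + e1) / 2 + (dcross - 1000) * (e1 + cutoff) / 2
  expect_equal(ihh(NULL, cv), want, tolerance = 1e-9)
})

test_that("raw XP-EHH is zero for identical populations and antisymmetric
           under swap", {
  cfg <- sim_config(n_pops = 2, samples_per_pop = 12, n_snps = 500,
                    chrom_lengths = c(chr1 = 1e6), fst_matrix = 0.08,
                    seed = 19)
  pan <- simulate_populations(cfg)
  pan$haplotypes$pop2 <- pan$haplotypes$pop1  # identical sets
  xe <- xpehh_scan(pan, "pop1", "pop2", normalize = FALSE)
  expect_true(all(abs(xe$xpehh_raw[!is.na(xe$xpehh_raw)]) < 1e-12))

  pan2 <- simulate_populations(cfg)
  ab <- xpehh_scan(pan2, "pop1", "pop2")
  ba <- xpehh_scan(pan2, "pop2", "pop1")
  expect_equal(ab$xpehh_raw, -ba$xpehh_raw)
})

test_that("normalization gives mean 0 / sd 1 and rejects degenerate
           input", {
  set.seed(83)
  x <- c(rnorm(500), NA, Inf)
  z <- normalize_scores(x)
  fin <- is.finite(z)
  expect_lt(abs(mean(z[fin])), 1e-12)
  expect_lt(abs(sd(z[fin]) - 1), 1e-12)
  expect_true(is.na(z[501]))
  expect_error(normalize_scores(c(1, NA)), "at least 2")
  expect_error(normalize_scores(rep(2, 10)), "zero variance")
})

test_that("a simulated sweep drives normalized XP-EHH above 1 inside the
           truth interval in most seeds", {
  hits <- 0
  for (seed in 1:6) {
    cfg <- sim_config(n_pops = 2, samples_per_pop = 30, n_snps = 5000,
                      chrom_lengths = c(chr1 = 1e7), fst_matrix = 0.10,
                      sweeps = list(sweep_spec("pop1", "chr1", 5e6, 5e4,
                                               final_freq = 0.98,
                                               carrier_fraction = 0.9)),
                      seed = 1000 + seed)
    pan <- simulate_populations(cfg)
    xe <- xpehh_scan(pan, "pop1", "pop2")
    inside <- pan$variants$pos >= pan$truth$start &
      pan$variants$pos <= pan$truth$end
    if (any(abs(xe$xpehh_norm[inside]) >= 1, na.rm = TRUE))
      hits <- hits + 1
  }
  expect_gte(hits, 5)
})
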