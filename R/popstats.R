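#' Per-site genotype and allele counts by population
#'
#' Complete-case per population: missing genotypes are excluded site-wise.
#' A population with no calls at a site contributes `n = 0` there and the
#' site is flagged unusable if fewer than two populations have calls.
#'
#' @param genotypes Named list (one per population) of `N x M` 0/1/2 dosage
#'   matrices (`NA` = missing).
#' @return A `site_counts` list of populations-x-sites matrices: `n`
#'   (diploids with calls), `hom_ref`, `het`, `hom_alt`, `p` (alt allele
#'   frequency), `h` (observed het frequency), plus `usable` (logical, >= 2
#'   populations with n > 0).
#' @export
site_counts <- function(genotypes) {
  stopifnot(is.list(genotypes), length(genotypes) >= 1L)
  pops <- names(genotypes)
  by_pop <- function(f) {
    m <- do.call(rbind, lapply(genotypes, f))
    dimnames(m) <- list(pops, NULL)
    m
  }
  grab <- function(val) by_pop(function(G) colSums(G == val, na.rm = TRUE))
  n <- by_pop(function(G) colSums(!is.na(G)))
  het <- grab(1L)
  hom_alt <- grab(2L)
  hom_ref <- n - het - hom_alt
  p <- (2 * hom_alt + het) / (2 * n)  # NaN where n = 0
  h <- het / n
  structure(list(n = n, hom_ref = hom_ref, het = het, hom_alt = hom_alt,
                 p = p, h = h, usable = colSums(n > 0) >= 2L),
            class = "site_counts")
}

#' Per-site Weir-Cockerham FST (theta-hat)
#'
#' Variance-components estimator for r populations: with per-population
#' sample sizes n_i, alt-allele frequencies p_i and observed het
#' frequencies h_i,
#' \deqn{a = \frac{\bar n}{n_C}\left[s^2 - \frac{1}{\bar n - 1}
#'   \left(\bar p(1-\bar p) - \frac{r-1}{r}s^2 - \frac{\bar h}{4}\right)
#'   \right]}
#' \deqn{b = \frac{\bar n}{\bar n - 1}\left[\bar p(1-\bar p) -
#'   \frac{r-1}{r}s^2 - \frac{2\bar n - 1}{4\bar n}\bar h\right], \quad
#'   c = \bar h / 2}
#' and theta-hat = a / (a + b + c). Sites monomorphic across all usable
#' populations (a + b + c = 0) return `NA`; negative estimates are kept as
#' computed; sites with < 2 usable populations return `NA`.
#'
#' @param counts A `site_counts` object.
#' @return List with per-site vectors `theta`, `a`, `b`, `c`.
#' @export
wc_fst_site <- function(counts) {
  stopifnot(inherits(counts, "site_counts"))
  n <- counts$n; p <- counts$p; h <- counts$h
  use <- n > 0
  r <- colSums(use)
  M <- ncol(n)

  n_tot <- colSums(n)
  nbar <- n_tot / r
  p[!use] <- 0; h[!use] <- 0
  pbar <- colSums(n * p) / n_tot
  hbar <- colSums(n * h) / n_tot
  s2 <- colSums(n * (p - rep(pbar, each = nrow(p)))^2 * use) /
    ((r - 1) * nbar)
  nc <- (n_tot - colSums(n^2) / n_tot) / (r - 1)

  a <- nbar / nc *
    (s2 - 1 / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2

  denom <- a + b + cc
  theta <- ifelse(abs(denom) < .Machine$double.eps * 8, NA_real_, a / denom)
  bad <- r < 2 | nbar <= 1
  theta[bad] <- NA_real_
  a[bad] <- NA_real_; b[bad] <- NA_real_; cc[bad] <- NA_real_
  list(theta = theta, a = a, b = b, c = cc)
}

#' Genome-wide weighted (ratio-of-sums) FST
#'
#' `sum(a) / sum(a + b + c)` over usable sites, the "weighted" estimate
#' reported by VCFtools' `--weir-fst-pop`. Sites with undefined components
#' are excluded from both sums.
#'
#' @param counts A `site_counts` object, or the list from [wc_fst_site()].
#' @return Scalar FST.
#' @export
genomewide_fst <- function(counts) {
  comp <- if (inherits(counts, "site_counts")) wc_fst_site(counts) else counts
  ok <- is.finite(comp$a) & is.finite(comp$b) & is.finite(comp$c) &
    !is.na(comp$theta)
  if (!any(ok)) stop("no usable polymorphic sites for genome-wide FST")
  sum(comp$a[ok]) / sum(comp$a[ok] + comp$b[ok] + comp$c[ok])
}

#' Two-sided Fisher exact test on per-site allele counts
#'
#' For each site a 2x2 table of (ref, alt) allele counts in two populations
#' is tested by the point-probability rule: p is the sum of hypergeometric
#' probabilities of all tables with the same margins whose probability does
#' not exceed that of the observed table (within relative 1e-7, the
#' convention of standard exact-test implementations). Zero-margin tables
#' give p = 1.
#'
#' @param ref_a,alt_a,ref_b,alt_b Integer vectors of allele counts per site
#'   in populations A and B.
#' @return Vector of two-sided p-values.
#' @export
fisher_allele_test <- function(ref_a, alt_a, ref_b, alt_b) {
  stopifnot(length(ref_a) == length(alt_a),
            length(ref_a) == length(ref_b),
            length(ref_a) == length(alt_b))
  if (any(c(ref_a, alt_a, ref_b, alt_b) < 0, na.rm = TRUE))
    stop("negative allele counts")
  vapply(seq_along(ref_a), function(i) {
    m <- ref_a[i] + alt_a[i]          # population A total
    n <- ref_b[i] + alt_b[i]          # population B total
    k <- ref_a[i] + ref_b[i]          # ref-allele margin
    if (anyNA(c(m, n, k))) return(NA_real_)
    if (m == 0 || n == 0 || k == 0 || k == m + n) return(1)
    support <- max(0L, k - n):min(m, k)
    d <- dhyper(support, m, n, k)
    p_obs <- dhyper(ref_a[i], m, n, k)
    min(1, sum(d[d <= p_obs * (1 + 1e-7)]))
  }, numeric(1))
}

#' Bonferroni correction
#'
#' @param p Vector of raw p-values.
#' @param m Number of tests (default `length(p)`), e.g. the number of SNPs
#'   in the comparison.
#' @return `pmin(1, m * p)`.
#' @export
bonferroni <- function(p, m = length(p)) {
  if (m <= 0) stop("m must be positive")
  pmin(1, m * p)
}

#' Observed heterozygosity per individual and population mean
#'
#' Per individual: heterozygous calls / non-missing calls; the population
#' value is the unweighted mean over individuals (per-individual `--het`
#' semantics averaged). Individuals with zero calls are excluded and
#' counted in the result.
#'
#' @param G `N x M` 0/1/2 dosage matrix for one population.
#' @return List with `per_individual` (named vector) and `mean`.
#' @export
observed_heterozygosity <- function(G) {
  calls <- rowSums(!is.na(G))
  het <- rowSums(G == 1L, na.rm = TRUE)
  rate <- ifelse(calls > 0, het / calls, NA_real_)
  names(rate) <- rownames(G)
  n_dropped <- sum(calls == 0)
  if (n_dropped > 0)
    message("observed_heterozygosity: excluded ", n_dropped,
            " individual(s) with zero calls")
  list(per_individual = rate, mean = mean(rate, na.rm = TRUE),
       n_excluded = n_dropped)
}

#' Gene diversity (mean expected heterozygosity)
#'
#' Per-locus Nei gene diversity `1 - p^2 - q^2`, averaged over callable
#' loci. The unbiased small-sample corrected form multiplies each locus by
#' `2n/(2n - 1)` and is the default report; the uncorrected mean is also
#' returned.
#'
#' @param G `N x M` 0/1/2 dosage matrix for one population.
#' @return List with `corrected` (default report) and `uncorrected`.
#' @export
gene_diversity <- function(G) {
  n <- colSums(!is.na(G))
  ok <- n > 0
  if (!any(ok)) stop("no callable loci")
  p <- colSums(G, na.rm = TRUE)[ok] / (2 * n[ok])
  d <- 1 - p^2 - (1 - p)^2
  corr <- 2 * n[ok] / (2 * n[ok] - 1)
  list(corrected = mean(corr * d), uncorrected = mean(d))
}

#' Pairwise identity-by-state distance matrix
#'
#' IBS similarity between two diploids is the mean over pairwise-callable
#' sites of (shared alleles)/2; with 0/1/2 dosages shared alleles are
#' `2 - |g1 - g2|`, so distance = mean(|g1 - g2|)/2. Pairs with zero
#' overlapping calls get `NA`.
#'
#' @param G `N x M` 0/1/2 dosage matrix (all individuals, any population).
#' @return Symmetric `N x N` distance matrix, zero diagonal.
#' @export
ibs_distance_matrix <- function(G) {
  N <- nrow(G)
  D <- matrix(0, N, N, dimnames = list(rownames(G), rownames(G)))
  for (i in seq_len(N - 1)) {
    gi <- G[i, ]
    for (j in (i + 1):N) {
      d <- abs(gi - G[j, ])
      m <- mean(d, na.rm = TRUE) / 2
      D[i, j] <- D[j, i] <- if (is.nan(m)) NA_real_ else m
    }
  }
  D
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Exact conditional test on genotype counts: conditional on the observed
#' allele counts, p is the sum of probabilities of all heterozygote counts
#' whose conditional probability does not exceed that of the observed one
#' (within relative 1e-7). Empty or monomorphic sites return 1.
#'
#' @param hom_ref,het,hom_alt Integer vectors of genotype counts per site.
#' @return Vector of exact p-values in (0, 1].
#' @export
hwe_exact_test <- function(hom_ref, het, hom_alt) {
  if (any(c(hom_ref, het, hom_alt) < 0, na.rm = TRUE))
    stop("negative genotype counts")
  vapply(seq_along(het), function(i) {
    nAA <- hom_ref[i]; nAa <- het[i]; naa <- hom_alt[i]
    if (anyNA(c(nAA, nAa, naa))) return(NA_real_)
    n <- nAA + nAa + naa
    nA <- 2L * nAA + nAa
    na <- 2L * naa + nAa
    if (n == 0L || nA == 0L || na == 0L) return(1)
    rare <- min(nA, na)
    hets <- seq.int(rare %% 2L, rare, by = 2L)
    # log conditional probability of each possible het count, normalised
    lp <- lchoose(n, (nA - hets) / 2) +
      lchoose(n - (nA - hets) / 2, hets) +
      lchoose(n - (nA - hets) / 2 - hets, (na - hets) / 2) +
      hets * log(2)
    pr <- exp(lp - max(lp))
    pr <- pr / sum(pr)
    p_obs <- pr[match(nAa, hets)]
    min(1, sum(pr[pr <= p_obs * (1 + 1e-7)]))
  }, numeric(1))
}

#' Per-site QC: MAF, HWE exact p, missingness
#'
#' @param genotypes Named list of per-population dosage matrices; MAF, HWE
#'   and missingness are computed over all retained samples pooled.
#' @return data.frame with `maf`, `hwe_p`, `missingness` per site.
#' @export
variant_qc <- function(genotypes) {
  G <- do.call(rbind, genotypes)
  n <- colSums(!is.na(G))
  p <- ifelse(n > 0, colSums(G, na.rm = TRUE) / (2 * n), NA_real_)
  maf <- pmin(p, 1 - p)
  hwe_p <- hwe_exact_test(colSums(G == 0L, na.rm = TRUE),
                          colSums(G == 1L, na.rm = TRUE),
                          colSums(G == 2L, na.rm = TRUE))
  data.frame(maf = maf, hwe_p = hwe_p, missingness = 1 - n / nrow(G))
}

#' Filter a panel on MAF, HWE and missingness
#'
#' A site is kept iff MAF >= `maf_min`, HWE exact p >= `hwe_alpha`, and
#' missingness <= `missing_max`. The report attributes each removed site to
#' the first failing filter, applied in the order MAF, HWE, missingness.
#'
#' @param panel A `hap_panel`.
#' @param maf_min Minimum minor allele frequency (default 0; the diversity
#'   subset uses 0.2).
#' @param hwe_alpha HWE exact-test floor (default 1e-6).
#' @param missing_max Maximum per-site missingness (default 0.1).
#' @return List with the filtered `panel`, the per-site `qc` table, a
#'   logical `keep` vector and a `report` of counts removed per filter.
#' @export
apply_filters <- function(panel, maf_min = 0, hwe_alpha = 1e-6,
                          missing_max = 0.1) {
  stopifnot(maf_min >= 0, maf_min <= 1, hwe_alpha >= 0, hwe_alpha <= 1,
            missing_max >= 0, missing_max <= 1)
  genotypes <- lapply(names(panel$haplotypes),
                      function(p) panel_genotypes(panel, p))
  names(genotypes) <- names(panel$haplotypes)
  qc <- variant_qc(genotypes)
  fail_maf <- is.na(qc$maf) | qc$maf < maf_min
  fail_hwe <- !fail_maf & qc$hwe_p < hwe_alpha
  fail_miss <- !fail_maf & !fail_hwe & qc$missingness > missing_max
  keep <- !(fail_maf | fail_hwe | fail_miss)
  out <- panel
  out$variants <- panel$variants[keep, , drop = FALSE]
  rownames(out$variants) <- NULL
  out$haplotypes <- lapply(panel$haplotypes,
                           function(H) H[, keep, drop = FALSE])
  out$pop_freq <- if (!is.null(panel$pop_freq))
    panel$pop_freq[, keep, drop = FALSE]
  list(panel = out, qc = qc, keep = keep,
       report = c(input = length(keep), removed_maf = sum(fail_maf),
                  removed_hwe = sum(fail_hwe),
                  removed_missing = sum(fail_miss), retained = sum(keep)))
}
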