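# Independent reference implementations used as oracles. Each is written
# from the defining formulas, in a different style from the package code
# (scalar loops, explicit enumeration), and stays independent of the code
# paths it checks.

# Weir & Cockerham (1984) variance components for one site, r populations.
# Inputs: list per population of 0/1/2 genotype vectors (NA = missing).
wc_oracle_site <- function(geno_by_pop) {
  geno_by_pop <- lapply(geno_by_pop, function(g) g[!is.na(g)])
  geno_by_pop <- geno_by_pop[vapply(geno_by_pop, length, 1L) > 0]
  r <- length(geno_by_pop)
  if (r < 2) return(NA_real_)
  n_i <- vapply(geno_by_pop, length, numeric(1))
  p_i <- vapply(geno_by_pop, function(g) sum(g) / (2 * length(g)),
                numeric(1))
  h_i <- vapply(geno_by_pop, function(g) mean(g == 1), numeric(1))
  nbar <- mean(n_i)
  if (nbar <= 1) return(NA_real_)
  nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n_i * p_i) / (r * nbar)
  s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n_i * h_i) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  if (a + b + cc == 0) return(NA_real_)
  a / (a + b + cc)
}

# same, returning the components for ratio-of-sums checks
wc_oracle_abc <- function(geno_by_pop) {
  geno_by_pop <- lapply(geno_by_pop, function(g) g[!is.na(g)])
  r <- length(geno_by_pop)
  n_i <- vapply(geno_by_pop, length, numeric(1))
  p_i <- vapply(geno_by_pop, function(g) sum(g) / (2 * length(g)),
                numeric(1))
  h_i <- vapply(geno_by_pop, function(g) mean(g == 1), numeric(1))
  nbar <- mean(n_i)
  nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n_i * p_i) / (r * nbar)
  s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n_i * h_i) / (r * nbar)
  c(a = (nbar / nc) *
      (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1)),
    b = (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - s2 * (r - 1) / r -
         hbar * (2 * nbar - 1) / (4 * nbar)),
    c = hbar / 2)
}

# Two-sided Fisher p by full enumeration of tables with the observed
# margins; point-probability rule (probabilities within relative 1e-7 of
# the observed table count as ties).
fisher_oracle <- function(ref_a, alt_a, ref_b, alt_b) {
  m <- ref_a + alt_a
  n <- ref_b + alt_b
  k <- ref_a + ref_b
  if (m == 0 || n == 0 || k == 0 || k == m + n) return(1)
  total <- choose(m + n, k)
  probs <- sapply(max(0, k - n):min(m, k), function(x)
    choose(m, x) * choose(n, k - x) / total)
  p_obs <- choose(m, ref_a) * choose(n, ref_b) / total
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# Exact HWE p by enumeration of all heterozygote counts compatible with
# the observed allele counts; same tie rule.
hwe_oracle <- function(hom_ref, het, hom_alt) {
  n <- hom_ref + het + hom_alt
  nA <- 2 * hom_ref + het
  na <- 2 * hom_alt + het
  if (n == 0 || nA == 0 || na == 0) return(1)
  hets <- seq(min(nA, na) %% 2, min(nA, na), by = 2)
  pr <- sapply(hets, function(h) {
    aa <- (nA - h) / 2; bb <- (na - h) / 2
    exp(lfactorial(n) - lfactorial(aa) - lfactorial(h) - lfactorial(bb) +
          h * log(2) + lfactorial(nA) + lfactorial(na) - lfactorial(2 * n))
  })
  pr <- pr / sum(pr)
  p_obs <- pr[hets == het]
  min(1, sum(pr[pr <= p_obs * (1 + 1e-7)]))
}

# EHH by brute force: probability two distinct haplotypes are identical
# at every site from the core out to x (exclusive of the core column —
# EHH at distance 0 is 1 over all haplotypes jointly, the XP-EHH variant;
# inclusive of x); counts identical-row pairs directly.
ehh_oracle_at <- function(hap, core, x) {
  cols <- if (x > core) (core + 1):x else x:(core - 1)
  seg <- hap[, cols, drop = FALSE]
  key <- apply(seg, 1, paste, collapse = "")
  n <- nrow(hap)
  sum(sapply(unique(key), function(k) {
    ck <- sum(key == k); ck * (ck - 1) / 2
  })) / (n * (n - 1) / 2)
}

# One-sided iHH by hand trapezoid over the EHH curve from the core,
# truncating at the interpolated cutoff crossing, a gap > max_gap, or the
# chromosome end.
ihh_oracle_side <- function(hap, pos, core, dir, cutoff = 0.05,
                            max_gap = 2e5) {
  m <- ncol(hap)
  idx <- if (dir > 0) seq(core + 1, m) else seq(core - 1, 1)
  if (core + dir < 1 || core + dir > m) return(NA_real_)
  d_prev <- 0; e_prev <- 1; area <- 0; last_pos <- pos[core]
  for (x in idx) {
    if (abs(pos[x] - last_pos) > max_gap) break
    e <- ehh_oracle_at(hap, core, x)
    d <- abs(pos[x] - pos[core])
    if (e < cutoff) {
      dc <- d_prev + (d - d_prev) * (e_prev - cutoff) / (e_prev - e)
      return(area + (dc - d_prev) * (e_prev + cutoff) / 2)
    }
    area <- area + (d - d_prev) * (e_prev + e) / 2
    d_prev <- d; e_prev <- e; last_pos <- pos[x]
  }
  area
}

ihh_oracle <- function(hap, pos, core, cutoff = 0.05, max_gap = 2e5) {
  l <- ihh_oracle_side(hap, pos, core, -1, cutoff, max_gap)
  r <- ihh_oracle_side(hap, pos, core, +1, cutoff, max_gap)
  if (is.na(l) && is.na(r)) return(NA_real_)
  sum(c(l, r), na.rm = TRUE)
}

# Literal seed-and-extend region caller over a tier vector ("E"/"S"/"N"):
# walk out from each extreme SNP crossing runs of 1-2 N (any E/S resets
# the counter), stop at the first run of 3 N; separately, fragments
# delimited by runs of >= 3 N with > 5 significant SNPs and no extreme are
# regions spanning their outermost non-N sites; overlapping regions merge.
grow_oracle <- function(tier) {
  m <- length(tier)
  regions <- list()
  for (s in which(tier == "E")) {
    lo <- s; hi <- s
    nrun <- 0; i <- s
    while (i < m) {
      i <- i + 1
      if (tier[i] == "N") { nrun <- nrun + 1; if (nrun >= 3) break }
      else { nrun <- 0; hi <- i }
    }
    nrun <- 0; i <- s
    while (i > 1) {
      i <- i - 1
      if (tier[i] == "N") { nrun <- nrun + 1; if (nrun >= 3) break }
      else { nrun <- 0; lo <- i }
    }
    regions[[length(regions) + 1]] <- c(lo, hi)
  }
  frag_lo <- 1; i <- 1; frags <- list()
  while (i <= m) {
    if (i + 2 <= m && tier[i] == "N" && tier[i + 1] == "N" &&
        tier[i + 2] == "N") {
      j <- i
      while (j < m && tier[j + 1] == "N") j <- j + 1
      frags[[length(frags) + 1]] <- c(frag_lo, i - 1)
      frag_lo <- j + 1; i <- j + 1
    } else i <- i + 1
  }
  frags[[length(frags) + 1]] <- c(frag_lo, m)
  for (fr in frags) {
    if (fr[1] > fr[2]) next
    seg <- tier[fr[1]:fr[2]]
    if (sum(seg == "E") == 0 && sum(seg == "S") > 5) {
      sig <- which(seg != "N") + fr[1] - 1
      regions[[length(regions) + 1]] <- c(min(sig), max(sig))
    }
  }
  if (length(regions) == 0) return(matrix(integer(0), ncol = 2))
  R <- do.call(rbind, regions)
  R <- R[order(R[, 1], R[, 2]), , drop = FALSE]
  out <- R[1, , drop = FALSE]
  if (nrow(R) > 1) for (k in 2:nrow(R)) {
    if (R[k, 1] <= out[nrow(out), 2])
      out[nrow(out), 2] <- max(out[nrow(out), 2], R[k, 2])
    else out <- rbind(out, R[k, , drop = FALSE])
  }
  out
}

# small random phased panel builder for property tests
random_hap_matrix <- function(n_hap, m, seed) {
  set.seed(seed)
  matrix(rbinom(n_hap * m, 1, runif(m, 0.1, 0.9)[rep(seq_len(m),
                                                     each = n_hap)]),
         nrow = n_hap)
}

# write a small GFF3 annotation to a temp file
write_toy_gff3 <- function(genes, path = tempfile(fileext = ".gff3")) {
  lines <- "##gff-version 3"
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    attrs <- paste0("ID=", g$gene_id,
                    if (!is.na(g$name)) paste0(";Name=", g$name))
    lines <- c(lines,
               paste(g$chrom, "test", "gene", g$start, g$end, ".",
                     g$strand, ".", attrs, sep = "\t"),
               paste(g$chrom, "test", "mRNA", g$start, g$end, ".",
                     g$strand, ".",
                     paste0("ID=", g$gene_id, ".t1;Parent=", g$gene_id),
                     sep = "\t"))
  }
  writeLines(lines, path)
  path
}
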