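#' Simulation configuration for diverged populations with sweeps
#'
#' Describes a multi-population panel drawn under the Balding-Nichols model:
#' each site has an ancestral allele frequency `p ~ Uniform(maf_floor,
#' 1 - maf_floor)`; population `i` with divergence parameter `F_i` draws its
#' site frequency from `Beta(p (1 - F_i) / F_i, (1 - p)(1 - F_i) / F_i)`
#' (degenerate `F_i = 0` keeps the ancestral frequency); haplotype alleles
#' are independent Bernoulli draws at the population frequency. Sweeps from
#' [sweep_spec()] then overwrite a carrier fraction of the target
#' population's haplotypes with one shared core haplotype over the sweep
#' span, producing the extended haplotype identity and near-fixed frequency
#' contrast that cross-population scans detect.
#'
#' Per-population divergence parameters are derived from the requested
#' pairwise `fst_matrix` through the small-F approximation
#' `FST(i, j) ~ (F_i + F_j) / 2`: for every population the average of its
#' pairwise targets is solved by least squares (closed form for 3
#' populations) and clamped to `[0, 0.95]`. Only realized FST is ever
#' asserted against, not this mapping.
#'
#' @param n_pops Number of populations.
#' @param samples_per_pop Integer vector (recycled to `n_pops`) of diploid
#'   sample counts per population.
#' @param n_snps Total biallelic SNP count, apportioned to chromosomes
#'   proportionally to `chrom_lengths`.
#' @param chrom_lengths Named numeric vector of chromosome lengths in bp.
#' @param fst_matrix Symmetric matrix (zero diagonal, entries in `[0, 1)`) of
#'   nominal pairwise divergence, or a single scalar F applied to every pair.
#' @param maf_floor Minimum ancestral allele frequency (default 0.05).
#' @param sweeps List of [sweep_spec()] objects.
#' @param missing_rate Fraction of genotype calls set missing, for testing
#'   QC filters (default 0; missingness is genotype-wise, both haplotypes).
#' @param pop_labels Population labels; default `pop1`, `pop2`, ...
#' @param merge_sublines Optional named list `list(BRs = c("BRA", "BRB"))`
#'   recorded in the config so that writers can emit sub-line labels that a
#'   population map later merges; the simulator itself treats merged
#'   sub-lines as one population.
#' @param seed Integer RNG seed; fixes all output exactly.
#'
#' @return An object of class `sim_config`.
#' @seealso [simulate_populations()], [sweep_spec()]
#' @export
sim_config <- function(n_pops = 2L,
                       samples_per_pop = 30L,
                       n_snps = 5000L,
                       chrom_lengths = c(chr1 = 10e6),
                       fst_matrix = 0.10,
                       maf_floor = 0.05,
                       sweeps = list(),
                       missing_rate = 0,
                       pop_labels = NULL,
                       merge_sublines = NULL,
                       seed = 1L) {
  n_pops <- as.integer(n_pops)
  stopifnot(n_pops >= 1L, n_snps > 0L, all(chrom_lengths > 0),
            maf_floor >= 0, maf_floor < 0.5,
            missing_rate >= 0, missing_rate < 1)
  samples_per_pop <- as.integer(rep_len(samples_per_pop, n_pops))
  stopifnot(all(samples_per_pop >= 1L))
  if (is.null(pop_labels)) pop_labels <- paste0("pop", seq_len(n_pops))
  stopifnot(length(pop_labels) == n_pops, !anyDuplicated(pop_labels))
  if (is.null(names(chrom_lengths)))
    names(chrom_lengths) <- paste0("chr", seq_along(chrom_lengths))

  if (length(fst_matrix) == 1L) {
    f <- as.numeric(fst_matrix)
    fst_matrix <- matrix(f, n_pops, n_pops)
    diag(fst_matrix) <- 0
  }
  fst_matrix <- as.matrix(fst_matrix)
  if (nrow(fst_matrix) != n_pops || ncol(fst_matrix) != n_pops)
    stop("fst_matrix must be ", n_pops, "x", n_pops)
  if (any(abs(fst_matrix - t(fst_matrix)) > 1e-12))
    stop("fst_matrix must be symmetric")
  if (any(diag(fst_matrix) != 0)) stop("fst_matrix diagonal must be zero")
  if (any(fst_matrix < 0) || any(fst_matrix >= 1))
    stop("fst_matrix entries must be in [0, 1)")
  dimnames(fst_matrix) <- list(pop_labels, pop_labels)

  for (sw in sweeps) {
    if (!inherits(sw, "sweep_spec")) stop("sweeps must be sweep_spec objects")
    if (!sw$target_pop %in% pop_labels)
      stop("sweep target population '", sw$target_pop, "' not in pop_labels")
    if (!sw$chrom %in% names(chrom_lengths))
      stop("sweep chromosome '", sw$chrom, "' not in chrom_lengths")
    if (sw$center - sw$half_width < 1 ||
        sw$center + sw$half_width > chrom_lengths[[sw$chrom]])
      stop("sweep on ", sw$chrom, " at ", sw$center, " +/- ", sw$half_width,
           " extends outside chromosome bounds")
  }

  structure(list(
    n_pops = n_pops, samples_per_pop = samples_per_pop,
    n_snps = as.integer(n_snps), chrom_lengths = chrom_lengths,
    fst_matrix = fst_matrix, maf_floor = maf_floor, sweeps = sweeps,
    missing_rate = missing_rate, pop_labels = pop_labels,
    merge_sublines = merge_sublines, seed = as.integer(seed)
  ), class = "sim_config")
}

#' Specification of one injected selective sweep
#'
#' @param target_pop Population label whose haplotypes are homogenized.
#' @param chrom Chromosome id.
#' @param center Sweep center in bp.
#' @param half_width Half-width of the sweep span in bp.
#' @param final_freq Post-sweep derived (alt) allele frequency in the target
#'   population, in `(0.5, 1]`.
#' @param carrier_fraction Fraction of target-population haplotypes replaced
#'   by the shared core haplotype over the span, in `(0, 1]`.
#'
#' @return An object of class `sweep_spec`.
#' @export
sweep_spec <- function(target_pop, chrom, center, half_width,
                       final_freq = 0.95, carrier_fraction = 0.9) {
  stopifnot(final_freq > 0.5, final_freq <= 1,
            carrier_fraction > 0, carrier_fraction <= 1,
            half_width > 0, center > 0)
  structure(list(target_pop = target_pop, chrom = as.character(chrom),
                 center = as.numeric(center),
                 half_width = as.numeric(half_width),
                 final_freq = final_freq,
                 carrier_fraction = carrier_fraction),
            class = "sweep_spec")
}

# Least-squares per-population F from a pairwise target matrix under the
# small-F approximation FST(i,j) ~ (F_i + F_j)/2. Exact for 3 populations.
per_pop_f <- function(fst_matrix) {
  r <- nrow(fst_matrix)
  if (r == 1L) return(setNames(0, rownames(fst_matrix)))
  if (r == 2L) {
    f <- fst_matrix[1, 2]
    return(setNames(c(f, f), rownames(fst_matrix)))
  }
  # minimise sum_{i<j} ((F_i+F_j)/2 - fst_ij)^2: normal equations
  A <- matrix(0.25, r, r)
  diag(A) <- 0.25 * (r - 1)
  b <- 0.5 * rowSums(fst_matrix)
  f <- solve(A, b)
  setNames(pmin(pmax(f, 0), 0.95), rownames(fst_matrix))
}

#' Simulate phased diverged populations with injected sweeps
#'
#' Draws a phased biallelic panel under the Balding-Nichols model described
#' in [sim_config()], then applies each sweep: the carrier fraction of
#' target-population haplotypes is overwritten with a single all-derived
#' core haplotype over the sweep span, and non-carrier haplotypes are
#' redrawn there at frequency `(final_freq - carrier) / (1 - carrier)`
#' (clamped to `[0, 1]`) so the realized site frequency lands near
#' `final_freq`. The same seed yields identical output.
#'
#' @param config A [sim_config()] object.
#' @return A `hap_panel`: list with `variants` (data.frame `chrom`, `pos`,
#'   `ref`, `alt`), `haplotypes` (named list per population of
#'   `2N x n_snps` 0/1 integer matrices, rows `<sample>_1`, `<sample>_2`),
#'   `samples` (named list of sample ids per population), `phased = TRUE`,
#'   `truth` (data.frame of realized sweep intervals, 1-based inclusive),
#'   `pop_freq` (populations x sites matrix of post-sweep expected alt
#'   frequencies) and the `config`.
#' @export
simulate_populations <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  M <- config$n_snps
  labels <- config$pop_labels

  # apportion sites to chromosomes by length, largest-remainder rounding
  lens <- config$chrom_lengths
  raw <- M * lens / sum(lens)
  n_chr <- floor(raw)
  rem <- M - sum(n_chr)
  if (rem > 0) {
    up <- order(raw - n_chr, decreasing = TRUE)[seq_len(rem)]
    n_chr[up] <- n_chr[up] + 1
  }

  chrom <- rep(names(lens), n_chr)
  pos <- unlist(lapply(seq_along(lens), function(i) {
    k <- n_chr[[i]]
    if (k == 0) return(numeric(0))
    p <- sort(sample.int(lens[[i]], k))
    p
  }), use.names = FALSE)

  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, M, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), character(1))
  variants <- data.frame(chrom = chrom, pos = as.integer(pos),
                         ref = ref, alt = unname(alt),
                         stringsAsFactors = FALSE)

  p_anc <- runif(M, config$maf_floor, 1 - config$maf_floor)
  f_pop <- per_pop_f(config$fst_matrix)

  pop_freq <- matrix(NA_real_, config$n_pops, M,
                     dimnames = list(labels, NULL))
  haplotypes <- vector("list", config$n_pops)
  names(haplotypes) <- labels
  samples <- vector("list", config$n_pops)
  names(samples) <- labels

  for (i in seq_len(config$n_pops)) {
    Fi <- f_pop[[i]]
    q <- if (Fi <= 0) p_anc else {
      shape_scale <- (1 - Fi) / Fi
      rbeta(M, p_anc * shape_scale, (1 - p_anc) * shape_scale)
    }
    pop_freq[i, ] <- q
    n_hap <- 2L * config$samples_per_pop[i]
    H <- matrix(rbinom(n_hap * M, 1L, rep(q, each = n_hap)),
                nrow = n_hap, ncol = M)
    sid <- sprintf("%s_%02d", labels[i], seq_len(config$samples_per_pop[i]))
    rownames(H) <- paste0(rep(sid, each = 2), "_", c(1L, 2L))
    haplotypes[[i]] <- H
    samples[[i]] <- sid
  }

  truth <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), target_pop = character(0),
                      final_freq = numeric(0), n_snps = integer(0),
                      stringsAsFactors = FALSE)
  for (sw in config$sweeps) {
    span <- which(variants$chrom == sw$chrom &
                  variants$pos >= sw$center - sw$half_width &
                  variants$pos <= sw$center + sw$half_width)
    H <- haplotypes[[sw$target_pop]]
    n_hap <- nrow(H)
    n_car <- max(1L, round(sw$carrier_fraction * n_hap))
    carriers <- sample.int(n_hap, n_car)
    if (length(span) > 0) {
      H[carriers, span] <- 1L  # shared core haplotype: derived allele fixed
      c_real <- n_car / n_hap
      q_bg <- if (c_real >= 1) 0 else
        min(max((sw$final_freq - c_real) / (1 - c_real), 0), 1)
      non <- setdiff(seq_len(n_hap), carriers)
      if (length(non) > 0)
        H[non, span] <- matrix(rbinom(length(non) * length(span), 1L, q_bg),
                               nrow = length(non))
      pop_freq[sw$target_pop, span] <- c_real + (1 - c_real) * q_bg
      haplotypes[[sw$target_pop]] <- H
    }
    truth <- rbind(truth, data.frame(
      chrom = sw$chrom,
      start = as.integer(sw$center - sw$half_width),
      end = as.integer(sw$center + sw$half_width),
      target_pop = sw$target_pop, final_freq = sw$final_freq,
      n_snps = length(span), stringsAsFactors = FALSE))
  }

  if (config$missing_rate > 0) {
    for (i in seq_len(config$n_pops)) {
      H <- haplotypes[[i]]
      n_ind <- nrow(H) / 2L
      miss <- matrix(runif(n_ind * M) < config$missing_rate, n_ind, M)
      idx <- which(miss, arr.ind = TRUE)
      if (nrow(idx) > 0) {
        H[cbind(2L * idx[, 1] - 1L, idx[, 2])] <- NA_integer_
        H[cbind(2L * idx[, 1], idx[, 2])] <- NA_integer_
      }
      haplotypes[[i]] <- H
    }
  }

  structure(list(variants = variants, haplotypes = haplotypes,
                 samples = samples, phased = TRUE, truth = truth,
                 pop_freq = pop_freq, config = config),
            class = "hap_panel")
}

#' @export
print.hap_panel <- function(x, ...) {
  cat("hap_panel:", nrow(x$variants), "biallelic SNPs on",
      length(unique(x$variants$chrom)), "chromosome(s);",
      length(x$haplotypes), "population(s):",
      paste(sprintf("%s (%d)", names(x$samples),
                    vapply(x$samples, length, 1L)), collapse = ", "),
      if (isTRUE(x$phased)) "[phased]" else "[unphased]", "\n")
  if (!is.null(x$truth) && nrow(x$truth) > 0)
    cat("  truth sweeps:", nrow(x$truth), "\n")
  invisible(x)
}

#' Diploid genotype matrix (0/1/2 alt-allele dosage) for one population
#'
#' @param panel A `hap_panel`.
#' @param pop Population label.
#' @return `N x M` integer matrix, rownames = sample ids; `NA` where either
#'   haplotype call is missing.
#' @export
panel_genotypes <- function(panel, pop) {
  H <- panel$haplotypes[[pop]]
  if (is.null(H)) stop("unknown population '", pop, "'")
  n <- nrow(H) / 2L
  G <- H[2L * seq_len(n) - 1L, , drop = FALSE] +
       H[2L * seq_len(n), , drop = FALSE]
  rownames(G) <- panel$samples[[pop]]
  G
}

#' Write true sweep intervals as BED
#'
#' Emits 0-based half-open records (`start - 1`, `end`), one per sweep,
#' sorted by chromosome then start; an empty sweep list yields a file with
#' only the header comment.
#'
#' @param truth Data frame with `chrom`, `start`, `end` (1-based inclusive),
#'   e.g. the `truth` component of [simulate_populations()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_bed <- function(truth, path) {
  lines <- "# true sweep intervals (BED, 0-based half-open)"
  if (!is.null(truth) && nrow(truth) > 0) {
    o <- order(truth$chrom, truth$start)
    truth <- truth[o, , drop = FALSE]
    lines <- c(lines, sprintf("%s\t%d\t%d", truth$chrom,
                              as.integer(truth$start) - 1L,
                              as.integer(truth$end)))
  }
  writeLines(lines, path)
  invisible(path)
}
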