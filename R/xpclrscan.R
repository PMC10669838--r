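#' Linkage-disequilibrium down-weighting of SNPs in a window
#'
#' Pairwise r-squared between SNP columns is computed on the reference
#' population's phased haplotype alleles; SNPs are grouped by
#' single-linkage clustering on r-squared > `r2_cutoff` and each SNP's
#' weight is 1 / (cluster size), so a clique of duplicated columns carries
#' total weight 1. Monomorphic columns have undefined r-squared and are
#' never linked (weight 1).
#'
#' @param H `n x m` 0/1 reference haplotype matrix for the window's SNPs.
#' @param r2_cutoff Linkage cutoff (default 0.95).
#' @return Numeric vector of per-SNP weights in (0, 1]; length-0 input
#'   returns length-0 output.
#' @export
ld_weights <- function(H, r2_cutoff = 0.95) {
  m <- ncol(H)
  if (m == 0) return(numeric(0))
  if (m == 1) return(1)
  r2 <- suppressWarnings(stats::cor(H))^2
  r2[!is.finite(r2)] <- 0
  linked <- r2 > r2_cutoff
  # connected components by label propagation (single linkage)
  comp <- seq_len(m)
  repeat {
    changed <- FALSE
    for (i in seq_len(m)) {
      nb <- which(linked[i, ])
      new <- min(comp[c(i, nb)])
      if (new < comp[i]) { comp[c(i, nb)] <- new; changed <- TRUE }
      else if (any(comp[nb] > new)) { comp[nb] <- new; changed <- TRUE }
    }
    if (!changed) break
  }
  sizes <- table(comp)
  1 / as.numeric(sizes[as.character(comp)])
}

#' Drift parameter from genome-wide FST
#'
#' The neutral model drifts the object-population allele frequency around
#' the reference frequency p with variance `omega * p * (1 - p)`;
#' `omega = F / (1 - F)` maps the genome-wide divergence onto that scale.
#'
#' @param fst Genome-wide FST in (0, 1).
#' @return omega > 0.
#' @export
estimate_omega <- function(fst) {
  if (!is.finite(fst) || fst <= 0) stop("FST must be positive")
  if (fst >= 1) stop("FST must be < 1")
  fst / (1 - fst)
}

#' Composite log-likelihood ratio for one window
#'
#' Neutral model: the object-population frequency q of each SNP drifted
#' from the reference frequency p with variance `omega * p * (1 - p)`
#' (normal approximation, integrated over a 64-point grid on (0,1) with the
#' out-of-range normal mass placed as point masses on the boundaries);
#' the observed object allele count is binomial given q. Sweep model with
#' decay rate alpha (per bp): with probability `c = exp(-alpha * d)` at
#' distance d from the window center a lineage hitchhiked to fixation, so
#' the drift density is mixed with boundary masses (weight p on fixation of
#' the alternate allele, 1 - p on the reference allele):
#' `L_sweep = (1 - c) L_neutral + c (p [k = n] + (1 - p) [k = 0])`.
#' The raw score is `2 * max_alpha sum_i w_i (log L_sweep,i - log
#' L_neutral,i)`, floored at 0 (the alpha -> Inf limit is the neutral
#' model). Sites monomorphic in the reference are excluded; a window with
#' none left is `NA`.
#'
#' @param p_ref Reference alt-allele frequencies per SNP.
#' @param k_obj,n_obj Object-population alt-allele counts and total allele
#'   counts per SNP.
#' @param dist Distance of each SNP to the window center (bp).
#' @param weights Per-SNP weights from [ld_weights()].
#' @param omega Drift parameter from [estimate_omega()].
#' @param alpha_grid Selection decay grid (per bp); default 20 log-spaced
#'   points over 1e-6..1e-2.
#' @param n_quad Interior quadrature points (default 64).
#' @return Raw composite log-likelihood ratio (>= 0), or `NA`.
#' @export
window_cl_ratio <- function(p_ref, k_obj, n_obj, dist, weights, omega,
                            alpha_grid = 10^seq(-6, -2, length.out = 20),
                            n_quad = 64) {
  stopifnot(omega > 0)
  ok <- is.finite(p_ref) & p_ref > 0 & p_ref < 1 & is.finite(k_obj) &
    n_obj > 0
  if (!any(ok)) return(NA_real_)
  p <- p_ref[ok]; k <- k_obj[ok]; n <- n_obj[ok]
  d <- abs(dist[ok]); w <- weights[ok]
  m <- length(p)

  qg <- (seq_len(n_quad) - 0.5) / n_quad   # midpoint grid on (0,1)
  dq <- 1 / n_quad
  sigma <- sqrt(omega * p * (1 - p))
  dens <- outer(seq_len(m), seq_len(n_quad), function(i, j)
    stats::dnorm(qg[j], p[i], sigma[i])) * dq
  mass0 <- stats::pnorm(0, p, sigma)
  mass1 <- stats::pnorm(1, p, sigma, lower.tail = FALSE)
  tot <- rowSums(dens) + mass0 + mass1
  dens <- dens / tot; mass0 <- mass0 / tot; mass1 <- mass1 / tot

  B <- matrix(stats::dbinom(rep(k, n_quad), rep(n, n_quad),
                            rep(qg, each = m)), nrow = m)
  l_neut <- rowSums(dens * B) + mass0 * (k == 0) + mass1 * (k == n)
  boundary <- p * (k == n) + (1 - p) * (k == 0)

  best <- 0
  for (alpha in alpha_grid) {
    cc <- exp(-alpha * d)
    score <- sum(w * (log((1 - cc) * l_neut + cc * boundary) - log(l_neut)))
    if (is.finite(score) && score > best) best <- score
  }
  2 * best
}

#' Windowed composite likelihood scan over a panel
#'
#' Tiles each chromosome with non-overlapping windows from position 1
#' (default 25 kb; a final partial window is kept if it holds at least one
#' SNP), caps each window at `max_snps` SNPs by deterministic uniform
#' thinning along position, LD-down-weights SNPs with [ld_weights()] on
#' the reference haplotypes, scores each window with [window_cl_ratio()],
#' and z-normalizes the raw scores genome-wide into `xpclr_norm`.
#'
#' @param panel A phased `hap_panel`.
#' @param object,reference Population labels (object = putatively swept).
#' @param window Window length in bp (default 25000).
#' @param max_snps Per-window SNP cap (default 500).
#' @param ld_cutoff r-squared cutoff for weighting (default 0.95).
#' @param omega Drift parameter; default `estimate_omega()` of the
#'   genome-wide FST between the two populations.
#' @param alpha_grid,n_quad Passed to [window_cl_ratio()].
#' @return data.frame `chrom`, `start`, `end` (1-based inclusive),
#'   `n_snps`, `xpclr_raw`, `xpclr_norm`.
#' @export
xpclr_scan <- function(panel, object, reference, window = 25000L,
                       max_snps = 500L, ld_cutoff = 0.95, omega = NULL,
                       alpha_grid = 10^seq(-6, -2, length.out = 20),
                       n_quad = 64) {
  for (p in c(object, reference))
    if (is.null(panel$haplotypes[[p]])) stop("unknown population '", p, "'")
  v <- panel$variants
  GA <- panel_genotypes(panel, object)
  GB <- panel_genotypes(panel, reference)
  if (is.null(omega)) {
    cnt <- site_counts(list(A = GA, B = GB))
    omega <- estimate_omega(genomewide_fst(cnt))
  }
  nB <- colSums(!is.na(GB))
  p_ref <- ifelse(nB > 0, colSums(GB, na.rm = TRUE) / (2 * nB), NA_real_)
  k_obj <- colSums(GA, na.rm = TRUE)
  n_obj <- 2 * colSums(!is.na(GA))
  HB <- panel$haplotypes[[reference]]

  out <- list()
  for (chr in unique(v$chrom)) {
    on_chr <- which(v$chrom == chr)
    pos <- v$pos[on_chr]
    starts <- seq(1L, max(pos), by = window)
    for (ws in starts) {
      we <- ws + window - 1L
      idx <- on_chr[pos >= ws & pos <= we]
      if (length(idx) == 0) {
        out[[length(out) + 1]] <- data.frame(
          chrom = chr, start = ws, end = we, n_snps = 0L,
          xpclr_raw = NA_real_, stringsAsFactors = FALSE)
        next
      }
      if (length(idx) > max_snps)
        idx <- idx[unique(round(seq(1, length(idx),
                                    length.out = max_snps)))]
      w <- ld_weights(HB[, idx, drop = FALSE], ld_cutoff)
      center <- (ws + we) / 2
      raw <- window_cl_ratio(p_ref[idx], k_obj[idx], n_obj[idx],
                             v$pos[idx] - center, w, omega,
                             alpha_grid = alpha_grid, n_quad = n_quad)
      out[[length(out) + 1]] <- data.frame(
        chrom = chr, start = ws, end = we, n_snps = length(idx),
        xpclr_raw = raw, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res$xpclr_norm <- normalize_scores(res$xpclr_raw)
  res
}

#' Call the top fraction of windows
#'
#' `xpclr_norm` must be present (z-scores of the raw scores over finite
#' windows). The threshold is the k-th largest finite normalized score
#' with `k = max(1, floor(n_finite * top_fraction))`; every window at or
#' above the threshold is called, so ties at the boundary are all
#' included.
#'
#' @param windows data.frame from [xpclr_scan()].
#' @param top_fraction Fraction called (default 0.01).
#' @return The called subset of `windows`, with a `threshold` attribute.
#' @export
call_top_windows <- function(windows, top_fraction = 0.01) {
  z <- windows$xpclr_norm
  fin <- which(is.finite(z))
  if (length(fin) == 0) stop("no finite window scores")
  k <- max(1L, floor(length(fin) * top_fraction))
  thr <- sort(z[fin], decreasing = TRUE)[k]
  called <- windows[fin[z[fin] >= thr], , drop = FALSE]
  attr(called, "threshold") <- thr
  called
}
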