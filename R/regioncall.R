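#' Two-tier per-SNP significance classification
#'
#' FST track: *extremely significant* SNPs carry the top 0.01% of FST
#' values AND Bonferroni-corrected Fisher p < 0.01; *significant* SNPs have
#' FST >= 0.4 AND corrected p < 0.01. XP-EHH track: extreme = top 0.1% of
#' |normalized XP-EHH|; significant = |normalized XP-EHH| >= 1. Quantile
#' thresholds are computed genome-wide over finite scores of the
#' comparison, values exactly at the cutoff are included, and the stricter
#' label wins. `NA` sites are excluded from the quantile computation and
#' classified nonsignificant.
#'
#' @param scores data.frame with `fst` and `p_adj` columns (fst method) or
#'   an `xpehh_norm` column (xpehh method).
#' @param method `"fst"` or `"xpehh"`.
#' @param extreme_quantile Upper tail fraction for the extreme tier
#'   (default 1e-4 for fst, 1e-3 for xpehh).
#' @param fst_sig,p_sig,xpehh_sig Fixed significant-tier thresholds
#'   (defaults 0.4, 0.01, 1).
#' @return Factor vector of tiers `E` (extreme), `S` (significant), `N`.
#' @export
classify_snps <- function(scores, method = c("fst", "xpehh"),
                          extreme_quantile = NULL,
                          fst_sig = 0.4, p_sig = 0.01, xpehh_sig = 1) {
  method <- match.arg(method)
  if (nrow(scores) == 0) stop("empty score table")
  if (method == "fst") {
    if (is.null(extreme_quantile)) extreme_quantile <- 1e-4
    x <- scores$fst; p <- scores$p_adj
    fin <- is.finite(x)
    if (!any(fin)) stop("no finite FST values")
    k <- max(1L, floor(sum(fin) * extreme_quantile))
    thr <- sort(x[fin], decreasing = TRUE)[k]
    extreme <- fin & x >= thr & !is.na(p) & p < p_sig
    signif_ <- fin & x >= fst_sig & !is.na(p) & p < p_sig
  } else {
    if (is.null(extreme_quantile)) extreme_quantile <- 1e-3
    x <- abs(scores$xpehh_norm)
    fin <- is.finite(x)
    if (!any(fin)) stop("no finite XP-EHH values")
    k <- max(1L, floor(sum(fin) * extreme_quantile))
    thr <- sort(x[fin], decreasing = TRUE)[k]
    extreme <- fin & x >= thr
    signif_ <- fin & x >= xpehh_sig
  }
  tier <- rep("N", nrow(scores))
  tier[signif_] <- "S"
  tier[extreme] <- "E"
  factor(tier, levels = c("E", "S", "N"))
}

# Core tier-string region logic, shared by grow_regions().
#
# Seed-and-extend reading: from each extreme (E) SNP, extension in each
# direction crosses runs of 1-2 nonsignificant (N) SNPs (any E/S resets
# the counter) and stops at the first run of >= 3 consecutive N; the
# boundary is the outermost E/S SNP reached. A maximal stretch delimited
# the same way that has > 5 significant (S) SNPs and no E is also a
# region. Overlapping extensions merge. This is equivalent to: split the
# sequence at every run of >= 3 N; a fragment is a region iff it contains
# >= 1 E or > 5 S, spanning its first to last non-N site.
tier_regions <- function(tier) {
  tier <- as.character(tier)
  m <- length(tier)
  if (m == 0) return(matrix(integer(0), ncol = 2))
  r <- rle(tier == "N")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  breakrun <- r$values & r$lengths >= 3L
  # fragment boundaries between break runs
  frag_start <- c(1L, ends[breakrun] + 1L)
  frag_end <- c(starts[breakrun] - 1L, m)
  out <- matrix(integer(0), ncol = 2)
  for (f in seq_along(frag_start)) {
    lo <- frag_start[f]; hi <- frag_end[f]
    if (lo > hi) next
    seg <- tier[lo:hi]
    nE <- sum(seg == "E"); nS <- sum(seg == "S")
    if (nE >= 1L || nS > 5L) {
      sig <- which(seg != "N")
      out <- rbind(out, c(lo + sig[1] - 1L, lo + sig[length(sig)] - 1L))
    }
  }
  out
}

#' Grow selected regions from classified SNPs
#'
#' Within each chromosome (sites in position order), regions are seeded on
#' extremely significant SNPs and extended SNP-by-SNP in both directions
#' until more than two consecutive nonsignificant SNPs are met (a
#' significant or extreme SNP resets the counter); the region boundary is
#' the outermost significant-or-extreme SNP reached, so regions never
#' include trailing nonsignificant positions. A stretch delimited the same
#' way that contains more than five significant SNPs but no extreme SNP is
#' also called. Overlapping regions merge; chromosome ends terminate
#' extension.
#'
#' @param chrom,pos Per-SNP chromosome and position (sorted within
#'   chromosome).
#' @param tier Tier vector from [classify_snps()].
#' @param method Method label stored on each region.
#' @return data.frame `chrom`, `start`, `end` (bp, 1-based inclusive, at
#'   member SNP positions), `n_extreme`, `n_significant`, `n_snps` (span
#'   size in SNPs), `method`.
#' @export
grow_regions <- function(chrom, pos, tier, method = "fst") {
  stopifnot(length(chrom) == length(pos), length(pos) == length(tier))
  out <- list()
  for (chr in unique(chrom)) {
    idx <- which(chrom == chr)
    idx <- idx[order(pos[idx])]
    t_chr <- as.character(tier[idx])
    reg <- tier_regions(t_chr)
    if (nrow(reg) == 0) next
    for (k in seq_len(nrow(reg))) {
      span <- reg[k, 1]:reg[k, 2]
      out[[length(out) + 1]] <- data.frame(
        chrom = chr, start = pos[idx[reg[k, 1]]],
        end = pos[idx[reg[k, 2]]],
        n_extreme = sum(t_chr[span] == "E"),
        n_significant = sum(t_chr[span] == "S"),
        n_snps = length(span), method = method,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0)
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), n_extreme = integer(0),
                      n_significant = integer(0), n_snps = integer(0),
                      method = character(0), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Merge called windows into selected regions (XP-CLR track)
#'
#' Adjacent or overlapping called windows on one chromosome merge into one
#' region labelled `"xpclr"`.
#'
#' @param called data.frame from [call_top_windows()].
#' @return data.frame `chrom`, `start`, `end`, `n_windows`, `method`.
#' @export
regions_from_windows <- function(called) {
  if (nrow(called) == 0)
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), n_windows = integer(0),
                      method = character(0), stringsAsFactors = FALSE))
  out <- list()
  for (chr in unique(called$chrom)) {
    w <- called[called$chrom == chr, , drop = FALSE]
    w <- w[order(w$start), , drop = FALSE]
    cur_s <- w$start[1]; cur_e <- w$end[1]; n <- 1L
    flush <- function(s, e, n) data.frame(
      chrom = chr, start = s, end = e, n_windows = n, method = "xpclr",
      stringsAsFactors = FALSE)
    if (nrow(w) > 1) for (k in 2:nrow(w)) {
      if (w$start[k] <= cur_e + 1L) {
        cur_e <- max(cur_e, w$end[k]); n <- n + 1L
      } else {
        out[[length(out) + 1]] <- flush(cur_s, cur_e, n)
        cur_s <- w$start[k]; cur_e <- w$end[k]; n <- 1L
      }
    }
    out[[length(out) + 1]] <- flush(cur_s, cur_e, n)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
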