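#' Extended haplotype homozygosity decay curve
#'
#' EHH at site x is the probability that two haplotypes drawn without
#' replacement are identical at every site from the core out to x:
#' `sum_h C(c_h, 2) / C(n, 2)` over identity classes of size `c_h`. This is
#' the joint (unpartitioned-by-core-allele) variant used inside XP-EHH, so
#' EHH at distance 0 is 1 over all haplotypes. The curve is truncated when
#' EHH drops below `cutoff` (the first sub-cutoff point is retained so the
#' crossing can be interpolated), when a gap larger than `max_gap` bp is
#' met, or at the chromosome end.
#'
#' @param hap `n x M` 0/1 haplotype matrix (rows = haplotypes) for one
#'   chromosome, columns in position order.
#' @param pos Site positions (bp), strictly increasing.
#' @param core Core site index (1-based column).
#' @param direction `"left"` or `"right"`.
#' @param cutoff EHH truncation level (default 0.05).
#' @param max_gap Maximum inter-site gap in bp (default 200000).
#' @return An `ehh_curve`: list with `core`, `direction`, `distance` (bp
#'   from core) and `ehh`; distance 0 / EHH 1 is implicit.
#' @export
ehh <- function(hap, pos, core, direction = c("right", "left"),
                cutoff = 0.05, max_gap = 2e5) {
  direction <- match.arg(direction)
  if (nrow(hap) < 2) stop("EHH needs at least 2 haplotypes")
  stopifnot(ncol(hap) == length(pos), core >= 1, core <= ncol(hap))
  if (anyNA(hap)) stop("EHH requires complete haplotype calls")
  res <- ehh_side_cpp(hap, as.numeric(pos), as.integer(core),
                      if (direction == "right") 1L else -1L,
                      cutoff, max_gap)
  structure(list(core = core, direction = direction,
                 distance = res$distance, ehh = res$ehh,
                 cutoff = cutoff),
            class = "ehh_curve")
}

#' Integrated EHH over both directions
#'
#' Trapezoidal integration of the EHH decay over physical distance,
#' starting from the implicit point (0 bp, EHH = 1), both sides summed.
#' A side whose final point fell below the cutoff is integrated only up to
#' the linearly interpolated cutoff crossing; sides stopped by a gap or
#' the chromosome end integrate to their last point. A core with no
#' flanking site on either side returns `NA`.
#'
#' @param left,right `ehh_curve` objects sharing the same core (either may
#'   be `NULL` for a core at a chromosome edge).
#' @return iHH in bp-weighted homozygosity units.
#' @export
ihh <- function(left = NULL, right = NULL) {
  if (!is.null(left) && !is.null(right) && left$core != right$core)
    stop("curves must share the core site")
  one <- function(cv) {
    if (is.null(cv) || length(cv$distance) == 0) return(NA_real_)
    d <- c(0, cv$distance); e <- c(1, cv$ehh)
    area <- 0
    for (k in seq_along(cv$distance)) {
      if (e[k + 1] < cv$cutoff) {
        dcross <- d[k] + (d[k + 1] - d[k]) * (e[k] - cv$cutoff) /
          max(e[k] - e[k + 1], 1e-300)
        return(area + 0.5 * (dcross - d[k]) * (e[k] + cv$cutoff))
      }
      area <- area + 0.5 * (d[k + 1] - d[k]) * (e[k] + e[k + 1])
    }
    area
  }
  l <- one(left); r <- one(right)
  if (is.na(l) && is.na(r)) return(NA_real_)
  sum(c(l, r), na.rm = TRUE)
}

#' Cross-population XP-EHH scan
#'
#' For every site, iHH is computed in the object population A and the
#' reference population B (same variant table), and the raw statistic is
#' `ln(iHH_A / iHH_B)`. Sites where either iHH is `NA` or 0 get `NA`.
#' Positive raw values indicate longer haplotype homozygosity around the
#' site in the object population. Normalized z-scores (genome-wide) are
#' added by [normalize_scores()].
#'
#' @param panel A phased `hap_panel`.
#' @param object,reference Population labels: A (numerator) and B.
#' @param cutoff,max_gap See [ehh()].
#' @param normalize Add genome-wide z-scores (default TRUE; disable for
#'   degenerate panels, e.g. identical populations, where the raw scores
#'   have zero variance).
#' @return data.frame `chrom`, `pos`, `ihh_a`, `ihh_b`, `xpehh_raw`,
#'   `xpehh_norm` (`NA` when `normalize = FALSE`).
#' @export
xpehh_scan <- function(panel, object, reference, cutoff = 0.05,
                       max_gap = 2e5, normalize = TRUE) {
  if (!isTRUE(panel$phased))
    stop("XP-EHH requires phased haplotypes; this panel is unphased")
  for (p in c(object, reference))
    if (is.null(panel$haplotypes[[p]])) stop("unknown population '", p, "'")
  v <- panel$variants
  ihh_a <- ihh_b <- rep(NA_real_, nrow(v))
  for (chr in unique(v$chrom)) {
    idx <- which(v$chrom == chr)
    pos <- as.numeric(v$pos[idx])
    HA <- panel$haplotypes[[object]][, idx, drop = FALSE]
    HB <- panel$haplotypes[[reference]][, idx, drop = FALSE]
    if (anyNA(HA) || anyNA(HB))
      stop("XP-EHH requires complete haplotype calls; filter missing sites")
    ihh_a[idx] <- ihh_scan_cpp(HA, pos, cutoff, max_gap)
    ihh_b[idx] <- ihh_scan_cpp(HB, pos, cutoff, max_gap)
  }
  # log difference (not log of the ratio) keeps swap antisymmetry exact
  raw <- ifelse(!is.na(ihh_a) & !is.na(ihh_b) & ihh_a > 0 & ihh_b > 0,
                log(ihh_a) - log(ihh_b), NA_real_)
  data.frame(chrom = v$chrom, pos = v$pos, ihh_a = ihh_a, ihh_b = ihh_b,
             xpehh_raw = raw,
             xpehh_norm = if (normalize) normalize_scores(raw) else
               NA_real_,
             stringsAsFactors = FALSE)
}

#' Genome-wide z-normalization of a score vector
#'
#' `(x - mean) / sd` over all finite scores; `NA` propagated. Errors when
#' fewer than two finite scores exist or the variance is zero.
#'
#' @param x Numeric scores.
#' @return Normalized scores, same length.
#' @export
normalize_scores <- function(x) {
  fin <- is.finite(x)
  if (sum(fin) < 2) stop("normalization needs at least 2 finite scores")
  s <- sd(x[fin])
  if (s == 0) stop("normalization undefined: zero variance")
  out <- rep(NA_real_, length(x))
  out[fin] <- (x[fin] - mean(x[fin])) / s
  out
}
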