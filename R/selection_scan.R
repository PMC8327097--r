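## Windowed F_ST Z-score outlier scan and EHH / iHH / XP-EHH haplotype scan.

#' Per-SNP allele frequencies for two groups
#'
#' @param ds a [GenotypeDataset-class]
#' @param popA,popB population labels
#' @return data.frame with `p1`, `p2` (alternate-allele frequency per
#'   group) and `pr = (p1 + p2)/2` (unweighted mean across the two groups;
#'   set `weighted = TRUE` for sample-size-weighted pooling)
#' @param weighted use sample-size-weighted pooled frequency?
#' @export
popAlleleFreqs <- function(ds, popA, popB, weighted = FALSE) {
  pops <- unname(popLabels(ds))
  gA <- genotypes(ds)[, pops == popA, drop = FALSE]
  gB <- genotypes(ds)[, pops == popB, drop = FALSE]
  nA <- rowSums(!is.na(gA)); nB <- rowSums(!is.na(gB))
  p1 <- rowSums(gA, na.rm = TRUE) / (2 * nA)
  p2 <- rowSums(gB, na.rm = TRUE) / (2 * nB)
  pr <- if (weighted) (rowSums(gA, na.rm = TRUE) + rowSums(gB, na.rm = TRUE)) /
          (2 * (nA + nB))
        else (p1 + p2) / 2
  data.frame(p1 = p1, p2 = p2, pr = pr)
}

#' Per-SNP F_ST between two allele-frequency sets
#'
#' F_ST = 1 - (p1 q1 + p2 q2) / (2 pr qr), with q = 1 - p and pr the
#' across-group frequency.  SNPs with `pr qr = 0` (monomorphic in the
#' pooled sense) return `NA` and are counted by the caller.
#'
#' @param p1,p2 per-group alternate-allele frequencies
#' @param pr across-group frequency; default unweighted mean
#' @return numeric vector of per-SNP F_ST
#' @export
snpFst <- function(p1, p2, pr = (p1 + p2) / 2) {
  qr <- 1 - pr
  denom <- 2 * pr * qr
  ifelse(denom > 0, 1 - (p1 * (1 - p1) + p2 * (1 - p2)) / denom, NA_real_)
}

.tileWindows <- function(chrom_max, window_bp, step_bp) {
  if (chrom_max < window_bp) return(cbind(start = 1, stop = chrom_max))
  starts <- seq(1, chrom_max - window_bp + 1, by = step_bp)
  cbind(start = starts, stop = starts + window_bp - 1)
}

#' Sliding-window F_ST scan with Z-standardization
#'
#' Windows tile each chromosome from bp 1 (size `window_bp`, step
#' `step_bp`, kept while they fit inside the chromosome span); the window
#' statistic is the mean per-SNP F_ST ([snpFst()]).  Windows with fewer
#' than `min_snps` informative SNPs are dropped; the remainder are
#' standardized to Z(F_ST) using the mean and SD over all retained windows
#' of the comparison.  Candidates are the top 0.1% positive Z values
#' (ceiling(0.001 x windows) windows).
#'
#' @param ds a [GenotypeDataset-class]
#' @param popA,popB population labels (>= 2 samples each)
#' @param window_bp,step_bp window size and slide step (defaults 200 kb /
#'   60 kb)
#' @param min_snps minimum informative SNPs per window
#' @param top_fraction candidate fraction (default 0.001)
#' @param weighted sample-size-weighted pooled frequencies?
#' @return list with `windows` (chrom, start, stop, n_snps, fst, zfst,
#'   candidate), `mu`, `sigma`, and `per_snp` F_ST values
#' @export
windowFstScan <- function(ds, popA, popB, window_bp = 2e5, step_bp = 6e4,
                          min_snps = 3L, top_fraction = 0.001,
                          weighted = FALSE) {
  pops <- unname(popLabels(ds))
  if (sum(pops == popA) < 2L || sum(pops == popB) < 2L)
    stop("need >= 2 samples per group")
  fr <- popAlleleFreqs(ds, popA, popB, weighted = weighted)
  fst <- snpFst(fr$p1, fr$p2, fr$pr)
  chr <- chromOf(ds); pos <- posBp(ds)
  rows <- list()
  for (cc in unique(chr)) {
    sel <- chr == cc
    w <- .tileWindows(max(pos[sel]), window_bp, step_bp)
    for (k in seq_len(nrow(w))) {
      in_w <- sel & pos >= w[k, 1L] & pos <= w[k, 2L] & !is.na(fst)
      n <- sum(in_w)
      if (n < min_snps) next
      rows[[length(rows) + 1L]] <-
        data.frame(chrom = cc, start = w[k, 1L], stop = w[k, 2L],
                   n_snps = n, fst = mean(fst[in_w]))
    }
  }
  if (!length(rows)) stop("no windows with enough SNPs")
  win <- do.call(rbind, rows)
  mu <- mean(win$fst); sigma <- stats::sd(win$fst)
  if (!is.finite(sigma) || sigma == 0)
    stop("degenerate scan: all windows have identical F_ST")
  win$zfst <- (win$fst - mu) / sigma
  k <- ceiling(top_fraction * nrow(win))
  win$candidate <- rank(-win$zfst, ties.method = "first") <= k & win$zfst > 0
  per_snp <- data.frame(variant_id = variantIds(ds), chrom = chr, pos = pos,
                        p1 = fr$p1, p2 = fr$p2, fst = fst)
  list(windows = win, mu = mu, sigma = sigma, per_snp = per_snp,
       n_monomorphic_skipped = sum(is.na(fst)))
}

#' Candidate intervals from a window F_ST scan
#'
#' Overlapping candidate windows are merged into intervals tagged
#' `method = "FST"`.
#'
#' @param scan result of [windowFstScan()]
#' @param comparison comparison tag
#' @return a `GRanges`
#' @export
fstCandidateRegions <- function(scan, comparison = "comparison") {
  cand <- scan$windows[scan$windows$candidate, , drop = FALSE]
  if (!nrow(cand))
    return(genomicIntervals(character(0), integer(0), integer(0)))
  gr <- reduce(GRanges(cand$chrom, IRanges(cand$start, cand$stop)))
  genomicIntervals(as.character(seqnames(gr)), start(gr), end(gr),
                   method = "FST", comparison = comparison)
}

## EHH on one side of the core among a fixed set of haplotype columns.
## Returns the homozygosity sequence at each successive site, computed by
## refining haplotype-identity groups; EHH_j = sum_h C(n_h,2) / C(n,2).
.ehhSide <- function(h, carriers, site_order, truncation = 0) {
  n <- length(carriers)
  pairs_tot <- n * (n - 1) / 2
  g <- rep(1L, n)
  out <- numeric(length(site_order))
  for (k in seq_along(site_order)) {
    key <- g * 2L + h[site_order[k], carriers]
    g <- match(key, unique(key))
    cnt <- tabulate(g)
    out[k] <- sum(cnt * (cnt - 1) / 2) / pairs_tot
    if (out[k] < truncation) { out <- out[seq_len(k)]; break }
  }
  out
}

#' Extended haplotype homozygosity around a core SNP
#'
#' Among carriers of `core_allele` at the core site, EHH at displacement j
#' is the fraction of carrier pairs identical over the span core..j;
#' EHH(core) = 1 and the curve is non-increasing outward.  Computed in both
#' directions.
#'
#' @param hs a [HaplotypeSet-class] (complete phased data)
#' @param core_index variant row index of the core SNP
#' @param core_allele 0 or 1
#' @return list with `left` and `right` data frames (`index`, `pos`,
#'   `map_cm`, `ehh`, core row included first) and `n_carriers`
#' @export
ehh <- function(hs, core_index, core_allele) {
  h <- haplotypes(hs)
  chr <- chromOf(hs)
  on_c <- which(chr == chr[core_index])
  carriers <- which(h[core_index, ] == core_allele)
  if (length(carriers) < 2L)
    stop("fewer than 2 carriers of the core allele")
  pos <- posBp(hs); cm <- mapCm(hs)
  right_idx <- on_c[on_c > core_index]
  left_idx <- rev(on_c[on_c < core_index])
  side <- function(idx) {
    e <- if (length(idx)) .ehhSide(h, carriers, idx) else numeric(0)
    data.frame(index = c(core_index, idx[seq_along(e)]),
               pos = c(pos[core_index], pos[idx[seq_along(e)]]),
               map_cm = c(cm[core_index], cm[idx[seq_along(e)]]),
               ehh = c(1, e))
  }
  list(left = side(left_idx), right = side(right_idx),
       n_carriers = length(carriers))
}

#' Integrated EHH (iHH)
#'
#' Trapezoidal integral of the EHH curve over genetic distance (cM) on each
#' side of the core, truncated when EHH falls below `truncation` (points
#' past the crossing trapezoid contribute nothing); the two sides are
#' summed.  A curve that decays immediately gives 0.
#'
#' @param ehh_curve result of [ehh()]
#' @param truncation EHH truncation level (default 0.05)
#' @return scalar iHH in cM units
#' @export
ihh <- function(ehh_curve, truncation = 0.05) {
  one_side <- function(d) {
    if (nrow(d) < 2L) return(0)
    x <- abs(d$map_cm - d$map_cm[1L])
    y <- d$ehh
    total <- 0
    for (k in seq_len(nrow(d) - 1L)) {
      total <- total + (y[k] + y[k + 1L]) / 2 * (x[k + 1L] - x[k])
      if (y[k + 1L] < truncation) break
    }
    total
  }
  one_side(ehh_curve$left) + one_side(ehh_curve$right)
}

## Carrier classes for the site-level EHH of one population: each core
## allele with >= 2 carriers contributes its refinement groups, weighted by
## the allele frequency.  The weighted EHH at the core is the sum of the
## valid weights (1 when both alleles are scorable).
.coreClasses <- function(h, j) {
  x <- h[j, ]
  f1 <- mean(x)
  cls <- list()
  for (al in 0:1) {
    w <- if (al == 1L) f1 else 1 - f1
    car <- which(x == al)
    if (w > 0 && length(car) >= 2L)
      cls[[length(cls) + 1L]] <-
        list(w = w, car = car, g = rep(1L, length(car)),
             np = length(car) * (length(car) - 1) / 2)
  }
  cls
}

.classEhh <- function(cls) {
  e <- 0
  for (cl in cls) {
    cnt <- tabulate(cl$g)
    e <- e + cl$w * sum(cnt * (cnt - 1)) / 2 / cl$np
  }
  e
}

.refineClasses <- function(cls, h, site) {
  for (i in seq_along(cls)) {
    key <- cls[[i]]$g * 2L + h[site, cls[[i]]$car]
    cls[[i]]$g <- match(key, unique(key))
  }
  cls
}

## One-sided joint iHH: both populations are integrated over the same
## interval, stopping after the first trapezoid whose right endpoint has
## weighted EHH below `truncation` in BOTH populations (the shared-boundary
## convention of cross-population EHH scans).  Returns c(area_A, area_B)
## in cM units.
.pairIhhSide <- function(hA, hB, cm, idx, j, truncation) {
  clsA <- .coreClasses(hA, j)
  clsB <- .coreClasses(hB, j)
  eA <- .classEhh(clsA); eB <- .classEhh(clsB)
  areaA <- areaB <- 0
  x_prev <- 0
  cm0 <- cm[j]
  for (k in seq_along(idx)) {
    clsA <- .refineClasses(clsA, hA, idx[k])
    clsB <- .refineClasses(clsB, hB, idx[k])
    eA_new <- .classEhh(clsA); eB_new <- .classEhh(clsB)
    x <- abs(cm[idx[k]] - cm0)
    areaA <- areaA + (eA + eA_new) / 2 * (x - x_prev)
    areaB <- areaB + (eB + eB_new) / 2 * (x - x_prev)
    if (eA_new < truncation && eB_new < truncation) break
    eA <- eA_new; eB <- eB_new; x_prev <- x
  }
  c(areaA, areaB)
}

## Site-level iHH pair for both populations at one core SNP.
.sitePairIhh <- function(hA, hB, cm, chr_idx, j_local, truncation = 0.05) {
  j <- chr_idx[j_local]
  right <- chr_idx[seq_along(chr_idx) > j_local]
  left <- rev(chr_idx[seq_along(chr_idx) < j_local])
  .pairIhhSide(hA, hB, cm, left, j, truncation) +
    .pairIhhSide(hA, hB, cm, right, j, truncation)
}

#' Cross-population XP-EHH scan
#'
#' For every core SNP the site-level iHH (frequency-weighted over the two
#' core alleles) is computed in each population, both populations being
#' integrated over the same interval on each side of the core — the
#' integration stops where the weighted EHH has fallen below `truncation`
#' in both populations, so the two iHH values are directly comparable.
#' The raw statistic is
#' ln(iHH_A / iHH_B), standardized to Z over all defined SNPs of the scan,
#' with one-sided p-values per tail from the standard normal.  Large
#' positive values point to extended haplotypes (recent selection) in
#' population A.  SNPs where either iHH is 0 are flagged undefined and
#' excluded from standardization.
#'
#' @param hapsA,hapsB [HaplotypeSet-class] objects on the same variant grid
#' @param truncation EHH truncation (default 0.05)
#' @param min_maf cores with pooled minor allele frequency below this are
#'   skipped (default 0.05; near-fixed cores carry no haplotype signal)
#' @param p_threshold significance threshold (default 0.001)
#' @return data.frame with `variant_id`, `chrom`, `pos`, `ihh_a`, `ihh_b`,
#'   `raw`, `z`, `p_pos`, `p_neg`, `significant`, `direction`
#' @export
xpehhScan <- function(hapsA, hapsB, truncation = 0.05, min_maf = 0.05,
                      p_threshold = 0.001) {
  if (!identical(variantIds(hapsA), variantIds(hapsB)) ||
      !identical(posBp(hapsA), posBp(hapsB)))
    stop("populations must share the same variant grid")
  hA <- haplotypes(hapsA); hB <- haplotypes(hapsB)
  n_var <- nrow(hA)
  p_pool <- (rowMeans(hA) * ncol(hA) + rowMeans(hB) * ncol(hB)) /
    (ncol(hA) + ncol(hB))
  maf <- pmin(p_pool, 1 - p_pool)
  chr <- chromOf(hapsA); cm <- mapCm(hapsA)
  ihh_a <- ihh_b <- rep(NA_real_, n_var)
  for (cc in unique(chr)) {
    chr_idx <- which(chr == cc)
    for (jl in seq_along(chr_idx)) {
      j <- chr_idx[jl]
      if (maf[j] < min_maf) next
      pair <- .sitePairIhh(hA, hB, cm, chr_idx, jl, truncation)
      ihh_a[j] <- pair[1L]
      ihh_b[j] <- pair[2L]
    }
  }
  raw <- ifelse(!is.na(ihh_a) & !is.na(ihh_b) & ihh_a > 0 & ihh_b > 0,
                log(ihh_a / ihh_b), NA_real_)
  ok <- !is.na(raw)
  if (sum(ok) < 2L) stop("too few defined XP-EHH records")
  z <- rep(NA_real_, n_var)
  z[ok] <- (raw[ok] - mean(raw[ok])) / stats::sd(raw[ok])
  p_pos <- stats::pnorm(z, lower.tail = FALSE)
  p_neg <- stats::pnorm(z, lower.tail = TRUE)
  sig <- !is.na(z) & (p_pos < p_threshold | p_neg < p_threshold)
  data.frame(variant_id = variantIds(hapsA), chrom = chromOf(hapsA),
             pos = posBp(hapsA), ihh_a = ihh_a, ihh_b = ihh_b,
             raw = raw, z = z, p_pos = p_pos, p_neg = p_neg,
             significant = sig,
             direction = ifelse(!is.na(z) & z > 0, "A", "B"))
}

#' Merge significant scan SNPs into candidate intervals
#'
#' Significant SNPs of the same direction at most `merge_gap_bp` apart on a
#' chromosome are merged into one interval tagged `method = "XP-EHH"`.
#'
#' @param records data.frame from [xpehhScan()]
#' @param merge_gap_bp merge distance (default 200 kb)
#' @param comparison comparison tag
#' @return a `GRanges`
#' @export
significantRegions <- function(records, merge_gap_bp = 2e5,
                               comparison = "comparison") {
  sig <- records[records$significant, , drop = FALSE]
  if (!nrow(sig))
    return(genomicIntervals(character(0), integer(0), integer(0)))
  out <- list()
  for (dr in unique(sig$direction)) {
    s <- sig[sig$direction == dr, , drop = FALSE]
    for (cc in unique(s$chrom)) {
      p <- sort(s$pos[s$chrom == cc])
      brk <- c(0, which(diff(p) > merge_gap_bp), length(p))
      for (k in seq_len(length(brk) - 1L)) {
        seg <- p[(brk[k] + 1L):brk[k + 1L]]
        out[[length(out) + 1L]] <-
          data.frame(chrom = cc, start = min(seg), stop = max(seg),
                     direction = dr)
      }
    }
  }
  m <- do.call(rbind, out)
  gr <- genomicIntervals(m$chrom, m$start, m$stop,
                         method = "XP-EHH", comparison = comparison)
  mcols(gr)$direction <- m$direction
  gr
}
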