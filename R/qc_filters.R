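## Sample/variant quality control, identity-by-descent relatedness pruning,
## and linkage-disequilibrium pruning.  Threshold defaults follow common
## array-QC practice for livestock 600K data: samples > 10% missing out,
## SNPs with call rate < 90%, MAF < 1% or HWE exact p < 1e-10 out, Pi-HAT
## pruning at 0.1875, LD pruning at window 50 kb / step 5 kb / r^2 0.5.

#' QC threshold bundle
#'
#' @param max_sample_missing maximum tolerated per-sample missing fraction
#'   (samples with *more* than this are removed)
#' @param min_snp_call_rate minimum per-variant call rate
#' @param hwe_p_min minimum Hardy-Weinberg exact p-value
#' @param maf_min minimum minor allele frequency
#' @param pihat_cutoff relatedness pruning cutoff; 0.1875 is the midpoint of
#'   the expected Pi-HAT for 2nd-degree (0.25) and 3rd-degree (0.125)
#'   relatives
#' @param pihat_window reporting window (min, max) for Pi-HAT output
#' @param ld_window_kb,ld_step_kb,ld_r2_max LD pruning parameters
#' @return a list of class `qcThresholds`
#' @export
qcThresholds <- function(max_sample_missing = 0.10, min_snp_call_rate = 0.90,
                         hwe_p_min = 1e-10, maf_min = 0.01,
                         pihat_cutoff = 0.1875,
                         pihat_window = c(0.05, 1),
                         ld_window_kb = 50, ld_step_kb = 5,
                         ld_r2_max = 0.5) {
  stopifnot(max_sample_missing >= 0, max_sample_missing <= 1,
            min_snp_call_rate >= 0, min_snp_call_rate <= 1,
            hwe_p_min >= 0, hwe_p_min <= 1, maf_min >= 0, maf_min <= 0.5,
            pihat_cutoff >= 0, pihat_cutoff <= 1,
            ld_window_kb >= ld_step_kb)
  structure(as.list(environment()), class = "qcThresholds")
}

#' Hardy-Weinberg exact test
#'
#' Exact conditional test: given the allele counts, the p-value is the sum of
#' the probabilities of all heterozygote counts (same parity) that are no
#' more probable than the observed one.  The plain (not mid-) p-value is
#' returned.
#'
#' @param n_AA,n_Aa,n_aa genotype counts
#' @return p-value in (0, 1]
#' @export
hweExactP <- function(n_AA, n_Aa, n_aa) {
  stopifnot(n_AA >= 0, n_Aa >= 0, n_aa >= 0)
  n <- n_AA + n_Aa + n_aa
  if (n == 0L) stop("undefined: zero genotypes")
  nA <- 2L * n_AA + n_Aa
  ## feasible het counts share the parity of nA
  h <- seq(nA %% 2L, min(nA, 2L * n - nA), by = 2L)
  logp <- lgamma(n + 1) - lgamma((nA - h) / 2 + 1) - lgamma(h + 1) -
    lgamma(n - (nA + h) / 2 + 1) + h * log(2) -
    (lgamma(2 * n + 1) - lgamma(nA + 1) - lgamma(2 * n - nA + 1))
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- p[match(n_Aa, h)]
  min(1, sum(p[p <= obs * (1 + 1e-12)]))
}

.missingFraction <- function(g, margin) {
  apply(is.na(g), margin, mean)
}

.altFreq <- function(g) {
  rowMeans(g, na.rm = TRUE) / 2
}

.maf <- function(g) {
  p <- .altFreq(g)
  p[is.nan(p)] <- 0
  pmin(p, 1 - p)
}

#' Variant-level QC filter
#'
#' Keeps variants with call rate >= `min_snp_call_rate`, MAF >= `maf_min`
#' and HWE exact p >= `hwe_p_min` (all rules evaluated on the input
#' dataset).  The report lists per-rule removal counts; a variant can fail
#' several rules.
#'
#' @param ds a [GenotypeDataset-class]
#' @param thresholds a [qcThresholds()]
#' @return list with `dataset` (filtered) and `report`
#' @export
filterVariants <- function(ds, thresholds = qcThresholds()) {
  g <- genotypes(ds)
  if (!nrow(g)) stop("empty dataset")
  call_rate <- 1 - .missingFraction(g, 1L)
  maf <- .maf(g)
  hwe_p <- vapply(seq_len(nrow(g)), function(j) {
    gj <- g[j, ]; gj <- gj[!is.na(gj)]
    if (!length(gj)) return(1)
    hweExactP(sum(gj == 0L), sum(gj == 1L), sum(gj == 2L))
  }, numeric(1))
  fail_call <- call_rate < thresholds$min_snp_call_rate
  fail_maf <- maf < thresholds$maf_min
  fail_hwe <- hwe_p < thresholds$hwe_p_min
  keep <- !(fail_call | fail_maf | fail_hwe)
  if (!any(keep)) stop("all variants removed by QC")
  report <- list(n_in = nrow(g), n_kept = sum(keep),
                 removed_call_rate = sum(fail_call),
                 removed_maf = sum(fail_maf),
                 removed_hwe = sum(fail_hwe),
                 removed_ids = variantIds(ds)[!keep])
  list(dataset = ds[keep, ], report = report)
}

#' Sample-level QC filter
#'
#' Removes samples with *more* than `max_sample_missing` missing genotypes
#' (a sample at exactly the threshold is retained).
#'
#' @inheritParams filterVariants
#' @return list with `dataset` and `report`
#' @export
filterSamples <- function(ds, thresholds = qcThresholds()) {
  g <- genotypes(ds)
  if (!ncol(g)) stop("empty dataset")
  miss <- .missingFraction(g, 2L)
  keep <- miss <= thresholds$max_sample_missing
  if (!any(keep)) stop("all samples removed by QC")
  report <- list(n_in = ncol(g), n_kept = sum(keep),
                 removed_ids = sampleIds(ds)[!keep],
                 missing_fraction = miss)
  list(dataset = ds[, keep], report = report)
}

#' Method-of-moments Pi-HAT relatedness matrix
#'
#' For every sample pair, IBS0/IBS1/IBS2 counts over mutually genotyped SNPs
#' are combined with their allele-frequency expectations to solve for
#' P(IBD=0), P(IBD=1), P(IBD=2); probabilities are truncated to [0, 1] and
#' renormalized, and PI_HAT = P(IBD=2) + 0.5 P(IBD=1).  Allele frequencies
#' are estimated from the full sample set (or supplied).  Pairs with zero
#' overlapping genotyped SNPs get `NA`.
#'
#' @param ds a QC-filtered [GenotypeDataset-class]
#' @param freqs optional alternate-allele frequencies per variant
#' @return symmetric matrix of PI_HAT values, diagonal 1 by convention
#' @export
pihatMatrix <- function(ds, freqs = NULL) {
  g <- genotypes(ds)
  n <- ncol(g)
  if (is.null(freqs)) freqs <- .altFreq(g)
  p <- freqs; q <- 1 - p
  e0_ibs0 <- 2 * p^2 * q^2
  e0_ibs1 <- 4 * p^3 * q + 4 * p * q^3
  e0_ibs2 <- p^4 + q^4 + 4 * p^2 * q^2
  e1_ibs1 <- 2 * p * q
  e1_ibs2 <- 1 - e1_ibs1
  pihat <- matrix(NA_real_, n, n, dimnames = list(sampleIds(ds), sampleIds(ds)))
  diag(pihat) <- 1
  obs <- !is.na(g)
  for (i in seq_len(n - 1L)) {
    gi <- g[, i]
    for (j in seq((i + 1L), n)) {
      ok <- obs[, i] & obs[, j]
      m <- sum(ok)
      if (m == 0L) next
      d <- abs(gi[ok] - g[ok, j])
      N0 <- sum(d == 2L); N2 <- sum(d == 0L); N1 <- m - N0 - N2
      S00 <- sum(e0_ibs0[ok]); S10 <- sum(e0_ibs1[ok])
      S20 <- sum(e0_ibs2[ok])
      S11 <- sum(e1_ibs1[ok]); S21 <- sum(e1_ibs2[ok])
      P0 <- if (S00 > 0) N0 / S00 else 0
      P1 <- if (S11 > 0) (N1 - P0 * S10) / S11 else 0
      P2 <- (N2 - P0 * S20 - P1 * S21) / m
      pr <- pmin(pmax(c(P0, P1, P2), 0), 1)
      pr <- pr / sum(pr)
      pihat[i, j] <- pihat[j, i] <- pr[3L] + 0.5 * pr[2L]
    }
  }
  pihat
}

#' Pi-HAT pair report within a reporting window
#'
#' Mirrors the "genome --min --max" style report: pairs whose PI_HAT falls
#' inside the window, one row per pair.  The window affects reporting only,
#' never the pruning arithmetic.
#'
#' @param rel matrix from [pihatMatrix()]
#' @param window reporting window, default c(0.05, 1)
#' @return data.frame with `id1`, `id2`, `pihat`
#' @export
pihatReport <- function(rel, window = c(0.05, 1)) {
  idx <- which(upper.tri(rel) & rel >= window[1L] & rel <= window[2L],
               arr.ind = TRUE)
  out <- data.frame(id1 = rownames(rel)[idx[, 1L]],
                    id2 = colnames(rel)[idx[, 2L]],
                    pihat = rel[idx])
  out[order(-out$pihat), , drop = FALSE]
}

#' Greedy relatedness pruning
#'
#' While any pair exceeds the cutoff, remove the member involved in more
#' exceeding pairs (ties broken by higher missingness, then by later sample
#' order), until no pair exceeds the cutoff.  The default cutoff 0.1875 is
#' the midpoint between expected 2nd-degree (0.25) and 3rd-degree (0.125)
#' relatedness.
#'
#' @param rel matrix from [pihatMatrix()]
#' @param cutoff Pi-HAT cutoff
#' @param missingness optional per-sample missing fraction used in
#'   tie-breaks
#' @return list with `kept` and `removed` sample id vectors
#' @export
relatednessPrune <- function(rel, cutoff = 0.1875, missingness = NULL) {
  ids <- rownames(rel)
  if (is.null(missingness)) missingness <- stats::setNames(numeric(length(ids)), ids)
  keep <- rep(TRUE, length(ids))
  adj <- !is.na(rel) & rel > cutoff
  diag(adj) <- FALSE
  repeat {
    deg <- rowSums(adj[keep, keep, drop = FALSE])
    if (!any(deg > 0)) break
    cand <- which(deg == max(deg))
    kept_ids <- ids[keep]
    if (length(cand) > 1L) {
      mm <- missingness[kept_ids[cand]]
      cand <- cand[mm == max(mm)]
      cand <- cand[length(cand)]           # later sample order
    }
    keep[match(kept_ids[cand], ids)] <- FALSE
  }
  list(kept = ids[keep], removed = ids[!keep])
}

#' Sliding-window LD pruning
#'
#' Within each bp window (size `window_kb`, advancing by `step_kb`), while
#' any pair of retained variants has squared genotype-dosage correlation
#' above `r2_max`, the member of the strongest such pair with the lower MAF
#' is removed (tie: later position).  Windows are interpreted in kb.
#'
#' @param ds a [GenotypeDataset-class]
#' @param window_kb,step_kb,r2_max pruning parameters
#' @return list with `dataset` (pruned) and `removed` variant ids
#' @export
ldPrune <- function(ds, window_kb = 50, step_kb = 5, r2_max = 0.5) {
  g <- genotypes(ds)
  chr <- chromOf(ds); pos <- posBp(ds)
  maf <- .maf(g)
  keep <- rep(TRUE, nrow(g))
  win <- window_kb * 1000; stp <- step_kb * 1000
  for (cc in unique(chr)) {
    on_c <- which(chr == cc)
    cmax <- max(pos[on_c])
    start <- 1
    while (start <= cmax) {
      w <- on_c[keep[on_c] & pos[on_c] >= start & pos[on_c] < start + win]
      if (length(w) >= 2L) {
        repeat {
          r2 <- suppressWarnings(
            stats::cor(g[w, , drop = FALSE] |> t(),
                       use = "pairwise.complete.obs"))^2
          r2[!is.finite(r2)] <- 0
          diag(r2) <- 0
          if (max(r2) <= r2_max) break
          hit <- which(r2 == max(r2), arr.ind = TRUE)[1L, ]
          a <- w[hit[1L]]; b <- w[hit[2L]]
          drop <- if (maf[a] < maf[b]) a
                  else if (maf[b] < maf[a]) b
                  else max(a, b)            # tie: later position
          keep[drop] <- FALSE
          w <- setdiff(w, drop)
          if (length(w) < 2L) break
        }
      }
      start <- start + stp
    }
  }
  list(dataset = ds[keep, ], removed = variantIds(ds)[!keep])
}
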