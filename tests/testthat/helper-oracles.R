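suppressPackageStartupMessages(library(GenomicRanges))

## Independent brute-force oracles and fixture builders used across the
## suite.  Oracles recompute each quantity from first principles (full
## enumeration / O(n^2) scans) without sharing code with the package
## internals they check.

## ---- Hardy-Weinberg exact test by full enumeration ------------------------
## Enumerates every genotype configuration compatible with the observed
## allele counts and sums the probabilities of configurations no more
## probable than the observed one.
hweEnumOracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  nA <- 2 * n_AA + n_Aa
  hets <- seq(nA %% 2, min(nA, 2 * n - nA), by = 2)
  w <- vapply(hets, function(h) {
    aa <- (nA - h) / 2
    bb <- n - aa - h
    factorial(n) / (factorial(aa) * factorial(h) * factorial(bb)) * 2^h
  }, numeric(1))
  pr <- w / sum(w)
  obs <- pr[hets == n_Aa]
  sum(pr[pr <= obs * (1 + 1e-12)])
}

## ---- consecutive-method ROH by brute-force feasibility --------------------
## feasible(i, j): every inter-SNP gap <= max_gap, het count <= max_het,
## missing count <= max_missing -- checked from scratch for each sub-run.
## Feasibility is monotone under extension, so the greedy run starting at k
## is [k, J(k)] with J(k) the largest feasible end; the scan then restarts
## after the violating SNP (het/missing violation) or at the next SNP (gap
## violation).
bruteForceRoh <- function(pos, gcalls, params) {
  n <- length(pos)
  feasible <- function(i, j) {
    if (j > i && any(diff(pos[i:j]) > params$max_gap_bp)) return(FALSE)
    seg <- gcalls[i:j]
    sum(seg == 1L, na.rm = TRUE) <= params$max_het_per_run &&
      sum(is.na(seg)) <= params$max_missing_per_run
  }
  passes <- function(i, j) {
    len <- pos[j] - pos[i]
    (j - i + 1) >= params$min_consecutive_snps &&
      len >= params$min_length_bp && (j - i + 1) / len >= params$min_density
  }
  out <- list()
  k <- 1L
  while (k <= n) {
    J <- k
    for (j in seq(k, n)) if (feasible(k, j)) J <- j else break
    if (passes(k, J))
      out[[length(out) + 1L]] <- c(start = pos[k], stop = pos[J],
                                   n_snps = J - k + 1L)
    if (J == n) break
    gap_violation <- pos[J + 1L] - pos[J] > params$max_gap_bp
    k <- if (gap_violation) J + 1L else J + 2L
  }
  out
}

## ---- EHH by exhaustive distinct-haplotype counting ------------------------
## Concatenates the carrier alleles over the span core..j into strings and
## counts identical pairs directly.
ehhEnumOracle <- function(h, carriers, span_rows) {
  n <- length(carriers)
  strs <- apply(h[span_rows, carriers, drop = FALSE], 2, paste, collapse = "")
  cnt <- table(strs)
  sum(choose(cnt, 2)) / choose(n, 2)
}

## ---- interval overlap by O(n^2) scan --------------------------------------
bruteIntersect <- function(a, b) {
  ## a, b: data.frames with chrom, start, stop (1-based inclusive)
  out <- list()
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    if (a$chrom[i] != b$chrom[j]) next
    s <- max(a$start[i], b$start[j]); e <- min(a$stop[i], b$stop[j])
    if (s <= e)
      out[[length(out) + 1L]] <- data.frame(query = i, subject = j,
                                            overlap_start = s,
                                            overlap_stop = e,
                                            overlap_bp = e - s + 1L)
  }
  if (!length(out)) return(data.frame(query = integer(), subject = integer(),
                                      overlap_start = integer(),
                                      overlap_stop = integer(),
                                      overlap_bp = integer()))
  do.call(rbind, out)
}

## ---- fixture builders ------------------------------------------------------
## Random minor-coded genotype dataset (alternate allele is the minor or
## tied allele at every SNP, matching the reader's load-time convention).
randomDataset <- function(n_samples, n_variants, seed, missing_rate = 0,
                          n_chrom = 1) {
  set.seed(seed)
  p <- runif(n_variants, 0.1, 0.45)
  g <- matrix(rbinom(n_variants * n_samples, 2, rep(p, n_samples)),
              n_variants, n_samples)
  flip <- rowSums(g) > n_samples           # ensure alt is minor or tied
  g[flip, ] <- 2L - g[flip, ]
  if (missing_rate > 0) g[runif(length(g)) < missing_rate] <- NA_integer_
  chrom <- as.character(rep_len(seq_len(n_chrom), n_variants))
  pos <- unlist(lapply(split(seq_len(n_variants), chrom), function(ix)
    sort(sample.int(n_variants * 1000, length(ix)))))
  o <- order(chrom, pos)
  GenotypeDataset(g, chrom[o], pos[o])
}

randomHaplotypeSet <- function(n_samples, n_variants, seed) {
  set.seed(seed)
  p <- runif(n_variants, 0.1, 0.9)
  h <- matrix(rbinom(n_variants * 2 * n_samples, 1, rep(p, 2 * n_samples)),
              n_variants, 2 * n_samples)
  HaplotypeSet(h, rep("1", n_variants),
               sort(sample.int(n_variants * 1000, n_variants)))
}
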