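## Per-individual/per-population diversity statistics and Weir-Cockerham
## F_ST (variance-components estimator, ratio of averages over loci) with
## label-permutation significance.

#' Observed/expected heterozygosity and inbreeding
#'
#' Per individual: H_O = heterozygous calls / non-missing calls, and the
#' method-of-moments inbreeding coefficient
#' F = (O_hom - E_hom) / (M - E_hom), with the expected homozygous count
#' E_hom accumulated from sample allele frequencies over that individual's
#' M non-missing SNPs.  Per population: mean and SD of H_O and F across
#' individuals, and H_E = mean across SNPs of the unbiased expected
#' heterozygosity 2*p*q*n/(n-1) (SD across SNPs; the choice of axis for the
#' SD is stated in the output).  Populations with fewer than 2 samples get
#' `NA` H_E.
#'
#' @param ds a QC-filtered [GenotypeDataset-class]
#' @param he_sd_axis `"snps"` (default) or `"individuals"`: whether the H_E
#'   dispersion is taken across SNPs or across individuals' per-SNP values
#' @return list with `per_individual` and `per_population` data frames
#' @export
hetStats <- function(ds, he_sd_axis = c("snps", "individuals")) {
  he_sd_axis <- match.arg(he_sd_axis)
  g <- genotypes(ds)
  obs <- !is.na(g)
  n_j <- rowSums(obs)                       # samples genotyped per SNP
  p_j <- rowSums(g, na.rm = TRUE) / (2 * n_j)
  exp_hom_j <- 1 - 2 * p_j * (1 - p_j) * n_j / pmax(n_j - 1, 1)
  het <- !is.na(g) & g == 1L
  M <- colSums(obs)
  o_het <- colSums(het)
  h_o <- o_het / M
  o_hom <- M - o_het
  e_hom <- colSums(exp_hom_j * obs)
  f <- (o_hom - e_hom) / (M - e_hom)
  pops <- popLabels(ds)
  per_ind <- data.frame(sample_id = sampleIds(ds),
                        population = unname(pops),
                        n_nonmissing = M, h_o = h_o, f = f,
                        row.names = NULL)
  per_pop <- do.call(rbind, lapply(split(seq_along(pops), unname(pops)),
                                   function(ix) {
    sub <- g[, ix, drop = FALSE]
    nk <- rowSums(!is.na(sub))
    pk <- rowSums(sub, na.rm = TRUE) / (2 * nk)
    ok <- nk >= 2
    he_j <- ifelse(ok, 2 * pk * (1 - pk) * nk / pmax(nk - 1, 1), NA_real_)
    he_mean <- if (length(ix) >= 2) mean(he_j, na.rm = TRUE) else NA_real_
    he_sd <- if (length(ix) < 2) NA_real_
             else if (he_sd_axis == "snps") stats::sd(he_j, na.rm = TRUE)
             else stats::sd(colMeans(2 * pk * (1 - pk) + 0 * sub, na.rm = TRUE))
    data.frame(population = unname(pops)[ix[1L]], n = length(ix),
               ho_mean = mean(h_o[ix]), ho_sd = stats::sd(h_o[ix]),
               he_mean = he_mean, he_sd = he_sd,
               f_mean = mean(f[ix]), f_sd = stats::sd(f[ix]))
  }))
  rownames(per_pop) <- NULL
  attr(per_pop, "he_sd_axis") <- he_sd_axis
  list(per_individual = per_ind, per_population = per_pop)
}

## Per-locus WC84 variance components for a two-group split.
## Returns sum(a) and sum(a+b+c) over usable loci.
.wcComponents <- function(NM, DOS, HET, zA, zB) {
  n1 <- as.vector(NM %*% zA); n2 <- as.vector(NM %*% zB)
  ok <- n1 >= 1 & n2 >= 1 & (n1 + n2) > 2
  s1 <- as.vector(DOS %*% zA); s2d <- as.vector(DOS %*% zB)
  h1 <- as.vector(HET %*% zA) / n1
  h2 <- as.vector(HET %*% zB) / n2
  p1 <- s1 / (2 * n1); p2 <- s2d / (2 * n2)
  nbar <- (n1 + n2) / 2
  nc <- 2 * nbar - (n1^2 + n2^2) / (2 * nbar)
  pbar <- (n1 * p1 + n2 * p2) / (2 * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / nbar
  hbar <- (n1 * h1 + n2 * h2) / (2 * nbar)
  pq <- pbar * (1 - pbar)
  a <- (nbar / nc) * (s2 - (pq - s2 / 2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) * (pq - s2 / 2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  ok <- ok & is.finite(a) & is.finite(b) & is.finite(cc) & nc > 0
  c(sum(a[ok]), sum((a + b + cc)[ok]))
}

#' Pairwise Weir-Cockerham F_ST with permutation significance
#'
#' Multi-locus theta is the ratio of summed per-locus `a` components over
#' summed `a + b + c` (ratio of averages).  Significance comes from
#' permuting population labels among the two groups' samples:
#' p = (1 + #\{theta_perm >= theta_obs\}) / (n_perm + 1).
#'
#' @param ds a [GenotypeDataset-class]
#' @param popA,popB population labels to compare (>= 2 samples each)
#' @param n_perm number of label permutations (0 skips the test)
#' @param seed RNG seed for the permutations
#' @return list with `theta`, `p_value`, `n_perm`
#' @export
wcFst <- function(ds, popA, popB, n_perm = 1000L, seed = 1L) {
  pops <- unname(popLabels(ds))
  ix <- which(pops %in% c(popA, popB))
  if (sum(pops == popA) < 2L || sum(pops == popB) < 2L)
    stop("need >= 2 samples per population")
  g <- genotypes(ds)[, ix, drop = FALSE]
  z <- pops[ix]
  NM <- (!is.na(g)) * 1
  DOS <- g; DOS[is.na(DOS)] <- 0L
  HET <- (g == 1L & !is.na(g)) * 1
  zA <- as.numeric(z == popA); zB <- 1 - zA
  comp <- .wcComponents(NM, DOS, HET, zA, zB)
  if (comp[2L] == 0) stop("theta undefined: no polymorphic loci")
  theta <- comp[1L] / comp[2L]
  p_value <- NA_real_
  if (n_perm > 0L) {
    set.seed(seed)
    hits <- 0L
    for (b in seq_len(n_perm)) {
      zp <- sample(zA)
      cp <- .wcComponents(NM, DOS, HET, zp, 1 - zp)
      tp <- if (cp[2L] == 0) 0 else cp[1L] / cp[2L]
      if (tp >= theta) hits <- hits + 1L
    }
    p_value <- (1 + hits) / (n_perm + 1)
  }
  list(theta = theta, p_value = p_value, n_perm = n_perm)
}

#' All-pairs F_ST distance matrix
#'
#' Convenience wrapper around [wcFst()] for every population pair; the
#' resulting symmetric matrix (negative estimates floored at 0) is the
#' genetic-distance input for [njTree()].
#'
#' @param ds a [GenotypeDataset-class]
#' @param n_perm permutations per pair (default 0: no p-values)
#' @param seed RNG seed
#' @return list with `theta` (symmetric matrix, zero diagonal) and
#'   `p_value` matrix
#' @export
pairwiseFstMatrix <- function(ds, n_perm = 0L, seed = 1L) {
  pops <- sort(unique(unname(popLabels(ds))))
  k <- length(pops)
  th <- matrix(0, k, k, dimnames = list(pops, pops))
  pv <- matrix(NA_real_, k, k, dimnames = list(pops, pops))
  for (i in seq_len(k - 1L)) for (j in seq((i + 1L), k)) {
    res <- wcFst(ds, pops[i], pops[j], n_perm = n_perm, seed = seed)
    th[i, j] <- th[j, i] <- max(res$theta, 0)
    pv[i, j] <- pv[j, i] <- res$p_value
  }
  list(theta = th, p_value = pv)
}
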