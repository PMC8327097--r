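## LD decay curves and effective-population-size trajectories via Sved's
## relation N_E(t) = (1/4c)(1/r2 - 1), with t = 1/(2c).

#' Pairwise genotype-dosage r-squared
#'
#' Squared Pearson correlation of genotype dosages (composite LD, no EM
#' haplotyping) for all within-chromosome variant pairs up to `max_dist_bp`
#' apart.  Genetic distance per pair comes from the dataset's `map_cm`
#' column when present, otherwise from the constant-rate default 1 cM/Mb
#' (c = bp x 1e-8 Morgan).  Pairs involving a zero-variance SNP are skipped
#' and counted in `attr(, "n_skipped")`.
#'
#' @param ds a QC-filtered [GenotypeDataset-class] (MAF filter applied)
#' @param max_dist_bp maximum pair distance in bp (default 5 Mb)
#' @param thin_to optional cap on the number of pairs (deterministic
#'   subsample under `seed`)
#' @param seed RNG seed used only when thinning
#' @return data.frame: `id1`, `id2`, `chrom`, `dist_bp`, `dist_morgan`,
#'   `r2`
#' @export
pairwiseR2 <- function(ds, max_dist_bp = 5e6, thin_to = NULL, seed = 1L) {
  g <- genotypes(ds)
  chr <- chromOf(ds); pos <- posBp(ds)
  rd <- rowData(ds)
  cm <- if ("map_cm" %in% colnames(rd) && any(rd$map_cm > 0)) rd$map_cm
        else pos * 1e-6
  v <- apply(g, 1L, stats::var, na.rm = TRUE)
  out <- list(); skipped <- 0L
  for (cc in unique(chr)) {
    sel <- which(chr == cc)
    for (ii in seq_along(sel)) {
      i <- sel[ii]
      js <- sel[ii + which(pos[sel[-seq_len(ii)]] - pos[i] <= max_dist_bp)]
      if (!length(js)) next
      ok <- !is.na(v[js]) & v[js] > 0
      skipped <- skipped + sum(!ok)
      if (is.na(v[i]) || v[i] == 0) { skipped <- skipped + sum(ok); next }
      js <- js[ok]
      if (!length(js)) next
      r <- suppressWarnings(stats::cor(g[i, ], t(g[js, , drop = FALSE]),
                                       use = "pairwise.complete.obs"))
      out[[length(out) + 1L]] <- data.frame(
        id1 = variantIds(ds)[i], id2 = variantIds(ds)[js], chrom = cc,
        dist_bp = pos[js] - pos[i],
        dist_morgan = abs(cm[js] - cm[i]) / 100,
        r2 = as.vector(r)^2)
    }
  }
  res <- if (length(out)) do.call(rbind, out)
         else data.frame(id1 = character(), id2 = character(),
                         chrom = character(), dist_bp = numeric(),
                         dist_morgan = numeric(), r2 = numeric())
  res <- res[!is.na(res$r2), , drop = FALSE]
  rownames(res) <- NULL
  if (!is.null(thin_to) && nrow(res) > thin_to) {
    set.seed(seed)
    res <- res[sort(sample.int(nrow(res), thin_to)), , drop = FALSE]
  }
  attr(res, "n_skipped") <- skipped
  res
}

#' LD decay curve
#'
#' Arithmetic mean r-squared per physical-distance bin.
#'
#' @param pairs data.frame from [pairwiseR2()]
#' @param bin_edges_bp increasing bin edges in bp
#' @return data.frame: `bin_mid_bp`, `mean_r2`, `n_pairs` (empty bins have
#'   `NA` mean and 0 pairs)
#' @export
ldDecay <- function(pairs, bin_edges_bp) {
  if (!nrow(pairs)) stop("no pairs")
  stopifnot(length(bin_edges_bp) >= 2L, !is.unsorted(bin_edges_bp))
  bin <- cut(pairs$dist_bp, bin_edges_bp, include.lowest = TRUE)
  mid <- (bin_edges_bp[-1L] + bin_edges_bp[-length(bin_edges_bp)]) / 2
  mean_r2 <- tapply(pairs$r2, bin, mean)
  n <- tapply(pairs$r2, bin, length)
  data.frame(bin_mid_bp = mid,
             mean_r2 = as.vector(mean_r2),
             n_pairs = ifelse(is.na(n), 0L, as.vector(n)),
             row.names = NULL)
}

#' Effective population size trajectory (Sved's relation)
#'
#' For each t in `t_grid`: the target genetic distance is c* = 1/(2t);
#' pairs with c within `c* * [1 - tolerance, 1 + tolerance]` contribute
#' their mean r-squared (optionally reduced by the 1/n chromosome-sample
#' correction), and N_E(t) = (1/(4 c*)) (1/r2 - 1).  Bins with fewer than
#' `min_pairs` pairs are flagged unreliable; r2 >= 1 gives N_E = 0 and an
#' adjusted r2 <= 0 is flagged unstable (`NA`).
#'
#' @param pairs data.frame from [pairwiseR2()]
#' @param t_grid generations-ago grid (positive)
#' @param tolerance relative half-width of the c-bin (default 0.1)
#' @param sample_size_adj subtract 1/n from mean r2? Off by default (the
#'   bare Sved relation)
#' @param n_samples diploid sample count, required when adjusting
#' @param min_pairs reliability threshold per bin
#' @return data.frame: `t`, `c`, `n_pairs`, `mean_r2`, `ne`, `reliable`
#' @export
neTrajectory <- function(pairs, t_grid = round(exp(seq(log(4), log(1000),
                                                       length.out = 25))),
                         tolerance = 0.1, sample_size_adj = FALSE,
                         n_samples = NULL, min_pairs = 50L) {
  stopifnot(all(t_grid > 0))
  if (sample_size_adj && is.null(n_samples))
    stop("n_samples required for the sample-size adjustment")
  res <- lapply(t_grid, function(t) {
    c_star <- 1 / (2 * t)
    sel <- pairs$dist_morgan >= c_star * (1 - tolerance) &
           pairs$dist_morgan <= c_star * (1 + tolerance)
    n <- sum(sel)
    if (n == 0L)
      return(data.frame(t = t, c = c_star, n_pairs = 0L,
                        mean_r2 = NA_real_, ne = NA_real_,
                        reliable = FALSE))
    r2 <- mean(pairs$r2[sel])
    r2a <- if (sample_size_adj) r2 - 1 / n_samples else r2
    ne <- if (r2a >= 1) 0
          else if (r2a <= 0) NA_real_          # unstable under adjustment
          else (1 / (4 * c_star)) * (1 / r2a - 1)
    data.frame(t = t, c = c_star, n_pairs = n, mean_r2 = r2, ne = ne,
               reliable = n >= min_pairs & !is.na(ne))
  })
  do.call(rbind, res)
}

#' Closed-form Sved N_E evaluation
#'
#' @param r2 mean r-squared
#' @param c genetic distance in Morgan
#' @return N_E = (1/(4c))(1/r2 - 1)
#' @export
svedNe <- function(r2, c) {
  stopifnot(c > 0, r2 > 0)
  (1 / (4 * c)) * (1 / r2 - 1)
}
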