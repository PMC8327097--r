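## Genotype PCA and neighbor-joining tree from a pairwise F_ST distance
## matrix.

#' PCA of the genotype matrix
#'
#' Missing genotypes are mean-imputed per SNP; each SNP column is centered
#' by 2*p and, under Patterson scaling (the default), divided by
#' sqrt(2*p*(1-p)).  Sample coordinates are eigenvectors of the sample
#' covariance scaled by the square root of their eigenvalues; variance
#' fractions are eigenvalue shares.
#'
#' @param ds a QC-filtered, LD-pruned [GenotypeDataset-class]
#' @param k number of components (truncated to the matrix rank with a
#'   warning if larger)
#' @param scaling `"patterson"` or `"center"` (plain centering)
#' @return list with `coords` (samples x k), `var_frac`, `population`
#' @export
pcaGenotypes <- function(ds, k = 10L, scaling = c("patterson", "center")) {
  scaling <- match.arg(scaling)
  g <- genotypes(ds)
  p <- rowMeans(g, na.rm = TRUE) / 2
  poly <- !is.na(p) & p > 0 & p < 1
  g <- g[poly, , drop = FALSE]; p <- p[poly]
  x <- g - 2 * p
  x[is.na(x)] <- 0                       # mean imputation after centering
  if (scaling == "patterson") x <- x / sqrt(2 * p * (1 - p))
  m <- nrow(x)
  cov_s <- crossprod(x) / m              # samples x samples
  eig <- eigen(cov_s, symmetric = TRUE)
  ev <- pmax(eig$values, 0)
  rank <- sum(ev > max(ev) * 1e-10)
  if (k > rank) {
    warning("k exceeds matrix rank; truncated to ", rank)
    k <- rank
  }
  coords <- eig$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(ev[seq_len(k)]), k)
  rownames(coords) <- sampleIds(ds)
  colnames(coords) <- sprintf("PC%d", seq_len(k))
  list(coords = coords, var_frac = ev[seq_len(k)] / sum(ev),
       population = unname(popLabels(ds)))
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining (standard Q-matrix selection and
#' branch-length formulas).  Negative branch lengths are clamped to zero
#' with the deficit moved to the adjacent branch, so path lengths between
#' the affected tips are preserved where possible.
#'
#' @param dist_matrix symmetric non-negative matrix with zero diagonal and
#'   taxa names (e.g. `pairwiseFstMatrix(ds)$theta`)
#' @return an `ape::phylo` tree
#' @export
njTree <- function(dist_matrix) {
  d <- as.matrix(dist_matrix)
  if (!isSymmetric(unname(d), tol = 1e-8)) stop("distance matrix must be symmetric")
  if (nrow(d) < 3L) stop("need >= 3 taxa")
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <-
      sprintf("t%d", seq_len(nrow(d)))
  tr <- ape::nj(stats::as.dist(d))
  neg <- which(tr$edge.length < 0)
  for (e in neg) {
    deficit <- -tr$edge.length[e]
    tr$edge.length[e] <- 0
    node <- tr$edge[e, 1L]                       # parent of the negative edge
    adj <- setdiff(which(tr$edge[, 1L] == node | tr$edge[, 2L] == node), e)
    if (length(adj)) {
      tgt <- adj[which.max(tr$edge.length[adj])]
      tr$edge.length[tgt] <- tr$edge.length[tgt] + deficit
    }
  }
  tr
}

#' Newick text for a tree
#'
#' @param tree an `ape::phylo` (see [njTree()])
#' @param file optional path; when `NULL` the Newick string is returned
#' @return Newick string (invisibly when written to file)
#' @export
njNewick <- function(tree, file = NULL) {
  txt <- ape::write.tree(tree)
  if (!is.null(file)) { writeLines(txt, file); return(invisible(txt)) }
  txt
}
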