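## Consecutive-method runs of homozygosity, genomic inbreeding (F_ROH),
## group ROH islands, and private islands.

#' ROH detection parameters
#'
#' Defaults follow the usual consecutive-method settings for 600K array
#' data: runs of at least 50 consecutive SNPs spanning at least 1 Mb, at
#' most 1 heterozygous and 5 missing calls per run, density at least
#' 1 SNP / 100 kb, and no gap between consecutive SNPs above 1 Mb.  The
#' sliding-window SNP count of window-based detectors is redundant under
#' the consecutive method and is recorded only.
#'
#' @param min_snps_window recorded for provenance; not separately enforced
#' @param min_length_bp minimum run span in bp
#' @param min_consecutive_snps minimum SNPs per run
#' @param max_het_per_run maximum heterozygous calls per run
#' @param max_missing_per_run maximum missing calls per run
#' @param min_density minimum SNP density (SNPs per bp; default 1/100 kb)
#' @param max_gap_bp maximum gap between consecutive SNPs in a run
#' @return a list of class `rohParams`
#' @export
rohParams <- function(min_snps_window = 50L, min_length_bp = 1e6,
                      min_consecutive_snps = 50L, max_het_per_run = 1L,
                      max_missing_per_run = 5L, min_density = 1 / 1e5,
                      max_gap_bp = 1e6) {
  stopifnot(min_length_bp > 0, min_consecutive_snps > 0,
            max_het_per_run >= 0, max_missing_per_run >= 0,
            min_density > 0, max_gap_bp > 0)
  structure(as.list(environment()), class = "rohParams")
}

## Greedy consecutive scan of one sample on one chromosome.  Runs grow while
## the heterozygote/missing budgets and the gap rule hold; a budget
## violation closes the run at the last compliant SNP and restarts after the
## violating SNP, a gap violation restarts at the next SNP.  Because run
## feasibility is monotone (budgets only grow with extension), each closed
## run is the maximal feasible extension of its start.
.scanConsecutive <- function(pos, gcalls, params) {
  n <- length(pos)
  runs <- list()
  close_run <- function(a, b) {
    if (b < a) return()
    seg <- gcalls[a:b]
    n_snps <- b - a + 1L
    len <- pos[b] - pos[a]
    if (n_snps >= params$min_consecutive_snps &&
        len >= params$min_length_bp &&
        n_snps / len >= params$min_density)
      runs[[length(runs) + 1L]] <<- c(pos[a], pos[b], n_snps,
                                      sum(seg == 1L, na.rm = TRUE),
                                      sum(is.na(seg)))
  }
  k <- 1L
  while (k <= n) {
    het <- if (!is.na(gcalls[k]) && gcalls[k] == 1L) 1L else 0L
    mis <- if (is.na(gcalls[k])) 1L else 0L
    j <- k
    restart <- n + 1L
    while (j < n) {
      nxt <- j + 1L
      if (pos[nxt] - pos[j] > params$max_gap_bp) { restart <- nxt; break }
      het2 <- het + (!is.na(gcalls[nxt]) && gcalls[nxt] == 1L)
      mis2 <- mis + is.na(gcalls[nxt])
      if (het2 > params$max_het_per_run ||
          mis2 > params$max_missing_per_run) { restart <- nxt + 1L; break }
      het <- het2; mis <- mis2; j <- nxt
    }
    close_run(k, j)
    k <- restart
  }
  runs
}

#' Detect runs of homozygosity (consecutive method)
#'
#' Scans each sample and chromosome for maximal runs of consecutive SNPs
#' satisfying all [rohParams()] constraints.  Runs are non-overlapping per
#' sample/chromosome; the segment length is `stop_bp - start_bp` (first to
#' last SNP of the run).
#'
#' @param ds a [GenotypeDataset-class] (positions must be sorted; the
#'   container guarantees this, and unsorted input is an error, never a
#'   silent re-sort)
#' @param params a [rohParams()]
#' @return data.frame of segments: `sample_id`, `chrom`, `start_bp`,
#'   `stop_bp`, `n_snps`, `n_het`, `n_missing`, `length_bp`
#' @export
detectRoh <- function(ds, params = rohParams()) {
  chr <- chromOf(ds); pos <- posBp(ds)
  for (cc in unique(chr))
    if (is.unsorted(pos[chr == cc], strictly = TRUE))
      stop("positions must be strictly increasing within chromosome")
  g <- genotypes(ds)
  out <- list()
  for (i in seq_len(ncol(g))) {
    for (cc in unique(chr)) {
      sel <- chr == cc
      runs <- .scanConsecutive(pos[sel], g[sel, i], params)
      for (r in runs)
        out[[length(out) + 1L]] <-
          data.frame(sample_id = sampleIds(ds)[i], chrom = cc,
                     start_bp = r[1L], stop_bp = r[2L], n_snps = r[3L],
                     n_het = r[4L], n_missing = r[5L],
                     length_bp = r[2L] - r[1L])
    }
  }
  if (!length(out))
    return(data.frame(sample_id = character(), chrom = character(),
                      start_bp = numeric(), stop_bp = numeric(),
                      n_snps = integer(), n_het = integer(),
                      n_missing = integer(), length_bp = numeric()))
  do.call(rbind, out)
}

#' Genomic inbreeding from ROH (F_ROH)
#'
#' F_ROH = total ROH length / autosome length (default 2.45 Gb, the sheep
#' autosomal genome).  Samples without segments get 0.
#'
#' @param segments data.frame from [detectRoh()]
#' @param sample_ids all samples to report (including segment-free ones)
#' @param autosome_length_bp denominator, default 2.45e9
#' @return data.frame with per-sample `total_mb`, `mean_segment_mb`,
#'   `n_segments`, `f_roh`
#' @export
froh <- function(segments, sample_ids, autosome_length_bp = 2.45e9) {
  tot <- tapply(segments$length_bp, segments$sample_id, sum)
  cnt <- tapply(segments$length_bp, segments$sample_id, length)
  total <- ifelse(is.na(tot[sample_ids]), 0, tot[sample_ids])
  nseg <- ifelse(is.na(cnt[sample_ids]), 0L, cnt[sample_ids])
  data.frame(sample_id = sample_ids,
             n_segments = as.integer(nseg),
             total_mb = total / 1e6,
             mean_segment_mb = ifelse(nseg > 0, total / nseg / 1e6, 0),
             f_roh = total / autosome_length_bp,
             row.names = NULL)
}

#' Per-SNP ROH occupancy within a group
#'
#' Fraction of the group's samples whose ROH segments cover each SNP — the
#' Manhattan-plot quantity behind island calling.
#'
#' @param segments data.frame from [detectRoh()]
#' @param group_samples sample ids forming the group
#' @param ds the [GenotypeDataset-class] the segments came from
#' @return numeric vector, one occupancy per variant of `ds`
#' @export
rohOccupancy <- function(segments, group_samples, ds) {
  if (!length(group_samples)) stop("empty group")
  chr <- chromOf(ds); pos <- posBp(ds)
  cov <- numeric(length(pos))
  seg <- segments[segments$sample_id %in% group_samples, , drop = FALSE]
  for (i in seq_len(nrow(seg)))
    cov <- cov + (chr == seg$chrom[i] &
                  pos >= seg$start_bp[i] & pos <= seg$stop_bp[i])
  cov / length(group_samples)
}

#' Group ROH islands
#'
#' Maximal runs of consecutive SNPs whose ROH occupancy within the group is
#' at least `freq_threshold` (default 50%) become island intervals spanning
#' the first to last qualifying SNP.
#'
#' @inheritParams rohOccupancy
#' @param freq_threshold occupancy threshold in (0, 1]
#' @param group_name tag recorded in the `comparison` column
#' @return `GRanges` of islands tagged `method = "ROH"`
#' @export
rohIslands <- function(segments, group_samples, ds, freq_threshold = 0.5,
                       group_name = "group") {
  if (length(group_samples) < 2L) stop("group must have >= 2 samples")
  occ <- rohOccupancy(segments, group_samples, ds)
  chr <- chromOf(ds); pos <- posBp(ds)
  qual <- occ >= freq_threshold
  out <- list()
  for (cc in unique(chr)) {
    sel <- which(chr == cc)
    q <- qual[sel]
    if (!any(q)) next
    r <- rle(q)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      a <- sel[starts[k]]; b <- sel[ends[k]]
      out[[length(out) + 1L]] <- c(cc, pos[a], pos[b])
    }
  }
  if (!length(out))
    return(genomicIntervals(character(0), integer(0), integer(0)))
  m <- do.call(rbind, out)
  genomicIntervals(m[, 1L], as.numeric(m[, 2L]), as.numeric(m[, 3L]),
                   method = "ROH", comparison = group_name)
}

#' Private ROH islands (interval subtraction)
#'
#' Parts of A-islands that have zero bp overlap with any B-island.  Each
#' output interval keeps its source tags and records whether the whole
#' A-island survived or only a segment of it.
#'
#' @param islands_A,islands_B `GRanges` of islands on the same coordinate
#'   system
#' @return `GRanges` with an extra `retention` column ("whole"/"segment")
#' @export
privateIslands <- function(islands_A, islands_B) {
  if (!length(islands_A)) return(islands_A)
  b <- reduce(islands_B)
  pieces <- list()
  for (i in seq_along(islands_A)) {
    a <- islands_A[i]
    left <- GenomicRanges::setdiff(a, b)
    if (!length(left)) next
    mcols(left)$method <- mcols(a)$method
    mcols(left)$comparison <- mcols(a)$comparison
    mcols(left)$retention <-
      if (length(left) == 1L && width(left) == width(a)) "whole" else "segment"
    pieces[[length(pieces) + 1L]] <- left
  }
  if (!length(pieces)) {
    out <- genomicIntervals(character(0), integer(0), integer(0))
    mcols(out)$retention <- character(0)
    return(out)
  }
  do.call(c, pieces)
}
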