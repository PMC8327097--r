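## Interval arithmetic and multi-evidence consensus candidate calling: a
## locus supported by at least two methods (ROH, F_ST, XP-EHH) and/or at
## least two comparisons is retained.

#' All overlapping interval pairs
#'
#' Every pair of intervals from `a` and `b` with at least 1 bp overlap
#' (1-based inclusive coordinates), with the overlap span.
#'
#' @param a,b `GRanges`
#' @return data.frame: `query`, `subject`, `chrom`, `overlap_start`,
#'   `overlap_stop`, `overlap_bp`
#' @export
intersectIntervals <- function(a, b) {
  hits <- findOverlaps(a, b, minoverlap = 1L)
  if (!length(hits))
    return(data.frame(query = integer(), subject = integer(),
                      chrom = character(), overlap_start = integer(),
                      overlap_stop = integer(), overlap_bp = integer()))
  ov <- pintersect(a[S4Vectors::queryHits(hits)],
                   b[S4Vectors::subjectHits(hits)])
  data.frame(query = S4Vectors::queryHits(hits),
             subject = S4Vectors::subjectHits(hits),
             chrom = as.character(seqnames(ov)),
             overlap_start = start(ov), overlap_stop = end(ov),
             overlap_bp = width(ov))
}

#' Interval length in Mb
#'
#' `(stop - start) / 1e6`, rounded half-away-from-zero to 3 decimals —
#' the Size-column convention of candidate-region tables (span between the
#' first and last position, no +1).
#'
#' @param intervals a `GRanges`, or `start`/`stop` given separately
#' @param start_bp,stop_bp alternative scalar/vector interface
#' @return numeric vector of sizes in Mb
#' @export
intervalLengthMb <- function(intervals = NULL, start_bp = NULL,
                             stop_bp = NULL) {
  if (!is.null(intervals)) {
    start_bp <- start(intervals); stop_bp <- end(intervals)
  }
  x <- (stop_bp - start_bp) / 1e6
  sign(x) * floor(abs(x) * 1000 + 0.5) / 1000
}

#' Multi-evidence consensus candidate loci
#'
#' Tagged regions are merged into loci by single-linkage bp overlap; a
#' locus is retained when the number of distinct supporting methods is at
#' least `min_methods` or (mode `"or"`, the default) the number of
#' distinct comparisons is at least `min_comparisons`; mode `"and"`
#' requires both.
#'
#' @param tagged_regions `GRanges` with `method` and `comparison` tags on
#'   every element (untagged regions are an error)
#' @param min_methods,min_comparisons support thresholds (default 2 each)
#' @param mode `"or"` or `"and"`
#' @return data.frame of merged loci: `chrom`, `start_bp`, `stop_bp`,
#'   `size_mb`, `methods`, `comparisons`, `n_methods`, `n_comparisons`,
#'   `retained`
#' @export
consensusCandidates <- function(tagged_regions, min_methods = 2L,
                                min_comparisons = 2L,
                                mode = c("or", "and")) {
  mode <- match.arg(mode)
  m <- mcols(tagged_regions)
  if (!all(c("method", "comparison") %in% colnames(m)) ||
      anyNA(m$method) || anyNA(m$comparison))
    stop("every region must carry method and comparison tags")
  loci <- reduce(tagged_regions, ignore.strand = TRUE)
  hits <- findOverlaps(loci, tagged_regions)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  rows <- lapply(seq_along(loci), function(i) {
    sup <- sh[qh == i]
    meth <- unique(m$method[sup]); comp <- unique(m$comparison[sup])
    keep <- if (mode == "or")
      length(meth) >= min_methods || length(comp) >= min_comparisons
    else length(meth) >= min_methods && length(comp) >= min_comparisons
    data.frame(chrom = as.character(seqnames(loci))[i],
               start_bp = start(loci)[i], stop_bp = end(loci)[i],
               size_mb = intervalLengthMb(start_bp = start(loci)[i],
                                          stop_bp = end(loci)[i]),
               methods = paste(sort(meth), collapse = ","),
               comparisons = paste(sort(comp), collapse = ","),
               n_methods = length(meth), n_comparisons = length(comp),
               retained = keep)
  })
  out <- do.call(rbind, rows)
  out[order(out$chrom, out$start_bp), , drop = FALSE]
}

#' Read a gene BED file
#'
#' BED4 with the gene name in column 4 (0-based half-open on disk).
#'
#' @param bed_file path
#' @return `GRanges` with a `gene` column, 1-based inclusive
#' @export
readGeneBed <- function(bed_file) {
  if (!file.exists(bed_file))
    stop("gene BED file not found: ", bed_file,
         " (annotation is strictly local; no network fetch)")
  lines <- readLines(bed_file)
  lines <- lines[nzchar(lines) & !startsWith(lines, "track") &
                 !startsWith(lines, "#")]
  if (!length(lines)) {
    gr <- GRanges()
    mcols(gr)$gene <- character(0)
    return(gr)
  }
  f <- do.call(rbind, strsplit(lines, "\t"))
  gr <- GRanges(f[, 1L], IRanges(as.integer(f[, 2L]) + 1L,
                                 as.integer(f[, 3L])))
  mcols(gr)$gene <- if (ncol(f) >= 4L) f[, 4L] else
    sprintf("gene%d", seq_len(nrow(f)))
  gr
}

#' Annotate regions with overlapping genes
#'
#' Genes with at least 1 bp overlap are listed per region, ordered by gene
#' start.
#'
#' @param regions `GRanges` of candidate regions
#' @param gene_bed a gene `GRanges` (see [readGeneBed()]) or a BED path
#' @return data.frame: region coordinates, `n_genes`, `genes`
#'   (comma-separated)
#' @export
annotateRegions <- function(regions, gene_bed) {
  genes <- if (is.character(gene_bed)) readGeneBed(gene_bed) else gene_bed
  hits <- findOverlaps(regions, genes)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  rows <- lapply(seq_along(regions), function(i) {
    gi <- sh[qh == i]
    gi <- gi[order(start(genes)[gi])]
    data.frame(chrom = as.character(seqnames(regions))[i],
               start_bp = start(regions)[i], stop_bp = end(regions)[i],
               n_genes = length(gi),
               genes = paste(mcols(genes)$gene[gi], collapse = ","))
  })
  do.call(rbind, rows)
}
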