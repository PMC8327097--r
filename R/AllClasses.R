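#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<- metadata metadata<-
#' @importFrom IRanges IRanges
#' @importFrom GenomicRanges GRanges seqnames start end width findOverlaps
#'   reduce pintersect
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   rowRanges colData rowData rowData<-
#' @importClassesFrom SummarizedExperiment RangedSummarizedExperiment
#' @importFrom ape nj write.tree
#' @importFrom yaml read_yaml write_yaml
#' @importFrom tools md5sum
NULL

#' Diploid SNP genotype container
#'
#' `GenotypeDataset` extends `RangedSummarizedExperiment` and stores diploid
#' biallelic genotypes as an integer assay named `"genotype"` with one row per
#' variant and one column per sample.  Codes count copies of the alternate
#' allele: 0, 1, 2, or `NA` for missing.  Row ranges give the variant
#' positions (1-based bp, width 1); `colData` carries `sample_id` and
#' `population` labels.  Variants are stored sorted by (chromosome, position),
#' strictly increasing within each chromosome.
#'
#' @export
setClass("GenotypeDataset", contains = "RangedSummarizedExperiment")

#' Phased haplotype container
#'
#' `HaplotypeSet` extends `RangedSummarizedExperiment` with a binary assay
#' `"haplotype"` (one row per variant, two columns per sample — no missing
#' values; haplotype scans require complete phased data).  `colData` has
#' `sample_id` (each id twice) and `hap` (1 or 2); `rowData$map_cm` holds the
#' genetic-map position in centiMorgan, non-decreasing within a chromosome.
#'
#' @export
setClass("HaplotypeSet", contains = "RangedSummarizedExperiment")

.validGenotypeDataset <- function(object) {
  msg <- character()
  if (!"genotype" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'genotype' is required")
  else {
    g <- assay(object, "genotype")
    bad <- !is.na(g) & !(g %in% 0:2)
    if (any(bad)) msg <- c(msg, "genotype codes must be 0, 1, 2 or NA")
  }
  cd <- colData(object)
  if (!all(c("sample_id", "population") %in% colnames(cd)))
    msg <- c(msg, "colData must contain sample_id and population")
  if (anyDuplicated(cd$sample_id))
    msg <- c(msg, "sample ids must be unique")
  chr <- as.character(seqnames(rowRanges(object)))
  pos <- start(rowRanges(object))
  for (cc in unique(chr)) {
    p <- pos[chr == cc]
    if (length(p) > 1L && any(diff(p) <= 0)) {
      msg <- c(msg, sprintf("positions not strictly increasing on %s", cc))
      break
    }
  }
  if (length(msg)) msg else TRUE
}
setValidity("GenotypeDataset", .validGenotypeDataset)

.validHaplotypeSet <- function(object) {
  msg <- character()
  h <- assay(object, "haplotype")
  if (anyNA(h)) msg <- c(msg, "haplotypes must not contain missing alleles")
  else if (!all(h %in% 0:1)) msg <- c(msg, "haplotype alleles must be 0/1")
  if (ncol(h) %% 2L != 0L)
    msg <- c(msg, "haplotype count must be 2 x sample count")
  cd <- colData(object)
  if (!all(c("sample_id", "hap") %in% colnames(cd)))
    msg <- c(msg, "colData must contain sample_id and hap")
  rd <- rowData(object)
  if (!"map_cm" %in% colnames(rd)) msg <- c(msg, "rowData$map_cm is required")
  else {
    if (any(rd$map_cm < 0)) msg <- c(msg, "map_cm must be non-negative")
    chr <- as.character(seqnames(rowRanges(object)))
    for (cc in unique(chr)) {
      m <- rd$map_cm[chr == cc]
      if (length(m) > 1L && any(diff(m) < 0)) {
        msg <- c(msg, sprintf("map_cm decreasing on %s", cc))
        break
      }
    }
  }
  if (length(msg)) msg else TRUE
}
setValidity("HaplotypeSet", .validHaplotypeSet)

.variantRanges <- function(chrom, pos_bp, variant_ids) {
  gr <- GRanges(chrom, IRanges(pos_bp, width = 1L))
  names(gr) <- variant_ids
  gr
}

#' Construct a GenotypeDataset
#'
#' @param genotype integer matrix, variants in rows, samples in columns;
#'   entries 0/1/2/NA count alternate-allele copies.
#' @param chrom chromosome per variant (character).
#' @param pos_bp 1-based physical position per variant.
#' @param variant_ids,sample_ids identifiers; defaults generated if `NULL`.
#' @param population population label per sample.
#' @param sort sort variants by (chrom, pos)? Default `TRUE`.
#' @return a [GenotypeDataset-class] object.
#' @export
GenotypeDataset <- function(genotype, chrom, pos_bp, variant_ids = NULL,
                            sample_ids = NULL, population = NULL,
                            sort = TRUE) {
  genotype <- as.matrix(genotype)
  storage.mode(genotype) <- "integer"
  if (is.null(variant_ids))
    variant_ids <- sprintf("snp%0*d", nchar(nrow(genotype)), seq_len(nrow(genotype)))
  if (is.null(sample_ids))
    sample_ids <- sprintf("s%03d", seq_len(ncol(genotype)))
  if (is.null(population)) population <- rep("pop1", ncol(genotype))
  stopifnot(length(chrom) == nrow(genotype),
            length(pos_bp) == nrow(genotype),
            length(variant_ids) == nrow(genotype),
            length(sample_ids) == ncol(genotype),
            length(population) == ncol(genotype))
  chrom <- as.character(chrom)
  pos_bp <- as.integer(pos_bp)
  if (any(pos_bp < 1L)) stop("pos_bp must be positive 1-based integers")
  if (sort) {
    o <- order(chrom, pos_bp)
    genotype <- genotype[o, , drop = FALSE]
    chrom <- chrom[o]; pos_bp <- pos_bp[o]; variant_ids <- variant_ids[o]
  }
  rownames(genotype) <- variant_ids
  colnames(genotype) <- sample_ids
  se <- SummarizedExperiment(
    assays = list(genotype = genotype),
    rowRanges = .variantRanges(chrom, pos_bp, variant_ids),
    colData = DataFrame(sample_id = sample_ids,
                        population = as.character(population),
                        row.names = sample_ids))
  new("GenotypeDataset", se)
}

#' Construct a HaplotypeSet
#'
#' @param haplotype binary matrix, variants in rows, 2 columns per sample in
#'   sample order (hap 1 then hap 2 adjacent).
#' @param chrom,pos_bp,variant_ids variant metadata as in [GenotypeDataset()].
#' @param sample_ids one id per sample (`ncol(haplotype)/2` of them).
#' @param population population label per sample.
#' @param map_cm genetic position in cM per variant; default 1 cM/Mb
#'   (`pos_bp * 1e-6`), the constant-rate map used when no map is supplied.
#' @param sort sort variants by (chrom, pos)? Default `TRUE`.
#' @return a [HaplotypeSet-class] object.
#' @export
HaplotypeSet <- function(haplotype, chrom, pos_bp, variant_ids = NULL,
                         sample_ids = NULL, population = NULL,
                         map_cm = NULL, sort = TRUE) {
  haplotype <- as.matrix(haplotype)
  storage.mode(haplotype) <- "integer"
  n_samp <- ncol(haplotype) / 2L
  if (is.null(variant_ids))
    variant_ids <- sprintf("snp%0*d", nchar(nrow(haplotype)), seq_len(nrow(haplotype)))
  if (is.null(sample_ids)) sample_ids <- sprintf("s%03d", seq_len(n_samp))
  if (is.null(population)) population <- rep("pop1", n_samp)
  chrom <- as.character(chrom)
  pos_bp <- as.integer(pos_bp)
  if (is.null(map_cm)) map_cm <- pos_bp * 1e-6
  stopifnot(length(chrom) == nrow(haplotype),
            length(pos_bp) == nrow(haplotype),
            length(map_cm) == nrow(haplotype),
            length(sample_ids) == n_samp,
            length(population) == n_samp)
  if (sort) {
    o <- order(chrom, pos_bp)
    haplotype <- haplotype[o, , drop = FALSE]
    chrom <- chrom[o]; pos_bp <- pos_bp[o]
    variant_ids <- variant_ids[o]; map_cm <- map_cm[o]
  }
  hap_ids <- paste(rep(sample_ids, each = 2L), rep(1:2, n_samp), sep = "_")
  rownames(haplotype) <- variant_ids
  colnames(haplotype) <- hap_ids
  gr <- .variantRanges(chrom, pos_bp, variant_ids)
  mcols(gr)$map_cm <- as.numeric(map_cm)
  se <- SummarizedExperiment(
    assays = list(haplotype = haplotype),
    rowRanges = gr,
    colData = DataFrame(sample_id = rep(sample_ids, each = 2L),
                        population = rep(as.character(population), each = 2L),
                        hap = rep(1:2, n_samp),
                        row.names = hap_ids))
  new("HaplotypeSet", se)
}

## ---- accessors -------------------------------------------------------------

#' @export
setGeneric("genotypes", function(x) standardGeneric("genotypes"))
#' Genotype matrix (variants x samples)
#' @param x a `GenotypeDataset`
#' @export
setMethod("genotypes", "GenotypeDataset", function(x) assay(x, "genotype"))

#' @export
setGeneric("haplotypes", function(x) standardGeneric("haplotypes"))
#' Haplotype matrix (variants x 2*samples)
#' @param x a `HaplotypeSet`
#' @export
setMethod("haplotypes", "HaplotypeSet", function(x) assay(x, "haplotype"))

#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))
#' @export
setMethod("sampleIds", "GenotypeDataset", function(x) colData(x)$sample_id)
#' @export
setMethod("sampleIds", "HaplotypeSet",
          function(x) unique(colData(x)$sample_id))

#' @export
setGeneric("popLabels", function(x) standardGeneric("popLabels"))
#' Population label per sample
#' @param x a `GenotypeDataset` or `HaplotypeSet`
#' @export
setMethod("popLabels", "GenotypeDataset", function(x) {
  stats::setNames(colData(x)$population, colData(x)$sample_id)
})
#' @export
setMethod("popLabels", "HaplotypeSet", function(x) {
  cd <- colData(x)[colData(x)$hap == 1L, ]
  stats::setNames(cd$population, cd$sample_id)
})

#' @export
setGeneric("variantIds", function(x) standardGeneric("variantIds"))
#' @export
setMethod("variantIds", "RangedSummarizedExperiment",
          function(x) names(rowRanges(x)))

#' @export
setGeneric("chromOf", function(x) standardGeneric("chromOf"))
#' Chromosome per variant
#' @param x a genotype or haplotype container
#' @export
setMethod("chromOf", "RangedSummarizedExperiment",
          function(x) as.character(seqnames(rowRanges(x))))

#' @export
setGeneric("posBp", function(x) standardGeneric("posBp"))
#' 1-based physical position per variant
#' @param x a genotype or haplotype container
#' @export
setMethod("posBp", "RangedSummarizedExperiment",
          function(x) start(rowRanges(x)))

#' @export
setGeneric("mapCm", function(x) standardGeneric("mapCm"))
#' Genetic-map position (cM) per variant
#' @param x a `HaplotypeSet`
#' @export
setMethod("mapCm", "HaplotypeSet", function(x) rowData(x)$map_cm)

#' Number of variants / samples
#' @param x container
#' @export
nVariants <- function(x) nrow(x)
#' @rdname nVariants
#' @export
nSamples <- function(x) length(sampleIds(x))

setMethod("show", "GenotypeDataset", function(object) {
  g <- genotypes(object)
  cat(sprintf("GenotypeDataset: %d variants x %d samples (%.2f%% missing)\n",
              nrow(g), ncol(g), 100 * mean(is.na(g))))
  cat(" chromosomes:", paste(unique(chromOf(object)), collapse = ", "), "\n")
  pops <- table(popLabels(object))
  cat(" populations:",
      paste(sprintf("%s (n=%d)", names(pops), as.integer(pops)),
            collapse = ", "), "\n")
})

setMethod("show", "HaplotypeSet", function(object) {
  h <- haplotypes(object)
  cat(sprintf("HaplotypeSet: %d variants x %d haplotypes (%d samples)\n",
              nrow(h), ncol(h), ncol(h) %/% 2L))
  cat(" chromosomes:", paste(unique(chromOf(object)), collapse = ", "), "\n")
})

## ---- derived conversions ---------------------------------------------------

#' Collapse phased haplotypes to genotype dosages
#'
#' Genotype = sum of the two haplotypes at every site.
#'
#' @param hs a [HaplotypeSet-class]
#' @return a [GenotypeDataset-class] with no missing calls
#' @export
genotypesFromHaps <- function(hs) {
  h <- haplotypes(hs)
  n <- ncol(h) %/% 2L
  g <- h[, seq(1L, 2L * n, by = 2L), drop = FALSE] +
       h[, seq(2L, 2L * n, by = 2L), drop = FALSE]
  GenotypeDataset(g, chromOf(hs), posBp(hs), variantIds(hs),
                  sampleIds(hs), unname(popLabels(hs)), sort = FALSE)
}

#' Subset a dataset to one population group
#'
#' @param x `GenotypeDataset` or `HaplotypeSet`
#' @param pops character vector of population labels to keep
#' @return object of the same class restricted to those samples
#' @export
subsetPop <- function(x, pops) {
  keep <- colData(x)$population %in% pops
  if (!any(keep)) stop("no samples with population in: ",
                       paste(pops, collapse = ", "))
  x[, keep]
}

#' Build tagged genomic intervals
#'
#' Candidate regions are plain `GRanges` (1-based, inclusive) carrying
#' provenance tags in metadata columns `method` and `comparison`.
#'
#' @param chrom,start_bp,stop_bp interval coordinates (1-based inclusive)
#' @param method,comparison provenance tags recycled along intervals
#' @return a `GRanges`
#' @export
genomicIntervals <- function(chrom, start_bp, stop_bp,
                             method = NA_character_,
                             comparison = NA_character_) {
  if (any(stop_bp < start_bp)) stop("stop_bp must be >= start_bp")
  gr <- GRanges(chrom, IRanges(start_bp, stop_bp))
  mcols(gr)$method <- rep_len(as.character(method), length(gr))
  mcols(gr)$comparison <- rep_len(as.character(comparison), length(gr))
  gr
}
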