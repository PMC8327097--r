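## PLINK text (PED/MAP), minimal phased VCF, and BED interchange.
## Internal coordinates are 1-based inclusive; BED export converts to
## 0-based half-open.

#' Read PLINK text genotypes (PED + MAP)
#'
#' Parses the PLINK text dialect: the MAP file has 4 columns (chromosome,
#' variant id, genetic position in cM, bp position); the PED file has 6
#' metadata columns (family, individual, father, mother, sex, phenotype)
#' followed by two allele columns per variant.  Alleles are recoded to 0/1/2
#' counts of the alternate allele, where the alternate is the minor allele at
#' load time (ties broken by taking the lexicographically later allele as
#' alternate).  "0 0" becomes a missing call.  Variants are sorted by
#' (chromosome, position).  The family id column is used as the population
#' label.
#'
#' @param ped_file,map_file paths to the PED and MAP files.
#' @return a [GenotypeDataset-class]; `rowData` keeps `ref_allele`,
#'   `alt_allele` and the MAP cM column (`map_cm`) for loss-free writing.
#' @seealso [writePlinkText()]
#' @export
readPlinkText <- function(ped_file, map_file) {
  map <- utils::read.table(map_file, header = FALSE,
                           colClasses = c("character", "character",
                                          "numeric", "integer"))
  colnames(map) <- c("chrom", "id", "cm", "bp")
  ped <- utils::read.table(ped_file, header = FALSE, colClasses = "character")
  n_var <- nrow(map)
  if (ncol(ped) != 6L + 2L * n_var)
    stop(sprintf(
      "PED/MAP column mismatch: PED implies %s variants, MAP has %d",
      format((ncol(ped) - 6L) / 2), n_var))
  n_samp <- nrow(ped)
  a1 <- as.matrix(ped[, 6L + 2L * seq_len(n_var) - 1L, drop = FALSE])
  a2 <- as.matrix(ped[, 6L + 2L * seq_len(n_var), drop = FALSE])
  geno <- matrix(NA_integer_, nrow = n_var, ncol = n_samp)
  ref <- alt <- character(n_var)
  for (j in seq_len(n_var)) {
    x1 <- a1[, j]; x2 <- a2[, j]
    miss <- x1 == "0" | x2 == "0"
    obs <- c(x1[!miss], x2[!miss])
    alleles <- sort(unique(obs))
    if (length(alleles) > 2L)
      stop(sprintf("variant %s is not biallelic (alleles: %s)",
                   map$id[j], paste(alleles, collapse = ",")))
    if (length(alleles) == 0L) {        # all missing
      ref[j] <- "0"; alt[j] <- "0"
      next
    }
    if (length(alleles) == 1L) {
      ref[j] <- alleles; alt[j] <- "0"
      geno[j, !miss] <- 0L
      next
    }
    cnt <- c(sum(obs == alleles[1L]), sum(obs == alleles[2L]))
    ## alternate = minor; on a tie the lexicographically later allele
    alt_j <- if (cnt[1L] < cnt[2L]) alleles[1L] else alleles[2L]
    ref_j <- setdiff(alleles, alt_j)
    ref[j] <- ref_j; alt[j] <- alt_j
    geno[j, !miss] <- (x1[!miss] == alt_j) + (x2[!miss] == alt_j)
  }
  ds <- GenotypeDataset(geno, map$chrom, map$bp, map$id,
                        sample_ids = ped[[2L]], population = ped[[1L]])
  o <- order(map$chrom, map$bp)
  rowData(ds)$ref_allele <- ref[o]
  rowData(ds)$alt_allele <- alt[o]
  rowData(ds)$map_cm <- map$cm[o]
  ds
}

#' Write PLINK text genotypes (PED + MAP)
#'
#' Inverse of [readPlinkText()]: loss-free for genotype codes 0/1/2/missing.
#' When the dataset does not carry allele labels, `A` (reference) and `C`
#' (alternate) are used; missing calls are written as `0 0`.
#'
#' @param ds a [GenotypeDataset-class]
#' @param ped_file,map_file output paths
#' @return invisibly, the two paths
#' @export
writePlinkText <- function(ds, ped_file, map_file) {
  g <- genotypes(ds)
  rd <- rowData(ds)
  ref <- if ("ref_allele" %in% colnames(rd)) rd$ref_allele else rep("A", nrow(g))
  alt <- if ("alt_allele" %in% colnames(rd)) rd$alt_allele else rep("C", nrow(g))
  alt[alt == "0"] <- "C"   # monomorphic: any placeholder, never emitted
  cm <- if ("map_cm" %in% colnames(rd)) rd$map_cm else rep(0, nrow(g))
  utils::write.table(
    data.frame(chromOf(ds), variantIds(ds), cm, posBp(ds)),
    map_file, quote = FALSE, sep = "\t",
    row.names = FALSE, col.names = FALSE)
  pops <- unname(popLabels(ds))
  lines <- vapply(seq_len(ncol(g)), function(i) {
    gi <- g[, i]
    x1 <- ifelse(is.na(gi), "0", ifelse(gi >= 1L, alt, ref))
    x2 <- ifelse(is.na(gi), "0", ifelse(gi == 2L, alt, ref))
    paste(c(pops[i], sampleIds(ds)[i], "0", "0", "0", "-9",
            as.vector(rbind(x1, x2))), collapse = " ")
  }, character(1))
  writeLines(lines, ped_file)
  invisible(c(ped_file, map_file))
}

#' Read phased genotypes from a minimal VCF
#'
#' Accepts biallelic records with phased `GT` fields ("0|1").  Unphased
#' separators ("/") or missing genotypes are errors: haplotype scans require
#' complete phased data.  Positions are 1-based as in VCF.
#'
#' @param vcf_file path to an uncompressed VCF (v4.x, GT only)
#' @param map_cm optional genetic positions per variant; default 1 cM/Mb
#' @param population optional population label per sample
#' @return a [HaplotypeSet-class]
#' @export
readVcfPhased <- function(vcf_file, map_cm = NULL, population = NULL) {
  lines <- readLines(vcf_file)
  hdr <- grep("^#CHROM", lines)
  if (length(hdr) != 1L) stop("no #CHROM header line in VCF")
  cols <- strsplit(sub("^#", "", lines[hdr]), "\t")[[1L]]
  samples <- cols[-(1:9)]
  body <- lines[-seq_len(hdr)]
  body <- body[nzchar(body)]
  if (!length(body)) stop("VCF has no records")
  fields <- strsplit(body, "\t")
  n_var <- length(fields)
  n_samp <- length(samples)
  hap <- matrix(NA_integer_, n_var, 2L * n_samp)
  chrom <- ids <- character(n_var)
  pos <- integer(n_var)
  for (j in seq_len(n_var)) {
    f <- fields[[j]]
    if (grepl(",", f[5L]))
      stop(sprintf("record %s:%s is multi-allelic; biallelic VCF required",
                   f[1L], f[2L]))
    chrom[j] <- f[1L]; pos[j] <- as.integer(f[2L])
    ids[j] <- if (f[3L] == ".") sprintf("%s_%s", f[1L], f[2L]) else f[3L]
    gt <- sub(":.*", "", f[-(1:9)])
    if (any(grepl("/", gt, fixed = TRUE)))
      stop(sprintf("unphased genotype at %s:%s; phased data ('|') required",
                   f[1L], f[2L]))
    if (any(grepl("\\.", gt)))
      stop(sprintf("missing genotype at %s:%s; haplotype scans require complete data",
                   f[1L], f[2L]))
    al <- matrix(as.integer(unlist(strsplit(gt, "|", fixed = TRUE))), nrow = 2L)
    hap[j, ] <- as.vector(al)
  }
  HaplotypeSet(hap, chrom, pos, ids, sample_ids = samples,
               population = population, map_cm = map_cm)
}

#' Write phased haplotypes to a minimal VCF
#'
#' @param hs a [HaplotypeSet-class]
#' @param vcf_file output path
#' @return invisibly, the path
#' @export
writeVcfPhased <- function(hs, vcf_file) {
  h <- haplotypes(hs)
  n <- ncol(h) %/% 2L
  gt <- matrix(paste0(h[, seq(1L, 2L * n, 2L), drop = FALSE], "|",
                      h[, seq(2L, 2L * n, 2L), drop = FALSE]),
               nrow = nrow(h))
  header <- c("##fileformat=VCFv4.2",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", sampleIds(hs)), collapse = "\t"))
  recs <- vapply(seq_len(nrow(h)), function(j) {
    paste(c(chromOf(hs)[j], posBp(hs)[j], variantIds(hs)[j], "A", "C",
            ".", "PASS", ".", "GT", gt[j, ]), collapse = "\t")
  }, character(1))
  writeLines(c(header, recs), vcf_file)
  invisible(vcf_file)
}

#' Write intervals as BED
#'
#' Converts the internal 1-based inclusive intervals to the BED convention
#' (0-based half-open): start − 1, stop.  Provenance tags are packed into the
#' BED name column as `method|comparison`.
#'
#' @param intervals a `GRanges` (see [genomicIntervals()])
#' @param bed_file output path
#' @return invisibly, the path
#' @export
writeBed <- function(intervals, bed_file) {
  if (!length(intervals)) {
    writeLines(character(0), bed_file)
    return(invisible(bed_file))
  }
  m <- mcols(intervals)
  nm <- paste(if ("method" %in% colnames(m)) m$method else ".",
              if ("comparison" %in% colnames(m)) m$comparison else ".",
              sep = "|")
  lines <- paste(as.character(seqnames(intervals)),
                 format(start(intervals) - 1L, scientific = FALSE, trim = TRUE),
                 format(end(intervals), scientific = FALSE, trim = TRUE),
                 nm, sep = "\t")
  writeLines(lines, bed_file)
  invisible(bed_file)
}

#' Read a BED file into tagged intervals
#'
#' @param bed_file BED3+name path (0-based half-open on disk)
#' @return a `GRanges` with 1-based inclusive coordinates and unpacked
#'   `method` / `comparison` tags
#' @export
readBed <- function(bed_file) {
  lines <- readLines(bed_file)
  lines <- lines[nzchar(lines) & !startsWith(lines, "track") &
                 !startsWith(lines, "#")]
  if (!length(lines))
    return(genomicIntervals(character(0), integer(0), integer(0)))
  f <- do.call(rbind, strsplit(lines, "\t"))
  nm <- if (ncol(f) >= 4L) f[, 4L] else rep(".|.", nrow(f))
  tags <- do.call(rbind, strsplit(paste0(nm, "|"), "|", fixed = TRUE))
  genomicIntervals(f[, 1L], as.integer(f[, 2L]) + 1L, as.integer(f[, 3L]),
                   method = tags[, 1L],
                   comparison = if (ncol(tags) >= 2L) tags[, 2L] else ".")
}

#' Restrict a dataset to autosomes
#'
#' X-linked and unmapped variants (any chromosome label that is not a plain
#' number) are dropped with a reported count; downstream scans are autosomal.
#'
#' @param x `GenotypeDataset` or `HaplotypeSet`
#' @param autosomes optional explicit set of chromosome names to keep
#' @return the filtered object
#' @export
keepAutosomes <- function(x, autosomes = NULL) {
  chr <- chromOf(x)
  keep <- if (is.null(autosomes)) grepl("^(chr)?[0-9]+$", chr)
          else chr %in% autosomes
  if (!all(keep))
    message(sum(!keep), " non-autosomal/unmapped variants dropped (",
            sum(keep), " kept)")
  x[keep, ]
}
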