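## Seeded generators: Balding-Nichols divergent populations built as Markov
## mosaics of founder haplotypes, injected sweeps and autozygous tracts, and
## a small forward Wright-Fisher simulator used as an oracle for the LD/Ne
## stage.  Every generator is deterministic given its seed and returns its
## ground truth alongside the data.

#' Simulation configuration
#'
#' Bundles the parameters of [simulateDivergentPops()].  Populations diverge
#' to a target F_ST under the Balding-Nichols model: per-population allele
#' frequencies are drawn Beta(p(1-F)/F, (1-p)(1-F)/F) around an ancestral
#' frequency p ~ Uniform(0.05, 0.95), so F is an explicit parameter that
#' estimator-recovery tests can check.  Haplotypes are Markov mosaics of
#' population-specific founder haplotypes; the per-bp switch rate sets the
#' scale of linkage disequilibrium (the default 1e-6 gives LD decaying within
#' a few hundred kb).  The founder pool defaults to `2 * n_per_pop`
#' haplotypes so that founder-pool sampling noise matches the sample-size
#' correction built into the Weir-Cockerham estimator.
#'
#' @param n_pops number of populations
#' @param n_per_pop diploid samples per population
#' @param n_variants total variant count
#' @param chrom_length_bp chromosome length (bp)
#' @param n_chrom number of chromosomes (variants split evenly)
#' @param target_fst Balding-Nichols F in [0, 1)
#' @param mosaic_switch_rate founder-switch probability per bp
#' @param founders_per_pop founder haplotypes per population
#' @param missing_rate genotype missingness rate (genotypes only; haplotypes
#'   stay complete)
#' @param rng_seed mandatory integer seed
#' @return a list of class `simConfig`
#' @export
simConfig <- function(n_pops = 2L, n_per_pop = 100L, n_variants = 5000L,
                      chrom_length_bp = 1e8, n_chrom = 1L,
                      target_fst = 0.10, mosaic_switch_rate = 1e-6,
                      founders_per_pop = 2L * n_per_pop,
                      missing_rate = 0, rng_seed) {
  if (missing(rng_seed)) stop("rng_seed is mandatory (reproducibility)")
  stopifnot(n_pops >= 1L, n_per_pop >= 1L, n_variants >= 1L,
            chrom_length_bp >= n_variants,
            target_fst >= 0, target_fst < 1,
            mosaic_switch_rate >= 0, founders_per_pop >= 2L,
            missing_rate >= 0, missing_rate < 1)
  structure(list(n_pops = as.integer(n_pops),
                 n_per_pop = as.integer(n_per_pop),
                 n_variants = as.integer(n_variants),
                 chrom_length_bp = chrom_length_bp,
                 n_chrom = as.integer(n_chrom),
                 target_fst = target_fst,
                 mosaic_switch_rate = mosaic_switch_rate,
                 founders_per_pop = as.integer(founders_per_pop),
                 missing_rate = missing_rate,
                 rng_seed = as.integer(rng_seed)),
            class = "simConfig")
}

.mosaicHaplotype <- function(founders, p_switch_first) {
  ## founders: n_variants x m; p_switch_first: switch prob per variant, with
  ## 1 at the first variant of each chromosome (mosaic restarts there)
  n <- nrow(founders)
  m <- ncol(founders)
  sw <- stats::runif(n) < p_switch_first
  sw[1L] <- TRUE
  seg <- cumsum(sw)
  fid <- sample.int(m, seg[n], replace = TRUE)[seg]
  founders[cbind(seq_len(n), fid)]
}

#' Simulate populations diverged to a target F_ST
#'
#' Draws Balding-Nichols per-population allele frequencies, builds
#' population founder pools, then composes each sample haplotype as a Markov
#' mosaic over its population's founders (switch probability per bp
#' `mosaic_switch_rate`).  Genotypes are the sum of the two haplotypes;
#' optional missingness is applied to genotypes only.  Deterministic given
#' `cfg$rng_seed`.
#'
#' @param cfg a [simConfig()]
#' @return list with `genotypes` ([GenotypeDataset-class]), `haplotypes`
#'   ([HaplotypeSet-class]) and `truth` (ancestral and per-population allele
#'   frequencies, founder pools, config)
#' @export
simulateDivergentPops <- function(cfg) {
  stopifnot(inherits(cfg, "simConfig"))
  set.seed(cfg$rng_seed)
  n_var <- cfg$n_variants
  per_chrom <- diff(round(seq(0, n_var, length.out = cfg$n_chrom + 1L)))
  chrom <- rep(as.character(seq_len(cfg$n_chrom)), per_chrom)
  pos <- unlist(lapply(per_chrom, function(k)
    sort(sample.int(cfg$chrom_length_bp, k))), use.names = FALSE)
  first <- !duplicated(chrom)
  gap <- c(0, diff(pos)); gap[first] <- 0
  p_switch <- 1 - exp(-cfg$mosaic_switch_rate * gap)
  p_switch[first] <- 1

  p_anc <- stats::runif(n_var, 0.05, 0.95)
  F <- cfg$target_fst
  pop_names <- sprintf("pop%d", seq_len(cfg$n_pops))
  pop_freq <- matrix(NA_real_, n_var, cfg$n_pops,
                     dimnames = list(NULL, pop_names))
  founders <- vector("list", cfg$n_pops)
  hap <- matrix(0L, n_var, 2L * cfg$n_per_pop * cfg$n_pops)
  for (k in seq_len(cfg$n_pops)) {
    pk <- if (F == 0) p_anc else
      stats::rbeta(n_var, p_anc * (1 - F) / F, (1 - p_anc) * (1 - F) / F)
    pop_freq[, k] <- pk
    fd <- matrix(stats::rbinom(n_var * cfg$founders_per_pop, 1L, pk),
                 n_var, cfg$founders_per_pop)
    founders[[k]] <- fd
    off <- (k - 1L) * 2L * cfg$n_per_pop
    for (h in seq_len(2L * cfg$n_per_pop))
      hap[, off + h] <- .mosaicHaplotype(fd, p_switch)
  }
  population <- rep(pop_names, each = cfg$n_per_pop)
  sample_ids <- sprintf("%s_s%03d", population,
                        rep(seq_len(cfg$n_per_pop), cfg$n_pops))
  hs <- HaplotypeSet(hap, chrom, pos, sample_ids = sample_ids,
                     population = population, sort = FALSE)
  ds <- genotypesFromHaps(hs)
  if (cfg$missing_rate > 0) {
    g <- genotypes(ds)
    g[stats::runif(length(g)) < cfg$missing_rate] <- NA_integer_
    ds <- GenotypeDataset(g, chrom, pos, variantIds(ds), sample_ids,
                          population, sort = FALSE)
  }
  truth <- list(ancestral_freq = p_anc, pop_freq = pop_freq,
                founders = founders, config = cfg)
  list(genotypes = ds, haplotypes = hs, truth = truth)
}

#' Inject a selective sweep into phased haplotypes
#'
#' A fraction `carrier_fraction` of the target population's haplotypes have
#' their alleles over `[core_bp - tract/2, core_bp + tract/2]` replaced by
#' one fixed donor haplotype, producing the long shared haplotype at high
#' frequency that XP-EHH detects.  A tract extending beyond the chromosome
#' is clipped with a warning.
#'
#' @param hs a [HaplotypeSet-class]
#' @param sweep_spec list with `chrom`, `core_bp`, `carrier_fraction` in
#'   (0, 1], `tract_length_bp`, and `pop` (target population label)
#' @param seed integer seed for carrier/donor choice
#' @return the modified `HaplotypeSet`; `metadata(x)$sweep` records the
#'   donor, carriers and tract actually applied
#' @export
injectSweep <- function(hs, sweep_spec, seed = 1L) {
  s <- sweep_spec
  stopifnot(is.list(s), s$carrier_fraction > 0, s$carrier_fraction <= 1)
  set.seed(seed)
  chr <- chromOf(hs); pos <- posBp(hs)
  on_chr <- chr == as.character(s$chrom)
  if (!any(on_chr)) stop("no variants on chromosome ", s$chrom)
  chrom_max <- max(pos[on_chr])
  if (s$core_bp < 1 || s$core_bp > chrom_max)
    stop("core_bp outside chromosome")
  lo <- s$core_bp - s$tract_length_bp / 2
  hi <- s$core_bp + s$tract_length_bp / 2
  if (lo < 1 || hi > chrom_max) {
    warning("sweep tract clipped to chromosome bounds")
    lo <- max(1, lo); hi <- min(chrom_max, hi)
  }
  in_tract <- on_chr & pos >= lo & pos <= hi
  hap_pop <- colData(hs)$population == s$pop
  idx <- which(hap_pop)
  if (!length(idx)) stop("no haplotypes in population ", s$pop)
  n_car <- max(2L, ceiling(s$carrier_fraction * length(idx)))
  carriers <- sort(sample(idx, min(n_car, length(idx))))
  donor <- sample(idx, 1L)
  h <- haplotypes(hs)
  h[in_tract, carriers] <- h[in_tract, donor]
  out <- HaplotypeSet(h, chr, pos, variantIds(hs), sampleIds(hs),
                      unname(popLabels(hs)), mapCm(hs), sort = FALSE)
  metadata(out)$sweep <- list(spec = s, donor = donor, carriers = carriers,
                              tract = c(lo, hi),
                              core_bp = s$core_bp)
  out
}

.mergeTracts <- function(df) {
  ## merge overlapping/adjacent tracts per sample and chromosome
  out <- lapply(split(df, list(df$sample_id, df$chrom), drop = TRUE),
                function(d) {
    d <- d[order(d$start_bp), , drop = FALSE]
    keep <- d[1L, , drop = FALSE]
    for (i in seq_len(nrow(d))[-1L]) {
      last <- nrow(keep)
      if (d$start_bp[i] <= keep$stop_bp[last] + 1)
        keep$stop_bp[last] <- max(keep$stop_bp[last], d$stop_bp[i])
      else keep <- rbind(keep, d[i, , drop = FALSE])
    }
    keep
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$sample_id, out$chrom, out$start_bp), , drop = FALSE]
}

#' Inject autozygous tracts (ground truth for ROH detection)
#'
#' Within each tract the individual's second haplotype is overwritten by the
#' first, making every genotype in the tract homozygous.  Overlapping tracts
#' for one sample are merged before application; the merged truth list is
#' returned for detector-recovery tests.  When only genotypes are available,
#' heterozygous calls inside a tract are resolved to a homozygote by an
#' implied first-haplotype allele drawn Bernoulli(0.5).
#'
#' @param x a [HaplotypeSet-class], [GenotypeDataset-class], or the list
#'   returned by [simulateDivergentPops()]
#' @param tracts data.frame with `sample_id`, `chrom`, `start_bp`, `stop_bp`
#' @param seed seed for genotype-only resolution
#' @return list with `genotypes`, `haplotypes` (`NULL` if genotype-only
#'   input) and `tracts` (merged truth)
#' @export
injectAutozygosity <- function(x, tracts, seed = 1L) {
  stopifnot(all(c("sample_id", "chrom", "start_bp", "stop_bp") %in%
                colnames(tracts)))
  tracts$chrom <- as.character(tracts$chrom)
  tracts <- .mergeTracts(tracts)
  if (!is(x, "HaplotypeSet") && !is(x, "GenotypeDataset") &&
      is.list(x) && !is.null(x$haplotypes))
    x <- x$haplotypes
  if (is(x, "HaplotypeSet")) {
    h <- haplotypes(x)
    sid <- colData(x)$sample_id
    chr <- chromOf(x); pos <- posBp(x)
    for (i in seq_len(nrow(tracts))) {
      cols <- which(sid == tracts$sample_id[i])
      if (length(cols) != 2L) stop("unknown sample ", tracts$sample_id[i])
      rows <- chr == tracts$chrom[i] &
              pos >= tracts$start_bp[i] & pos <= tracts$stop_bp[i]
      h[rows, cols[2L]] <- h[rows, cols[1L]]
    }
    hs <- HaplotypeSet(h, chr, pos, variantIds(x), sampleIds(x),
                       unname(popLabels(x)), mapCm(x), sort = FALSE)
    return(list(genotypes = genotypesFromHaps(hs), haplotypes = hs,
                tracts = tracts))
  }
  stopifnot(is(x, "GenotypeDataset"))
  set.seed(seed)
  g <- genotypes(x)
  chr <- chromOf(x); pos <- posBp(x)
  for (i in seq_len(nrow(tracts))) {
    col <- match(tracts$sample_id[i], sampleIds(x))
    if (is.na(col)) stop("unknown sample ", tracts$sample_id[i])
    rows <- which(chr == tracts$chrom[i] &
                  pos >= tracts$start_bp[i] & pos <= tracts$stop_bp[i])
    het <- rows[!is.na(g[rows, col]) & g[rows, col] == 1L]
    g[het, col] <- 2L * stats::rbinom(length(het), 1L, 0.5)
  }
  ds <- GenotypeDataset(g, chr, pos, variantIds(x), sampleIds(x),
                        unname(popLabels(x)), sort = FALSE)
  list(genotypes = ds, haplotypes = NULL, tracts = tracts)
}

#' Forward Wright-Fisher simulation with recombination
#'
#' Discrete-generation neutral Wright-Fisher model for a constant diploid
#' population: each offspring haplotype is a recombinant gamete of a random
#' parent (crossovers Poisson along the chromosome), with symmetric per-site
#' mutation.  Desk-scale only (`n_diploid` <= 200, `n_generations` <= 500);
#' the output's LD reflects the constant effective size, which is what the
#' Sved-equation stage is checked against.
#'
#' @param n_diploid constant diploid population size
#' @param n_generations generations to evolve
#' @param chrom_length_bp chromosome length
#' @param n_sites number of polymorphic-site positions tracked
#' @param mut_rate per-site per-generation flip probability
#' @param recomb_rate per-bp per-generation crossover rate (Morgan/bp)
#' @param seed mandatory integer seed
#' @param init `"segregating"` (initial frequencies Uniform(0.1, 0.9)) or
#'   `"monomorphic"` (all zero)
#' @return a [HaplotypeSet-class]; `rowData$map_cm` uses the true
#'   recombination rate
#' @export
forwardWrightFisher <- function(n_diploid, n_generations, chrom_length_bp,
                                n_sites = 500L, mut_rate = 1e-5,
                                recomb_rate = 1e-8, seed,
                                init = c("segregating", "monomorphic")) {
  init <- match.arg(init)
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(n_diploid >= 2L, n_diploid <= 200L,
            n_generations >= 1L, n_generations <= 500L)
  set.seed(seed)
  pos <- sort(sample.int(chrom_length_bp, n_sites))
  n_hap <- 2L * n_diploid
  H <- if (init == "monomorphic") matrix(0L, n_hap, n_sites)
       else {
         p0 <- stats::runif(n_sites, 0.1, 0.9)
         matrix(stats::rbinom(n_hap * n_sites, 1L, rep(p0, each = n_hap)),
                n_hap, n_sites)
       }
  exp_co <- recomb_rate * chrom_length_bp
  for (g in seq_len(n_generations)) {
    parents <- sample.int(n_diploid, n_hap, replace = TRUE)
    n_co <- stats::rpois(n_hap, exp_co)
    start_hap <- sample.int(2L, n_hap, replace = TRUE)
    Hnew <- matrix(0L, n_hap, n_sites)
    for (i in seq_len(n_hap)) {
      h1 <- H[2L * parents[i] - 1L, ]
      h2 <- H[2L * parents[i], ]
      if (start_hap[i] == 2L) { tmp <- h1; h1 <- h2; h2 <- tmp }
      if (n_co[i] == 0L) Hnew[i, ] <- h1
      else {
        br <- sort(stats::runif(n_co[i], 0, chrom_length_bp))
        seg <- findInterval(pos, br) %% 2L
        Hnew[i, ] <- ifelse(seg == 0L, h1, h2)
      }
    }
    H <- Hnew
    if (mut_rate > 0) {
      n_mut <- stats::rbinom(1L, n_hap * n_sites, mut_rate)
      if (n_mut > 0L) {
        idx <- sample.int(n_hap * n_sites, n_mut)
        H[idx] <- 1L - H[idx]
      }
    }
  }
  HaplotypeSet(t(H), rep("1", n_sites), pos,
               sample_ids = sprintf("wf_s%03d", seq_len(n_diploid)),
               population = rep("wf", n_diploid),
               map_cm = pos * recomb_rate * 100, sort = FALSE)
}
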