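test_that("single clean run is detected with its SNP count", {
  set.seed(71)
  pos <- sort(sample(2:1199999, 58)); pos <- c(1, pos, 1200001)
  ds <- GenotypeDataset(matrix(0L, 60, 1), rep("1", 60), pos)
  seg <- detectRoh(ds)
  expect_equal(nrow(seg), 1L)
  expect_equal(seg$n_snps, 60L)
  expect_equal(seg$length_bp, 1200000)
})

test_that("a large gap splits a run and short fragments are dropped", {
  ## 60 homozygous SNPs: first 30 span 0.6 Mb (dropped), gap of 1.5 Mb,
  ## last 30 span 1.2 Mb (kept)
  pos <- c(seq(1, 600001, length.out = 30),
           seq(2100001, 3300001, length.out = 30))
  ds <- GenotypeDataset(matrix(0L, 60, 1), rep("1", 60), round(pos),
                        variant_ids = sprintf("v%02d", 1:60))
  p <- rohParams(min_consecutive_snps = 30)
  seg <- detectRoh(ds, p)
  expect_equal(nrow(seg), 1L)
  expect_gte(seg$start_bp, 2100001)
})

test_that("runs violating the density rule are rejected", {
  pos <- round(seq(1, 6e6, length.out = 50))   # 50 SNPs over 6 Mb: 1/120 kb
  expect_true(all(diff(pos) <= 1e6))
  ds <- GenotypeDataset(matrix(0L, 50, 1), rep("1", 50), pos)
  expect_equal(nrow(detectRoh(ds)), 0L)
})

test_that("heterozygote and missing budgets are enforced", {
  set.seed(72)
  pos <- seq(1, 1.5e6, length.out = 100)
  g <- matrix(0L, 100, 1)
  g[c(30, 60), 1] <- 1L                    # two hets: run must break
  ds <- GenotypeDataset(g, rep("1", 100), round(pos))
  seg <- detectRoh(ds, rohParams(min_consecutive_snps = 20,
                                 min_length_bp = 2e5))
  expect_true(all(seg$n_het <= 1))
  expect_gt(nrow(seg), 1L)
})

test_that("detector equals the brute-force sub-run oracle on random fixtures", {
  p <- rohParams(min_consecutive_snps = 15, min_length_bp = 3e5,
                 max_missing_per_run = 2, max_gap_bp = 2e5)
  set.seed(73)
  for (rep in 1:5) {
    n <- 1500
    pos <- sort(sample.int(3e7, n))
    g <- matrix(NA_integer_, n, 5)
    for (s in 1:5) {
      ## blocky genotypes: stretches of homozygosity with sprinkled hets
      state <- rbinom(n, 1, 0.02)
      g[, s] <- ifelse(cumsum(state) %% 2 == 0,
                       ifelse(runif(n) < 0.03, 1L, 0L),
                       rbinom(n, 2, 0.5))
      g[runif(n) < 0.02, s] <- NA
    }
    ds <- GenotypeDataset(g, rep("1", n), pos)
    seg <- detectRoh(ds, p)
    for (s in 1:5) {
      oracle <- bruteForceRoh(pos, g[, s], p)
      mine <- seg[seg$sample_id == sampleIds(ds)[s], , drop = FALSE]
      expect_equal(nrow(mine), length(oracle))
      if (length(oracle)) {
        om <- do.call(rbind, oracle)
        expect_equal(mine$start_bp, unname(om[, "start"]))
        expect_equal(mine$stop_bp, unname(om[, "stop"]))
        expect_equal(mine$n_snps, unname(om[, "n_snps"]))
      }
    }
  }
})

test_that("F_ROH is the forced length ratio and monotone in added segments", {
  seg <- data.frame(sample_id = "s1", chrom = "1", start_bp = 1,
                    stop_bp = 24500001, n_snps = 1000, n_het = 0,
                    n_missing = 0, length_bp = 24.5e6)
  fr <- froh(seg, c("s1", "s2"))
  expect_equal(fr$f_roh[fr$sample_id == "s1"], 0.01)
  expect_equal(fr$f_roh[fr$sample_id == "s2"], 0)
  seg2 <- rbind(seg, data.frame(sample_id = "s1", chrom = "2", start_bp = 1,
                                stop_bp = 1e6 + 1, n_snps = 100, n_het = 0,
                                n_missing = 0, length_bp = 1e6))
  fr2 <- froh(seg2, c("s1", "s2"))
  expect_gt(fr2$f_roh[1], fr$f_roh[1])
})

test_that("detector recovers injected autozygous tracts", {
  sim <- simulateDivergentPops(simConfig(n_per_pop = 8, n_variants = 4000,
                                         chrom_length_bp = 4e7,
                                         rng_seed = 74))
  sid <- sampleIds(sim$genotypes)[1:3]
  tracts <- data.frame(sample_id = sid, chrom = "1",
                       start_bp = c(5e6, 1e7, 2e7),
                       stop_bp = c(7e6, 1.3e7, 2.25e7))
  inj <- injectAutozygosity(sim, tracts)
  seg <- detectRoh(inj$genotypes)
  for (k in 1:3) {
    mine <- seg[seg$sample_id == sid[k], , drop = FALSE]
    expect_gte(nrow(mine), 1L)
    cover <- sum(pmax(0, pmin(mine$stop_bp, tracts$stop_bp[k]) -
                        pmax(mine$start_bp, tracts$start_bp[k]) + 1))
    expect_gte(cover / (tracts$stop_bp[k] - tracts$start_bp[k]), 0.95)
  }
})

test_that("outbred simulations yield no ROH passing the 1 Mb / 50 SNP rule", {
  hits <- vapply(1:5, function(s) {
    sim <- simulateDivergentPops(simConfig(n_pops = 1, n_per_pop = 10,
                                           n_variants = 2000,
                                           chrom_length_bp = 2e7,
                                           mosaic_switch_rate = 1e-5,
                                           rng_seed = 100 + s))
    nrow(detectRoh(sim$genotypes))
  }, numeric(1))
  expect_lte(sum(hits > 0), 1)             # none in nearly all replicates
})

test_that("island intervals match the occupancy oracle", {
  sim <- simulateDivergentPops(simConfig(n_per_pop = 10, n_variants = 3000,
                                         chrom_length_bp = 3e7,
                                         rng_seed = 75))
  ids <- sampleIds(sim$genotypes)[1:10]
  tracts <- data.frame(sample_id = rep(ids[1:7], each = 1), chrom = "1",
                       start_bp = 1e7, stop_bp = 1.2e7)
  inj <- injectAutozygosity(sim, tracts)
  seg <- detectRoh(inj$genotypes)
  occ <- rohOccupancy(seg, ids, inj$genotypes)
  isl <- rohIslands(seg, ids, inj$genotypes, freq_threshold = 0.5)
  pos <- posBp(inj$genotypes)
  in_island <- rep(FALSE, length(pos))
  for (i in seq_along(isl))
    in_island <- in_island |
      (chromOf(inj$genotypes) == as.character(seqnames(isl))[i] &
       pos >= start(isl)[i] & pos <= end(isl)[i])
  ## SNP-level agreement with the >= 50% occupancy rule
  expect_identical(in_island, occ >= 0.5)
  expect_true(any(occ >= 0.5))             # 7/10 tract really made an island
})

test_that("occupancy thresholds: 6/10 is an island, 4/10 is not", {
  n <- 200
  pos <- seq_len(n) * 1e4
  seg <- do.call(rbind, lapply(1:6, function(k)
    data.frame(sample_id = sprintf("s%03d", k), chrom = "1",
               start_bp = 5e5, stop_bp = 1e6, n_snps = 50, n_het = 0,
               n_missing = 0, length_bp = 5e5)))
  ds <- GenotypeDataset(matrix(0L, n, 10), rep("1", n), pos)
  occ <- rohOccupancy(seg, sampleIds(ds), ds)
  expect_true(all(occ[pos >= 5e5 & pos <= 1e6] == 0.6))
  isl <- rohIslands(seg, sampleIds(ds), ds)
  expect_equal(length(isl), 1L)
  seg4 <- seg[1:4, ]
  expect_equal(length(rohIslands(seg4, sampleIds(ds), ds)), 0L)
})

test_that("private islands follow interval subtraction", {
  a <- genomicIntervals("1", c(100, 1000), c(200, 2000), method = "ROH",
                        comparison = "g1")
  b_far <- genomicIntervals("1", 5000, 6000)
  expect_equal(length(privateIslands(a, b_far)), 2L)     # disjoint: unchanged
  expect_equal(length(privateIslands(a, a)), 0L)          # identical: empty
  b <- genomicIntervals("1", 150, 300)
  pr <- privateIslands(a[1], b)
  expect_equal(start(pr), 100)
  expect_equal(end(pr), 149)
  expect_equal(mcols(pr)$retention, "segment")
})
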