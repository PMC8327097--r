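test_that("generators are deterministic under a fixed seed", {
  cfg <- simConfig(n_per_pop = 20, n_variants = 300, chrom_length_bp = 1e7,
                   rng_seed = 42)
  a <- simulateDivergentPops(cfg)
  b <- simulateDivergentPops(cfg)
  expect_identical(genotypes(a$genotypes), genotypes(b$genotypes))
  expect_identical(haplotypes(a$haplotypes), haplotypes(b$haplotypes))
  w1 <- forwardWrightFisher(10, 20, 1e6, n_sites = 50, seed = 5)
  w2 <- forwardWrightFisher(10, 20, 1e6, n_sites = 50, seed = 5)
  expect_identical(haplotypes(w1), haplotypes(w2))
  expect_error(simConfig(n_per_pop = 5, n_variants = 10,
                         chrom_length_bp = 1e5), "rng_seed")
})

test_that("genotypes equal the sum of the two haplotypes everywhere", {
  sim <- simulateDivergentPops(simConfig(n_per_pop = 15, n_variants = 200,
                                         chrom_length_bp = 5e6,
                                         rng_seed = 8))
  h <- haplotypes(sim$haplotypes)
  g <- genotypes(sim$genotypes)
  expect_identical(unname(h[, seq(1, 59, 2)] + h[, seq(2, 60, 2)]),
                   unname(g))
})

test_that("undiverged populations show near-zero differentiation", {
  sim <- simulateDivergentPops(simConfig(n_per_pop = 100, n_variants = 5000,
                                         chrom_length_bp = 1e8,
                                         target_fst = 0, rng_seed = 21))
  th <- wcFst(sim$genotypes, "pop1", "pop2", n_perm = 0)$theta
  expect_lt(abs(th), 0.02)
})

test_that("Weir-Cockerham theta recovers the Balding-Nichols F parameter", {
  th <- vapply(1:3, function(s) {
    sim <- simulateDivergentPops(simConfig(n_per_pop = 100,
                                           n_variants = 5000,
                                           chrom_length_bp = 1e8,
                                           target_fst = 0.10, rng_seed = s))
    wcFst(sim$genotypes, "pop1", "pop2", n_perm = 0)$theta
  }, numeric(1))
  expect_true(all(abs(th - 0.10) <= 0.02))
})

test_that("a full sweep makes every carrier identical across the tract", {
  sim <- simulateDivergentPops(simConfig(n_per_pop = 20, n_variants = 500,
                                         chrom_length_bp = 1e7,
                                         rng_seed = 13))
  hs <- injectSweep(sim$haplotypes,
                    list(chrom = "1", core_bp = 5e6, carrier_fraction = 1,
                         tract_length_bp = 2e6, pop = "pop1"), seed = 2)
  core <- which.min(abs(posBp(hs) - 5e6))
  al <- haplotypes(hs)[core, 1]            # pop1 haplotypes all identical
  curve <- ehh(subsetPop(hs, "pop1"), core, al)
  tract <- metadata(hs)$sweep$tract
  in_tract_r <- curve$right$pos <= tract[2]
  in_tract_l <- curve$left$pos >= tract[1]
  expect_true(all(curve$right$ehh[in_tract_r] == 1))
  expect_true(all(curve$left$ehh[in_tract_l] == 1))
})

test_that("a partial sweep bounds EHH at the tract edge by the carrier pairs", {
  sim <- simulateDivergentPops(simConfig(n_per_pop = 40, n_variants = 500,
                                         chrom_length_bp = 1e7,
                                         rng_seed = 14))
  hs <- injectSweep(sim$haplotypes,
                    list(chrom = "1", core_bp = 5e6, carrier_fraction = 0.5,
                         tract_length_bp = 2e6, pop = "pop1"), seed = 3)
  md <- metadata(hs)$sweep
  expect_equal(length(md$carriers), 40)    # 0.5 of 80 haplotypes
  h1 <- subsetPop(hs, "pop1")
  core <- which.min(abs(posBp(h1) - 5e6))
  al <- haplotypes(hs)[core, md$carriers[1]]   # the donor allele at the core
  curve <- ehh(h1, core, al)
  edge_ehh <- min(curve$right$ehh[curve$right$pos <= md$tract[2]])
  n_core <- curve$n_carriers
  expect_gte(edge_ehh, choose(40, 2) / choose(n_core, 2) - 1e-12)
})

test_that("a one-population sweep yields positive mean XP-EHH near the core", {
  sim <- simulateDivergentPops(simConfig(n_per_pop = 30, n_variants = 600,
                                         chrom_length_bp = 1.5e7,
                                         target_fst = 0.02, rng_seed = 15))
  hs <- injectSweep(sim$haplotypes,
                    list(chrom = "1", core_bp = 7.5e6,
                         carrier_fraction = 0.8, tract_length_bp = 1e6,
                         pop = "pop1"), seed = 4)
  rec <- xpehhScan(subsetPop(hs, "pop1"), subsetPop(hs, "pop2"))
  near <- abs(rec$pos - 7.5e6) <= 5e5
  expect_gt(mean(rec$raw[near], na.rm = TRUE), 0)
})

test_that("tracts exceeding the chromosome are clipped with a warning", {
  sim <- simulateDivergentPops(simConfig(n_per_pop = 10, n_variants = 200,
                                         chrom_length_bp = 2e6,
                                         rng_seed = 16))
  expect_warning(injectSweep(sim$haplotypes,
                             list(chrom = "1", core_bp = 1e5,
                                  carrier_fraction = 1,
                                  tract_length_bp = 1e6, pop = "pop1"),
                             seed = 1), "clipped")
})

test_that("injected autozygous tracts are fully homozygous and merged", {
  sim <- simulateDivergentPops(simConfig(n_per_pop = 10, n_variants = 1000,
                                         chrom_length_bp = 2e7,
                                         rng_seed = 17))
  sid <- sampleIds(sim$genotypes)[1]
  tracts <- data.frame(sample_id = sid, chrom = "1",
                       start_bp = c(2e6, 3.5e6, 1e7),
                       stop_bp = c(4e6, 5e6, 1.2e7))
  inj <- injectAutozygosity(sim, tracts)
  expect_equal(nrow(inj$tracts), 2L)       # first two overlap -> merged
  expect_equal(inj$tracts$stop_bp[1], 5e6)
  g <- genotypes(inj$genotypes)[, sid]
  pos <- posBp(inj$genotypes)
  in_tract <- (pos >= 2e6 & pos <= 5e6) | (pos >= 1e7 & pos <= 1.2e7)
  expect_true(all(g[in_tract] %in% c(0L, 2L)))
})

test_that("Wright-Fisher with no mutation from a monomorphic start stays monomorphic", {
  hs <- forwardWrightFisher(10, 50, 1e6, n_sites = 40, mut_rate = 0,
                            seed = 6, init = "monomorphic")
  expect_true(all(haplotypes(hs) == 0L))
})
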