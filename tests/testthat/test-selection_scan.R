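test_that("per-SNP F_ST matches the printed formula", {
  expect_equal(snpFst(0.5, 0.5), 0)
  expect_equal(snpFst(1, 0), 1)
  expect_equal(snpFst(0.8, 0.2), 0.36)
  expect_true(is.na(snpFst(0, 0)))         # pooled-monomorphic skipped
  ## zero whenever p1 = p2; one iff fixed difference
  p <- seq(0.05, 0.95, by = 0.05)
  expect_true(all(abs(snpFst(p, p)) < 1e-12))
  expect_true(all(snpFst(p, rev(p))[p != 0.5] < 1))
})

test_that("window tiling follows the bp-1 anchored convention", {
  w <- ovisweep:::.tileWindows(1e6, 2e5, 6e4)
  expect_equal(nrow(w), 14L)
  expect_equal(w[1, ], c(start = 1, stop = 2e5))
  expect_equal(unname(w[14, "start"]), 780001)
  expect_lte(max(w[, "stop"]), 1e6)
})

test_that("ZF_ST is standardized and candidates are the top 0.1% by construction", {
  sim <- simulateDivergentPops(simConfig(n_per_pop = 30, n_variants = 4000,
                                         chrom_length_bp = 6e7,
                                         target_fst = 0.05, rng_seed = 91))
  sc <- windowFstScan(sim$genotypes, "pop1", "pop2")
  z <- sc$windows$zfst
  expect_lt(abs(mean(z)), 1e-9)
  expect_lt(abs(sd(z) - 1), 1e-9)
  expect_equal(sum(sc$windows$candidate),
               ceiling(0.001 * nrow(sc$windows)))
  expect_true(all(sc$windows$zfst[sc$windows$candidate] > 0))
})

test_that("a locus-specific divergence spike is ranked first", {
  hits <- vapply(1:5, function(s) {
    set.seed(900 + s)
    m <- 2000; n <- 50
    p <- runif(m, 0.1, 0.9)
    f_locus <- rep(0.05, m)
    spike <- 901:950                      # one 50-SNP block at high F
    f_locus[spike] <- 0.5
    p1 <- rbeta(m, p * (1 - f_locus) / f_locus,
                (1 - p) * (1 - f_locus) / f_locus)
    p2 <- rbeta(m, p * (1 - f_locus) / f_locus,
                (1 - p) * (1 - f_locus) / f_locus)
    g <- cbind(matrix(rbinom(m * n, 2, rep(p1, n)), m, n),
               matrix(rbinom(m * n, 2, rep(p2, n)), m, n))
    pos <- seq_len(m) * 1e4               # spike spans 9.01-9.5 Mb
    ds <- GenotypeDataset(g, rep("1", m), pos,
                          population = rep(c("A", "B"), each = n))
    sc <- windowFstScan(ds, "A", "B")
    top <- sc$windows[which.max(sc$windows$zfst), ]
    top$stop >= 9.01e6 && top$start <= 9.5e6
  }, logical(1))
  expect_gte(sum(hits), 4)
})

test_that("identical windows trigger the degenerate-scan error", {
  g <- matrix(rep(c(0L, 2L), each = 4, times = 60), 60, 8, byrow = TRUE)
  ds <- GenotypeDataset(g, rep("1", 60), seq_len(60) * 1e4,
                        population = rep(c("A", "B"), each = 4))
  expect_error(windowFstScan(ds, "A", "B", window_bp = 1e5, step_bp = 1e5),
               "degenerate")
})

test_that("EHH matches pair enumeration and is non-increasing", {
  ## 4 carriers splitting 2/2 at the first flanking SNP: EHH = 1/3
  h <- matrix(0L, 3, 8)
  h[1, ] <- c(1, 1, 1, 1, 0, 0, 0, 0)      # core: carriers are haps 1-4
  h[2, ] <- c(0, 0, 1, 1, 0, 0, 0, 0)      # 2/2 split among carriers
  h[3, ] <- c(0, 1, 0, 1, 0, 0, 0, 0)
  hs <- HaplotypeSet(h, rep("1", 3), c(1e5, 2e5, 3e5),
                     sample_ids = sprintf("s%d", 1:4))
  curve <- ehh(hs, 1, 1)
  ## site 2 splits carriers 2/2 (EHH = 1/3); site 3 makes all four distinct
  expect_equal(curve$right$ehh, c(1, 1 / 3, 0))
  ## identical carriers: EHH stays 1
  h2 <- matrix(0L, 5, 6); h2[1, 1:4] <- 1L
  hs2 <- HaplotypeSet(h2, rep("1", 5), (1:5) * 1e5,
                      sample_ids = sprintf("t%d", 1:3))
  expect_true(all(ehh(hs2, 1, 1)$right$ehh == 1))
  ## refinement property on random data
  hs3 <- randomHaplotypeSet(10, 40, seed = 92)
  cv <- ehh(hs3, 20, haplotypes(hs3)[20, 1])
  expect_true(all(diff(cv$right$ehh) <= 1e-12))
  expect_true(all(diff(cv$left$ehh) <= 1e-12))
  expect_error(ehh(hs2, 2, 1), "carriers")
})

test_that("EHH equals the exhaustive distinct-haplotype oracle", {
  set.seed(93)
  for (rep in 1:4) {
    hs <- randomHaplotypeSet(25, 100, seed = 930 + rep)  # 50 haplotypes
    h <- haplotypes(hs)
    core <- sample(20:80, 1)
    al <- h[core, 1]
    carriers <- which(h[core, ] == al)
    curve <- ehh(hs, core, al)
    for (k in 2:min(8, nrow(curve$right)))
      expect_equal(curve$right$ehh[k],
                   ehhEnumOracle(h, carriers, core:(curve$right$index[k])))
    for (k in 2:min(8, nrow(curve$left)))
      expect_equal(curve$left$ehh[k],
                   ehhEnumOracle(h, carriers, (curve$left$index[k]):core))
  }
})

test_that("iHH integrates a flat curve to the rectangle and truncates", {
  ## EHH == 1 over 1 cM each side: iHH = 2
  mk <- function(cm, e) data.frame(index = seq_along(cm), pos = cm * 1e6,
                                   map_cm = cm, ehh = e)
  curve <- list(left = mk(seq(5, 4, by = -0.25), rep(1, 5)),
                right = mk(seq(5, 6, by = 0.25), rep(1, 5)))
  expect_equal(ihh(curve), 2)
  ## points below truncation add nothing beyond the crossing trapezoid
  r <- mk(c(5, 5.1, 5.2, 5.3), c(1, 0.5, 0.01, 0.8))
  curve2 <- list(left = mk(5, 1), right = r)
  manual <- (1 + 0.5) / 2 * 0.1 + (0.5 + 0.01) / 2 * 0.1
  expect_equal(ihh(curve2), manual)
})

test_that("trapezoidal iHH agrees with a 10x denser refinement oracle", {
  ## smooth exponential decay sampled coarsely vs densely
  x <- seq(0, 3, length.out = 31)
  xd <- seq(0, 3, length.out = 301)
  mk <- function(cm, e) data.frame(index = seq_along(cm), pos = cm * 1e6,
                                   map_cm = cm, ehh = e)
  coarse <- list(left = mk(5, 1), right = mk(5 + x, exp(-1.5 * x)))
  dense <- list(left = mk(5, 1), right = mk(5 + xd, exp(-1.5 * xd)))
  expect_lt(abs(ihh(coarse) - ihh(dense)) / ihh(dense), 0.05)
})

test_that("the joint scan path equals the per-allele ihh(ehh(.)) route", {
  ## without truncation the shared integration boundary is the chromosome
  ## end for both populations, so the joint fast path must reproduce the
  ## frequency-weighted per-allele reference exactly
  hsA <- randomHaplotypeSet(15, 60, seed = 94)
  set.seed(294)                            # same variant grid, new haplotypes
  hB <- matrix(rbinom(60 * 30, 1, runif(60, 0.2, 0.8)), 60, 30)
  hsB <- HaplotypeSet(hB, chromOf(hsA), posBp(hsA))
  hA <- haplotypes(hsA); hB <- haplotypes(hsB)
  cm <- mapCm(hsA)
  ref <- function(hs, h, j) {
    out <- 0
    for (al in 0:1) {
      w <- mean(h[j, ] == 1); w <- if (al == 1) w else 1 - w
      if (w == 0 || sum(h[j, ] == al) < 2) next
      out <- out + w * ihh(ehh(hs, j, al), truncation = 0)
    }
    out
  }
  for (j in c(5, 25, 47)) {
    fast <- ovisweep:::.sitePairIhh(hA, hB, cm, seq_len(nrow(hA)), j,
                                    truncation = 0)
    expect_equal(fast[1], ref(hsA, hA, j), tolerance = 1e-9)
    expect_equal(fast[2], ref(hsB, hB, j), tolerance = 1e-9)
  }
})

test_that("XP-EHH is zero for identical populations and antisymmetric", {
  hs <- randomHaplotypeSet(20, 80, seed = 95)
  rec <- xpehhScan(hs, hs)
  expect_true(all(abs(rec$raw[!is.na(rec$raw)]) < 1e-12))
  ## two different populations: swapping negates raw and preserves |Z|
  sim <- simulateDivergentPops(simConfig(n_per_pop = 20, n_variants = 300,
                                         chrom_length_bp = 6e6,
                                         target_fst = 0.05, rng_seed = 96))
  a <- subsetPop(sim$haplotypes, "pop1")
  b <- subsetPop(sim$haplotypes, "pop2")
  r1 <- xpehhScan(a, b)
  r2 <- xpehhScan(b, a)
  ok <- !is.na(r1$raw)
  expect_equal(r1$raw[ok], -r2$raw[ok], tolerance = 1e-12)
  expect_equal(abs(r1$z[ok]), abs(r2$z[ok]), tolerance = 1e-9)
})

test_that("an injected sweep is detected inside its tract", {
  sim <- simulateDivergentPops(simConfig(n_per_pop = 40, n_variants = 1200,
                                         chrom_length_bp = 1.6e7,
                                         target_fst = 0.05, rng_seed = 97))
  hs <- injectSweep(sim$haplotypes,
                    list(chrom = "1", core_bp = 8e6, carrier_fraction = 0.8,
                         tract_length_bp = 1e6, pop = "pop1"), seed = 5)
  rec <- xpehhScan(subsetPop(hs, "pop1"), subsetPop(hs, "pop2"))
  top <- rec[which.max(rec$z), ]
  expect_gte(top$pos, 7.5e6)
  expect_lte(top$pos, 8.5e6)
  expect_equal(top$direction, "A")
})

test_that("significant SNPs merge into directional regions like a naive gap-merge", {
  rec <- data.frame(variant_id = sprintf("v%d", 1:8), chrom = "1",
                    pos = c(1e5, 1.4e5, 2e5, 8e5, 8.5e5, 2e6, 2.05e6, 3e6),
                    significant = c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE,
                                    TRUE, TRUE),
                    direction = c("A", "A", "A", "A", "A", "B", "B", "A"))
  gr <- significantRegions(rec, merge_gap_bp = 2e5)
  ## naive merge, per direction: A {1e5..2e5}, {8e5}, {3e6}; B {2e6..2.05e6}
  expect_equal(length(gr), 4L)
  a <- gr[mcols(gr)$direction == "A"]
  expect_equal(sort(start(a)), c(1e5, 8e5, 3e6))
  expect_equal(sort(end(a)), c(2e5, 8e5, 3e6))
  expect_equal(length(significantRegions(rec[rec$direction == "Z", ])), 0L)
})
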