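svRow <- function(p1, p2, cls = "DEL", chrom = "chr1", sample = "S1") {
  strands <- switch(cls, DEL = c("+", "-"), DUP = c("-", "+"),
                    h2hINV = c("+", "+"), t2tINV = c("-", "-"))
  data.frame(sample = sample, chrom1 = chrom, pos1 = p1,
             strand1 = strands[1], chrom2 = chrom, pos2 = p2,
             strand2 = strands[2], sv_class = cls,
             stringsAsFactors = FALSE)
}

test_that("interleaving means overlapping but not nested intervals", {
  svs <- rbind(svRow(1, 10), svRow(5, 20))
  cl <- interleavedClusters(svs)
  expect_length(cl, 1L)
  expect_equal(nrow(cl[[1L]]), 2L)
  # nested intervals do not interleave
  svs <- rbind(svRow(1, 100), svRow(10, 20))
  cl <- interleavedClusters(svs)
  expect_length(cl, 2L)
  # chained intervals form a single connected component
  chain <- do.call(rbind, lapply(1:7, function(i)
    svRow(i * 10, i * 10 + 15)))
  cl <- interleavedClusters(chain)
  expect_length(cl, 1L)
  expect_equal(nrow(cl[[1L]]), 7L)
})

test_that("interleaving clusters match the brute-force component oracle", {
  set.seed(44)
  for (rep in 1:5) {
    m <- 12
    p1 <- sample.int(1e6, m)
    p2 <- p1 + sample.int(3e5, m)
    svs <- do.call(rbind, lapply(seq_len(m), function(i)
      svRow(p1[i], p2[i])))
    cl <- interleavedClusters(svs)
    oracle <- bruteInterleaveClusters(sort(p1),
                                      p2[order(p1)])
    # same multiset of cluster sizes
    expect_equal(sort(vapply(cl, nrow, integer(1))),
                 sort(as.integer(table(oracle))))
  }
})

test_that("oscillation run length matches the brute-force oracle", {
  expect_equal(maxAlternatingRun(c(2, 1, 2, 1, 2, 1, 2)), 7L)
  expect_equal(maxAlternatingRun(c(2, 2, 2)), 1L)
  expect_equal(maxAlternatingRun(integer(0)), 0L)
  # oracle-computed value for a run switching its second value mid-way
  v <- c(2, 1, 2, 3, 2, 3, 2, 3, 2)
  expect_equal(bruteMaxAlt(v), 7L)
  expect_equal(maxAlternatingRun(v), bruteMaxAlt(v))
  set.seed(12)
  for (i in 1:20) {
    v <- sample(1:3, sample(3:12, 1), replace = TRUE)
    expect_equal(maxAlternatingRun(v), bruteMaxAlt(v))
  }
})

test_that("maxOscillation reads segments overlapping the region in order", {
  prof <- makeProfile("S1", rep("chr1", 7), seq(0, 600, by = 100),
                      seq(100, 700, by = 100),
                      c(2, 1, 2, 1, 2, 1, 2), c(1, 0, 1, 0, 1, 0, 1))
  expect_equal(maxOscillation(prof, "chr1", 0, 700), 7L)
  expect_equal(maxOscillation(prof, "chr1", 150, 350), 3L)
  expect_equal(maxOscillation(prof, "chr2", 0, 700), 0L)
})

test_that("fragment-joins GOF agrees with closed forms and the oracle", {
  # perfectly uniform counts: p = 1
  cls <- rep(c("DEL", "DUP", "h2hINV", "t2tINV"), each = 3)
  expect_equal(fragmentJoinsTest(cls), 1.0)
  # extreme skew at n = 20 uses the chi-square branch: X2 = 60, df 3
  cls <- rep("DEL", 20)
  expect_equal(fragmentJoinsTest(cls),
               pchisq(60, df = 3, lower.tail = FALSE), tolerance = 1e-9)
  expect_lt(fragmentJoinsTest(rep("DEL", 12)), 0.001)
  # exact multinomial equals the enumeration oracle for small n
  set.seed(3)
  for (i in 1:6) {
    n <- sample(3:10, 1)
    cls <- sample(c("DEL", "DUP", "h2hINV", "t2tINV"), n, replace = TRUE)
    counts <- as.integer(table(factor(cls, c("DEL", "DUP", "h2hINV",
                                             "t2tINV"))))
    expect_equal(fragmentJoinsTest(cls), exactJoinsOracle(counts),
                 tolerance = 1e-9)
  }
  expect_error(fragmentJoinsTest(c("DEL", "DUP")), "at least 3")
})

test_that("breakpoint enrichment is the closed-form binomial tail", {
  g <- GenomeBuild(data.frame(
    chrom = c("chr1", "chr1", "chr2", "chr2"), arm = c("p", "q", "p", "q"),
    start = c(0, 30, 0, 500), end = c(25, 50, 450, 950)))
  # chr1 holds 5% of the genome; all 20 breakends on it
  svs <- do.call(rbind, lapply(1:10, function(i) svRow(i, i + 5)))
  p <- breakpointEnrichmentTest(svs, "chr1", g)
  expect_equal(p, 0.05^20, tolerance = 1e-9)
  expect_equal(p, 9.5e-27, tolerance = 0.01)
  # no breakends on the chromosome: p = 1
  expect_equal(breakpointEnrichmentTest(svs, "chr2", g), 1)
  # breakends proportional to length: unremarkable p
  svs2 <- do.call(rbind, lapply(1:19, function(i)
    svRow(i, i + 5, chrom = "chr2")))
  p2 <- breakpointEnrichmentTest(rbind(svs, svs2), "chr2", g)
  expect_gt(p2, 0.2)
})

test_that("exponential-spacing test rejects regular grids, is valid under
           the null, and no-tests tiny inputs", {
  # perfectly regular grid: gaps are constant, nothing like exponential
  grid <- seq(0, 49e5, by = 1e5)
  res <- exponentialSpacingTest(grid)
  expect_true(res$tested)
  expect_lt(res$p, 1e-6)
  # iid exponential gaps: p-values are valid (never anti-conservative);
  # estimating the rate from the same gaps makes them conservative, so
  # uniformity is not expected
  set.seed(5)
  ps <- replicate(100, {
    bp <- cumsum(c(0, rexp(49, 1 / 1e5)))
    exponentialSpacingTest(bp)$p
  })
  expect_lte(mean(ps < 0.05), 0.07)
  expect_gt(median(ps), 0.3)
  # fewer than 3 breakpoints: flagged no-test
  res <- exponentialSpacingTest(c(1, 2))
  expect_false(res$tested)
  expect_equal(res$p, 1)
})

test_that("planted events satisfy criteria set 1; thresholds are strict", {
  g <- hg19Genome()
  cfg <- simulationConfig()
  set.seed(2024)
  prof <- simulateCNProfile(4, g, cfg)
  sim <- simulateSVSet(prof, cfg, g, plantChromothripsis = TRUE)
  calls <- callChromothripsis(sim$svs, sim$profile, g)
  hit <- calls[calls$chrom == sim$event$chrom, ]
  expect_true(any(hit$high_confidence & hit$criteria_set == 1L))
  expect_gte(max(hit$n_intra_interleaved), 12L)
  expect_gte(max(hit$max_oscillation_run), 7L)
})

test_that("six interleaved SVs with oscillation below 7 are not called", {
  g <- toyGenome()
  # 6 mutually interleaved deletion-like SVs, skewed joins; the
  # breakpoint hull spans the profile's oscillating segments
  p1 <- seq(10, 60, by = 10)
  p2 <- p1 + 600
  svs <- do.call(rbind, lapply(1:6, function(i)
    svRow(p1[i], p2[i], cls = if (i <= 5) "DEL" else "DUP")))
  # oscillating profile with run length 6 only
  prof <- makeProfile("S1", rep("chr1", 6), seq(0, 500, by = 100),
                      seq(100, 600, by = 100),
                      c(2, 1, 2, 1, 2, 1), c(1, 0, 1, 0, 1, 0))
  calls <- callChromothripsis(svs, prof, g)
  expect_equal(calls$max_oscillation_run, 6L)
  expect_false(any(calls$high_confidence))
  # same cluster over a 7-long oscillation qualifies (enrichment on a
  # chromosome holding most breakends of the sample)
  prof7 <- makeProfile("S1", rep("chr1", 7), seq(0, 600, by = 100),
                       seq(100, 700, by = 100),
                       c(2, 1, 2, 1, 2, 1, 2), c(1, 0, 1, 0, 1, 0, 1))
  calls7 <- callChromothripsis(svs, prof7, g)
  expect_true(any(calls7$high_confidence & calls7$criteria_set == 1L))
})

test_that("criteria set 2 rescues small clusters with many translocations", {
  g <- toyGenome()
  # note: with the exact multinomial joins test, the smallest cluster that
  # can reach p < 0.05 has 4 SVs of one class (p = 4/256)
  p1 <- c(100, 150, 200, 250)
  p2 <- p1 + 600
  svs <- do.call(rbind, lapply(1:4, function(i)
    svRow(p1[i], p2[i], cls = "DEL")))
  tra <- do.call(rbind, lapply(1:4, function(i)
    data.frame(sample = "S1", chrom1 = "chr1", pos1 = 150 + i * 10,
               strand1 = "+", chrom2 = "chr2", pos2 = i * 100,
               strand2 = "-", sv_class = "TRA", stringsAsFactors = FALSE)))
  prof <- makeProfile("S1", rep("chr1", 8), seq(0, 700, by = 100),
                      seq(100, 800, by = 100),
                      c(2, 1, 2, 1, 2, 1, 2, 1), c(1, 0, 1, 0, 1, 0, 1, 0))
  calls <- callChromothripsis(svs = rbind(svs, tra), prof, g,
                              minIntra = 6L)
  idx <- which(calls$n_intra_interleaved == 4L)
  expect_equal(calls$n_inter_sv[idx], 4L)
  expect_equal(calls$criteria_set[idx], 2L)
  expect_true(calls$high_confidence[idx])
  # flipping the joins direction disqualifies the (skewed) cluster
  flipped <- callChromothripsis(rbind(svs, tra), prof, g,
                                joinsDirection = "above")
  expect_false(any(flipped$high_confidence))
})
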