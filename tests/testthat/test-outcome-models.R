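hgg <- hg19Genome()

neutralProfile <- function(id) {
  a <- armRanges(hgg, autosomesOnly = TRUE)
  CNProfile(id, data.frame(
    chrom = as.character(GenomicRanges::seqnames(a)),
    start = GenomicRanges::start(a) - 1, end = GenomicRanges::end(a),
    tcn = 2, mcnMinor = 1))
}

emptyVariants <- function() {
  data.frame(sample = character(), chrom = character(), pos = numeric(),
             ref = character(), alt = character(), t_alt = integer(),
             t_depth = integer(), n_alt = integer(), n_depth = integer(),
             n_callers = integer(), pop_maf = numeric(),
             is_coding = logical(), is_nonsynonymous = logical(),
             gene = character(), stringsAsFactors = FALSE)
}

emptySVs <- function() {
  data.frame(sample = character(), chrom1 = character(), pos1 = numeric(),
             strand1 = character(), chrom2 = character(), pos2 = numeric(),
             strand2 = character(), sv_class = character(),
             stringsAsFactors = FALSE)
}

test_that("marker assembly flags mutations, SVs, deletions and exact ORs", {
  profs <- list(S1 = neutralProfile("S1"), S2 = neutralProfile("S2"),
                S3 = neutralProfile("S3"), S4 = neutralProfile("S4"))
  # S2: homozygous deletion over CDKN2A; S3: arm-level 22q loss;
  # S4: focal 9q21.11 deletion
  profs$S2 <- CNProfile("S2", rbind(
    segmentDf <- data.frame(chrom = "chr9", start = 21960000,
                            end = 22010000, tcn = 0, mcnMinor = 0),
    data.frame(chrom = "chr1", start = 0, end = 1e6, tcn = 2,
               mcnMinor = 1)))
  profs$S3 <- CNProfile("S3", data.frame(
    chrom = c("chr22", "chr1"), start = c(16000000, 0),
    end = c(51304566, 1e6), tcn = c(1, 2), mcnMinor = c(0, 1)))
  profs$S4 <- CNProfile("S4", data.frame(
    chrom = c("chr9", "chr1"), start = c(70900000, 0),
    end = c(71800000, 1e6), tcn = c(1, 2), mcnMinor = c(0, 1)))
  v <- data.frame(sample = "S1", chrom = "chr3", pos = 52600000,
                  ref = "C", alt = "T", t_alt = 10L, t_depth = 60L,
                  n_alt = 0L, n_depth = 40L, n_callers = 3L, pop_maf = 0,
                  is_coding = TRUE, is_nonsynonymous = TRUE,
                  gene = "PBRM1", stringsAsFactors = FALSE)
  mk <- assembleMarkers(v, emptySVs(), profs, hgg)
  expect_equal(mk$pbrm1_plus, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(mk$cdkn2ab_plus, c(FALSE, TRUE, FALSE, FALSE))
  expect_equal(mk$del22q, c(FALSE, FALSE, TRUE, FALSE))
  expect_equal(mk$del9q21_focal, c(FALSE, FALSE, FALSE, TRUE))
  expect_equal(mk$combined_css, mk$pbrm1_plus | mk$del22q)
  expect_equal(mk$combined_rfs,
               mk$pbrm1_plus | mk$del9q21_focal | mk$del22q)
  # an SV breakend inside a gene interval also flags it
  sv <- data.frame(sample = "S2", chrom1 = "chr3", pos1 = 52600000,
                   strand1 = "+", chrom2 = "chr8", pos2 = 1e7,
                   strand2 = "-", sv_class = "TRA",
                   stringsAsFactors = FALSE)
  mk2 <- assembleMarkers(v, sv, profs, hgg)
  expect_true(mk2$pbrm1_plus[mk2$sample == "S2"])
  # synonymous variants do not count
  vSyn <- v; vSyn$is_nonsynonymous <- FALSE
  mk3 <- assembleMarkers(vSyn, emptySVs(), profs, hgg)
  expect_false(any(mk3$pbrm1_plus))
  # a missing locus definition is a named error
  expect_error(assembleMarkers(v, emptySVs(), profs, hgg,
                               loci = defaultGeneLoci()[1:3, ]),
               "missing locus definition")
})

test_that("mutual exclusivity is the one-sided hypergeometric tail", {
  a <- c(rep(TRUE, 5), rep(FALSE, 15))
  b <- c(rep(FALSE, 5), rep(TRUE, 5), rep(FALSE, 10))
  res <- mutualExclusivity(a, b)
  expect_equal(res$overlap, 0L)
  # oracle: P(X <= 0), X ~ Hypergeom(drawn 5 of 20 with 5 successes)
  expect_equal(res$p, phyper(0, 5, 15, 5), tolerance = 1e-9)
  # identical flags co-occur maximally: no evidence of exclusivity
  res2 <- mutualExclusivity(a, a)
  expect_equal(res2$overlap, 5L)
  expect_gt(res2$p, 0.99)
  # degenerate all-false flag
  res3 <- mutualExclusivity(a, rep(FALSE, 20))
  expect_true(res3$degenerate)
  expect_equal(res3$p, 1)
})

test_that("independent random flags give calibrated exclusivity p-values", {
  set.seed(60)
  ps <- replicate(200, {
    a <- runif(40) < 0.4
    b <- runif(40) < 0.4
    if (!any(a) || !any(b)) return(NA_real_)
    mutualExclusivity(a, b)$p
  })
  ps <- ps[!is.na(ps)]
  # valid p-values: never anti-conservative at the 10% level
  expect_lte(mean(ps < 0.1), 0.12)
})

test_that("the Cox fit matches an independent Efron partial likelihood", {
  set.seed(14)
  n <- 50
  x <- rbinom(n, 1, 0.4)
  time <- round(rexp(n, 0.05 * exp(0.8 * x)), 0) + 1  # integer months: ties
  status <- runif(n) < 0.8
  md <- data.frame(sample = sprintf("P%02d", 1:n), age = 50, sex = "F",
                   histology = "c", pre_rt = FALSE, post_rt = FALSE,
                   recurred = status, rfs_months = time, died = status,
                   os_months = time, stringsAsFactors = FALSE)
  mk <- data.frame(sample = md$sample, m = x == 1)
  fit <- fitPH(md, mk, "m", "css", adjust = character())
  oracle <- optimize(function(b) efronNegLogLik(b, time, status,
                                                matrix(x, ncol = 1)),
                     interval = c(-5, 5), tol = 1e-10)
  expect_equal(log(fit$hr), oracle$minimum, tolerance = 1e-6)
})

test_that("no-fit guards: constant markers and event-free strata", {
  md <- data.frame(sample = c("A", "B", "C", "D"), age = 50, sex = "F",
                   histology = "c", pre_rt = FALSE, post_rt = FALSE,
                   recurred = c(TRUE, TRUE, FALSE, FALSE),
                   rfs_months = c(5, 8, 20, 30),
                   died = c(TRUE, TRUE, FALSE, FALSE),
                   os_months = c(10, 12, 40, 50), stringsAsFactors = FALSE)
  mk <- data.frame(sample = md$sample, m = c(TRUE, TRUE, TRUE, TRUE))
  res <- fitPH(md, mk, "m", "css")
  expect_false(res$fitted)
  expect_match(res$reason, "constant")
  mk$m <- c(TRUE, TRUE, FALSE, FALSE)
  md$died <- c(TRUE, TRUE, FALSE, FALSE)
  res <- fitPH(md, mk, "m", "css")
  expect_false(res$fitted)
  expect_match(res$reason, "no events")
})

test_that("KM curves expose per-stratum step data", {
  set.seed(2)
  n <- 30
  md <- data.frame(sample = sprintf("P%02d", 1:n), age = 50, sex = "F",
                   histology = "c", pre_rt = FALSE, post_rt = FALSE,
                   recurred = runif(n) < 0.7,
                   rfs_months = rexp(n, 0.05), died = runif(n) < 0.3,
                   os_months = rexp(n, 0.02) + 1, stringsAsFactors = FALSE)
  md$rfs_months <- pmin(md$rfs_months, md$os_months)
  mk <- data.frame(sample = md$sample, m = rbinom(n, 1, 0.5) == 1)
  km <- kmCurves(md, mk, "m", "rfs")
  expect_setequal(unique(km$stratum), c("m+", "m-"))
  expect_true(all(km$surv >= 0 & km$surv <= 1))
  expect_true(all(diff(km$surv[km$stratum == "m+"]) <= 1e-12))
})

test_that("the arm scan applies the Bonferroni arithmetic exactly", {
  # correction arithmetic, checked directly on the reported fields
  set.seed(4)
  n <- 60
  md <- data.frame(sample = sprintf("P%02d", 1:n), age = rnorm(n, 50, 10),
                   sex = sample(c("M", "F"), n, TRUE), histology = "c",
                   pre_rt = FALSE, post_rt = runif(n) < 0.5,
                   recurred = NA, rfs_months = NA, died = NA,
                   os_months = NA, stringsAsFactors = FALSE)
  flag <- rbinom(n, 1, 0.4) == 1
  t <- rexp(n, 0.02 * exp(1.2 * flag))
  cens <- runif(n, 20, 100)
  md$died <- md$recurred <- t <= cens
  md$os_months <- md$rfs_months <- pmin(t, cens)
  armFlags <- data.frame(sample = md$sample, del22q = flag,
                         del1p = rbinom(n, 1, 0.3) == 1)
  res <- armScan(md, armFlags, "css", m = 17L)
  expect_equal(res$bonferroni_m, c(17L, 17L))
  expect_equal(res$p_adj, pmin(1, 17 * res$p))
  # the printed-arithmetic anchor: p = 0.0027 over 17 tests -> 0.0459
  expect_equal(min(1, 17 * 0.0027), 0.0459, tolerance = 1e-12)
  # capping and m = 1 pass-through
  expect_equal(min(1, 17 * 0.5), 1)
})

test_that("shared fractions follow the union convention", {
  g <- toyGenome()
  mkv <- function(sample, pos, ref = "A", alt = "G")
    data.frame(sample = sample, chrom = "chr1", pos = pos, ref = ref,
               alt = alt, stringsAsFactors = FALSE)
  pP <- makeProfile("P", c("chr1", "chr2"), c(0, 0), c(1000, 800),
                    c(1, 2), c(0, 1))
  pR <- makeProfile("R", c("chr1", "chr2"), c(0, 0), c(1000, 800),
                    c(1, 2), c(0, 1))
  # identical pair: all SCNA alteration bp and all SNVs shared
  vP <- mkv("P", c(10, 20, 30, 40))
  res <- sharedFraction(vP, mkv("R", c(10, 20, 30, 40)), pP, pR, g)
  expect_equal(res$shared[res$class == "SCNA"], 1)
  expect_equal(res$shared[res$class == "SNV"], 1)
  expect_equal(res$primary_only[res$class == "SNV"], 0)
  # 3 of 4 SNVs shared, union of 5 -> shared 0.6; of 4 with one private
  # each side is the documented union convention
  res2 <- sharedFraction(mkv("P", c(10, 20, 30)),
                         mkv("R", c(10, 20, 30, 40)), pP, pR, g)
  expect_equal(res2$shared[res2$class == "SNV"], 0.75)
  expect_equal(res2$recurrence_only[res2$class == "SNV"], 0.25)
  # disjoint SNV sets share nothing
  res3 <- sharedFraction(mkv("P", c(1, 2)), mkv("R", c(3, 4)), pP, pR, g)
  expect_equal(res3$shared[res3$class == "SNV"], 0)
  # rows are proper proportions
  expect_equal(rowSums(res2[, c("shared", "primary_only",
                                "recurrence_only")]),
               c(1, 1, NA))   # no indels in the pair
  # discordant SCNA: primary-only and recurrence-only split the genome
  pR2 <- makeProfile("R", c("chr1", "chr2"), c(0, 0), c(1000, 800),
                     c(4, 2), c(1, 1))
  res4 <- sharedFraction(vP, vP, pP, pR2, g)
  expect_equal(res4$shared[res4$class == "SCNA"], 0)
})
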