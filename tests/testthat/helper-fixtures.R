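# Shared fixtures and independent oracles used across the suite.

# small two-chromosome genome (1 kb scale) for exhaustive per-bp oracles
toyGenome <- function() {
  GenomeBuild(data.frame(
    chrom = c("chr1", "chr1", "chr2", "chr2"),
    arm = c("p", "q", "p", "q"),
    start = c(0, 500, 0, 350),
    end = c(400, 1000, 300, 800)
  ))
}

makeProfile <- function(id, chrom, start, end, tcn, minor) {
  CNProfile(id, data.frame(chrom = chrom, start = start, end = end,
                           tcn = tcn, mcnMinor = minor))
}

# literal per-bp CN-state distance (brute force; toy genomes only)
perBpDistance <- function(pa, pb, genome, normalize = TRUE) {
  expand <- function(p) {
    states <- list()
    for (ch in chromNames(genome)) {
      v <- rep(NA_character_, chromLengths(genome)[[ch]])
      seg <- segments(p)
      sel <- as.character(GenomicRanges::seqnames(seg)) == ch
      seg <- seg[sel]
      mc <- S4Vectors::mcols(seg)
      st <- classifyState(mc$tcn, mc$mcnMinor)
      for (i in seq_along(seg))
        v[GenomicRanges::start(seg)[i]:GenomicRanges::end(seg)[i]] <- st[i]
      states[[ch]] <- v
    }
    unlist(states, use.names = FALSE)
  }
  a <- expand(pa); b <- expand(pb)
  both <- !is.na(a) & !is.na(b)
  if (normalize) sum(a[both] != b[both]) / sum(both) else
    sum(a[both] != b[both])
}

# brute-force longest two-value alternating run
bruteMaxAlt <- function(v) {
  n <- length(v)
  if (n == 0L) return(0L)
  best <- 0L
  for (i in seq_len(n)) for (j in i:n) {
    s <- v[i:j]
    if (length(unique(s)) <= 2L && (length(s) == 1L || all(diff(s) != 0)))
      best <- max(best, j - i + 1L)
  }
  best
}

# brute-force interleaving clusters: connected components over all pairs
bruteInterleaveClusters <- function(p1, p2) {
  m <- length(p1)
  adj <- matrix(FALSE, m, m)
  for (i in seq_len(m)) for (j in seq_len(m)) {
    if (i == j) next
    overlaps <- p1[i] < p2[j] && p1[j] < p2[i]
    nested <- (p1[i] <= p1[j] && p2[i] >= p2[j]) ||
      (p1[j] <= p1[i] && p2[j] >= p2[i])
    adj[i, j] <- overlaps && !nested
  }
  comp <- rep(0L, m); cur <- 0L
  for (s in seq_len(m)) {
    if (comp[s] > 0L) next
    cur <- cur + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      if (comp[v] > 0L) next
      comp[v] <- cur
      queue <- c(queue, which(adj[v, ] & comp == 0L))
    }
  }
  comp
}

# exact multinomial GOF p-value by composition enumeration with dmultinom
exactJoinsOracle <- function(counts) {
  n <- sum(counts)
  pObs <- stats::dmultinom(counts, prob = rep(0.25, 4))
  tot <- 0
  for (a in 0:n) for (b in 0:(n - a)) for (cc in 0:(n - a - b)) {
    y <- c(a, b, cc, n - a - b - cc)
    p <- stats::dmultinom(y, prob = rep(0.25, 4))
    if (p <= pObs * (1 + 1e-9)) tot <- tot + p
  }
  tot
}

# independent Efron partial likelihood (negated) for a Cox model
efronNegLogLik <- function(beta, time, status, X) {
  eta <- as.numeric(X %*% beta)
  w <- exp(eta)
  ll <- 0
  for (t in sort(unique(time[status == 1]))) {
    D <- which(time == t & status == 1)
    R <- which(time >= t)
    d <- length(D)
    sumD <- sum(w[D]); sumR <- sum(w[R])
    ll <- ll + sum(eta[D])
    for (l in seq_len(d) - 1L) ll <- ll - log(sumR - (l / d) * sumD)
  }
  -ll
}

# 10-record retention-filter fixture: 6 clean records and 4 designed to
# fail one rule each (callers, tumor VAF, alt count, population MAF)
filterToyTable <- function() {
  rec <- function(sample, n_callers = 3L, t_alt = 10L, t_depth = 80L,
                  n_alt = 0L, n_depth = 40L, pop_maf = 0,
                  is_coding = TRUE) {
    data.frame(sample = sample, chrom = "chr1",
               pos = sample.int(1e6, 1L), ref = "A", alt = "G",
               t_alt = t_alt, t_depth = t_depth, n_alt = n_alt,
               n_depth = n_depth, n_callers = n_callers,
               pop_maf = pop_maf, is_coding = is_coding,
               is_nonsynonymous = is_coding, gene = "",
               stringsAsFactors = FALSE)
  }
  rbind(
    rec("S1"), rec("S1"), rec("S1"), rec("S2"), rec("S2"), rec("S2"),
    rec("S1", n_callers = 1L),                      # fails n_callers
    rec("S1", t_alt = 5L, t_depth = 80L),           # VAF 0.0625 < 0.07
    rec("S2", t_alt = 2L, t_depth = 20L),           # alt reads < 3
    rec("S2", pop_maf = 0.01)                       # population MAF > 0.1%
  )
}
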