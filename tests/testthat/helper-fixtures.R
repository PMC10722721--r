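# Shared fixtures built in code. Small by design: unit tests exercise logic,
# the heavier statistical checks live in test-acceptance.R.

# a tiny deterministic genotype matrix: 6 samples x 4 loci
tiny_gm <- function() {
  geno <- matrix(
    c(0L, 0L, 1L, 2L, 2L, 2L,
      0L, 1L, NA, 1L, 2L, 2L,
      0L, 0L, 0L, 2L, 2L, NA,
      1L, 0L, 2L, 1L, 1L, 2L),
    nrow = 6, ncol = 4,
    dimnames = list(c("a1", "a2", "b1", "b2", "c1", "c2"), NULL))
  loci <- tibble::tibble(
    locus_id = c("chr1_100", "chr1_200", "chr1_300", "chr2_50"),
    chrom = c("chr1", "chr1", "chr1", "chr2"),
    pos = c(100L, 200L, 300L, 50L),
    ref = c("A", "C", "G", "A"),
    alt = c("T", "G", "A", "AT"),
    focal = "ALT")
  geno_matrix(geno, loci)
}

tiny_assignments <- function() {
  tibble::tibble(sample_id = c("a1", "a2", "b1", "b2", "c1", "c2"),
                 label = c("S0", "S0", "S1", "S1", "TEST", "TEST"))
}

# a small simulated hybrid zone reused by several files
small_sim <- function(seed = 7, n_test = 60, n_loci = 40, ...) {
  simulate_dataset(sim_config(
    n_s0 = 12, n_s1 = 12, n_test = n_test, n_loci = n_loci, seed = seed, ...))
}

# independent brute-force oracle for WAIC (direct formula, no shortcuts)
waic_oracle <- function(ll) {
  lppd <- 0; p <- 0
  for (j in seq_len(nrow(ll))) {
    lppd <- lppd + log(mean(exp(ll[j, ])))
    p <- p + var(ll[j, ])
  }
  c(lppd = lppd, p_waic = p, waic = -2 * (lppd - p))
}

# independent brute-force oracle for region pooling
pool_oracle <- function(chrom, pos, max_gap, min_variants) {
  d <- data.frame(chrom = chrom, pos = pos)
  d <- d[order(d$chrom, d$pos), ]
  out <- list()
  for (ch in unique(d$chrom)) {
    p <- d$pos[d$chrom == ch]
    members <- p[1]
    for (i in seq_along(p)[-1]) {
      if (p[i] - p[i - 1] < max_gap) {
        members <- c(members, p[i])
      } else {
        if (length(members) >= min_variants) {
          out[[length(out) + 1]] <- data.frame(
            chrom = ch, start = min(members), end = max(members),
            n_scv = length(members))
        }
        members <- p[i]
      }
    }
    if (length(members) >= min_variants) {
      out[[length(out) + 1]] <- data.frame(
        chrom = ch, start = min(members), end = max(members),
        n_scv = length(members))
    }
  }
  if (!length(out)) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), n_scv = integer()))
  }
  do.call(rbind, out)
}

# independent Weir & Cockerham (1984) theta oracle, written directly from
# the published component formulas, one population at a time
wc_oracle <- function(geno_by_pop) {
  n <- vapply(geno_by_pop, function(g) sum(!is.na(g)), numeric(1))
  p <- vapply(geno_by_pop, function(g) sum(g, na.rm = TRUE), numeric(1)) / (2 * n)
  h <- vapply(geno_by_pop, function(g) mean(g[!is.na(g)] == 1), numeric(1))
  r <- length(n)
  nbar <- sum(n) / r
  nc <- (sum(n) - sum(n^2) / sum(n)) / (r - 1)
  pbar <- sum(n * p) / sum(n)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n * h) / sum(n)
  a <- (nbar / nc) * (s2 - 1 / (nbar - 1) *
                        (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  a / (a + b + cc)
}
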