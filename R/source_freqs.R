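#' Estimate source-population allele frequencies with credible intervals
#'
#' For each locus and source population, counts focal-allele copies among
#' non-missing genotypes and reports the conjugate Beta posterior of the
#' allele frequency: with `k` focal copies of `n` total, the posterior is
#' `Beta(k + prior_a, n - k + prior_b)` (Jeffreys `Beta(0.5, 0.5)` by
#' default), summarised by its mean and equal-tailed 95% credible interval.
#'
#' Loci are re-oriented so the S1 frequency is at least the S0 frequency
#' (posterior means compared); where the focal allele is flipped the
#' genotype matrix returned alongside is recoded accordingly, so downstream
#' cline parameters are invariant to the original REF/ALT labelling.
#'
#' @param gm a [geno_matrix()].
#' @param assignments tibble (`sample_id`, `label`) from
#'   [assign_populations()] or a simulation.
#' @param prior_a,prior_b Beta prior parameters (default Jeffreys 0.5, 0.5).
#' @param level credible level for the equal-tailed interval.
#' @return list with `freqs` — a tibble (`locus_id`, `chrom`, `pos`,
#'   `flipped`, `k0`, `n0`, `k1`, `n1`, `p0_mean`, `p0_lo`, `p0_hi`,
#'   `p1_mean`, `p1_lo`, `p1_hi`, `usable`) — and `genotypes`, the
#'   (possibly re-oriented) `geno_matrix`. Loci with zero called copies in
#'   either source are flagged `usable = FALSE`.
#' @export
estimate_source_freqs <- function(gm, assignments, prior_a = 0.5,
                                  prior_b = 0.5, level = 0.95) {
  stopifnot(inherits(gm, "geno_matrix"))
  s0 <- assignments$sample_id[assignments$label == "S0"]
  s1 <- assignments$sample_id[assignments$label == "S1"]
  if (length(s0) < 2 || length(s1) < 2) {
    abort("need at least 2 samples in each source population.")
  }
  alpha <- (1 - level) / 2
  count_source <- function(ids) {
    g <- gm$geno[rownames(gm$geno) %in% ids, , drop = FALSE]
    list(k = unname(colSums(g, na.rm = TRUE)),
         n = 2L * unname(colSums(!is.na(g))))
  }
  c0 <- count_source(s0); c1 <- count_source(s1)
  post <- function(k, n) {
    a <- k + prior_a; b <- n - k + prior_b
    list(mean = a / (a + b), lo = qbeta(alpha, a, b),
         hi = qbeta(1 - alpha, a, b))
  }
  f0 <- post(c0$k, c0$n); f1 <- post(c1$k, c1$n)
  flip <- f1$mean < f0$mean
  freqs <- tibble(
    locus_id = gm$loci$locus_id, chrom = gm$loci$chrom, pos = gm$loci$pos,
    flipped = flip,
    k0 = ifelse(flip, c0$n - c0$k, c0$k), n0 = c0$n,
    k1 = ifelse(flip, c1$n - c1$k, c1$k), n1 = c1$n,
    p0_mean = ifelse(flip, 1 - f0$mean, f0$mean),
    p0_lo = ifelse(flip, 1 - f0$hi, f0$lo),
    p0_hi = ifelse(flip, 1 - f0$lo, f0$hi),
    p1_mean = ifelse(flip, 1 - f1$mean, f1$mean),
    p1_lo = ifelse(flip, 1 - f1$hi, f1$lo),
    p1_hi = ifelse(flip, 1 - f1$lo, f1$hi),
    usable = c0$n > 0 & c1$n > 0)
  if (any(!freqs$usable)) {
    inform(sprintf("estimate_source_freqs: %d loci with no called copies in a source flagged unusable.",
                   sum(!freqs$usable)))
  }
  gm2 <- if (any(flip)) flip_focal(gm, freqs$locus_id[flip]) else gm
  list(freqs = freqs, genotypes = gm2)
}

#' Keep loci whose source allele-frequency credible intervals are disjoint
#'
#' Retains a locus only when the 95% credible intervals of the S0 and S1
#' allele frequencies do not overlap (strict inequality: touching intervals
#' count as overlapping), i.e. only loci with high-confidence frequency
#' differences between the ancestries. Unusable loci are removed too.
#'
#' @param freqs the `freqs` tibble from [estimate_source_freqs()].
#' @return the retained subset of `freqs`, with a message on counts.
#' @export
filter_ci_overlap <- function(freqs) {
  lower_src_hi <- ifelse(freqs$p0_mean <= freqs$p1_mean, freqs$p0_hi, freqs$p1_hi)
  higher_src_lo <- ifelse(freqs$p0_mean <= freqs$p1_mean, freqs$p1_lo, freqs$p0_lo)
  keep <- freqs$usable & (lower_src_hi < higher_src_lo)
  inform(sprintf("filter_ci_overlap: retained %d of %d loci.",
                 sum(keep), length(keep)))
  freqs[keep, ]
}
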