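#' Configuration for the hybrid-zone genotype simulator
#'
#' Bundles the study-design parameters of a simulated hybrid zone: two
#' divergent source populations (S0, S1), a set of admixed test individuals
#' with known hybrid indices, and per-locus cline parameters. Neutral loci
#' have steepness `v = 1` (`ln v = 0`) and centre `c = 0.5`; barrier loci get
#' the steepness/centre you request. All defaults are package choices made to
#' mimic a strongly divergent two-source hybrid zone with no near-pure-S1
#' hybrids; every one is configurable.
#'
#' @param n_s0,n_s1,n_test individual counts for source 0, source 1 and the
#'   admixed test set.
#' @param n_loci total locus count; must equal the sum of `chrom_layout`
#'   locus counts.
#' @param chrom_layout list of `list(chrom =, n_loci =, spacing_bp =)`
#'   entries; default a single chromosome with 10-kb spacing.
#' @param freq_model list with `p0_range`, `p1_range` (uniform sampling
#'   ranges for the source allele frequencies; defaults `c(0, 0.2)` and
#'   `c(0.8, 1)`) and `uninformative_frac`, the fraction of loci at which the
#'   two sources share a common frequency drawn from `common_range`
#'   (default `c(0.2, 0.8)`), so their frequency intervals overlap.
#' @param h_model list with `min`, `max`: true hybrid indices of test
#'   individuals are Uniform(min, max); default `(0.2, 0.95)`.
#' @param barrier_spec list of `list(frac =, lnv =, centre =, clustered =)`
#'   entries; fractions must sum to at most 1. Clustered entries are placed
#'   as consecutive loci on the first chromosome (physical spacing is that
#'   chromosome's `spacing_bp`) to exercise region pooling.
#' @param missing_rate probability each genotype is independently missing.
#' @param indel_frac fraction of loci written as 1-bp insertions rather than
#'   SNPs (default 0.08, a typical whole-genome variant mix); affects only
#'   the REF/ALT allele strings, not the genetics.
#' @param seed integer RNG seed; identical seeds give byte-identical output.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_s0 = 20, n_s1 = 20, n_test = 200, n_loci = 1000,
                       chrom_layout = NULL,
                       freq_model = list(), h_model = list(),
                       barrier_spec = list(), missing_rate = 0,
                       indel_frac = 0.08, seed = 1L) {
  chrom_layout <- chrom_layout %||%
    list(list(chrom = "chr1", n_loci = n_loci, spacing_bp = 10000L))
  fm <- utils::modifyList(
    list(p0_range = c(0, 0.2), p1_range = c(0.8, 1),
         uninformative_frac = 0, common_range = c(0.2, 0.8)),
    freq_model)
  hm <- utils::modifyList(list(min = 0.2, max = 0.95), h_model)
  if (any(c(n_s0, n_s1, n_test, n_loci) <= 0)) abort("all counts must be > 0.")
  if (missing_rate < 0 || missing_rate >= 1) abort("missing_rate must be in [0, 1).")
  layout_total <- sum(vapply(chrom_layout, function(x) x$n_loci, numeric(1)))
  if (layout_total != n_loci) {
    abort("`n_loci` is inconsistent with `chrom_layout` locus counts.")
  }
  fracs <- vapply(barrier_spec, function(b) b$frac, numeric(1))
  if (length(fracs) && sum(fracs) > 1) abort("barrier fractions sum to > 1.")
  for (b in barrier_spec) {
    if (b$centre <= 0 || b$centre >= 1) abort("barrier centre must be in (0, 1).")
  }
  rng <- range(fm$p0_range, fm$p1_range, fm$common_range)
  if (rng[1] < 0 || rng[2] > 1) abort("frequency ranges must lie in [0, 1].")
  if (indel_frac < 0 || indel_frac > 1) abort("indel_frac must be in [0, 1].")
  structure(
    list(n_s0 = n_s0, n_s1 = n_s1, n_test = n_test, n_loci = n_loci,
         chrom_layout = chrom_layout, freq_model = fm, h_model = hm,
         barrier_spec = barrier_spec, missing_rate = missing_rate,
         indel_frac = indel_frac, seed = stopifnot_scalar_seed(seed)),
    class = "sim_config")
}

#' Simulate a hybrid-zone genotype dataset with known truth
#'
#' The generative inverse of the cline model. Source individuals draw both
#' allele copies from their own population frequency. For each allele copy of
#' a test individual at locus l, ancestry is S1 with probability
#' `cline_function(h_i, v_l, c_l)`; conditional on ancestry the focal allele
#' is Bernoulli(`p1_l`) under S1 ancestry and Bernoulli(`p0_l`) under S0.
#' Allele copies are sampled independently (no linkage or ancestry tracts),
#' matching the per-variant cline likelihood.
#'
#' @param config a [sim_config()].
#' @return an `hz_sim` list with elements `genotypes` (a [geno_matrix()]),
#'   `assignments` (tibble: `sample_id`, `label`), and `truth` (list of
#'   tibbles `loci` — `locus_id`, `chrom`, `pos`, `p0`, `p1`, `lnv`,
#'   `centre`, `is_barrier` — and `individuals` — `sample_id`, `label`,
#'   `true_h`).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  L <- config$n_loci

  loci <- purrr::map_dfr(config$chrom_layout, function(cl) {
    tibble(chrom = cl$chrom,
           pos = as.integer(cl$spacing_bp) * seq_len(cl$n_loci))
  })
  loci$locus_id <- sprintf("%s_%d", loci$chrom, loci$pos)
  loci$ref <- "A"
  loci$alt <- ifelse(runif(L) < config$indel_frac, "AT", "T")
  loci$focal <- "ALT"

  fm <- config$freq_model
  p0 <- runif(L, fm$p0_range[1], fm$p0_range[2])
  p1 <- runif(L, fm$p1_range[1], fm$p1_range[2])
  n_unif <- round(fm$uninformative_frac * L)

  lnv <- rep(0, L)
  centre <- rep(0.5, L)
  is_barrier <- rep(FALSE, L)

  # clustered barrier blocks first (consecutive loci on chromosome 1),
  # then unclustered barriers and uninformative loci on what remains
  free <- seq_len(L)
  next_block_start <- 1L
  spec_order <- order(!vapply(config$barrier_spec, function(b)
    isTRUE(b$clustered), logical(1)))
  for (b in config$barrier_spec[spec_order]) {
    k <- round(b$frac * L)
    if (k == 0) next
    if (isTRUE(b$clustered)) {
      idx <- seq.int(next_block_start, length.out = k)
      next_block_start <- next_block_start + k
    } else {
      pool <- setdiff(free, seq_len(next_block_start - 1L))
      idx <- sort(sample(pool, k))
    }
    lnv[idx] <- b$lnv
    centre[idx] <- b$centre
    is_barrier[idx] <- TRUE
    free <- setdiff(free, idx)
  }
  if (n_unif > 0) {
    idx <- sort(sample(free, min(n_unif, length(free))))
    common <- runif(length(idx), fm$common_range[1], fm$common_range[2])
    p0[idx] <- common
    p1[idx] <- common
  }

  ids <- c(sprintf("S0_%03d", seq_len(config$n_s0)),
           sprintf("S1_%03d", seq_len(config$n_s1)),
           sprintf("T_%03d", seq_len(config$n_test)))
  label <- rep(c("S0", "S1", "TEST"),
               c(config$n_s0, config$n_s1, config$n_test))
  h_true <- c(rep(0, config$n_s0), rep(1, config$n_s1),
              runif(config$n_test, config$h_model$min, config$h_model$max))

  n <- length(ids)
  geno <- matrix(NA_integer_, n, L, dimnames = list(ids, loci$locus_id))
  is_s0 <- label == "S0"; is_s1 <- label == "S1"; is_t <- label == "TEST"
  geno[is_s0, ] <- rbinom(sum(is_s0) * L, 2L, rep(p0, each = sum(is_s0)))
  geno[is_s1, ] <- rbinom(sum(is_s1) * L, 2L, rep(p1, each = sum(is_s1)))

  # test individuals: per-copy ancestry through the cline, then allele draw
  nt <- sum(is_t)
  lh <- qlogis(h_true[is_t])
  v <- exp(lnv); lc <- qlogis(centre)
  phi <- plogis(outer(lh, rep(1, L)) * rep(v, each = nt) -
                  rep(v * lc, each = nt))            # nt x L
  pfoc1 <- matrix(rep(p1, each = nt), nt, L)
  pfoc0 <- matrix(rep(p0, each = nt), nt, L)
  copy_draw <- function() {
    anc1 <- matrix(runif(nt * L), nt, L) < phi
    allele_p <- ifelse(anc1, pfoc1, pfoc0)
    (matrix(runif(nt * L), nt, L) < allele_p) + 0L
  }
  geno[is_t, ] <- copy_draw() + copy_draw()

  if (config$missing_rate > 0) {
    geno[matrix(runif(n * L), n, L) < config$missing_rate] <- NA_integer_
  }

  gm <- geno_matrix(geno, loci[c("locus_id", "chrom", "pos", "ref", "alt", "focal")])
  truth_loci <- tibble(locus_id = loci$locus_id, chrom = loci$chrom,
                       pos = loci$pos, p0 = p0, p1 = p1, lnv = lnv,
                       centre = centre, is_barrier = is_barrier)
  truth_ind <- tibble(sample_id = ids, label = label, true_h = h_true)
  structure(
    list(genotypes = gm,
         assignments = tibble(sample_id = ids, label = label),
         truth = list(loci = truth_loci, individuals = truth_ind),
         config = config),
    class = "hz_sim")
}

#' @export
print.hz_sim <- function(x, ...) {
  cat(sprintf("<hz_sim> %d individuals (%d S0, %d S1, %d test), %d loci, %d barrier loci\n",
              nrow(x$genotypes$geno), x$config$n_s0, x$config$n_s1,
              x$config$n_test, x$config$n_loci, sum(x$truth$loci$is_barrier)))
  invisible(x)
}

#' Synthetic admixture Q-matrix for a simulated dataset
#'
#' Builds a two-cluster ancestry-proportion matrix from the simulation truth
#' (cluster 1 = S0 ancestry `1 - h`, cluster 2 = S1 ancestry `h`), in the
#' whitespace-delimited layout ADMIXTURE writes. Useful as a fixture for
#' [assign_populations()].
#'
#' @param sim an `hz_sim`.
#' @return tibble: `sample_id`, `Q1`, `Q2`.
#' @export
sim_qmatrix <- function(sim) {
  h <- sim$truth$individuals$true_h
  tibble(sample_id = sim$truth$individuals$sample_id,
         Q1 = 1 - h, Q2 = h)
}

#' Simulate a per-sire recombination map with designated hot- and coldspots
#'
#' Generates crossover counts for two sires in 1-Mb bins covering the
#' simulated chromosomes. Background counts are Poisson with mean
#' `background_lambda` (zeros replaced by 1 so designated coldspot runs stay
#' unique); designated hotspot bins receive `hotspot_count` crossovers in
#' both sires; designated coldspot runs receive 0 in one sire for a run of
#' the requested number of consecutive bins.
#'
#' @param chrom_layout as in [sim_config()].
#' @param n_hotspots number of hotspot bins to designate.
#' @param coldspot_runs integer vector of coldspot run lengths (each >= 3 to
#'   satisfy the coldspot definition).
#' @param seed RNG seed.
#' @param bin_size bin width in bp (1 Mb).
#' @param background_lambda Poisson mean of background crossover counts.
#' @param hotspot_count crossover count planted in hotspot bins.
#' @return tibble: `chrom`, `start` (1-based), `end`, `sire1`, `sire2`,
#'   `designated` in `{"hotspot", "coldspot", "other"}`.
#' @export
simulate_recomb_map <- function(chrom_layout, n_hotspots = 0,
                                coldspot_runs = integer(), seed = 1L,
                                bin_size = 1e6, background_lambda = 8,
                                hotspot_count = 150) {
  set.seed(stopifnot_scalar_seed(seed))
  bins <- purrr::map_dfr(chrom_layout, function(cl) {
    len <- cl$n_loci * cl$spacing_bp
    nb <- max(1L, ceiling(len / bin_size))
    tibble(chrom = cl$chrom,
           start = as.integer((seq_len(nb) - 1L) * bin_size + 1),
           end = as.integer(seq_len(nb) * bin_size))
  })
  nb <- nrow(bins)
  s1 <- rpois(nb, background_lambda)
  s2 <- rpois(nb, background_lambda)
  s1[s1 == 0] <- 1L
  s2[s2 == 0] <- 1L
  designated <- rep("other", nb)

  need <- n_hotspots + sum(coldspot_runs)
  if (need > nb) abort("more hotspot/coldspot bins requested than bins exist.")

  taken <- rep(FALSE, nb)
  # place coldspot runs within single chromosomes, non-overlapping
  for (run in coldspot_runs) {
    if (run < 3) abort("coldspot runs must span >= 3 bins.")
    placed <- FALSE
    for (attempt in seq_len(500)) {
      start <- sample(nb - run + 1L, 1L)
      idx <- seq.int(start, length.out = run)
      same_chrom <- length(unique(bins$chrom[idx])) == 1L
      # require a non-taken flanking buffer so runs never merge
      buf <- unique(pmin(pmax(c(idx, start - 1L, start + run), 1L), nb))
      if (same_chrom && !any(taken[buf])) {
        s1[idx] <- 0L
        designated[idx] <- "coldspot"
        taken[buf] <- TRUE
        placed <- TRUE
        break
      }
    }
    if (!placed) abort("could not place a coldspot run without overlap.")
  }
  if (n_hotspots > 0) {
    pool <- which(!taken)
    if (length(pool) < n_hotspots) abort("no room left for hotspot bins.")
    idx <- sort(sample(pool, n_hotspots))
    s1[idx] <- hotspot_count
    s2[idx] <- hotspot_count
    designated[idx] <- "hotspot"
    taken[idx] <- TRUE
  }
  bins$sire1 <- as.integer(s1)
  bins$sire2 <- as.integer(s2)
  bins$designated <- designated
  bins
}
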