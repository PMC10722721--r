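#' Multi-population Weir & Cockerham FST per locus
#'
#' The Weir & Cockerham (1984) theta estimator for r subpopulations,
#' computed from per-population allele frequencies, sample sizes and observed
#' heterozygote proportions at each biallelic locus. Missing genotypes are
#' excluded per locus per population; a locus usable in fewer than two
#' populations gets `NA`. Raw theta can be negative; the `fst_clamped`
#' column sets negatives to zero.
#'
#' @param gm a [geno_matrix()].
#' @param populations tibble (`sample_id`, `population`) giving the
#'   subpopulation of each sample; samples absent from it are ignored.
#' @param min_samples drop populations with fewer samples than this
#'   (default 2).
#' @return tibble: `locus_id`, `chrom`, `pos`, `fst_raw`, `fst_clamped`,
#'   `n_pops`.
#' @export
weir_fst_multipop <- function(gm, populations, min_samples = 2) {
  stopifnot(inherits(gm, "geno_matrix"))
  populations <- as_tibble(populations)
  counts <- table(populations$population)
  pops <- names(counts)[counts >= min_samples]
  if (length(pops) < 2) abort("need >= 2 populations with enough samples.")
  ids_by_pop <- lapply(pops, function(p) {
    intersect(populations$sample_id[populations$population == p],
              rownames(gm$geno))
  })

  L <- ncol(gm$geno)
  r_max <- length(pops)
  n_mat <- p_mat <- h_mat <- matrix(NA_real_, r_max, L)
  for (i in seq_len(r_max)) {
    g <- gm$geno[ids_by_pop[[i]], , drop = FALSE]
    called <- colSums(!is.na(g))
    n_mat[i, ] <- called
    p_mat[i, ] <- colSums(g, na.rm = TRUE) / (2 * called)
    h_mat[i, ] <- colSums(g == 1L, na.rm = TRUE) / called
  }

  theta <- vapply(seq_len(L), function(j) {
    ok <- which(n_mat[, j] > 0)
    if (length(ok) < 2) return(NA_real_)
    wc_theta(n_mat[ok, j], p_mat[ok, j], h_mat[ok, j])
  }, numeric(1))
  n_pops <- colSums(n_mat > 0)

  tibble(locus_id = gm$loci$locus_id, chrom = gm$loci$chrom,
         pos = gm$loci$pos, fst_raw = theta,
         fst_clamped = pmin(pmax(theta, 0), 1), n_pops = n_pops)
}

# Weir & Cockerham (1984) theta from per-population sample sizes (diploid
# individuals), focal-allele frequencies and heterozygote proportions.
wc_theta <- function(n, p, h) {
  r <- length(n)
  nbar <- mean(n)
  if (nbar <= 1) return(NA_real_)
  nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n * p) / (r * nbar)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n * h) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  denom <- a + b + cc
  if (denom == 0) return(0)
  a / denom
}

#' ANOVA of cline steepness across FST bins
#'
#' Bins loci by their (clamped) multi-population FST and tests whether mean
#' `ln(v)` differs among bins with a one-way ANOVA; also reports the Pearson
#' correlation between FST and `ln(v)`. Default bins are 0.05 wide with a
#' terminal `> 0.4` bin.
#'
#' @param fst tibble from [weir_fst_multipop()].
#' @param cline_tbl tibble with `locus_id` and `lnv_mean`.
#' @param bin_edges increasing break points covering `[0, 1]`.
#' @return list: `group_means` (tibble `fst_bin`, `n`, `mean_lnv`),
#'   `f_statistic`, `p_value`, `pearson_r`.
#' @export
fst_group_anova <- function(fst, cline_tbl,
                            bin_edges = c(seq(0, 0.4, by = 0.05), 1)) {
  d <- dplyr::inner_join(
    select(as_tibble(fst), "locus_id", "fst_clamped"),
    select(as_tibble(cline_tbl), "locus_id", "lnv_mean"),
    by = "locus_id") %>%
    filter(is.finite(.data$fst_clamped), is.finite(.data$lnv_mean)) %>%
    mutate(fst_bin = cut(.data$fst_clamped, breaks = bin_edges,
                         include.lowest = TRUE, right = FALSE))
  empty <- setdiff(levels(d$fst_bin), unique(as.character(d$fst_bin)))
  if (length(empty)) {
    warn(paste0("dropping empty FST bins: ", paste(empty, collapse = ", ")))
    d$fst_bin <- droplevels(d$fst_bin)
  }
  if (nlevels(d$fst_bin) < 2) abort("need >= 2 populated FST bins.")
  fit <- aov(lnv_mean ~ fst_bin, data = d)
  s <- summary(fit)[[1]]
  list(
    group_means = d %>% group_by(.data$fst_bin) %>%
      summarise(n = n(), mean_lnv = mean(.data$lnv_mean), .groups = "drop"),
    f_statistic = s[["F value"]][1], p_value = s[["Pr(>F)"]][1],
    pearson_r = cor(d$fst_clamped, d$lnv_mean))
}

#' Classify variants as SNP or indel from allele lengths
#'
#' SNP when REF and ALT are both single bases; indel when their lengths
#' differ; multi-base substitutions of equal length (MNPs) get `NA` and are
#' excluded from comparisons.
#'
#' @param ref,alt allele strings.
#' @return character vector `"SNP"`, `"indel"` or `NA`.
#' @export
variant_type <- function(ref, alt) {
  dplyr::case_when(
    nchar(ref) == 1L & nchar(alt) == 1L ~ "SNP",
    nchar(ref) != nchar(alt) ~ "indel",
    TRUE ~ NA_character_)
}

#' Linear regression of cline steepness on variant-consequence category
#'
#' Ordinary least squares of `ln(v)` on the most-severe consequence category,
#' fitted without an intercept so each category is reported as its own mean
#' with a 95% confidence interval; the overall F test comes from the
#' with-intercept parameterisation of the same model. Categories with fewer
#' than `min_count` variants are dropped.
#'
#' @param cline_tbl tibble with `locus_id`, `lnv_mean`.
#' @param annotation tibble with `locus_id`, `consequence` (one most-severe
#'   consequence per variant).
#' @param min_count minimum variants per category (default 1000).
#' @return list: `estimates` (tibble `consequence`, `n`, `estimate`, `lo95`,
#'   `hi95`), `f_statistic`, `p_value`.
#' @export
effect_regression <- function(cline_tbl, annotation, min_count = 1000) {
  d <- dplyr::inner_join(
    select(as_tibble(cline_tbl), "locus_id", "lnv_mean"),
    select(as_tibble(annotation), "locus_id", "consequence"),
    by = "locus_id") %>%
    filter(is.finite(.data$lnv_mean), !is.na(.data$consequence)) %>%
    group_by(.data$consequence) %>% filter(n() >= min_count) %>% ungroup()
  if (dplyr::n_distinct(d$consequence) < 2) {
    abort("fewer than 2 consequence categories after the count filter.")
  }
  d$consequence <- factor(d$consequence)
  fit0 <- lm(lnv_mean ~ 0 + consequence, data = d)
  ci <- confint(fit0)
  fit1 <- lm(lnv_mean ~ consequence, data = d)
  fstat <- summary(fit1)$fstatistic
  counts <- d %>% count(.data$consequence)
  list(
    estimates = tibble(
      consequence = levels(d$consequence),
      n = counts$n[match(levels(d$consequence), counts$consequence)],
      estimate = unname(coef(fit0)), lo95 = ci[, 1], hi95 = ci[, 2]),
    f_statistic = unname(fstat[1]),
    p_value = unname(pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)))
}

#' Compare cline steepness between SNPs and indels
#'
#' Two-sided Mann-Whitney-Wilcoxon test of `ln(v)` between variant types
#' (normal approximation with tie correction), with per-type means and SDs.
#'
#' @param cline_tbl tibble with `locus_id`, `lnv_mean`, `ref`, `alt` (or a
#'   pre-computed `type` column).
#' @return list: `summary` (tibble `type`, `n`, `mean_lnv`, `sd_lnv`),
#'   `p_value`, `statistic`.
#' @export
snp_indel_test <- function(cline_tbl) {
  d <- as_tibble(cline_tbl)
  if (!"type" %in% names(d)) {
    if (!all(c("ref", "alt") %in% names(d))) {
      abort("need `ref`/`alt` (or `type`) columns.")
    }
    d$type <- variant_type(d$ref, d$alt)
  }
  n_mnp <- sum(is.na(d$type))
  if (n_mnp > 0) inform(sprintf("snp_indel_test: excluded %d MNP variants.", n_mnp))
  d <- d %>% filter(!is.na(.data$type), is.finite(.data$lnv_mean))
  if (dplyr::n_distinct(d$type) < 2) abort("both SNP and indel types required.")
  wt <- wilcox.test(lnv_mean ~ type, data = d, exact = FALSE, correct = TRUE)
  list(
    summary = d %>% group_by(type = .data$type) %>%
      summarise(n = n(), mean_lnv = mean(.data$lnv_mean),
                sd_lnv = sd(.data$lnv_mean), .groups = "drop"),
    p_value = wt$p.value, statistic = unname(wt$statistic))
}

#' Categorise recombination-map bins (and variants) as hotspot/coldspot/other
#'
#' A bin is a hotspot when its crossover count exceeds
#' `mean + sd_mult * SD` of the per-bin counts in BOTH sires (or when it is
#' named in `hotspot_bins`); a bin is a coldspot when it lies inside a
#' maximal run of at least `coldspot_min_run` consecutive zero-count bins in
#' EITHER sire. If a bin qualifies as both, hotspot takes precedence and the
#' conflict is flagged. Variant positions, if supplied, inherit the category
#' of their containing bin; positions outside the map get `"other"` with a
#' warning.
#'
#' @param map tibble from [simulate_recomb_map()] or with columns `chrom`,
#'   `start`, `end`, `sire1`, `sire2`.
#' @param hotspot_bins optional tibble (`chrom`, `start`) of externally
#'   defined hotspot bins, bypassing the mean/SD rule.
#' @param coldspot_min_run minimum zero-run length in bins (default 3).
#' @param sd_mult hotspot threshold multiplier (default 2.5).
#' @param variants optional tibble (`locus_id`, `chrom`, `pos`).
#' @return list: `bins` (map plus `category`, `conflict`) and `variants`
#'   (input plus `category`; NULL if not supplied).
#' @export
classify_recomb <- function(map, hotspot_bins = NULL, coldspot_min_run = 3,
                            sd_mult = 2.5, variants = NULL) {
  map <- as_tibble(map)
  need <- c("chrom", "start", "end", "sire1", "sire2")
  if (!all(need %in% names(map))) {
    abort(paste0("malformed map; need columns: ", paste(need, collapse = ", ")))
  }
  map <- arrange(map, .data$chrom, .data$start)
  if (is.null(hotspot_bins)) {
    thr1 <- mean(map$sire1) + sd_mult * sd(map$sire1)
    thr2 <- mean(map$sire2) + sd_mult * sd(map$sire2)
    hot <- map$sire1 > thr1 & map$sire2 > thr2
  } else {
    hot <- paste(map$chrom, map$start) %in%
      paste(hotspot_bins$chrom, hotspot_bins$start)
  }
  zero_runs <- function(z, chrom) {
    out <- logical(length(z))
    for (ch in unique(chrom)) {
      idx <- which(chrom == ch)
      r <- rle(z[idx] == 0)
      flag <- rep(r$values & r$lengths >= coldspot_min_run, r$lengths)
      out[idx] <- flag
    }
    out
  }
  cold <- zero_runs(map$sire1, map$chrom) | zero_runs(map$sire2, map$chrom)
  conflict <- hot & cold
  if (any(conflict)) {
    warn(sprintf("%d bins qualify as both hotspot and coldspot; hotspot takes precedence.",
                 sum(conflict)))
  }
  map$category <- ifelse(hot, "hotspot", ifelse(cold, "coldspot", "other"))
  map$conflict <- conflict

  var_out <- NULL
  if (!is.null(variants)) {
    variants <- as_tibble(variants)
    cat <- rep("other", nrow(variants))
    covered <- rep(FALSE, nrow(variants))
    for (ch in unique(variants$chrom)) {
      vi <- which(variants$chrom == ch)
      bi <- which(map$chrom == ch)
      if (!length(bi)) next
      hit <- findInterval(variants$pos[vi], map$start[bi])
      in_bin <- hit >= 1 & variants$pos[vi] <= map$end[bi][pmax(hit, 1)]
      cat[vi[in_bin]] <- map$category[bi][hit[in_bin]]
      covered[vi[in_bin]] <- TRUE
    }
    if (any(!covered)) {
      warn(sprintf("%d variants fall outside the recombination map; categorised 'other'.",
                   sum(!covered)))
    }
    variants$category <- cat
    var_out <- variants
  }
  list(bins = map, variants = var_out)
}

#' Regression of a response on recombination category with Tukey contrasts
#'
#' One-way linear model of the response (`ln(v)` or FST) on the
#' hotspot/coldspot/other category, with Tukey HSD pairwise contrasts at
#' family-wise 95% confidence.
#'
#' @param data tibble with columns `response` and `category` (>= 2 populated
#'   categories).
#' @return list: `estimates` (tibble `category`, `n`, `mean`), `f_statistic`,
#'   `p_value`, `tukey` (tibble `contrast`, `diff`, `lo95`, `hi95`, `p_adj`).
#' @export
recomb_category_regression <- function(data) {
  d <- as_tibble(data) %>%
    filter(is.finite(.data$response), !is.na(.data$category))
  if (dplyr::n_distinct(d$category) < 2) abort("need >= 2 categories.")
  d$category <- factor(d$category)
  fit <- aov(response ~ category, data = d)
  s <- summary(fit)[[1]]
  tk <- TukeyHSD(fit)$category
  list(
    estimates = d %>% group_by(category = .data$category) %>%
      summarise(n = n(), mean = mean(.data$response), .groups = "drop"),
    f_statistic = s[["F value"]][1], p_value = s[["Pr(>F)"]][1],
    tukey = tibble(contrast = rownames(tk), diff = tk[, "diff"],
                   lo95 = tk[, "lwr"], hi95 = tk[, "upr"],
                   p_adj = tk[, "p adj"]))
}

#' Chi-square test of centre-class composition, SCVs vs all variants
#'
#' Pearson chi-square (no continuity correction) on the 2 x 3 table of
#' cline-centre class counts in the SCV set against a comparison set: either
#' all variants (`mode = "vs_all"`, the printed-table construction, where
#' the SCV set is a subset of the comparison) or the non-SCV complement
#' (`mode = "vs_complement"`).
#'
#' @param scv_counts named integer vector of SCV counts per centre class.
#' @param all_counts matching counts for the unfiltered variant set.
#' @param mode `"vs_all"` or `"vs_complement"`.
#' @return tibble: `statistic`, `df`, `p_value`.
#' @export
centre_class_chisq <- function(scv_counts, all_counts,
                               mode = c("vs_all", "vs_complement")) {
  mode <- match.arg(mode)
  if (length(scv_counts) != length(all_counts)) {
    abort("class count vectors must align.")
  }
  other <- if (mode == "vs_all") all_counts else all_counts - scv_counts
  tab <- rbind(scv = scv_counts, comparison = other)
  if (any(colSums(tab) == 0) || any(rowSums(tab) == 0)) {
    abort("zero marginal in the contingency table.")
  }
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  tibble(statistic = unname(ct$statistic), df = unname(ct$parameter),
         p_value = unname(ct$p.value))
}

#' Pearson correlation on paired finite values
#'
#' @param x,y numeric vectors of equal length; pairs with non-finite entries
#'   are dropped; at least 3 complete pairs required.
#' @return the Pearson correlation coefficient.
#' @export
correlate <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3) abort("need >= 3 complete pairs.")
  if (sd(x[ok]) == 0 || sd(y[ok]) == 0) abort("zero-variance input.")
  cor(x[ok], y[ok])
}
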