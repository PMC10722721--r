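make_pop_gm <- function(geno_by_pop) {
  g <- do.call(rbind, geno_by_pop)
  rownames(g) <- sprintf("s%d", seq_len(nrow(g)))
  L <- ncol(g)
  loci <- tibble::tibble(locus_id = sprintf("c1_%d", seq_len(L) * 10),
                         chrom = "c1", pos = seq_len(L) * 10L,
                         ref = "A", alt = "T", focal = "ALT")
  gm <- geno_matrix(g, loci)
  pops <- tibble::tibble(
    sample_id = rownames(g),
    population = rep(sprintf("P%d", seq_along(geno_by_pop)),
                     vapply(geno_by_pop, nrow, integer(1))))
  list(gm = gm, pops = pops)
}

test_that("Weir-Cockerham FST hits the fixed-difference and null endpoints", {
  # two populations of 10 fixed for alternate alleles -> theta = 1
  fx <- make_pop_gm(list(matrix(0L, 10, 1), matrix(2L, 10, 1)))
  out <- weir_fst_multipop(fx$gm, fx$pops)
  expect_equal(out$fst_raw, 1)
  # identical HWE-ish genotype counts -> theta <= 0, clamped to 0
  block <- matrix(rep(c(0L, 1L, 1L, 2L), 4), 16, 1)
  fx0 <- make_pop_gm(list(block, block))
  out0 <- weir_fst_multipop(fx0$gm, fx0$pops)
  expect_lte(out0$fst_raw, 0)
  expect_equal(out0$fst_clamped, 0)
})

test_that("multi-population FST matches the independent W&C oracle", {
  set.seed(31)
  for (i in 1:25) {
    r <- sample(2:5, 1)
    geno_by_pop <- lapply(seq_len(r), function(p) {
      n <- sample(5:12, 1)
      pr <- runif(1)
      m <- matrix(rbinom(n * 3, 2, pr), n, 3)
      m[sample(length(m), 2)] <- NA
      storage.mode(m) <- "integer"
      m
    })
    fx <- make_pop_gm(geno_by_pop)
    got <- weir_fst_multipop(fx$gm, fx$pops)
    for (j in 1:3) {
      per_pop <- lapply(geno_by_pop, function(m) m[, j])
      skip_pop <- vapply(per_pop, function(g) all(is.na(g)), logical(1))
      want <- wc_oracle(per_pop[!skip_pop])
      expect_equal(got$fst_raw[j], want, tolerance = 1e-12)
    }
    # permutation of population labels leaves theta unchanged
    perm <- fx$pops
    map <- setNames(sample(unique(perm$population)), unique(perm$population))
    perm$population <- map[perm$population]
    expect_equal(weir_fst_multipop(fx$gm, perm)$fst_raw, got$fst_raw,
                 tolerance = 1e-12)
  }
})

test_that("FST-group ANOVA recovers constructed monotone structure", {
  set.seed(32)
  n <- 600
  fst <- tibble::tibble(locus_id = sprintf("l%d", 1:n),
                        fst_clamped = runif(n, 0, 0.6))
  cl <- tibble::tibble(locus_id = fst$locus_id,
                       lnv_mean = 2 * fst$fst_clamped + rnorm(n, 0, 0.1))
  res <- suppressWarnings(fst_group_anova(fst, cl))
  expect_true(all(diff(res$group_means$mean_lnv) > 0))
  expect_lt(res$p_value, 1e-10)
  expect_gt(res$pearson_r, 0.8)
  # two-bin case reproduces F = t^2
  res2 <- fst_group_anova(fst, cl, bin_edges = c(0, 0.3, 1))
  d <- dplyr::inner_join(fst, cl, by = "locus_id")
  tt <- t.test(lnv_mean ~ fst_clamped < 0.3, data = d, var.equal = TRUE)
  expect_equal(res2$f_statistic, unname(tt$statistic)^2, tolerance = 1e-8)
  # null: no association -> p roughly uniform (single broad check)
  cl_null <- tibble::tibble(locus_id = fst$locus_id, lnv_mean = rnorm(n))
  res3 <- suppressWarnings(fst_group_anova(fst, cl_null))
  expect_gt(res3$p_value, 1e-4)
})

test_that("variant typing and the SNP/indel comparison behave", {
  expect_identical(variant_type(c("A", "A", "AT", "AT"),
                                c("G", "AT", "A", "GC")),
                   c("SNP", "indel", "indel", NA))
  set.seed(33)
  n <- 400
  tbl <- tibble::tibble(
    locus_id = sprintf("l%d", 1:n),
    ref = rep(c("A", "A"), n / 2),
    alt = rep(c("G", "ATT"), n / 2),
    lnv_mean = rnorm(n) + rep(c(0, 1), n / 2))  # indels shifted up by 1
  res <- suppressMessages(snp_indel_test(tbl))
  expect_lt(res$p_value, 1e-6)
  m <- setNames(res$summary$mean_lnv, res$summary$type)
  expect_gt(m[["indel"]], m[["SNP"]])
  # identical distributions: p not systematically small
  tbl$lnv_mean <- rnorm(n)
  expect_gt(suppressMessages(snp_indel_test(tbl))$p_value, 1e-3)
  expect_error(snp_indel_test(tbl[tbl$alt == "G", ]), "both")
})

test_that("effect regression drops rare categories and finds shifts", {
  set.seed(34)
  counts <- c(intergenic = 1500, intron = 1200, missense = 999)
  ann <- tibble::tibble(
    locus_id = sprintf("l%d", seq_len(sum(counts))),
    consequence = rep(names(counts), counts))
  cl <- tibble::tibble(
    locus_id = ann$locus_id,
    lnv_mean = rnorm(sum(counts)) + ifelse(ann$consequence == "intron", 1, 0))
  res <- effect_regression(cl, ann, min_count = 1000)
  expect_setequal(res$estimates$consequence, c("intergenic", "intron"))
  est <- setNames(res$estimates$estimate, res$estimates$consequence)
  expect_equal(est[["intron"]] - est[["intergenic"]], 1, tolerance = 0.15)
  expect_lt(res$p_value, 1e-10)
  # equal means: F small, p large
  cl0 <- cl; cl0$lnv_mean <- rnorm(nrow(cl))
  res0 <- effect_regression(cl0, ann, min_count = 1000)
  expect_gt(res0$p_value, 0.001)
  expect_error(effect_regression(cl, ann, min_count = 2000), "categories")
})

test_that("recombination classification finds zero runs and hotspots", {
  map <- tibble::tibble(
    chrom = "c1", start = seq(1, by = 1e6, length.out = 12),
    end = seq(1e6, by = 1e6, length.out = 12),
    sire1 = c(5, 4, 0, 0, 0, 6, 5, 4, 0, 0, 5, 80),
    sire2 = c(4, 5, 3, 2, 4, 5, 4, 5, 3, 2, 4, 90))
  cl <- classify_recomb(map)
  expect_identical(cl$bins$category[3:5], rep("coldspot", 3))  # zero run of 3
  expect_identical(cl$bins$category[9:10], rep("other", 2))    # run of 2 only
  expect_identical(cl$bins$category[12], "hotspot")            # high in both
  # variants inherit the containing bin's category
  vars <- tibble::tibble(locus_id = c("a", "b", "c"), chrom = "c1",
                         pos = c(2.5e6, 11.5e6, 99e6))
  expect_warning(cv <- classify_recomb(map, variants = vars), "outside")
  expect_identical(cv$variants$category, c("coldspot", "hotspot", "other"))
  expect_error(classify_recomb(map[, 1:3]), "malformed")
})

test_that("category regression with Tukey contrasts flags a raised group", {
  set.seed(36)
  d <- tibble::tibble(
    category = rep(c("hotspot", "coldspot", "other"), c(60, 60, 300)),
    response = rnorm(420) + ifelse(rep(c("hotspot", "coldspot", "other"),
                                       c(60, 60, 300)) == "coldspot", 0.8, 0))
  res <- recomb_category_regression(d)
  tk <- res$tukey
  cold_other <- tk[tk$contrast %in% c("other-coldspot", "coldspot-other"), ]
  expect_lt(cold_other$p_adj, 0.01)
  expect_false(dplyr::between(0, cold_other$lo95, cold_other$hi95))
  # equal means: all contrasts cover zero
  d0 <- d; d0$response <- rnorm(420)
  tk0 <- recomb_category_regression(d0)$tukey
  expect_true(all(tk0$lo95 < 0 & tk0$hi95 > 0))
  # two categories: Tukey reduces to the pooled t-test
  d2 <- d[d$category != "other", ]
  res2 <- recomb_category_regression(d2)
  tt <- t.test(response ~ category, data = d2, var.equal = TRUE)
  expect_equal(res2$tukey$p_adj, tt$p.value, tolerance = 1e-8)
  expect_error(recomb_category_regression(d2[d2$category == "hotspot", ]),
               "categories")
})

test_that("centre-class chi-square matches the direct formula", {
  # proportional rows give statistic 0
  z <- centre_class_chisq(c(10, 20, 10), c(100, 200, 100), mode = "vs_all")
  expect_equal(z$statistic, 0)
  expect_equal(z$df, 2)
  chisq_oracle <- function(tab) {
    e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    sum((tab - e)^2 / e)
  }
  set.seed(37)
  for (i in 1:20) {
    scv <- rpois(3, 50) + 1
    all <- scv + rpois(3, 500) + 1
    got <- centre_class_chisq(scv, all, mode = "vs_all")
    expect_equal(got$statistic, chisq_oracle(rbind(scv, all)),
                 tolerance = 1e-10)
    got2 <- centre_class_chisq(scv, all, mode = "vs_complement")
    expect_equal(got2$statistic, chisq_oracle(rbind(scv, all - scv)),
                 tolerance = 1e-10)
  }
  expect_error(centre_class_chisq(c(0, 0, 0), c(0, 10, 10)), "marginal")
})

test_that("correlation helper matches the covariance formula and validates", {
  expect_equal(correlate(1:10, 1:10), 1)
  expect_equal(correlate(1:10, -(1:10)), -1)
  set.seed(38)
  x <- rnorm(50); y <- rnorm(50)
  want <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(correlate(x, y), want, tolerance = 1e-12)
  x[1] <- NA
  expect_equal(correlate(x, y), cor(x, y, use = "complete.obs"))
  expect_error(correlate(c(1, 1, 1), 1:3), "variance")
  expect_error(correlate(1:2, 1:2), "pairs")
})
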