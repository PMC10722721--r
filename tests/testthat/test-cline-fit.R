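test_that("cline function matches its closed form and boundary limits", {
  h <- seq(0, 1, by = 0.05)
  expect_equal(cline_function(h, v = 1, c = 0.5), h)           # identity cline
  for (v in c(0.5, 2, 10)) {
    expect_equal(cline_function(0.37, v = v, c = 0.37), 0.5)   # centre: phi = 1/2
  }
  expect_equal(cline_function(0.7, v = 10, c = 0.5),
               plogis(10 * log(0.7 / 0.3)), tolerance = 1e-12)
  expect_identical(cline_function(c(0, 1), v = 3, c = 0.2), c(0, 1))
  expect_error(cline_function(0.5, v = 0, c = 0.5), "v")
  expect_error(cline_function(0.5, v = 1, c = 1), "c")
})

test_that("cline function is increasing in h and reflection-symmetric", {
  h <- seq(0.01, 0.99, by = 0.01)
  for (pars in list(c(2, 0.3), c(0.7, 0.5), c(10, 0.8))) {
    phi <- cline_function(h, pars[1], pars[2])
    expect_true(all(diff(phi) > 0))
    expect_equal(cline_function(1 - h, pars[1], 1 - pars[2]), 1 - phi,
                 tolerance = 1e-12)
  }
})

test_that("WAIC matches a direct-formula oracle and its edge cases", {
  # constant draws: p_waic = 0, waic = -2 * sum(ll)
  ll_const <- matrix(-1.3, nrow = 4, ncol = 5)
  w <- compute_waic(ll_const)
  expect_equal(w$p_waic, 0)
  expect_equal(w$waic, -2 * 4 * (-1.3))
  # tiny toy matrix against the brute-force oracle
  ll <- matrix(c(-1.0, -0.5, -2.0,
                 -0.8, -1.1, -0.6), nrow = 2, byrow = TRUE)
  got <- compute_waic(ll)
  want <- waic_oracle(ll)
  expect_equal(got$lppd, unname(want["lppd"]), tolerance = 1e-12)
  expect_equal(got$p_waic, unname(want["p_waic"]), tolerance = 1e-12)
  expect_equal(got$waic, unname(want["waic"]), tolerance = 1e-12)
  # duplicating an observation row adds exactly its contributions
  ll3 <- rbind(ll, ll[1, ])
  expect_equal(compute_waic(ll3)$waic,
               -2 * ((got$lppd - got$p_waic) +
                       (log(mean(exp(ll[1, ]))) - var(ll[1, ]))),
               tolerance = 1e-10)
  # weights are multiplicities
  expect_equal(compute_waic(ll, weights = c(2, 1))$waic,
               compute_waic(ll3)$waic, tolerance = 1e-12)
  # random matrices against the oracle
  set.seed(99)
  for (i in 1:10) {
    m <- matrix(rnorm(60, -2, 1), nrow = 6)
    expect_equal(compute_waic(m)$waic, unname(waic_oracle(m)["waic"]),
                 tolerance = 1e-12)
  }
  expect_error(compute_waic(matrix(1, 2, 1)), "draws")
  expect_error(compute_waic(matrix(c(1, Inf), 1, 2)), "finite")
})

test_that("model comparison applies the full-minus-reduced sign convention", {
  tf <- tibble::tibble(locus_id = c("l1", "l2"), waic = c(100, 50),
                       n_obs = c(10, 10))
  tr <- tibble::tibble(locus_id = c("l1", "l2"), waic = c(120, 50),
                       n_obs = c(10, 10))
  dw <- compare_models(tf, tr)
  expect_equal(dw$delta_waic, c(-20, 0))
  tr_bad <- tr; tr_bad$n_obs <- c(9, 10)
  expect_error(compare_models(tf, tr_bad), "observation counts")
  expect_error(compare_models(tf, tr[1, ]), "different loci")
})

# shared small fixture for the fitting tests
cline_fixture <- function(seed = 61, n_test = 60, n_loci = 20, ...) {
  sim <- simulate_dataset(sim_config(
    n_s0 = 15, n_s1 = 15, n_test = n_test, n_loci = n_loci,
    freq_model = list(p0_range = c(0, 0.05), p1_range = c(0.95, 1)),
    seed = seed, ...))
  sf <- estimate_source_freqs(sim$genotypes, sim$assignments)
  ret <- suppressMessages(filter_ci_overlap(sf$freqs))
  h <- tibble::tibble(
    sample_id = sim$truth$individuals$sample_id,
    h_mean = sim$truth$individuals$true_h)  # true h: isolates the cline fit
  list(sim = sim, gm = sf$genotypes, freqs = ret, h = h,
       asg = sim$assignments)
}

test_that("reduced model pins ln(v) to zero with zero variance", {
  fx <- cline_fixture(n_loci = 5)
  fit <- fit_clines(fx$gm, fx$h, fx$freqs, fx$asg, nitt = 600, burnin = 200,
                    fix_v = TRUE, seed = 1)
  est <- tidy(fit)
  expect_true(all(est$lnv_mean == 0))
  expect_true(all(est$lnv_var == 0))
  expect_true(all(est$v_mean == 1))
})

test_that("MCMC posterior matches a dense 2-D grid quadrature on a small locus", {
  fx <- cline_fixture(seed = 67, n_test = 20, n_loci = 2)
  j <- 1
  # matched prior variance 2 on both latent parameters keeps the small-locus
  # posterior concentrated enough for a tight quadrature comparison
  fit <- fit_clines(fx$gm, fx$h, fx$freqs[j, ], fx$asg, nitt = 82000,
                    burnin = 2000, prior_var_v = 2, prior_var_c = 2,
                    estimate_freqs = FALSE, seed = 2)
  est <- tidy(fit)

  # independent oracle: direct quadrature of the same posterior
  gt <- fx$gm$geno[, fx$freqs$locus_id[j]]
  lab <- fx$asg$label[match(rownames(fx$gm$geno), fx$asg$sample_id)]
  hh <- ifelse(lab == "S0", 0, ifelse(lab == "S1", 1,
               fx$h$h_mean[match(rownames(fx$gm$geno), fx$h$sample_id)]))
  use <- !is.na(gt)
  p0 <- fx$freqs$p0_mean[j]; p1 <- fx$freqs$p1_mean[j]
  grid_lnv <- seq(-6, 6, length.out = 241)
  grid_lc <- seq(-7, 7, length.out = 241)
  logpost <- matrix(NA_real_, 241, 241)
  for (a in seq_along(grid_lnv)) {
    for (b in seq_along(grid_lc)) {
      phi <- cline_function(hh[use], exp(grid_lnv[a]), plogis(grid_lc[b]))
      f <- phi * p1 + (1 - phi) * p0
      logpost[a, b] <- sum(gt[use] * log(f) + (2 - gt[use]) * log1p(-f)) -
        grid_lnv[a]^2 / 4 - grid_lc[b]^2 / 4
    }
  }
  w <- exp(logpost - max(logpost)); w <- w / sum(w)
  mean_lnv <- sum(rowSums(w) * grid_lnv)
  mean_lc <- sum(colSums(w) * grid_lc)
  expect_lt(abs(est$lnv_mean - mean_lnv), 0.05)
  expect_lt(abs(est$logitc_mean - mean_lc), 0.05)
})

test_that("steep barrier loci are recovered and supported by delta WAIC", {
  fx <- cline_fixture(seed = 71, n_test = 200, n_loci = 12, barrier_spec =
    list(list(frac = 0.5, lnv = 2.5, centre = 0.5, clustered = FALSE)))
  full <- fit_clines(fx$gm, fx$h, fx$freqs, fx$asg, seed = 3)
  red <- fit_clines(fx$gm, fx$h, fx$freqs, fx$asg, fix_v = TRUE, seed = 4)
  dw <- compare_models(full, red)
  tb <- dplyr::inner_join(tidy(full), dw, by = "locus_id")
  tb <- dplyr::inner_join(tb, fx$sim$truth$loci[, c("locus_id", "lnv")],
                          by = "locus_id")
  barrier <- tb$lnv > 0
  expect_gt(mean(tb$lnv_mean[barrier] > 2.0 & tb$lnv_mean[barrier] < 3.0), 0.7)
  expect_true(all(tb$delta_waic[barrier] < -10))
  expect_gt(mean(abs(tb$lnv_mean[!barrier]) < 0.5), 0.7)
})

test_that("S0<->S1 swap leaves v unchanged and reflects the centre", {
  fx <- cline_fixture(seed = 73, n_test = 150, n_loci = 8, barrier_spec =
    list(list(frac = 0.5, lnv = 2, centre = 0.35, clustered = FALSE)))
  fit_a <- fit_clines(fx$gm, fx$h, fx$freqs, fx$asg, seed = 5)

  swapped <- fx$asg
  swapped$label <- c(S0 = "S1", S1 = "S0", TEST = "TEST")[swapped$label]
  h_sw <- fx$h; h_sw$h_mean <- 1 - h_sw$h_mean
  sf2 <- estimate_source_freqs(fx$sim$genotypes, swapped)
  ret2 <- suppressMessages(filter_ci_overlap(sf2$freqs))
  fit_b <- fit_clines(sf2$genotypes, h_sw, ret2, swapped, seed = 6)
  d <- dplyr::inner_join(tidy(fit_a), tidy(fit_b), by = "locus_id",
                         suffix = c("_a", "_b"))
  expect_lt(max(abs(d$lnv_mean_a - d$lnv_mean_b)), 0.35)
  expect_lt(max(abs(d$c_mean_a - (1 - d$c_mean_b))), 0.06)
})

test_that("REF/ALT relabelling leaves cline estimates unchanged", {
  fx <- cline_fixture(seed = 79, n_test = 80, n_loci = 6)
  fit_a <- fit_clines(fx$gm, fx$h, fx$freqs, fx$asg, nitt = 2000,
                      burnin = 500, seed = 7)
  flipped <- flip_focal(fx$sim$genotypes, fx$sim$genotypes$loci$locus_id)
  sf2 <- estimate_source_freqs(flipped, fx$asg)
  ret2 <- suppressMessages(filter_ci_overlap(sf2$freqs))
  fit_b <- fit_clines(sf2$genotypes, fx$h, ret2, fx$asg, nitt = 2000,
                      burnin = 500, seed = 7)
  # re-orientation makes the fits identical draw for draw
  expect_equal(tidy(fit_a)$lnv_mean, tidy(fit_b)$lnv_mean, tolerance = 1e-12)
  expect_equal(tidy(fit_a)$c_mean, tidy(fit_b)$c_mean, tolerance = 1e-12)
})

test_that("monomorphic loci are flagged instead of fitted", {
  fx <- cline_fixture(n_loci = 3)
  gm <- fx$gm
  gm$geno[, 1] <- 2L  # every copy focal
  sf <- estimate_source_freqs(gm, fx$asg)
  fit <- fit_clines(sf$genotypes, fx$h, fx$freqs, fx$asg, nitt = 600,
                    burnin = 200, seed = 8)
  est <- tidy(fit)
  expect_equal(est$flag[1], "monomorphic")
  expect_true(is.na(est$lnv_mean[1]))
  expect_true(all(est$flag[-1] == "ok"))
})
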