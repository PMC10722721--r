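#' Fit logit-logistic genomic clines locus by locus
#'
#' Per-locus Bayesian fit of the cline steepness `v` and centre `c` on the
#' latent scale (`ln v`, `logit c`), where each non-missing allele copy of
#' individual `i` is the focal allele with probability
#' `phi(h_i; v, c) * p1 + (1 - phi(h_i; v, c)) * p0` (see
#' [cline_function()]). Test individuals enter with `h_i` fixed at its
#' posterior mean from [esth()]; source individuals (if `include_source`)
#' enter with `h = 0` (S0) or `h = 1` (S1). By default
#' (`estimate_freqs = TRUE`) the source allele frequencies are estimated
#' jointly with the cline: each iteration draws the latent ancestry of every
#' test allele copy and then updates `p0`, `p1` from conjugate Beta
#' posteriors combining the oriented source allele counts (the Jeffreys
#' pseudo-counts of [estimate_source_freqs()]) with the ancestry-assigned
#' test copies. This propagates source-frequency uncertainty into
#' `delta_waic` and keeps its null calibration correct when source panels
#' are small. With `estimate_freqs = FALSE` the frequencies stay fixed at
#' their posterior means; source individuals' likelihood terms are then
#' constant in `(v, c)` and only enter the WAIC observation set.
#' Priors are independent normals on the latent scale
#' (`ln v ~ N(0, prior_var_v)`, `logit c ~ N(0, prior_var_c)`).
#'
#' Sampling is joint adaptive random-walk Metropolis on `(ln v, logit c)`
#' with a per-locus proposal scale adapted during burn-in only; all loci are
#' advanced together as one vectorised chain (each locus still has its own
#' independent posterior and acceptance decisions). With `fix_v = TRUE` the
#' reduced (neutral-steepness) model is fitted: `ln v` pinned to 0 and only
#' `logit c` sampled. The WAIC of each fit is computed from the post-burn-in
#' pointwise log-likelihood draws; `waic_unit` sets the observation unit.
#'
#' Original-scale summaries `v_mean`, `c_mean` are posterior means of the
#' transformed draws (not transforms of latent means); credible intervals
#' are equal-tailed quantiles. Bayesian p-values are two-sided normal tail
#' probabilities of the latent posterior mean/SD against 0. The derived
#' shift `u = v * logit(c)` is reported as its posterior mean. Monomorphic
#' loci (all usable allele copies identical) are returned with
#' `flag = "monomorphic"` and NA estimates rather than forced fits.
#'
#' @param gm a [geno_matrix()] (re-oriented, from [estimate_source_freqs()]).
#' @param h_fit a `hybrid_index_fit` from [esth()], or a tibble with columns
#'   `sample_id`, `h_mean`.
#' @param freqs retained source-frequency tibble ([filter_ci_overlap()]);
#'   only loci present here are fitted.
#' @param assignments tibble (`sample_id`, `label`).
#' @param nitt,burnin chain length and burn-in (`nitt > burnin`).
#' @param fix_v fit the reduced model with `v = 1`.
#' @param include_source include S0/S1 individuals as observations.
#' @param prior_var_v,prior_var_c latent prior variances (default 10).
#' @param estimate_freqs jointly estimate the source allele frequencies
#'   within the per-locus MCMC (default) instead of fixing them at their
#'   posterior means.
#' @param waic_unit pointwise WAIC observation unit: `"genotype"` (default;
#'   the two allele copies of an individual at a locus form one pointwise
#'   observation) or `"copy"` (each allele copy separately). The unit sets
#'   the granularity of the effective-parameter penalty and therefore the
#'   calibration of `delta_waic`: with genotype units the mild criterion
#'   `delta_waic < -2` flags ~5% of truly neutral loci, the conventional
#'   behaviour for this model comparison; copy units give a laxer penalty.
#'   Genotype-unit WAIC omits the binomial coefficient of heterozygotes, a
#'   constant that cancels in any model comparison.
#' @param seed integer seed; results are reproducible given the seed and
#'   the fitted locus set.
#' @return a `cline_fit` object; [tidy()] gives one row per locus with
#'   latent and original-scale posterior summaries, Bayesian p-values,
#'   `waic`, `lppd`, `p_waic`, `n_obs`, `u`, ESS and acceptance diagnostics,
#'   and a `flag` column (`"ok"` or `"monomorphic"`).
#' @export
fit_clines <- function(gm, h_fit, freqs, assignments, nitt = 5000,
                       burnin = 2000, fix_v = FALSE, include_source = TRUE,
                       prior_var_v = 10, prior_var_c = 10,
                       estimate_freqs = TRUE,
                       waic_unit = c("genotype", "copy"), seed = 1L) {
  stopifnot(inherits(gm, "geno_matrix"))
  waic_unit <- match.arg(waic_unit)
  if (nitt <= burnin) abort("`nitt` must exceed `burnin`.")
  seed <- stopifnot_scalar_seed(seed)
  h_tbl <- if (inherits(h_fit, "hybrid_index_fit")) h_fit$estimates else as_tibble(h_fit)

  gm <- subset_loci(gm, freqs$locus_id)
  fr <- freqs[match(gm$loci$locus_id, freqs$locus_id), ]
  L_all <- nrow(fr)

  # observation set: test individuals with estimated h, sources at h = 0/1
  test_ids <- assignments$sample_id[assignments$label == "TEST"]
  test_ids <- intersect(test_ids, h_tbl$sample_id)
  h_test <- h_tbl$h_mean[match(test_ids, h_tbl$sample_id)]
  h_test <- pmin(pmax(h_test, 1e-6), 1 - 1e-6)
  src <- assignments[assignments$label %in% c("S0", "S1"), ]
  if (!include_source) src <- src[0, ]

  geno_t <- gm$geno[match(test_ids, rownames(gm$geno)), , drop = FALSE]
  geno_s <- gm$geno[match(src$sample_id, rownames(gm$geno)), , drop = FALSE]
  h_src <- ifelse(src$label == "S1", 1, 0)
  n <- length(test_ids)

  # focal / non-focal copy counts per individual x locus (NA -> 0 weight)
  K1 <- geno_t; K1[is.na(K1)] <- 0L; storage.mode(K1) <- "double"
  K0 <- 2 - geno_t; K0[is.na(K0)] <- 0L; storage.mode(K0) <- "double"
  KS1 <- geno_s; KS1[is.na(KS1)] <- 0L; storage.mode(KS1) <- "double"
  KS0 <- 2 - geno_s; KS0[is.na(KS0)] <- 0L; storage.mode(KS0) <- "double"

  # monomorphic guard: loci without both allele states among usable copies
  tot1 <- colSums(K1) + colSums(KS1)
  tot0 <- colSums(K0) + colSums(KS0)
  fit_mask <- colSums(K1 + K0) > 0 & tot1 > 0 & tot0 > 0
  na_tbl <- function(idx) tibble(
    locus_id = gm$loci$locus_id[idx], chrom = gm$loci$chrom[idx],
    pos = gm$loci$pos[idx],
    lnv_mean = NA_real_, lnv_var = NA_real_, logitc_mean = NA_real_,
    logitc_var = NA_real_, latent_cov = NA_real_, v_mean = NA_real_,
    v_lo95 = NA_real_, v_hi95 = NA_real_, c_mean = NA_real_,
    c_lo95 = NA_real_, c_hi95 = NA_real_, u = NA_real_,
    p_lnv = NA_real_, p_logitc = NA_real_, lppd = NA_real_,
    p_waic = NA_real_, waic = NA_real_, n_obs = NA_real_,
    ess_lnv = NA_real_, ess_logitc = NA_real_, accept_rate = NA_real_,
    flag = "monomorphic")

  keep_idx <- which(fit_mask)
  L <- length(keep_idx)
  if (L == 0) {
    est <- na_tbl(seq_len(L_all))
  } else {
    # observation rows: test individuals first, then source individuals.
    # Source rows get logit(h) = +/-Inf, which propagates to phi = 1 or 0
    # exactly for any v > 0, so their f is p1 or p0.
    K1t <- K1[, keep_idx, drop = FALSE]; K0t <- K0[, keep_idx, drop = FALSE]
    K1all <- rbind(K1t, KS1[, keep_idx, drop = FALSE])
    K0all <- rbind(K0t, KS0[, keep_idx, drop = FALSE])
    n_all <- nrow(K1all)
    LHall <- rbind(matrix(qlogis(h_test), n, L),
                   matrix(ifelse(h_src == 1, Inf, -Inf), length(h_src), L))
    test_rows <- seq_len(n)

    p0v <- fr$p0_mean[keep_idx]; p1v <- fr$p1_mean[keep_idx]
    # Beta pseudo-counts for the allele-frequency components: the oriented
    # source allele counts plus the Jeffreys prior
    a1 <- fr$k1[keep_idx] + 0.5; b1 <- fr$n1[keep_idx] - fr$k1[keep_idx] + 0.5
    a0 <- fr$k0[keep_idx] + 0.5; b0 <- fr$n0[keep_idx] - fr$k0[keep_idx] + 0.5
    k1tot <- colSums(K1t); k0tot <- colSums(K0t)

    set.seed(seed)
    n_keep <- nitt - burnin

    as_row_mat <- function(v) matrix(v, n_all, L, byrow = TRUE)
    loglik <- function(lnv, lc, P0, P1) {
      phi <- plogis((LHall - as_row_mat(lc)) * as_row_mat(exp(lnv)))
      f <- phi * P1 + (1 - phi) * P0
      list(ll = colSums(K1all * log(f) + K0all * log1p(-f)), f = f, phi = phi)
    }
    lprior <- function(lnv, lc) {
      -0.5 * lnv^2 / prior_var_v - 0.5 * lc^2 / prior_var_c
    }

    P0 <- as_row_mat(p0v); P1 <- as_row_mat(p1v)
    lnv <- rep(0, L); lc <- rep(0, L)
    cur <- loglik(lnv, lc, P0, P1)
    lp <- cur$ll + lprior(lnv, lc)
    Fcur <- cur$f; PHIcur <- cur$phi
    step <- rep(0.3, L)
    target <- if (fix_v) 0.44 else 0.30
    acc_batch <- numeric(L); acc_post <- numeric(L)

    dr_lnv <- matrix(0, n_keep, L); dr_lc <- matrix(0, n_keep, L)
    # WAIC accumulators over post-burn-in draws (exact: exp(log f) = f, so
    # predictive densities are posterior moments of f)
    sum_f <- matrix(0, n_all, L); sum_f2 <- matrix(0, n_all, L)
    sum_lf <- matrix(0, n_all, L); sum_lf2 <- matrix(0, n_all, L)
    sum_l1f <- matrix(0, n_all, L); sum_l1f2 <- matrix(0, n_all, L)
    sum_lfl1f <- matrix(0, n_all, L)

    for (it in seq_len(nitt)) {
      if (estimate_freqs) {
        # latent ancestry of each test allele copy given (v, c, p0, p1),
        # then conjugate Beta updates of the frequency components
        PHIt <- PHIcur[test_rows, , drop = FALSE]
        Ft <- Fcur[test_rows, , drop = FALSE]
        P1t <- P1[test_rows, , drop = FALSE]
        t1f <- colSums(matrix(
          rbinom(n * L, K1t, PHIt * P1t / Ft), n, L))
        t1n <- colSums(matrix(
          rbinom(n * L, K0t, PHIt * (1 - P1t) / (1 - Ft)), n, L))
        p1v <- pmin(pmax(rbeta(L, a1 + t1f, b1 + t1n), 1e-9), 1 - 1e-9)
        p0v <- pmin(pmax(rbeta(L, a0 + k1tot - t1f, b0 + k0tot - t1n),
                         1e-9), 1 - 1e-9)
        P0 <- as_row_mat(p0v); P1 <- as_row_mat(p1v)
        cur <- loglik(lnv, lc, P0, P1)
        lp <- cur$ll + lprior(lnv, lc)
        Fcur <- cur$f; PHIcur <- cur$phi
      }
      lnv_p <- if (fix_v) lnv else lnv + rnorm(L, 0, step)
      lc_p <- lc + rnorm(L, 0, step)
      cand <- loglik(lnv_p, lc_p, P0, P1)
      lp_p <- cand$ll + lprior(lnv_p, lc_p)
      acc <- log(runif(L)) < lp_p - lp
      if (any(acc)) {
        lnv[acc] <- lnv_p[acc]; lc[acc] <- lc_p[acc]; lp[acc] <- lp_p[acc]
        Fcur[, acc] <- cand$f[, acc]; PHIcur[, acc] <- cand$phi[, acc]
      }
      if (it <= burnin) {
        acc_batch <- acc_batch + acc
        if (it %% 25L == 0L) {
          step <- pmin(pmax(step * exp((acc_batch / 25 - target) * 0.5),
                            1e-3), 10)
          acc_batch <- numeric(L)
        }
      } else {
        s <- it - burnin
        acc_post <- acc_post + acc
        dr_lnv[s, ] <- lnv; dr_lc[s, ] <- lc
        lf <- log(Fcur); l1f <- log1p(-Fcur)
        sum_f <- sum_f + Fcur; sum_f2 <- sum_f2 + Fcur * Fcur
        sum_lf <- sum_lf + lf; sum_lf2 <- sum_lf2 + lf * lf
        sum_l1f <- sum_l1f + l1f; sum_l1f2 <- sum_l1f2 + l1f * l1f
        sum_lfl1f <- sum_lfl1f + lf * l1f
      }
    }

    # pointwise WAIC terms; p_waic_j is the draw variance of the pointwise
    # log-likelihood (denominator S - 1). With unit "copy" each allele copy
    # is an observation (lppd_j = log(mean f) or log(mean(1 - f))); with
    # unit "genotype" the two copies of an individual form one observation,
    # whose predictive density is a posterior moment of f (E[f^2],
    # E[f(1 - f)] or E[(1 - f)^2]) and whose log-likelihood variance uses
    # the covariance of log f and log(1 - f).
    S <- n_keep
    var_of <- function(sx, sx2) (sx2 - sx^2 / S) / (S - 1)
    cov_of <- function(sx, sy, sxy) (sxy - sx * sy / S) / (S - 1)
    if (waic_unit == "copy") {
      lppd <- colSums(K1all * log(sum_f / S) + K0all * log1p(-sum_f / S))
      p_waic <- colSums(K1all * var_of(sum_lf, sum_lf2) +
                          K0all * var_of(sum_l1f, sum_l1f2))
      n_obs <- colSums(K1all + K0all)
    } else {
      Ef <- sum_f / S; Ef2 <- sum_f2 / S
      used <- (K1all + K0all) > 0
      hom1 <- K1all == 2; het <- K1all == 1 & K0all == 1; hom0 <- K0all == 2
      dens <- hom1 * Ef2 + het * (Ef - Ef2) + hom0 * (1 - 2 * Ef + Ef2)
      dens[!used] <- 1  # log 0 contribution for unused cells
      lppd <- colSums(log(dens))
      p_waic <- colSums(K1all^2 * var_of(sum_lf, sum_lf2) +
                          K0all^2 * var_of(sum_l1f, sum_l1f2) +
                          2 * K1all * K0all *
                            cov_of(sum_lf, sum_l1f, sum_lfl1f))
      n_obs <- colSums(used)
    }

    v_dr <- exp(dr_lnv); c_dr <- plogis(dr_lc)
    lnv_mean <- colMeans(dr_lnv); lc_mean <- colMeans(dr_lc)
    lnv_var <- col_vars(dr_lnv)
    lc_var <- col_vars(dr_lc)
    lat_cov <- colMeans(dr_lnv * dr_lc) * S / (S - 1) -
      lnv_mean * lc_mean * S / (S - 1)
    qv <- apply(v_dr, 2L, quantile, probs = c(0.025, 0.975), names = FALSE)
    qc <- apply(c_dr, 2L, quantile, probs = c(0.025, 0.975), names = FALSE)
    pval <- function(m, v) 2 * pnorm(-abs(m) / pmax(sqrt(v), 1e-12))
    est_fit <- tibble(
      locus_id = gm$loci$locus_id[keep_idx],
      chrom = gm$loci$chrom[keep_idx], pos = gm$loci$pos[keep_idx],
      lnv_mean = lnv_mean, lnv_var = lnv_var,
      logitc_mean = lc_mean, logitc_var = lc_var, latent_cov = lat_cov,
      v_mean = colMeans(v_dr), v_lo95 = qv[1, ], v_hi95 = qv[2, ],
      c_mean = colMeans(c_dr), c_lo95 = qc[1, ], c_hi95 = qc[2, ],
      u = colMeans(v_dr * dr_lc),
      p_lnv = if (fix_v) NA_real_ else pval(lnv_mean, lnv_var),
      p_logitc = pval(lc_mean, lc_var),
      lppd = lppd, p_waic = p_waic, waic = -2 * (lppd - p_waic),
      n_obs = n_obs,
      ess_lnv = if (fix_v) NA_real_ else
        apply(dr_lnv, 2L, ess_autocorr),
      ess_logitc = apply(dr_lc, 2L, ess_autocorr),
      accept_rate = acc_post / n_keep, flag = "ok")
    est <- bind_rows(est_fit, na_tbl(which(!fit_mask)))
    est <- est[match(gm$loci$locus_id, est$locus_id), ]
  }

  out <- list(estimates = est,
              settings = list(nitt = nitt, burnin = burnin, seed = seed,
                              fix_v = fix_v, include_source = include_source,
                              prior_var_v = prior_var_v,
                              prior_var_c = prior_var_c))
  class(out) <- "cline_fit"
  out
}

# column variances with denominator S - 1 (no matrixStats dependency)
col_vars <- function(m) {
  S <- nrow(m)
  (colSums(m * m) - colSums(m)^2 / S) / (S - 1)
}

#' @export
print.cline_fit <- function(x, ...) {
  cat(sprintf("<cline_fit> %d loci (%s model; nitt = %d, burnin = %d)\n",
              nrow(x$estimates),
              if (x$settings$fix_v) "reduced, v = 1" else "full",
              x$settings$nitt, x$settings$burnin))
  print(x$estimates, n = 5)
  invisible(x)
}

#' @rdname fit_clines
#' @param x a `cline_fit`.
#' @param ... unused.
#' @method tidy cline_fit
#' @export
tidy.cline_fit <- function(x, ...) x$estimates

#' @rdname fit_clines
#' @method glance cline_fit
#' @export
glance.cline_fit <- function(x, ...) {
  ok <- x$estimates$flag == "ok"
  tibble(n_loci = nrow(x$estimates), n_flagged = sum(!ok),
         model = if (x$settings$fix_v) "reduced" else "full",
         nitt = x$settings$nitt, burnin = x$settings$burnin,
         seed = x$settings$seed,
         mean_accept = mean(x$estimates$accept_rate[ok]),
         min_ess = suppressWarnings(min(x$estimates$ess_logitc[ok])))
}

#' Plot per-locus cline steepness along the genome
#'
#' `ln v` posterior means against position, faceted by chromosome, with the
#' steep-cline threshold drawn for reference.
#'
#' @param object a `cline_fit`.
#' @param lnv_threshold reference line (default 2.3).
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot cline_fit
#' @export
autoplot.cline_fit <- function(object, lnv_threshold = 2.3, ...) {
  d <- dplyr::filter(object$estimates, .data$flag == "ok")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$pos / 1e6, y = .data$lnv_mean)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.7) +
    ggplot2::geom_hline(yintercept = lnv_threshold, linetype = 2,
                        colour = "firebrick") +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = "posterior mean ln(v)") +
    ggplot2::theme_minimal()
}
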