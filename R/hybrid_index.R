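#' Estimate genome-wide hybrid indices by MCMC
#'
#' Per-sample Bayesian estimation of the hybrid index `h` (0 = pure S0,
#' 1 = pure S1). Each non-missing allele copy at locus `l` is the focal
#' allele with probability `f = h * p1_l + (1 - h) * p0_l`, with the source
#' frequencies fixed at their posterior means (see
#' [estimate_source_freqs()]); the prior on `h` is Beta(`prior`). Sampling
#' is adaptive random-walk Metropolis on `logit(h)`, with proposal-scale
#' adaptation (targeting ~0.44 acceptance) confined to the burn-in so the
#' post-burn-in chain satisfies detailed balance. Chains are independent per
#' sample and reproducible given `(seed, sample_id)`.
#'
#' @param gm a [geno_matrix()] — use the re-oriented matrix returned by
#'   [estimate_source_freqs()].
#' @param freqs source-frequency tibble, typically after
#'   [filter_ci_overlap()]; only its loci are used.
#' @param assignments tibble (`sample_id`, `label`).
#' @param prior length-2 Beta prior on `h`; default uniform `c(1, 1)`.
#' @param nitt total iterations; `burnin` of them are discarded.
#' @param burnin burn-in iterations (`< nitt`).
#' @param seed integer seed.
#' @param include_source also estimate `h` for S0/S1 source samples.
#' @param resample_freqs redraw `p0`, `p1` from their Beta posteriors at
#'   every iteration instead of fixing them at posterior means (sensitivity
#'   analysis; default off).
#' @param keep_draws keep the post-burn-in draws (for [diagnose_chain()]).
#' @return a `hybrid_index_fit`: tibble via [tidy()] with columns
#'   `sample_id`, `label`, `h_mean`, `h_sd`, `h_lo95`, `h_hi95`, `ess`,
#'   `accept_rate`; settings via [glance()].
#' @export
esth <- function(gm, freqs, assignments, prior = c(1, 1), nitt = 2000,
                 burnin = 1000, seed = 1L, include_source = TRUE,
                 resample_freqs = FALSE, keep_draws = FALSE) {
  stopifnot(inherits(gm, "geno_matrix"))
  if (nitt <= burnin) abort("`nitt` must exceed `burnin`.")
  seed <- stopifnot_scalar_seed(seed)
  gm <- subset_loci(gm, freqs$locus_id)
  ord <- match(gm$loci$locus_id, freqs$locus_id)
  fr <- freqs[ord, ]
  if (nrow(fr) == 0) abort("no usable loci for hybrid-index estimation.")
  p0 <- fr$p0_mean; p1 <- fr$p1_mean
  a0 <- fr$k0 + 0.5; b0 <- fr$n0 - fr$k0 + 0.5
  a1 <- fr$k1 + 0.5; b1 <- fr$n1 - fr$k1 + 0.5

  todo <- assignments
  if (!include_source) todo <- todo[todo$label == "TEST", ]
  todo <- todo[todo$sample_id %in% rownames(gm$geno), ]

  theta_max <- qlogis(1 - 1e-6)
  lpa <- prior[1]; lpb <- prior[2]  # exponents on h, 1-h incl. Jacobian

  one_sample <- function(id) {
    g <- gm$geno[id, ]
    use <- !is.na(g)
    if (!any(use)) abort(paste0("sample ", id, " has zero usable loci."))
    k1 <- as.numeric(g[use]); k0 <- 2 - k1
    q0 <- p0[use]; q1 <- p1[use]
    loglik <- function(h, q0., q1.) {
      f <- h * q1. + (1 - h) * q0.
      sum(k1 * log(f) + k0 * log1p(-f))
    }
    set.seed((seed + sum(utf8ToInt(id))) %% 2147483647L)
    fbar <- sum(k1) / sum(k1 + k0)
    h0 <- (fbar - mean(q0)) / max(mean(q1) - mean(q0), 1e-3)
    theta <- qlogis(min(max(h0, 0.02), 0.98))
    h <- plogis(theta)
    lp <- loglik(h, q0, q1) + lpa * log(h) + lpb * log1p(-h)
    step <- 0.5
    n_keep <- nitt - burnin
    draws <- numeric(n_keep)
    acc_post <- 0L; acc_batch <- 0L
    for (it in seq_len(nitt)) {
      if (resample_freqs) {
        q0 <- rbeta(length(a0), a0, b0)[use]
        q1 <- rbeta(length(a1), a1, b1)[use]
        lp <- loglik(h, q0, q1) + lpa * log(h) + lpb * log1p(-h)
      }
      prop <- theta + rnorm(1, 0, step)
      prop <- min(max(prop, -theta_max), theta_max)
      hp <- plogis(prop)
      lp_prop <- loglik(hp, q0, q1) + lpa * log(hp) + lpb * log1p(-hp)
      if (log(runif(1)) < lp_prop - lp) {
        theta <- prop; h <- hp; lp <- lp_prop
        if (it > burnin) acc_post <- acc_post + 1L else acc_batch <- acc_batch + 1L
      }
      if (it <= burnin && it %% 25L == 0L) {
        step <- step * exp((acc_batch / 25 - 0.44) * 0.5)
        step <- min(max(step, 1e-3), 10)
        acc_batch <- 0L
      }
      if (it > burnin) draws[it - burnin] <- h
    }
    qs <- unname(quantile(draws, c(0.025, 0.975)))
    list(row = tibble(
      sample_id = id, h_mean = mean(draws), h_sd = sd(draws),
      h_lo95 = qs[1], h_hi95 = qs[2], ess = ess_autocorr(draws),
      accept_rate = acc_post / n_keep),
      draws = if (keep_draws) draws else NULL)
  }

  res <- purrr::map(todo$sample_id, one_sample)
  est <- bind_rows(purrr::map(res, "row")) %>%
    left_join(assignments, by = "sample_id") %>%
    select("sample_id", "label", dplyr::everything())
  out <- list(
    estimates = est,
    draws = if (keep_draws) setNames(purrr::map(res, "draws"), todo$sample_id),
    settings = list(nitt = nitt, burnin = burnin, seed = seed, prior = prior,
                    n_loci = nrow(fr), resample_freqs = resample_freqs))
  class(out) <- "hybrid_index_fit"
  out
}

#' @export
print.hybrid_index_fit <- function(x, ...) {
  cat(sprintf("<hybrid_index_fit> %d samples, %d loci (nitt = %d, burnin = %d)\n",
              nrow(x$estimates), x$settings$n_loci, x$settings$nitt,
              x$settings$burnin))
  print(x$estimates, n = 5)
  invisible(x)
}

#' @rdname esth
#' @param x a `hybrid_index_fit`.
#' @param ... unused.
#' @method tidy hybrid_index_fit
#' @export
tidy.hybrid_index_fit <- function(x, ...) x$estimates

#' @rdname esth
#' @method glance hybrid_index_fit
#' @export
glance.hybrid_index_fit <- function(x, ...) {
  tibble(n_samples = nrow(x$estimates), n_loci = x$settings$n_loci,
         nitt = x$settings$nitt, burnin = x$settings$burnin,
         seed = x$settings$seed, min_ess = min(x$estimates$ess),
         mean_accept = mean(x$estimates$accept_rate))
}

#' Plot hybrid-index estimates
#'
#' Samples ordered by posterior mean `h` with 95% credible intervals,
#' coloured by population label.
#'
#' @param object a `hybrid_index_fit`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot hybrid_index_fit
#' @export
autoplot.hybrid_index_fit <- function(object, ...) {
  d <- object$estimates %>%
    arrange(.data$h_mean) %>%
    mutate(rank = row_number())
  ggplot2::ggplot(d, ggplot2::aes(x = .data$rank, y = .data$h_mean,
                                  colour = .data$label)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$h_lo95,
                                          ymax = .data$h_hi95),
                             linewidth = 0.3, size = 0.2) +
    ggplot2::labs(x = "sample (ordered by h)", y = "hybrid index h",
                  colour = "group") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' MCMC chain diagnostics
#'
#' Autocorrelation-based effective sample size and a Geweke-style z-score
#' comparing the means of the first 10% and last 50% of the chain. A warning
#' flag is set when `ess < 100` or `|z| > 3`.
#'
#' @param draws numeric vector of at least 100 post-burn-in draws.
#' @return one-row tibble: `ess`, `geweke_z`, `warn`.
#' @export
diagnose_chain <- function(draws) {
  if (length(draws) < 100) abort("need >= 100 post-burn-in draws.")
  ess <- ess_autocorr(draws)
  z <- geweke_z(draws)
  tibble(ess = ess, geweke_z = z, warn = ess < 100 | abs(z) > 3)
}
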