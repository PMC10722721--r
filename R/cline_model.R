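#' Logit-logistic genomic cline function
#'
#' Probability that an allele copy carried by an individual with hybrid index
#' `h` is of S1 ancestry at a locus with cline steepness `v` and centre `c`:
#' \deqn{\phi(h; v, c) = \mathrm{logistic}\{ v (\mathrm{logit}(h) -
#' \mathrm{logit}(c)) \}.}
#'
#' `v = 1, c = 0.5` gives the neutral cline `phi = h`. `v > 1` steepens the
#' transition around the centre (restricted gene flow); a centre away from
#' 0.5 shifts which ancestry is favoured. The boundary values `phi(0) = 0`
#' and `phi(1) = 1` are returned exactly.
#'
#' @param h hybrid index, in `[0, 1]`; vectorised.
#' @param v cline steepness, `> 0`.
#' @param c cline centre, in `(0, 1)`.
#' @return numeric vector of S1-ancestry probabilities, same length as the
#'   longest argument.
#' @examples
#' cline_function(0.3, v = 1, c = 0.5)    # neutral cline: returns h
#' cline_function(0.5, v = 8, c = 0.5)    # at the centre phi = 0.5 for any v
#' @export
cline_function <- function(h, v, c) {
  if (any(v <= 0)) abort("`v` must be > 0.")
  if (any(c <= 0 | c >= 1)) abort("`c` must be in (0, 1).")
  if (any(h < 0 | h > 1, na.rm = TRUE)) abort("`h` must be in [0, 1].")
  out <- plogis(v * (qlogis(h) - qlogis(c)))
  # qlogis(0) = -Inf and qlogis(1) = Inf propagate to exact 0/1 under
  # finite v, but guard explicitly so v * Inf never yields NaN.
  out[h == 0] <- 0
  out[h == 1] <- 1
  out
}

#' Widely applicable information criterion from pointwise log-likelihood draws
#'
#' Computes `waic = -2 * (lppd - p_waic)` where `lppd` is the summed
#' log pointwise predictive density, `lppd = sum_j log( mean_s exp(ll_js) )`
#' (log-sum-exp stabilised), and the effective number of parameters
#' `p_waic = sum_j Var_s(ll_js)` uses the sample variance over draws
#' (denominator `S - 1`).
#'
#' @param ll matrix of pointwise log-likelihoods, observations in rows and
#'   posterior draws in columns (`n_obs x n_draws`, `n_draws >= 2`).
#' @param weights optional non-negative observation multiplicities (for
#'   collapsed duplicate observations); defaults to 1 per row.
#' @return a one-row tibble with columns `lppd`, `p_waic`, `waic`, `n_obs`,
#'   `n_draws`.
#' @export
compute_waic <- function(ll, weights = NULL) {
  ll <- as.matrix(ll)
  if (ncol(ll) < 2L) abort("`ll` needs at least 2 posterior draws.")
  if (any(!is.finite(ll))) abort("non-finite pointwise log-likelihoods.")
  w <- weights %||% rep(1, nrow(ll))
  if (length(w) != nrow(ll) || any(w < 0)) {
    abort("`weights` must be non-negative, one per observation row.")
  }
  lppd <- sum(w * row_log_mean_exp(ll))
  p_waic <- sum(w * row_var(ll))
  tibble(
    lppd = lppd, p_waic = p_waic, waic = -2 * (lppd - p_waic),
    n_obs = sum(w), n_draws = ncol(ll)
  )
}

#' Compare full and reduced cline models by WAIC
#'
#' `delta_waic = waic_full - waic_reduced`; negative values support the full
#' (free-steepness) model over the reduced neutral model with `v` fixed at 1.
#'
#' @param fit_full,fit_reduced `cline_fit` objects (see [fit_clines()]) on
#'   identical observation sets, or tibbles with columns `locus_id`, `waic`
#'   and `n_obs`.
#' @return tibble with one row per locus: `locus_id`, `waic_full`,
#'   `waic_reduced`, `delta_waic`.
#' @export
compare_models <- function(fit_full, fit_reduced) {
  tf <- if (inherits(fit_full, "cline_fit")) tidy(fit_full) else as_tibble(fit_full)
  tr <- if (inherits(fit_reduced, "cline_fit")) tidy(fit_reduced) else as_tibble(fit_reduced)
  joined <- dplyr::inner_join(
    dplyr::select(tf, "locus_id", waic_full = "waic", n_full = "n_obs"),
    dplyr::select(tr, "locus_id", waic_reduced = "waic", n_red = "n_obs"),
    by = "locus_id"
  )
  if (nrow(joined) != nrow(tf) || nrow(joined) != nrow(tr)) {
    abort("full and reduced fits cover different loci.")
  }
  if (any(joined$n_full != joined$n_red)) {
    abort("mismatched observation counts between full and reduced fits.")
  }
  joined %>%
    mutate(delta_waic = .data$waic_full - .data$waic_reduced) %>%
    select("locus_id", "waic_full", "waic_reduced", "delta_waic")
}
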