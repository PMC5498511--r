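#' MCMC sampler settings
#'
#' Chain controls and priors for the Bayes-B / Bayes-C Gibbs samplers.
#' Variance priors are scaled-inverse-chi-square; their scales are derived
#' from `prior_r2`, the prior expectation of the proportion of phenotypic
#' variance explained by markers: the residual scale targets
#' `(1 - prior_r2) * var(y)` and the marker-effect scale targets
#' `prior_r2 * var(y) / ((1 - pi) * sum_j var(x_j))`, each converted so the
#' prior mode sits at the target.
#'
#' @param n_iter total Gibbs iterations.
#' @param burn_in discarded initial iterations (`< n_iter`).
#' @param thin keep every `thin`-th post-burn-in draw.
#' @param seed integer seed (drives R's RNG, so chains are reproducible).
#' @param prior_df degrees of freedom of both variance priors (> 2).
#' @param prior_r2 prior marker-explained variance proportion in (0, 1).
#' @return a list of class `mcmc_settings`.
#' @export
mcmc_settings <- function(n_iter = 5000, burn_in = 1000, thin = 5,
                          seed = 1L, prior_df = 5, prior_r2 = 0.5) {
  stopifnot(thin >= 1, prior_df > 2, prior_r2 > 0, prior_r2 < 1)
  if (burn_in >= n_iter) stop("burn_in must be smaller than n_iter", call. = FALSE)
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), seed = as.integer(seed),
                 prior_df = prior_df, prior_r2 = prior_r2),
            class = "mcmc_settings")
}

#' Bayes-C whole-genome regression
#'
#' Single-site Gibbs sampler for the spike-and-slab mixture: each marker
#' effect is zero with probability `pi_zero` or drawn from a common
#' N(0, sigma_u^2) slab. The common marker variance and the residual
#' variance get scaled-inverse-chi-square full conditionals; inclusion
#' indicators are sampled from their marginal odds with the effect
#' integrated out. Reported effects are posterior means over post-burn-in
#' thinned draws, so predictions from them are posterior-mean genetic
#' values.
#'
#' @inheritParams fit_rrblup
#' @param settings an [mcmc_settings()].
#' @param pi_zero prior probability that a marker effect is exactly zero.
#' @param update_pi if `TRUE`, `pi_zero` is sampled under a Beta prior
#'   centred at `pi_prior_probin` inclusion probability with weight
#'   `pi_prior_counts`; if `FALSE` it stays fixed.
#' @param pi_prior_counts,pi_prior_probin Beta-prior parameters used when
#'   `update_pi = TRUE`.
#' @param fixed_variances optional list `list(marker, residual)` pinning
#'   both variance components (no variance updating); used for
#'   conjugate-oracle checks.
#' @return a `wgr_fit` (see [fit_rrblup()]) with `pi_zero`,
#'   posterior inclusion probabilities and sampler metadata filled in.
#' @export
fit_bayesC <- function(X, y, settings = mcmc_settings(), pi_zero = 0.95,
                       update_pi = TRUE, pi_prior_counts = 10,
                       pi_prior_probin = 0.5, fixed_variances = NULL) {
  fit_bayes_mixture(X, y, settings, pi_zero, update_pi, pi_prior_counts,
                    pi_prior_probin, fixed_variances,
                    locus_specific_variance = FALSE, update_scale = FALSE,
                    model = "bayesC")
}

#' Bayes-B whole-genome regression
#'
#' As [fit_bayesC()], but every included marker carries its own effect
#' variance with a scaled-inverse-chi-square prior (common scale), giving
#' a point-mass-at-zero plus scaled-t mixture. Loci excluded at an
#' iteration have their variance refreshed from the prior.
#'
#' @inheritParams fit_bayesC
#' @return a `wgr_fit`.
#' @export
fit_bayesB <- function(X, y, settings = mcmc_settings(), pi_zero = 0.95,
                       update_pi = TRUE, pi_prior_counts = 10,
                       pi_prior_probin = 0.5, fixed_variances = NULL,
                       update_scale = TRUE) {
  fit_bayes_mixture(X, y, settings, pi_zero, update_pi, pi_prior_counts,
                    pi_prior_probin, fixed_variances,
                    locus_specific_variance = TRUE,
                    update_scale = update_scale, model = "bayesB")
}

fit_bayes_mixture <- function(X, y, settings, pi_zero, update_pi,
                              pi_prior_counts, pi_prior_probin,
                              fixed_variances, locus_specific_variance,
                              update_scale, model) {
  stopifnot(inherits(settings, "mcmc_settings"),
            pi_zero >= 0, pi_zero <= 1)
  X <- as.matrix(X)
  if (nrow(X) != length(y)) stop("rows of X must match length of y", call. = FALSE)
  if (nrow(X) < 3) stop("need at least 3 training individuals", call. = FALSE)
  effects <- stats::setNames(numeric(ncol(X)),
                             colnames(X) %||% paste0("m", seq_len(ncol(X))))
  centers <- stats::setNames(colMeans(X), names(effects))
  keep <- which(matrixStats_colSds(X) > 0)
  if (stats::var(y) == 0) {
    warning("constant phenotype: returning zero effects", call. = FALSE)
    return(new_wgr_fit(model, intercept = y[1], effects = effects,
                       marker_variance = 0, residual_variance = 1e-12,
                       column_centers = centers, pi_zero = pi_zero))
  }
  if (length(keep) == 0) stop("no polymorphic column in X", call. = FALSE)
  if (length(keep) < ncol(X)) {
    warning(ncol(X) - length(keep),
            " monomorphic training column(s) dropped (zero effect)",
            call. = FALSE)
  }

  Z <- sweep(X[, keep, drop = FALSE], 2, centers[keep])
  yc <- y - mean(y)
  vy <- stats::var(y)
  sum_var_x <- sum(colSums(Z^2)) / (nrow(Z) - 1)
  # expected slab fraction: the prior inclusion probability when pi is
  # sampled, otherwise 1 - pi_zero
  slab_frac <- if (update_pi) pi_prior_probin else max(1 - pi_zero, 0.01)
  nu <- settings$prior_df
  if (is.null(fixed_variances)) {
    target_b <- settings$prior_r2 * vy / (slab_frac * sum_var_x)
    target_e <- (1 - settings$prior_r2) * vy
    Sb <- target_b * (nu + 2) / nu
    Se <- target_e * (nu + 2) / nu
    nub <- nu; nue <- nu
  } else {
    # pin variances by a degenerate prior (huge df): the full conditional
    # then sits at the fixed value
    Sb <- fixed_variances$marker
    Se <- fixed_variances$residual
    nub <- 1e9; nue <- 1e9
  }

  set.seed(settings$seed)
  res <- gibbs_bayes_mixture(Z, yc, settings$n_iter, settings$burn_in,
                             settings$thin, pi_zero, update_pi,
                             pi_prior_counts, pi_prior_probin,
                             nub, Sb, nue, Se, locus_specific_variance,
                             update_scale && is.null(fixed_variances), 1.1)
  effects[keep] <- res$effects
  pip <- stats::setNames(numeric(length(effects)), names(effects))
  pip[keep] <- res$inclusion_prob
  new_wgr_fit(model,
              intercept = mean(y) + res$intercept,
              effects = effects,
              marker_variance = res$marker_variance,
              residual_variance = res$residual_variance,
              column_centers = centers,
              pi_zero = res$pi_zero,
              inclusion_prob = pip,
              sampler_meta = list(n_iter = settings$n_iter,
                                  burn_in = settings$burn_in,
                                  thin = settings$thin,
                                  seed = settings$seed,
                                  prior_df = settings$prior_df,
                                  prior_r2 = settings$prior_r2,
                                  n_kept = res$n_kept,
                                  update_pi = update_pi))
}
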