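#' Sample QTL positions
#'
#' Draws `n_qtl` locus indices uniformly without replacement and returns
#' them sorted.
#'
#' @param panel a [genotype_panel()].
#' @param n_qtl number of causal loci, at most the panel's locus count.
#' @param seed integer seed.
#' @return sorted integer vector of locus indices.
#' @export
sample_qtl <- function(panel, n_qtl, seed = 1L) {
  L <- ncol(panel$dosages)
  if (n_qtl < 1 || n_qtl > L) {
    stop("n_qtl must be between 1 and the number of loci (", L, ")",
         call. = FALSE)
  }
  set.seed(seed)
  sort(sample.int(L, n_qtl))
}

#' Sample additive QTL effect sizes
#'
#' `standard_normal` draws effects from N(0, 1). `gamma_signed` draws
#' magnitudes from Gamma(shape = 0.4, scale = 1.66) with a random sign, a
#' conventional heavy-tailed alternative in genomic-selection simulation.
#'
#' @param n_qtl number of effects.
#' @param distribution `"standard_normal"` or `"gamma_signed"`.
#' @param seed integer seed.
#' @return numeric vector of allele-substitution effects (trait units per
#'   dosage unit).
#' @export
sample_effects <- function(n_qtl,
                           distribution = c("standard_normal", "gamma_signed"),
                           seed = 1L) {
  distribution <- match.arg(distribution)
  if (n_qtl == 0) return(numeric(0))
  set.seed(seed)
  switch(distribution,
         standard_normal = stats::rnorm(n_qtl),
         gamma_signed = stats::rgamma(n_qtl, shape = 0.4, scale = 1.66) *
           sample(c(-1, 1), n_qtl, replace = TRUE))
}

#' Sample a QTL architecture
#'
#' Combines [sample_qtl()] and [sample_effects()] into a tidy architecture
#' table.
#'
#' @inheritParams sample_qtl
#' @inheritParams sample_effects
#' @return a tibble of class `qtl_architecture` with columns `qtl_index`,
#'   `locus_id`, `effect`; the distribution and seed are kept as
#'   attributes.
#' @export
sample_architecture <- function(panel, n_qtl,
                                distribution = c("standard_normal", "gamma_signed"),
                                seed = 1L) {
  distribution <- match.arg(distribution)
  idx <- sample_qtl(panel, n_qtl, seed = seed)
  eff <- sample_effects(n_qtl, distribution, seed = seed + 1L)
  out <- tibble::tibble(qtl_index = idx,
                        locus_id = panel$loci$locus_id[idx],
                        effect = eff)
  structure(out, class = c("qtl_architecture", class(out)),
            distribution = distribution, seed = seed)
}

#' Simulate an additive quantitative trait
#'
#' True genetic values are `g = Zc %*% effects` where `Zc` is the
#' column-centered QTL dosage submatrix. The residual variance is set from
#' the realised `var(g)` so that the nominal heritability is exact
#' in-sample: `sigma_e^2 = var(g) (1 - h2) / h2`. Residuals are i.i.d.
#' normal and phenotypes are `y = g + e` (for `h2 = 1`, `e = 0`).
#'
#' @param panel a [genotype_panel()].
#' @param arch a [sample_architecture()] table (or any data frame with
#'   `qtl_index` and `effect` columns).
#' @param h2 nominal heritability in `(0, 1]`.
#' @param seed integer seed for the residual draw.
#' @return a tibble of class `simulated_trait` with columns
#'   `individual_id`, `g`, `e`, `y`; `h2_nominal` and `residual_variance`
#'   are attributes.
#' @export
simulate_trait <- function(panel, arch, h2, seed = 1L) {
  stopifnot(h2 > 0, h2 <= 1)
  idx <- arch$qtl_index
  if (anyDuplicated(idx) || any(idx < 1 | idx > ncol(panel$dosages))) {
    stop("architecture indices must be unique and within panel bounds",
         call. = FALSE)
  }
  Z <- panel$dosages[, idx, drop = FALSE]
  Zc <- sweep(Z, 2, colMeans(Z))
  g <- drop(Zc %*% arch$effect)
  vg <- stats::var(g)
  if (vg == 0) {
    stop("genetic variance is zero (all QTL monomorphic?)", call. = FALSE)
  }
  if (h2 == 1) {
    e <- rep(0, length(g))
    ve <- 0
  } else {
    ve <- vg * (1 - h2) / h2
    set.seed(seed)
    e <- stats::rnorm(length(g), 0, sqrt(ve))
  }
  out <- tibble::tibble(individual_id = rownames(panel$dosages),
                        g = g, e = e, y = g + e)
  structure(out, class = c("simulated_trait", class(out)),
            h2_nominal = h2, residual_variance = ve, seed = seed)
}
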