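#' Ridge-regression BLUP of marker effects
#'
#' Fits the whole-genome regression `y = 1*mu + Z u + e` with
#' `u ~ N(0, I sigma_u^2)` and `e ~ N(0, I sigma_e^2)`. `Z` is the
#' column-centered dosage matrix. The two variance components are
#' estimated by REML through a single spectral decomposition of the
#' `Z Z'` kernel and a one-dimensional optimisation in the variance ratio
#' `lambda = sigma_e^2 / sigma_u^2`; effects are then recovered as
#' `u = Z' (Z Z' + lambda I)^{-1} (y - mu)`. This is the GBLUP model in its
#' marker-effect parameterisation: predictions are identical to those from
#' the genomic-relationship-kernel formulation.
#'
#' Columns that are monomorphic in the training data carry no information
#' and are dropped from the fit with a warning; they are reported with a
#' zero effect.
#'
#' @param X training dosage matrix (individuals x loci, named columns).
#' @param y training phenotypes, one per row of `X`.
#' @param lambda optional fixed variance ratio; skips REML (useful for
#'   pure ridge regression at a known shrinkage).
#' @return an object of classes `wgr_rrblup`, `wgr_fit`: a list with the
#'   intercept, per-locus `effects`, `marker_variance`,
#'   `residual_variance`, `lambda`, and the `column_centers` used.
#' @export
fit_rrblup <- function(X, y, lambda = NULL) {
  X <- as.matrix(X)
  if (nrow(X) != length(y)) stop("rows of X must match length of y", call. = FALSE)
  if (nrow(X) < 3) stop("need at least 3 training individuals", call. = FALSE)
  keep <- which(matrixStats_colSds(X) > 0)
  effects <- stats::setNames(numeric(ncol(X)),
                             colnames(X) %||% paste0("m", seq_len(ncol(X))))
  centers <- stats::setNames(colMeans(X), names(effects))
  if (length(keep) < ncol(X)) {
    warning(ncol(X) - length(keep),
            " monomorphic training column(s) dropped (zero effect)",
            call. = FALSE)
  }
  if (stats::var(y) == 0) {
    warning("constant phenotype: returning zero effects", call. = FALSE)
    return(new_wgr_fit("rrblup", intercept = y[1], effects = effects,
                       marker_variance = 0, residual_variance = 1e-12,
                       lambda = Inf, column_centers = centers))
  }
  if (length(keep) == 0) stop("no polymorphic column in X", call. = FALSE)

  Z <- sweep(X[, keep, drop = FALSE], 2, centers[keep])
  n <- nrow(Z)
  K <- tcrossprod(Z)
  eK <- eigen(K, symmetric = TRUE)
  d <- pmax(eK$values, 0)
  U <- eK$vectors

  if (is.null(lambda)) {
    # REML on the intercept-projected kernel (EMMA-style). Column
    # centering puts the 1-vector in K's null space, so the projected
    # kernel equals K; the rotated centered phenotype has no component
    # along the intercept direction, and exactly one zero eigenvalue is
    # dropped from the log-determinant.
    yc <- y - mean(y)
    eta <- drop(crossprod(U, yc))
    ll <- function(log10_lam) {
      lam <- 10^log10_lam
      su2 <- sum(eta^2 / (d + lam)) / (n - 1)
      -0.5 * ((n - 1) * log(su2) + sum(log(d + lam)) - log(lam))
    }
    opt <- stats::optimize(ll, interval = c(-8, 8), maximum = TRUE)
    lambda <- 10^opt$maximum
    marker_variance <- sum(eta^2 / (d + lambda)) / (n - 1)
    residual_variance <- marker_variance * lambda
  } else {
    marker_variance <- NA_real_
    residual_variance <- NA_real_
  }

  # GLS intercept and BLUP effects at the chosen lambda
  w <- 1 / (d + lambda)
  U1 <- drop(crossprod(U, rep(1, n)))
  Uy <- drop(crossprod(U, y))
  mu <- sum(U1 * w * Uy) / sum(U1 * w * U1)
  alpha <- U %*% (w * drop(crossprod(U, y - mu)))
  effects[keep] <- drop(crossprod(Z, alpha))
  new_wgr_fit("rrblup", intercept = mu, effects = effects,
              marker_variance = marker_variance,
              residual_variance = residual_variance,
              lambda = lambda, column_centers = centers)
}

matrixStats_colSds <- function(X) {
  apply(X, 2, stats::sd)
}

new_wgr_fit <- function(model, intercept, effects, marker_variance,
                        residual_variance, lambda = NA_real_,
                        column_centers, pi_zero = NA_real_,
                        inclusion_prob = NULL, sampler_meta = NULL) {
  structure(
    list(model = model, intercept = unname(intercept), effects = effects,
         marker_variance = marker_variance,
         residual_variance = residual_variance, lambda = lambda,
         pi_zero = pi_zero, inclusion_prob = inclusion_prob,
         column_centers = column_centers, sampler_meta = sampler_meta),
    class = c(paste0("wgr_", model), "wgr_fit")
  )
}

#' @export
print.wgr_fit <- function(x, ...) {
  cat("<wgr_fit> model:", x$model, "|", length(x$effects), "loci\n")
  cat("  intercept:", signif(x$intercept, 4),
      " marker var:", signif(x$marker_variance, 4),
      " residual var:", signif(x$residual_variance, 4), "\n")
  if (!is.na(x$pi_zero)) cat("  pi_zero:", signif(x$pi_zero, 4), "\n")
  invisible(x)
}

#' Predict genetic values from a fitted whole-genome regression
#'
#' Computes `g_hat = (X_new - column_centers) %*% effects`: centering uses
#' the training-column means and the intercept is excluded, so predictions
#' are genetic values on the training-centered scale.
#'
#' @param object a `wgr_fit`.
#' @param newdata dosage matrix whose columns cover the fitted loci (by
#'   name when both are named).
#' @param ... unused.
#' @return numeric vector of predicted genetic values.
#' @export
predict.wgr_fit <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  nm <- names(object$effects)
  if (!is.null(colnames(X)) && !is.null(nm)) {
    missing <- setdiff(nm, colnames(X))
    if (length(missing) > 0) {
      stop("newdata lacks fitted loci: ",
           paste(utils::head(missing, 5), collapse = ", "),
           if (length(missing) > 5) " ...", call. = FALSE)
    }
    X <- X[, nm, drop = FALSE]
  } else if (ncol(X) != length(object$effects)) {
    stop("newdata has ", ncol(X), " columns; fit has ",
         length(object$effects), call. = FALSE)
  }
  drop(sweep(X, 2, object$column_centers) %*% object$effects)
}

#' Validation-set prediction accuracy
#'
#' Pearson correlation between predicted and true values.
#'
#' @param predicted,truth numeric vectors of equal length (>= 3), both
#'   non-constant.
#' @return the correlation coefficient.
#' @export
accuracy <- function(predicted, truth) {
  stopifnot(length(predicted) == length(truth), length(predicted) >= 3)
  if (stats::sd(predicted) == 0 || stats::sd(truth) == 0) {
    stop("accuracy undefined for constant input", call. = FALSE)
  }
  stats::cor(predicted, truth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
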