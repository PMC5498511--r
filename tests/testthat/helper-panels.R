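# small deterministic panels built in code for unit tests

# inbred panel from an explicit 0/2 dosage matrix
toy_panel <- function(dosages, ids = NULL) {
  dosages <- as.matrix(dosages)
  colnames(dosages) <- ids %||% sprintf("Chr01_%d", seq_len(ncol(dosages)) * 100)
  rownames(dosages) <- sprintf("ind_%02d", seq_len(nrow(dosages)))
  genotype_panel(dosages)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random inbred panel with independent loci (known Me = L oracle regime)
independent_panel <- function(n, L, seed = 1, p_range = c(0.1, 0.9)) {
  set.seed(seed)
  p <- runif(L, p_range[1], p_range[2])
  d <- matrix(rbinom(n * L, 1, rep(p, each = n)) * 2, n, L)
  toy_panel(d)
}

# brute-force r2 between two columns, independent of ld_r2
brute_r2 <- function(x, y) {
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  num <- sum((x - mx) * (y - my))^2
  den <- sum((x - mx)^2) * sum((y - my)^2)
  num / den
}

quick_mcmc <- function(n_iter = 800, burn_in = 200, seed = 1) {
  mcmc_settings(n_iter = n_iter, burn_in = burn_in, thin = 2, seed = seed)
}
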