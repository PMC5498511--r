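#' Configuration for the haplotype-mosaic genotype simulator
#'
#' The simulator emulates a large inbred (selfing) diversity panel with a
#' two-level haplotype-mosaic model. A handful of ancestral haplotypes
#' carry a U-shaped allele-frequency spectrum; founder haplotypes are
#' blockwise mosaics of the ancestors (block switches at rate
#' `founder_block_rate` per locus, plus rare `mutation_rate` flips), so
#' loci within an ancestral block segregate as a few distinct haplotype
#' patterns — strong local LD — while loci in different blocks are nearly
#' independent. Each individual is then a hidden-Markov mosaic of founder
#' templates (switch probability `switch_rate` per locus step), and
#' subpopulations bias which founders an individual copies from,
#' creating genome-wide structure.
#'
#' Defaults are calibrated so that a full-size panel (800 individuals,
#' 20,000 retained loci) behaves like a soybean diversity extract:
#' inbred 0/2 coding, MAF >= 0.05 after filtering, an effective segment
#' number ([estimate_effective_segments()]) in the low hundreds, and
#' near-independence of randomly drawn (unlinked) loci.
#'
#' @param n_individuals number of individuals (default 800).
#' @param n_loci number of loci retained after MAF filtering.
#' @param n_founder_haplotypes number of founder templates (>= 2).
#' @param n_ancestral_haplotypes number of deep ancestral haplotypes the
#'   founders are mosaics of; sets how many distinct patterns segregate
#'   within a haplotype block.
#' @param founder_block_rate per-locus probability that a founder switches
#'   ancestral template; its inverse is the typical haplotype-block length
#'   in loci.
#' @param mutation_rate per-locus probability that a founder's allele is
#'   flipped relative to its ancestral template.
#' @param switch_rate per-locus probability of switching founder template.
#' @param n_subpopulations number of subpopulations.
#' @param structure_strength fraction of founders private to a
#'   subpopulation (0 = panmictic, 1 = fully private founder pools).
#' @param maf_min minor-allele-frequency threshold in `[0, 0.5)`; loci with
#'   MAF strictly below it are discarded (boundary retained).
#' @param n_chromosomes number of chromosomes loci are spread over.
#' @param inbred if `TRUE` (default) one haplotype per individual is
#'   doubled, giving 0/2 dosages; otherwise two independent mosaics are
#'   summed.
#' @param seed integer seed; fixed seed gives bit-identical panels.
#' @return a list of class `generator_config`.
#' @export
generator_config <- function(n_individuals = 800,
                             n_loci = 20000,
                             n_founder_haplotypes = 64,
                             n_ancestral_haplotypes = 2,
                             founder_block_rate = 0.005,
                             mutation_rate = 0.003,
                             switch_rate = 0.0005,
                             n_subpopulations = 4,
                             structure_strength = 0.1,
                             maf_min = 0.05,
                             n_chromosomes = 20,
                             inbred = TRUE,
                             seed = 1L) {
  cfg <- list(
    n_individuals = as.integer(n_individuals),
    n_loci = as.integer(n_loci),
    n_founder_haplotypes = as.integer(n_founder_haplotypes),
    n_ancestral_haplotypes = as.integer(n_ancestral_haplotypes),
    founder_block_rate = founder_block_rate,
    mutation_rate = mutation_rate,
    switch_rate = switch_rate,
    n_subpopulations = as.integer(n_subpopulations),
    structure_strength = structure_strength,
    maf_min = maf_min,
    n_chromosomes = as.integer(n_chromosomes),
    inbred = isTRUE(inbred),
    seed = as.integer(seed)
  )
  with(cfg, {
    stopifnot(
      n_individuals > 0, n_loci > 0, n_chromosomes > 0,
      switch_rate >= 0, switch_rate <= 1,
      founder_block_rate >= 0, founder_block_rate <= 1,
      mutation_rate >= 0, mutation_rate < 0.5,
      n_ancestral_haplotypes >= 2,
      maf_min >= 0, maf_min < 0.5,
      structure_strength >= 0, structure_strength <= 1,
      n_subpopulations >= 1
    )
  })
  if (cfg$n_founder_haplotypes < 2) {
    stop("n_founder_haplotypes must be at least 2", call. = FALSE)
  }
  structure(cfg, class = "generator_config")
}

#' Simulate a genotype panel
#'
#' Draws founder haplotypes from a U-shaped (Beta(1/2, 1/2)) allele
#' frequency spectrum truncated at `maf_min`, builds each individual as a
#' founder-template mosaic (per-locus switch probability `switch_rate`,
#' templates restarted at chromosome boundaries), doubles one haplotype if
#' inbred, and MAF-filters the result. Oversampled loci are generated so
#' that exactly `n_loci` loci survive filtering; the retained loci are an
#' evenly spaced subset, preserving genome coverage.
#'
#' @param config a [generator_config()].
#' @return a [genotype_panel()] with `n_loci` loci, all at MAF >=
#'   `maf_min`.
#' @export
generate_panel <- function(config = generator_config()) {
  if (!inherits(config, "generator_config")) {
    config <- do.call(generator_config, config)
  }
  set.seed(config$seed)
  margin <- if (config$n_ancestral_haplotypes == 2) 3.5 else 1.4
  for (attempt in 1:4) {
    panel <- generate_panel_once(config, ceiling(config$n_loci * margin))
    got <- ncol(panel$dosages)
    if (got >= config$n_loci) {
      keep <- unique(round(seq(1, got, length.out = config$n_loci)))
      return(subset_loci(panel, keep))
    }
    # grow the oversampling margin in proportion to the observed shortfall
    margin <- margin * min(4, max(1.5, 1.3 * config$n_loci / max(got, 1)))
  }
  stop("could not generate ", config$n_loci, " loci at MAF >= ",
       config$maf_min, " after repeated oversampling (last attempt kept ",
       ncol(panel$dosages), ")", call. = FALSE)
}

generate_panel_once <- function(cfg, L) {
  n <- cfg$n_individuals
  nf <- cfg$n_founder_haplotypes
  na <- cfg$n_ancestral_haplotypes

  chrom_of <- sort(rep_len(seq_len(cfg$n_chromosomes), L))
  chrom_start <- !duplicated(chrom_of)

  # ancestral haplotypes: truncated U-shaped allele-frequency spectrum
  lo <- stats::pbeta(cfg$maf_min, 0.5, 0.5)
  hi <- stats::pbeta(1 - cfg$maf_min, 0.5, 0.5)
  p <- stats::qbeta(stats::runif(L, lo, hi), 0.5, 0.5)
  ancestors <- matrix(stats::rbinom(na * L, 1, rep(p, each = na)), nrow = na)

  # founders: blockwise mosaics of the ancestors plus rare mutations.
  # Block boundaries (recombination hotspots) are shared by all founders,
  # so inside a block the founders collapse to at most n_ancestral
  # haplotype patterns — strong within-block LD with near-perfect marker
  # proxies, as in real diversity panels — while templates reshuffle
  # independently across blocks.
  boundary <- stats::runif(L) < cfg$founder_block_rate
  boundary[chrom_start] <- TRUE
  block <- cumsum(boundary)
  n_blocks <- block[L]
  founders <- matrix(0L, nf, L)
  for (f in seq_len(nf)) {
    a <- sample.int(na, n_blocks, replace = TRUE)
    hap <- ancestors[cbind(a[block], seq_len(L))]
    mut <- stats::runif(L) < cfg$mutation_rate
    founders[f, ] <- ifelse(mut, 1L - hap, hap)
  }

  # founder pools: a structure_strength fraction is private per subpopulation
  n_private <- floor(cfg$structure_strength * nf / cfg$n_subpopulations) *
    cfg$n_subpopulations
  pools <- lapply(seq_len(cfg$n_subpopulations), function(k) {
    shared <- if (n_private < nf) (n_private + 1):nf else integer(0)
    private <- if (n_private > 0) {
      per <- n_private / cfg$n_subpopulations
      ((k - 1) * per + 1):(k * per)
    } else integer(0)
    c(private, shared)
  })
  subpop <- rep_len(seq_len(cfg$n_subpopulations), n)

  n_hap <- if (cfg$inbred) 1L else 2L
  dos <- matrix(0, n, L)
  for (i in seq_len(n)) {
    pool <- pools[[subpop[i]]]
    for (h in seq_len(n_hap)) {
      sw <- stats::runif(L) < cfg$switch_rate
      sw[chrom_start] <- TRUE
      seg <- cumsum(sw)
      f <- pool[sample.int(length(pool), seg[L], replace = TRUE)]
      hap <- founders[cbind(f[seg], seq_len(L))]
      dos[i, ] <- dos[i, ] + hap
    }
  }
  if (cfg$inbred) dos <- 2 * dos

  # per-chromosome strictly increasing positions
  pos <- integer(L)
  for (c_i in seq_len(cfg$n_chromosomes)) {
    idx <- which(chrom_of == c_i)
    pos[idx] <- sort(sample.int(5e7, length(idx)))
  }
  loci <- tibble::tibble(
    locus_id = sprintf("Chr%02d_%d", chrom_of, pos),
    chrom = sprintf("Chr%02d", chrom_of),
    pos = pos
  )
  panel <- genotype_panel(dos, loci, inbred = cfg$inbred)
  maf <- locus_maf(panel)
  keep <- which(maf >= cfg$maf_min - 1e-9)
  subset_loci(panel, keep)
}

#' Effective number of independent chromosome segments
#'
#' Computes `Me = 1 / var(offdiag(G))` where `G` is the centered-and-scaled
#' genomic relationship matrix. This is a standard approximation to the
#' effective number of independently segregating segments, the quantity
#' that governs genome-wide prediction accuracy; it is used here to
#' calibrate the simulator against real diversity panels.
#'
#' @param panel a [genotype_panel()] with at least 2 individuals and 2
#'   polymorphic loci.
#' @return a single positive number.
#' @export
estimate_effective_segments <- function(panel) {
  d <- panel$dosages
  if (nrow(d) < 2 || ncol(d) < 2) {
    stop("need at least 2 individuals and 2 loci", call. = FALSE)
  }
  sds <- apply(d, 2, stats::sd)
  use <- sds > 0
  if (sum(use) < 2) stop("fewer than 2 polymorphic loci", call. = FALSE)
  Z <- scale(d[, use, drop = FALSE])
  G <- tcrossprod(Z) / sum(use)
  off <- G[lower.tri(G)]
  v <- stats::var(off)
  if (v == 0) {
    stop("off-diagonal relationship variance is zero (identical individuals?)",
         call. = FALSE)
  }
  1 / v
}
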