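#' Squared-correlation linkage disequilibrium between two loci
#'
#' Composite r-squared: the squared Pearson product-moment correlation of
#' the two dosage vectors. For fully inbred lines this equals the
#' haplotype r-squared.
#'
#' @param x,y dosage vectors of equal length (>= 2), both polymorphic.
#' @return a value in `[0, 1]`.
#' @export
ld_r2 <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("r2 undefined for a monomorphic locus", call. = FALSE)
  }
  stats::cor(x, y)^2
}

# r2 of each QTL column against every locus; monomorphic candidates get NA.
# One standardized crossproduct, so the genome-wide HLD scan is a single
# BLAS call.
r2_matrix <- function(panel, qtl_indices) {
  d <- panel$dosages
  n <- nrow(d)
  sds <- apply(d, 2, stats::sd)
  Z <- sweep(d, 2, colMeans(d))
  Z[, sds > 0] <- sweep(Z[, sds > 0, drop = FALSE], 2, sds[sds > 0], "/")
  r <- crossprod(Z[, qtl_indices, drop = FALSE], Z) / (n - 1)
  r[, sds == 0] <- NA_real_
  r2 <- r^2
  rownames(r2) <- panel$loci$locus_id[qtl_indices]
  r2
}

#' Highest-LD marker for a QTL
#'
#' Returns the index of the non-excluded locus with the largest r-squared
#' to the QTL column; ties break to the lowest locus index.
#'
#' @param panel a [genotype_panel()].
#' @param qtl_index locus index of the QTL.
#' @param excluded integer indices ineligible as markers (the QTL itself is
#'   always excluded).
#' @return a single locus index.
#' @export
hld_for_qtl <- function(panel, qtl_index, excluded = integer(0)) {
  r2 <- drop(r2_matrix(panel, qtl_index))
  r2[c(qtl_index, excluded)] <- NA_real_
  if (all(is.na(r2))) stop("no polymorphic candidate marker", call. = FALSE)
  unname(which.max(r2))
}

#' Top-k markers by LD with a QTL
#'
#' The `k` eligible loci with largest r-squared, in descending r-squared
#' order (ties to the lower index). Returns fewer than `k`, with a
#' warning, when candidates run out.
#'
#' @inheritParams hld_for_qtl
#' @param k number of markers requested.
#' @return integer vector of locus indices, length at most `k`.
#' @export
top_k_r2 <- function(panel, qtl_index, k, excluded = integer(0)) {
  stopifnot(k >= 1)
  r2 <- drop(r2_matrix(panel, qtl_index))
  r2[c(qtl_index, excluded)] <- NA_real_
  ok <- which(!is.na(r2))
  if (length(ok) == 0) stop("no polymorphic candidate marker", call. = FALSE)
  if (length(ok) < k) {
    warning("only ", length(ok), " candidates available for k = ", k,
            call. = FALSE)
  }
  ord <- unname(ok[order(-r2[ok], ok)])
  utils::head(ord, k)
}

#' Build an LD-defined marker panel
#'
#' The seven panel rules (q = number of QTL):
#' * `mp1` — the QTL themselves (ideal functional markers).
#' * `mp2` — QTL plus, per QTL, its highest-LD (HLD) marker.
#' * `mp3` — all genome-wide loci, QTL included.
#' * `mp4` — per QTL, its HLD marker; QTL excluded from candidacy.
#' * `mp5` — all loci minus the QTL.
#' * `mp6` — per QTL, 2 markers drawn uniformly from its top-20 LD loci
#'   (QTL excluded from candidacy).
#' * `mp7` — `mp6` plus q random loci outside QTL and mp6 (random markers
#'   each falsely standing in for a QTL).
#'
#' A marker may be selected for several QTL; the panel is a set, so
#' duplicates collapse and the realised size is reported by the row count.
#' LD is computed on the full panel supplied (construct panels before any
#' train/validation split, or pass the training subset for a
#' training-only variant).
#'
#' @param kind one of `"mp1"` ... `"mp7"`.
#' @param arch a [sample_architecture()] table.
#' @param panel a [genotype_panel()].
#' @param seed integer seed for the random draws in mp6/mp7.
#' @param top_k size of the high-LD candidate list for mp6 (loci, not
#'   distinct r-squared values).
#' @return a tibble of class `marker_panel` with columns `locus_index`,
#'   `locus_id`, `provenance` (one of QTL, HLD, HLDr2, rSNP, genome_wide),
#'   sorted by locus index; panel `name` and `seed` kept as attributes.
#' @export
build_panel <- function(kind, arch, panel, seed = 1L, top_k = 20L) {
  build_panels(kind, arch, panel, seed = seed, top_k = top_k)[[1]]
}

#' Build several marker panels sharing one LD scan
#'
#' Equivalent to calling [build_panel()] per kind, but the QTL-by-genome
#' r-squared matrix is computed once and reused, which matters when panels
#' are rebuilt per replicate on large genotype matrices.
#'
#' @inheritParams build_panel
#' @param kinds character vector of panel kinds.
#' @return a named list of `marker_panel` tibbles.
#' @export
build_panels <- function(kinds, arch, panel, seed = 1L, top_k = 20L) {
  kinds <- vapply(kinds, function(k) match.arg(k, paste0("mp", 1:7)), "")
  qtl <- arch$qtl_index
  L <- ncol(panel$dosages)
  r2m <- if (any(kinds %in% c("mp2", "mp4", "mp6", "mp7"))) {
    r2_matrix(panel, qtl)
  }
  out <- lapply(kinds, function(kind) {
    sel <- switch(
      kind,
      mp1 = tibble::tibble(locus_index = qtl, provenance = "QTL"),
      mp2 = {
        hld <- hld_all(r2m, qtl, exclude_qtl = FALSE)
        tibble::tibble(locus_index = c(qtl, hld),
                       provenance = rep(c("QTL", "HLD"), c(length(qtl), length(hld))))
      },
      mp3 = tibble::tibble(locus_index = seq_len(L),
                           provenance = ifelse(seq_len(L) %in% qtl, "QTL", "genome_wide")),
      mp4 = tibble::tibble(locus_index = hld_all(r2m, qtl, exclude_qtl = TRUE),
                           provenance = "HLD"),
      mp5 = tibble::tibble(locus_index = setdiff(seq_len(L), qtl),
                           provenance = "genome_wide"),
      mp6 = build_mp6(r2m, qtl, seed, top_k),
      mp7 = {
        mp6 <- build_mp6(r2m, qtl, seed, top_k)
        set.seed(seed + 1L)
        pool <- setdiff(seq_len(L), c(qtl, mp6$locus_index))
        rsnp <- sort(pool[sample.int(length(pool), min(length(qtl), length(pool)))])
        dplyr::bind_rows(mp6, tibble::tibble(locus_index = rsnp, provenance = "rSNP"))
      }
    )
    sel <- sel |>
      dplyr::distinct(.data$locus_index, .keep_all = TRUE) |>
      dplyr::arrange(.data$locus_index) |>
      dplyr::mutate(locus_id = panel$loci$locus_id[.data$locus_index],
                    .after = "locus_index")
    structure(sel, class = c("marker_panel", class(sel)),
              name = kind, seed = seed)
  })
  stats::setNames(out, kinds)
}

# batched HLD search on a precomputed r2 matrix; which.max ties resolve to
# the lowest index, matching hld_for_qtl
hld_all <- function(r2m, qtl, exclude_qtl) {
  if (exclude_qtl) r2m[, qtl] <- NA_real_ else r2m[cbind(seq_along(qtl), qtl)] <- NA_real_
  r2m[is.na(r2m)] <- -Inf
  unname(apply(r2m, 1, which.max))
}

build_mp6 <- function(r2m, qtl, seed, top_k) {
  r2m[, qtl] <- NA_real_
  set.seed(seed)
  picks <- lapply(seq_along(qtl), function(i) {
    ri <- r2m[i, ]
    ok <- unname(which(!is.na(ri)))
    top <- ok[order(-ri[ok], ok)][seq_len(min(top_k, length(ok)))]
    top[sample.int(length(top), min(2L, length(top)))]
  })
  tibble::tibble(locus_index = unlist(picks), provenance = "HLDr2")
}
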