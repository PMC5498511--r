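#' Filter loci by minor-allele frequency
#'
#' Removes loci whose MAF (computed from non-missing dosages) is strictly
#' below `min_maf`; a locus sitting exactly on the threshold is retained.
#' Column order is preserved.
#'
#' @param panel a [genotype_panel()].
#' @param min_maf frequency threshold in `[0, 0.5)`.
#' @return the filtered [genotype_panel()].
#' @export
maf_filter <- function(panel, min_maf = 0.05) {
  stopifnot(min_maf >= 0, min_maf < 0.5)
  maf <- locus_maf(panel)
  keep <- which(maf >= min_maf - 1e-9)
  if (length(keep) == 0) {
    stop("maf_filter removed every locus (min_maf = ", min_maf, ")",
         call. = FALSE)
  }
  subset_loci(panel, keep)
}

#' Impute missing dosages
#'
#' `column_mode` replaces each missing value with the most frequent dosage
#' at that locus. `haplotype_window` replaces it with the dosage implied by
#' the most frequent local haplotype: among individuals observed at the
#' locus and matching the target individual's observed dosages over a
#' window of `w` flanking loci each side, the most frequent dosage wins.
#' When no individual matches the flank, the column mode is used as
#' fallback. All ties resolve to the lower dosage.
#'
#' @param panel a [genotype_panel()].
#' @param strategy `"column_mode"` or `"haplotype_window"`.
#' @param w flanking loci per side for `haplotype_window`.
#' @return a [genotype_panel()] with no missing entries.
#' @export
impute_missing <- function(panel, strategy = c("haplotype_window", "column_mode"),
                           w = 2L) {
  strategy <- match.arg(strategy)
  d <- panel$dosages
  if (!anyNA(d)) return(panel)
  all_missing <- colSums(!is.na(d)) == 0
  if (any(all_missing)) {
    stop("locus entirely missing: ",
         paste(panel$loci$locus_id[all_missing], collapse = ", "),
         call. = FALSE)
  }
  modes <- apply(d, 2, dosage_mode)
  miss <- which(is.na(d), arr.ind = TRUE)
  if (strategy == "column_mode") {
    d[miss] <- modes[miss[, "col"]]
  } else {
    L <- ncol(d)
    for (k in seq_len(nrow(miss))) {
      i <- miss[k, "row"]; j <- miss[k, "col"]
      flank <- setdiff(max(1, j - w):min(L, j + w), j)
      flank <- flank[!is.na(d[i, flank])]
      if (length(flank) == 0) {
        d[i, j] <- modes[j]
        next
      }
      cand <- which(!is.na(panel$dosages[, j]))
      match_flank <- cand[apply(
        panel$dosages[cand, flank, drop = FALSE], 1,
        function(row) !anyNA(row) && all(row == d[i, flank])
      )]
      d[i, j] <- if (length(match_flank) > 0) {
        dosage_mode(panel$dosages[match_flank, j])
      } else {
        modes[j]
      }
    }
  }
  genotype_panel(d, panel$loci, inbred = !any(d == 1))
}

# most frequent dosage; ties go to the lower dosage
dosage_mode <- function(x) {
  x <- x[!is.na(x)]
  counts <- table(factor(x, levels = c(0, 1, 2)))
  as.numeric(names(counts)[which.max(counts)])
}

#' Drop loci on unanchored scaffolds
#'
#' Keeps only loci whose chromosome label is in `chromosomes`, modelling
#' the removal of scaffold-placed SNPs from an assembly-anchored panel.
#'
#' @param panel a [genotype_panel()].
#' @param chromosomes character vector of chromosome labels to keep.
#' @return the filtered [genotype_panel()].
#' @export
drop_scaffold_loci <- function(panel, chromosomes) {
  keep <- which(panel$loci$chrom %in% chromosomes)
  if (length(keep) == 0) stop("no loci left after scaffold filter", call. = FALSE)
  subset_loci(panel, keep)
}
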