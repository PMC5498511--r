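#' Genotype panel objects
#'
#' A `genotype_panel` holds an individuals-by-loci allele-dosage matrix
#' together with its locus metadata. Dosages count copies of the alternate
#' allele, so entries are 0, 1 or 2 (or `NA` for missing calls). Fully
#' inbred material (e.g. selfing-derived soybean accessions) is coded 0/2
#' only and flagged with `inbred`.
#'
#' @param dosages numeric or integer matrix, individuals in rows, loci in
#'   columns. Row names are individual ids; if absent, `ind_001`-style ids
#'   are created.
#' @param loci a data frame with columns `locus_id`, `chrom`, `pos`
#'   (1-based base pairs). If `NULL`, minimal metadata is synthesised from
#'   the matrix column names.
#' @param inbred logical; `TRUE` declares all individuals fully homozygous
#'   (no dosage may equal 1). If `NULL`, inferred from the data.
#'
#' @return An object of class `genotype_panel`: a list with elements
#'   `dosages` (matrix), `loci` (tibble) and `inbred` (flag).
#' @export
genotype_panel <- function(dosages, loci = NULL, inbred = NULL) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  if (is.null(rownames(dosages))) {
    rownames(dosages) <- sprintf("ind_%03d", seq_len(nrow(dosages)))
  }
  if (is.null(loci)) {
    ids <- colnames(dosages)
    if (is.null(ids)) ids <- sprintf("locus_%05d", seq_len(ncol(dosages)))
    loci <- parse_locus_ids(ids)
  }
  loci <- tibble::as_tibble(loci)
  stopifnot(all(c("locus_id", "chrom", "pos") %in% names(loci)))
  colnames(dosages) <- loci$locus_id
  if (is.null(inbred)) {
    inbred <- !any(dosages == 1, na.rm = TRUE)
  }
  out <- structure(
    list(dosages = dosages, loci = loci, inbred = inbred),
    class = "genotype_panel"
  )
  validate_genotype_panel(out)
  out
}

validate_genotype_panel <- function(x) {
  d <- x$dosages
  if (nrow(x$loci) != ncol(d)) {
    stop("locus metadata rows (", nrow(x$loci),
         ") do not match dosage columns (", ncol(d), ")", call. = FALSE)
  }
  if (anyDuplicated(x$loci$locus_id)) {
    stop("duplicated locus_id in panel", call. = FALSE)
  }
  bad <- !(d %in% c(0, 1, 2)) & !is.na(d)
  if (any(bad)) stop("dosages must be 0, 1, 2 or NA", call. = FALSE)
  if (isTRUE(x$inbred) && any(d == 1, na.rm = TRUE)) {
    stop("inbred panel contains heterozygous dosages (1)", call. = FALSE)
  }
  pos_ok <- x$loci |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(ok = !is.unsorted(.data$pos, strictly = TRUE)) |>
    dplyr::pull(.data$ok)
  if (!all(pos_ok)) {
    stop("positions must be strictly increasing within each chromosome",
         call. = FALSE)
  }
  invisible(x)
}

# locus ids of the form "<chrom>_<pos>" round-trip their metadata through
# plain dosage TSV; anything else gets placeholder coordinates
parse_locus_ids <- function(ids) {
  m <- regmatches(ids, regexec("^(.*)_([0-9]+)$", ids))
  ok <- lengths(m) == 3L
  chrom <- ifelse(ok, vapply(m, function(g) if (length(g) == 3) g[2] else "", ""), "1")
  pos <- ifelse(ok, as.numeric(vapply(m, function(g) if (length(g) == 3) g[3] else "0", "")),
                seq_along(ids))
  tb <- tibble::tibble(locus_id = ids, chrom = chrom, pos = as.integer(pos))
  # placeholder coordinates must still be strictly increasing per chromosome
  dup <- tb |>
    dplyr::group_by(.data$chrom) |>
    dplyr::mutate(bad = duplicated(.data$pos) | is.unsorted(.data$pos, strictly = TRUE)) |>
    dplyr::pull(.data$bad)
  if (any(dup)) {
    tb$chrom <- "1"
    tb$pos <- seq_along(ids)
  }
  tb
}

#' @export
print.genotype_panel <- function(x, ...) {
  d <- x$dosages
  cat("<genotype_panel> ", nrow(d), " individuals x ", ncol(d), " loci",
      if (isTRUE(x$inbred)) " (inbred, 0/2 coding)" else "",
      "\n", sep = "")
  n_mis <- sum(is.na(d))
  if (n_mis > 0) cat("  missing entries: ", n_mis, "\n", sep = "")
  cat("  chromosomes: ", length(unique(x$loci$chrom)),
      "; MAF range: ", paste(round(range(locus_maf(x), na.rm = TRUE), 3),
                             collapse = " - "), "\n", sep = "")
  invisible(x)
}

#' @export
dim.genotype_panel <- function(x) dim(x$dosages)

#' Per-locus minor-allele frequency
#'
#' Alternate-allele frequency is computed from non-missing dosages; the
#' minor-allele frequency is the smaller of it and its complement.
#'
#' @param panel a [genotype_panel()].
#' @return numeric vector, one MAF per locus.
#' @export
locus_maf <- function(panel) {
  p <- colMeans(panel$dosages, na.rm = TRUE) / 2
  pmin(p, 1 - p)
}

#' Subset a panel to a set of loci
#'
#' @param panel a [genotype_panel()].
#' @param loci integer locus indices (column positions) or character
#'   locus ids.
#' @return a [genotype_panel()] restricted to those loci, order preserved.
#' @export
subset_loci <- function(panel, loci) {
  if (is.character(loci)) loci <- match(loci, panel$loci$locus_id)
  if (anyNA(loci) || any(loci < 1 | loci > ncol(panel$dosages))) {
    stop("locus selection out of bounds", call. = FALSE)
  }
  genotype_panel(panel$dosages[, loci, drop = FALSE],
                 panel$loci[loci, ], inbred = panel$inbred)
}
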