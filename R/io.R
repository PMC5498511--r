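#' Read a genotype matrix
#'
#' Supported formats:
#' * `tsv` — header row of locus ids, first column `individual_id`,
#'   entries in `{0, 1, 2, NA}` counting alternate alleles.
#' * `vcf` — dosage is the count of ALT alleles in the GT field; missing
#'   GT gives a missing entry; multiallelic records are skipped with a
#'   warning. Parsed with the vcfR package.
#' * `hapmap` — diploid letter pairs mapped against the two alleles in
#'   the `alleles` column (`"A/T"`: first letter is reference).
#'
#' @param path file path.
#' @param format `"tsv"`, `"vcf"` or `"hapmap"`; default guesses from the
#'   file extension.
#' @return a [genotype_panel()].
#' @export
read_genotypes <- function(path, format = c("auto", "tsv", "vcf", "hapmap")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(sub("\\.gz$", "", path))),
                     vcf = "vcf", hmp = "hapmap", txt = "hapmap", "tsv")
  }
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (file.size(path) == 0) stop("empty file: ", path, call. = FALSE)
  switch(format,
         tsv = read_genotypes_tsv(path),
         vcf = read_genotypes_vcf(path),
         hapmap = read_genotypes_hapmap(path))
}

read_genotypes_tsv <- function(path) {
  tb <- utils::read.delim(path, check.names = FALSE, colClasses = "character")
  if (ncol(tb) < 2) stop("malformed dosage TSV (line 1): need id column plus loci",
                         call. = FALSE)
  ids <- tb[[1]]
  m_chr <- as.matrix(tb[, -1, drop = FALSE])
  na_mask <- is.na(m_chr)
  m <- suppressWarnings(array(as.numeric(m_chr), dim = dim(m_chr),
                              dimnames = dimnames(m_chr)))
  bad_cell <- which(!na_mask & (is.na(m) | !(m %in% c(0, 1, 2))), arr.ind = TRUE)
  if (nrow(bad_cell) > 0) {
    stop("malformed dosage TSV at line ", bad_cell[1, 1] + 1L,
         ": entries must be 0, 1, 2 or NA", call. = FALSE)
  }
  rownames(m) <- ids
  genotype_panel(m, parse_locus_ids(colnames(m)))
}

read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  multi <- grepl(",", fix[, "ALT"])
  if (any(multi)) {
    warning(sum(multi), " multiallelic record(s) skipped", call. = FALSE)
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1, dimnames = list(rownames(v@fix), colnames(v@gt)[-1]))
  gt <- gt[!multi, , drop = FALSE]
  fix <- fix[!multi, , drop = FALSE]
  if (nrow(fix) == 0) stop("no usable biallelic records in ", path, call. = FALSE)
  # count ALT alleles in the GT string, phased or unphased
  dos <- matrix(NA_real_, nrow = ncol(gt), ncol = nrow(gt))
  for (j in seq_len(nrow(gt))) {
    g <- gt[j, ]
    alleles <- strsplit(g, "[/|]")
    dos[, j] <- vapply(alleles, function(a) {
      if (any(is.na(a)) || any(a == ".")) NA_real_ else sum(a == "1")
    }, numeric(1))
  }
  rownames(dos) <- colnames(gt)
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0(fix[, "CHROM"], "_", fix[, "POS"])[is.na(ids) | ids == "."]
  loci <- tibble::tibble(locus_id = ids, chrom = fix[, "CHROM"],
                         pos = as.integer(fix[, "POS"]))
  genotype_panel(dos, loci)
}

read_genotypes_hapmap <- function(path) {
  tb <- utils::read.delim(path, check.names = FALSE, colClasses = "character",
                          comment.char = "")
  meta_cols <- 11L
  if (ncol(tb) <= meta_cols) {
    stop("malformed HapMap file (line 1): expected 11 metadata columns plus samples",
         call. = FALSE)
  }
  alleles <- strsplit(tb[["alleles"]], "/", fixed = TRUE)
  bad <- which(lengths(alleles) != 2)
  if (length(bad) > 0) {
    stop("malformed HapMap alleles field at line ", bad[1] + 1L, call. = FALSE)
  }
  gmat <- as.matrix(tb[, -(1:meta_cols), drop = FALSE])
  dos <- matrix(NA_real_, nrow = ncol(gmat), ncol = nrow(gmat))
  for (j in seq_len(nrow(gmat))) {
    alt <- alleles[[j]][2]
    calls <- strsplit(gmat[j, ], "")
    dos[, j] <- vapply(calls, function(a) {
      if (length(a) != 2 || any(a %in% c("N", "-"))) NA_real_ else sum(a == alt)
    }, numeric(1))
  }
  rownames(dos) <- colnames(gmat)
  loci <- tibble::tibble(locus_id = tb[[1]], chrom = tb[["chrom"]],
                         pos = as.integer(tb[["pos"]]))
  genotype_panel(dos, loci)
}

#' Write a genotype matrix
#'
#' `tsv` writes the dosage matrix losslessly (locus ids as header,
#' `individual_id` first column, `NA` for missing). `vcf` writes a minimal
#' VCF 4.2 with synthetic `A`/`T` REF/ALT letters and GT-only genotypes.
#'
#' @param panel a [genotype_panel()].
#' @param path output file path.
#' @param format `"tsv"` or `"vcf"`.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(panel, path, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  if (format == "tsv") {
    d <- panel$dosages
    df <- data.frame(individual_id = rownames(d), d, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    d <- panel$dosages
    gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
    lines <- c(
      "##fileformat=VCFv4.2",
      "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
      paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
              "INFO", "FORMAT", rownames(d)), collapse = "\t")
    )
    body <- vapply(seq_len(ncol(d)), function(j) {
      g <- gt_code[as.character(d[, j])]
      g[is.na(g)] <- "./."
      paste(c(panel$loci$chrom[j], panel$loci$pos[j], panel$loci$locus_id[j],
              "A", "T", ".", "PASS", ".", "GT", g), collapse = "\t")
    }, character(1))
    writeLines(c(lines, body), path)
  }
  invisible(path)
}

#' Write simulated trait values or a QTL architecture as TSV
#'
#' @param x a [simulate_trait()] result or a [sample_architecture()] result.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trait <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Serialise a fitted whole-genome regression to JSON
#'
#' @param fit a `wgr_fit` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_wgr_json <- function(fit, path) {
  jsonlite::write_json(unclass(fit), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
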