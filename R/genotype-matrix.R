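#' Construct a genotype matrix
#'
#' Container for an accessions x variants dosage table together with variant
#' metadata. Dosages are alternate-allele counts: 0 (homozygous reference),
#' 2 (homozygous alternate), 1 (heterozygous; tolerated but flagged for inbred
#' panels) or `NA` (missing). Variants are stored sorted by chromosome and
#' position; the dosage column order always matches the variant order.
#'
#' @param dosage Numeric matrix, accessions in rows (rownames = accession ids),
#'   variants in columns. Values in `{0, 1, 2, NA}`.
#' @param variants Data frame with one row per dosage column and columns
#'   `id`, `chrom`, `pos`, `ref`, `alt` plus optional `qual`, `qd`, `fs`, `mq`.
#' @return An object of class `genotype_matrix`: a list with elements
#'   `dosage` and `variants`.
#' @export
genotype_matrix <- function(dosage, variants) {
  if (!is.matrix(dosage)) dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "double"
  if (is.null(rownames(dosage))) {
    stop("`dosage` must have accession ids as rownames")
  }
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  req <- c("id", "chrom", "pos", "ref", "alt")
  miss <- setdiff(req, names(variants))
  if (length(miss) > 0) {
    stop("`variants` is missing columns: ", paste(miss, collapse = ", "))
  }
  for (col in c("qual", "qd", "fs", "mq")) {
    if (is.null(variants[[col]])) variants[[col]] <- NA_real_
  }
  if (nrow(variants) != ncol(dosage)) {
    stop("number of variant rows (", nrow(variants),
         ") does not match dosage columns (", ncol(dosage), ")")
  }
  if (any(variants$pos < 1)) stop("variant positions must be >= 1")
  if (any(variants$ref == variants$alt)) {
    stop("ref and alt alleles must differ")
  }
  bad <- !(dosage %in% c(0, 1, 2) | is.na(dosage))
  if (any(bad)) stop("dosages must be 0, 1, 2 or NA")
  if (anyDuplicated(variants$id)) stop("variant ids must be unique")
  ord <- order(variants$chrom, variants$pos)
  variants <- variants[ord, , drop = FALSE]
  rownames(variants) <- NULL
  dosage <- dosage[, ord, drop = FALSE]
  colnames(dosage) <- variants$id
  structure(list(dosage = dosage, variants = variants),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  n_het <- sum(x$dosage == 1, na.rm = TRUE)
  n_mis <- sum(is.na(x$dosage))
  cat(sprintf(
    "genotype_matrix: %d accessions x %d variants (%d het calls, %d missing)\n",
    nrow(x$dosage), ncol(x$dosage), n_het, n_mis))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' Accession identifiers of a genotype matrix
#' @param G A `genotype_matrix`.
#' @return Character vector of accession ids, in row order.
#' @export
accessions <- function(G) rownames(G$dosage)

#' Per-variant minor allele frequency
#'
#' Allele frequencies are computed from non-missing dosages; heterozygous
#' calls contribute one copy of each allele.
#'
#' @param G A `genotype_matrix`.
#' @return Numeric vector of minor allele frequencies, named by variant id.
#' @export
variant_maf <- function(G) {
  p_alt <- colMeans(G$dosage, na.rm = TRUE) / 2
  maf <- pmin(p_alt, 1 - p_alt)
  names(maf) <- G$variants$id
  maf
}

#' Subset a genotype matrix by variant id
#'
#' @param G A `genotype_matrix`.
#' @param ids Variant ids to retain (order within `G` is preserved).
#' @return A `genotype_matrix` restricted to the requested variants.
#' @export
subset_variants <- function(G, ids) {
  keep <- G$variants$id %in% ids
  if (!any(keep)) stop("none of the requested variant ids are present")
  genotype_matrix(G$dosage[, keep, drop = FALSE],
                  G$variants[keep, , drop = FALSE])
}
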