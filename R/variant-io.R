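#' Read a VCF into a genotype matrix
#'
#' Parses a VCF 4.x file (via \pkg{vcfR}), keeping biallelic records only;
#' multiallelic records are dropped with a message reporting the count.
#' Dosages are alternate-allele counts from the GT field (`0/0` -> 0,
#' `0/1` -> 1, `1/1` -> 2, `./.` -> `NA`; phased separators are accepted).
#' QUAL and the INFO keys QD, FS and MQ are carried into the variant table
#' when present.
#'
#' @param path Path to a VCF file.
#' @return A [genotype_matrix()].
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("VCF not found: ", path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) stop("VCF contains no records: ", path)
  multi <- grepl(",", fix$ALT, fixed = TRUE)
  if (any(multi)) {
    message("read_vcf: dropped ", sum(multi), " multiallelic record(s)")
  }
  keep <- !multi
  fix <- fix[keep, , drop = FALSE]
  gt <- vcfR::extract.gt(vcf, element = "GT")[keep, , drop = FALSE]
  info_num <- function(key) {
    val <- suppressWarnings(
      vcfR::extract.info(vcf, element = key, as.numeric = TRUE))
    if (is.null(val)) rep(NA_real_, sum(keep)) else val[keep]
  }
  ids <- fix$ID
  no_id <- is.na(ids) | ids == "."
  ids[no_id] <- paste0(fix$CHROM[no_id], "_", fix$POS[no_id])
  variants <- data.frame(
    id = ids, chrom = fix$CHROM, pos = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT,
    qual = suppressWarnings(as.numeric(fix$QUAL)),
    qd = info_num("QD"), fs = info_num("FS"), mq = info_num("MQ"),
    stringsAsFactors = FALSE)
  core <- sub(":.*", "", gt)
  core <- gsub("|", "/", core, fixed = TRUE)
  lookup <- c("0/0" = 0, "0/1" = 1, "1/0" = 1, "1/1" = 2)
  dos <- t(matrix(unname(lookup[core]), nrow = nrow(core),
                  ncol = ncol(core)))
  rownames(dos) <- colnames(gt)
  unknown <- !(core %in% c(names(lookup), "./.", ".")) & !is.na(core)
  if (any(unknown)) {
    stop("read_vcf: unparseable GT value(s), e.g. '",
         core[unknown][1], "' in ", path)
  }
  genotype_matrix(dos, variants)
}

#' Write a genotype matrix to VCF 4.2
#'
#' Emits one biallelic record per variant with QUAL and INFO keys QD/FS/MQ
#' (when available) and diploid unphased GT calls. Reading the file back with
#' [read_vcf()] reproduces the dosage matrix exactly.
#'
#' @param G A [genotype_matrix()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_vcf <- function(G, path) {
  v <- G$variants
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=haplopheno",
    "##INFO=<ID=QD,Number=1,Type=Float,Description=\"Quality by depth\">",
    "##INFO=<ID=FS,Number=1,Type=Float,Description=\"Fisher strand bias\">",
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"RMS mapping quality\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(G$dosage)), collapse = "\t"))
  info <- vapply(seq_len(nrow(v)), function(i) {
    keys <- c(QD = v$qd[i], FS = v$fs[i], MQ = v$mq[i])
    keys <- keys[!is.na(keys)]
    if (length(keys) == 0) "." else
      paste(sprintf("%s=%s", names(keys), format(keys, trim = TRUE)),
            collapse = ";")
  }, character(1))
  gt_code <- c("0" = "0/0", "1" = "0/1", "2" = "1/1")
  gt <- matrix("./.", nrow = nrow(G$dosage), ncol = ncol(G$dosage))
  ok <- !is.na(G$dosage)
  gt[ok] <- gt_code[as.character(G$dosage[ok])]
  qual <- ifelse(is.na(v$qual), ".", format(v$qual, trim = TRUE))
  records <- vapply(seq_len(nrow(v)), function(i) {
    paste(c(v$chrom[i], v$pos[i], v$id[i], v$ref[i], v$alt[i], qual[i],
            "PASS", info[i], "GT", gt[, i]), collapse = "\t")
  }, character(1))
  writeLines(c(header, records), path)
  invisible(path)
}

#' Hard-filter a variant set on site quality annotations
#'
#' Removes every record failing any of the GATK-style hard-filter criteria
#' QUAL < 30, QD < 4.0, FS > 60.0 or MQ < 40.0 (strict inequalities;
#' boundary values are retained). A criterion whose annotation is absent for
#' a record is not applied to that record, and the decision is logged. Per-
#' criterion removal counts are attached as the `"filter_report"` attribute.
#'
#' @param G A [genotype_matrix()].
#' @param min_qual,min_qd,max_fs,min_mq Filter thresholds; the defaults are
#'   the standard hard-filtering values for targeted resequencing callsets.
#' @return The filtered `genotype_matrix`, with a `filter_report` attribute
#'   (data frame: criterion, n_removed, n_not_applied).
#' @export
hard_filter <- function(G, min_qual = 30, min_qd = 4.0, max_fs = 60.0,
                        min_mq = 40.0) {
  v <- G$variants
  crit <- list(
    QUAL = v$qual < min_qual,
    QD = v$qd < min_qd,
    FS = v$fs > max_fs,
    MQ = v$mq < min_mq)
  n_na <- vapply(crit, function(x) sum(is.na(x)), integer(1))
  fails <- vapply(crit, function(x) !is.na(x) & x, logical(nrow(v)))
  if (nrow(v) == 1) fails <- matrix(fails, nrow = 1)
  removed <- rowSums(fails) > 0
  report <- data.frame(
    criterion = names(crit),
    n_removed = colSums(fails),
    n_not_applied = n_na,
    row.names = NULL)
  if (any(n_na > 0)) {
    message("hard_filter: absent annotations skipped for ",
            paste(sprintf("%s (%d)", names(crit)[n_na > 0], n_na[n_na > 0]),
                  collapse = ", "))
  }
  message("hard_filter: removed ", sum(removed), "/", nrow(v), " record(s)")
  out <- genotype_matrix(G$dosage[, !removed, drop = FALSE],
                         v[!removed, , drop = FALSE])
  attr(out, "filter_report") <- report
  out
}

#' Write a hard-filter report to TSV
#' @param G A filtered `genotype_matrix` carrying a `filter_report` attribute.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_filter_report <- function(G, path) {
  rep <- attr(G, "filter_report")
  if (is.null(rep)) stop("no filter_report attribute; run hard_filter first")
  utils::write.table(rep, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
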