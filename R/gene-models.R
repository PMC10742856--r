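#' Gene model table
#'
#' Gene models are stored as a plain data frame with one row per gene and
#' 1-based inclusive genomic intervals (VCF convention): columns `gene`,
#' `chrom`, `strand` (`+`/`-`), `tx_start`, `tx_end`, `cds_start`, `cds_end`,
#' `exon_starts`, `exon_ends` (comma-separated lists) and optionally
#' `cds_seq`, the spliced coding sequence in translation order. The promoter
#' is defined as the 2000 bp upstream of the strand-aware transcription start
#' (truncated at the contig start).
#'
#' @param df Data frame with the columns above.
#' @return A validated gene model data frame.
#' @export
gene_models <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  req <- c("gene", "chrom", "strand", "tx_start", "tx_end",
           "cds_start", "cds_end", "exon_starts", "exon_ends")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0) {
    stop("gene model table is missing columns: ", paste(miss, collapse = ", "))
  }
  if (!all(df$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  for (i in seq_len(nrow(df))) {
    ex <- exon_intervals(df[i, ])
    if (is.unsorted(ex$start) || any(ex$start[-1] <= ex$end[-nrow(ex)])) {
      stop("exons of gene ", df$gene[i], " must be sorted and non-overlapping")
    }
    if (df$cds_start[i] < min(ex$start) || df$cds_end[i] > max(ex$end)) {
      stop("CDS of gene ", df$gene[i], " extends outside the exons")
    }
  }
  df
}

exon_intervals <- function(gene_row) {
  data.frame(
    start = as.integer(strsplit(as.character(gene_row$exon_starts), ",")[[1]]),
    end = as.integer(strsplit(as.character(gene_row$exon_ends), ",")[[1]]))
}

#' Promoter interval of a gene
#'
#' The 2000 bp immediately upstream of the strand-aware transcription start
#' site, truncated at position 1 for genes near the contig start.
#'
#' @param gene_row One row of a gene model table.
#' @param promoter_bp Promoter length in bp (default 2000).
#' @return Integer vector `c(start, end)`, 1-based inclusive.
#' @export
promoter_interval <- function(gene_row, promoter_bp = 2000L) {
  if (gene_row$strand == "+") {
    c(max(1L, as.integer(gene_row$tx_start) - promoter_bp),
      as.integer(gene_row$tx_start) - 1L)
  } else {
    c(as.integer(gene_row$tx_end) + 1L,
      as.integer(gene_row$tx_end) + promoter_bp)
  }
}

#' Full span of a gene including its promoter
#'
#' @inheritParams promoter_interval
#' @return Integer vector `c(start, end)` covering promoter plus transcript.
#' @export
gene_span <- function(gene_row, promoter_bp = 2000L) {
  pr <- promoter_interval(gene_row, promoter_bp)
  range(c(pr, as.integer(gene_row$tx_start), as.integer(gene_row$tx_end)))
}

#' Assign a genomic position to a gene region
#'
#' Labels a position relative to one gene model, strand-aware. UTRs are the
#' exonic portions of the transcript outside the CDS; 5' vs 3' follows the
#' strand. Positions upstream of the transcription start (within
#' `promoter_bp`) are promoter; anything else outside the transcript is
#' intergenic. Indels are assigned by their left-anchored VCF position.
#'
#' @param chrom,pos Variant chromosome and 1-based position.
#' @param gene_row One row of a gene model table (same chromosome).
#' @param promoter_bp Promoter length in bp.
#' @return One of `"promoter"`, `"5UTR"`, `"exon_cds"`, `"intron"`,
#'   `"3UTR"`, `"intergenic"`.
#' @export
annotate_region <- function(chrom, pos, gene_row, promoter_bp = 2000L) {
  if (chrom != gene_row$chrom) {
    stop("variant on ", chrom, " cannot be annotated against gene ",
         gene_row$gene, " on ", gene_row$chrom)
  }
  pos <- as.integer(pos)
  pr <- promoter_interval(gene_row, promoter_bp)
  if (pos >= pr[1] && pos <= pr[2]) return("promoter")
  if (pos < gene_row$tx_start || pos > gene_row$tx_end) return("intergenic")
  ex <- exon_intervals(gene_row)
  exonic <- any(pos >= ex$start & pos <= ex$end)
  if (!exonic) return("intron")
  if (pos >= gene_row$cds_start && pos <= gene_row$cds_end) return("exon_cds")
  upstream_of_cds <- pos < gene_row$cds_start
  if (gene_row$strand == "+") {
    if (upstream_of_cds) "5UTR" else "3UTR"
  } else {
    if (upstream_of_cds) "3UTR" else "5UTR"
  }
}

#' Assign variants to genes by containing span
#'
#' A variant belongs to the gene whose promoter-plus-transcript span contains
#' it; when several spans contain the position the first gene in table order
#' wins. Variants contained in no span are labelled `NA` (intergenic).
#'
#' @param variants Variant data frame with `chrom` and `pos`.
#' @param genes Gene model table.
#' @param promoter_bp Promoter length in bp.
#' @return Character vector of gene ids (or `NA`), one per variant.
#' @export
assign_gene <- function(variants, genes, promoter_bp = 2000L) {
  spans <- t(vapply(seq_len(nrow(genes)), function(i) {
    gene_span(genes[i, ], promoter_bp)
  }, numeric(2)))
  vapply(seq_len(nrow(variants)), function(v) {
    hit <- which(genes$chrom == variants$chrom[v] &
                   spans[, 1] <= variants$pos[v] &
                   spans[, 2] >= variants$pos[v])
    if (length(hit) == 0) NA_character_ else genes$gene[hit[1]]
  }, character(1))
}

cds_genomic_positions <- function(gene_row) {
  ex <- exon_intervals(gene_row)
  pos <- unlist(lapply(seq_len(nrow(ex)), function(i) {
    seq(max(ex$start[i], gene_row$cds_start),
        min(ex$end[i], gene_row$cds_end))
  }))
  pos[pos >= gene_row$cds_start & pos <= gene_row$cds_end]
}

complement_base <- function(b) chartr("ACGT", "TGCA", b)

#' Classify the coding consequence of a variant
#'
#' For substitutions inside the CDS the affected codon is translated before
#' and after the change (standard genetic code); indels are frameshift when
#' the length difference is not a multiple of 3, in-frame otherwise. A
#' substitution creating a stop codon upstream of the native stop is a
#' premature stop (`stop_gain`). Variants whose anchor position falls outside
#' the CDS are `non_coding`.
#'
#' @param ref,alt Reference and alternate allele strings.
#' @param pos 1-based genomic position (left-anchored for indels).
#' @param gene_row One row of a gene model table.
#' @param cds_seq Spliced CDS sequence in translation order (5' to 3' of the
#'   coding strand); length must be a multiple of 3. Defaults to the
#'   `cds_seq` column of the gene row.
#' @return One of `"synonymous"`, `"nonsynonymous"`, `"stop_gain"`,
#'   `"frameshift"`, `"inframe_indel"`, `"non_coding"`.
#' @export
classify_coding_effect <- function(ref, alt, pos, gene_row, cds_seq = NULL) {
  if (is.null(cds_seq)) cds_seq <- gene_row$cds_seq
  if (is.null(cds_seq) || is.na(cds_seq)) stop("no CDS sequence available")
  cds_seq <- toupper(cds_seq)
  if (nchar(cds_seq) %% 3 != 0) {
    stop("CDS length of gene ", gene_row$gene, " is not a multiple of 3")
  }
  gpos <- cds_genomic_positions(gene_row)
  if (length(gpos) != nchar(cds_seq)) {
    stop("CDS sequence length does not match the gene model CDS intervals")
  }
  pos <- as.integer(pos)
  if (!(pos %in% gpos)) return("non_coding")
  if (nchar(ref) != nchar(alt)) {
    shift <- abs(nchar(ref) - nchar(alt)) %% 3
    return(if (shift != 0) "frameshift" else "inframe_indel")
  }
  if (nchar(ref) != 1) return("non_coding")  # MNVs not classified
  # CDS index in translation order; minus-strand genes read high-to-low
  idx <- if (gene_row$strand == "+") match(pos, gpos) else
    match(pos, rev(gpos))
  allele <- if (gene_row$strand == "+") alt else complement_base(alt)
  codon_i <- (idx - 1L) %/% 3L
  within <- (idx - 1L) %% 3L + 1L
  codon <- substr(cds_seq, codon_i * 3L + 1L, codon_i * 3L + 3L)
  new_codon <- codon
  substr(new_codon, within, within) <- allele
  code <- Biostrings::GENETIC_CODE
  aa_old <- unname(code[codon])
  aa_new <- unname(code[new_codon])
  if (is.na(aa_old) || is.na(aa_new)) stop("non-ACGT codon encountered")
  if (aa_old == aa_new) return("synonymous")
  if (aa_new == "*") return("stop_gain")
  "nonsynonymous"
}

#' Read a gene model table from TSV
#' @param path Path to a tab-separated gene model file.
#' @return A validated gene model data frame.
#' @export
read_gene_models <- function(path) {
  gene_models(utils::read.delim(path, stringsAsFactors = FALSE,
                                colClasses = c(exon_starts = "character",
                                               exon_ends = "character")))
}

#' Write a gene model table to TSV
#' @param genes Gene model table.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gene_models <- function(genes, path) {
  utils::write.table(genes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
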