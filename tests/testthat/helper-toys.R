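# Shared toy builders. Everything is generated in code; no stored fixtures.

toy_variants <- function(p, chrom = "chr01", pos = NULL) {
  if (is.null(pos)) pos <- seq(100L, by = 100L, length.out = p)
  data.frame(id = paste0("v", seq_len(p)), chrom = chrom, pos = pos,
             ref = "A", alt = "T", stringsAsFactors = FALSE)
}

rand_inbred_G <- function(n, p, seed = 1, maf = NULL) {
  set.seed(seed)
  if (is.null(maf)) maf <- runif(p, 0.1, 0.5)
  dos <- sapply(maf, function(f) sample(c(0, 2), n, TRUE, c(1 - f, f)))
  rownames(dos) <- sprintf("acc%03d", seq_len(n))
  genotype_matrix(dos, toy_variants(p))
}

# 20-record site-quality toy with boundary values; expected retention is
# worked out by hand from the strict-inequality filter definition.
qc_toy_matrix <- function() {
  v <- toy_variants(20)
  v$qual <- c(50, 29.99, 30, 50, 50, 50, 50, 50, 50, 25,
              50, 20, 1e6, 50, 50, 50, 30.01, 50, 50, 29)
  v$qd <- c(10, 10, 10, 3.99, 4.0, 10, 10, 10, 10, 2,
            NA, NA, 10, 10, 10, 100, 10, 10, 10, 10)
  v$fs <- c(5, 5, 5, 5, 5, 60.0, 60.01, 5, 5, 5,
            5, 5, 5, 0, 5, 5, 5, 59.999, 5, 5)
  v$mq <- c(50, 50, 50, 50, 50, 50, 50, 39.99, 40, 50,
            50, 50, 50, 50, 10, 50, 50, 50, 40.01, 50)
  dos <- matrix(rep(c(0, 2), 20), nrow = 2, ncol = 20,
                dimnames = list(c("a1", "a2"), NULL))
  G <- genotype_matrix(dos, v)
  attr(G, "expect_removed") <- paste0("v", c(2, 4, 7, 8, 10, 12, 15, 20))
  G
}

# Plus-strand toy gene: promoter 1001-3000, tx 3001-3900, exon1 3001-3200,
# intron 3201-3400, exon2 3401-3900, CDS 3101-3702 (len 100 + 302 = 402),
# 5'UTR 3001-3100, 3'UTR 3703-3900.
toy_plus_gene <- function() {
  gene_models(data.frame(
    gene = "toy1", chrom = "chr01", strand = "+",
    tx_start = 3001L, tx_end = 3900L, cds_start = 3101L, cds_end = 3702L,
    exon_starts = "3001,3401", exon_ends = "3200,3900",
    stringsAsFactors = FALSE))
}

# Single-exon plus-strand coding toy with a known CDS sequence (20 codons;
# genomic positions 101..160 map one-to-one onto CDS indices 1..60).
toy_coding_gene <- function() {
  cds_plus <- paste0("ATGGCTTGGTTTGGGCCCAAATTTGGGCCCAAA",
                     "TTTGGGCCCAAATTTGGGCCCAATTGA")  # 60 bases
  stopifnot(nchar(cds_plus) == 60)
  gene_models(data.frame(
    gene = "cg1", chrom = "chr02", strand = "+",
    tx_start = 101L, tx_end = 160L, cds_start = 101L, cds_end = 160L,
    exon_starts = "101", exon_ends = "160", cds_seq = cds_plus,
    stringsAsFactors = FALSE))
}

# Minus-strand coding toy: translation-order CDS "ATGTACTGA"; the genomic
# bases 101..109 are its reverse complement, so genomic position p maps to
# CDS index 110 - p and alleles are complemented.
toy_coding_gene_minus <- function() {
  gene_models(data.frame(
    gene = "cg2", chrom = "chr02", strand = "-",
    tx_start = 101L, tx_end = 109L, cds_start = 101L, cds_end = 109L,
    exon_starts = "101", exon_ends = "109", cds_seq = "ATGTACTGA",
    stringsAsFactors = FALSE))
}

# Genotype matrix realizing a given set of haplotype strings (A/T alleles)
# with the given group sizes; accession order interleaves groups.
hap_toy_G <- function(strings, sizes, chrom = "chr01") {
  stopifnot(length(strings) == length(sizes))
  s <- nchar(strings[1])
  acc <- sprintf("acc%03d", seq_len(sum(sizes)))
  lab <- rep(seq_along(strings), sizes)
  dos <- matrix(NA_real_, nrow = sum(sizes), ncol = s,
                dimnames = list(acc, NULL))
  for (i in seq_along(acc)) {
    chars <- strsplit(strings[lab[i]], "")[[1]]
    dos[i, ] <- ifelse(chars == "A", 0, 2)
  }
  G <- genotype_matrix(dos, toy_variants(s, chrom = chrom))
  attr(G, "true_group") <- stats::setNames(lab, acc)
  G
}

# Independent Duncan oracle: a pair of sorted means is non-significant iff
# SOME covering span has a range not exceeding its critical range.
duncan_oracle_ns <- function(m_sorted, crit) {
  k <- length(m_sorted)
  ns <- matrix(FALSE, k, k)
  for (a in seq_len(k - 1)) {
    for (b in seq(a + 1, k)) {
      covered <- FALSE
      for (i in seq_len(a)) {
        for (j in seq(b, k)) {
          if (m_sorted[i] - m_sorted[j] <= crit[j - i + 1]) covered <- TRUE
        }
      }
      ns[a, b] <- ns[b, a] <- covered
    }
  }
  ns
}

# Brute-force minimal covering panel size for the marker set-cover.
min_cover_size <- function(sep) {
  n_sites <- nrow(sep)
  for (size in seq_len(n_sites)) {
    combs <- utils::combn(n_sites, size)
    for (cc in seq_len(ncol(combs))) {
      if (all(colSums(sep[combs[, cc], , drop = FALSE]) > 0)) return(size)
    }
  }
  Inf
}
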