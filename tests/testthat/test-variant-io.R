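test_that("VCF GT fields map to dosages and multiallelic records are dropped", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=QD,Number=1,Type=Float,Description=\"qd\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"gt\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "s1", "s2", "s3"), collapse = "\t"),
    "chr01\t100\t.\tA\tT\t50\tPASS\tQD=10\tGT\t0/0\t1/1\t./.",
    "chr01\t200\t.\tG\tC\t60\tPASS\t.\tGT\t0/1\t1|1\t0|0",
    "chr01\t300\t.\tG\tC,T\t70\tPASS\t.\tGT\t0/0\t1/1\t2/2"),
    path)
  expect_message(G <- read_vcf(path), "multiallelic")
  expect_equal(dim(G), c(3L, 2L))
  expect_equal(unname(G$dosage[, 1]), c(0, 2, NA))
  expect_equal(unname(G$dosage[, 2]), c(1, 2, 0))
  expect_equal(G$variants$qual, c(50, 60))
  expect_equal(G$variants$qd, c(10, NA))
})

test_that("hard filter removes exactly the strict-inequality violations", {
  G <- qc_toy_matrix()
  expect_message(Gf <- hard_filter(G), "removed 8/20")
  removed <- setdiff(G$variants$id, Gf$variants$id)
  expect_setequal(removed, attr(G, "expect_removed"))
  # boundary values are retained: thresholds themselves do not fail
  expect_true(all(c("v3", "v5", "v6", "v9") %in% Gf$variants$id))
  rep <- attr(Gf, "filter_report")
  expect_equal(rep$n_removed[rep$criterion == "QUAL"], 4)
  expect_equal(rep$n_not_applied[rep$criterion == "QD"], 2)
  # idempotent, and output is a subset of the input
  Gff <- suppressMessages(hard_filter(Gf))
  expect_identical(Gff$variants$id, Gf$variants$id)
  expect_true(all(Gf$variants$id %in% G$variants$id))
})

test_that("VCF round trip is lossless on dosages, positions and QC fields", {
  cfg <- sim_config(n_accessions = 25, n_genes = 4, sites_per_gene = 6,
                    causal_spec = list(),
                    trait_spec = default_trait_spec()["GL"],
                    missing_rate = 0.05, qc_fail_fraction = 0.1, seed = 31)
  panel <- simulate_panel(cfg)
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(panel$genotypes, path)
  G2 <- read_vcf(path)
  expect_identical(G2$dosage, panel$genotypes$dosage)
  expect_identical(G2$variants$pos, panel$genotypes$variants$pos)
  expect_equal(G2$variants$qual, panel$genotypes$variants$qual)
  expect_equal(G2$variants$qd, panel$genotypes$variants$qd)
  expect_equal(G2$variants$mq, panel$genotypes$variants$mq)
})

test_that("region labels partition the toy gene and match an interval oracle", {
  g <- toy_plus_gene()[1, ]
  # independent oracle: explicit position sets
  promoter <- 1001:3000
  exon1 <- 3001:3200; exon2 <- 3401:3900
  cds <- c(3101:3200, 3401:3702)
  utr5 <- 3001:3100; utr3 <- 3703:3900
  intron <- 3201:3400
  for (pos in seq(950, 3950, by = 7)) {
    expected <- if (pos %in% promoter) "promoter"
      else if (pos %in% cds) "exon_cds"
      else if (pos %in% utr5) "5UTR"
      else if (pos %in% utr3) "3UTR"
      else if (pos %in% intron) "intron"
      else "intergenic"
    expect_identical(annotate_region("chr01", pos, g), expected)
  }
  # the worked promoter example: TSS - 1500
  expect_identical(annotate_region("chr01", 3001 - 1500, g), "promoter")
  expect_error(annotate_region("chr02", 3100, g), "chr02")
})

test_that("minus-strand labels equal plus-strand labels after reflection", {
  g <- toy_plus_gene()[1, ]
  L <- 10000L
  refl <- function(x) L + 1L - x
  gm <- gene_models(data.frame(
    gene = "toy1m", chrom = "chr01", strand = "-",
    tx_start = refl(g$tx_end), tx_end = refl(g$tx_start),
    cds_start = refl(g$cds_end), cds_end = refl(g$cds_start),
    exon_starts = paste(refl(c(3900L, 3200L)), collapse = ","),
    exon_ends = paste(refl(c(3401L, 3001L)), collapse = ","),
    stringsAsFactors = FALSE))[1, ]
  for (pos in seq(950, 3950, by = 11)) {
    expect_identical(annotate_region("chr01", refl(pos), gm),
                     annotate_region("chr01", pos, g))
  }
})

test_that("coding effects are classified from the affected codon", {
  g <- toy_coding_gene()[1, ]
  # codon 2 GCT: third-position T>C keeps alanine
  expect_identical(classify_coding_effect("T", "C", 106, g), "synonymous")
  # codon 2 first position G>A turns Ala into Thr
  expect_identical(classify_coding_effect("G", "A", 104, g), "nonsynonymous")
  # codon 3 TGG -> TGA: premature stop upstream of the native stop
  expect_identical(classify_coding_effect("G", "A", 109, g), "stop_gain")
  # indel length rules inside the CDS
  expect_identical(classify_coding_effect("TT", "T", 120, g), "frameshift")
  expect_identical(classify_coding_effect("TTTT", "T", 120, g),
                   "inframe_indel")
  expect_identical(classify_coding_effect("A", "G", 90, g), "non_coding")
  bad <- g; bad$cds_seq <- "ATGGCTT"
  expect_error(classify_coding_effect("T", "C", 106, bad), "multiple of 3")
})

test_that("minus-strand coding changes are read on the coding strand", {
  g <- toy_coding_gene_minus()[1, ]
  # genomic 109 is CDS index 1 ('A' of ATG); genomic T>C reads as A>G
  expect_identical(classify_coding_effect("T", "C", 109, g), "nonsynonymous")
  # genomic 104 is CDS index 6; TAC -> TAG creates a stop
  expect_identical(classify_coding_effect("G", "C", 104, g), "stop_gain")
})
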