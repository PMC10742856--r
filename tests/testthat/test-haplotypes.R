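test_that("haplotype grouping equals brute-force string comparison", {
  G <- hap_toy_G(c("ATA", "TTA", "ATT"), sizes = c(3, 2, 1))
  a <- call_haplotypes(G, "g", c("v1", "v2", "v3"))
  # brute force: group accessions by the literal allele strings
  strings <- apply(G$dosage, 1, function(d) {
    paste(ifelse(d == 0, "A", "T"), collapse = "")
  })
  for (i in accessions(G)) for (j in accessions(G)) {
    expect_identical(a$labels[i] == a$labels[j], strings[i] == strings[j])
  }
  # labels ranked by frequency: H1 is the 3-member group
  expect_identical(unname(a$labels[1]), "H1")
  expect_equal(a$groups$count, c(3, 2, 1))
  expect_error(call_haplotypes(G, "g", character(0)), "empty")
})

test_that("one 90/10 site labels the common allele string H1", {
  G <- hap_toy_G(c("A", "T"), sizes = c(18, 2))
  a <- call_haplotypes(G, "g", "v1")
  expect_identical(a$groups$hap_string[a$groups$label == "H1"], "A")
  expect_equal(a$groups$percent, c(90, 10))
})

test_that("missing or heterozygous sites give a missing haplotype", {
  G <- hap_toy_G(c("AA", "TT"), sizes = c(4, 4))
  G$dosage[1, 2] <- NA
  G$dosage[5, 1] <- 1
  a <- suppressMessages(call_haplotypes(G, "g", c("v1", "v2")))
  expect_true(is.na(a$labels[1]) && is.na(a$labels[5]))
  expect_equal(sum(a$groups$count), 6)
  # percent denominators still use the full panel
  expect_equal(sum(a$groups$percent), 100 * 6 / 8)
})

test_that("rare-haplotype exclusion keeps groups with more than three members", {
  G <- hap_toy_G(c("AAA", "TTT", "ATT"), sizes = c(12, 4, 3))
  a <- call_haplotypes(G, "g", c("v1", "v2", "v3"))
  af <- suppressMessages(filter_rare_haplotypes(a))
  expect_setequal(af$groups$label, c("H1", "H2"))  # the 3-member group goes
  expect_true(all(is.na(af$labels_retained[af$labels == "H3"])))
  # percent mode: 1% of 19 accessions keeps everything here
  ap <- filter_rare_haplotypes(a, mode = "percent", min_percent = 1)
  expect_equal(nrow(ap$groups), 3)
  # all groups rare -> error
  G2 <- hap_toy_G(c("AA", "TT"), sizes = c(2, 2))
  a2 <- call_haplotypes(G2, "g", c("v1", "v2"))
  expect_error(filter_rare_haplotypes(a2), "no analyzable")
})

test_that("pooled t-test matches the closed-form t distribution", {
  x <- c(5.1, 4.8, 5.6, 5.0, 5.3)
  y <- c(4.2, 4.6, 4.1, 4.4, 4.0)
  p <- two_group_test(x, y)
  sp2 <- (sum((x - mean(x))^2) + sum((y - mean(y))^2)) / 8
  tstat <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / 5 + 1 / 5))
  expect_equal(p, 2 * pt(-abs(tstat), df = 8), tolerance = 1e-10)
  expect_equal(two_group_test(y, x), p, tolerance = 1e-12)
  expect_equal(two_group_test(x, x), 1)
  expect_warning(p0 <- two_group_test(c(1, 1), c(2, 2)), "zero")
  expect_equal(p0, 0)
})

test_that("two-group t and one-way F agree (t^2 = F)", {
  set.seed(17)
  g1 <- rnorm(9, 10); g2 <- rnorm(7, 11)
  p_t <- two_group_test(g1, g2)
  ve <- variance_explained(list(a = g1, b = g2))
  expect_equal(p_t, ve$p, tolerance = 1e-12)
})

test_that("Duncan letters: degenerate and well-separated cases", {
  set.seed(4)
  same <- lapply(1:4, function(i) rnorm(6, 10, 0.5))
  same <- lapply(same, function(x) x - mean(x) + 10)  # identical means
  dl <- duncan_letters(same)
  expect_true(all(dl$letters == "a"))
  far <- list(a = rnorm(6, 0, 0.01), b = rnorm(6, 0.1, 0.01),
              c = rnorm(6, 50, 0.01))
  dl2 <- duncan_letters(far)
  expect_equal(length(unique(dl2$letters)), 3)
  expect_error(duncan_letters(far[1:2]), "two_group_test")
})

test_that("Duncan letter display matches the span-enumeration oracle", {
  set.seed(8)
  for (rep in 1:12) {
    k <- sample(3:6, 1)
    values <- lapply(seq_len(k), function(i) {
      rnorm(sample(4:10, 1), mean = sample(c(0, 0.4, 1, 3), 1), sd = 1)
    })
    names(values) <- paste0("g", seq_len(k))
    dl <- duncan_letters(values, alpha = 0.05)
    crit <- attr(dl, "critical_ranges")
    ns <- duncan_oracle_ns(dl$mean, crit)
    # two groups share a letter exactly when the oracle calls them NS
    for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
      shared <- length(intersect(strsplit(dl$letters[i], "")[[1]],
                                 strsplit(dl$letters[j], "")[[1]])) > 0
      expect_identical(shared, ns[i, j],
                       label = sprintf("rep %d pair (%d,%d)", rep, i, j))
    }
  }
})

test_that("variance explained is the one-way eta-squared", {
  set.seed(23)
  vals <- list(a = rnorm(20, 10), b = rnorm(25, 11), c = rnorm(15, 9))
  ve <- variance_explained(vals)
  # direct SS decomposition, written independently
  y <- unlist(vals); g <- rep(names(vals), lengths(vals))
  ssb <- sum(tapply(y, g, function(v) length(v) * (mean(v) - mean(y))^2))
  expect_equal(ve$r2, 100 * ssb / sum((y - mean(y))^2), tolerance = 1e-10)
  # degenerate cases
  eq <- list(a = c(1, 2, 3), b = c(3, 2, 1))
  expect_equal(variance_explained(eq)$r2, 0, tolerance = 1e-12)
  pure <- list(a = rep(1, 4), b = rep(2, 4))
  expect_equal(variance_explained(pure)$r2, 100)
  expect_warning(variance_explained(list(a = rep(1, 3), b = rep(1, 3))),
                 "zero")
})

test_that("eta-squared approaches the closed-form two-group limit", {
  set.seed(31)
  d <- 1.3
  vals <- list(a = rnorm(6000, 0), b = rnorm(6000, d))
  ve <- variance_explained(vals)
  expect_equal(ve$r2, 100 * d^2 / (d^2 + 4), tolerance = 0.06)
})

test_that("superior haplotype follows direction with ties to larger groups", {
  gs <- data.frame(label = c("H1", "H2"), mean = c(9.01, 8.34),
                   count = c(171, 9))
  expect_identical(superior_haplotype(gs, "maximize"), "H1")
  expect_identical(superior_haplotype(gs, "minimize"), "H2")
  gs2 <- data.frame(label = c("H1", "H2", "H3"), mean = c(5, 5, 4),
                    count = c(10, 30, 50))
  expect_message(lab <- superior_haplotype(gs2, "maximize"), "tie")
  expect_identical(lab, "H2")
})

test_that("haplotype combinations enumerate tuples and degenerate to one gene", {
  G1 <- hap_toy_G(c("A", "T"), sizes = c(12, 8))
  G2 <- hap_toy_G(c("A", "T"), sizes = c(10, 10))
  G2$variants$ref <- "C"; G2$variants$alt <- "G"
  G2$variants$id <- "w1"; G2$variants$pos <- 5000L
  a1 <- call_haplotypes(G1, "gA", "v1")
  a2 <- call_haplotypes(genotype_matrix(G2$dosage, G2$variants), "gB", "w1")
  comb <- combine_haplotypes(list(a1, a2))
  expect_lte(nrow(comb$groups), 4)
  expect_lte(sum(comb$groups$count), comb$panel_size)
  expect_true(all(grepl("^HC", comb$groups$label)))
  expect_true(all(grepl("/", comb$groups$component)))
  # frequencies are non-increasing in label order
  expect_true(all(diff(comb$groups$count) <= 0))
  # single-gene combination is the single-gene assignment
  expect_identical(combine_haplotypes(list(a1))$groups, a1$groups)
})

test_that("combining a causal with a non-causal gene cannot lower R2", {
  set.seed(61)
  # gene A causal (two haplotypes, planted gap), gene B pure noise
  GA <- hap_toy_G(c("A", "T"), sizes = c(40, 40))
  GB <- hap_toy_G(c("A", "T"), sizes = c(45, 35))
  GB$variants$id <- "w1"; GB$variants$ref <- "C"; GB$variants$alt <- "G"
  GB$variants$pos <- 9000L
  GB <- genotype_matrix(GB$dosage[sample(80), , drop = FALSE], GB$variants)
  aA <- call_haplotypes(GA, "gA", "v1")
  aB <- call_haplotypes(GB, "gB", "w1")
  y <- setNames(rnorm(80) + ifelse(aA$labels == "H2", 1.5, 0),
                names(aA$labels))
  rA <- variance_explained(split(y[names(aA$labels)], aA$labels))$r2
  rB <- variance_explained(split(y[names(aB$labels)], aB$labels))$r2
  comb <- combine_haplotypes(list(aA, aB))
  rC <- variance_explained(split(y[names(comb$labels)], comb$labels))$r2
  expect_gte(rC, rB - 1e-9)  # refinement cannot lose between-group SS
  expect_gte(rC, rA - 1e-9)
})

test_that("haplo_pheno assembles the full group report", {
  set.seed(77)
  G <- hap_toy_G(c("AAT", "TTA", "TAA"), sizes = c(80, 60, 40))
  a <- call_haplotypes(G, "g", c("v1", "v2", "v3"))
  shift <- c(H1 = 0, H2 = 1.2, H3 = 0.4)
  y <- setNames(rnorm(180, 10, 0.8) + shift[a$labels], names(a$labels))
  hp <- haplo_pheno(a, y, direction = "maximize")
  expect_s3_class(hp, "haplo_pheno_result")
  expect_identical(hp$superior, "H2")
  expect_equal(nrow(hp$table), 3)
  expect_true(all(c("count", "percent", "mean", "letters") %in%
                    names(hp$table)))
  expect_true(hp$r2 > 0 && hp$r2 < 100)
  expect_lt(hp$p_overall, 1e-6)
  # two-group path reports the pairwise Student p
  G2 <- hap_toy_G(c("A", "T"), sizes = c(100, 80))
  a2 <- call_haplotypes(G2, "g2", "v1")
  y2 <- setNames(rnorm(180, 10) + ifelse(a2$labels == "H2", 0.8, 0),
                 names(a2$labels))
  hp2 <- haplo_pheno(a2, y2, direction = "minimize")
  expect_identical(hp2$superior, "H1")
  expect_false(is.na(hp2$p_pairwise))
})
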