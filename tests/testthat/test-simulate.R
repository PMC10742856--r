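small_trait <- function() {
  list(T1 = list(mu = 10, Vg_bg = 1, env_effects = c(env1 = 0, env2 = 0.5),
                 Vge = 0, Ve = 0.5, r = 1L, direction = "maximize"))
}

test_that("configuration invariants are enforced", {
  expect_error(sim_config(founders_per_gene = 1), ">= 2")
  expect_error(sim_config(n_accessions = 3, founders_per_gene = 5,
                          causal_spec = list(), trait_spec = small_trait()),
               "exceed")
  expect_error(sim_config(missing_rate = 1.5), "\\[0, 1\\]")
  expect_error(sim_config(causal_spec = list(
    list(gene = "gene01", trait = "nope", effects = c(0, 1))),
    trait_spec = small_trait()), "absent from trait_spec")
  expect_error(sim_config(trait_spec = list(
    T1 = list(mu = 0, Vg_bg = -1, env_effects = 0, Ve = 1))), ">= 0")
})

test_that("same seed and config give byte-identical fixtures", {
  cfg <- sim_config(n_accessions = 20, n_genes = 3, sites_per_gene = 5,
                    causal_spec = list(), trait_spec = small_trait(),
                    missing_rate = 0.02, qc_fail_fraction = 0.1, seed = 55)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  s1 <- simulate_study(cfg); s2 <- simulate_study(cfg)
  p1 <- write_fixture(d1, s1$genotypes, s1$genes, s1$phenotypes, s1$truth)
  p2 <- write_fixture(d2, s2$genotypes, s2$genes, s2$phenotypes, s2$truth)
  for (f in names(p1)) {
    expect_identical(readLines(p1[f]), readLines(p2[f]), label = f)
  }
})

test_that("full inbreeding yields homozygous dosages; founders bound haplotypes", {
  cfg <- sim_config(n_accessions = 40, n_genes = 4, sites_per_gene = 6,
                    founders_per_gene = 2, inbreeding = 1, missing_rate = 0,
                    causal_spec = list(), trait_spec = small_trait(),
                    seed = 12)
  panel <- simulate_panel(cfg)
  expect_true(all(panel$genotypes$dosage %in% c(0, 2)))
  # at most 2 distinct haplotype strings per gene
  for (g in panel$genes$gene) {
    ids <- panel$genotypes$variants$id[
      assign_gene(panel$genotypes$variants, panel$genes) == g]
    a <- call_haplotypes(panel$genotypes, g, ids)
    expect_lte(nrow(a$groups), 2)
  }
  # every variant lies within its gene's promoter-to-transcript span
  expect_false(anyNA(assign_gene(panel$genotypes$variants, panel$genes)))
})

test_that("realized founder frequencies track the configured frequencies", {
  freqs <- c()
  for (s in 1:3) {
    cfg <- sim_config(n_accessions = 700, n_genes = 2, sites_per_gene = 3,
                      founders_per_gene = 2, founder_freq = c(0.8, 0.2),
                      subpop_divergence = 0, causal_spec = list(),
                      trait_spec = small_trait(), seed = 700 + s)
    panel <- simulate_panel(cfg)
    freqs <- c(freqs, colMeans(panel$truth$assignment == 2))
  }
  expect_true(all(abs(freqs - 0.2) < 0.05))
  expect_lt(abs(mean(freqs) - 0.2), 0.03)
})

test_that("degenerate phenotype model returns mu plus environment exactly", {
  cfg <- sim_config(n_accessions = 15, n_genes = 2, sites_per_gene = 4,
                    causal_spec = list(),
                    trait_spec = list(T1 = list(
                      mu = 10, Vg_bg = 0, env_effects = c(a = 0, b = 2),
                      Vge = 0, Ve = 0, r = 1L, direction = "maximize")),
                    seed = 9)
  st <- simulate_study(cfg)
  ph <- st$phenotypes
  expect_equal(ph$value[ph$environment == "a"], rep(10, 15))
  expect_equal(ph$value[ph$environment == "b"], rep(12, 15))
})

test_that("planted effects reproduce the configured group mean difference", {
  cfg <- sim_config(n_accessions = 1500, n_genes = 2, sites_per_gene = 4,
                    founders_per_gene = 2, founder_freq = c(0.5, 0.5),
                    subpop_divergence = 0,
                    causal_spec = list(list(gene = "gene01", trait = "T1",
                                            effects = c(0, 4))),
                    trait_spec = list(T1 = list(
                      mu = 10, Vg_bg = 0, env_effects = c(e1 = 0, e2 = 0),
                      Vge = 0, Ve = 1, r = 1L, direction = "maximize")),
                    seed = 44)
  st <- simulate_study(cfg)
  f <- st$truth$assignment[, "gene01"]
  acc_mean <- tapply(st$phenotypes$value, st$phenotypes$accession, mean)
  acc_mean <- acc_mean[rownames(st$truth$assignment)]
  gap <- mean(acc_mean[f == 2]) - mean(acc_mean[f == 1])
  expect_lt(abs(gap - 4), 3 * sqrt(4 / 1500 * 0.5))
  expect_identical(st$truth$causal[[1]]$superior_founder, 2L)
})

test_that("realized background genetic variance matches the configuration", {
  # with Ve ~ 0 the per-environment values expose g directly
  devs <- sapply(1:30, function(s) {
    cfg <- sim_config(n_accessions = 120, n_genes = 3, sites_per_gene = 4,
                      causal_spec = list(),
                      trait_spec = list(T1 = list(
                        mu = 0, Vg_bg = 2, env_effects = c(e1 = 0),
                        Vge = 0, Ve = 1e-8, r = 1L,
                        direction = "maximize")),
                      seed = 3000 + s)
    st <- simulate_study(cfg)
    var(st$phenotypes$value)
  })
  se <- sd(devs) / sqrt(length(devs))
  expect_lt(abs(mean(devs) - 2), 3 * se + 0.02)
})

test_that("zero divergence leaves subpopulation founder frequencies exchangeable", {
  pvals <- sapply(1:15, function(s) {
    cfg <- sim_config(n_accessions = 240, n_genes = 1, sites_per_gene = 3,
                      founders_per_gene = 2, subpop_divergence = 0,
                      causal_spec = list(), trait_spec = small_trait(),
                      seed = 5000 + s)
    panel <- simulate_panel(cfg)
    tab <- table(panel$truth$assignment[, 1], panel$truth$subpop)
    suppressWarnings(chisq.test(tab)$p.value)
  })
  # calibrated null p-values: few small ones, not clustered at 0
  expect_lte(sum(pvals < 0.01), 2)
  expect_gt(mean(pvals), 0.2)
})

test_that("iid background gives marker-independent genetic values", {
  ts <- small_trait()
  ts$T1$bg <- "iid"
  ts$T1$Ve <- 1e-8
  ts$T1$Vg_bg <- 2
  cfg <- sim_config(n_accessions = 200, n_genes = 3, sites_per_gene = 4,
                    causal_spec = list(), trait_spec = ts, seed = 17)
  st <- simulate_study(cfg)
  v <- var(st$phenotypes$value[st$phenotypes$environment == "env1"])
  expect_lt(abs(v - 2), 3 * 2 * sqrt(2 / 199))
  expect_error(sim_config(trait_spec = list(T1 = list(
    mu = 0, Vg_bg = 1, env_effects = 0, Ve = 1, bg = "nope"))),
    "'kinship' or 'iid'")
})

test_that("truth JSON records the configured causal genes", {
  cfg <- sim_config(n_accessions = 20, n_genes = 3, sites_per_gene = 4,
                    founders_per_gene = 2,
                    causal_spec = list(list(gene = "gene02", trait = "T1",
                                            effects = c(1, 0))),
                    trait_spec = small_trait(), seed = 66)
  st <- simulate_study(cfg)
  d <- withr::local_tempdir()
  paths <- write_fixture(d, st$genotypes, st$genes, st$phenotypes, st$truth)
  tj <- jsonlite::read_json(paths["truth"])
  expect_equal(vapply(tj$causal, function(x) x$gene, ""), "gene02")
  expect_equal(tj$causal[[1]]$superior_founder, 1)
  expect_true("realized_h2" %in% names(tj))
})
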