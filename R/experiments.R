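# Calibration experiments: repeatable simulation studies that measure the
# operating characteristics of the pipeline (type-I error of the scan,
# superior-haplotype recovery, heritability recovery) under known truth.
# They are used by the test suite and by scripts/acceptance.R, and are
# exported so users can rerun them at other settings.

#' Type-I error of the consistency-scan under a null panel
#'
#' Simulates panels with no planted haplotype effects and independent
#' accession-level noise (the genetic term is i.i.d., uncorrelated with
#' the markers), scans every dataset (each environment and the BLUPs)
#' with the exact mixed model, and measures the fraction of
#' variant-dataset tests with p below `alpha`. Panels carry
#' subpopulation structure and use one variant site per gene so that
#' test statistics are close to independent across genes.
#'
#' `background = "kinship"` runs the harder null in which the genetic
#' term is drawn from the marker kinship itself; with only a few hundred
#' candidate-gene markers in `K` the structure correction is then
#' slightly imperfect and the measured rate sits near 0.011 rather than
#' 0.010 (see the methods vignette).
#'
#' @param n_panels Number of simulated panels.
#' @param seed0 Base seed; panel `i` uses `seed0 + i`.
#' @param alpha Nominal per-test level (default 0.01).
#' @param n_genes Genes (= variant sites) per panel.
#' @param background `"iid"` (independent noise null) or `"kinship"`.
#' @return List with `rate`, `n_tests`, `n_included`, `alpha`.
#' @export
experiment_type1 <- function(n_panels = 12L, seed0 = 1000L, alpha = 0.01,
                             n_genes = 340L,
                             background = c("iid", "kinship")) {
  background <- match.arg(background)
  n_inc <- 0L; n_tot <- 0L
  for (i in seq_len(n_panels)) {
    cfg <- sim_config(
      n_accessions = 180, n_genes = n_genes, sites_per_gene = 1,
      founders_per_gene = 2, subpop_divergence = 0.15,
      causal_spec = list(),
      trait_spec = list(NT = list(
        mu = 10, Vg_bg = 1, env_effects = c(env1 = 0, env2 = 0.3),
        Vge = 0, Ve = 0.5, r = 1L, direction = "maximize",
        bg = background)),
      seed = seed0 + i)
    st <- simulate_study(cfg)
    K <- centered_kinship(st$genotypes)
    vc <- variance_components(st$phenotypes, "NT")
    ys <- dataset_values(st$phenotypes, "NT", vc)
    for (y in ys) {
      sc <- lmm_scan(y, st$genotypes, K)
      ok <- is.na(sc$skipped)
      n_inc <- n_inc + sum(sc$p[ok] < alpha)
      n_tot <- n_tot + sum(ok)
    }
  }
  list(rate = n_inc / n_tot, n_tests = n_tot, n_included = n_inc,
       alpha = alpha)
}

#' Configuration of the superior-haplotype recovery experiment
#'
#' One causal gene among 42, two equifrequent founder haplotypes, and a
#' planted effect equal to one phenotypic standard deviation under a
#' broad-sense heritability of 0.85 over two environments. With background
#' polygenic variance fixed at 1, those two constraints force the planted
#' gap `delta = sqrt(92/45)` and residual variance `Ve = 24/45`; the
#' population eta-squared of the causal haplotype split on accession means
#' is then `100 * d^2 / (d^2 + 4)` with `d^2 = 92/57` (28.75%).
#'
#' @param seed Simulation seed.
#' @return A [sim_config()].
#' @export
recovery_config <- function(seed) {
  delta <- sqrt(92 / 45)
  sim_config(
    n_accessions = 180, n_genes = 42, sites_per_gene = 8,
    founders_per_gene = 2, founder_freq = c(0.5, 0.5),
    subpop_divergence = 0.15,
    causal_spec = list(list(gene = "gene01", trait = "CT",
                            effects = c(0, delta))),
    trait_spec = list(CT = list(
      mu = 10, Vg_bg = 1, env_effects = c(env1 = 0, env2 = 0.3),
      Vge = 0, Ve = 24 / 45, r = 1L, direction = "maximize")),
    seed = seed)
}

#' Analytic eta-squared limit of the recovery experiment
#' @return Percent of variance explained expected for the causal gene.
#' @export
recovery_r2_limit <- function() {
  d2 <- (92 / 45) / (57 / 45)  # squared gap over within-group variance
  100 * d2 / (d2 + 4)
}

#' Superior-haplotype recovery across simulated panels
#'
#' Runs the full analysis on [recovery_config()] panels: kinship from the
#' LD-pruned set, exact mixed-model scans of both environments and the
#' BLUPs, the p < alpha consistency rule, haplotype calling at the causal
#' gene from its associated variants, and superior-group identification on
#' BLUP values. A panel counts as recovered when the superior haplotype
#' group is exactly the set of accessions carrying the planted superior
#' founder haplotype.
#'
#' @param n_seeds Number of panels.
#' @param seed0 Base seed; panel `i` uses `seed0 + i`.
#' @param alpha Consistency-rule threshold.
#' @return List with `n_recovered`, `n_seeds`, `r2` (per detected panel),
#'   `r2_mean`, `r2_limit`.
#' @export
experiment_recovery <- function(n_seeds = 100L, seed0 = 2000L,
                                alpha = 0.01) {
  rec <- 0L; r2s <- numeric(0)
  for (i in seq_len(n_seeds)) {
    st <- simulate_study(recovery_config(seed0 + i))
    G <- st$genotypes
    Gp <- subset_variants(G, ld_prune(G))
    K <- centered_kinship(Gp)
    vc <- variance_components(st$phenotypes, "CT")
    ys <- dataset_values(st$phenotypes, "CT", vc)
    scans <- lapply(ys, function(y) lmm_scan(y, G, K))
    assoc <- consistent_associations(scans, alpha = alpha,
                                     genes = st$genes, G = G)
    hits <- assoc$id[assoc$consistent & !is.na(assoc$gene) &
                       assoc$gene == "gene01"]
    if (length(hits) == 0) next
    a <- call_haplotypes(G, "gene01", hits)
    hp <- haplo_pheno(a, ys$BLUP, direction = "maximize")
    sup_acc <- names(a$labels)[!is.na(a$labels) & a$labels == hp$superior]
    truth_sup <- st$truth$causal[[1]]$superior_founder
    truth_acc <- rownames(st$truth$assignment)[
      st$truth$assignment[, "gene01"] == truth_sup]
    if (setequal(sup_acc, truth_acc)) rec <- rec + 1L
    r2s <- c(r2s, hp$r2)
  }
  list(n_recovered = rec, n_seeds = n_seeds, r2 = r2s,
       r2_mean = mean(r2s), r2_limit = recovery_r2_limit())
}

#' Heritability recovery on panels with a configured h2
#'
#' Simulates panels whose generative variance components give a broad-sense
#' heritability of `h2_target` over two environments (one value each) and
#' averages the moment-estimator heritability across seeds.
#'
#' @param n_seeds Number of panels.
#' @param seed0 Base seed.
#' @param h2_target Configured heritability (default 0.85, via `Vg = 4`
#'   and `Ve` solved from the two-environment formula).
#' @return List with `h2_hat` (per seed), `mean`, `target`.
#' @export
experiment_h2 <- function(n_seeds = 50L, seed0 = 3000L, h2_target = 0.85) {
  Vg <- 4
  Ve <- 2 * Vg * (1 - h2_target) / h2_target
  est <- vapply(seq_len(n_seeds), function(i) {
    cfg <- sim_config(
      n_accessions = 180, n_genes = 12, sites_per_gene = 4,
      causal_spec = list(),
      trait_spec = list(HT = list(
        mu = 10, Vg_bg = Vg, env_effects = c(env1 = 0, env2 = 0.5),
        Vge = 0, Ve = Ve, r = 1L, direction = "maximize")),
      seed = seed0 + i)
    st <- simulate_study(cfg)
    heritability(variance_components(st$phenotypes, "HT"))
  }, numeric(1))
  list(h2_hat = est, mean = mean(est), target = h2_target)
}
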