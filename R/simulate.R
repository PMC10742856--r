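# Synthetic inbred diversity panels with gene-structured variants, founder
# haplotype mosaics, subpopulation divergence and multi-environment
# phenotypes with planted haplotype effects. Stands in for real targeted
# resequencing panels, which are rarely deposited; every planted quantity
# is recorded in a truth table so recovery can be scored.

dirichlet1 <- function(alpha) {
  x <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(x) == 0) x <- alpha / sum(alpha) else x <- x / sum(x)
  x
}

#' Simulation configuration
#'
#' Defaults emulate a targeted-capture diversity panel of a selfing crop:
#' 180 fully inbred accessions, 42 candidate genes with a handful of
#' founder haplotypes each, three subpopulations, two trial years with one
#' pooled value per accession and year, four correlated grain-morphology
#' traits (length, width, length/width ratio, thousand-grain weight) with
#' high broad-sense heritability, and one to five causal genes per trait
#' whose haplotype effects are planted in trait units.
#'
#' @param n_accessions Number of inbred accessions.
#' @param n_genes Number of candidate genes.
#' @param founders_per_gene Founder haplotypes per gene (scalar or vector
#'   of length `n_genes`; each >= 2).
#' @param sites_per_gene Variant sites per gene (promoter through
#'   transcript end).
#' @param n_subpops Number of subpopulations.
#' @param subpop_props Subpopulation proportions (default 39/58/83 out of
#'   180-style split, rescaled).
#' @param subpop_divergence Balding-Nichols-style divergence F in
#'   `[0, 0.99]`: founder frequencies per subpopulation are drawn from a
#'   Dirichlet centered on the panel-wide frequencies with concentration
#'   `(1 - F) / F`. 0 = identical frequencies in all subpopulations.
#' @param founder_freq Optional panel-wide founder frequencies (vector
#'   summing to 1, recycled over genes); default: Dirichlet(1) per gene.
#' @param causal_spec List of planted effects: each element
#'   `list(gene =, trait =, effects =)` with one additive effect (trait
#'   units) per founder haplotype of that gene.
#' @param trait_spec Named list per trait:
#'   `list(mu =, Vg_bg =, env_effects =, Vge =, Ve =, r =, direction =)`.
#'   `Vg_bg` is the background polygenic variance, drawn with covariance
#'   proportional to the realized kinship of the trait's non-causal genes
#'   (`bg = "kinship"`, the default) or i.i.d. across accessions
#'   (`bg = "iid"`); `env_effects` are the fixed environment mean offsets
#'   (length = number of environments), `r` the replicates per environment
#'   (default 1, one pooled value per year) and `direction` the breeding
#'   direction.
#' @param inbreeding Probability that an accession's two gene copies come
#'   from the same founder (1 = fully homozygous).
#' @param missing_rate Fraction of dosage entries set to missing.
#' @param qc_fail_fraction Fraction of variant records planted to fail
#'   each site-quality hard-filter criterion.
#' @param seed Integer seed; same seed and config give byte-identical
#'   output.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_accessions = 180L,
                       n_genes = 42L,
                       founders_per_gene = 3L,
                       sites_per_gene = 8L,
                       n_subpops = 3L,
                       subpop_props = NULL,
                       subpop_divergence = 0.15,
                       founder_freq = NULL,
                       causal_spec = default_causal_spec(),
                       trait_spec = default_trait_spec(),
                       inbreeding = 1,
                       missing_rate = 0,
                       qc_fail_fraction = 0,
                       seed = 1L) {
  if (is.null(subpop_props)) {
    subpop_props <- if (n_subpops == 3) c(39, 58, 83) / 180 else
      rep(1 / n_subpops, n_subpops)
  }
  founders_per_gene <- as.integer(rep(founders_per_gene,
                                      length.out = n_genes))
  if (any(founders_per_gene < 2)) {
    stop("founders_per_gene must be >= 2")
  }
  if (any(founders_per_gene > n_accessions)) {
    stop("founders_per_gene cannot exceed n_accessions")
  }
  stopifnot(length(subpop_props) == n_subpops,
            abs(sum(subpop_props) - 1) < 1e-8)
  for (fr in list(inbreeding, missing_rate, qc_fail_fraction)) {
    if (fr < 0 || fr > 1) stop("fractions must lie in [0, 1]")
  }
  if (subpop_divergence < 0 || subpop_divergence > 0.99) {
    stop("subpop_divergence must lie in [0, 0.99]")
  }
  for (tr in names(trait_spec)) {
    ts <- trait_spec[[tr]]
    if (is.null(ts$r)) trait_spec[[tr]]$r <- 1L
    if (is.null(ts$Vge)) trait_spec[[tr]]$Vge <- 0
    if (is.null(ts$direction)) trait_spec[[tr]]$direction <- "maximize"
    if (is.null(ts$bg)) trait_spec[[tr]]$bg <- "kinship"
    if (!trait_spec[[tr]]$bg %in% c("kinship", "iid")) {
      stop("trait bg must be 'kinship' or 'iid'")
    }
    if (any(c(ts$Vg_bg, trait_spec[[tr]]$Vge, ts$Ve) < 0)) {
      stop("variance components must be >= 0 (trait ", tr, ")")
    }
    if (length(ts$env_effects) < 1) stop("need >= 1 environment")
  }
  for (cs in causal_spec) {
    if (!cs$trait %in% names(trait_spec)) {
      stop("causal trait ", cs$trait, " absent from trait_spec")
    }
  }
  if (!is.null(founder_freq) &&
      abs(sum(founder_freq) - 1) > 1e-8) {
    stop("founder_freq must sum to 1")
  }
  seed <- as.integer(seed)
  if (is.na(seed) || seed < 0 || seed > 2^31 - 10) {
    stop("seed must be a non-negative integer below 2^31 - 10")
  }
  structure(list(
    n_accessions = as.integer(n_accessions),
    n_genes = as.integer(n_genes),
    founders_per_gene = founders_per_gene,
    sites_per_gene = as.integer(sites_per_gene),
    n_subpops = as.integer(n_subpops),
    subpop_props = subpop_props,
    subpop_divergence = subpop_divergence,
    founder_freq = founder_freq,
    causal_spec = causal_spec,
    trait_spec = trait_spec,
    inbreeding = inbreeding,
    missing_rate = missing_rate,
    qc_fail_fraction = qc_fail_fraction,
    seed = seed), class = "sim_config")
}

#' Default planted causal effects
#'
#' Five causal genes spread over four traits, with effect sizes on the
#' scale of published haplotype-group mean gaps for grain traits (tenths
#' of a millimeter for grain dimensions, grams for thousand-grain weight).
#' Two genes are pleiotropic: gene01 affects length and length/width,
#' gene03 affects width, length/width and weight.
#'
#' @return List of causal-effect entries for [sim_config()].
#' @export
default_causal_spec <- function() {
  list(
    list(gene = "gene01", trait = "GL", effects = c(0, -0.67, -0.25)),
    list(gene = "gene02", trait = "GL", effects = c(0, -1.11, -0.50)),
    list(gene = "gene03", trait = "GW", effects = c(0.43, 0, 0.20)),
    list(gene = "gene01", trait = "LW", effects = c(0, -0.37, -0.15)),
    list(gene = "gene03", trait = "LW", effects = c(-0.73, 0, -0.30)),
    list(gene = "gene04", trait = "TGW", effects = c(2.96, 0, 1.50)),
    list(gene = "gene05", trait = "TGW", effects = c(3.89, 0, 2.00)),
    list(gene = "gene03", trait = "TGW", effects = c(2.48, 0, 1.00)),
    list(gene = "gene06", trait = "TGW", effects = c(0, 3.89, 2.00)),
    list(gene = "gene07", trait = "TGW", effects = c(0, 3.20, 1.50)))
}

#' Default trait specification
#'
#' Four grain-morphology traits with background polygenic and residual
#' variances tuned so that broad-sense heritability over two trial years
#' (one pooled value per year) lands in the 0.8-0.95 range typical of
#' grain-size traits.
#'
#' @return Named list of trait specifications for [sim_config()].
#' @export
default_trait_spec <- function() {
  list(
    GL = list(mu = 8.9, Vg_bg = 0.25, env_effects = c(env1 = 0, env2 = 0.10),
              Vge = 0, Ve = 0.07, r = 1L, direction = "maximize"),
    GW = list(mu = 2.8, Vg_bg = 0.03, env_effects = c(env1 = 0, env2 = -0.03),
              Vge = 0, Ve = 0.016, r = 1L, direction = "maximize"),
    LW = list(mu = 3.3, Vg_bg = 0.08, env_effects = c(env1 = 0, env2 = 0.05),
              Vge = 0, Ve = 0.036, r = 1L, direction = "maximize"),
    TGW = list(mu = 25, Vg_bg = 3, env_effects = c(env1 = 0, env2 = 0.80),
               Vge = 0, Ve = 5.0, r = 1L, direction = "maximize"))
}

# Random gene structure on a 12-chromosome genome: promoter (2000 bp),
# UTRs, 2-3 exons with a CDS whose length is a multiple of 3.
simulate_gene_structure <- function(i) {
  chrom <- sprintf("chr%02d", (i - 1L) %% 12L + 1L)
  slot <- (i - 1L) %/% 12L
  tx_start <- 50000L + slot * 60000L
  u5 <- sample(50:300, 1)
  u3 <- sample(50:300, 1)
  cds_len <- 3L * sample(150:400, 1)
  exonic <- u5 + cds_len + u3
  n_exons <- sample(2:3, 1)
  cuts <- sort(sample(seq(100L, exonic - 100L), n_exons - 1L))
  exon_len <- diff(c(0L, cuts, exonic))
  intron_len <- sample(100:800, n_exons - 1L, replace = TRUE)
  exon_starts <- integer(n_exons)
  exon_ends <- integer(n_exons)
  pos <- tx_start
  for (e in seq_len(n_exons)) {
    exon_starts[e] <- pos
    exon_ends[e] <- pos + exon_len[e] - 1L
    pos <- exon_ends[e] + 1L + if (e < n_exons) intron_len[e] else 0L
  }
  # genomic coordinate of the j-th exonic base
  exonic_pos <- unlist(mapply(seq, exon_starts, exon_ends,
                              SIMPLIFY = FALSE))
  cds_start <- exonic_pos[u5 + 1L]
  cds_end <- exonic_pos[u5 + cds_len]
  strand <- sample(c("+", "-"), 1)
  bases <- c("A", "C", "G", "T")
  cds_bases <- sample(bases, cds_len, replace = TRUE)
  cds_seq <- if (strand == "+") paste(cds_bases, collapse = "") else
    paste(rev(chartr("ACGT", "TGCA", cds_bases)), collapse = "")
  list(row = data.frame(
         gene = sprintf("gene%02d", i), chrom = chrom, strand = strand,
         tx_start = tx_start, tx_end = exon_ends[n_exons],
         cds_start = cds_start, cds_end = cds_end,
         exon_starts = paste(exon_starts, collapse = ","),
         exon_ends = paste(exon_ends, collapse = ","),
         cds_seq = cds_seq, stringsAsFactors = FALSE),
       cds_pos = exonic_pos[(u5 + 1L):(u5 + cds_len)],
       cds_bases = cds_bases)
}

#' Simulate an inbred candidate-gene panel
#'
#' Generates gene models, founder haplotypes, subpopulation-structured
#' founder frequencies (Balding-Nichols-style Dirichlet perturbation of
#' panel-wide frequencies) and per-accession genotypes. Each accession
#' carries whole founder haplotypes at each gene (no intra-gene
#' recombination); with `inbreeding = 1` both copies come from one founder
#' and all dosages are homozygous. Site-quality annotations (QUAL, QD, FS,
#' MQ) are drawn from passing distributions, with `qc_fail_fraction` of
#' records planted to fail each hard-filter criterion.
#'
#' @param config A [sim_config()].
#' @return List with `genotypes` (a [genotype_matrix()]), `genes` (gene
#'   model table with CDS sequences) and `truth` (founder haplotypes,
#'   per-accession founder assignment, subpopulation labels, causal genes
#'   and their true superior haplotypes).
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_accessions
  acc <- sprintf("acc%03d", seq_len(n))
  subpop_counts <- diff(round(cumsum(c(0, config$subpop_props)) * n))
  subpop <- rep(seq_len(config$n_subpops), subpop_counts)
  names(subpop) <- acc
  bases <- c("A", "C", "G", "T")
  genes <- list(); var_list <- list(); dos_list <- list()
  founders <- list()
  assign1 <- matrix(NA_integer_, n, config$n_genes)
  assign2 <- matrix(NA_integer_, n, config$n_genes)
  F <- config$subpop_divergence
  for (i in seq_len(config$n_genes)) {
    gs <- simulate_gene_structure(i)
    g <- gs$row
    genes[[i]] <- g
    k <- config$founders_per_gene[i]
    m <- config$sites_per_gene
    span <- gene_span(g)  # strand-aware: includes the promoter side
    pos <- sort(sample(seq(span[1], span[2]), m))
    in_cds <- pos %in% gs$cds_pos
    ref <- character(m); alt <- character(m)
    for (j in seq_len(m)) {
      if (in_cds[j]) {
        ref[j] <- gs$cds_bases[match(pos[j], gs$cds_pos)]
        alt[j] <- sample(setdiff(bases, ref[j]), 1)
      } else if (stats::runif(1) < 0.2) {   # indel outside CDS
        ins <- paste(sample(bases, sample(1:3, 1), replace = TRUE),
                     collapse = "")
        anchor <- sample(bases, 1)
        if (stats::runif(1) < 0.5) {
          ref[j] <- anchor; alt[j] <- paste0(anchor, ins)
        } else {
          ref[j] <- paste0(anchor, ins); alt[j] <- anchor
        }
      } else {
        ref[j] <- sample(bases, 1)
        alt[j] <- sample(setdiff(bases, ref[j]), 1)
      }
    }
    # founder haplotypes: distinct allele vectors over the gene's sites
    repeat {
      fa <- matrix(stats::rbinom(k * m, 1, 0.5), nrow = k)
      if (nrow(unique(fa)) == k) break
    }
    p_base <- if (is.null(config$founder_freq)) dirichlet1(rep(1, k)) else
      rep(config$founder_freq, length.out = k)
    p_sub <- matrix(NA_real_, config$n_subpops, k)
    for (s in seq_len(config$n_subpops)) {
      p_sub[s, ] <- if (F == 0) p_base else
        dirichlet1(p_base * (1 - F) / F)
    }
    f1 <- integer(n); f2 <- integer(n)
    for (a in seq_len(n)) {
      pr <- p_sub[subpop[a], ]
      f1[a] <- sample.int(k, 1, prob = pr)
      f2[a] <- if (stats::runif(1) < config$inbreeding) f1[a] else
        sample.int(k, 1, prob = pr)
    }
    assign1[, i] <- f1
    assign2[, i] <- f2
    dos <- fa[f1, , drop = FALSE] + fa[f2, , drop = FALSE]
    founders[[g$gene]] <- list(
      alleles = fa,
      strings = apply(fa, 1, function(z) {
        paste(ifelse(z == 0, ref, alt), collapse = "")
      }),
      base_freq = p_base, subpop_freq = p_sub)
    var_list[[i]] <- data.frame(
      id = sprintf("%s_%d", g$chrom, pos), chrom = g$chrom, pos = pos,
      ref = ref, alt = alt, stringsAsFactors = FALSE)
    dos_list[[i]] <- dos
  }
  genes <- gene_models(do.call(rbind, genes))
  variants <- do.call(rbind, var_list)
  dosage <- do.call(cbind, dos_list)
  rownames(dosage) <- acc
  p_rec <- nrow(variants)
  variants$qual <- round(stats::runif(p_rec, 60, 2000), 2)
  variants$qd <- round(stats::runif(p_rec, 8, 30), 2)
  variants$fs <- round(stats::runif(p_rec, 0, 20), 3)
  variants$mq <- round(stats::runif(p_rec, 50, 60), 2)
  if (config$qc_fail_fraction > 0) {
    f <- config$qc_fail_fraction
    plant <- function(n_) stats::runif(p_rec) < f
    i1 <- plant(); variants$qual[i1] <- round(stats::runif(sum(i1), 2, 29), 2)
    i2 <- plant(); variants$qd[i2] <- round(stats::runif(sum(i2), 0.1, 3.9), 2)
    i3 <- plant(); variants$fs[i3] <- round(stats::runif(sum(i3), 61, 200), 2)
    i4 <- plant(); variants$mq[i4] <- round(stats::runif(sum(i4), 10, 39), 2)
  }
  if (config$missing_rate > 0) {
    dosage[stats::runif(length(dosage)) < config$missing_rate] <- NA
  }
  dimnames(assign1) <- dimnames(assign2) <- list(acc, genes$gene)
  truth <- list(
    founders = founders,
    assignment = assign1,
    assignment2 = assign2,
    subpop = subpop,
    causal = lapply(config$causal_spec, function(cs) {
      dir <- config$trait_spec[[cs$trait]]$direction
      sup <- if (dir == "minimize") which.min(cs$effects) else
        which.max(cs$effects)
      c(cs, list(superior_founder = as.integer(sup)))
    }),
    realized_h2 = NULL)
  list(genotypes = genotype_matrix(dosage, variants), genes = genes,
       truth = truth)
}

# True dosage matrix (no missingness) reconstructed from founder truth,
# used for the kinship of the background polygenic term. Columns are
# labelled by gene so causal genes can be excluded per trait.
truth_dosage <- function(truth) {
  acc <- rownames(truth$assignment)
  cols <- lapply(names(truth$founders), function(g) {
    fa <- truth$founders[[g]]$alleles
    gi <- match(g, colnames(truth$assignment))
    fa[truth$assignment[, gi], , drop = FALSE] +
      fa[truth$assignment2[, gi], , drop = FALSE]
  })
  X <- do.call(cbind, cols)
  rownames(X) <- acc
  attr(X, "gene") <- rep(names(truth$founders),
                         vapply(cols, ncol, integer(1)))
  X
}

# Cholesky-like factor of the background kinship over a gene subset; the
# polygenic deviate is L %*% z with z standard normal.
bg_factor <- function(X, keep_gene) {
  Xb <- X[, attr(X, "gene") %in% keep_gene, drop = FALSE]
  poly <- apply(Xb, 2, function(x) stats::var(x) > 0)
  Xb <- Xb[, poly, drop = FALSE]
  if (ncol(Xb) < 2) return(diag(nrow(X)))  # no usable background loci
  W <- scale(Xb, center = TRUE, scale = FALSE)
  K <- tcrossprod(W) / ncol(W)
  K <- K / mean(diag(K))
  eg <- eigen(K, symmetric = TRUE)
  eg$vectors %*% diag(sqrt(pmax(eg$values, 0)))
}

#' Simulate multi-environment phenotypes with planted haplotype effects
#'
#' Generative model per trait:
#' `y_ijk = mu + g_i + h_i + E_j + (gE)_ij + eps_ijk`, with `g` a
#' background polygenic deviate drawn with covariance proportional to the
#' realized kinship of the simulated genotypes, `h` the sum of planted
#' haplotype effects of the causal genes, `E_j` fixed environment offsets,
#' `(gE)` an interaction deviate with variance `Vge` and `eps` residual
#' noise with variance `Ve` over `r` replicates. Realized broad-sense
#' heritabilities (from realized variance components) are recorded in the
#' returned truth table.
#'
#' @param config A [sim_config()].
#' @param truth Truth table from [simulate_panel()].
#' @return List with `phenotypes` (long-format data frame) and `truth`
#'   (input truth with `realized_h2` filled in).
#' @export
simulate_phenotypes <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  acc <- rownames(truth$assignment)
  n <- length(acc)
  X <- truth_dosage(truth)
  all_genes <- colnames(truth$assignment)
  # The background polygenic term for a trait is drawn from the kinship of
  # the genes that are NOT causal for that trait: the planted haplotype
  # effects carry the causal loci, and loading the background on them too
  # would distort the planted group contrast.
  causal_by_trait <- lapply(
    stats::setNames(names(config$trait_spec), names(config$trait_spec)),
    function(tr) {
      unique(vapply(Filter(function(cs) cs$trait == tr, config$causal_spec),
                    function(cs) cs$gene, character(1)))
    })
  factors <- list()
  records <- list()
  realized <- list()
  for (tr in names(config$trait_spec)) {
    ts <- config$trait_spec[[tr]]
    e <- length(ts$env_effects)
    r <- ts$r
    envs <- names(ts$env_effects)
    if (is.null(envs)) envs <- paste0("env", seq_len(e))
    if (ts$bg == "iid") {
      g_bg <- sqrt(ts$Vg_bg) * stats::rnorm(n)
    } else {
      keep <- setdiff(all_genes, causal_by_trait[[tr]])
      key <- paste(keep, collapse = ",")
      if (is.null(factors[[key]])) factors[[key]] <- bg_factor(X, keep)
      g_bg <- sqrt(ts$Vg_bg) * as.numeric(factors[[key]] %*% stats::rnorm(n))
    }
    h <- rep(0, n)
    for (cs in config$causal_spec) {
      if (cs$trait != tr) next
      gi <- match(cs$gene, colnames(truth$assignment))
      if (is.na(gi)) stop("causal gene ", cs$gene, " not simulated")
      eff <- cs$effects
      if (length(eff) != nrow(truth$founders[[cs$gene]]$alleles)) {
        stop("effects length must equal founders of ", cs$gene)
      }
      h <- h + (eff[truth$assignment[, gi]] +
                  eff[truth$assignment2[, gi]]) / 2
    }
    ge <- matrix(stats::rnorm(n * e, sd = sqrt(ts$Vge)), n, e)
    eps <- array(stats::rnorm(n * e * r, sd = sqrt(ts$Ve)), c(n, e, r))
    for (j in seq_len(e)) {
      for (kk in seq_len(r)) {
        records[[length(records) + 1]] <- data.frame(
          accession = acc, trait = tr, environment = envs[j],
          replicate = kk,
          value = ts$mu + g_bg + h + ts$env_effects[j] + ge[, j] +
            eps[, j, kk],
          stringsAsFactors = FALSE)
      }
    }
    vg_real <- stats::var(g_bg + h)
    vge_real <- if (ts$Vge > 0) stats::var(as.numeric(ge)) else 0
    ve_real <- stats::var(as.numeric(eps))
    realized[[tr]] <- vg_real /
      (vg_real + vge_real / e + ve_real / (r * e))
  }
  truth$realized_h2 <- unlist(realized)
  pheno <- do.call(rbind, records)
  rownames(pheno) <- NULL
  list(phenotypes = pheno, truth = truth)
}

#' Simulate a complete study
#'
#' Convenience wrapper: [simulate_panel()] plus [simulate_phenotypes()].
#'
#' @param config A [sim_config()].
#' @return List with `genotypes`, `genes`, `phenotypes`, `truth`.
#' @export
simulate_study <- function(config) {
  panel <- simulate_panel(config)
  ph <- simulate_phenotypes(config, panel$truth)
  list(genotypes = panel$genotypes, genes = panel$genes,
       phenotypes = ph$phenotypes, truth = ph$truth)
}

#' Write a simulated study to disk as plain-text fixtures
#'
#' Writes `panel.vcf` (VCF 4.2 with QUAL/QD/FS/MQ), `genes.tsv` (gene
#' models), `phenotypes.tsv` (long format) and `truth.json`. Reading the
#' VCF back with [read_vcf()] reproduces the dosage matrix exactly.
#'
#' @param outdir Output directory (created if needed).
#' @param genotypes A [genotype_matrix()].
#' @param genes Gene model table.
#' @param phenotypes Phenotype data frame.
#' @param truth Truth table.
#' @return Invisibly, the named vector of file paths.
#' @export
write_fixture <- function(outdir, genotypes, genes, phenotypes, truth) {
  if (!dir.exists(outdir)) {
    ok <- dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory ", outdir)
  }
  paths <- c(vcf = file.path(outdir, "panel.vcf"),
             genes = file.path(outdir, "genes.tsv"),
             phenotypes = file.path(outdir, "phenotypes.tsv"),
             truth = file.path(outdir, "truth.json"))
  write_vcf(genotypes, paths["vcf"])
  write_gene_models(genes, paths["genes"])
  write_phenotypes(phenotypes, paths["phenotypes"])
  truth_json <- list(
    subpop = as.list(truth$subpop),
    founder_strings = lapply(truth$founders, function(f) f$strings),
    assignment = apply(truth$assignment, 2, identity, simplify = FALSE),
    causal = lapply(truth$causal, function(cs) {
      list(gene = cs$gene, trait = cs$trait, effects = cs$effects,
           superior_founder = cs$superior_founder)
    }),
    realized_h2 = as.list(truth$realized_h2))
  jsonlite::write_json(truth_json, paths["truth"], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}
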