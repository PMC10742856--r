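# End-to-end orchestration. Each stage reads its inputs from files, writes
# its outputs under the configured directory and records its bookkeeping in
# a manifest, so stages can be run separately or chained with run_all().

#' Pipeline configuration
#'
#' Collects the file paths, thresholds and modes of the full haplo-pheno
#' pipeline. All defaults are the standard analysis settings: hard-filter
#' thresholds QUAL/QD/FS/MQ = 30/4.0/60.0/40.0, LD pruning 100/50/0.2,
#' association alpha 0.01 with the two-year + BLUP consistency rule, and
#' rare-haplotype exclusion at more than three member accessions.
#'
#' @param outdir Output directory for all stages.
#' @param vcf,genes,phenotypes Input paths (defaults: the fixture files
#'   written by [run_simulate()] under `outdir`).
#' @param directions Named character vector of breeding directions per
#'   trait (`"maximize"`/`"minimize"`); unlisted traits maximize.
#' @param alpha Per-dataset association significance threshold.
#' @param min_qual,min_qd,max_fs,min_mq Hard-filter thresholds.
#' @param prune_window,prune_step,prune_r2 LD pruning parameters (variant
#'   counts and maximum r-squared).
#' @param min_hap_count,rare_mode,min_hap_percent Rare-haplotype rule.
#' @param maf_min Association scan minor-allele-frequency floor.
#' @param lambda_mode `"exact"` or `"null"` (see [lmm_scan()]).
#' @param welch Use Welch's t for two-group haplotype comparisons.
#' @param assoc_on_pruned Run the association scan on the LD-pruned set
#'   instead of the full filtered set (kinship always uses the pruned set).
#' @param marker_trait Trait whose superior haplotype combination receives
#'   a discriminating marker panel (default `"TGW"` when present).
#' @param sim Optional [sim_config()] used by [run_simulate()].
#' @param seed Integer seed for the simulation stage.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(outdir,
                            vcf = file.path(outdir, "fixture", "panel.vcf"),
                            genes = file.path(outdir, "fixture", "genes.tsv"),
                            phenotypes = file.path(outdir, "fixture",
                                                   "phenotypes.tsv"),
                            directions = NULL,
                            alpha = 0.01,
                            min_qual = 30, min_qd = 4.0, max_fs = 60.0,
                            min_mq = 40.0,
                            prune_window = 100L, prune_step = 50L,
                            prune_r2 = 0.2,
                            min_hap_count = 4L,
                            rare_mode = c("count", "percent"),
                            min_hap_percent = 1,
                            maf_min = 0.01,
                            lambda_mode = c("exact", "null"),
                            welch = FALSE,
                            assoc_on_pruned = FALSE,
                            marker_trait = NULL,
                            sim = NULL,
                            seed = 1L) {
  stopifnot(alpha > 0, min_hap_count > 0, prune_window > 0, prune_step > 0,
            prune_r2 > 0)
  structure(list(
    outdir = outdir, vcf = vcf, genes = genes, phenotypes = phenotypes,
    directions = directions, alpha = alpha,
    min_qual = min_qual, min_qd = min_qd, max_fs = max_fs, min_mq = min_mq,
    prune_window = as.integer(prune_window),
    prune_step = as.integer(prune_step), prune_r2 = prune_r2,
    min_hap_count = as.integer(min_hap_count),
    rare_mode = match.arg(rare_mode),
    min_hap_percent = min_hap_percent,
    maf_min = maf_min, lambda_mode = match.arg(lambda_mode),
    welch = welch, assoc_on_pruned = assoc_on_pruned,
    marker_trait = marker_trait,
    sim = sim, seed = as.integer(seed)), class = "pipeline_config")
}

trait_direction <- function(config, trait) {
  d <- config$directions
  if (!is.null(d) && trait %in% names(d)) d[[trait]] else "maximize"
}

update_manifest <- function(config, stage, entries) {
  path <- file.path(config$outdir, "manifest.json")
  manifest <- if (file.exists(path)) jsonlite::read_json(path) else
    list(seed = config$seed, stages = list())
  manifest$stages[[stage]] <- entries
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

require_stage <- function(path, stage) {
  if (!file.exists(path)) {
    stop("missing upstream output ", path, "; run ", stage, " first",
         call. = FALSE)
  }
  path
}

#' Simulation stage: write a synthetic fixture
#' @param config A [pipeline_config()].
#' @return Invisibly, the fixture file paths.
#' @export
run_simulate <- function(config) {
  sc <- config$sim
  if (is.null(sc)) sc <- sim_config(seed = config$seed)
  study <- simulate_study(sc)
  paths <- write_fixture(file.path(config$outdir, "fixture"),
                         study$genotypes, study$genes, study$phenotypes,
                         study$truth)
  update_manifest(config, "simulate", list(
    n_accessions = nrow(study$genotypes$dosage),
    n_variants = ncol(study$genotypes$dosage),
    n_genes = nrow(study$genes),
    traits = names(sc$trait_spec), seed = sc$seed))
  invisible(paths)
}

#' QC stage: hard-filter the variant set
#' @param config A [pipeline_config()].
#' @return Invisibly, paths of the filtered VCF and filter report.
#' @export
run_qc <- function(config) {
  require_stage(config$vcf, "simulate (or supply a VCF)")
  G <- read_vcf(config$vcf)
  Gf <- hard_filter(G, min_qual = config$min_qual, min_qd = config$min_qd,
                    max_fs = config$max_fs, min_mq = config$min_mq)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  vcf_out <- file.path(config$outdir, "filtered.vcf")
  rep_out <- file.path(config$outdir, "filter_report.tsv")
  write_vcf(Gf, vcf_out)
  write_filter_report(Gf, rep_out)
  update_manifest(config, "qc", list(
    n_input = ncol(G$dosage), n_retained = ncol(Gf$dosage),
    removed_per_criterion = stats::setNames(
      as.list(attr(Gf, "filter_report")$n_removed),
      attr(Gf, "filter_report")$criterion)))
  invisible(c(vcf = vcf_out, report = rep_out))
}

#' Per-accession analysis datasets for one trait
#'
#' The association scan runs once per dataset: each environment (cell
#' means over replicates) and the BLUPs. This helper assembles those named
#' value vectors from a phenotype table.
#'
#' @param pheno Phenotype data frame.
#' @param trait Trait name.
#' @param vc `variance_components` for the BLUP shrinkage.
#' @return Named list of per-accession numeric vectors (one per
#'   environment, plus `BLUP`).
#' @export
dataset_values <- function(pheno, trait, vc) {
  ph <- pheno[pheno$trait == trait, , drop = FALSE]
  cell <- stats::aggregate(value ~ accession + environment, ph, mean)
  envs <- sort(unique(cell$environment))
  out <- lapply(envs, function(ev) {
    v <- cell$value[cell$environment == ev]
    stats::setNames(v, cell$accession[cell$environment == ev])
  })
  names(out) <- envs
  b <- blup(pheno, trait, vc)
  out$BLUP <- b$blup
  out
}

#' Association stage: kinship, per-dataset mixed-model scans, consistency
#'
#' For every trait: estimates variance components and BLUPs, builds the
#' centered kinship from the LD-pruned variant set, scans each environment
#' and the BLUP values with the exact mixed model, and declares variants
#' associated when p < alpha in every dataset.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, the list of written paths.
#' @export
run_assoc <- function(config) {
  vcf <- require_stage(file.path(config$outdir, "filtered.vcf"), "qc")
  G <- read_vcf(vcf)
  genes <- read_gene_models(require_stage(config$genes, "simulate"))
  pheno <- read_phenotypes(require_stage(config$phenotypes, "simulate"))
  pruned_ids <- ld_prune(G, window = config$prune_window,
                         step = config$prune_step, r2_max = config$prune_r2)
  Gp <- subset_variants(G, pruned_ids)
  K <- centered_kinship(Gp)
  Gs <- if (config$assoc_on_pruned) Gp else G
  write_kinship(K, file.path(config$outdir, "kinship.tsv"))
  utils::write.table(data.frame(id = pruned_ids),
                     file.path(config$outdir, "pruned_variants.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  herit <- heritability_report(pheno)
  utils::write.table(herit, file.path(config$outdir, "heritability.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(kinship = file.path(config$outdir, "kinship.tsv"),
             heritability = file.path(config$outdir, "heritability.tsv"))
  blup_rows <- list()
  counts <- list()
  for (tr in unique(pheno$trait)) {
    vc <- variance_components(pheno, tr)
    ys <- dataset_values(pheno, tr, vc)
    common <- Reduce(intersect, c(lapply(ys, names),
                                  list(accessions(Gs))))
    scans <- lapply(ys, function(y) {
      lmm_scan(y[common], Gs, K, maf_min = config$maf_min,
               lambda_mode = config$lambda_mode)
    })
    assoc <- consistent_associations(scans, alpha = config$alpha,
                                     genes = genes, G = Gs)
    for (ds in names(scans)) {
      p <- file.path(config$outdir, sprintf("assoc_%s_%s.tsv", tr, ds))
      utils::write.table(scans[[ds]], p, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      paths[sprintf("assoc_%s_%s", tr, ds)] <- p
    }
    p <- file.path(config$outdir, sprintf("associated_%s.tsv", tr))
    utils::write.table(assoc, p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths[sprintf("associated_%s", tr)] <- p
    psum <- file.path(config$outdir, sprintf("associated_summary_%s.tsv", tr))
    utils::write.table(associated_set_summary(assoc), psum, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    blup_rows[[tr]] <- data.frame(accession = names(ys$BLUP), trait = tr,
                                  blup = unname(ys$BLUP))
    counts[[tr]] <- list(
      n_scanned = sum(is.na(scans[[1]]$skipped)),
      n_associated = sum(assoc$consistent),
      genes = unique(assoc$gene[assoc$consistent & !is.na(assoc$gene)]))
  }
  blup_path <- file.path(config$outdir, "blup.tsv")
  utils::write.table(do.call(rbind, blup_rows), blup_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  paths["blup"] <- blup_path
  update_manifest(config, "assoc", list(
    n_variants = ncol(Gs$dosage), n_pruned = length(pruned_ids),
    per_trait = counts))
  invisible(paths)
}

read_blups <- function(config) {
  path <- require_stage(file.path(config$outdir, "blup.tsv"), "assoc")
  b <- utils::read.delim(path, stringsAsFactors = FALSE)
  split(stats::setNames(b$blup, b$accession), b$trait)
}

#' Haplo-pheno stage: haplotype tables and combination tables
#'
#' For each trait with consistently associated variants: calls per-gene
#' haplotypes, excludes rare groups, computes group means, significance and
#' variance explained against the trait BLUPs, identifies the superior
#' haplotype, and repeats the analysis on multi-gene haplotype
#' combinations when two or more genes are associated.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, the list of written paths.
#' @export
run_haplo <- function(config) {
  vcf <- require_stage(file.path(config$outdir, "filtered.vcf"), "qc")
  G <- read_vcf(vcf)
  blups <- read_blups(config)
  hap_rows <- list(); comb_rows <- list(); assign_rows <- list()
  long_rows <- list()
  counts <- list()
  for (tr in names(blups)) {
    apath <- require_stage(
      file.path(config$outdir, sprintf("associated_%s.tsv", tr)), "assoc")
    assoc <- utils::read.delim(apath, stringsAsFactors = FALSE)
    hits <- assoc[assoc$consistent & !is.na(assoc$gene), , drop = FALSE]
    if (nrow(hits) == 0) next
    dir <- trait_direction(config, tr)
    assigns <- list()
    for (g in unique(hits$gene)) {
      a <- call_haplotypes(G, g, hits$id[hits$gene == g])
      assigns[[g]] <- a
      hp <- haplo_pheno(a, blups[[tr]], direction = dir,
                        min_count = config$min_hap_count,
                        mode = config$rare_mode,
                        min_percent = config$min_hap_percent,
                        welch = config$welch)
      hap_rows[[paste(tr, g)]] <- data.frame(
        trait = tr, gene = g, haplotype = hp$table$label,
        n = hp$table$count, percent = hp$table$percent,
        mean = hp$table$mean, letters = hp$table$letters,
        r2 = hp$r2, p = if (nrow(hp$table) == 2) hp$p_pairwise else
          hp$p_overall,
        superior = hp$superior == hp$table$label)
      long_rows[[paste(tr, g)]] <- data.frame(
        trait = tr, gene = g,
        accession = names(a$labels)[!is.na(a$labels)],
        haplotype = a$labels[!is.na(a$labels)],
        value = unname(blups[[tr]][names(a$labels)[!is.na(a$labels)]]))
      assign_rows[[paste(tr, g)]] <- data.frame(
        trait = tr, gene = g, accession = names(a$labels),
        haplotype = unname(a$labels))
    }
    if (length(assigns) >= 2) {
      comb <- combine_haplotypes(assigns)
      hp <- haplo_pheno(comb, blups[[tr]], direction = dir,
                        min_count = config$min_hap_count,
                        mode = config$rare_mode,
                        min_percent = config$min_hap_percent,
                        welch = config$welch)
      comb_rows[[tr]] <- data.frame(
        trait = tr, combination = hp$table$label,
        component = hp$table$component,
        n = hp$table$count, percent = hp$table$percent,
        mean = hp$table$mean, letters = hp$table$letters,
        r2 = hp$r2, p = if (nrow(hp$table) == 2) hp$p_pairwise else
          hp$p_overall,
        superior = hp$superior == hp$table$label)
    }
    counts[[tr]] <- list(n_genes = length(assigns))
  }
  if (length(hap_rows) == 0) {
    stop("no trait has consistently associated variants; nothing to analyze")
  }
  paths <- c(haplotypes = file.path(config$outdir, "haplotypes.tsv"),
             combinations = file.path(config$outdir, "combinations.tsv"),
             assignments = file.path(config$outdir, "hap_assignments.tsv"),
             values = file.path(config$outdir, "hap_values_long.tsv"))
  utils::write.table(do.call(rbind, hap_rows), paths["haplotypes"],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (length(comb_rows) > 0) {
    utils::write.table(do.call(rbind, comb_rows), paths["combinations"],
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  utils::write.table(do.call(rbind, assign_rows), paths["assignments"],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(do.call(rbind, long_rows), paths["values"],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  update_manifest(config, "haplo", list(per_trait = counts))
  invisible(paths)
}

#' Marker stage: discriminating panel for the superior combination
#'
#' Rebuilds the haplotype (or combination) assignment of the marker trait,
#' selects the minimal discriminating site panel for its superior group
#' and genotypes the whole panel with it as a self-consistency report.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, the list of written paths.
#' @export
run_markers <- function(config) {
  vcf <- require_stage(file.path(config$outdir, "filtered.vcf"), "qc")
  G <- read_vcf(vcf)
  blups <- read_blups(config)
  tr <- config$marker_trait
  if (is.null(tr)) tr <- if ("TGW" %in% names(blups)) "TGW" else
    names(blups)[1]
  apath <- require_stage(
    file.path(config$outdir, sprintf("associated_%s.tsv", tr)), "assoc")
  assoc <- utils::read.delim(apath, stringsAsFactors = FALSE)
  hits <- assoc[assoc$consistent & !is.na(assoc$gene), , drop = FALSE]
  if (nrow(hits) == 0) stop("no associated variants for trait ", tr)
  assigns <- lapply(unique(hits$gene), function(g) {
    call_haplotypes(G, g, hits$id[hits$gene == g])
  })
  a <- if (length(assigns) >= 2) combine_haplotypes(assigns) else
    assigns[[1]]
  hp <- haplo_pheno(a, blups[[tr]], direction = trait_direction(config, tr),
                    min_count = config$min_hap_count,
                    mode = config$rare_mode,
                    min_percent = config$min_hap_percent,
                    welch = config$welch)
  af <- filter_rare_haplotypes(a, min_count = config$min_hap_count,
                               mode = config$rare_mode,
                               min_percent = config$min_hap_percent)
  panel <- discriminating_sites(af, hp$superior)
  calls <- genotype_panel(G, panel)
  paths <- c(panel = file.path(config$outdir, "marker_panel.tsv"),
             calls = file.path(config$outdir, "marker_calls.tsv"))
  write_marker_panel(panel, paths["panel"])
  utils::write.table(
    data.frame(accession = names(calls), call = unname(calls)),
    paths["calls"], sep = "\t", quote = FALSE, row.names = FALSE)
  update_manifest(config, "markers", list(
    trait = tr, target = hp$superior, n_sites = nrow(panel$sites),
    n_target_calls = sum(calls == "target")))
  invisible(paths)
}

#' Run the full pipeline
#'
#' Chains simulate (when no input VCF exists), qc, assoc, haplo and
#' markers; outputs accumulate under `config$outdir` with a manifest
#' recording per-stage record counts.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a named list of per-stage output paths.
#' @export
run_all <- function(config) {
  out <- list()
  if (!file.exists(config$vcf)) out$simulate <- run_simulate(config)
  out$qc <- run_qc(config)
  out$assoc <- run_assoc(config)
  out$haplo <- run_haplo(config)
  out$markers <- run_markers(config)
  invisible(out)
}
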