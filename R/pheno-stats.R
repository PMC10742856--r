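#' Read a long-format phenotype table
#'
#' Expected columns: `accession`, `trait`, `environment`, `replicate`,
#' `value` (tab-separated). Duplicate (accession, trait, environment,
#' replicate) keys and non-finite values are rejected.
#'
#' @param path Path to a phenotype TSV.
#' @return A phenotype data frame.
#' @export
read_phenotypes <- function(path) {
  ph <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_phenotypes(ph)
}

#' Write a phenotype table to TSV
#' @param pheno Phenotype data frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_phenotypes <- function(pheno, path) {
  utils::write.table(pheno, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

validate_phenotypes <- function(ph) {
  req <- c("accession", "trait", "environment", "replicate", "value")
  miss <- setdiff(req, names(ph))
  if (length(miss) > 0) {
    stop("phenotype table is missing columns: ", paste(miss, collapse = ", "))
  }
  if (any(!is.finite(ph$value))) stop("phenotype values must be finite")
  key <- paste(ph$accession, ph$trait, ph$environment, ph$replicate)
  if (anyDuplicated(key)) {
    stop("duplicate (accession, trait, environment, replicate) records")
  }
  ph
}

# Restrict one trait's records to accessions with complete, balanced
# environment x replicate coverage; exclusions are logged.
balanced_subset <- function(pheno, trait) {
  ph <- pheno[pheno$trait == trait, , drop = FALSE]
  if (nrow(ph) == 0) stop("no records for trait ", trait)
  envs <- sort(unique(ph$environment))
  r <- max(stats::aggregate(value ~ accession + environment, ph,
                            length)$value)
  tab <- table(ph$accession, ph$environment)
  complete <- rownames(tab)[apply(tab == r, 1, all)]
  dropped <- setdiff(unique(ph$accession), complete)
  if (length(dropped) > 0) {
    message("excluding ", length(dropped),
            " accession(s) without complete environment coverage")
  }
  list(data = ph[ph$accession %in% complete, , drop = FALSE],
       envs = envs, e = length(envs), r = r)
}

#' Variance components of a multi-environment trait
#'
#' Method-of-moments estimates from the expected mean squares of a two-way
#' (accession x environment) ANOVA. With replicates (`r > 1`):
#' `Vg = (MS_G - MS_GE) / (r e)`, `Vge = (MS_GE - MS_err) / r`,
#' `Ve = MS_err`. With one value per environment (`r = 1`) the interaction
#' and residual are confounded: `Vg = (MS_G - MS_GE) / e`, `Ve = MS_GE`,
#' `Vge = 0` (logged). Negative moment estimates are truncated at zero.
#' Accessions lacking complete environment coverage are excluded (logged).
#'
#' @param pheno Phenotype data frame (long format).
#' @param trait Trait name.
#' @return A `variance_components` object: list with `Vg`, `Vge`, `Ve`,
#'   `e`, `r`, `trait`, `grand_mean` and the mean squares used.
#' @export
variance_components <- function(pheno, trait) {
  bs <- balanced_subset(validate_phenotypes(pheno), trait)
  ph <- bs$data
  if (bs$e < 2) {
    stop("variance components require >= 2 environments; ",
         "use per-environment summaries for single-environment data")
  }
  ph$accession <- factor(ph$accession)
  ph$environment <- factor(ph$environment)
  e <- bs$e
  r <- bs$r
  if (r > 1) {
    fit <- stats::aov(value ~ accession * environment, data = ph)
    ms <- summary(fit)[[1]][, "Mean Sq"]
    names(ms) <- trimws(rownames(summary(fit)[[1]]))
    ms_g <- ms[["accession"]]
    ms_ge <- ms[["accession:environment"]]
    ms_err <- ms[["Residuals"]]
    Vg <- (ms_g - ms_ge) / (r * e)
    Vge <- (ms_ge - ms_err) / r
    Ve <- ms_err
  } else {
    fit <- stats::aov(value ~ accession + environment, data = ph)
    ms <- summary(fit)[[1]][, "Mean Sq"]
    names(ms) <- trimws(rownames(summary(fit)[[1]]))
    ms_g <- ms[["accession"]]
    ms_ge <- ms[["Residuals"]]
    ms_err <- NA_real_
    Vg <- (ms_g - ms_ge) / e
    Vge <- 0
    Ve <- ms_ge
    message("r = 1: genotype-by-environment and residual variance are ",
            "confounded; Vge set to 0 and Ve = MS(GxE)")
  }
  trunc <- c(Vg = Vg, Vge = Vge, Ve = Ve) < 0
  if (any(trunc)) {
    message("negative moment estimate(s) truncated to 0: ",
            paste(names(trunc)[trunc], collapse = ", "))
  }
  structure(list(
    Vg = max(0, Vg), Vge = max(0, Vge), Ve = max(0, Ve),
    e = e, r = r, trait = trait, grand_mean = mean(ph$value),
    mean_squares = c(MS_G = ms_g, MS_GE = ms_ge, MS_err = ms_err)),
    class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf(
    "variance components for %s: Vg = %.4g, Vge = %.4g, Ve = %.4g (e = %d, r = %d)\n",
    x$trait, x$Vg, x$Vge, x$Ve, x$e, x$r))
  invisible(x)
}

#' Broad-sense heritability across environments
#'
#' `h2 = Vg / (Vg + Vge / e + Ve / (r e))`: the proportion of phenotypic
#' variance of an accession mean (over `e` environments with `r` replicates
#' each) attributable to genotype.
#'
#' @param vc A `variance_components` object.
#' @return Heritability in `[0, 1]`.
#' @export
heritability <- function(vc) {
  denom <- vc$Vg + vc$Vge / vc$e + vc$Ve / (vc$r * vc$e)
  if (denom <= 0) {
    stop("all variance components are zero; heritability is undefined")
  }
  vc$Vg / denom
}

#' Per-accession BLUPs of genotypic value
#'
#' Best linear unbiased predictions under the balanced two-way model with
#' environments fixed: environment means are removed by centering, accession
#' means are shrunk toward the grand mean by
#' `s = Vg / (Vg + Vge / e + Ve / (r e))` (the reliability of an accession
#' mean, identical to the broad-sense heritability of that mean). For
#' accessions observed in fewer environments the shrinkage uses their own
#' environment count, which reproduces the mixed-model-equation solution.
#'
#' @param pheno Phenotype data frame.
#' @param trait Trait name.
#' @param vc `variance_components` for the same trait (estimated if omitted).
#' @return A `blup_vector` object: list with `blup` (named numeric),
#'   `grand_mean` and `shrinkage`.
#' @export
blup <- function(pheno, trait, vc = NULL) {
  if (is.null(vc)) vc <- variance_components(pheno, trait)
  ph <- validate_phenotypes(pheno)
  ph <- ph[ph$trait == trait, , drop = FALSE]
  if (nrow(ph) == 0) stop("no records for trait ", trait)
  # collapse replicates to cell means; per-cell residual variance Vge + Ve/r
  cell <- stats::aggregate(value ~ accession + environment, ph, mean)
  mu <- mean(cell$value)
  env_eff <- stats::aggregate(value ~ environment, cell, mean)
  cell$centered <- cell$value -
    env_eff$value[match(cell$environment, env_eff$environment)] + mu
  acc <- stats::aggregate(centered ~ accession, cell, mean)
  n_env <- table(cell$accession)[acc$accession]
  sigma2_cell <- vc$Vge + vc$Ve / vc$r
  if (vc$Vg == 0) {
    warning("Vg = 0: all BLUPs equal the grand mean")
    s <- rep(0, nrow(acc))
  } else {
    s <- vc$Vg / (vc$Vg + sigma2_cell / as.numeric(n_env))
  }
  pred <- mu + s * (acc$centered - mu)
  names(pred) <- acc$accession
  structure(list(blup = pred, grand_mean = mu,
                 shrinkage = stats::setNames(s, acc$accession),
                 trait = trait),
            class = "blup_vector")
}

#' @export
print.blup_vector <- function(x, ...) {
  cat(sprintf(
    "BLUPs for %s: %d accessions, grand mean %.4g, shrinkage %.3f\n",
    x$trait, length(x$blup), x$grand_mean, mean(x$shrinkage)))
  invisible(x)
}

#' Pairwise Pearson correlations between trait BLUPs
#'
#' @param blups Named list of `blup_vector` objects (one per trait), or a
#'   numeric matrix/data frame of accession x trait values.
#' @return List with matrices `r` (Pearson correlation), `p` (two-sided
#'   p-value from the t transform with n - 2 df), `stars` (`**` for
#'   p < 0.01, `***` for p < 0.001) and the common accession count `n`.
#' @export
trait_correlations <- function(blups) {
  if (is.list(blups) && !is.data.frame(blups) &&
      all(vapply(blups, inherits, logical(1), "blup_vector"))) {
    common <- Reduce(intersect, lapply(blups, function(b) names(b$blup)))
    if (length(common) < 3) stop("need >= 3 common accessions")
    mat <- vapply(blups, function(b) b$blup[common],
                  numeric(length(common)))
  } else {
    mat <- as.matrix(blups)
  }
  if (nrow(mat) < 3) stop("need >= 3 common accessions")
  k <- ncol(mat)
  sds <- apply(mat, 2, stats::sd)
  if (any(sds == 0)) {
    warning("zero-variance trait(s): ",
            paste(colnames(mat)[sds == 0], collapse = ", "),
            "; correlations undefined (NA)")
  }
  r <- suppressWarnings(stats::cor(mat))
  n <- nrow(mat)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  diag(p) <- NA
  stars <- matrix("", k, k, dimnames = dimnames(r))
  stars[!is.na(p) & p < 0.01] <- "**"
  stars[!is.na(p) & p < 0.001] <- "***"
  list(r = r, p = p, stars = stars, n = n)
}

#' Per-trait heritability report
#'
#' Convenience wrapper: variance components and broad-sense heritability for
#' every trait in a phenotype table.
#'
#' @param pheno Phenotype data frame.
#' @return Data frame with columns trait, Vg, Vge, Ve, e, r, h2.
#' @export
heritability_report <- function(pheno) {
  traits <- unique(pheno$trait)
  do.call(rbind, lapply(traits, function(tr) {
    vc <- variance_components(pheno, tr)
    data.frame(trait = tr, Vg = vc$Vg, Vge = vc$Vge, Ve = vc$Ve,
               e = vc$e, r = vc$r, h2 = heritability(vc))
  }))
}
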