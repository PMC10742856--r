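# Exact mixed-model association scan.
#
# Model per variant: y = 1*a + x*b (+ covariates) + u + e, with
# u ~ N(0, s2 * lambda * K) and e ~ N(0, s2 * I). K is eigendecomposed
# once; in the rotated basis the covariance is diagonal with weights
# lambda * d_i + 1, so each variant costs one 1-D REML optimization over
# lambda plus a generalized least squares fit.

# Restricted log-likelihood (up to an additive constant) of the rotated
# model at a given lambda. Xt: rotated design (n x q), yt: rotated
# response, d: kinship eigenvalues.
reml_loglik <- function(log10_lambda, d, yt, Xt) {
  lam <- 10^log10_lambda
  w <- 1 / (lam * d + 1)
  A <- crossprod(Xt, w * Xt)
  b <- crossprod(Xt, w * yt)
  beta <- solve(A, b)
  rss <- sum(w * yt^2) - sum(b * beta)
  n <- length(yt)
  q <- ncol(Xt)
  -0.5 * (sum(log(lam * d + 1)) + determinant(A)$modulus[1] +
            (n - q) * log(rss))
}

# GLS fit at a fixed lambda; returns effect, s.e., Wald t and p for the
# last design column, with a t reference on n - q df.
gls_fit <- function(log10_lambda, d, yt, Xt) {
  lam <- 10^log10_lambda
  w <- 1 / (lam * d + 1)
  A <- crossprod(Xt, w * Xt)
  b <- crossprod(Xt, w * yt)
  Ainv <- solve(A)
  beta <- Ainv %*% b
  rss <- sum(w * yt^2) - sum(b * beta)
  n <- length(yt)
  q <- ncol(Xt)
  df <- n - q
  s2 <- rss / df
  se <- sqrt(s2 * Ainv[q, q])
  tt <- beta[q] / se
  list(beta = beta[q], se = se, t = tt,
       p = 2 * stats::pt(-abs(tt), df = df),
       lambda = lam, df = df)
}

# Vectorized REML profile over a shared lambda grid for all variants at
# once (intercept-only covariate case). Returns an L x p matrix of
# restricted log-likelihoods.
reml_profile_grid <- function(log10_grid, d, yt, u1, Xt_all) {
  n <- length(yt)
  p <- ncol(Xt_all)
  Xt2 <- Xt_all^2
  out <- matrix(NA_real_, nrow = length(log10_grid), ncol = p)
  for (l in seq_along(log10_grid)) {
    lam <- 10^log10_grid[l]
    w <- 1 / (lam * d + 1)
    s11 <- sum(w * u1^2)
    s1y <- sum(w * u1 * yt)
    syy <- sum(w * yt^2)
    s1x <- crossprod(Xt_all, w * u1)[, 1]
    sxy <- crossprod(Xt_all, w * yt)[, 1]
    sxx <- crossprod(Xt2, w)[, 1]
    detA <- s11 * sxx - s1x^2
    b1 <- (sxx * s1y - s1x * sxy) / detA
    b2 <- (s11 * sxy - s1x * s1y) / detA
    rss <- syy - (b1 * s1y + b2 * sxy)
    out[l, ] <- -0.5 * (sum(log(lam * d + 1)) + log(detA) +
                          (n - 2) * log(rss))
  }
  out
}

#' Exact mixed-model association scan
#'
#' Per-variant Wald tests of a phenotype against dosages under a linear
#' mixed model with a polygenic random effect whose covariance is
#' proportional to the kinship matrix. The kinship matrix is
#' eigendecomposed once; for each variant the variance ratio `lambda`
#' (polygenic / residual) is profiled out by restricted maximum likelihood
#' using a log-scale grid bracket refined with Brent's method, and the
#' variant effect is estimated by generalized least squares with an
#' intercept. Two-sided p-values use a t reference with `n - q` degrees of
#' freedom (`q` = number of fixed effects, 2 when no covariates are given),
#' which reduces exactly to the ordinary t-test when `K` is the identity.
#'
#' @param y Named numeric vector of per-accession phenotype values (one
#'   value per accession, e.g. a single environment or BLUPs).
#' @param G A [genotype_matrix()]; rows must cover `names(y)`.
#' @param K Kinship matrix with accession dimnames.
#' @param maf_min Variants with minor allele frequency below this floor are
#'   skipped (default 0.01), as are monomorphic variants.
#' @param lambda_mode `"exact"` (per-variant REML optimization of lambda)
#'   or `"null"` (lambda fitted once on the no-variant model and reused;
#'   faster, approximate).
#' @param lambda_range Search range for lambda (default `c(1e-5, 1e5)`).
#' @param grid_points Number of log-spaced bracketing grid points.
#' @param covariates Optional numeric matrix of additional fixed effects
#'   (rows = accessions in the order of `y`).
#' @return Data frame with one row per variant: `id`, `maf`, `beta`, `se`,
#'   `wald_t`, `p`, `lambda`, `skipped` (reason or `NA`).
#' @export
lmm_scan <- function(y, G, K, maf_min = 0.01,
                     lambda_mode = c("exact", "null"),
                     lambda_range = c(1e-5, 1e5), grid_points = 61L,
                     covariates = NULL) {
  lambda_mode <- match.arg(lambda_mode)
  if (is.null(names(y))) stop("`y` must be named by accession")
  if (any(!is.finite(y))) stop("phenotype values must be finite")
  if (stats::var(y) == 0) stop("phenotype has zero variance; nothing to test")
  acc <- accessions(G)
  if (!all(names(y) %in% acc)) stop("phenotype/genotype accession mismatch")
  Gd <- G$dosage[names(y), , drop = FALSE]
  K <- K[names(y), names(y)]
  n <- length(y)
  # mean-impute missing dosages for the regression
  mu <- colMeans(Gd, na.rm = TRUE)
  idx <- which(is.na(Gd), arr.ind = TRUE)
  if (nrow(idx) > 0) Gd[idx] <- mu[idx[, 2]]
  eg <- eigen((K + t(K)) / 2, symmetric = TRUE)
  d <- eg$values
  if (any(d < 0)) {
    message("lmm_scan: flooring ", sum(d < 0),
            " negative kinship eigenvalue(s) at 0")
    d <- pmax(d, 0)
  }
  U <- eg$vectors
  yt <- crossprod(U, y)[, 1]
  u1 <- crossprod(U, rep(1, n))[, 1]
  Ct <- if (!is.null(covariates)) crossprod(U, as.matrix(covariates))
  Xt_all <- crossprod(U, Gd)
  p_alt <- colMeans(Gd) / 2
  maf <- pmin(p_alt, 1 - p_alt)
  mono <- apply(Gd, 2, function(x) stats::var(x) == 0)
  skipped <- ifelse(mono, "monomorphic",
                    ifelse(maf < maf_min, "maf_below_floor", NA))
  testable <- which(is.na(skipped))
  log10_grid <- seq(log10(lambda_range[1]), log10(lambda_range[2]),
                    length.out = grid_points)
  res <- data.frame(
    id = G$variants$id, maf = unname(maf), beta = NA_real_, se = NA_real_,
    wald_t = NA_real_, p = NA_real_, lambda = NA_real_,
    skipped = skipped, stringsAsFactors = FALSE)
  if (length(testable) == 0) return(res)

  refine <- function(profile_vals, design, ytv) {
    i <- which.max(profile_vals)
    lo <- log10_grid[max(1, i - 1)]
    hi <- log10_grid[min(length(log10_grid), i + 1)]
    if (lo == hi) return(log10_grid[i])
    opt <- stats::optimize(reml_loglik, c(lo, hi), maximum = TRUE,
                           d = d, yt = ytv, Xt = design, tol = 1e-6)
    if (opt$objective >= profile_vals[i]) opt$maximum else log10_grid[i]
  }

  if (lambda_mode == "null") {
    design0 <- cbind(u1, Ct)
    prof0 <- vapply(log10_grid, reml_loglik, numeric(1),
                    d = d, yt = yt, Xt = design0)
    l0 <- refine(prof0, design0, yt)
    for (j in testable) {
      design <- cbind(u1, Ct, Xt_all[, j])
      fit <- gls_fit(l0, d, yt, design)
      res[j, c("beta", "se", "wald_t", "p", "lambda")] <-
        c(fit$beta, fit$se, fit$t, fit$p, fit$lambda)
    }
    return(res)
  }

  if (is.null(Ct)) {
    prof <- reml_profile_grid(log10_grid, d, yt, u1,
                              Xt_all[, testable, drop = FALSE])
    for (k in seq_along(testable)) {
      j <- testable[k]
      design <- cbind(u1, Xt_all[, j])
      l_hat <- refine(prof[, k], design, yt)
      fit <- gls_fit(l_hat, d, yt, design)
      res[j, c("beta", "se", "wald_t", "p", "lambda")] <-
        c(fit$beta, fit$se, fit$t, fit$p, fit$lambda)
    }
  } else {
    for (j in testable) {
      design <- cbind(u1, Ct, Xt_all[, j])
      prof <- vapply(log10_grid, reml_loglik, numeric(1),
                     d = d, yt = yt, Xt = design)
      l_hat <- refine(prof, design, yt)
      fit <- gls_fit(l_hat, d, yt, design)
      res[j, c("beta", "se", "wald_t", "p", "lambda")] <-
        c(fit$beta, fit$se, fit$t, fit$p, fit$lambda)
    }
  }
  res
}

#' Cross-dataset consistency rule for associated variants
#'
#' A variant is declared trait-associated when its mixed-model p-value is
#' below `alpha` (strictly) in every dataset: each environment and the
#' BLUP values. Variants skipped in any scan are not associated.
#'
#' @param scans Named list of [lmm_scan()] results over identical variants
#'   (e.g. `list(env1 = ..., env2 = ..., BLUP = ...)`).
#' @param alpha Per-dataset significance threshold (default 0.01).
#' @param genes Optional gene model table: adds `gene` and `region` columns.
#' @return Data frame with one row per variant: per-dataset p-values
#'   (`p_<dataset>`), `consistent`, and annotation columns when `genes`
#'   and variant metadata are available.
#' @export
consistent_associations <- function(scans, alpha = 0.01, genes = NULL,
                                    G = NULL) {
  if (length(scans) < 2 || is.null(names(scans))) {
    stop("`scans` must be a named list of >= 2 association scans")
  }
  ids <- scans[[1]]$id
  for (s in scans[-1]) {
    if (!identical(s$id, ids)) {
      stop("association scans must cover identical variants in the same order")
    }
  }
  pm <- vapply(scans, function(s) s$p, numeric(length(ids)))
  if (length(ids) == 1) pm <- matrix(pm, nrow = 1)
  colnames(pm) <- paste0("p_", names(scans))
  consistent <- apply(pm, 1, function(p) all(!is.na(p) & p < alpha))
  out <- data.frame(id = ids, pm, consistent = consistent,
                    stringsAsFactors = FALSE)
  if (!is.null(genes) && !is.null(G)) {
    v <- G$variants[match(ids, G$variants$id), , drop = FALSE]
    out$gene <- assign_gene(v, genes)
    out$region <- vapply(seq_len(nrow(v)), function(i) {
      if (is.na(out$gene[i])) return("intergenic")
      annotate_region(v$chrom[i], v$pos[i],
                      genes[genes$gene == out$gene[i], ][1, ])
    }, character(1))
    out$type <- ifelse(nchar(v$ref) == nchar(v$alt), "SNP", "Indel")
  }
  out
}

#' Summarize associated variants per gene
#'
#' Counts of consistently associated SNPs and indels per gene and region
#' label, in the shape of an association-report table.
#'
#' @param assoc Result of [consistent_associations()] with gene annotation.
#' @return Data frame: gene, region, n_snp, n_indel.
#' @export
associated_set_summary <- function(assoc) {
  if (is.null(assoc$gene)) stop("association table lacks gene annotation")
  hits <- assoc[assoc$consistent & !is.na(assoc$gene), , drop = FALSE]
  if (nrow(hits) == 0) {
    return(data.frame(gene = character(), region = character(),
                      n_snp = integer(), n_indel = integer()))
  }
  agg <- stats::aggregate(cbind(n_snp = hits$type == "SNP",
                                n_indel = hits$type == "Indel"),
                          by = list(gene = hits$gene, region = hits$region),
                          FUN = sum)
  agg[order(agg$gene, agg$region), , drop = FALSE]
}
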