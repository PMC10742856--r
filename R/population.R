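#' Centered relatedness (kinship) matrix
#'
#' The centered kinship estimator used by exact mixed-model association
#' software: `K = W W' / p`, where `W` is the dosage matrix with each
#' variant (column) centered at its mean and `p` is the number of variants.
#' Missing dosages are mean-imputed per variant before centering (logged).
#'
#' @param G A [genotype_matrix()].
#' @param drop_monomorphic Drop variants with no allelic variation before
#'   computing the matrix (default `TRUE`).
#' @return A symmetric n x n matrix with accession ids as dimnames.
#' @export
centered_kinship <- function(G, drop_monomorphic = TRUE) {
  X <- G$dosage
  n_mis <- sum(is.na(X))
  if (n_mis > 0) {
    message("centered_kinship: mean-imputing ", n_mis, " missing dosage(s)")
    mu <- colMeans(X, na.rm = TRUE)
    idx <- which(is.na(X), arr.ind = TRUE)
    X[idx] <- mu[idx[, 2]]
  }
  if (drop_monomorphic) {
    poly <- apply(X, 2, function(x) stats::var(x) > 0)
    X <- X[, poly, drop = FALSE]
  }
  if (ncol(X) < 2) {
    stop("need >= 2 polymorphic variants to estimate kinship")
  }
  W <- scale(X, center = TRUE, scale = FALSE)
  K <- tcrossprod(W) / ncol(W)
  dimnames(K) <- list(rownames(G$dosage), rownames(G$dosage))
  K
}

#' Write a kinship matrix as square TSV
#' @param K Kinship matrix.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_kinship <- function(K, path) {
  utils::write.table(K, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

window_r2 <- function(X) {
  r <- suppressWarnings(stats::cor(X))
  r[is.na(r)] <- 0
  r^2
}

#' Sliding-window LD pruning
#'
#' Greedy within-window elimination of variants in high linkage
#' disequilibrium, in the style of `--indep-pairwise`: windows of `window`
#' variants advance by `step` variants along each chromosome; within a
#' window, while any retained pair has squared Pearson dosage correlation
#' above `r2_max`, the member of the worst pair with the smaller minor
#' allele frequency is removed (ties: the later position). Missing dosages
#' are mean-imputed for the correlation only.
#'
#' @param G A [genotype_matrix()].
#' @param window Window size in variant count (default 100).
#' @param step Window step in variant count (default 50).
#' @param r2_max Maximum tolerated pairwise r-squared (default 0.2).
#' @return Character vector of retained variant ids (position order).
#' @export
ld_prune <- function(G, window = 100L, step = 50L, r2_max = 0.2) {
  v <- G$variants
  X <- G$dosage
  mu <- colMeans(X, na.rm = TRUE)
  idx <- which(is.na(X), arr.ind = TRUE)
  if (nrow(idx) > 0) X[idx] <- mu[idx[, 2]]
  maf <- variant_maf(G)
  keep <- rep(TRUE, nrow(v))
  for (chr in unique(v$chrom)) {
    cix <- which(v$chrom == chr)  # already position-sorted
    start <- 1L
    repeat {
      win <- cix[seq(start, min(start + window - 1L, length(cix)))]
      active <- win[keep[win]]
      while (length(active) >= 2) {
        r2 <- window_r2(X[, active, drop = FALSE])
        diag(r2) <- 0
        if (max(r2) <= r2_max) break
        worst <- which(r2 == max(r2), arr.ind = TRUE)[1, ]
        pair <- active[worst]
        pair_maf <- maf[v$id[pair]]
        drop_ix <- if (pair_maf[1] == pair_maf[2]) {
          pair[which.max(v$pos[pair])]
        } else {
          pair[which.min(pair_maf)]
        }
        keep[drop_ix] <- FALSE
        active <- setdiff(active, drop_ix)
      }
      if (start + window - 1L >= length(cix)) break
      start <- start + step
    }
  }
  message("ld_prune: retained ", sum(keep), "/", nrow(v), " variant(s)")
  v$id[keep]
}
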