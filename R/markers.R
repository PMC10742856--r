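# Haplotype-specific marker panels: the smallest set of variant sites
# whose diagnostic alleles distinguish a target haplotype (or haplotype
# combination) from every other retained group. The sites and alleles are
# what an allele-specific PCR assay (KASP/PARMS style) would genotype;
# primer chemistry is out of scope.

#' Select discriminating marker sites for a target haplotype
#'
#' Chooses variant sites whose alleles separate the target haplotype group
#' from every other retained group. For small candidate sets
#' (<= `exact_limit` sites) the minimal covering panel is found by
#' exhaustive subset search; otherwise a greedy set cover repeatedly adds
#' the site separating the most still-unseparated groups (ties: earlier
#' genomic position). Errors if some non-target group carries an identical
#' haplotype string (the target is not discriminable).
#'
#' @param a A `haplotype_assignment` (single gene or combination), ideally
#'   after [filter_rare_haplotypes()] so that `groups` holds the retained
#'   groups.
#' @param target Label of the target group (e.g. `"H1"` or `"HC4"`).
#' @param exact_limit Maximum number of candidate sites for the exhaustive
#'   minimal search (default 15).
#' @return A `marker_panel`: list with `target`, `sites` (data frame: id,
#'   chrom, pos, ref, alt, diagnostic allele) and `coverage` (per
#'   non-target group, the panel site ids separating it).
#' @export
discriminating_sites <- function(a, target, exact_limit = 15L) {
  g <- a$groups
  if (!(target %in% g$label)) stop("target ", target,
                                   " is not a retained group")
  member <- vapply(g$label, function(lab) {
    names(a$labels)[which(a$labels == lab)[1]]
  }, character(1))
  alle <- a$site_alleles[member, , drop = FALSE]
  rownames(alle) <- g$label
  tgt <- alle[target, ]
  others <- setdiff(g$label, target)
  if (length(others) == 0) {
    stop("only one retained group; no discrimination needed")
  }
  sep <- vapply(others, function(o) alle[o, ] != tgt,
                logical(ncol(alle)))
  if (ncol(alle) == 1) sep <- matrix(sep, nrow = 1)
  # sep: sites x other-groups, TRUE when the site separates the group
  not_disc <- colSums(sep) == 0
  if (any(not_disc)) {
    stop("target not discriminable: group(s) ",
         paste(others[not_disc], collapse = ", "),
         " share the target haplotype string")
  }
  v <- a$variants
  n_sites <- nrow(v)
  chosen <- integer(0)
  if (n_sites <= exact_limit) {
    for (size in seq_len(n_sites)) {
      combs <- utils::combn(n_sites, size)
      found <- FALSE
      for (cc in seq_len(ncol(combs))) {
        if (all(colSums(sep[combs[, cc], , drop = FALSE]) > 0)) {
          chosen <- combs[, cc]
          found <- TRUE
          break
        }
      }
      if (found) break
    }
  } else {
    uncovered <- rep(TRUE, length(others))
    while (any(uncovered)) {
      gain <- rowSums(sep[, uncovered, drop = FALSE])
      best <- which(gain == max(gain))
      best <- best[order(v$chrom[best], v$pos[best])][1]
      chosen <- c(chosen, best)
      uncovered <- uncovered & !sep[best, ]
    }
  }
  chosen <- sort(chosen)
  sites <- v[chosen, c("id", "chrom", "pos", "ref", "alt"), drop = FALSE]
  sites$diagnostic_allele <- unname(tgt[chosen])
  coverage <- lapply(stats::setNames(seq_along(others), others), function(o) {
    v$id[chosen][sep[chosen, o]]
  })
  structure(list(target = target, sites = sites, coverage = coverage),
            class = "marker_panel")
}

#' @export
print.marker_panel <- function(x, ...) {
  cat(sprintf("marker_panel for %s: %d site(s) covering %d group(s)\n",
              x$target, nrow(x$sites), length(x$coverage)))
  print(x$sites)
  invisible(x)
}

#' Genotype accessions with a marker panel
#'
#' Calls each accession `target` when it carries every panel site's
#' diagnostic allele homozygously, `non-target` when it differs
#' homozygously at any panel site, and `inconclusive` when any panel site
#' is missing or heterozygous.
#'
#' @param G A [genotype_matrix()] containing the panel variants (e.g. new
#'   breeding lines genotyped at the panel sites).
#' @param panel A `marker_panel`.
#' @param accession_ids Accessions to call (default: all rows of `G`).
#' @return Named character vector of calls.
#' @export
genotype_panel <- function(G, panel, accession_ids = NULL) {
  ids <- panel$sites$id
  missing_sites <- setdiff(ids, G$variants$id)
  if (length(missing_sites) > 0) {
    stop("panel variant(s) absent from genotypes: ",
         paste(missing_sites, collapse = ", "))
  }
  if (is.null(accession_ids)) accession_ids <- accessions(G)
  sub <- subset_variants(G, ids)
  v <- sub$variants
  dos <- sub$dosage[accession_ids, , drop = FALSE]
  diag_allele <- panel$sites$diagnostic_allele[match(v$id, panel$sites$id)]
  diag_dos <- ifelse(diag_allele == v$ref, 0, 2)
  calls <- vapply(seq_along(accession_ids), function(i) {
    x <- dos[i, ]
    if (any(is.na(x)) || any(x == 1)) return("inconclusive")
    if (all(x == diag_dos)) "target" else "non-target"
  }, character(1))
  names(calls) <- accession_ids
  calls
}

#' Write a marker panel to TSV
#' @param panel A `marker_panel`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_marker_panel <- function(panel, path) {
  utils::write.table(panel$sites, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
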