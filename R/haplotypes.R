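# Haplo-pheno analysis: per-gene haplotype calling from associated
# variants, rare-group exclusion, group statistics and superior-haplotype
# identification. Haplotypes are trivially phased because the panel is
# inbred: an accession's haplotype is the string of alleles it carries at
# the gene's associated variant sites in position order.

hap_groups_from_strings <- function(hap, panel_size,
                                    label_prefix = "H",
                                    tie_key = NULL) {
  tab <- table(hap[!is.na(hap)])
  if (length(tab) == 0) stop("no non-missing haplotypes to group")
  key <- if (is.null(tie_key)) names(tab) else tie_key[names(tab)]
  ord <- order(-as.integer(tab), key)
  data.frame(
    label = paste0(label_prefix, seq_along(tab)),
    hap_string = names(tab)[ord],
    count = as.integer(tab)[ord],
    percent = 100 * as.integer(tab)[ord] / panel_size,
    stringsAsFactors = FALSE)
}

#' Call per-gene haplotypes from associated variants
#'
#' Builds each accession's haplotype string over the gene's associated
#' variant sites (position order): dosage 0 contributes the reference
#' allele, dosage 2 the alternate allele. Any missing or heterozygous site
#' makes the accession's haplotype missing (logged) — conservative for an
#' inbred panel. Haplotype labels `H1, H2, ...` are assigned by descending
#' group frequency, ties broken by lexicographic haplotype string.
#'
#' @param G A [genotype_matrix()].
#' @param gene Gene id (bookkeeping only).
#' @param variant_ids Ids of the gene's associated variants present in `G`.
#' @return A `haplotype_assignment`: list with `gene`, `variants` (site
#'   table in position order), `hap` (named allele strings, `NA` =
#'   missing), `labels` (named haplotype labels), `groups` (label,
#'   hap_string, count, percent) and `panel_size`.
#' @export
call_haplotypes <- function(G, gene, variant_ids) {
  if (length(variant_ids) == 0) stop("empty associated variant list")
  sub <- subset_variants(G, variant_ids)
  v <- sub$variants
  dos <- sub$dosage
  n <- nrow(dos)
  allele <- matrix(NA_character_, nrow = n, ncol = ncol(dos))
  for (j in seq_len(ncol(dos))) {
    allele[dos[, j] == 0, j] <- v$ref[j]
    allele[dos[, j] == 2, j] <- v$alt[j]
  }
  dimnames(allele) <- list(rownames(dos), v$id)
  ok <- rowSums(is.na(allele)) == 0
  if (any(!ok)) {
    message("call_haplotypes(", gene, "): ", sum(!ok),
            " accession(s) with missing/heterozygous sites -> missing")
  }
  hap <- rep(NA_character_, n)
  names(hap) <- rownames(dos)
  hap[ok] <- apply(allele[ok, , drop = FALSE], 1, paste, collapse = "")
  groups <- hap_groups_from_strings(hap, panel_size = n)
  labels <- groups$label[match(hap, groups$hap_string)]
  names(labels) <- names(hap)
  structure(list(gene = gene, variants = v, hap = hap, labels = labels,
                 groups = groups, panel_size = n, site_alleles = allele),
            class = "haplotype_assignment")
}

#' @export
print.haplotype_assignment <- function(x, ...) {
  cat(sprintf("haplotype_assignment for %s: %d site(s), %d group(s), %d/%d assigned\n",
              x$gene, nrow(x$variants), nrow(x$groups),
              sum(!is.na(x$labels)), x$panel_size))
  print(x$groups)
  invisible(x)
}

#' Exclude rare haplotype groups
#'
#' Retains groups large enough for group statistics. The default rule keeps
#' groups with more than three member accessions (`min_count = 4`); a
#' percent-based mode (`>= min_percent` of the panel) is also available.
#' Excluded accessions are dropped from group statistics but remain in the
#' denominator of panel percentages.
#'
#' @param a A `haplotype_assignment`.
#' @param min_count Minimum member count for retention (count mode).
#' @param mode `"count"` or `"percent"`.
#' @param min_percent Minimum panel percentage (percent mode).
#' @return The assignment with `groups` restricted to retained groups; the
#'   full group table is kept as `groups_all`, and labels of excluded
#'   accessions are set to `NA` in `labels_retained`.
#' @export
filter_rare_haplotypes <- function(a, min_count = 4L,
                                   mode = c("count", "percent"),
                                   min_percent = 1) {
  mode <- match.arg(mode)
  keep <- if (mode == "count") a$groups$count >= min_count
          else a$groups$percent >= min_percent
  if (!any(keep)) stop("no analyzable haplotype groups after rare-group exclusion")
  n_excl <- sum(!keep)
  if (n_excl > 0) {
    message("filter_rare_haplotypes(", a$gene, "): excluded ", n_excl,
            " rare group(s) carrying ", sum(a$groups$count[!keep]),
            " accession(s)")
  }
  a$groups_all <- a$groups
  a$groups <- a$groups[keep, , drop = FALSE]
  a$labels_retained <- ifelse(a$labels %in% a$groups$label, a$labels,
                              NA_character_)
  names(a$labels_retained) <- names(a$labels)
  a
}

#' Two-group comparison of haplotype means
#'
#' Pooled-variance Student's t-test (two-sided) between two haplotype
#' groups; Welch's correction is available behind a flag. Degenerate
#' zero-variance groups give p = 1 for equal means and p ~ 0 (flagged)
#' otherwise.
#'
#' @param x,y Numeric trait values of the two groups (each length >= 2).
#' @param welch Use Welch's unequal-variance t instead of pooled.
#' @return Two-sided p-value.
#' @export
two_group_test <- function(x, y, welch = FALSE) {
  if (length(x) < 2 || length(y) < 2) stop("each group needs >= 2 values")
  pooled_var <- (sum((x - mean(x))^2) + sum((y - mean(y))^2)) /
    (length(x) + length(y) - 2)
  if (pooled_var == 0) {
    if (isTRUE(all.equal(mean(x), mean(y)))) return(1)
    warning("zero within-group variance with unequal means; p -> 0")
    return(0)
  }
  stats::t.test(x, y, var.equal = !welch)$p.value
}

# Duncan step-down: spans of sorted means are declared homogeneous when
# their range is below the critical range for that span size; pairs inside
# a homogeneous span are protected from further testing.
duncan_ns_matrix <- function(m_sorted, crit_range) {
  k <- length(m_sorted)
  ns <- matrix(FALSE, k, k)
  visited <- matrix(FALSE, k, k)
  stack <- list(c(1L, k))
  while (length(stack) > 0) {
    span <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- span[1]; j <- span[2]
    if (j <= i || visited[i, j]) next
    visited[i, j] <- TRUE
    p <- j - i + 1L
    if (m_sorted[i] - m_sorted[j] <= crit_range[p]) {
      ns[i:j, i:j] <- TRUE
    } else {
      stack <- c(stack, list(c(i + 1L, j)), list(c(i, j - 1L)))
    }
  }
  ns
}

letters_from_ns <- function(m_sorted, ns) {
  k <- length(m_sorted)
  # maximal non-significant ranges of the descending-sorted means
  ranges <- list()
  for (i in seq_len(k)) {
    js <- which(ns[i, ] | seq_len(k) == i)
    j <- max(js[js >= i])
    if (length(ranges) == 0 ||
        !(ranges[[length(ranges)]][1] <= i &&
            j <= ranges[[length(ranges)]][2])) {
      ranges[[length(ranges) + 1]] <- c(i, j)
    }
  }
  lab <- rep("", k)
  for (r in seq_along(ranges)) {
    ix <- seq(ranges[[r]][1], ranges[[r]][2])
    lab[ix] <- paste0(lab[ix], letters[r])
  }
  lab
}

#' Duncan's multiple range test with compact letter display
#'
#' Step-down multiple comparison of >= 3 group means using studentized-range
#' critical values at the Duncan protection level
#' `alpha_p = 1 - (1 - alpha)^(p - 1)` for a span of `p` means. The
#' critical range for a span is `q(1 - alpha_p, p, df) * sqrt(MSE / n_h)`
#' with `n_h` the harmonic mean of group sizes and MSE/df from the one-way
#' ANOVA over all groups. Groups sharing a letter are not significantly
#' different.
#'
#' @param values Named list of numeric vectors, one per group.
#' @param alpha Nominal per-comparison significance level (default 0.05).
#' @return Data frame (descending mean order): group, n, mean, letters.
#'   Critical ranges are attached as attribute `"critical_ranges"`.
#' @export
duncan_letters <- function(values, alpha = 0.05) {
  k <- length(values)
  if (k < 3) stop("duncan_letters needs >= 3 groups; use two_group_test")
  if (is.null(names(values))) names(values) <- paste0("G", seq_len(k))
  ns_i <- lengths(values)
  means <- vapply(values, mean, numeric(1))
  all_y <- unlist(values, use.names = FALSE)
  grp <- factor(rep(names(values), ns_i), levels = names(values))
  fit <- stats::aov(all_y ~ grp)
  tab <- summary(fit)[[1]]
  mse <- tab["Residuals", "Mean Sq"]
  df_err <- tab["Residuals", "Df"]
  n_h <- k / sum(1 / ns_i)
  ord <- order(-means)
  m_sorted <- means[ord]
  crit <- c(NA, vapply(2:k, function(p) {
    alpha_p <- 1 - (1 - alpha)^(p - 1)
    stats::qtukey(1 - alpha_p, p, df_err) * sqrt(mse / n_h)
  }, numeric(1)))
  ns <- duncan_ns_matrix(m_sorted, crit)
  out <- data.frame(group = names(values)[ord], n = as.integer(ns_i[ord]),
                    mean = unname(m_sorted),
                    letters = letters_from_ns(m_sorted, ns),
                    stringsAsFactors = FALSE)
  attr(out, "critical_ranges") <- crit
  out
}

#' Percent of variation explained by haplotype groups
#'
#' One-way ANOVA eta-squared: `100 * SS_between / SS_total` of the trait
#' values (typically BLUPs) over the retained haplotype groups, reported
#' with the overall F-test p-value.
#'
#' @param values Named list of numeric vectors, one per retained group.
#' @return List with `r2` (percent), `p` (overall F p), `ss_between`,
#'   `ss_total`, `df`.
#' @export
variance_explained <- function(values) {
  if (length(values) < 2) stop("need >= 2 retained groups")
  all_y <- unlist(values, use.names = FALSE)
  grp <- factor(rep(seq_along(values), lengths(values)))
  sst <- sum((all_y - mean(all_y))^2)
  if (sst == 0) {
    warning("total sum of squares is zero; R2 undefined")
    return(list(r2 = NA_real_, p = NA_real_, ss_between = 0, ss_total = 0,
                df = c(length(values) - 1, length(all_y) - length(values))))
  }
  fit <- stats::aov(all_y ~ grp)
  tab <- summary(fit)[[1]]
  ssb <- tab["grp", "Sum Sq"]
  list(r2 = 100 * ssb / sst,
       p = tab["grp", "Pr(>F)"],
       ss_between = ssb, ss_total = sst,
       df = c(tab["grp", "Df"], tab["Residuals", "Df"]))
}

#' Identify the superior haplotype group
#'
#' The retained group whose trait mean is most favorable for the breeding
#' direction: maximal mean for `"maximize"`, minimal for `"minimize"`.
#' Ties are broken toward the larger group (logged).
#'
#' @param group_stats Data frame with columns `label`, `mean` and `count`
#'   for the retained groups.
#' @param direction `"maximize"` or `"minimize"`.
#' @return The superior group's label.
#' @export
superior_haplotype <- function(group_stats,
                               direction = c("maximize", "minimize")) {
  direction <- match.arg(direction)
  if (nrow(group_stats) == 0) stop("no retained groups")
  target <- if (direction == "maximize") max(group_stats$mean) else
    min(group_stats$mean)
  best <- group_stats[group_stats$mean == target, , drop = FALSE]
  if (nrow(best) > 1) {
    message("superior_haplotype: mean tie broken toward the larger group")
    best <- best[order(-best$count), , drop = FALSE]
  }
  best$label[1]
}

#' Combine haplotypes across a gene set
#'
#' Per accession, the tuple of per-gene haplotype labels becomes a
#' multi-gene haplotype combination; an accession missing at any gene has a
#' missing combination. Combinations are labelled `HC1, HC2, ...` by
#' descending frequency (ties by lexicographic label tuple). The returned
#' object is a `haplotype_assignment` over the pooled variant sites, so
#' rare-group filtering, group statistics and marker selection apply
#' unchanged; the per-gene composition of each combination is recorded in
#' the `component` column of `groups`.
#'
#' @param assignments List of >= 2 `haplotype_assignment` objects (one per
#'   gene) over overlapping accession sets.
#' @return A `haplotype_assignment` for the combination.
#' @export
combine_haplotypes <- function(assignments) {
  if (length(assignments) < 2) {
    if (length(assignments) == 1) return(assignments[[1]])
    stop("need >= 1 haplotype assignment")
  }
  genes <- vapply(assignments, function(a) a$gene, character(1))
  acc <- Reduce(intersect, lapply(assignments, function(a) names(a$labels)))
  if (length(acc) == 0) stop("assignments share no accessions")
  label_mat <- vapply(assignments, function(a) a$labels[acc],
                      character(length(acc)))
  hap_mat <- vapply(assignments, function(a) a$hap[acc],
                    character(length(acc)))
  ok <- rowSums(is.na(label_mat)) == 0
  tuple <- rep(NA_character_, length(acc))
  tuple[ok] <- apply(label_mat[ok, , drop = FALSE], 1, paste, collapse = "/")
  hap <- rep(NA_character_, length(acc))
  hap[ok] <- apply(hap_mat[ok, , drop = FALSE], 1, paste, collapse = "")
  names(hap) <- acc
  # concatenated allele strings and label tuples identify the same groups
  tie_key <- stats::setNames(tuple[ok], hap[ok])
  groups <- hap_groups_from_strings(hap, panel_size = length(acc),
                                    label_prefix = "HC", tie_key = tie_key)
  groups$component <- tie_key[groups$hap_string]
  labels <- groups$label[match(hap, groups$hap_string)]
  names(labels) <- acc
  variants <- do.call(rbind, lapply(assignments, function(a) a$variants))
  rownames(variants) <- NULL
  site_alleles <- do.call(cbind, lapply(assignments, function(a) {
    a$site_alleles[acc, , drop = FALSE]
  }))
  structure(list(gene = paste(genes, collapse = "+"), variants = variants,
                 hap = hap, labels = labels, groups = groups,
                 panel_size = length(acc), site_alleles = site_alleles),
            class = "haplotype_assignment")
}

#' Haplo-pheno analysis of one gene or gene set
#'
#' Full group comparison for a haplotype (or haplotype-combination)
#' assignment against per-accession trait values (typically BLUPs): rare
#' groups are excluded, group means and panel percentages tabulated, group
#' differences tested (pooled Student's t for two groups, Duncan's multiple
#' range test with compact letters for more), variance explained computed
#' as one-way ANOVA eta-squared, and the superior group identified
#' according to the breeding direction.
#'
#' @param a A `haplotype_assignment`.
#' @param values Named numeric vector of per-accession trait values.
#' @param direction `"maximize"` or `"minimize"`.
#' @param min_count,mode,min_percent Rare-group rule, see
#'   [filter_rare_haplotypes()].
#' @param alpha Significance level for the letter display.
#' @param welch Use Welch's t for two-group comparisons.
#' @return A `haplo_pheno_result`: list with `gene`, `table` (label,
#'   count, percent, mean, letters), `r2`, `p_overall`, `p_pairwise` (two
#'   groups only), `superior`, `n_used`.
#' @export
haplo_pheno <- function(a, values, direction = c("maximize", "minimize"),
                        min_count = 4L, mode = c("count", "percent"),
                        min_percent = 1, alpha = 0.05, welch = FALSE) {
  direction <- match.arg(direction)
  mode <- match.arg(mode)
  af <- filter_rare_haplotypes(a, min_count = min_count, mode = mode,
                               min_percent = min_percent)
  lab <- af$labels_retained
  acc <- names(lab)[!is.na(lab) & names(lab) %in% names(values)]
  group_values <- split(values[acc], lab[acc])
  group_values <- group_values[af$groups$label[af$groups$label %in%
                                                 names(group_values)]]
  if (length(group_values) == 0) stop("no retained group has trait values")
  tab <- af$groups[af$groups$label %in% names(group_values), , drop = FALSE]
  tab$mean <- vapply(group_values[tab$label], mean, numeric(1))
  p_pair <- NA_real_
  if (length(group_values) == 1) {
    tab$letters <- "a"
    p_over <- NA_real_
    r2 <- NA_real_
  } else if (length(group_values) == 2) {
    p_pair <- two_group_test(group_values[[1]], group_values[[2]],
                             welch = welch)
    ve <- variance_explained(group_values)
    r2 <- ve$r2
    p_over <- ve$p
    tab$letters <- if (p_pair < alpha) {
      c("a", "b")[rank(-tab$mean, ties.method = "first")]
    } else c("a", "a")
  } else {
    dl <- duncan_letters(group_values, alpha = alpha)
    tab$letters <- dl$letters[match(tab$label, dl$group)]
    ve <- variance_explained(group_values)
    r2 <- ve$r2
    p_over <- ve$p
  }
  superior <- superior_haplotype(tab, direction)
  structure(list(gene = a$gene, table = tab, r2 = r2,
                 p_overall = p_over, p_pairwise = p_pair,
                 superior = superior, direction = direction,
                 n_used = length(acc)),
            class = "haplo_pheno_result")
}

#' @export
print.haplo_pheno_result <- function(x, ...) {
  cat(sprintf("haplo-pheno result for %s (%s): superior = %s, R2 = %s%%\n",
              x$gene, x$direction, x$superior,
              ifelse(is.na(x$r2), "NA", sprintf("%.2f", x$r2))))
  print(x$table[, c("label", "count", "percent", "mean", "letters")])
  invisible(x)
}
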