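make_pheno <- function(values, trait = "T") {
  # values: accessions x environments matrix
  acc <- rownames(values); envs <- colnames(values)
  do.call(rbind, lapply(envs, function(ev) {
    data.frame(accession = acc, trait = trait, environment = ev,
               replicate = 1L, value = values[, ev],
               stringsAsFactors = FALSE)
  }))
}

test_that("variance components match a hand-computed two-way ANOVA", {
  vals <- matrix(c(10, 8, 12, 12, 9, 14), nrow = 3,
                 dimnames = list(c("A", "B", "C"), c("e1", "e2")))
  ph <- make_pheno(vals)
  vc <- suppressMessages(variance_components(ph, "T"))
  # independent arithmetic: sums of squares written out explicitly
  grand <- mean(vals)
  acc_m <- rowMeans(vals); env_m <- colMeans(vals)
  ss_acc <- 2 * sum((acc_m - grand)^2)
  ss_env <- 3 * sum((env_m - grand)^2)
  ss_tot <- sum((vals - grand)^2)
  ss_res <- ss_tot - ss_acc - ss_env
  ms_acc <- ss_acc / 2; ms_res <- ss_res / 2
  expect_equal(vc$Vg, (ms_acc - ms_res) / 2)
  expect_equal(vc$Ve, ms_res)
  expect_equal(vc$Vge, 0)  # confounded at r = 1
  expect_equal(vc$e, 2L); expect_equal(vc$r, 1)
})

test_that("no genotypic spread gives Vg = 0 and single-environment errors", {
  vals <- matrix(c(5, 5, 5, 7, 7, 7), nrow = 3,
                 dimnames = list(c("A", "B", "C"), c("e1", "e2")))
  vc <- suppressMessages(variance_components(make_pheno(vals), "T"))
  expect_equal(vc$Vg, 0)
  one_env <- make_pheno(vals[, 1, drop = FALSE])
  expect_error(suppressMessages(variance_components(one_env, "T")),
               ">= 2 environments")
})

test_that("heritability follows the printed formula exactly", {
  vc <- structure(list(Vg = 1, Vge = 1, Ve = 1, e = 2, r = 1),
                  class = "variance_components")
  expect_equal(heritability(vc), 0.5)
  vc$Vge <- 0; vc$Ve <- 0
  expect_equal(heritability(vc), 1)
  vc$Vg <- 0
  expect_error(heritability(vc), "undefined")
  vc2 <- structure(list(Vg = 2.5, Vge = 0.8, Ve = 1.3, e = 3, r = 2),
                   class = "variance_components")
  expect_equal(heritability(vc2), 2.5 / (2.5 + 0.8 / 3 + 1.3 / 6))
})

test_that("heritability is invariant to rescaling the phenotype", {
  set.seed(11)
  vals <- matrix(rnorm(20, 20, 3), nrow = 10,
                 dimnames = list(sprintf("a%02d", 1:10), c("e1", "e2")))
  vc1 <- suppressMessages(variance_components(make_pheno(vals), "T"))
  vc2 <- suppressMessages(variance_components(make_pheno(vals * 3.7), "T"))
  expect_equal(vc2$Vg, vc1$Vg * 3.7^2, tolerance = 1e-10)
  expect_equal(heritability(vc1), heritability(vc2), tolerance = 1e-12)
})

test_that("moment estimators recover simulated components with replicates", {
  truth <- c(Vg = 4, Vge = 1, Ve = 1)
  n <- 250; e <- 2; r <- 2
  est <- t(sapply(1:40, function(s) {
    set.seed(400 + s)
    g <- rnorm(n, 0, sqrt(truth["Vg"]))
    ph <- do.call(rbind, lapply(1:e, function(j) {
      ge <- rnorm(n, 0, sqrt(truth["Vge"]))
      do.call(rbind, lapply(1:r, function(k) {
        data.frame(accession = sprintf("a%03d", 1:n), trait = "T",
                   environment = paste0("e", j), replicate = k,
                   value = 10 + g + ge + rnorm(n, 0, sqrt(truth["Ve"])))
      }))
    }))
    vc <- variance_components(ph, "T")
    c(vc$Vg, vc$Vge, vc$Ve)
  }))
  for (i in 1:3) {
    se <- sd(est[, i]) / sqrt(nrow(est))
    expect_lt(abs(mean(est[, i]) - truth[i]), 3 * se + 0.02)
  }
})

test_that("BLUPs match the mixed-model equations and shrinkage limits", {
  set.seed(5)
  acc <- paste0("a", 1:5)
  vals <- matrix(rnorm(10, 10, 2), nrow = 5,
                 dimnames = list(acc, c("env1", "env2")))
  vals[, 2] <- vals[, 2] + 1.5
  ph <- make_pheno(vals)
  vc <- suppressMessages(variance_components(ph, "T"))
  b <- blup(ph, "T", vc)
  # Henderson MME oracle with the same variance components
  X <- stats::model.matrix(~ factor(ph$environment))
  Z <- stats::model.matrix(~ 0 + factor(ph$accession, levels = acc))
  k <- (vc$Vge + vc$Ve) / vc$Vg
  C <- rbind(cbind(crossprod(X), crossprod(X, Z)),
             cbind(crossprod(Z, X), crossprod(Z) + k * diag(5)))
  sol <- solve(C, rbind(crossprod(X, ph$value), crossprod(Z, ph$value)))
  pred_mme <- mean(X %*% sol[1:2]) + sol[-(1:2)]
  expect_equal(unname(b$blup[acc]), unname(pred_mme), tolerance = 1e-10)
  # deviations center on zero; ordering of accession means is preserved
  expect_equal(mean(b$blup) - b$grand_mean, 0, tolerance = 1e-10)
  centered_means <- rowMeans(sweep(vals, 2, colMeans(vals)))
  expect_identical(order(b$blup[acc]), order(centered_means))
  # no-shrinkage limit: huge Vg returns env-centered accession means
  vc_inf <- vc; vc_inf$Vg <- 1e12
  b_inf <- blup(ph, "T", vc_inf)
  expect_equal(unname(b_inf$blup[acc]),
               unname(centered_means + mean(vals)), tolerance = 1e-6)
  # full-shrinkage limit: Vg = 0 collapses to the grand mean
  vc0 <- vc; vc0$Vg <- 0
  expect_warning(b0 <- blup(ph, "T", vc0), "grand mean")
  expect_true(all(abs(b0$blup - b0$grand_mean) < 1e-12))
})

test_that("trait correlations match cor.test and flag degenerate traits", {
  set.seed(21)
  x <- rnorm(60); z <- rnorm(60)
  mat <- cbind(t1 = x, t2 = -x, t3 = 0.5 * x + z)
  tc <- trait_correlations(mat)
  expect_equal(diag(tc$r), c(t1 = 1, t2 = 1, t3 = 1))
  expect_equal(tc$r["t1", "t2"], -1)
  ct <- stats::cor.test(mat[, "t1"], mat[, "t3"])
  expect_equal(tc$r["t1", "t3"], unname(ct$estimate), tolerance = 1e-12)
  expect_equal(tc$p["t1", "t3"], ct$p.value, tolerance = 1e-12)
  expect_warning(trait_correlations(cbind(a = x, b = rep(1, 60))),
                 "zero-variance")
})
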