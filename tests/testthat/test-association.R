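make_trans_cohort <- function(n = 100, p = 300, n_effect = 0,
                              effect = -0.8, seed = 1) {
  set.seed(seed)
  feature <- rbinom(n, 1, 0.5)
  covs <- data.frame(age = rnorm(n, 60, 10),
                     gender = sample(c("F", "M"), n, TRUE),
                     purity = runif(n, 0.4, 0.9))
  Y <- matrix(rnorm(p * n), p, n,
              dimnames = list(sprintf("G%04d", seq_len(p)), NULL))
  if (n_effect > 0)
    Y[seq_len(n_effect), feature == 1] <-
      Y[seq_len(n_effect), feature == 1] + effect
  list(feature = feature, Y = Y, covs = covs)
}

test_that("trans_assoc t statistics equal a least-squares oracle", {
  ch <- make_trans_cohort(n = 60, p = 40, seed = 2)
  res <- trans_assoc(ch$feature, ch$Y, ch$covs, n_perm = 20, seed = 3)
  for (g in sample(rownames(ch$Y), 10)) {
    y <- inverse_normal_transform(ch$Y[g, ])
    fit <- summary(lm(y ~ ch$feature + age + gender + purity,
                      data = ch$covs))
    expect_equal(res$t[res$trait == g], fit$coefficients["ch$feature", 3],
                 tolerance = 1e-10)
    expect_equal(res$p[res$trait == g], fit$coefficients["ch$feature", 4],
                 tolerance = 1e-10)
  }
  expect_error(trans_assoc(rep(1, 60), ch$Y), "constant")
})

test_that("trans_assoc finds planted effects with correct direction", {
  ch <- make_trans_cohort(n = 100, p = 500, n_effect = 60, seed = 4)
  res <- trans_assoc(ch$feature, ch$Y, ch$covs, n_perm = 50, seed = 5)
  planted <- sprintf("G%04d", 1:60)
  hits <- res$trait[res$significant]
  expect_gte(length(intersect(hits, planted)) / 60, 0.8)
  expect_true(all(res$direction[res$significant &
                                  res$trait %in% planted] == -1))
})

test_that("eFDR curve is non-increasing and threshold deterministic", {
  ch <- make_trans_cohort(n = 80, p = 200, n_effect = 20, seed = 6)
  r1 <- trans_assoc(ch$feature, ch$Y, ch$covs, n_perm = 30, seed = 7)
  r2 <- trans_assoc(ch$feature, ch$Y, ch$covs, n_perm = 30, seed = 7)
  expect_identical(r1, r2)
  curve <- attr(r1, "efdr_curve")
  expect_true(all(diff(curve$efdr) <= 1e-12))
})

test_that("pathway_score behaves on ties, planted sets and matches U", {
  set.seed(8)
  genes <- sprintf("G%03d", 1:50)
  beta <- setNames(rnorm(50), genes)
  p <- setNames(runif(50), genes)
  # in-set identical to out-set: p = 1, score 0
  T_j <- -sign(beta) * log(p)
  same <- list(s = genes)   # set = everything fails the out-set, so craft:
  beta2 <- setNames(c(rep(1, 10), rep(1, 40)), genes)
  p2 <- setNames(rep(0.5, 50), genes)
  ps2 <- pathway_score(beta2, p2, list(s = genes[1:10]))
  expect_equal(ps2$p, 1, tolerance = 1e-12)
  expect_equal(ps2$score, 0)
  # planted up-set: all betas positive, tiny p
  beta3 <- beta; p3 <- p
  beta3[1:10] <- abs(beta3[1:10]); p3[1:10] <- 1e-8
  ps3 <- pathway_score(beta3, p3, list(up = genes[1:10]))
  expect_equal(ps3$direction, 1)
  expect_lt(ps3$p_adj, 0.05)
  expect_gt(ps3$score, 1)
  # rank-sum statistic matches brute force on a 10-vs-40 toy
  rs <- proteopipe:::.ranksum_p(T_j[1:10], T_j[11:50])
  expect_equal(rs$u, oracle_U(T_j[1:10], T_j[11:50]))
  expect_equal(rs$p,
               wilcox.test(T_j[1:10], T_j[11:50], exact = FALSE,
                           correct = FALSE)$p.value,
               tolerance = 1e-12)
})

make_cis_cohort <- function(n = 80, p = 60, seed = 1, effect_genes = 1:6,
                            meth_genes = 7:12) {
  set.seed(seed)
  genes <- sprintf("G%04d", seq_len(p))
  lr <- matrix(rnorm(p * n, 0, 0.3), p, n, dimnames = list(genes, NULL))
  baf <- matrix(rnorm(p * n, 0.5, 0.05), p, n, dimnames = list(genes, NULL))
  methy <- matrix(rbeta(p * n, 2, 2), p, n, dimnames = list(genes, NULL))
  base <- matrix(rnorm(p * n), p, n, dimnames = list(genes, NULL))
  mrna <- base + matrix(rnorm(p * n, 0, 0.4), p, n)
  prot <- base + matrix(rnorm(p * n, 0, 0.4), p, n)
  phos <- base + matrix(rnorm(p * n, 0, 0.4), p, n)
  for (g in effect_genes) {      # strong positive CNV-lr effect everywhere
    mrna[g, ] <- mrna[g, ] + 3 * lr[g, ]
    prot[g, ] <- prot[g, ] + 3 * lr[g, ]
    phos[g, ] <- phos[g, ] + 3 * lr[g, ]
  }
  for (g in meth_genes) {        # positive methylation effect (wrong sign)
    mrna[g, ] <- mrna[g, ] + 3 * methy[g, ]
    prot[g, ] <- prot[g, ] + 3 * methy[g, ]
    phos[g, ] <- phos[g, ] + 3 * methy[g, ]
  }
  dimnames(mrna) <- dimnames(prot) <- dimnames(phos) <- list(genes, NULL)
  list(traits = list(mrna = mrna, protein = prot, phospho = phos),
       variations = list(cnv_lr = lr, cnv_baf = baf, methy = methy),
       covs = data.frame(age = rnorm(n, 60, 10), purity = runif(n, .4, .9)))
}

test_that("cis_assoc labels configurations and honors directional filters", {
  ch <- make_cis_cohort(seed = 11)
  cc <- cis_assoc(ch$traits, ch$variations, ch$covs, n_perm = 40, seed = 12)
  # strong consistent positive CNV-lr effect on all three traits
  expect_true(all(cc$configurations[1:6, "cnv_lr"] == "all three"))
  # positive methylation associations are filtered out regardless of p
  meth_calls <- cc$calls[cc$calls$variation == "methy" &
                           cc$calls$gene %in% sprintf("G%04d", 7:12), ]
  expect_false(any(meth_calls$significant))
  expect_false(any(meth_calls$passes_filter))
  expect_error(cis_assoc(lapply(ch$traits, function(m) m[1:10, ]),
                         ch$variations, ch$covs), "30")
})

test_that("r2_decomposition matches the two-fit oracle and identities", {
  set.seed(21)
  n <- 50
  x1 <- rnorm(n); x2 <- rnorm(n); cov1 <- rnorm(n)
  y <- 2 * x1 + rnorm(n)
  vm <- cbind(v1 = x1, v2 = x2)
  d <- r2_decomposition(y, vm, data.frame(cov1 = cov1))
  f_full <- summary(lm(y ~ x1 + x2 + cov1))$r.squared
  f_no1 <- summary(lm(y ~ x2 + cov1))$r.squared
  f_no2 <- summary(lm(y ~ x1 + cov1))$r.squared
  expect_equal(unname(d["v1"]), f_full - f_no1)
  expect_equal(unname(d["v2"]), max(0, f_full - f_no2))
  # single predictor, no covariates: delta R2 = squared Pearson r
  d1 <- r2_decomposition(y, cbind(v1 = x1))
  expect_equal(unname(d1["v1"]), cor(y, x1)^2)
  # orthogonal variation: ~0
  expect_lt(unname(d["v2"]), 0.1)
  # collinear design errors with column names
  expect_error(r2_decomposition(y, cbind(a = x1, b = x1)), "b")
})

test_that("clinical_multivariate coefficients match lm and counts nulls", {
  set.seed(31)
  n <- 70; p <- 40
  clin <- data.frame(stage = sample(1:4, n, TRUE), age = rnorm(n, 60, 8),
                     gender = sample(c("F", "M"), n, TRUE))
  Y <- matrix(rnorm(p * n), p, n,
              dimnames = list(sprintf("G%03d", 1:p), NULL))
  Y[1:8, ] <- Y[1:8, ] + 0.8 * matrix(rep(clin$stage, each = 8), 8, n)
  res <- clinical_multivariate(Y, clin)
  for (g in c("G001", "G020", "G040")) {
    fit <- summary(lm(Y[g, ] ~ stage + age + gender, data = clin))
    expect_equal(unname(res$beta[g, "stage"]),
                 fit$coefficients["stage", 1], tolerance = 1e-10)
  }
  # planted stage effects dominate the stage calls
  called <- names(which(res$p_adj[, "stage"] < 0.1))
  expect_true(all(sprintf("G%03d", 1:8) %in% called))
  # independent covariate: few calls
  expect_lte(res$counts[["age"]], 4)
})

test_that("permuting covariates jointly with outcomes leaves t invariant", {
  ch <- make_trans_cohort(n = 50, p = 30, n_effect = 10, seed = 41)
  perm <- sample(50)
  r0 <- trans_assoc(ch$feature, ch$Y, ch$covs, n_perm = 10, seed = 1)
  r1 <- trans_assoc(ch$feature[perm], ch$Y[, perm],
                    ch$covs[perm, ], n_perm = 10, seed = 1)
  expect_equal(r0$t, r1$t, tolerance = 1e-9)
})
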