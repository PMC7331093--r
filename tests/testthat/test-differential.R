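mk_mat <- function(p, n, prefix, seed, mean = 0, sd = 1) {
  set.seed(seed)
  m <- matrix(rnorm(p * n, mean, sd), p, n,
              dimnames = list(sprintf("F%03d", seq_len(p)),
                              sprintf("%s%03d", prefix, seq_len(n))))
  m
}

test_that("wilcoxon_diff calls exactly the planted features", {
  tum <- mk_mat(100, 30, "T", 1)
  nat <- mk_mat(100, 30, "N", 2)
  tum[1:20, ] <- tum[1:20, ] * 0.1 + 2      # 4-fold (log2 = 2), tiny sd
  nat[1:20, ] <- nat[1:20, ] * 0.1
  res <- wilcoxon_diff(tum, nat)
  expect_setequal(res$feature[res$significant], sprintf("F%03d", 1:20))
  # identical groups: nothing significant, p = 1 region
  res0 <- wilcoxon_diff(tum, tum)
  expect_false(any(res0$significant))
  expect_true(all(res0$p > 0.9))
  # statistic equals the brute-force U oracle
  for (f in sample(rownames(tum), 10)) {
    expect_equal(res$statistic[res$feature == f],
                 oracle_U(tum[f, ], nat[f, ]))
  }
})

test_that("fit_purity_model recovers planted mixture parameters", {
  set.seed(31)
  n <- 80; p <- 60
  pur <- runif(n, 0.4, 0.9)
  muY <- rnorm(p, 0, 1.5); muZ <- rnorm(p, 0, 1.5)
  X <- sapply(seq_len(n), function(i)
    pur[i] * rnorm(p, muY, 0.5) + (1 - pur[i]) * rnorm(p, muZ, 0.5))
  rownames(X) <- sprintf("F%03d", seq_len(p))
  fit <- fit_purity_model(X, pur)
  # asymptotic SEs from the Fisher information of the mean parameters
  se_y <- sqrt(1 / sum(pur^2 / (pur^2 * 0.25 + (1 - pur)^2 * 0.25)))
  expect_gt(mean(abs(fit$mu_y - muY) < 3 * se_y * 2), 0.9)
  expect_lt(sqrt(mean((fit$mu_y - muY)^2)), 3 * se_y)
})

test_that("degenerate purity designs are handled as specified", {
  X <- mk_mat(10, 20, "S", 3)
  # all purity 1: muY = sample mean, muZ flagged unidentified
  f1 <- fit_purity_model(X, rep(1, 20))
  expect_true(attr(f1, "z_unidentified"))
  expect_equal(f1$mu_y, rowMeans(X), ignore_attr = TRUE)
  expect_true(all(is.na(f1$mu_z)))
  # constant purity < 1: error
  expect_error(fit_purity_model(X, rep(0.5, 20)), "unidentifiable")
  # zero-noise two-purity design: exact linear solve
  muY <- 1:5; muZ <- c(-2, 0, 2, -1, 1)
  pur2 <- rep(c(0.5, 1), each = 10)
  X2 <- sapply(pur2, function(p) p * muY + (1 - p) * muZ)
  rownames(X2) <- sprintf("G%d", 1:5)
  f2 <- fit_purity_model(X2, pur2)
  expect_equal(f2$mu_y, muY, tolerance = 1e-4, ignore_attr = TRUE)
  expect_equal(f2$mu_z, muZ, tolerance = 1e-4, ignore_attr = TRUE)
})

test_that("purity_diff is deterministic and finds masked effects", {
  set.seed(41)
  n <- 40; p <- 80
  purT <- runif(n, 0.35, 0.6)   # low purity: strong stromal dilution
  purN <- runif(n, 0.7, 0.95)
  muN <- rnorm(p); muS <- rnorm(p)
  muT <- muN
  planted <- 1:10
  muT[planted] <- muN[planted] + 3
  # stroma shifted the opposite way so the bulk difference is masked
  muS_T <- muS; muS_T[planted] <- muS[planted] - 3
  gen <- function(mu, muS, pur) sapply(pur, function(pp)
    pp * rnorm(p, mu, 0.3) + (1 - pp) * rnorm(p, muS, 0.3))
  X_T <- gen(muT, muS_T, purT); rownames(X_T) <- sprintf("F%03d", 1:p)
  X_N <- gen(muN, muS, purN); rownames(X_N) <- sprintf("F%03d", 1:p)
  colnames(X_T) <- sprintf("T%02d", 1:n)
  colnames(X_N) <- sprintf("N%02d", 1:n)
  pd <- purity_diff(X_T, X_N, purT, purN, n_perm = 60, seed = 5)
  called <- pd$feature[pd$significant]
  expect_gte(length(intersect(called, sprintf("F%03d", planted))), 8)
  # the bulk Wilcoxon misses most of the masked features
  wd <- wilcoxon_diff(X_T, X_N, fc_threshold = 2, fdr_threshold = 0.10)
  bulk_hits <- intersect(wd$feature[wd$significant],
                         sprintf("F%03d", planted))
  expect_lt(length(bulk_hits), length(intersect(called,
                                                sprintf("F%03d", planted))))
  # fixed seed: identical calls across runs
  pd2 <- purity_diff(X_T, X_N, purT, purN, n_perm = 60, seed = 5)
  expect_identical(pd, pd2)
})

test_that("purity_diff at purity 1 agrees with a t-test oracle", {
  set.seed(51)
  p <- 50; n <- 25
  X_T <- mk_mat(p, n, "T", 52); X_N <- mk_mat(p, n, "N", 53)
  X_T[1:5, ] <- X_T[1:5, ] + 4
  pd <- purity_diff(X_T, X_N, rep(1, n), rep(1, n), n_perm = 100, seed = 6)
  tt <- sapply(rownames(X_T), function(f)
    t.test(X_T[f, ], X_N[f, ])$p.value)
  # strong effects called by both, nulls by neither
  expect_setequal(pd$feature[pd$significant],
                  names(tt)[tt < 1e-6 & abs(rowMeans(X_T) -
                                              rowMeans(X_N)) > 1][1:5])
})

test_that("allocate_nat_regions assigns by highest signature score", {
  set.seed(61)
  regions <- list(cortex = sprintf("F%03d", 1:10),
                  medulla = sprintf("F%03d", 11:20),
                  infla = sprintf("F%03d", 21:30))
  p <- 30; n <- 30
  truth <- sample(names(regions), n, replace = TRUE)
  X <- matrix(rnorm(p * n, 0, 0.5), p, n,
              dimnames = list(sprintf("F%03d", 1:p),
                              sprintf("N%02d", 1:n)))
  for (i in seq_len(n))
    X[regions[[truth[i]]], i] <- X[regions[[truth[i]]], i] + 3
  out <- allocate_nat_regions(X, regions)
  expect_gte(mean(out$region == truth), 0.95)
  # exact tie: first declared region wins
  X2 <- matrix(0, 30, 2, dimnames = list(sprintf("F%03d", 1:30),
                                         c("a", "b")))
  X2[, 1] <- rep(c(1, 1, 0), each = 10)   # cortex & medulla tie in sample a
  X2[, 2] <- rep(c(0, 0, 1), each = 10)
  expect_message(out2 <- allocate_nat_regions(X2, regions), "tie")
  expect_equal(out2$region[1], "cortex")
})

test_that("bh_adjust matches the brute-force oracle", {
  set.seed(71)
  for (len in c(13, 500, 1000)) {
    pv <- runif(len)^2
    expect_equal(bh_adjust(pv), oracle_bh(pv))
  }
})
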