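design <- toy_design()

test_that("filter_psms applies each quality rule and redundancy resolution", {
  psm <- rbind(
    toy_psm_row("s01"),                                    # clean
    toy_psm_row("s02", labeled = FALSE),                   # (a)
    toy_psm_row("s03", ch01 = 0),                          # (b)
    toy_psm_row("s04", purity = 0.49, peptide = "PEPC"),   # (c) removed
    toy_psm_row("s05", purity = 0.50, peptide = "PEPD"),   # (c) kept
    toy_psm_row("s06", contaminant = TRUE),
    toy_psm_row("s07", peptide = "PEPB", ch02 = 10, ch03 = 10, ch01 = 10),
    toy_psm_row("s08", peptide = "PEPB", ch02 = 20, ch03 = 20, ch01 = 20))
  out <- filter_psms(psm, design)
  expect_setequal(out$spectrum_id, c("s01", "s05", "s08"))
  # lowest-intensity PSM of PEPB lost to redundancy, not percentile:
  # s07 and s08 share a peptide ion and only the higher sum survives
  expect_false("s07" %in% out$spectrum_id)
})

test_that("filter_psms matches the rule-at-a-time oracle on random tables", {
  for (seed in c(11L, 12L)) {
    psm <- random_psm_table(500L, seed)
    got <- filter_psms(psm, design)
    want <- oracle_filter(psm)
    expect_setequal(got$spectrum_id, want$spectrum_id)
  }
})

test_that("filter_psms is idempotent", {
  psm <- random_psm_table(300L, 21L)
  once <- filter_psms(psm, design)
  twice <- filter_psms(once, design)
  expect_equal(twice, once)
})

test_that("phospho mode keeps only phosphopeptides at the 2.5% percentile", {
  psm <- do.call(rbind, lapply(1:80, function(i)
    toy_psm_row(sprintf("s%03d", i), peptide = sprintf("P%03d", i),
                site = if (i %% 2 == 0) sprintf("S%d", i) else NA,
                ch01 = 50 + i, ch02 = 50 + i, ch03 = 50 + i)))
  out <- filter_psms(psm, design, phospho_mode = TRUE)
  expect_true(all(!is.na(out$site)))
  # 2.5th percentile of 80 rows removes the bottom sums only
  expect_lt(nrow(out), sum(!is.na(psm$site)))
})

test_that("psm_ratios computes log2 channel-over-reference, NA for zeros", {
  psm <- rbind(toy_psm_row("s01", ch01 = 100, ch02 = 100, ch03 = 200),
               toy_psm_row("s02", ch01 = 50, ch02 = 0, ch03 = 25))
  pr <- psm_ratios(psm, design)
  expect_equal(unname(pr$ratios[1, "S1_1"]), 0)
  expect_equal(unname(pr$ratios[1, "S1_2"]), 1)
  expect_true(is.na(pr$ratios[2, "S1_1"]))   # zero channel -> missing
  expect_equal(unname(pr$ratios[2, "S1_2"]), log2(25 / 50))
  # random table matches element-wise oracle
  psm2 <- random_psm_table(50L, 31L)
  psm2 <- filter_psms(psm2, design)
  pr2 <- psm_ratios(psm2, design)
  expect_equal(pr2$ratios[, "S1_1"],
               ifelse(psm2$ch02 > 0, log2(psm2$ch02) - log2(psm2$ch01), NA),
               ignore_attr = TRUE)
})

test_that("iqr_trim matches the brute-force fence oracle", {
  expect_equal(iqr_trim(c(1, 2, 3, 4, 100)), c(1, 2, 3, 4))
  expect_equal(iqr_trim(rep(7, 5)), rep(7, 5))
  set.seed(41)
  v <- rcauchy(1000)
  expect_equal(sort(iqr_trim(v)), sort(oracle_iqr_trim(v)))
  expect_error(iqr_trim(NA_real_), "finite")
})

test_that("summarize_level trims then takes the median per entry/sample", {
  psm <- rbind(
    toy_psm_row("s01", gene = "G1", peptide = "PA",
                ch01 = 100, ch02 = 100, ch03 = 100),
    toy_psm_row("s02", gene = "G1", peptide = "PB",
                ch01 = 100, ch02 = 100, ch03 = 100),
    toy_psm_row("s03", gene = "G1", peptide = "PC",
                ch01 = 100, ch02 = 100 * 2^10, ch03 = 100))
  pr <- psm_ratios(psm, design)
  m <- summarize_level(pr, "gene")
  # ratios for S1_1 are (0, 0, 10): the fence excludes 10, median(0, 0) = 0
  expect_equal(m["G1", "S1_1"], 0)
  expect_equal(m["G1", "S1_2"], 0)
})

test_that("mad_normalize implements the centering/scaling formulas", {
  set.seed(5)
  m <- matrix(rnorm(50 * 8), 50, 8,
              dimnames = list(sprintf("g%02d", 1:50), sprintf("s%d", 1:8)))
  out <- mad_normalize(m)
  M0 <- attr(out, "M0"); MAD0 <- attr(out, "MAD0")
  for (j in 1:8) {
    expect_equal(median(out[, j]), M0, tolerance = 1e-9)
    expect_equal(median(abs(out[, j] - median(out[, j]))), MAD0,
                 tolerance = 1e-9)
  }
  # single sample: formulas collapse to the identity
  one <- mad_normalize(m[, 1, drop = FALSE])
  expect_equal(unclass(one), m[, 1, drop = FALSE], ignore_attr = TRUE)
  # affine disturbance on one sample is removed
  m2 <- m; m2[, 3] <- 2 * m[, 3] + 5
  out2 <- mad_normalize(m2)
  expect_equal(out2[, 3], out[, 3], tolerance = 1e-9)
  # zero-MAD sample is a named error
  m3 <- m; m3[, 2] <- 1
  expect_error(mad_normalize(m3), "s2")
})

test_that("reference_intensity uses the top-3 peptide ions, weighted", {
  # single ion: REF = ms1 * ref fraction
  psm <- toy_psm_row("s01", ms1 = 100, ch01 = 30, ch02 = 140, ch03 = 130)
  expect_equal(unname(reference_intensity(psm, design, "gene")["G1"]),
               100 * 30 / 300)
  # five ions: only the three largest ms1 contribute
  psm5 <- do.call(rbind, lapply(1:5, function(i)
    toy_psm_row(sprintf("s%02d", i), peptide = sprintf("P%d", i),
                ms1 = i * 10, ch01 = 100, ch02 = 100, ch03 = 100)))
  got <- unname(reference_intensity(psm5, design, "gene")["G1"])
  want <- sum((c(30, 40, 50)) * (100 / 300))
  expect_equal(got, want)
  # random table matches a brute-force enumeration over peptide ions
  psm_r <- filter_psms(random_psm_table(200L, 51L), design)
  got_r <- reference_intensity(psm_r, design, "gene")
  want_r <- sapply(sort(unique(psm_r$gene)), function(g) {
    sub <- psm_r[psm_r$gene == g, ]
    refs <- sapply(unique(sub$plex), function(px) {
      s2 <- sub[sub$plex == px, ]
      s2 <- s2[order(-s2$ms1_intensity), ]
      s2 <- s2[!duplicated(s2$peptide), ]
      top <- head(s2[order(-s2$ms1_intensity), ], 3)
      sum(top$ms1_intensity * top$ch01 /
            (top$ch01 + top$ch02 + top$ch03))
    })
    mean(refs)
  })
  expect_equal(got_r, want_r[names(got_r)])
})

test_that("to_abundance shifts rows by log2(REF) and validates inputs", {
  m <- mad_normalize(matrix(rnorm(40), 10, 4,
                            dimnames = list(letters[1:10], LETTERS[1:4])))
  ref <- setNames(rep(8, 10), letters[1:10])
  a <- to_abundance(m, ref)
  expect_equal(unclass(a), unclass(m) + 3, ignore_attr = TRUE)
  ref1 <- setNames(rep(1, 10), letters[1:10])
  expect_equal(unclass(to_abundance(m, ref1)), unclass(m),
               ignore_attr = TRUE)
  expect_error(to_abundance(m, setNames(c(rep(1, 9), -1), letters[1:10])),
               "positive")
  expect_error(to_abundance(m, ref[1:5]), "align")
})

test_that("summarized ratios are monotone in a surviving PSM ratio", {
  base <- rbind(
    toy_psm_row("s01", peptide = "PA", ch02 = 100),
    toy_psm_row("s02", peptide = "PB", ch02 = 110),
    toy_psm_row("s03", peptide = "PC", ch02 = 120))
  v0 <- summarize_level(psm_ratios(base, design), "gene")["G1", "S1_1"]
  raised <- base; raised$ch02[2] <- 150
  v1 <- summarize_level(psm_ratios(raised, design), "gene")["G1", "S1_1"]
  expect_gte(v1, v0)
})
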