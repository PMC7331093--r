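seg_cfg <- function(...) cohort_config(seed = 13L, ...)

flat_track <- function(n = 600L, lr = 0, baf = 0.5, seed = 1L,
                       gc_slope = 0) {
  set.seed(seed)
  gc <- pmin(0.85, pmax(0.15, rnorm(n, 0.45, 0.1)))
  data.frame(chrom = "chr1", start = (seq_len(n) - 1L) * 1e4,
             end = seq_len(n) * 1e4, gc = gc, mappable = TRUE,
             lr = lr + gc_slope * (gc - 0.5) + rnorm(n, 0, 0.05),
             baf = pmin(1, pmax(0, baf + rnorm(n, 0, 0.02))))
}

test_that("gc_correct removes a planted linear GC trend", {
  tr <- flat_track(seed = 2L, gc_slope = 0.8)
  out <- gc_correct(tr)
  # post-correction regression slope of lr on gc is ~0
  fit <- lm(lr ~ gc, data = out[out$gc >= 0.3 & out$gc <= 0.7, ])
  ci <- confint(fit)["gc", ]
  expect_true(ci[1] < 0 && ci[2] > 0)
  expect_equal(median(out$lr), median(tr$lr), tolerance = 1e-6)
  # gc-independent track is left essentially unchanged
  tr0 <- flat_track(seed = 3L)
  out0 <- gc_correct(tr0)
  expect_lt(max(abs(out0$lr - tr0$lr)), 0.1)
  # out-of-range bins are corrected but excluded from fitting: spike the
  # lr of gc>0.7 bins; the fitted trend in-range must not chase them
  tr2 <- flat_track(seed = 4L)
  hi <- tr2$gc > 0.7
  tr2$lr[hi] <- tr2$lr[hi] + 5
  out2 <- gc_correct(tr2)
  expect_lt(abs(median(out2$lr[!hi]) - median(tr2$lr, na.rm = TRUE)), 0.2)
  expect_error(gc_correct(flat_track(n = 50L)), "100")
})

test_that("joint_segment finds LR and BAF-only breakpoints", {
  # single state, zero noise: one segment
  tr <- flat_track()
  tr$lr <- 0.2; tr$baf <- 0.5
  seg <- joint_segment(tr)
  expect_equal(nrow(seg), 1L)
  expect_equal(seg$n_bins, nrow(tr))
  # two planted states of 500 bins, SNR 5: breakpoint within +/- 2 bins
  set.seed(7)
  x <- c(rnorm(500, 0, 0.1), rnorm(500, 0.5, 0.1))
  tr2 <- flat_track(n = 1000L, seed = 8L)
  tr2$lr <- x; tr2$baf <- 0.5 + rnorm(1000, 0, 0.02)
  seg2 <- joint_segment(tr2)
  bp <- seg2$end[-nrow(seg2)] / 1e4
  expect_true(any(abs(bp - 500) <= 2))
  # copy-neutral LOH: flat LR, BAF shift drives the breakpoint
  set.seed(9)
  tr3 <- flat_track(n = 1000L, seed = 10L)
  tr3$lr <- rnorm(1000, 0, 0.05)
  mb <- c(rep(0.5, 500), rep(0.75, 500)) + rnorm(1000, 0, 0.02)
  flip <- runif(1000) < 0.5
  tr3$baf <- ifelse(flip, 1 - mb, mb)
  seg3 <- joint_segment(tr3)
  bp3 <- seg3$end[-nrow(seg3)] / 1e4
  expect_true(any(abs(bp3 - 500) <= 2))
})

test_that("fit_purity_ploidy recovers purity and integer states", {
  cfg <- seg_cfg(noise_sd = list(lr = 0.08, baf = 0.02))
  truth <- list(purity = c(A = 0.6),
                copy_states = data.frame(
                  sample = "A", chrom = c("chr1", "chr1", "chr2"),
                  arm = c("chr1p", "chr1p", "chr2p"),
                  start = c(0, 6e6, 0), end = c(6e6, 14e6, 14e6),
                  C = c(1L, 2L, 3L), K = c(0L, 1L, 1L)))
  tr <- generate_segments(cfg, truth)$A
  seg <- joint_segment(tr)
  fit <- fit_purity_ploidy(seg, sd_lr = 0.08, sd_baf = 0.02)
  expect_lte(abs(fit$best$purity - 0.6), 0.01)
  expect_false(fit$unidentifiable)
  # map called states back to truth by position
  st <- fit$states
  truth_c <- c(1L, 2L, 3L); truth_k <- c(0L, 1L, 1L)
  for (i in seq_len(nrow(truth$copy_states))) {
    hit <- st$chrom == truth$copy_states$chrom[i] &
      st$start < truth$copy_states$end[i] &
      st$end > truth$copy_states$start[i]
    expect_true(all(st$C[hit] == truth_c[i]))
    expect_true(all(st$K[hit] == truth_k[i]))
  }
})

test_that("all-diploid genome is flagged purity-unidentifiable", {
  seg <- data.frame(chrom = c("chr1", "chr2", "chr3"),
                    start = 0, end = 20e6, n_bins = 2000,
                    lr = c(0.001, -0.002, 0.001),
                    baf = c(0.501, 0.5, 0.499))
  fit <- fit_purity_ploidy(seg)
  expect_true(fit$unidentifiable)
})

test_that("WGD solution outranks lower-ploidy ones given anchor segments", {
  # truth: purity 0.8, (4,2)-dominant with a (3,1) segment (excludes the
  # halved solution: 1.5 copies is not integer) and a (1,0) deletion
  # (excludes the shift-by-minus-2 solution: -1 copies impossible)
  p <- 0.8
  elr <- function(C, tau) log2((p * C + 2 * (1 - p)) /
                                 (p * tau + 2 * (1 - p)))
  ebaf <- function(C, K) 1 - (p * K + (1 - p)) / (p * C + 2 * (1 - p))
  Cs <- c(4, 4, 4, 3, 1); Ks <- c(2, 2, 2, 1, 0)
  tau <- mean(Cs)          # equal-length segments
  seg <- data.frame(chrom = c("chr1", "chr1", "chr2", "chr3", "chr3"),
                    start = c(0, 30e6, 0, 0, 30e6),
                    end = c(30e6, 60e6, 30e6, 30e6, 60e6),
                    n_bins = 3000,
                    lr = elr(Cs, tau),
                    baf = ebaf(Cs, Ks))
  fit <- fit_purity_ploidy(seg, sd_lr = 0.05, sd_baf = 0.02)
  expect_equal(fit$states$C, Cs)
  expect_equal(fit$states$K, Ks)
  expect_gte(fit$best$ploidy, 3)
  expect_equal(fit$best$purity, 0.8, tolerance = 0.011)
})

test_that("arm_events computes length-weighted scores and LOH", {
  arms <- data.frame(chrom = "chr1", arm = "chr1p", start = 0, end = 100e6)
  # 100% (1,0): loss with LOH
  st <- data.frame(chrom = "chr1", start = 0, end = 100e6, C = 1L, K = 0L)
  ev <- arm_events(st, arms)
  expect_equal(ev$score, -1)
  expect_equal(ev$call, "loss")
  expect_equal(ev$loh_prop, 1)
  expect_true(ev$loh)
  # 60% (3,1) + 40% (2,1): score 0.6 -> gain
  st2 <- data.frame(chrom = "chr1", start = c(0, 60e6),
                    end = c(60e6, 100e6), C = c(3L, 2L), K = c(1L, 1L))
  ev2 <- arm_events(st2, arms)
  expect_equal(ev2$score, 0.6)
  expect_equal(ev2$call, "gain")
  # 100% (2,0): neutral with copy-neutral LOH
  st3 <- data.frame(chrom = "chr1", start = 0, end = 100e6, C = 2L, K = 0L)
  ev3 <- arm_events(st3, arms)
  expect_equal(ev3$call, "neutral")
  expect_true(ev3$loh)
  # loss-only LOH rule leaves non-loss arms NA
  ev4 <- arm_events(st3, arms, loh_on_loss_only = TRUE)
  expect_true(is.na(ev4$loh))
  # doubling lengths leaves the score unchanged
  st5 <- st2; st5$end <- st5$end * 2; st5$start <- st5$start * 2
  arms2 <- data.frame(chrom = "chr1", arm = "chr1p", start = 0, end = 200e6)
  expect_equal(arm_events(st5, arms2)$score, ev2$score)
})

test_that("genome_instability computes PGA with the 0.85 cutoff", {
  st <- data.frame(chrom = "chr1", start = c(0, 60e6),
                   end = c(60e6, 100e6), C = c(3L, 2L), K = c(1L, 1L))
  gi <- genome_instability(st)
  expect_equal(gi$pga, 0.6)
  expect_false(gi$unstable)
  st_all <- data.frame(chrom = "chr1", start = 0, end = 100e6,
                       C = 2L, K = 1L)
  expect_equal(genome_instability(st_all)$pga, 0)
  st_bad <- data.frame(chrom = "chr1", start = c(0, 90e6),
                       end = c(90e6, 100e6), C = c(1L, 2L), K = c(0L, 1L))
  gi2 <- genome_instability(st_bad)
  expect_equal(gi2$pga, 0.9)
  expect_true(gi2$unstable)
  # PGA invariant to splitting a segment into identical-state pieces
  st_split <- data.frame(chrom = "chr1",
                         start = c(0, 30e6, 60e6),
                         end = c(30e6, 60e6, 100e6),
                         C = c(3L, 3L, 2L), K = c(1L, 1L, 1L))
  expect_equal(genome_instability(st_split)$pga, 0.6)
})
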