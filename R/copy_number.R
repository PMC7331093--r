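#' @title Copy-number analysis
#' @description GC correction of binned log coverage ratios, joint
#'   LR/BAF segmentation based on circular binary segmentation, grid-search
#'   purity/ploidy inference with integer copy-state calling, arm-level
#'   event detection and genome-instability (PGA) classification.
#'
#'   A binned track is a data.frame with columns chrom, start, end, gc,
#'   mappable, lr, baf. A segment table has one row per segment with
#'   chrom, start, end, n_bins, lr (mean), baf (mean mirrored BAF) and,
#'   after calling, integer columns C (total) and K (minor allele).
#' @name copy_number
NULL

# run expr under a fixed seed, restoring the caller's RNG state
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' GC-bias correction by weighted LOESS
#'
#' Fits a LOESS curve (span 0.5) of LR on GC using mappable bins in the GC
#' range 0.3-0.7 and subtracts the fitted trend from all bins; the median
#' LR of the track is preserved.
#'
#' @param track binned track (see [copy_number]).
#' @param span LOESS span.
#' @param gc_range GC interval used for fitting.
#' @return the track with corrected `lr`.
#' @export
gc_correct <- function(track, span = 0.5, gc_range = c(0.3, 0.7),
                       max_fit_bins = 5000L) {
  fit_idx <- which(track$mappable & track$gc >= gc_range[1] &
                     track$gc <= gc_range[2] & is.finite(track$lr))
  if (length(fit_idx) < 100L)
    stop("gc_correct: need >= 100 mappable bins in the GC fitting range",
         call. = FALSE)
  # loess is quadratic in the fitting set; an evenly spaced (by GC)
  # subsample bounds the cost without biasing the trend
  if (length(fit_idx) > max_fit_bins) {
    ord <- fit_idx[order(track$gc[fit_idx])]
    fit_idx <- ord[unique(round(seq(1, length(ord),
                                    length.out = max_fit_bins)))]
  }
  fit <- stats::loess(lr ~ gc, data = track[fit_idx, ], span = span,
                      degree = 2,
                      control = stats::loess.control(surface = "direct"))
  # evaluate the curve on a GC grid and interpolate (constant beyond the
  # grid ends) rather than predicting per bin
  grid <- seq(min(track$gc, na.rm = TRUE), max(track$gc, na.rm = TRUE),
              length.out = 201L)
  curve <- stats::predict(fit, newdata = data.frame(gc = grid))
  trend <- stats::approx(grid, curve, xout = track$gc, rule = 2)$y
  med_before <- stats::median(track$lr, na.rm = TRUE)
  lr <- track$lr - trend
  lr <- lr + (med_before - stats::median(lr, na.rm = TRUE))
  track$lr <- lr
  track
}

.trimmed_sd <- function(x, trim) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 3L) return(stats::sd(x))
  k <- floor(n * trim)
  xs <- sort(x)
  if (k > 0L) xs <- xs[(k + 1L):(n - k)]
  stats::sd(xs)
}

# max standardized mean-split statistic over candidate breakpoints
.max_split_stat <- function(x, s, min_width) {
  n <- length(x)
  ks <- seq(min_width, n - min_width)
  if (!length(ks) || !is.finite(s) || s <= 0) return(list(stat = 0, k = NA))
  cs <- cumsum(x)
  m1 <- cs[ks] / ks
  m2 <- (cs[n] - cs[ks]) / (n - ks)
  t <- abs(m1 - m2) / (s * sqrt(1 / ks + 1 / (n - ks)))
  i <- which.max(t)
  list(stat = t[i], k = ks[i])
}

# binary segmentation with permutation p-values (CBS-style, non-circular)
.bseg <- function(x, alpha, trim, n_perm, min_width = 3L) {
  n <- length(x)
  if (n < 2L * min_width) return(integer())
  s <- .trimmed_sd(x, trim)
  obs <- .max_split_stat(x, s, min_width)
  if (!is.finite(obs$stat) || obs$stat == 0) return(integer())
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    perm <- .max_split_stat(sample(x), s, min_width)
    if (perm$stat >= obs$stat) exceed <- exceed + 1L
    if (exceed > alpha * (n_perm + 1L)) break  # early stop: cannot be sig.
  }
  p <- (1L + exceed) / (1L + n_perm)
  if (p > alpha) return(integer())
  k <- obs$k
  c(.bseg(x[seq_len(k)], alpha, trim, n_perm, min_width), k,
    k + .bseg(x[(k + 1L):n], alpha, trim, n_perm, min_width))
}

.segment_means <- function(track, breaks) {
  n <- nrow(track)
  bounds <- c(0L, breaks, n)
  mb <- pmax(track$baf, 1 - track$baf)
  do.call(rbind, lapply(seq_len(length(bounds) - 1L), function(i) {
    idx <- (bounds[i] + 1L):bounds[i + 1L]
    data.frame(chrom = track$chrom[idx[1L]],
               start = track$start[idx[1L]],
               end = track$end[idx[length(idx)]],
               n_bins = length(idx),
               lr = mean(track$lr[idx], na.rm = TRUE),
               baf = mean(mb[idx], na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
}

#' Joint LR/BAF segmentation
#'
#' Per chromosome, LR and mirrored BAF (folded to \[0.5, 1\]) are segmented
#' independently by permutation-tested binary segmentation (alpha, trim as
#' in the CBS parameterisation) and the candidate breakpoints pooled. The
#' resulting segmentation is then iteratively pruned by merging adjacent
#' segments whose LR means differ by less than `tol_lr` and whose mirrored
#' BAF means differ by less than `tol_baf`, shortest segments first.
#'
#' @param track GC-corrected binned track.
#' @param alpha permutation significance level for accepting a breakpoint.
#' @param trim fraction trimmed from each tail for the variance estimate.
#' @param tol_lr,tol_baf merge tolerances.
#' @param n_perm permutations per split test.
#' @param seed RNG seed for the permutation tests (restored on exit).
#' @return segment table (chrom, start, end, n_bins, lr, baf).
#' @export
joint_segment <- function(track, alpha = 0.01, trim = 0.025,
                          tol_lr = 0.1, tol_baf = 0.05, n_perm = 199L,
                          seed = 42L) {
  .with_seed(seed, {
    segs <- lapply(unique(track$chrom), function(ch) {
      tr <- track[track$chrom == ch, , drop = FALSE]
      if (nrow(tr) == 0L) {
        message("joint_segment: empty chromosome ", ch, ", skipped")
        return(NULL)
      }
      tr <- tr[order(tr$start), , drop = FALSE]
      mb <- pmax(tr$baf, 1 - tr$baf)
      bp <- sort(unique(c(.bseg(tr$lr, alpha, trim, n_perm),
                          .bseg(mb, alpha, trim, n_perm))))
      seg <- .segment_means(tr, bp)
      .merge_segments(seg, tol_lr, tol_baf)
    })
    out <- do.call(rbind, segs)
    rownames(out) <- NULL
    out
  })
}

.merge_segments <- function(seg, tol_lr, tol_baf) {
  repeat {
    if (nrow(seg) < 2L) return(seg)
    dlr <- abs(diff(seg$lr))
    dbaf <- abs(diff(seg$baf))
    cand <- which(dlr < tol_lr & dbaf < tol_baf)
    if (!length(cand)) return(seg)
    # merge the candidate pair involving the shortest segment first
    pair_min <- pmin(seg$n_bins[cand], seg$n_bins[cand + 1L])
    i <- cand[which.min(pair_min)]
    w <- seg$n_bins[c(i, i + 1L)]
    seg$end[i] <- seg$end[i + 1L]
    seg$lr[i] <- sum(seg$lr[c(i, i + 1L)] * w) / sum(w)
    seg$baf[i] <- sum(seg$baf[c(i, i + 1L)] * w) / sum(w)
    seg$n_bins[i] <- sum(w)
    seg <- seg[-(i + 1L), , drop = FALSE]
  }
}

# enumerate (C, K) states up to max_c with K <= floor(C/2)
.state_table <- function(max_c) {
  do.call(rbind, lapply(0:max_c, function(C)
    data.frame(C = C, K = 0:(C %/% 2))))
}

# Expected mean of mirrored (folded at 0.5) BAF given the raw expectation
# e >= 0.5 and per-bin noise sd: folding a Normal(e, sd) at 0.5 biases the
# mean upward (by sd*sqrt(2/pi) for balanced states); ignoring this lets
# spurious low-purity solutions absorb the bias.
.folded_baf <- function(e, sd) {
  m <- e - 0.5
  0.5 + m * (1 - 2 * stats::pnorm(-m / sd)) + 2 * sd * stats::dnorm(m / sd)
}

# maximum-likelihood (C, K) per segment at a fixed purity/ploidy
.call_states <- function(segments, p, tau, max_c, sd_lr, sd_baf, big0) {
  st <- .state_table(max_c)
  denom <- p * st$C + 2 * (1 - p)
  e_baf <- ifelse(denom > 0,
                  .folded_baf(1 - (p * st$K + (1 - p)) / denom, sd_baf),
                  NA_real_)
  e_lr <- log2(p * st$C + 2 * (1 - p)) - log2(p * tau + 2 * (1 - p))
  nS <- nrow(segments)
  ll <- segments$n_bins *
    (-0.5 * (outer(segments$lr, e_lr, `-`) / sd_lr)^2 -
       0.5 * (outer(segments$baf, e_baf, `-`) / sd_baf)^2)
  ll[!is.finite(ll)] <- -1e12
  if (any(big0)) ll[big0, st$C == 0L] <- -Inf
  j <- max.col(ll, ties.method = "first")
  data.frame(C = st$C[j], K = st$K[j])
}

#' Joint purity/ploidy inference by grid search
#'
#' For each candidate purity p and ploidy tau on a grid, every segment is
#' assigned the integer state (C, K) maximizing a Gaussian likelihood of
#' its (LR, mirrored BAF) means around the expectations
#' `E[lr] = log2(p*C + 2(1-p)) - log2(p*tau + 2(1-p))` and
#' `E[baf] = (p*K + (1-p)) / (p*C + 2(1-p))` (mirrored). Candidates are
#' ranked by total bin-weighted log-likelihood. Solutions placing a
#' homozygous deletion (C = 0) on a segment longer than
#' `max_homozygous_len` are rejected.
#'
#' @param segments segment table from [joint_segment()].
#' @param purity_grid,ploidy_grid candidate grids.
#' @param max_c maximum total copy number considered.
#' @param sd_lr,sd_baf per-bin noise standard deviations of LR and BAF.
#' @param max_homozygous_len length (bp) above which C = 0 is disallowed.
#' @param top_n number of ranked solutions to return in full.
#' @param tie_tol log-likelihood window within which solutions are treated
#'   as ties; `NULL` (default) uses `3 + 2e-3 * sum(n_bins)`, wide enough
#'   to absorb grid-discretization wobble between exactly degenerate
#'   solutions. The copy-number problem is degenerate: scaled
#'   (purity, ploidy, states) combinations can fit identically, so among
#'   near-ties the most parsimonious solution (ploidy closest to diploid,
#'   then highest purity) is ranked first — whole-genome-duplicated calls
#'   therefore need at least one segment a low-ploidy solution cannot
#'   explain.
#' @return list of class `ploidy_fit`: `solutions` (data.frame of purity,
#'   ploidy, loglik, rank), `states` (segment table with C, K of the top
#'   solution), `best` (top row), `unidentifiable` flag.
#' @export
fit_purity_ploidy <- function(segments,
                              purity_grid = seq(0.05, 1, by = 0.01),
                              ploidy_grid = seq(1, 6, by = 0.05),
                              max_c = 8L, sd_lr = 0.1, sd_baf = 0.03,
                              max_homozygous_len = 10e6, top_n = 5L,
                              tie_tol = NULL) {
  seg_len <- segments$end - segments$start
  if (nrow(segments) < 3L || sum(seg_len) < 10e6)
    stop("fit_purity_ploidy: need >= 3 segments spanning >= 10 Mb",
         call. = FALSE)
  st <- .state_table(max_c)
  nS <- nrow(segments)
  w <- segments$n_bins
  if (is.null(tie_tol)) tie_tol <- 3 + 2e-3 * sum(w)
  lr <- segments$lr
  mbaf <- segments$baf
  big0 <- seg_len > max_homozygous_len
  total <- numeric(length(purity_grid) * length(ploidy_grid))
  best_ll <- -Inf
  gi <- 0L
  for (p in purity_grid) {
    tot_c <- p * (0:max_c) + 2 * (1 - p)             # per C
    denom <- p * st$C + 2 * (1 - p)
    e_baf <- ifelse(denom > 0,
                    .folded_baf(1 - (p * st$K + (1 - p)) / denom, sd_baf),
                    NA_real_)
    # per-(segment, state) BAF loglik; collapse K -> best per (segment, C)
    ll_baf <- -0.5 * ((outer(mbaf, e_baf, `-`)) / sd_baf)^2 -
      log(sd_baf * sqrt(2 * pi))
    ll_baf[!is.finite(ll_baf)] <- -1e12   # zero-coverage states (p=1, C=0)
    bestK_ll <- matrix(-Inf, nS, max_c + 1L)
    bestK <- matrix(0L, nS, max_c + 1L)
    for (ci in 0:max_c) {
      cols <- which(st$C == ci)
      sub <- ll_baf[, cols, drop = FALSE]
      j <- max.col(sub, ties.method = "first")
      bestK_ll[, ci + 1L] <- sub[cbind(seq_len(nS), j)]
      bestK[, ci + 1L] <- st$K[cols][j]
    }
    base_lr <- log2(tot_c)                           # minus shift below
    for (tau in ploidy_grid) {
      gi <- gi + 1L
      shift <- log2(p * tau + 2 * (1 - p))
      e_lr <- base_lr - shift
      d <- outer(lr, e_lr, `-`)
      ll <- w * (-0.5 * (d / sd_lr)^2 - log(sd_lr * sqrt(2 * pi)) +
                   bestK_ll)
      # forbid large homozygous deletions
      if (any(big0)) ll[big0, 1L] <- -Inf
      jbest <- max.col(ll, ties.method = "first")
      tot <- sum(ll[cbind(seq_len(nS), jbest)])
      total[gi] <- tot
      if (tot > best_ll) best_ll <- tot
    }
  }
  # the loop varies ploidy fastest within each purity
  grid_pt <- expand.grid(ploidy = ploidy_grid, purity = purity_grid,
                         KEEP.OUT.ATTRS = FALSE)
  # parsimony tie-break among near-equal solutions (the problem is
  # degenerate under purity/ploidy rescaling): prefer ploidy nearest 2,
  # then the highest purity
  near <- which(total >= best_ll - tie_tol)
  sel <- near[order(abs(grid_pt$ploidy[near] - 2),
                    -grid_pt$purity[near])][1L]
  ord <- order(total, decreasing = TRUE)
  ord <- c(sel, setdiff(ord, sel))
  keep <- seq_len(min(top_n, length(ord)))
  sols <- data.frame(purity = grid_pt$purity[ord][keep],
                     ploidy = grid_pt$ploidy[ord][keep],
                     loglik = total[ord][keep],
                     rank = keep)
  states <- cbind(segments,
                  .call_states(segments, grid_pt$purity[sel],
                               grid_pt$ploidy[sel], max_c, sd_lr, sd_baf,
                               big0))
  # unidentifiability: near-optimal plateau spanning a wide purity range,
  # as happens for an all-neutral genome
  near <- total >= best_ll - 1e-6 * max(1, abs(best_ll))
  p_spread <- diff(range(grid_pt$purity[near]))
  unident <- p_spread > 0.5
  structure(list(solutions = sols, states = states, best = sols[1L, ],
                 unidentifiable = unident),
            class = "ploidy_fit")
}

#' Arm-level gain/loss and LOH calls
#'
#' Per chromosome arm the copy-number score is the segment-length-weighted
#' mean of (C - 2); gain is called for score > 0.5 and loss for score
#' < -0.5. The LOH proportion is the length fraction with K = 0 (including
#' copy-neutral LOH); LOH is called when it exceeds 0.5. With
#' `loh_on_loss_only = TRUE` the LOH call is only evaluated on arms called
#' loss (the rule used for 3p).
#'
#' @param states called segment table (with C, K).
#' @param arms data.frame chrom, arm, start, end (0-based half-open).
#' @param loh_on_loss_only restrict LOH calls to loss arms.
#' @return data.frame per arm: score, call (gain/loss/neutral),
#'   loh_prop, loh, covered length.
#' @export
arm_events <- function(states, arms, loh_on_loss_only = FALSE) {
  res <- lapply(seq_len(nrow(arms)), function(i) {
    a <- arms[i, ]
    ov_start <- pmax(states$start, a$start)
    ov_end <- pmin(states$end, a$end)
    len <- pmax(0, ov_end - ov_start)
    sel <- states$chrom == a$chrom & len > 0
    len <- len[sel]
    if (!length(len) || sum(len) == 0) {
      return(data.frame(arm = a$arm, score = NA_real_,
                        call = NA_character_, loh_prop = NA_real_,
                        loh = NA, covered = 0, stringsAsFactors = FALSE))
    }
    C <- states$C[sel]; K <- states$K[sel]
    score <- sum(len * (C - 2)) / sum(len)
    call <- if (score > 0.5) "gain" else if (score < -0.5) "loss"
            else "neutral"
    loh_prop <- sum(len[K == 0]) / sum(len)
    loh <- if (loh_on_loss_only && call != "loss") NA else loh_prop > 0.5
    data.frame(arm = a$arm, score = score, call = call,
               loh_prop = loh_prop, loh = loh, covered = sum(len),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Proportion of genome altered and instability call
#'
#' PGA is the total length of segments whose state differs from diploid
#' heterozygous (C = 2, K = 1), divided by the genome length; samples with
#' PGA at or above `cutoff` (default 0.85) are classified genome-unstable.
#'
#' @param states called segment table (with C, K).
#' @param genome_length total genome length; defaults to the summed
#'   segment length.
#' @param cutoff instability threshold on PGA.
#' @return list with `pga` and logical `unstable`.
#' @export
genome_instability <- function(states, genome_length = NULL,
                               cutoff = 0.85) {
  len <- states$end - states$start
  if (is.null(genome_length)) genome_length <- sum(len)
  altered <- sum(len[states$C != 2L | states$K != 1L])
  pga <- altered / genome_length
  list(pga = pga, unstable = pga >= cutoff)
}
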