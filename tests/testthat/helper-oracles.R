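# Independent brute-force oracles and small fixture builders shared by the
# unit and acceptance tests. These stay deliberately naive: each rule is
# applied one at a time, with loops, so they cannot share a defect with the
# implementation.

# --- fixtures -------------------------------------------------------------

# Minimal 2-plex design: channels ch01 (reference), ch02, ch03.
toy_design <- function(n_plex = 1L) {
  do.call(rbind, lapply(seq_len(n_plex), function(p) data.frame(
    plex = sprintf("plex%02d", p),
    channel = c("ch01", "ch02", "ch03"),
    sample = c("REF", sprintf("S%d_%d", p, 1:2)),
    is_reference = c(TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE)))
}

toy_psm_row <- function(spectrum_id, gene = "G1", peptide = "PEPA",
                        plex = "plex01", site = NA_character_,
                        labeled = TRUE, contaminant = FALSE,
                        purity = 0.9, ms1 = 1e6,
                        ch01 = 100, ch02 = 100, ch03 = 100) {
  data.frame(plex = plex, spectrum_id = spectrum_id, peptide = peptide,
             site = site, gene = gene, protein = paste0(gene, "_P1"),
             unique_razor = TRUE, contaminant = contaminant,
             labeled = labeled, purity = purity, ms1_intensity = ms1,
             ch01 = ch01, ch02 = ch02, ch03 = ch03,
             stringsAsFactors = FALSE)
}

# Randomized PSM table with planted failures of every filter rule.
random_psm_table <- function(n, seed) {
  set.seed(seed)
  rows <- lapply(seq_len(n), function(i) {
    toy_psm_row(sprintf("spec%05d", i),
                gene = sprintf("G%02d", sample(8, 1)),
                peptide = sprintf("PEP%03d", sample(40, 1)),
                labeled = runif(1) > 0.05,
                contaminant = runif(1) < 0.05,
                purity = runif(1, 0, 1),
                ms1 = rlnorm(1, 14, 1),
                ch01 = rlnorm(1, 5, 1) * (runif(1) > 0.05),
                ch02 = rlnorm(1, 5, 1),
                ch03 = rlnorm(1, 5, 1))
  })
  do.call(rbind, rows)
}

# --- oracles --------------------------------------------------------------

oracle_iqr_trim <- function(v) {
  v <- v[is.finite(v)]
  q1 <- unname(quantile(v, 0.25)); q3 <- unname(quantile(v, 0.75))
  lo <- q1 - 1.5 * (q3 - q1); hi <- q3 + 1.5 * (q3 - q1)
  out <- c()
  for (x in v) if (x >= lo && x <= hi) out <- c(out, x)
  out
}

# rule-at-a-time filter oracle (single reference channel "ch01")
oracle_filter <- function(psm, pct = 0.05) {
  keep <- rep(TRUE, nrow(psm))
  keep <- keep & psm$labeled
  keep <- keep & !is.na(psm$ch01) & psm$ch01 > 0
  keep <- keep & psm$purity >= 0.5
  sums <- psm$ch01 + psm$ch02 + psm$ch03
  # percentile computed on the rows surviving so far, per plex
  for (px in unique(psm$plex)) {
    i <- which(psm$plex == px & keep)
    thr <- unname(quantile(sums[i], pct))
    keep[i[sums[i] < thr]] <- FALSE
  }
  keep <- keep & !psm$contaminant
  # redundancy: per (plex, peptide) keep max summed intensity
  surv <- which(keep)
  drop <- c()
  for (px in unique(psm$plex)) for (pep in unique(psm$peptide)) {
    i <- surv[psm$plex[surv] == px & psm$peptide[surv] == pep]
    if (length(i) > 1L) {
      best <- i[order(-sums[i], psm$spectrum_id[i])][1L]
      drop <- c(drop, setdiff(i, best))
    }
  }
  keep[drop] <- FALSE
  psm[keep, , drop = FALSE]
}

oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  prev <- 1
  for (k in n:1) {
    val <- min(prev, p[o[k]] * n / k)
    adj[o[k]] <- val
    prev <- val
  }
  adj
}

oracle_U <- function(x, y) {
  u <- 0
  for (a in x) for (b in y) u <- u + (a > b) + 0.5 * (a == b)
  u
}

oracle_chisq <- function(tab) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - e)^2 / e)
}

# planted-cluster score matrix for consensus/transfer tests
archetype_scores <- function(n_per = 15L, n_ct = 20L, sep = 4, sd = 1,
                             seed = 1L, k = 4L, centroids = NULL) {
  set.seed(seed)
  if (is.null(centroids)) centroids <- matrix(rnorm(n_ct * k), n_ct) * sep
  labels <- rep(seq_len(k), each = n_per)
  m <- centroids[, labels] + matrix(rnorm(n_ct * length(labels), 0, sd),
                                    n_ct)
  colnames(m) <- sprintf("S%03d", seq_along(labels))
  rownames(m) <- sprintf("CT%02d", seq_len(n_ct))
  list(mat = m, labels = labels, centroids = centroids)
}

adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maxi <- (sum_a + sum_b) / 2
  (sum_ij - expected) / (maxi - expected)
}
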