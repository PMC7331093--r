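#' @title Cross-omic correlation and sample-alignment QC
#' @description Gene-wise and sample-wise Spearman correlation between
#'   mRNA and protein matrices, covariate models on sample-wise
#'   correlation, rank-sum set enrichment on correlation-ranked genes, and
#'   the rank-based cross-omic sample-alignment check.
#' @name crossomics
NULL

.complete_genes <- function(a, b) {
  genes <- intersect(rownames(a), rownames(b))
  ok <- genes[stats::complete.cases(a[genes, , drop = FALSE]) &
                stats::complete.cases(b[genes, , drop = FALSE])]
  ok
}

.spearman_p <- function(rho, n) {
  t <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  2 * stats::pt(-abs(t), n - 2)
}

#' Gene-wise mRNA-protein Spearman correlation
#'
#' Per gene, Spearman correlation across samples between the two data
#' types, computed on complete-case genes; BH adjustment across genes;
#' the fraction of significantly positive pairs is reported. If `groups`
#' is given, correlation and adjustment are computed within each group.
#'
#' @param mrna,protein matrices with matched sample columns.
#' @param groups optional per-sample group labels.
#' @param sig_threshold adjusted-p threshold for the positive fraction
#'   (default 0.01).
#' @return data.frame per gene (and group): rho, p, p_adj; attribute
#'   `positive_fraction` per group.
#' @export
genewise_corr <- function(mrna, protein, groups = NULL,
                          sig_threshold = 0.01) {
  samples <- intersect(colnames(mrna), colnames(protein))
  if (length(samples) < 5L)
    stop("genewise_corr: need >= 5 shared samples", call. = FALSE)
  if (is.null(groups)) groups <- rep("all", length(samples))
  genes <- .complete_genes(mrna[, samples, drop = FALSE],
                           protein[, samples, drop = FALSE])
  res <- do.call(rbind, lapply(unique(groups), function(gr) {
    cols <- samples[groups == gr]
    if (length(cols) < 5L)
      stop("genewise_corr: group ", gr, " has < 5 samples", call. = FALSE)
    a <- t(apply(mrna[genes, cols, drop = FALSE], 1L, rank))
    b <- t(apply(protein[genes, cols, drop = FALSE], 1L, rank))
    az <- (a - rowMeans(a)) / apply(a, 1L, stats::sd)
    bz <- (b - rowMeans(b)) / apply(b, 1L, stats::sd)
    rho <- rowSums(az * bz) / (length(cols) - 1L)
    p <- .spearman_p(rho, length(cols))
    data.frame(gene = genes, group = gr, rho = rho, p = p,
               p_adj = bh_adjust(p), stringsAsFactors = FALSE)
  }))
  rownames(res) <- NULL
  pos <- vapply(split(res, res$group), function(d)
    mean(d$p_adj < sig_threshold & d$rho > 0), numeric(1))
  attr(res, "positive_fraction") <- pos
  res
}

#' Sample-wise mRNA-protein Spearman correlation with tertiles
#'
#' Per sample, Spearman correlation across shared complete-case genes;
#' samples are ranked and split into high/middle/low tertiles.
#'
#' @inheritParams genewise_corr
#' @return data.frame per sample: rho, tertile.
#' @export
samplewise_corr <- function(mrna, protein) {
  samples <- intersect(colnames(mrna), colnames(protein))
  if (length(samples) < 5L)
    stop("samplewise_corr: need >= 5 shared samples", call. = FALSE)
  genes <- .complete_genes(mrna[, samples, drop = FALSE],
                           protein[, samples, drop = FALSE])
  rho <- vapply(samples, function(s)
    stats::cor(mrna[genes, s], protein[genes, s], method = "spearman"),
    numeric(1))
  r <- rank(-rho, ties.method = "first")
  k <- length(rho)
  tertile <- cut(r, breaks = c(0, k / 3, 2 * k / 3, k),
                 labels = c("high", "middle", "low"))
  data.frame(sample = samples, rho = rho, tertile = as.character(tertile),
             stringsAsFactors = FALSE)
}

#' Covariate models on sample-wise correlation
#'
#' For each covariate: a univariate linear model of the per-sample
#' correlation on the covariate, and the same model with tumor purity as
#' an additional covariate; both effects and p values are reported.
#'
#' @param rho per-sample correlation vector (named or aligned).
#' @param covariates data.frame of per-sample covariates.
#' @param purity per-sample purity vector.
#' @return data.frame per covariate: beta, p, beta_adj, p_adj_purity.
#' @export
corr_covariate_model <- function(rho, covariates, purity) {
  if (length(rho) < 10L)
    stop("corr_covariate_model: need >= 10 samples", call. = FALSE)
  res <- lapply(names(covariates), function(cv) {
    x <- covariates[[cv]]
    if (is.character(x)) x <- factor(x)
    if (is.factor(x)) x <- as.numeric(x)
    if (stats::sd(x, na.rm = TRUE) == 0) {
      message("corr_covariate_model: constant covariate skipped: ", cv)
      return(NULL)
    }
    f1 <- stats::lm(rho ~ x)
    f2 <- stats::lm(rho ~ x + purity)
    s1 <- summary(f1)$coefficients
    s2 <- summary(f2)$coefficients
    data.frame(covariate = cv, beta = s1["x", 1], p = s1["x", 4],
               beta_adj = s2["x", 1], p_adj_purity = s2["x", 4],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Rank-sum set enrichment on a per-gene score
#'
#' Two-sided rank-sum comparison of in-set vs out-of-set scores per gene
#' set (for example correlation-ranked genes); BH adjustment across sets;
#' direction by median comparison.
#'
#' @param scores named per-gene numeric scores.
#' @param gene_sets named list of gene vectors.
#' @return data.frame per set: n_in, p, p_adj, direction.
#' @export
rank_set_enrichment <- function(scores, gene_sets) {
  res <- .ranksum_sets(scores, gene_sets)
  res$p_adj <- bh_adjust(res$p)
  res
}

#' Cross-omic sample-alignment check
#'
#' Selects the `n_top` genes with the highest gene-wise correlation
#' between the two matrices under the nominal sample pairing,
#' rank-transforms their values per gene within each matrix, and scores
#' every sample pair by the Spearman correlation of the two rank
#' profiles. A sample's self-score is standardized against its cross-pair
#' scores; samples whose self z-score falls below `z_threshold` are
#' flagged as possible mislabels.
#'
#' @param a,b matrices with a shared gene index and matched sample
#'   columns (nominal pairing by column order/name).
#' @param n_top number of top-correlated genes to use (default 500; all
#'   genes with a warning when fewer are shared).
#' @param z_threshold self z-score below which a sample is flagged.
#' @return data.frame per sample: self_score, z, flagged; attribute
#'   `similarity` holds the full cross matrix.
#' @export
sample_alignment_check <- function(a, b, n_top = 500L, z_threshold = 2) {
  samples <- intersect(colnames(a), colnames(b))
  if (length(samples) < 20L)
    stop("sample_alignment_check: need >= 20 shared samples",
         call. = FALSE)
  genes <- intersect(rownames(a), rownames(b))
  if (length(genes) < n_top) {
    warning("sample_alignment_check: fewer than ", n_top,
            " shared genes; using all ", length(genes))
    n_top <- length(genes)
  }
  A <- a[genes, samples, drop = FALSE]
  B <- b[genes, samples, drop = FALSE]
  rho <- vapply(genes, function(g)
    stats::cor(A[g, ], B[g, ], method = "spearman"), numeric(1))
  top <- genes[order(-rho)][seq_len(n_top)]
  Ar <- t(apply(A[top, , drop = FALSE], 1L, rank))
  Br <- t(apply(B[top, , drop = FALSE], 1L, rank))
  S <- stats::cor(Ar, Br, method = "spearman")
  z <- vapply(seq_along(samples), function(i) {
    cross <- c(S[i, -i], S[-i, i])
    (S[i, i] - mean(cross)) / stats::sd(cross)
  }, numeric(1))
  out <- data.frame(sample = samples, self_score = diag(S), z = z,
                    flagged = z < z_threshold, stringsAsFactors = FALSE)
  attr(out, "similarity") <- S
  out
}
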