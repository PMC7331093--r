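#' @title Immune subtype discovery and transfer classification
#' @description Consensus clustering of cell-type score matrices,
#'   group-indicator differential regression, combined z-score signature
#'   scoring, one-vs-rest marker selection, and the two-score Spearman
#'   transfer classifier for external cohorts.
#' @name immune
NULL

#' Immune grouping of samples from cell-type scores
#'
#' Consensus clustering (PAM base, 80% subsampling) of the cell-score
#' matrix; a thin wrapper around [consensus_cluster()] with the immune
#' recipe's defaults.
#'
#' @param cell_scores cell-type x sample score matrix.
#' @param k number of immune groups.
#' @param repeats subsampling repeats (default 200).
#' @param seed RNG seed.
#' @return a `consensus_result` (see [consensus_cluster()]).
#' @export
immune_group <- function(cell_scores, k, repeats = 200L, seed = 1L) {
  consensus_cluster(cell_scores, k = k, repeats = repeats, fraction = 0.8,
                    base = "pam", seed = seed)
}

#' Group-indicator differential regression
#'
#' Each feature is z-scored across samples and modeled as
#' `X_ij = sum_k beta_kj 1(i in group k) + eps`, a no-intercept indicator
#' regression whose coefficient beta_kj is exactly the group-k mean of the
#' z-scored feature. p values test beta_kj = 0 with the pooled residual
#' variance; BH adjustment is applied per group across features.
#'
#' @param mat feature x sample matrix.
#' @param labels per-sample group labels.
#' @return data.frame per (feature, group): beta, p, p_adj.
#' @export
group_differential <- function(mat, labels) {
  stopifnot(ncol(mat) == length(labels))
  labels <- as.character(labels)
  groups <- sort(unique(labels))
  sizes <- table(labels)
  if (any(sizes < 2L)) {
    drop_g <- names(sizes)[sizes < 2L]
    warning("group_differential: singleton group(s) skipped: ",
            paste(drop_g, collapse = ", "))
    groups <- setdiff(groups, drop_g)
  }
  z <- zscore_rows(mat)
  keep <- apply(is.finite(z), 1L, all)
  if (any(!keep))
    message("group_differential: constant features dropped: ",
            paste(utils::head(rownames(mat)[!keep], 5L), collapse = ", "))
  z <- z[keep, , drop = FALSE]
  n <- ncol(z)
  k <- length(groups)
  res <- lapply(groups, function(g) {
    ing <- labels == g
    beta <- rowMeans(z[, ing, drop = FALSE])
    # pooled residual variance of the indicator regression
    resid2 <- vapply(groups, function(h) {
      cols <- labels == h
      rowSums((z[, cols, drop = FALSE] -
                 rowMeans(z[, cols, drop = FALSE]))^2)
    }, numeric(nrow(z)))
    s2 <- rowSums(resid2) / (n - k)
    t <- beta / sqrt(s2 / sum(ing))
    p <- 2 * stats::pt(-abs(t), n - k)
    data.frame(feature = rownames(z), group = g, beta = beta, p = p,
               p_adj = bh_adjust(p), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Combined z-score signature
#'
#' Per sample, genes are z-scored across samples and the signature score
#' is the sum of member z-scores divided by the square root of the number
#' of measured members.
#'
#' @param mat gene x sample matrix.
#' @param genes signature gene identifiers.
#' @return named per-sample score vector.
#' @export
combined_z <- function(mat, genes) {
  genes <- intersect(genes, rownames(mat))
  if (!length(genes)) stop("combined_z: no signature genes measured",
                           call. = FALSE)
  z <- zscore_rows(mat[genes, , drop = FALSE])
  colSums(z, na.rm = TRUE) / sqrt(length(genes))
}

#' One-vs-rest marker selection
#'
#' Per group, a Welch t-test of each gene against the rest of the cohort;
#' markers must pass the BH FDR cut-off and have a log fold change
#' strictly greater than `lfc`. Returns the union panel plus per-group
#' marker lists.
#'
#' @param expr log-scale gene x sample matrix.
#' @param labels per-sample group labels.
#' @param fdr BH threshold (default 0.10).
#' @param lfc log fold-change threshold, strict inequality (default 1).
#' @return character vector of panel genes; attribute `by_group` holds
#'   per-group marker lists.
#' @export
select_group_markers <- function(expr, labels, fdr = 0.10, lfc = 1) {
  labels <- as.character(labels)
  groups <- sort(unique(labels))
  by_group <- lapply(groups, function(g) {
    ing <- labels == g
    a <- expr[, ing, drop = FALSE]
    b <- expr[, !ing, drop = FALSE]
    d <- rowMeans(a) - rowMeans(b)
    va <- apply(a, 1L, stats::var) / ncol(a)
    vb <- apply(b, 1L, stats::var) / ncol(b)
    t <- d / sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (ncol(a) - 1L) + vb^2 / (ncol(b) - 1L))
    p <- 2 * stats::pt(-abs(t), df)
    sel <- bh_adjust(p) < fdr & abs(d) > lfc
    sel[is.na(sel)] <- FALSE
    rownames(expr)[sel]
  })
  names(by_group) <- groups
  empty <- groups[lengths(by_group) == 0L]
  if (length(empty))
    warning("select_group_markers: no markers for group(s): ",
            paste(empty, collapse = ", "))
  panel <- sort(unique(unlist(by_group)))
  attr(panel, "by_group") <- by_group
  panel
}

#' Train a centroid transfer model (fallback trainer)
#'
#' Builds per-group weight vectors as the centroids of the z-scored
#' training expression over the panel genes. This is a simple stand-in
#' for externally trained one-class regression weights, which can be
#' supplied directly to [transfer_classify()] instead.
#'
#' @param expr gene x sample training matrix (panel genes as rows).
#' @param labels per-sample group labels.
#' @return list of class `transfer_model`: `W` (gene x group weights),
#'   `Y` (training panel expression), `labels`, `panel`.
#' @export
train_transfer_model <- function(expr, labels) {
  labels <- as.character(labels)
  groups <- sort(unique(labels))
  z <- zscore_rows(expr)
  W <- vapply(groups, function(g)
    rowMeans(z[, labels == g, drop = FALSE]), numeric(nrow(expr)))
  rownames(W) <- rownames(expr)
  structure(list(W = W, Y = expr, labels = labels,
                 panel = rownames(expr)),
            class = "transfer_model")
}

.unit_scale <- function(x) {
  x <- x - min(x)
  mx <- max(x)
  if (mx > 0) x / mx else x
}

#' Two-score transfer classification of an external cohort
#'
#' Score 1: `Z_ik`, the Spearman correlation between group i's weight
#' vector and external sample k's panel expression, rescaled to \[0,1\] by
#' subtracting the minimum and dividing by the maximum. Score 2: Spearman
#' correlations `S_sk` between each training sample s and external sample
#' k, rescaled to \[0,1\] within each training group, then averaged over
#' the group's training samples to give `Q_ik`. The final score is
#' `X_ik = (Z_ik + Q_ik) / 2` and each external sample is assigned the
#' group with the highest score (ties broken by group order).
#'
#' @param model a `transfer_model` (weights `W`, training panel `Y`,
#'   training `labels`).
#' @param external gene x sample matrix of the external cohort.
#' @param min_coverage warn when panel coverage falls below this fraction.
#' @return data.frame per external sample: group, score; attribute
#'   `scores` (group x sample matrix of X).
#' @export
transfer_classify <- function(model, external, min_coverage = 0.8) {
  panel <- intersect(model$panel, rownames(external))
  if (length(panel) < min_coverage * length(model$panel))
    warning("transfer_classify: external matrix covers only ",
            round(100 * length(panel) / length(model$panel)),
            "% of the panel")
  groups <- colnames(model$W)
  E <- external[panel, , drop = FALSE]
  sd0 <- apply(E, 2L, stats::sd)
  usable <- sd0 > 0
  if (any(!usable))
    message("transfer_classify: zero-variance external sample(s) left ",
            "unassigned: ",
            paste(colnames(E)[!usable], collapse = ", "))
  Z <- stats::cor(model$W[panel, , drop = FALSE], E[, usable, drop = FALSE],
                  method = "spearman")
  Z <- .unit_scale(Z)
  S <- stats::cor(model$Y[panel, , drop = FALSE], E[, usable, drop = FALSE],
                  method = "spearman")
  Q <- do.call(rbind, lapply(groups, function(g) {
    Sg <- .unit_scale(S[model$labels == g, , drop = FALSE])
    colMeans(Sg)
  }))
  rownames(Q) <- groups
  X <- (Z + Q) / 2
  pick <- apply(X, 2L, function(s) {
    top <- which(s == max(s))
    if (length(top) > 1L)
      message("transfer_classify: tie broken by group order")
    top[1L]
  })
  out <- data.frame(sample = colnames(external),
                    group = NA_character_, score = NA_real_,
                    stringsAsFactors = FALSE)
  out$group[match(colnames(E)[usable], out$sample)] <- groups[pick]
  out$score[match(colnames(E)[usable], out$sample)] <-
    X[cbind(pick, seq_len(ncol(X)))]
  attr(out, "scores") <- X
  out
}
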