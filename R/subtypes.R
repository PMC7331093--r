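#' @title Consensus clustering and subtype calling
#' @description A general consensus-clustering engine (PAM or hierarchical
#'   base clusterers on random sample subsets), the methylation CIMP
#'   classifier, and chi-square association of subtype labels with
#'   categorical features.
#' @name subtypes
NULL

#' Consensus clustering
#'
#' Repeatedly subsamples a fraction of the samples without replacement,
#' clusters each subset into K groups with the base algorithm (PAM or
#' complete-linkage hierarchical clustering on Euclidean distances), and
#' records for every sample pair the fraction of co-sampled runs in which
#' the pair co-clustered. Final labels come from complete-linkage
#' clustering of 1 - consensus.
#'
#' @param mat feature x sample matrix.
#' @param k number of clusters.
#' @param repeats number of subsampling repeats.
#' @param fraction subsample fraction (default 0.8).
#' @param base base clusterer: "pam" or "hclust".
#' @param zscore z-score features across samples first.
#' @param seed RNG seed (restored on exit).
#' @return list of class `consensus_result`: `consensus` (sample x sample
#'   matrix in \[0,1\]), `labels` (named integer vector), `k`, `repeats`,
#'   `fraction`, `base`.
#' @export
consensus_cluster <- function(mat, k, repeats = 200L, fraction = 0.8,
                              base = c("pam", "hclust"), zscore = FALSE,
                              seed = 1L) {
  base <- match.arg(base)
  n <- ncol(mat)
  if (n < 5L * k)
    stop("consensus_cluster: need at least 5*k samples", call. = FALSE)
  if (zscore) {
    mat <- zscore_rows(mat)
    mat <- mat[stats::complete.cases(mat), , drop = FALSE]
  }
  m <- max(k + 1L, floor(fraction * n))
  co <- matrix(0, n, n)
  tog <- matrix(0, n, n)
  .with_seed(seed, {
    for (r in seq_len(repeats)) {
      idx <- sort(sample(n, m))
      d <- stats::dist(t(mat[, idx, drop = FALSE]))
      cl <- if (base == "pam")
        cluster::pam(d, k, cluster.only = TRUE)
      else stats::cutree(stats::hclust(d, method = "complete"), k)
      tog[idx, idx] <- tog[idx, idx] + 1
      same <- outer(cl, cl, `==`) * 1
      co[idx, idx] <- co[idx, idx] + same
    }
  })
  consensus <- ifelse(tog > 0, co / tog, NA_real_)
  diag(consensus) <- 1
  if (anyNA(consensus))
    warning("consensus_cluster: some sample pairs were never co-sampled")
  dimnames(consensus) <- list(colnames(mat), colnames(mat))
  dmat <- 1 - consensus
  dmat[is.na(dmat)] <- 1
  labels <- stats::cutree(stats::hclust(stats::as.dist(dmat),
                                        method = "complete"), k)
  names(labels) <- colnames(mat)
  structure(list(consensus = consensus, labels = labels, k = k,
                 repeats = repeats, fraction = fraction, base = base),
            class = "consensus_result")
}

#' CIMP classification from methylation beta values
#'
#' Hierarchical clustering (Euclidean distance, complete linkage, no
#' scaling) of samples on the marker probes, cut into two clusters; the
#' cluster with the higher mean beta over the markers is labeled CIMP+.
#'
#' @param beta probe x sample beta-value matrix.
#' @param probes marker probe identifiers (rows of `beta`).
#' @return data.frame per sample: cluster, cimp ("CIMP+"/"CIMP-").
#' @export
cimp_classify <- function(beta, probes) {
  probes <- intersect(probes, rownames(beta))
  if (!length(probes)) stop("cimp_classify: no marker probes measured",
                            call. = FALSE)
  sub <- beta[probes, , drop = FALSE]
  if (all(is.na(sub))) stop("cimp_classify: all marker values missing",
                            call. = FALSE)
  if (ncol(sub) < 2L) stop("cimp_classify: need >= 2 samples",
                           call. = FALSE)
  hc <- stats::hclust(stats::dist(t(sub)), method = "complete")
  if (max(hc$height) == 0)
    stop("cimp_classify: samples are identical; cannot split into 2",
         call. = FALSE)
  cl <- stats::cutree(hc, 2L)
  mean_beta <- tapply(colMeans(sub, na.rm = TRUE), cl, mean)
  pos <- as.integer(names(mean_beta)[which.max(mean_beta)])
  data.frame(sample = colnames(beta), cluster = cl,
             cimp = ifelse(cl == pos, "CIMP+", "CIMP-"),
             stringsAsFactors = FALSE)
}

#' Chi-square association of subtype labels with features
#'
#' Chi-square test of independence (no continuity correction) between the
#' labels and each categorical/binary feature column.
#'
#' @param labels per-sample cluster labels.
#' @param features data.frame of categorical features, rows aligned to
#'   `labels`.
#' @return data.frame per feature: statistic, df, p, low_expected
#'   (any expected count below 5).
#' @export
subtype_association <- function(labels, features) {
  res <- lapply(names(features), function(f) {
    x <- features[[f]]
    tab <- table(labels, x)
    if (nrow(tab) < 2L || ncol(tab) < 2L) {
      message("subtype_association: degenerate margin, skipped: ", f)
      return(NULL)
    }
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    low <- any(ct$expected < 5)
    if (low)
      message("subtype_association: expected counts < 5 for ", f)
    data.frame(feature = f, statistic = unname(ct$statistic),
               df = unname(ct$parameter), p = ct$p.value,
               low_expected = low, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
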