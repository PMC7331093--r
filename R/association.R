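#' @title Cis/trans association with permutation empirical FDR
#' @description Multiple-regression association of DNA-level features with
#'   molecular traits under covariate adjustment, significance by
#'   permutation empirical FDR (eFDR), signed rank-sum pathway scoring,
#'   R-squared decomposition, and multivariate clinical association.
#' @name association
NULL

# least squares with multiple right-hand sides; returns beta, t, p for the
# requested design columns. X: n x q, Y: n x m.
.lm_terms <- function(X, Y, term_cols) {
  n <- nrow(X); q <- ncol(X)
  qrx <- qr(X)
  if (qrx$rank < q)
    stop("design is rank deficient; aliased columns: ",
         paste(colnames(X)[qrx$pivot[(qrx$rank + 1L):q]], collapse = ", "),
         call. = FALSE)
  beta <- qr.coef(qrx, Y)
  res <- Y - X %*% beta
  df <- n - q
  sigma2 <- colSums(res^2) / df
  xtx_inv <- chol2inv(qr.R(qrx))[order(qrx$pivot), order(qrx$pivot),
                                 drop = FALSE]
  out <- lapply(term_cols, function(j) {
    se <- sqrt(sigma2 * xtx_inv[j, j])
    t <- beta[j, ] / se
    list(beta = beta[j, ], t = t, p = 2 * stats::pt(-abs(t), df))
  })
  names(out) <- colnames(X)[term_cols]
  out
}

.covariate_design <- function(covariates, n) {
  if (is.null(covariates)) return(matrix(nrow = n, ncol = 0))
  mm <- stats::model.matrix(~ ., data = as.data.frame(covariates))
  mm[, -1, drop = FALSE]
}

#' Trans association of a genomic feature with all traits of a data type
#'
#' Each trait (row) is rank-inverse-normal transformed, then regressed on
#' the feature plus covariates; the feature's t statistic is recorded. The
#' sample labels of the outcomes are permuted `n_perm` times (jointly
#' across traits, preserving trait-trait correlation) and the empirical
#' FDR at a cut-off T is the average permuted exceedance count over the
#' observed count; the smallest T with eFDR below `efdr` is the final
#' threshold.
#'
#' @param feature per-sample indicator or score (length = columns of
#'   `traits`).
#' @param traits trait x sample matrix.
#' @param covariates data.frame of per-sample covariates (optional).
#' @param n_perm number of permutations (default 100).
#' @param efdr empirical FDR level (default 0.10).
#' @param normalize apply the inverse-normal transform per trait.
#' @param seed RNG seed.
#' @return data.frame per trait: beta, t, p, direction, significant;
#'   attributes `threshold` and `efdr_curve`.
#' @export
trans_assoc <- function(feature, traits, covariates = NULL,
                        n_perm = 100L, efdr = 0.10, normalize = TRUE,
                        seed = 1L) {
  if (stats::sd(feature) == 0)
    stop("trans_assoc: feature is constant across samples", call. = FALSE)
  if (n_perm < 10L) warning("trans_assoc: n_perm < 10 is unstable")
  n <- ncol(traits)
  Y <- if (normalize) t(apply(traits, 1L, inverse_normal_transform))
       else traits
  X <- cbind(`(Intercept)` = 1, feature = feature,
             .covariate_design(covariates, n))
  obs <- .lm_terms(X, t(Y), 2L)[[1L]]
  perms <- .with_seed(seed, {
    replicate(n_perm, sample(n))
  })
  null_abs_t <- vapply(seq_len(n_perm), function(b) {
    abs(.lm_terms(X, t(Y[, perms[, b], drop = FALSE]), 2L)[[1L]]$t)
  }, numeric(nrow(Y)))
  grid <- sort(unique(abs(obs$t)))
  n_obs <- vapply(grid, function(T) sum(abs(obs$t) >= T), numeric(1))
  n_null <- vapply(grid, function(T) mean(colSums(null_abs_t >= T)),
                   numeric(1))
  curve <- ifelse(n_obs > 0, pmin(1, n_null / n_obs), 1)
  curve <- rev(cummin(rev(curve)))
  pass <- which(curve < efdr)
  threshold <- if (length(pass)) grid[min(pass)] else Inf
  out <- data.frame(trait = rownames(traits), beta = obs$beta, t = obs$t,
                    p = obs$p, direction = sign(obs$beta),
                    significant = abs(obs$t) >= threshold,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "threshold") <- threshold
  attr(out, "efdr_curve") <- data.frame(t = grid, efdr = curve)
  out
}

#' Signed rank-sum pathway scores
#'
#' Per gene the summary `T_j = -sign(beta_j) * log(p_j)` is computed (large
#' positive when the event upregulates the gene). For each gene set a
#' two-sided Wilcoxon rank-sum test compares in-set vs out-of-set T values;
#' p values are BH-adjusted across sets; the direction is up when the
#' in-set median exceeds the out-of-set median and the score is
#' `(+/-)log10(p_adj)`.
#'
#' @param beta,p named per-gene effect and p-value vectors (same names).
#' @param gene_sets named list of gene identifier vectors.
#' @return data.frame per set: n_in, p, p_adj, direction, score.
#' @export
pathway_score <- function(beta, p, gene_sets) {
  stopifnot(identical(names(beta), names(p)))
  p_clip <- pmax(p, .Machine$double.xmin)
  T_j <- -sign(beta) * log(p_clip)
  skipped <- names(gene_sets)[vapply(gene_sets, function(g)
    length(intersect(g, names(T_j))) < 2L, logical(1))]
  if (length(skipped))
    message("pathway_score: sets skipped (fewer than 2 measured members): ",
            paste(skipped, collapse = ", "))
  res <- .ranksum_sets(T_j, gene_sets)
  res$p_adj <- bh_adjust(res$p)
  res$score <- res$direction * -log10(pmax(res$p_adj,
                                           .Machine$double.xmin))
  res$score[res$p_adj >= 1] <- 0
  res
}

.cis_patterns <- c("none", "mRNA only", "global only", "phospho only",
                   "mRNA & global", "mRNA & phospho", "global & phospho",
                   "all three")

.cis_label <- function(sig) {     # sig: logical length 3 (mrna, prot, phos)
  key <- paste(as.integer(sig), collapse = "")
  switch(key,
         "000" = "none", "100" = "mRNA only", "010" = "global only",
         "001" = "phospho only", "110" = "mRNA & global",
         "101" = "mRNA & phospho", "011" = "global & phospho",
         "111" = "all three")
}

#' Cis association of DNA variations with multi-omic traits
#'
#' Per gene, each trait (mRNA, protein, phospho) is regressed on the
#' gene's CNV log-ratio, CNV BAF, methylation (and mutation status where
#' the cohort mutation rate exceeds `mutation_min_rate`) plus covariates.
#' The per-(variation, trait) evidence score is `-log10(p)` from that
#' regression. Directional biological filters are applied: CNV (lr) must
#' associate positively with all traits, methylation negatively with all
#' traits, CNV (baf) and mutation with a consistent direction across
#' traits. Significance thresholds on the evidence score are calibrated
#' per (variation, trait) by permutation empirical FDR (outcome columns
#' shuffled jointly per data type). Each gene/variation receives one of
#' eight configuration labels according to which traits pass.
#'
#' @param traits named list of gene x sample matrices: `mrna`, `protein`,
#'   `phospho` (gene-level).
#' @param variations named list of gene x sample matrices: `cnv_lr`,
#'   `cnv_baf`, `methy`, optionally `mutation` (0/1).
#' @param covariates per-sample covariate data.frame (optional).
#' @param n_perm permutations (default 100).
#' @param efdr empirical FDR level (default 0.05).
#' @param mutation_min_rate minimum mutation rate to include the mutation
#'   term.
#' @param normalize inverse-normal transform traits per gene.
#' @param seed RNG seed.
#' @return list of class `cis_call`: `calls` (long data.frame: gene,
#'   variation, trait, beta, score, passes_filter, significant),
#'   `configurations` (gene x variation label matrix), `thresholds`,
#'   `r2` (gene x variation x trait delta R-squared array).
#' @export
cis_assoc <- function(traits, variations, covariates = NULL,
                      n_perm = 100L, efdr = 0.05,
                      mutation_min_rate = 0.05, normalize = TRUE,
                      seed = 1L) {
  trait_names <- c("mrna", "protein", "phospho")
  stopifnot(all(trait_names %in% names(traits)))
  var_names <- intersect(c("cnv_lr", "cnv_baf", "methy", "mutation"),
                         names(variations))
  genes <- Reduce(intersect, c(lapply(traits, rownames),
                               lapply(variations, rownames)))
  if (length(genes) < 30L)
    stop("cis_assoc: need >= 30 genes for a stable permutation null",
         call. = FALSE)
  n <- ncol(traits$mrna)
  covM <- .covariate_design(covariates, n)
  perms <- .with_seed(seed, {
    lapply(trait_names, function(tn) replicate(n_perm, sample(n)))
  })
  names(perms) <- trait_names

  n_rep <- n_perm + 1L      # observed + permutations
  dims <- c(gene = length(genes), variation = length(var_names),
            trait = length(trait_names), rep = n_rep)
  beta_arr <- array(NA_real_, dims,
                    dimnames = list(genes, var_names, trait_names, NULL))
  score_arr <- beta_arr
  r2_arr <- array(NA_real_, dims[1:3],
                  dimnames = list(genes, var_names, trait_names))

  mut_rate <- if ("mutation" %in% var_names)
    rowMeans(variations$mutation[genes, , drop = FALSE] > 0) else NULL

  for (g in genes) {
    vmat <- lapply(var_names, function(v) variations[[v]][g, ])
    names(vmat) <- var_names
    use_mut <- "mutation" %in% var_names &&
      mut_rate[g] > mutation_min_rate &&
      stats::sd(vmat$mutation) > 0
    use_vars <- setdiff(var_names, if (use_mut) character() else "mutation")
    X <- cbind(`(Intercept)` = 1,
               do.call(cbind, vmat[use_vars]), covM)
    colnames(X)[seq_along(use_vars) + 1L] <- use_vars
    term_cols <- seq_along(use_vars) + 1L
    for (tn in trait_names) {
      y <- traits[[tn]][g, ]
      if (normalize) y <- inverse_normal_transform(y)
      Ymat <- cbind(y, vapply(seq_len(n_perm),
                              function(b) y[perms[[tn]][, b]],
                              numeric(n)))
      fit <- .lm_terms(X, Ymat, term_cols)
      for (v in use_vars) {
        beta_arr[g, v, tn, ] <- fit[[v]]$beta
        score_arr[g, v, tn, ] <- -log10(pmax(fit[[v]]$p,
                                             .Machine$double.xmin))
      }
      # delta R2 per variation (observed data only)
      r2_full <- 1 - sum((Ymat[, 1] - X %*% qr.coef(qr(X),
                                                    Ymat[, 1]))^2) /
        sum((Ymat[, 1] - mean(Ymat[, 1]))^2)
      for (v in use_vars) {
        Xr <- X[, setdiff(colnames(X), v), drop = FALSE]
        r2_red <- 1 - sum((Ymat[, 1] - Xr %*% qr.coef(qr(Xr),
                                                      Ymat[, 1]))^2) /
          sum((Ymat[, 1] - mean(Ymat[, 1]))^2)
        r2_arr[g, v, tn] <- max(0, r2_full - r2_red)
      }
    }
  }

  # directional filter per (gene, variation, rep)
  passes <- array(FALSE, dims, dimnames = dimnames(beta_arr))
  for (v in var_names) {
    b <- beta_arr[, v, , , drop = FALSE]
    pos <- apply(b > 0, c(1, 4), all)
    neg <- apply(b < 0, c(1, 4), all)
    pf <- switch(v,
                 cnv_lr = pos,
                 methy = neg,
                 cnv_baf = pos | neg,
                 mutation = pos | neg)
    for (tn in trait_names) passes[, v, tn, ] <- pf
  }

  # eFDR-calibrated score threshold per (variation, trait)
  thresholds <- matrix(Inf, length(var_names), length(trait_names),
                       dimnames = list(var_names, trait_names))
  for (v in var_names) for (tn in trait_names) {
    s_obs <- score_arr[, v, tn, 1L]
    f_obs <- passes[, v, tn, 1L]
    ok <- is.finite(s_obs)
    cand <- sort(unique(s_obs[ok & f_obs]))
    if (!length(cand)) next
    s_null <- score_arr[, v, tn, -1L, drop = FALSE]
    f_null <- passes[, v, tn, -1L, drop = FALSE]
    n_obs <- vapply(cand, function(a) sum(f_obs & s_obs >= a, na.rm = TRUE),
                    numeric(1))
    n_null <- vapply(cand, function(a)
      sum(f_null & s_null >= a, na.rm = TRUE) / n_perm, numeric(1))
    curve <- ifelse(n_obs > 0, pmin(1, n_null / n_obs), 1)
    curve <- rev(cummin(rev(curve)))
    pass_i <- which(curve < efdr)
    if (length(pass_i)) thresholds[v, tn] <- cand[min(pass_i)]
  }

  calls <- do.call(rbind, lapply(var_names, function(v)
    do.call(rbind, lapply(trait_names, function(tn) {
      data.frame(gene = genes, variation = v, trait = tn,
                 beta = beta_arr[, v, tn, 1L],
                 score = score_arr[, v, tn, 1L],
                 passes_filter = passes[, v, tn, 1L],
                 significant = passes[, v, tn, 1L] &
                   score_arr[, v, tn, 1L] >= thresholds[v, tn],
                 stringsAsFactors = FALSE)
    }))))
  calls$significant[is.na(calls$significant)] <- FALSE
  rownames(calls) <- NULL

  configurations <- matrix("none", length(genes), length(var_names),
                           dimnames = list(genes, var_names))
  for (g in genes) for (v in var_names) {
    sig <- vapply(trait_names, function(tn) {
      s <- calls$significant[calls$gene == g & calls$variation == v &
                               calls$trait == tn]
      isTRUE(s)
    }, logical(1))
    configurations[g, v] <- .cis_label(sig)
  }

  structure(list(calls = calls, configurations = configurations,
                 thresholds = thresholds, r2 = r2_arr),
            class = "cis_call")
}

#' R-squared decomposition for one regression
#'
#' Computes, for each named variation column, the drop in R-squared when
#' that column is removed from the full design (covariates always kept):
#' `deltaR2 = R2_full - R2_reduced`, clipped at 0 (clips are reported via
#' the `clipped` attribute).
#'
#' @param y response vector.
#' @param variation_mat n x k matrix of variation columns (named).
#' @param covariates optional data.frame of covariates.
#' @return named numeric vector of delta R-squared per variation;
#'   attribute `r2_full`.
#' @export
r2_decomposition <- function(y, variation_mat, covariates = NULL) {
  variation_mat <- as.matrix(variation_mat)
  n <- length(y)
  X <- cbind(`(Intercept)` = 1, variation_mat,
             .covariate_design(covariates, n))
  qrx <- qr(X)
  if (qrx$rank < ncol(X))
    stop("r2_decomposition: collinear design; aliased columns: ",
         paste(colnames(X)[qrx$pivot[(qrx$rank + 1L):ncol(X)]],
               collapse = ", "), call. = FALSE)
  tss <- sum((y - mean(y))^2)
  r2_of <- function(Xm) 1 - sum((y - Xm %*% qr.coef(qr(Xm), y))^2) / tss
  r2_full <- r2_of(X)
  vars <- colnames(variation_mat)
  out <- vapply(vars, function(v) {
    r2_full - r2_of(X[, setdiff(colnames(X), v), drop = FALSE])
  }, numeric(1))
  clipped <- names(out)[out < 0]
  if (length(clipped))
    message("r2_decomposition: negative deltas clipped to 0 for: ",
            paste(clipped, collapse = ", "))
  out <- pmax(out, 0)
  attr(out, "r2_full") <- r2_full
  out
}

#' Multivariate clinical association
#'
#' One joint linear regression of each trait on all clinical covariates;
#' per expanded covariate term, p values are BH-adjusted across genes and
#' the number of genes below `report_threshold` is tabulated.
#'
#' @param traits gene x sample matrix.
#' @param clinical data.frame of covariates; numeric columns enter as-is,
#'   character/factor columns are dummy-coded.
#' @param report_threshold adjusted-p reporting level (default 0.10).
#' @return list: `p_adj` (gene x term matrix), `beta`, `counts`
#'   (named vector of genes below threshold per term).
#' @export
clinical_multivariate <- function(traits, clinical,
                                  report_threshold = 0.10) {
  n <- ncol(traits)
  X <- cbind(`(Intercept)` = 1, .covariate_design(clinical, n))
  terms <- setdiff(colnames(X), "(Intercept)")
  fits <- .lm_terms(X, t(traits), match(terms, colnames(X)))
  p <- vapply(fits, function(f) f$p, numeric(nrow(traits)))
  beta <- vapply(fits, function(f) f$beta, numeric(nrow(traits)))
  rownames(p) <- rownames(beta) <- rownames(traits)
  p_adj <- apply(p, 2L, bh_adjust)
  counts <- colSums(p_adj < report_threshold, na.rm = TRUE)
  list(p_adj = p_adj, beta = beta, counts = counts)
}
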