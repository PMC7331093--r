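#' @title Kinase-substrate phosphoproteomic analysis
#' @description Fold-change ranking of annotated kinase-substrate
#'   phosphosite events across tumor/NAT pairs, grade comparison by
#'   Mann-Whitney test, and the module-correlation comparison test.
#' @name phospho
NULL

#' Rank annotated substrate events by tumor/NAT fold change
#'
#' Annotated phosphosite events (rows of the site matrix named
#' `GENE:SITE`) are matched against the kinase-substrate annotation;
#' unmatched annotation rows are dropped and counted. Per tumor/NAT pair,
#' the log2 fold change of each event is `site(tumor) - site(nat)`;
#' events with a fold change above `log2(fold)` are ranked descending
#' within each tumor. The summary counts, per event, the tumors where it
#' ranked first.
#'
#' @param site_mat phosphosite x sample log2 matrix, rownames
#'   `GENE:SITE`.
#' @param pairs data.frame with columns `tumor`, `nat` naming matched
#'   sample columns.
#' @param annotation data.frame with columns `kinase`, `substrate_gene`,
#'   `site`.
#' @param fold linear fold-change threshold (default 1.5, strict).
#' @return list of class `rank_table`: `ranks` (long data.frame: tumor,
#'   event, kinase, log2fc, rank), `summary` (per event: n_pass, n_top,
#'   top_fraction, majority_top), `n_dropped_annotations`.
#' @export
substrate_rank <- function(site_mat, pairs, annotation, fold = 1.5) {
  ann <- annotation
  ann$event <- paste0(ann$substrate_gene, ":", ann$site)
  matched <- ann$event %in% rownames(site_mat)
  n_dropped <- sum(!matched)
  ann <- ann[matched, , drop = FALSE]
  if (!nrow(ann))
    stop("substrate_rank: no annotation rows match the site matrix",
         call. = FALSE)
  ok_pair <- pairs$tumor %in% colnames(site_mat) &
    pairs$nat %in% colnames(site_mat)
  if (any(!ok_pair))
    message("substrate_rank: unpaired tumors skipped: ",
            paste(pairs$tumor[!ok_pair], collapse = ", "))
  pairs <- pairs[ok_pair, , drop = FALSE]
  if (!nrow(pairs)) stop("substrate_rank: no valid tumor/NAT pairs",
                         call. = FALSE)
  thr <- log2(fold)
  ranks <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
    fc <- site_mat[ann$event, pairs$tumor[i]] -
      site_mat[ann$event, pairs$nat[i]]
    pass <- which(is.finite(fc) & fc > thr)
    if (!length(pass)) return(NULL)
    ord <- order(-fc[pass])
    data.frame(tumor = pairs$tumor[i], event = ann$event[pass][ord],
               kinase = ann$kinase[pass][ord],
               log2fc = fc[pass][ord], rank = seq_along(ord),
               stringsAsFactors = FALSE)
  }))
  if (is.null(ranks))
    ranks <- data.frame(tumor = character(), event = character(),
                        kinase = character(), log2fc = numeric(),
                        rank = integer(), stringsAsFactors = FALSE)
  summary <- do.call(rbind, lapply(unique(ann$event), function(ev) {
    sub <- ranks[ranks$event == ev, , drop = FALSE]
    n_top <- sum(sub$rank == 1L)
    data.frame(event = ev, n_pass = nrow(sub), n_top = n_top,
               top_fraction = n_top / nrow(pairs),
               majority_top = n_top > nrow(pairs) / 2,
               stringsAsFactors = FALSE)
  }))
  rownames(summary) <- NULL
  structure(list(ranks = ranks, summary = summary,
                 n_dropped_annotations = n_dropped,
                 n_pairs = nrow(pairs)),
            class = "rank_table")
}

#' Grade comparison per phosphosite
#'
#' Two-sided Mann-Whitney U test of each site between two grade strata
#' (for example low = grades 1-2 vs high = grades 3-4).
#'
#' @param site_mat phosphosite x sample matrix.
#' @param strata per-sample factor with exactly two levels; NA samples
#'   are dropped.
#' @return data.frame per site: u, p, significant (p < 0.05).
#' @export
grade_compare <- function(site_mat, strata) {
  strata <- factor(strata)
  keep <- !is.na(strata)
  strata <- droplevels(strata[keep])
  site_mat <- site_mat[, keep, drop = FALSE]
  if (nlevels(strata) != 2L)
    stop("grade_compare: need exactly two strata", call. = FALSE)
  if (any(table(strata) < 3L))
    stop("grade_compare: each stratum needs >= 3 samples", call. = FALSE)
  lv <- levels(strata)
  res <- lapply(rownames(site_mat), function(s) {
    x <- site_mat[s, strata == lv[1L]]
    y <- site_mat[s, strata == lv[2L]]
    rs <- .ranksum_p(x[is.finite(x)], y[is.finite(y)])
    data.frame(site = s, u = rs$u, p = rs$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$significant <- out$p < 0.05
  rownames(out) <- NULL
  out
}

#' Module correlation comparison test
#'
#' For each module (gene list), all within-module pairwise correlations
#' are computed per data type; a one-sided two-sample t-test asks whether
#' the target data type's correlations exceed each comparator's.
#'
#' @param matrices named list of gene x sample matrices (data types).
#' @param modules named list of gene vectors.
#' @param target name of the data type expected to be more correlated
#'   (default first element).
#' @param method correlation method (default "pearson").
#' @return data.frame per (module, comparator): n_genes, mean_target,
#'   mean_other, t, p.
#' @export
module_corr_test <- function(matrices, modules, target = names(matrices)[1],
                             method = "pearson") {
  stopifnot(target %in% names(matrices))
  others <- setdiff(names(matrices), target)
  pair_cors <- function(mat, genes) {
    genes <- intersect(genes, rownames(mat))
    if (length(genes) < 3L) return(NULL)
    cm <- stats::cor(t(mat[genes, , drop = FALSE]), method = method)
    cm[upper.tri(cm)]
  }
  res <- lapply(names(modules), function(m) {
    ct <- pair_cors(matrices[[target]], modules[[m]])
    if (is.null(ct)) {
      message("module_corr_test: module too small, skipped: ", m)
      return(NULL)
    }
    do.call(rbind, lapply(others, function(o) {
      co <- pair_cors(matrices[[o]], modules[[m]])
      if (is.null(co)) return(NULL)
      tt <- stats::t.test(ct, co, alternative = "greater")
      data.frame(module = m, comparator = o,
                 n_genes = length(intersect(modules[[m]],
                                            rownames(matrices[[target]]))),
                 mean_target = mean(ct), mean_other = mean(co),
                 t = unname(tt$statistic), p = tt$p.value,
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
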