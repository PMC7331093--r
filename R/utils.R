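#' Benjamini-Hochberg adjustment
#'
#' Thin named wrapper so every module adjusts p values through one audited
#' entry point.
#'
#' @param p numeric vector of raw p values (NA allowed, passed through).
#' @return adjusted p values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  stats::p.adjust(p, method = "BH")
}

#' Rank-based inverse normal transform
#'
#' Maps a vector onto standard-normal quantiles via its mid-ranks
#' (qnorm((rank - 0.5) / n)); ties receive the average rank. Used to
#' normalize molecular traits to "match a standard normal distribution"
#' before regression.
#'
#' @param x numeric vector; NA preserved.
#' @return transformed vector.
#' @export
inverse_normal_transform <- function(x) {
  out <- rep(NA_real_, length(x))
  ok <- !is.na(x)
  n <- sum(ok)
  if (n == 0L) return(out)
  r <- rank(x[ok], ties.method = "average")
  out[ok] <- stats::qnorm((r - 0.5) / n)
  out
}

#' Z-score matrix rows
#'
#' Centers and scales each row (feature) across columns (samples). Rows with
#' zero variance become NA and are reported via the `dropped` attribute.
#'
#' @param mat numeric matrix, features x samples.
#' @return matrix of the same shape; attribute `scale` holds the per-row sd
#'   used (needed to convert effect sizes back to the original scale).
#' @export
zscore_rows <- function(mat) {
  mu <- rowMeans(mat, na.rm = TRUE)
  sd <- apply(mat, 1L, stats::sd, na.rm = TRUE)
  z <- (mat - mu) / sd
  z[sd == 0 | is.na(sd), ] <- NA_real_
  attr(z, "scale") <- sd
  attr(z, "center") <- mu
  z
}

#' Read a feature-by-sample matrix from TSV
#'
#' First column holds feature identifiers, remaining columns samples.
#'
#' @param path file path.
#' @return numeric matrix with rownames.
#' @export
read_matrix_tsv <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  m <- as.matrix(dt[, -1, drop = FALSE])
  rownames(m) <- as.character(dt[[1]])
  storage.mode(m) <- "double"
  m
}

#' Write a feature-by-sample matrix as TSV
#'
#' @param mat numeric matrix with rownames.
#' @param path destination file.
#' @param id_col name for the feature-identifier column.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(mat, path, id_col = "feature") {
  df <- data.frame(rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- id_col
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}

# Two-sided Wilcoxon rank-sum p via the normal approximation with tie
# correction (matches wilcox.test(correct = FALSE, exact = FALSE)).
# Vectorisation-friendly core used by the pathway scorer.
.ranksum_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  mu <- nx * ny / 2
  ties <- table(r)
  sigma2 <- nx * ny / 12 * ((nx + ny + 1) -
    sum(ties^3 - ties) / ((nx + ny) * (nx + ny - 1)))
  if (sigma2 <= 0) return(list(u = u, p = 1))
  z <- (u - mu) / sqrt(sigma2)
  list(u = u, p = 2 * stats::pnorm(-abs(z)))
}

# Rank-sum comparison of a score vector inside vs outside each gene set.
# Returns one row per set: n_in, p, direction (+1 in-set median higher).
.ranksum_sets <- function(scores, gene_sets) {
  stopifnot(!is.null(names(scores)))
  res <- lapply(names(gene_sets), function(set_name) {
    members <- intersect(gene_sets[[set_name]], names(scores))
    if (length(members) < 2L) return(NULL)
    t_in <- scores[members]
    t_out <- scores[setdiff(names(scores), members)]
    if (length(t_out) < 1L) return(NULL)
    rs <- .ranksum_p(t_in, t_out)
    data.frame(set = set_name, n_in = length(members),
               p = rs$p,
               direction = ifelse(stats::median(t_in) > stats::median(t_out),
                                  1L, -1L),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  if (is.null(res)) {
    res <- data.frame(set = character(), n_in = integer(), p = numeric(),
                      direction = integer(), stringsAsFactors = FALSE)
  }
  res
}

# Deterministic integer sub-seed derived from a base seed; keeps values
# below 2^31 so they remain valid R integers.
.sub_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + k * 104729) %% 2147483647L)
}
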