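#' @title TMT reporter-ion quantification
#' @description Functions that turn a filtered PSM table into normalized
#'   gene/protein/peptide/site abundance matrices. A PSM table is a
#'   data.frame with one row per peptide-spectrum match and columns
#'   `plex`, `spectrum_id`, `peptide`, `site`, `gene`, `protein`,
#'   `unique_razor`, `contaminant`, `labeled`, `purity`, `ms1_intensity`
#'   and one intensity column per reporter channel. The plex design is a
#'   data.frame with columns `plex`, `channel`, `sample`, `is_reference`
#'   mapping channels to samples; exactly one channel per plex is the
#'   pooled reference.
#' @name tmt_quant
NULL

.reporter_channels <- function(psm, design) {
  ch <- unique(design$channel)
  missing <- setdiff(ch, colnames(psm))
  if (length(missing))
    stop("PSM table lacks reporter columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  ch
}

.reference_channel <- function(design, plex) {
  ref <- design$channel[design$plex == plex & design$is_reference]
  if (length(ref) != 1L)
    stop("plex ", plex, " must designate exactly one reference channel",
         call. = FALSE)
  ref
}

# peptide-ion key: sequence plus site configuration (site-level entries of
# the same sequence are distinct ions for redundancy purposes)
.ion_key <- function(psm) {
  paste(psm$peptide, ifelse(is.na(psm$site), "", psm$site), sep = "|")
}

#' Filter a PSM table by the quantification quality rules
#'
#' Removes, in order: (a) unlabeled PSMs; (b) PSMs with zero/missing
#' reference-channel intensity; (c) precursor purity < 50%; (d) summed
#' reporter intensity below the 5th percentile of the plex's PSM file
#' (2.5th in phospho mode); (e) non-phosphorylated peptides in phospho
#' mode; then contaminants; finally, among redundant PSMs of the same
#' peptide ion in one plex, keeps the single PSM with the highest summed
#' reporter intensity (ties broken by spectrum id order).
#'
#' @param psm PSM table (see [tmt_quant]).
#' @param design plex design.
#' @param phospho_mode logical; enables the 2.5% intensity percentile and
#'   the phosphopeptide requirement.
#' @return the filtered PSM table; the per-plex intensity floors used are
#'   attached as attribute `psm_intensity_floor` and reused when an
#'   already-filtered table is filtered again (making the filter
#'   idempotent).
#' @export
filter_psms <- function(psm, design, phospho_mode = FALSE) {
  if (nrow(psm) == 0L) stop("empty PSM table", call. = FALSE)
  .reporter_channels(psm, design)
  keep <- psm$labeled
  psm <- psm[keep, , drop = FALSE]
  # (b) missing reference quantification, per plex
  ok <- logical(nrow(psm))
  for (px in unique(psm$plex)) {
    ref <- .reference_channel(design, px)
    i <- psm$plex == px
    ok[i] <- !is.na(psm[[ref]][i]) & psm[[ref]][i] > 0
  }
  psm <- psm[ok, , drop = FALSE]
  psm <- psm[psm$purity >= 0.5, , drop = FALSE]
  # (d) summed reporter intensity percentile, per plex file. A filtered
  # table carries its thresholds as an attribute so that re-filtering is
  # idempotent rather than shaving another percentile off the survivors.
  pct <- if (phospho_mode) 0.025 else 0.05
  ch_all <- unique(design$channel)
  sums <- rowSums(as.matrix(psm[, intersect(ch_all, colnames(psm)),
                                drop = FALSE]), na.rm = TRUE)
  floors <- attr(psm, "psm_intensity_floor")
  if (is.null(floors)) floors <- c()
  keep <- logical(nrow(psm))
  for (px in unique(psm$plex)) {
    i <- which(psm$plex == px)
    if (is.null(floors[px]) || is.na(floors[px]))
      floors[px] <- stats::quantile(sums[i], pct, names = FALSE, type = 7)
    keep[i] <- sums[i] >= floors[px]
  }
  psm <- psm[keep, , drop = FALSE]
  sums <- sums[keep]
  if (phospho_mode) {
    has_phos <- !is.na(psm$site) & nzchar(psm$site)
    psm <- psm[has_phos, , drop = FALSE]
    sums <- sums[has_phos]
  }
  notcon <- !psm$contaminant
  psm <- psm[notcon, , drop = FALSE]
  sums <- sums[notcon]
  # redundancy: best PSM per (plex, peptide ion)
  key <- paste(psm$plex, .ion_key(psm), sep = "@")
  ord <- order(key, -sums, psm$spectrum_id)
  psm <- psm[ord, , drop = FALSE]
  psm <- psm[!duplicated(key[ord]), , drop = FALSE]
  out <- psm[order(psm$spectrum_id), , drop = FALSE]
  attr(out, "psm_intensity_floor") <- floors
  out
}

#' Per-PSM log2 ratios to the reference channel
#'
#' For each PSM, each sample channel's intensity is log2 transformed and
#' the log2 reference intensity subtracted. Zero intensities in sample
#' channels become NA (missing), not -Inf.
#'
#' @inheritParams filter_psms
#' @return list with `ratios` (PSM x sample matrix, NA where a sample is
#'   not in the PSM's plex) and the input `psm` rows, aligned.
#' @export
psm_ratios <- function(psm, design) {
  samples <- design$sample[!design$is_reference]
  ratios <- matrix(NA_real_, nrow(psm), length(samples),
                   dimnames = list(NULL, samples))
  for (px in unique(psm$plex)) {
    ref <- .reference_channel(design, px)
    dsub <- design[design$plex == px & !design$is_reference, , drop = FALSE]
    i <- which(psm$plex == px)
    ref_int <- psm[[ref]][i]
    for (r in seq_len(nrow(dsub))) {
      v <- psm[[dsub$channel[r]]][i]
      v[!is.na(v) & v <= 0] <- NA_real_
      ratios[i, dsub$sample[r]] <- log2(v) - log2(ref_int)
    }
  }
  list(ratios = ratios, psm = psm)
}

#' IQR outlier trim
#'
#' Keeps values v with Q1 - 1.5*IQR <= v <= Q3 + 1.5*IQR, where Q1/Q3 are
#' computed by linear interpolation between order statistics (quantile
#' type 7).
#'
#' @param values numeric vector; NA dropped.
#' @return the surviving values.
#' @export
iqr_trim <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) == 0L) stop("iqr_trim: no finite values", call. = FALSE)
  q <- stats::quantile(values, c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[2] - q[1]
  values[values >= q[1] - 1.5 * iqr & values <= q[2] + 1.5 * iqr]
}

.level_key <- function(psm, level) {
  switch(level,
         gene = psm$gene,
         protein = psm$protein,
         peptide = psm$peptide,
         site = paste0(psm$peptide, "|",
                       ifelse(is.na(psm$site), "<unlocalized>", psm$site)),
         stop("unknown level: ", level, call. = FALSE))
}

#' Summarize PSM ratios to an entry-level ratio matrix
#'
#' Groups PSM ratios by the level key (gene symbol, protein accession,
#' peptide sequence, or peptide + site configuration), applies the IQR trim
#' per entry per sample, and takes the median of survivors. Entries with no
#' surviving PSM in a plex are missing for that plex's samples.
#'
#' @param pr result of [psm_ratios()].
#' @param level one of "gene", "protein", "peptide", "site".
#' @return `ratio_matrix`: entries x samples matrix of log2 ratios.
#' @export
summarize_level <- function(pr, level = c("gene", "protein", "peptide",
                                          "site")) {
  level <- match.arg(level)
  key <- .level_key(pr$psm, level)
  entries <- sort(unique(key))
  out <- matrix(NA_real_, length(entries), ncol(pr$ratios),
                dimnames = list(entries, colnames(pr$ratios)))
  idx_by_entry <- split(seq_len(nrow(pr$psm)), key)
  for (e in entries) {
    rows <- idx_by_entry[[e]]
    sub <- pr$ratios[rows, , drop = FALSE]
    for (j in seq_len(ncol(sub))) {
      v <- sub[, j]
      v <- v[is.finite(v)]
      if (length(v)) out[e, j] <- stats::median(iqr_trim(v))
    }
  }
  structure(out, class = c("ratio_matrix", class(out)), level = level)
}

#' MAD-normalize a ratio matrix
#'
#' Implements the normalization `R^N_ij = (R^C_ij / MAD_i) * MAD_0 + M_0`
#' with `R^C_ij = R_ij - M_i`, where `M_i` is sample i's median ratio,
#' `M_0` the median of the `M_i`, `MAD_i = median(|R^C_ij|)` and `MAD_0`
#' the median of the `MAD_i`. Missing values pass through untouched. After
#' normalization every sample's column has median `M_0` and MAD `M_0`-scale
#' `MAD_0` exactly (up to floating point).
#'
#' @param mat entries x samples ratio matrix ([summarize_level()] output or
#'   any numeric matrix with sample columns).
#' @return normalized matrix with attributes `M0`, `MAD0`, `Mi`, `MADi`.
#' @export
mad_normalize <- function(mat) {
  if (any(colSums(is.finite(mat)) < 2L))
    stop("mad_normalize: each sample needs >= 2 finite entries",
         call. = FALSE)
  Mi <- apply(mat, 2L, stats::median, na.rm = TRUE)
  M0 <- stats::median(Mi)
  centered <- sweep(mat, 2L, Mi)
  MADi <- apply(abs(centered), 2L, stats::median, na.rm = TRUE)
  bad <- which(MADi == 0)
  if (length(bad))
    stop("mad_normalize: zero MAD in sample(s): ",
         paste(colnames(mat)[bad], collapse = ", "), call. = FALSE)
  MAD0 <- stats::median(MADi)
  out <- sweep(centered, 2L, MADi, `/`) * MAD0 + M0
  attributes(out)$dimnames <- dimnames(mat)
  structure(out, class = class(mat), level = attr(mat, "level"),
            M0 = M0, MAD0 = MAD0, Mi = Mi, MADi = MADi)
}

#' Reference-channel intensity per entry
#'
#' For each entry and plex, `REF_ik` is the weighted sum of the MS1
#' intensities of the top three most intense peptide ions of that entry in
#' that plex, each weighted by the proportion of the reference-channel
#' reporter intensity to the total summed reporter intensity of its PSM.
#' The overall `REF_i` is the mean of `REF_ik` over all plexes, with plexes
#' where the entry was not quantified imputed by the global minimum
#' observed `REF_ik`.
#'
#' @inheritParams filter_psms
#' @param level summarization level.
#' @return named numeric vector of REF_i (> 0) per entry.
#' @export
reference_intensity <- function(psm, design, level = "gene") {
  key <- .level_key(psm, level)
  plexes <- unique(design$plex)
  ch_all <- unique(design$channel)
  sum_rep <- rowSums(as.matrix(psm[, intersect(ch_all, colnames(psm)),
                                   drop = FALSE]), na.rm = TRUE)
  ref_int <- numeric(nrow(psm))
  for (px in unique(psm$plex)) {
    i <- psm$plex == px
    ref_int[i] <- psm[[.reference_channel(design, px)]][i]
  }
  w <- ifelse(sum_rep > 0, ref_int / sum_rep, 0)
  contrib <- psm$ms1_intensity * w
  ion <- .ion_key(psm)
  entries <- sort(unique(key))
  ref_ik <- matrix(NA_real_, length(entries), length(plexes),
                   dimnames = list(entries, plexes))
  df <- data.frame(entry = key, plex = psm$plex, ion = ion,
                   ms1 = psm$ms1_intensity, contrib = contrib,
                   stringsAsFactors = FALSE)
  grp <- split(df, list(df$entry, df$plex), drop = TRUE, sep = "\r")
  for (nm in names(grp)) {
    g <- grp[[nm]]
    # one row per peptide ion (redundancy already resolved upstream, but
    # guard by keeping the most intense PSM per ion)
    g <- g[order(g$ion, -g$ms1), , drop = FALSE]
    g <- g[!duplicated(g$ion), , drop = FALSE]
    top <- utils::head(g[order(-g$ms1), , drop = FALSE], 3L)
    ref_ik[g$entry[1L], g$plex[1L]] <- sum(top$contrib)
  }
  if (all(is.na(ref_ik)))
    stop("reference_intensity: no quantified entries", call. = FALSE)
  none <- rownames(ref_ik)[rowSums(!is.na(ref_ik)) == 0L]
  if (length(none))
    stop("reference_intensity: entries with no qualifying PSMs: ",
         paste(utils::head(none, 5L), collapse = ", "), call. = FALSE)
  gmin <- min(ref_ik, na.rm = TRUE)
  ref_ik[is.na(ref_ik)] <- gmin
  rowMeans(ref_ik)
}

#' Convert normalized ratios to the absolute abundance scale
#'
#' `A_ij = R^N_ij + log2(REF_i)`; missingness is preserved.
#'
#' @param ratio normalized ratio matrix ([mad_normalize()] output).
#' @param ref named REF_i vector covering the ratio rows.
#' @return `abundance_matrix`: entries x samples log2 abundances with
#'   attribute `REF`.
#' @export
to_abundance <- function(ratio, ref) {
  if (!all(rownames(ratio) %in% names(ref)))
    stop("to_abundance: entry sets do not align", call. = FALSE)
  ref <- ref[rownames(ratio)]
  if (any(!is.finite(ref)) || any(ref <= 0))
    stop("to_abundance: REF must be positive", call. = FALSE)
  out <- ratio + log2(ref)
  structure(unclass(out), class = c("abundance_matrix", "matrix", "array"),
            level = attr(ratio, "level"), REF = ref,
            M0 = attr(ratio, "M0"), MAD0 = attr(ratio, "MAD0"))
}

#' Full quantification pipeline
#'
#' filter -> per-PSM ratios -> level summarization with IQR trim ->
#' MAD normalization -> back-conversion to the intensity scale.
#'
#' @inheritParams filter_psms
#' @param level summarization level.
#' @return list with `ratio` (normalized ratio matrix) and `abundance`.
#' @export
tmt_quantify <- function(psm, design, level = "gene", phospho_mode = FALSE) {
  flt <- filter_psms(psm, design, phospho_mode = phospho_mode)
  pr <- psm_ratios(flt, design)
  rm <- summarize_level(pr, level)
  rn <- mad_normalize(rm)
  ref <- reference_intensity(flt, design, level)
  list(ratio = rn, abundance = to_abundance(rn, ref))
}
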