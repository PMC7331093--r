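#' Synthetic proteogenomic cohort configuration
#'
#' Builds and validates the configuration for [generate_cohort()]. The
#' defaults describe a small but structurally complete tumor/NAT cohort:
#' TMT 10-plex design with one pooled reference channel per plex, a
#' gene -> peptide -> PSM hierarchy with lognormal MS1 intensities and
#' multiplicative reporter noise, tumor and NAT samples mixed from distinct
#' pure-tissue and pure-stroma profiles by per-sample purity, whole-arm
#' integer copy states driving LR/BAF tracks and dosage (cis) effects,
#' planted arm-level trans effects, planted cis methylation coupling,
#' four planted immune archetypes in cell-score space, and planted
#' kinase-substrate phosphosite fold changes.
#'
#' @param n_tumor,n_nat number of tumor and normal-adjacent samples.
#' @param n_genes number of genes.
#' @param peptides_per_gene,psms_per_peptide integer length-2 ranges.
#' @param plex_size channels per plex; one is reserved for the pooled
#'   reference.
#' @param purity_range tumor purity drawn Uniform(min, max); values must lie
#'   in (0, 1].
#' @param nat_purity_range purity of the NAT epithelial component.
#' @param effect_tables named list of planted effects; see Details.
#' @param noise_sd named list of per-layer noise standard deviations:
#'   `tissue` (latent pure-profile sd, log2), `mrna` (extra mRNA noise),
#'   `phospho`, `reporter` (log2 multiplicative reporter noise), `ms1`
#'   (lognormal sdlog), `lr`, `baf`, `cell_score`.
#' @param low_quality_rates named list of planted PSM failure rates:
#'   `unlabeled`, `low_purity`, `contaminant`, `missing_ref`.
#' @param dropout_rate probability that a gene is absent from an entire plex.
#' @param n_celltypes number of cell types in the cell-score matrix.
#' @param subtype_separation distance scale between planted immune
#'   archetype centroids, in within-group sd units.
#' @param seed integer RNG seed; fixes every emitted byte.
#'
#' @details `effect_tables` entries (all optional):
#' \describe{
#'   \item{tumor}{data.frame(gene, log2fc): pure-tumor vs pure-NAT shift.}
#'   \item{cis_cnv}{character vector of genes whose expression tracks copy
#'     dosage.}
#'   \item{cis_methy}{character vector of genes with negative methylation
#'     coupling.}
#'   \item{trans}{data.frame(arm, sign, n_genes): an arm event shifting a
#'     random trans gene set.}
#'   \item{kinase_sub}{data.frame(kinase, substrate_gene, site, log2fc):
#'     planted phosphosite increases in tumors.}
#' }
#' @return a validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_tumor = 30L, n_nat = 30L, n_genes = 200L,
                          peptides_per_gene = c(2L, 4L),
                          psms_per_peptide = c(1L, 3L),
                          plex_size = 10L,
                          purity_range = c(0.4, 0.9),
                          nat_purity_range = c(0.7, 0.95),
                          effect_tables = list(),
                          noise_sd = list(),
                          low_quality_rates = list(),
                          dropout_rate = 0.02,
                          n_celltypes = 20L,
                          subtype_separation = 3,
                          seed = 1L) {
  noise_defaults <- list(tissue = 0.25, mrna = 0.5, phospho = 0.3,
                         reporter = 0.1, ms1 = 1, lr = 0.1, baf = 0.03,
                         cell_score = 1)
  noise_sd <- utils::modifyList(noise_defaults, noise_sd)
  lq_defaults <- list(unlabeled = 0.02, low_purity = 0.03,
                      contaminant = 0.02, missing_ref = 0.02)
  low_quality_rates <- utils::modifyList(lq_defaults, low_quality_rates)
  cfg <- list(n_tumor = as.integer(n_tumor), n_nat = as.integer(n_nat),
              n_genes = as.integer(n_genes),
              peptides_per_gene = as.integer(peptides_per_gene),
              psms_per_peptide = as.integer(psms_per_peptide),
              plex_size = as.integer(plex_size),
              purity_range = as.numeric(purity_range),
              nat_purity_range = as.numeric(nat_purity_range),
              effect_tables = effect_tables, noise_sd = noise_sd,
              low_quality_rates = low_quality_rates,
              dropout_rate = dropout_rate,
              n_celltypes = as.integer(n_celltypes),
              subtype_separation = subtype_separation,
              seed = as.integer(seed))
  counts <- c(cfg$n_tumor, cfg$n_nat, cfg$n_genes, cfg$peptides_per_gene,
              cfg$psms_per_peptide, cfg$plex_size, cfg$n_celltypes)
  if (any(!is.finite(counts)) || any(counts <= 0L))
    stop("cohort_config: all counts must be positive", call. = FALSE)
  if (cfg$plex_size < 2L)
    stop("cohort_config: plex_size must leave room for a reference channel",
         call. = FALSE)
  for (r in list(cfg$purity_range, cfg$nat_purity_range)) {
    if (any(r <= 0) || any(r > 1) || r[1] > r[2])
      stop("cohort_config: purity ranges must lie in (0, 1]", call. = FALSE)
  }
  if (any(unlist(cfg$noise_sd) < 0))
    stop("cohort_config: noise_sd must be non-negative", call. = FALSE)
  class(cfg) <- "cohort_config"
  cfg
}

# Chromosome-arm model used throughout: six arms of 100 Mb on three
# chromosomes; plenty for arm-level calls without genome bookkeeping.
.arm_table <- function() {
  data.frame(
    chrom = rep(c("chr1", "chr2", "chr3"), each = 2L),
    arm = c("chr1p", "chr1q", "chr2p", "chr2q", "chr3p", "chr3q"),
    start = rep(c(0, 100e6), 3L),
    end = rep(c(100e6, 200e6), 3L),
    stringsAsFactors = FALSE)
}

#' Chromosome-arm definitions of the synthetic genome
#'
#' @return data.frame with columns chrom, arm, start, end (0-based half-open).
#' @export
synthetic_arms <- function() .arm_table()

.default_effects <- function(cfg, genes) {
  eff <- cfg$effect_tables
  n <- cfg$n_genes
  if (is.null(eff$tumor)) {
    n_up <- max(1L, round(n * 0.1)); n_dn <- max(1L, round(n * 0.1))
    eff$tumor <- data.frame(
      gene = genes[seq_len(n_up + n_dn)],
      log2fc = c(rep(1, n_up), rep(-1, n_dn)),
      stringsAsFactors = FALSE)
  }
  if (is.null(eff$cis_cnv)) eff$cis_cnv <- genes[seq_len(max(2L, n %/% 10))]
  if (is.null(eff$cis_methy))
    eff$cis_methy <- genes[seq(max(2L, n %/% 10) + 1L,
                               length.out = max(2L, n %/% 10))]
  if (is.null(eff$trans))
    eff$trans <- data.frame(arm = "chr1p", sign = -1,
                            n_genes = max(5L, n %/% 10),
                            stringsAsFactors = FALSE)
  if (is.null(eff$kinase_sub)) {
    ks_genes <- genes[seq_len(min(5L, n))]
    eff$kinase_sub <- data.frame(
      kinase = genes[seq(min(6L, n), length.out = length(ks_genes))],
      substrate_gene = ks_genes,
      site = paste0("S", seq_along(ks_genes) * 10L),
      log2fc = 2, stringsAsFactors = FALSE)
  }
  eff
}

#' Generate a complete synthetic cohort with recorded ground truth
#'
#' Deterministic for a fixed seed. Observed tumor abundance of gene j in
#' sample i is `pi_i * y_ij + (1 - pi_i) * z_ij` where y and z are draws
#' around the pure-tumor and pure-stroma profiles; the same mixture applies
#' to NAT samples with their own pure-tissue profile.
#'
#' @param config a [cohort_config()].
#' @return list of class `synthetic_cohort` with elements
#'   `psm` (PSM table), `design` (plex/channel/sample map with reference
#'   flags), `abundance` (list of log2 matrices: protein, mrna, phospho),
#'   `methylation` (beta matrix), `cnv` (list: lr, baf gene-level matrices),
#'   `cell_scores`, `clinical`, and `truth` (ground-truth list).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  cfg <- config
  genes <- sprintf("G%04d", seq_len(cfg$n_genes))
  tumor_ids <- sprintf("T%03d", seq_len(cfg$n_tumor))
  nat_ids <- sprintf("N%03d", seq_len(cfg$n_nat))
  samples <- c(tumor_ids, nat_ids)
  eff <- .default_effects(cfg, genes)

  arms <- .arm_table()
  gene_arm <- arms$arm[1L + (seq_len(cfg$n_genes) - 1L) %% nrow(arms)]
  names(gene_arm) <- genes

  # pure profiles (log2 scale, relative units)
  mu_stroma <- stats::rnorm(cfg$n_genes, 0, 1); names(mu_stroma) <- genes
  mu_nat <- stats::rnorm(cfg$n_genes, 0, 1); names(mu_nat) <- genes
  mu_tumor <- mu_nat
  idx <- match(eff$tumor$gene, genes)
  mu_tumor[idx] <- mu_tumor[idx] + eff$tumor$log2fc

  purity_t <- stats::runif(cfg$n_tumor, cfg$purity_range[1],
                           cfg$purity_range[2])
  purity_n <- stats::runif(cfg$n_nat, cfg$nat_purity_range[1],
                           cfg$nat_purity_range[2])
  purity <- c(purity_t, purity_n); names(purity) <- samples

  # whole-arm copy states per tumor sample; NATs are diploid
  event_arm <- eff$trans$arm[1]
  has_event <- stats::runif(cfg$n_tumor) < 0.5
  copy_states <- do.call(rbind, lapply(seq_len(cfg$n_tumor), function(i) {
    st <- data.frame(sample = tumor_ids[i], chrom = arms$chrom,
                     arm = arms$arm, start = arms$start, end = arms$end,
                     C = 2L, K = 1L, stringsAsFactors = FALSE)
    if (has_event[i]) {
      j <- match(event_arm, st$arm)
      if (eff$trans$sign[1] < 0) { st$C[j] <- 1L; st$K[j] <- 0L }
      else st$C[j] <- 3L
    }
    # one random additional gain to vary dosage
    j2 <- sample(setdiff(seq_len(nrow(st)), match(event_arm, st$arm)), 1L)
    if (stats::runif(1) < 0.3) st$C[j2] <- 3L
    st
  }))

  # per-gene copy number per tumor sample (from its arm state)
  cn <- matrix(2, cfg$n_genes, length(samples),
               dimnames = list(genes, samples))
  for (i in seq_len(cfg$n_tumor)) {
    st <- copy_states[copy_states$sample == tumor_ids[i], ]
    cn[, i] <- st$C[match(gene_arm, st$arm)]
  }

  sdt <- cfg$noise_sd$tissue
  draw <- function(mu, n) matrix(stats::rnorm(length(mu) * n, mu, sdt),
                                 length(mu), n)
  y_t <- draw(mu_tumor, cfg$n_tumor)
  z_t <- draw(mu_stroma, cfg$n_tumor)
  y_n <- draw(mu_nat, cfg$n_nat)
  z_n <- draw(mu_stroma, cfg$n_nat)

  # dosage (cis CNV) effect on the pure tumor component
  cis_idx <- match(eff$cis_cnv, genes)
  y_t[cis_idx, ] <- y_t[cis_idx, ] +
    0.5 * (cn[cis_idx, seq_len(cfg$n_tumor), drop = FALSE] - 2)

  # planted trans effect: arm event shifts a remote gene set in carriers
  trans_pool <- genes[gene_arm != event_arm]
  trans_genes <- trans_pool[seq_len(min(eff$trans$n_genes[1],
                                        length(trans_pool)))]
  tr_idx <- match(trans_genes, genes)
  y_t[tr_idx, has_event] <- y_t[tr_idx, has_event] +
    eff$trans$sign[1] * 0.8

  x_t <- sweep(y_t, 2L, purity_t, `*`) +
    sweep(z_t, 2L, 1 - purity_t, `*`)
  x_n <- sweep(y_n, 2L, purity_n, `*`) +
    sweep(z_n, 2L, 1 - purity_n, `*`)
  protein <- cbind(x_t, x_n)
  dimnames(protein) <- list(genes, samples)

  mrna <- protein + matrix(stats::rnorm(length(protein), 0,
                                        cfg$noise_sd$mrna),
                           nrow(protein), ncol(protein))
  dimnames(mrna) <- dimnames(protein)

  # methylation beta values; planted cis genes get negative coupling
  methy <- matrix(stats::rbeta(cfg$n_genes * length(samples), 2, 2),
                  cfg$n_genes, length(samples),
                  dimnames = list(genes, samples))
  me_idx <- match(eff$cis_methy, genes)
  pz <- protein[me_idx, , drop = FALSE]
  pz <- (pz - rowMeans(pz)) / pmax(apply(pz, 1L, stats::sd), 1e-8)
  methy[me_idx, ] <- stats::plogis(-1.5 * pz +
    matrix(stats::rnorm(length(pz), 0, 0.3), nrow(pz), ncol(pz)))
  # and expression of cis-methylation genes responds to their beta value
  protein[me_idx, ] <- protein[me_idx, ] - 1.0 * (methy[me_idx, ] - 0.5)
  mrna[me_idx, ] <- mrna[me_idx, ] - 1.0 * (methy[me_idx, ] - 0.5)

  # gene-level CNV tracks as seen by association analyses
  pur_mat <- matrix(rep(purity, each = cfg$n_genes), cfg$n_genes)
  cnv_lr <- log2((pur_mat * cn + 2 * (1 - pur_mat)) / 2) +
    matrix(stats::rnorm(length(cn), 0, cfg$noise_sd$lr), nrow(cn))
  k_mat <- ifelse(cn == 1L, 0L, 1L)
  cnv_baf <- (pur_mat * k_mat + (1 - pur_mat)) /
    (pur_mat * cn + 2 * (1 - pur_mat)) +
    matrix(stats::rnorm(length(cn), 0, cfg$noise_sd$baf), nrow(cn))
  dimnames(cnv_lr) <- dimnames(cnv_baf) <- dimnames(protein)

  # phosphosites: 1-2 per gene riding on protein abundance
  n_sites <- sample(1:2, cfg$n_genes, replace = TRUE)
  site_gene <- rep(genes, n_sites)
  site_pos <- unlist(lapply(n_sites, function(k) seq_len(k) * 17L))
  site_ids <- paste0(site_gene, ":S", site_pos)
  phospho <- protein[site_gene, , drop = FALSE] +
    matrix(stats::rnorm(length(site_gene) * length(samples), 0,
                        cfg$noise_sd$phospho),
           length(site_gene), length(samples))
  rownames(phospho) <- site_ids
  ks <- eff$kinase_sub
  ks$site_id <- paste0(ks$substrate_gene, ":", ks$site)
  ks_rows <- match(ks$site_id, site_ids)
  planted_sites <- !is.na(ks_rows)
  if (any(planted_sites)) {
    extra <- matrix(0, length(site_ids), length(samples))
    extra[ks_rows[planted_sites], seq_len(cfg$n_tumor)] <-
      rep(ks$log2fc[planted_sites], cfg$n_tumor)
    phospho <- phospho + extra
  }

  # immune archetypes in cell-score space (tumor samples only)
  ct <- sprintf("CT%02d", seq_len(cfg$n_celltypes))
  subtype <- sample(rep_len(1:4, cfg$n_tumor))
  centroids <- matrix(stats::rnorm(cfg$n_celltypes * 4L), cfg$n_celltypes) *
    cfg$subtype_separation
  cell_t <- centroids[, subtype, drop = FALSE] +
    matrix(stats::rnorm(cfg$n_celltypes * cfg$n_tumor, 0,
                        cfg$noise_sd$cell_score), cfg$n_celltypes)
  cell_n <- matrix(stats::rnorm(cfg$n_celltypes * cfg$n_nat, 0,
                                cfg$noise_sd$cell_score), cfg$n_celltypes)
  cell_scores <- cbind(cell_t, cell_n)
  dimnames(cell_scores) <- list(ct, samples)
  names(subtype) <- tumor_ids

  clinical <- data.frame(
    sample = samples,
    tissue = rep(c("tumor", "nat"), c(cfg$n_tumor, cfg$n_nat)),
    age = round(stats::rnorm(length(samples), 60, 10)),
    gender = sample(c("F", "M"), length(samples), replace = TRUE),
    ischemic_time = round(stats::rlnorm(length(samples), log(20), 0.4), 1),
    grade = c(sample(1:4, cfg$n_tumor, replace = TRUE),
              rep(NA_integer_, cfg$n_nat)),
    purity = purity,
    stringsAsFactors = FALSE)

  psm_parts <- .generate_psms(cfg, protein, genes, samples)

  truth <- list(mu_tumor = mu_tumor, mu_stroma = mu_stroma, mu_nat = mu_nat,
                purity = purity,
                planted_cis = data.frame(
                  gene = c(eff$cis_cnv, eff$cis_methy),
                  variation = rep(c("cnv_lr", "methy"),
                                  c(length(eff$cis_cnv),
                                    length(eff$cis_methy))),
                  sign = rep(c(1, -1),
                             c(length(eff$cis_cnv), length(eff$cis_methy))),
                  stringsAsFactors = FALSE),
                planted_trans = list(arm = event_arm,
                                     carriers = tumor_ids[has_event],
                                     genes = trans_genes,
                                     sign = eff$trans$sign[1]),
                planted_tumor_effects = eff$tumor,
                planted_kinase_sub = ks,
                planted_subtype = subtype,
                copy_states = copy_states,
                protein_expected = protein,
                gene_arm = gene_arm)

  out <- list(psm = psm_parts$psm, design = psm_parts$design,
              abundance = list(protein = protein, mrna = mrna,
                               phospho = phospho),
              methylation = methy,
              cnv = list(lr = cnv_lr, baf = cnv_baf),
              cell_scores = cell_scores, clinical = clinical, truth = truth)
  class(out) <- "synthetic_cohort"
  out
}

# Build the PSM table and plex design. Reporter intensities are the pooled
# 2^abundance scaled per peptide ion with multiplicative lognormal noise;
# the reference channel carries the cohort mean profile.
.generate_psms <- function(cfg, protein, genes, samples) {
  per_plex <- cfg$plex_size - 1L
  n_plex <- ceiling(length(samples) / per_plex)
  channels <- sprintf("ch%02d", seq_len(cfg$plex_size))
  design <- do.call(rbind, lapply(seq_len(n_plex), function(p) {
    idx <- seq((p - 1L) * per_plex + 1L, min(p * per_plex, length(samples)))
    data.frame(plex = sprintf("plex%02d", p),
               channel = c(channels[1L], channels[1L + seq_along(idx)]),
               sample = c("REF", samples[idx]),
               is_reference = c(TRUE, rep(FALSE, length(idx))),
               stringsAsFactors = FALSE)
  }))
  ref_profile <- rowMeans(protein)     # pooled reference: all samples
  gene_base <- stats::rnorm(cfg$n_genes, 20, 2)  # absolute log2 offset
  lq <- cfg$low_quality_rates
  rows <- vector("list", n_plex * cfg$n_genes)
  k <- 0L
  spec_counter <- 0L
  for (p in seq_len(n_plex)) {
    plex_id <- sprintf("plex%02d", p)
    dsub <- design[design$plex == plex_id, ]
    for (g in seq_len(cfg$n_genes)) {
      if (stats::runif(1) < cfg$dropout_rate) next
      n_pep <- sample(cfg$peptides_per_gene[1]:cfg$peptides_per_gene[2], 1L)
      pep_off <- stats::rnorm(n_pep, 0, 1)
      for (pep in seq_len(n_pep)) {
        pep_seq <- sprintf("%s_PEP%02d", genes[g], pep)
        ms1 <- stats::rlnorm(1, log(1e7) + pep_off[pep] * log(2),
                             cfg$noise_sd$ms1)
        n_psm <- sample(cfg$psms_per_peptide[1]:cfg$psms_per_peptide[2], 1L)
        ab <- numeric(nrow(dsub))
        ab[dsub$is_reference] <- ref_profile[g]
        ab[!dsub$is_reference] <-
          protein[g, dsub$sample[!dsub$is_reference]]
        for (s in seq_len(n_psm)) {
          spec_counter <- spec_counter + 1L
          base <- gene_base[g] + pep_off[pep]
          inten <- stats::setNames(rep(0, cfg$plex_size), channels)
          inten[dsub$channel] <-
            2^(base + ab + stats::rnorm(nrow(dsub), 0,
                                        cfg$noise_sd$reporter))
          low_purity <- stats::runif(1) < lq$low_purity
          prec_purity <- if (low_purity) stats::runif(1, 0, 0.499)
                         else stats::runif(1, 0.5, 1)
          if (stats::runif(1) < lq$missing_ref) inten[channels[1L]] <- 0
          k <- k + 1L
          rows[[k]] <- c(list(
            plex = plex_id,
            spectrum_id = sprintf("spec%07d", spec_counter),
            peptide = pep_seq, site = NA_character_,
            gene = genes[g], protein = paste0(genes[g], "_P1"),
            unique_razor = TRUE,
            contaminant = stats::runif(1) < lq$contaminant,
            labeled = stats::runif(1) >= lq$unlabeled,
            purity = prec_purity, ms1_intensity = ms1),
            as.list(inten))
        }
      }
    }
  }
  psm <- as.data.frame(data.table::rbindlist(rows[seq_len(k)]))
  rownames(psm) <- NULL
  list(psm = psm, design = design)
}

#' Generate binned LR/BAF tracks from copy states
#'
#' For a bin in state (C, K) at purity p the expected log coverage ratio is
#' `log2((p*C + 2*(1-p)) / 2)` and the expected B-allele frequency is
#' `(p*K + (1-p)) / (p*C + 2*(1-p))`; BAF is emitted mirrored at random
#' around 0.5 as phasing is unobserved. A GC covariate is attached per bin
#' with a configurable additive bias on LR.
#'
#' @param config a [cohort_config()] (supplies noise sds and seed).
#' @param truth ground-truth list with `purity` and `copy_states` as
#'   produced by [generate_cohort()]; `copy_states` may contain sub-arm
#'   segments.
#' @param bin_width bin size in bp (default 10 kb).
#' @param gc_slope additive LR bias per unit GC deviation from 0.5.
#' @param samples which samples to emit (default: all in copy_states).
#' @return named list of per-sample data.frames with columns
#'   chrom, start, end, gc, mappable, lr, baf.
#' @export
generate_segments <- function(config, truth, bin_width = 10e3,
                              gc_slope = 0, samples = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  if (is.null(truth$copy_states))
    stop("generate_segments: truth$copy_states not defined", call. = FALSE)
  set.seed(.sub_seed(config$seed, 77L))
  cs <- truth$copy_states
  if (is.null(samples)) samples <- unique(cs$sample)
  out <- lapply(samples, function(sm) {
    st <- cs[cs$sample == sm, , drop = FALSE]
    p <- truth$purity[[sm]]
    bins <- do.call(rbind, lapply(seq_len(nrow(st)), function(i) {
      starts <- seq(st$start[i], st$end[i] - 1, by = bin_width)
      n <- length(starts)
      tot <- p * st$C[i] + 2 * (1 - p)
      e_lr <- log2(tot / 2)
      e_baf <- (p * st$K[i] + (1 - p)) / tot
      gc <- pmin(0.85, pmax(0.15, stats::rnorm(n, 0.45, 0.08)))
      lr <- e_lr + gc_slope * (gc - 0.5) +
        stats::rnorm(n, 0, config$noise_sd$lr)
      baf <- e_baf + stats::rnorm(n, 0, config$noise_sd$baf)
      flip <- stats::runif(n) < 0.5
      baf[flip] <- 1 - baf[flip]
      baf <- pmin(1, pmax(0, baf))
      data.frame(chrom = st$chrom[i], start = starts,
                 end = starts + bin_width, gc = gc, mappable = TRUE,
                 lr = lr, baf = baf, stringsAsFactors = FALSE)
    }))
    rownames(bins) <- NULL
    bins
  })
  names(out) <- samples
  out
}

#' Write a synthetic cohort to TSV files
#'
#' PSM table, plex design, abundance matrices, methylation, CNV tracks,
#' cell scores, clinical table and ground-truth tables are written as
#' tab-separated text under `dir`.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fw <- function(x, f) data.table::fwrite(x, file.path(dir, f), sep = "\t")
  fw(cohort$psm, "psm.tsv")
  fw(cohort$design, "design.tsv")
  for (nm in names(cohort$abundance))
    write_matrix_tsv(cohort$abundance[[nm]],
                     file.path(dir, paste0(nm, "_abundance.tsv")))
  write_matrix_tsv(cohort$methylation, file.path(dir, "methylation.tsv"))
  write_matrix_tsv(cohort$cnv$lr, file.path(dir, "cnv_lr.tsv"))
  write_matrix_tsv(cohort$cnv$baf, file.path(dir, "cnv_baf.tsv"))
  write_matrix_tsv(cohort$cell_scores, file.path(dir, "cell_scores.tsv"))
  fw(cohort$clinical, "clinical.tsv")
  fw(cohort$truth$copy_states, "truth_copy_states.tsv")
  fw(data.frame(sample = names(cohort$truth$purity),
                purity = unname(cohort$truth$purity)), "truth_purity.tsv")
  invisible(dir)
}
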