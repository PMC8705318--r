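# Synthetic two-genotype x three-stage rhizosphere experiments.
#
# The generator emulates the study design this package targets: a wild-type
# and an ethylene-insensitive mutant tomato line sampled at three
# developmental stages, with shotgun metagenomes on six replicates per
# genotype x stage condition (36 samples) and root-exudate metabolomes on
# three replicates per condition (18 samples), on *different* plants, so the
# two assays are unpaired. Ground truth (per-sample gene relative abundances,
# planted effects, planted condition-mean correlations) is returned alongside
# the data so every downstream stage can be tested against it.
#
# Model: taxon log-abundances have a fixed baseline, condition-level shifts
# for planted genotype/stage effects, and log-normal replicate noise; reads
# are then drawn multinomially per sample with probability proportional to
# gene abundance x gene length, which makes gene counts overdispersed
# relative to a fixed-proportion multinomial. Metabolite intensities are
# log-normal around condition means. Correlation between a taxon and a
# metabolite is planted at the condition-mean level (the 6-cell genotype x
# stage grid): random pairing of unpaired replicates destroys replicate-level
# coupling, so only mean-level correlation is recoverable, and that is what
# the generator controls — exactly, via an empirical Gaussian-copula
# construction, for pairs that share no feature.

#' Configuration for a synthetic experiment
#'
#' Defaults reproduce the target study design: 2 genotypes x 3 stages,
#' 6 metagenome and 3 exudate replicates per condition, 200 taxa, 300
#' metabolite ions, 20 genotype-differential taxa (half enriched in the
#' mutant, half suppressed), 10 genotype-differential ions, and 5 planted
#' taxon-metabolite pairs with condition-mean correlation `rho`.
#'
#' @param genotypes,stages factor level labels; the second genotype is the
#'   mutant ("Nr") line, effects are expressed relative to the first (WT).
#' @param n_reps_metagenome,n_reps_exudate replicates per genotype x stage
#'   condition for each assay.
#' @param n_genes,n_taxa,n_kos,n_metabolites catalog and table sizes.
#' @param n_reads_per_sample reads drawn per metagenome sample.
#' @param multiread_fraction proportion of reads given 2-3 candidate genes.
#' @param n_diff_taxa,n_diff_metabolites number of features given a genotype
#'   effect (split evenly between directions).
#' @param n_stage_diff_taxa taxa given a developmental-stage effect.
#' @param effect_log2_taxa,effect_log2_metabolites,stage_log2 planted log2
#'   effect sizes.
#' @param n_corr_pairs planted correlated (taxon, metabolite) pairs, drawn
#'   from the differential features with effect directions consistent with
#'   the sign of `rho`.
#' @param rho target condition-mean Pearson correlation of planted pairs.
#' @param sigma_condition copula amplitude on the log scale: spread of the
#'   condition-mean profiles of correlated features beyond their planted
#'   genotype effect.
#' @param sigma_base_taxa spread of baseline taxon log-abundances.
#' @param sigma_rep_taxa,sigma_rep_metab replicate-level log-scale noise.
#' @param ko_annotated_fraction proportion of genes carrying a KEGG ortholog.
#' @param mean_log_intensity baseline metabolite log-intensity.
#' @param effects optional explicit effect table (columns `feature`,
#'   `factor`, `level`, `log2fc`, `applies_to`) overriding the planted
#'   defaults; use a zero-row data.frame for a null experiment.
#' @param correlations optional explicit correlation table (columns `taxon`,
#'   `metabolite`, `rho`) overriding the planted defaults.
#' @param seed integer seed; identical configurations with identical seeds
#'   generate identical experiments.
#' @return A list of class `design_config`.
#' @export
design_config <- function(genotypes = c("WT", "Nr"),
                          stages = c("seedling", "flowering", "fruiting"),
                          n_reps_metagenome = 6L,
                          n_reps_exudate = 3L,
                          n_genes = 1000L,
                          n_taxa = 200L,
                          n_kos = 150L,
                          n_metabolites = 300L,
                          n_reads_per_sample = 20000L,
                          multiread_fraction = 0.1,
                          n_diff_taxa = 20L,
                          n_diff_metabolites = 10L,
                          n_stage_diff_taxa = 20L,
                          effect_log2_taxa = 2,
                          effect_log2_metabolites = 2,
                          stage_log2 = 1,
                          n_corr_pairs = 5L,
                          rho = 0.9,
                          sigma_condition = 1,
                          sigma_base_taxa = 1,
                          sigma_rep_taxa = 0.3,
                          sigma_rep_metab = 0.1,
                          ko_annotated_fraction = 0.7,
                          mean_log_intensity = log(1e5),
                          effects = NULL,
                          correlations = NULL,
                          seed = 1L) {
  cfg <- list(genotypes = genotypes, stages = stages,
              n_reps_metagenome = as.integer(n_reps_metagenome),
              n_reps_exudate = as.integer(n_reps_exudate),
              n_genes = as.integer(n_genes), n_taxa = as.integer(n_taxa),
              n_kos = as.integer(n_kos),
              n_metabolites = as.integer(n_metabolites),
              n_reads_per_sample = as.integer(n_reads_per_sample),
              multiread_fraction = multiread_fraction,
              n_diff_taxa = as.integer(n_diff_taxa),
              n_diff_metabolites = as.integer(n_diff_metabolites),
              n_stage_diff_taxa = as.integer(n_stage_diff_taxa),
              effect_log2_taxa = effect_log2_taxa,
              effect_log2_metabolites = effect_log2_metabolites,
              stage_log2 = stage_log2,
              n_corr_pairs = as.integer(n_corr_pairs), rho = rho,
              sigma_condition = sigma_condition,
              sigma_base_taxa = sigma_base_taxa,
              sigma_rep_taxa = sigma_rep_taxa,
              sigma_rep_metab = sigma_rep_metab,
              ko_annotated_fraction = ko_annotated_fraction,
              mean_log_intensity = mean_log_intensity,
              effects = effects, correlations = correlations,
              seed = as.integer(seed))
  counts <- c("n_reps_metagenome", "n_reps_exudate", "n_genes", "n_taxa",
              "n_kos", "n_metabolites")
  for (f in counts)
    if (cfg[[f]] < 1L) stop(f, " must be >= 1", call. = FALSE)
  if (length(genotypes) < 2L) stop("need at least two genotypes", call. = FALSE)
  if (multiread_fraction < 0 || multiread_fraction > 1)
    stop("multiread_fraction must be in [0, 1]", call. = FALSE)
  if (abs(rho) > 1) stop("|rho| must be <= 1", call. = FALSE)
  if (cfg$n_genes < cfg$n_taxa)
    stop("n_genes must be >= n_taxa (every taxon needs a gene)", call. = FALSE)
  structure(cfg, class = "design_config")
}

# ---- read-level simulation -------------------------------------------------

#' Simulate one sample's read-to-gene mapping table
#'
#' Reads are drawn from the catalog with probability proportional to
#' `true_abundance * length_bp`. A fraction `multiread_fraction` of reads is
#' made multi-mapped: the true source gene is kept as first candidate and 1-2
#' decoy genes are added uniformly at random among the other genes (the
#' hardest case for abundance-proportional redistribution, since decoys carry
#' no signal).
#'
#' @param true_abundance named per-gene relative abundances summing to one.
#' @param catalog gene catalog, see [check_catalog()].
#' @param n_reads number of reads to draw.
#' @param multiread_fraction proportion of multi-mapped reads in [0, 1].
#' @param seed optional integer seed (uses the current RNG stream when NULL).
#' @return data.frame with columns `read_id` and `gene_ids` (comma-separated
#'   candidates, source gene first).
#' @export
generate_read_mappings <- function(true_abundance, catalog, n_reads,
                                   multiread_fraction = 0, seed = NULL) {
  check_catalog(catalog)
  if (nrow(catalog) == 0L) stop("catalog is empty", call. = FALSE)
  if (n_reads < 0) stop("n_reads must be >= 0", call. = FALSE)
  if (abs(sum(true_abundance) - 1) > 1e-8)
    stop("true_abundance must sum to 1", call. = FALSE)
  gen <- function() {
    G <- nrow(catalog)
    ids <- catalog$gene_id
    p <- true_abundance[ids]
    if (any(is.na(p))) stop("true_abundance must cover all catalog genes",
                            call. = FALSE)
    if (n_reads == 0L)
      return(data.frame(read_id = character(0), gene_ids = character(0),
                        stringsAsFactors = FALSE))
    prob <- p * catalog$length_bp
    src <- sample.int(G, n_reads, replace = TRUE, prob = prob)
    is_multi <- G >= 2L & stats::runif(n_reads) < multiread_fraction
    gene_ids <- ids[src]
    n_multi <- sum(is_multi)
    if (n_multi > 0) {
      prim <- src[is_multi]
      # one decoy always; a second (distinct) decoy for about half the reads
      two_decoys <- G >= 3L & stats::runif(n_multi) < 0.5
      off1 <- sample.int(G - 1L, n_multi, replace = TRUE)
      d1 <- (prim - 1L + off1) %% G + 1L           # uniform over genes != prim
      strs <- paste(ids[prim], ids[d1], sep = ",")
      if (any(two_decoys)) {
        n2 <- sum(two_decoys)
        off2r <- sample.int(G - 2L, n2, replace = TRUE)
        off2 <- off2r + (off2r >= off1[two_decoys])  # distinct from off1
        d2 <- (prim[two_decoys] - 1L + off2) %% G + 1L
        strs[two_decoys] <- paste(strs[two_decoys], ids[d2], sep = ",")
      }
      gene_ids[is_multi] <- strs
    }
    data.frame(read_id = sprintf("r%07d", seq_len(n_reads)),
               gene_ids = gene_ids, stringsAsFactors = FALSE)
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

# ---- copula construction ---------------------------------------------------

# Residualize v against the columns of X (plus intercept) and scale to
# empirical sd 1. Returns NULL when the residual is degenerate.
ortho_unit <- function(v, X) {
  fit <- stats::lm.fit(cbind(1, X), v)
  r <- fit$residuals
  s <- stats::sd(r)
  if (!is.finite(s) || s < 1e-10) return(NULL)
  r / s
}

# Exact empirical copula for one disjoint pair: given deterministic
# condition-profiles d_t, d_m (length n cells) and amplitude sigma, return
# components u (taxon) and z (metabolite) with empirical sd 1, orthogonal to
# {1, d_t, d_m}, such that cor(d_t + sigma*u, d_m + sigma*z) == rho exactly.
# The random components vary at the *stage* level only (constant across
# genotypes within a stage, `stage_idx` mapping cells to stages) so that
# planting a correlation never perturbs the within-stage genotype contrast
# that makes the pair's features differentially abundant.
plant_pair_profiles <- function(d_t, d_m, rho, sigma, stage_idx) {
  n <- length(d_t)
  n_stages <- max(stage_idx)
  stage_means <- cbind(tapply(d_t, stage_idx, mean),
                       tapply(d_m, stage_idx, mean))
  expand <- function(v3) {
    v <- v3[stage_idx]
    s <- stats::sd(v)
    if (!is.finite(s) || s < 1e-10) return(NULL)
    v / s
  }
  u <- e <- NULL
  for (try in 1:50) {
    u3 <- ortho_unit(stats::rnorm(n_stages), stage_means)
    if (!is.null(u3)) u <- expand(u3)
    if (!is.null(u)) break
  }
  for (try in 1:50) {
    e3 <- ortho_unit(stats::rnorm(n_stages),
                     cbind(stage_means, tapply(u, stage_idx, mean)))
    if (!is.null(e3)) e <- expand(e3)
    if (!is.null(e)) break
  }
  if (is.null(u) || is.null(e))
    stop("condition grid too small for exact correlation planting",
         call. = FALSE)
  var_t <- stats::var(d_t) + sigma^2
  var_m <- stats::var(d_m) + sigma^2
  rho_z <- (rho * sqrt(var_t * var_m) - stats::cov(d_t, d_m)) / sigma^2
  if (!is.finite(rho_z) || abs(rho_z) > 1)
    stop("infeasible correlation target rho = ", rho,
         " given the planted effects of this pair; adjust sigma_condition ",
         "or align effect directions with the sign of rho", call. = FALSE)
  z <- rho_z * u + sqrt(1 - rho_z^2) * e
  list(u = u, z = z, rho_z = rho_z)
}

# Approximate joint draw used when correlation pairs share features: latent
# standard-normal stage-level profiles with target cross-correlation via
# Cholesky (distributional, not empirically exact).
plant_joint_profiles <- function(pairs, n_cells) {
  vars <- c(paste0("t:", unique(pairs$taxon)),
            paste0("m:", unique(pairs$metabolite)))
  R <- diag(length(vars))
  dimnames(R) <- list(vars, vars)
  for (i in seq_len(nrow(pairs))) {
    a <- paste0("t:", pairs$taxon[i]); b <- paste0("m:", pairs$metabolite[i])
    R[a, b] <- R[b, a] <- pairs$rho[i]
  }
  L <- tryCatch(chol(R), error = function(e) NULL)
  if (is.null(L)) {
    ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
    stop("correlation specification is not positive semi-definite ",
         "(min eigenvalue ", signif(min(ev), 3), "); offending pairs: ",
         paste(paste0("(", pairs$taxon, ", ", pairs$metabolite, ")"),
               collapse = " "), call. = FALSE)
  }
  Z <- matrix(stats::rnorm(n_cells * length(vars)), n_cells) %*% L
  colnames(Z) <- vars
  Z
}

plant_joint_profiles_stage <- function(pairs, stage_idx) {
  Z3 <- plant_joint_profiles(pairs, max(stage_idx))
  Z <- Z3[stage_idx, , drop = FALSE]
  rownames(Z) <- NULL
  Z
}

# ---- experiment generation -------------------------------------------------

default_effects <- function(cfg, taxa_ids, metab_ids, base_mu) {
  eff <- list()
  ln_ok <- base_mu > stats::quantile(base_mu, 0.25)  # keep planted taxa above
  eligible <- taxa_ids[ln_ok]                        # the detection-filter tail
  if (cfg$n_diff_taxa > 0) {
    picked <- sample(eligible, cfg$n_diff_taxa)
    n_up <- ceiling(cfg$n_diff_taxa / 2)
    eff$geno_taxa <- data.frame(
      feature = picked,
      factor = "genotype", level = cfg$genotypes[2],
      log2fc = rep(c(cfg$effect_log2_taxa, -cfg$effect_log2_taxa),
                   c(n_up, cfg$n_diff_taxa - n_up)),
      applies_to = "taxon", stringsAsFactors = FALSE)
  }
  if (cfg$n_stage_diff_taxa > 0 && length(cfg$stages) > 1) {
    pool <- setdiff(taxa_ids, eff$geno_taxa$feature)
    picked <- sample(pool, min(cfg$n_stage_diff_taxa, length(pool)))
    late <- cfg$stages[-1]
    eff$stage_taxa <- data.frame(
      feature = rep(picked, each = length(late)),
      factor = "stage", level = rep(late, length(picked)),
      log2fc = cfg$stage_log2, applies_to = "taxon",
      stringsAsFactors = FALSE)
  }
  if (cfg$n_diff_metabolites > 0) {
    picked <- sample(metab_ids, cfg$n_diff_metabolites)
    n_up <- ceiling(cfg$n_diff_metabolites / 2)
    eff$metab <- data.frame(
      feature = picked,
      factor = "genotype", level = cfg$genotypes[2],
      log2fc = rep(c(cfg$effect_log2_metabolites, -cfg$effect_log2_metabolites),
                   c(n_up, cfg$n_diff_metabolites - n_up)),
      applies_to = "metabolite", stringsAsFactors = FALSE)
  }
  do.call(rbind, unname(eff))
}

default_correlations <- function(cfg, effects) {
  if (cfg$n_corr_pairs == 0)
    return(data.frame(taxon = character(0), metabolite = character(0),
                      rho = numeric(0)))
  gt <- effects[effects$applies_to == "taxon" & effects$factor == "genotype", ]
  gm <- effects[effects$applies_to == "metabolite", ]
  # pair taxa and ions whose effect directions are consistent with sign(rho)
  want_same <- sign(cfg$rho) >= 0
  up_t <- gt$feature[gt$log2fc > 0]; dn_t <- gt$feature[gt$log2fc < 0]
  up_m <- gm$feature[gm$log2fc > 0]; dn_m <- gm$feature[gm$log2fc < 0]
  taxa <- character(0); metab <- character(0)
  iu <- id <- 0L
  for (k in seq_len(cfg$n_corr_pairs)) {
    use_up <- k %% 2L == 1L
    if (use_up && iu < min(length(up_t), length(if (want_same) up_m else dn_m))) {
      iu <- iu + 1L
      taxa <- c(taxa, up_t[iu])
      metab <- c(metab, if (want_same) up_m[iu] else dn_m[iu])
    } else if (id < min(length(dn_t), length(if (want_same) dn_m else up_m))) {
      id <- id + 1L
      taxa <- c(taxa, dn_t[id])
      metab <- c(metab, if (want_same) dn_m[id] else up_m[id])
    }
  }
  if (length(taxa) < cfg$n_corr_pairs)
    stop("not enough differential features to plant ", cfg$n_corr_pairs,
         " correlated pairs", call. = FALSE)
  data.frame(taxon = taxa, metabolite = metab, rho = cfg$rho,
             stringsAsFactors = FALSE)
}

#' Generate a complete synthetic experiment
#'
#' Produces read-to-gene mappings for every metagenome sample, a metabolite
#' intensity table for every exudate sample, sample metadata, the gene
#' catalog, and the ground truth used to plant effects and correlations.
#'
#' @param config a [design_config()].
#' @return A list of class `rhizo_experiment` with elements `mappings`
#'   (named list of per-sample mapping data.frames), `metabolites`
#'   (samples x ions intensity matrix), `metadata` (data.frame with columns
#'   sample_id, assay, genotype, stage, replicate), `catalog`, and `truth`
#'   (list: `gene_ra` and `taxa_ra` per-sample true relative abundances,
#'   `effects`, `correlations` with the realized condition-mean Pearson
#'   correlation per pair, `cond_mean_log_taxa`, `cond_mean_log_metab`,
#'   `cells`).
#' @export
generate_experiment <- function(config = design_config()) {
  stopifnot(inherits(config, "design_config"))
  withr::with_seed(config$seed, generate_experiment_impl(config))
}

generate_experiment_impl <- function(cfg) {
  taxa_ids <- sprintf("taxon_%03d", seq_len(cfg$n_taxa))
  metab_ids <- sprintf("ion_%04d", seq_len(cfg$n_metabolites))
  ko_ids <- sprintf("K%05d", seq_len(cfg$n_kos))
  gene_ids <- sprintf("gene_%05d", seq_len(cfg$n_genes))

  # catalog: every taxon gets at least one gene, remainder assigned uniformly
  gene_taxon <- c(taxa_ids,
                  sample(taxa_ids, cfg$n_genes - cfg$n_taxa, replace = TRUE))
  gene_taxon <- sample(gene_taxon)  # shuffle so taxon blocks are not ordered
  has_ko <- stats::runif(cfg$n_genes) < cfg$ko_annotated_fraction
  catalog <- data.frame(
    gene_id = gene_ids,
    length_bp = sample(300:3000, cfg$n_genes, replace = TRUE),
    taxon = gene_taxon,
    ko = ifelse(has_ko, sample(ko_ids, cfg$n_genes, replace = TRUE),
                NA_character_),
    stringsAsFactors = FALSE)

  cells <- expand.grid(genotype = cfg$genotypes, stage = cfg$stages,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  n_cells <- nrow(cells)

  base_mu <- stats::setNames(stats::rnorm(cfg$n_taxa, 0, cfg$sigma_base_taxa),
                             taxa_ids)
  base_met <- stats::setNames(stats::rnorm(cfg$n_metabolites,
                                           cfg$mean_log_intensity, 1),
                              metab_ids)

  effects <- cfg$effects
  if (is.null(effects))
    effects <- default_effects(cfg, taxa_ids, metab_ids, base_mu)
  if (is.null(effects)) effects <- data.frame(
    feature = character(0), factor = character(0), level = character(0),
    log2fc = numeric(0), applies_to = character(0))
  if (nrow(effects)) {
    known <- c(taxa_ids, metab_ids, ko_ids)
    bad <- setdiff(effects$feature, known)
    if (length(bad)) stop("effect feature(s) not in catalog: ",
                          paste(bad, collapse = ", "), call. = FALSE)
    if (any(!is.finite(effects$log2fc)))
      stop("effect sizes must be finite", call. = FALSE)
  }

  correlations <- cfg$correlations
  if (is.null(correlations) && nrow(effects))
    correlations <- default_correlations(cfg, effects)
  if (is.null(correlations))
    correlations <- data.frame(taxon = character(0), metabolite = character(0),
                               rho = numeric(0))
  if (nrow(correlations) && any(abs(correlations$rho) > 1))
    stop("|rho| must be <= 1", call. = FALSE)

  # deterministic condition-mean profiles (log scale) from planted effects
  eff_profile <- function(ids, kind) {
    W <- matrix(0, n_cells, length(ids), dimnames = list(NULL, ids))
    sub <- effects[effects$applies_to == kind, , drop = FALSE]
    for (i in seq_len(nrow(sub))) {
      rows <- if (sub$factor[i] == "genotype") cells$genotype == sub$level[i]
              else cells$stage == sub$level[i]
      W[rows, sub$feature[i]] <- W[rows, sub$feature[i]] + log(2) * sub$log2fc[i]
    }
    W
  }
  Wt <- sweep(eff_profile(taxa_ids, "taxon"), 2, base_mu, "+")
  Wm <- sweep(eff_profile(metab_ids, "metabolite"), 2, base_met, "+")

  # plant condition-mean correlations
  realized <- rep(NA_real_, nrow(correlations))
  if (nrow(correlations)) {
    shared <- anyDuplicated(correlations$taxon) ||
      anyDuplicated(correlations$metabolite)
    if (!shared) {
      stage_idx <- match(cells$stage, cfg$stages)
      for (i in seq_len(nrow(correlations))) {
        t_id <- correlations$taxon[i]; m_id <- correlations$metabolite[i]
        pp <- plant_pair_profiles(Wt[, t_id], Wm[, m_id],
                                  correlations$rho[i], cfg$sigma_condition,
                                  stage_idx)
        Wt[, t_id] <- Wt[, t_id] + cfg$sigma_condition * pp$u
        Wm[, m_id] <- Wm[, m_id] + cfg$sigma_condition * pp$z
        realized[i] <- stats::cor(Wt[, t_id], Wm[, m_id])
      }
    } else {
      Z <- plant_joint_profiles_stage(correlations, match(cells$stage, cfg$stages))
      for (v in colnames(Z)) {
        id <- sub("^[tm]:", "", v)
        if (startsWith(v, "t:")) Wt[, id] <- Wt[, id] + cfg$sigma_condition * Z[, v]
        else Wm[, id] <- Wm[, id] + cfg$sigma_condition * Z[, v]
      }
      realized <- vapply(seq_len(nrow(correlations)), function(i)
        stats::cor(Wt[, correlations$taxon[i]],
                   Wm[, correlations$metabolite[i]]), numeric(1))
    }
  }
  correlations$realized_cond_cor <- realized

  # fixed within-taxon gene weights
  gene_w <- stats::rlnorm(cfg$n_genes, 0, 0.5)
  tot_w <- tapply(gene_w, gene_taxon, sum)
  gene_w_norm <- gene_w / as.numeric(tot_w[gene_taxon])

  sample_cells <- function(n_reps) {
    data.frame(cell = rep(seq_len(n_cells), each = n_reps),
               replicate = rep(seq_len(n_reps), n_cells))
  }

  # metagenome samples
  mg <- sample_cells(cfg$n_reps_metagenome)
  mg$sample_id <- sprintf("MG_%s_%s_%d", cells$genotype[mg$cell],
                          cells$stage[mg$cell], mg$replicate)
  taxa_ra <- matrix(0, nrow(mg), cfg$n_taxa,
                    dimnames = list(mg$sample_id, taxa_ids))
  gene_ra <- matrix(0, nrow(mg), cfg$n_genes,
                    dimnames = list(mg$sample_id, gene_ids))
  mappings <- vector("list", nrow(mg))
  names(mappings) <- mg$sample_id
  for (s in seq_len(nrow(mg))) {
    lw <- Wt[mg$cell[s], ] + stats::rnorm(cfg$n_taxa, 0, cfg$sigma_rep_taxa)
    ra <- exp(lw - max(lw)); ra <- ra / sum(ra)
    taxa_ra[s, ] <- ra
    g_ra <- as.numeric(ra[gene_taxon]) * gene_w_norm
    gene_ra[s, ] <- g_ra
    mappings[[s]] <- generate_read_mappings(
      stats::setNames(g_ra, gene_ids), catalog,
      cfg$n_reads_per_sample, cfg$multiread_fraction)
  }

  # exudate samples
  ex <- sample_cells(cfg$n_reps_exudate)
  ex$sample_id <- sprintf("EX_%s_%s_%d", cells$genotype[ex$cell],
                          cells$stage[ex$cell], ex$replicate)
  metab <- matrix(0, nrow(ex), cfg$n_metabolites,
                  dimnames = list(ex$sample_id, metab_ids))
  for (s in seq_len(nrow(ex)))
    metab[s, ] <- exp(Wm[ex$cell[s], ] +
                        stats::rnorm(cfg$n_metabolites, 0, cfg$sigma_rep_metab))

  metadata <- rbind(
    data.frame(sample_id = mg$sample_id, assay = "metagenome",
               genotype = cells$genotype[mg$cell], stage = cells$stage[mg$cell],
               replicate = mg$replicate, stringsAsFactors = FALSE),
    data.frame(sample_id = ex$sample_id, assay = "exudate",
               genotype = cells$genotype[ex$cell], stage = cells$stage[ex$cell],
               replicate = ex$replicate, stringsAsFactors = FALSE))

  truth <- list(gene_ra = gene_ra, taxa_ra = taxa_ra, effects = effects,
                correlations = correlations, cond_mean_log_taxa = Wt,
                cond_mean_log_metab = Wm, cells = cells)
  structure(list(mappings = mappings, metabolites = metab,
                 metadata = metadata, catalog = catalog, truth = truth,
                 config = cfg),
            class = "rhizo_experiment")
}

#' @export
print.rhizo_experiment <- function(x, ...) {
  cat("Synthetic rhizosphere experiment\n")
  cat("  metagenome samples: ", length(x$mappings), "\n", sep = "")
  cat("  exudate samples:    ", nrow(x$metabolites), "\n", sep = "")
  cat("  genes/taxa/ions:    ", x$config$n_genes, "/", x$config$n_taxa, "/",
      x$config$n_metabolites, "\n", sep = "")
  cat("  planted effects:    ", nrow(x$truth$effects), "\n", sep = "")
  cat("  planted pairs:      ", nrow(x$truth$correlations), "\n", sep = "")
  invisible(x)
}
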