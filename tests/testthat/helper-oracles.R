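# Independent oracles and fixture builders. Everything here is written as
# plain, loop-based reference code, deliberately sharing no logic with the
# package implementation it checks.

# --- brute-force evaluator of the gene-abundance equations -----------------
# Ab(U)_g = sum over unique reads of g of 1/l_g
# Co_g    = Ab(U)_g / sum over the read's candidates of Ab(U)  (0/0 -> 1/N)
# Ab(M)_g = sum over multireads containing g of Co_g / l_g
# Ab(S)   = Ab(U) + Ab(M)
brute_force_abundance <- function(mapping, catalog) {
  len <- setNames(catalog$length_bp, catalog$gene_id)
  abU <- setNames(numeric(nrow(catalog)), catalog$gene_id)
  cand <- lapply(strsplit(mapping$gene_ids, ",", fixed = TRUE), unique)
  for (cs in cand)
    if (length(cs) == 1L) abU[cs] <- abU[cs] + 1 / len[cs]
  abM <- setNames(numeric(nrow(catalog)), catalog$gene_id)
  for (cs in cand) {
    if (length(cs) < 2L) next
    denom <- sum(abU[cs])
    for (g in cs) {
      co <- if (denom > 0) abU[g] / denom else 1 / length(cs)
      abM[g] <- abM[g] + co / len[g]
    }
  }
  data.frame(gene_id = catalog$gene_id, abU = as.numeric(abU),
             abM = as.numeric(abM), abS = as.numeric(abU + abM),
             stringsAsFactors = FALSE)
}

# random small quantification instance
random_instance <- function(n_genes_max = 10, n_reads_max = 200) {
  n_genes <- sample(2:n_genes_max, 1)
  ids <- paste0("g", seq_len(n_genes))
  catalog <- data.frame(gene_id = ids,
                        length_bp = sample(1:50, n_genes, replace = TRUE),
                        taxon = sample(paste0("t", 1:3), n_genes, replace = TRUE),
                        ko = NA_character_, stringsAsFactors = FALSE)
  n_reads <- sample(0:n_reads_max, 1)
  gene_ids <- vapply(seq_len(n_reads), function(i) {
    k <- sample(1:min(3, n_genes), 1)
    paste(sample(ids, k), collapse = ",")
  }, character(1))
  mapping <- data.frame(read_id = sprintf("r%d", seq_len(n_reads)),
                        gene_ids = gene_ids, stringsAsFactors = FALSE)
  list(catalog = catalog, mapping = mapping)
}

# --- Benjamini-Hochberg by the definitional min-step-up ---------------------
bh_brute <- function(p) {
  m <- length(p)
  if (m == 0L) return(numeric(0))
  o <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    r <- which(o == i)  # rank of p[i]
    vals <- vapply(r:m, function(k) m * p[o[k]] / k, numeric(1))
    adj[i] <- min(1, min(vals))
  }
  adj
}

# --- Anderson SS partitioning of a distance matrix, by loops ----------------
manual_permanova_F <- function(d, grouping) {
  d <- as.matrix(d)
  n <- nrow(d)
  grouping <- as.character(grouping)
  ss_t <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) ss_t <- ss_t + d[i, j]^2
  ss_t <- ss_t / n
  ss_w <- 0
  for (g in unique(grouping)) {
    idx <- which(grouping == g)
    m <- length(idx)
    s <- 0
    if (m > 1)
      for (i in 1:(m - 1)) for (j in (i + 1):m)
        s <- s + d[idx[i], idx[j]]^2
    ss_w <- ss_w + s / m
  }
  ss_a <- ss_t - ss_w
  a <- length(unique(grouping))
  f <- (ss_a / (a - 1)) / (ss_w / (n - a))
  list(ss_total = ss_t, ss_within = ss_w, ss_between = ss_a,
       pseudo_f = f, r2 = ss_a / ss_t)
}

# exact permutation p for two equal groups by full enumeration of label
# assignments (choose(n, n/2) of them)
exact_permutation_p <- function(d, grouping) {
  n <- length(grouping)
  lev <- unique(grouping)
  f_obs <- manual_permanova_F(d, grouping)$pseudo_f
  combs <- combn(n, sum(grouping == lev[1]))
  f_all <- apply(combs, 2, function(idx) {
    g <- rep(lev[2], n)
    g[idx] <- lev[1]
    manual_permanova_F(d, g)$pseudo_f
  })
  mean(f_all >= f_obs - 1e-12)
}

# --- small two-assay fixture for the pairing correlation --------------------
# `cond_taxon`, `cond_metab`: per-condition mean value of the single planted
# feature pair; `noise`: within-condition sd; reps per assay configurable.
pairing_fixture <- function(cond_taxon, cond_metab, n_reps_taxa = 3,
                            n_reps_metab = 3, noise = 0, n_extra_taxa = 1,
                            seed = 1) {
  stopifnot(length(cond_taxon) == length(cond_metab))
  n_cond <- length(cond_taxon)
  stages <- paste0("st", seq_len(ceiling(n_cond / 2)))
  cells <- expand.grid(genotype = c("WT", "Nr"), stage = stages,
                       stringsAsFactors = FALSE)[seq_len(n_cond), ]
  withr::with_seed(seed, {
    mk <- function(prefix, n_reps, cond_vals, n_feat, feat_prefix) {
      rows <- do.call(rbind, lapply(seq_len(n_cond), function(c_) {
        vals <- sapply(seq_len(n_feat), function(f)
          cond_vals[c_] * f + rnorm(n_reps, 0, noise))
        m <- matrix(vals, n_reps, n_feat)
        rownames(m) <- sprintf("%s_%s_%s_%d", prefix, cells$genotype[c_],
                               cells$stage[c_], seq_len(n_reps))
        m
      }))
      colnames(rows) <- paste0(feat_prefix, seq_len(n_feat))
      rows
    }
    taxa <- mk("MG", n_reps_taxa, cond_taxon, n_extra_taxa, "tax")
    metab <- mk("EX", n_reps_metab, cond_metab, 1, "ion")
  })
  meta <- function(tab, assay) {
    parts <- strsplit(rownames(tab), "_", fixed = TRUE)
    data.frame(sample_id = rownames(tab), assay = assay,
               genotype = sapply(parts, `[`, 2),
               stage = sapply(parts, `[`, 3),
               replicate = as.integer(sapply(parts, `[`, 4)),
               stringsAsFactors = FALSE)
  }
  list(taxa = taxa, metab = metab,
       metadata = rbind(meta(taxa, "metagenome"), meta(metab, "exudate")))
}

# tiny balanced community table with metadata for the differential tests
two_group_table <- function(wt, nr, stage = "seedling", prefix = "S") {
  stopifnot(ncol(wt) == ncol(nr))
  tab <- rbind(wt, nr)
  rownames(tab) <- c(paste0(prefix, "_WT_", seq_len(nrow(wt))),
                     paste0(prefix, "_Nr_", seq_len(nrow(nr))))
  colnames(tab) <- paste0("f", seq_len(ncol(tab)))
  md <- data.frame(sample_id = rownames(tab), assay = "metagenome",
                   genotype = rep(c("WT", "Nr"), c(nrow(wt), nrow(nr))),
                   stage = stage,
                   replicate = c(seq_len(nrow(wt)), seq_len(nrow(nr))),
                   stringsAsFactors = FALSE)
  list(table = tab, metadata = md)
}
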