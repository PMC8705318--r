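# End-to-end orchestration: simulate (or load) an experiment, quantify gene
# and taxon abundances, run community statistics, differential analyses per
# stage, and the random-pairing correlation between the taxa that are
# differential at every stage (with a consistent direction) and the ions
# that are differential at any stage. One global seed fans out to per-stage
# seeds through a fixed counter scheme so every stage is independently
# reproducible.

#' Run the full analysis pipeline
#'
#' @param config a [design_config()] describing the experiment to simulate,
#'   or an already generated `rhizo_experiment`.
#' @param out_dir optional directory; when given, all result tables are
#'   written there as TSV/JSON and a provenance manifest is included.
#' @param n_permutations permutations for the PERMANOVA tests (default 999).
#' @param n_pairings Monte-Carlo pairings for the correlation stage
#'   (default 10000).
#' @param min_ra relative-abundance filter for the taxon tests
#'   (default 1e-4).
#' @param alpha significance level (default 0.05).
#' @param threshold display threshold on |mean r| (default 0.5).
#' @param seed global seed governing simulation, permutations and pairings.
#' @return List of class `rhizo_run` with elements `experiment`,
#'   `taxa_ra`, `ko_table`, `alpha` (Shannon + richness), `pca`,
#'   `permanova_by_stage`, `permanova_twoway`, `diff_metabolites` (per
#'   stage), `diff_taxa` (per stage), `diff_taxa_consistent`,
#'   `unique_taxa`, `correlations`, `heatmap`.
#' @export
run_all <- function(config = design_config(), out_dir = NULL,
                    n_permutations = 999L, n_pairings = 10000L,
                    min_ra = 1e-4, alpha = 0.05, threshold = 0.5,
                    seed = NULL) {
  if (inherits(config, "design_config")) {
    if (!is.null(seed)) config$seed <- as.integer(seed)
    experiment <- generate_experiment(config)
  } else if (inherits(config, "rhizo_experiment")) {
    experiment <- config
    if (is.null(seed)) seed <- experiment$config$seed
  } else {
    stop("config must be a design_config or a rhizo_experiment", call. = FALSE)
  }
  if (is.null(seed)) seed <- config$seed
  md <- experiment$metadata
  stages <- unique(md$stage)
  genotypes <- unique(md$genotype)

  report <- validate_tables(list(metabolites = experiment$metabolites), md)
  errs <- report[report$level == "error", , drop = FALSE]
  if (nrow(errs))
    stop("input validation failed at stage 'validate': ",
         errs$message[1], call. = FALSE)

  # --- quantification ---
  gene_tab <- gene_abundance_table(experiment$mappings, experiment$catalog)
  taxa_tab <- aggregate_by_annotation(gene_tab, experiment$catalog, "taxon")
  ko_tab <- suppressMessages(
    aggregate_by_annotation(gene_tab, experiment$catalog, "ko"))
  taxa_ra <- relative_abundance(taxa_tab)
  md_mg <- md[md$assay == "metagenome", ]
  md_ex <- md[md$assay == "exudate", ]

  # --- diversity / ordination ---
  alpha_tab <- data.frame(sample_id = rownames(taxa_ra),
                          shannon = shannon(taxa_ra),
                          richness = richness(taxa_ra),
                          row.names = NULL, stringsAsFactors = FALSE)
  pca <- pca_ordination(hellinger(taxa_ra), n_components = 2L)
  dm <- bray_curtis(taxa_ra)
  md_mg_o <- md_mg[match(rownames(taxa_ra), md_mg$sample_id), ]
  perm_stage <- lapply(seq_along(stages), function(i) {
    st <- stages[i]
    keep <- md_mg_o$stage == st
    permanova(stats::as.dist(as.matrix(dm)[keep, keep]),
              md_mg_o$genotype[keep], n_permutations,
              seed = derive_seed(seed, i))
  })
  names(perm_stage) <- stages
  perm_two <- permanova_twoway(dm, md_mg_o$genotype, md_mg_o$stage,
                               n_permutations, seed = derive_seed(seed, 10L))

  # --- differential analyses per stage ---
  diff_met <- lapply(stages, function(st)
    differential_metabolites(experiment$metabolites, md_ex, stage = st,
                             alpha = alpha))
  names(diff_met) <- stages
  diff_taxa <- lapply(stages, function(st)
    differential_features(taxa_ra, md_mg, stage = st, min_ra = min_ra,
                          alpha = alpha))
  names(diff_taxa) <- stages
  uniq <- unique_features(taxa_ra, md_mg)

  # taxa significant at every stage with a consistent direction (the
  # mutant-suppressed / mutant-enriched sets carried into the correlation)
  sig_sets <- lapply(diff_taxa, function(d)
    stats::setNames(d$direction[d$significant], d$feature[d$significant]))
  common <- Reduce(intersect, lapply(sig_sets, names))
  consistent <- common[vapply(common, function(f) {
    dirs <- vapply(sig_sets, `[[`, character(1), f)
    length(unique(dirs)) == 1L
  }, logical(1))]
  directions <- vapply(consistent, function(f) sig_sets[[1]][[f]], character(1))

  # ions significant at any stage
  sig_ions <- sort(unique(unlist(lapply(diff_met, function(d)
    d$feature[d$direction != "unrelated"]))))

  correlations <- NULL
  heatmap <- NULL
  if (length(consistent) && length(sig_ions)) {
    correlations <- random_pairing_correlation(
      taxa_ra, experiment$metabolites, md,
      taxa_ids = consistent, metab_ids = sig_ions,
      n_pairings = n_pairings, threshold = threshold,
      directions = directions, seed = derive_seed(seed, 20L))
    heatmap <- correlation_heatmap_table(correlations, directions)
  }

  result <- structure(list(
    experiment = experiment, gene_table = gene_tab, taxa_ra = taxa_ra,
    ko_table = ko_tab, alpha = alpha_tab, pca = pca,
    permanova_by_stage = perm_stage, permanova_twoway = perm_two,
    diff_metabolites = diff_met, diff_taxa = diff_taxa,
    diff_taxa_consistent = directions, unique_taxa = uniq,
    correlations = correlations, heatmap = heatmap,
    seed = seed), class = "rhizo_run")

  if (!is.null(out_dir)) write_run(result, out_dir,
                                   n_permutations = n_permutations,
                                   n_pairings = n_pairings)
  result
}

write_run <- function(result, out_dir, n_permutations, n_pairings) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_feature_table(result$gene_table, file.path(out_dir, "gene_abundance.tsv"))
  write_feature_table(result$taxa_ra, file.path(out_dir, "taxa.tsv"))
  write_feature_table(result$ko_table, file.path(out_dir, "ko.tsv"))
  write_tsv(result$alpha, file.path(out_dir, "alpha.tsv"))
  write_feature_table(result$pca$scores, file.path(out_dir, "pca_scores.tsv"))
  perm <- c(lapply(result$permanova_by_stage, as.data.frame),
            list(twoway = as.data.frame(result$permanova_twoway)))
  jsonlite::write_json(perm, file.path(out_dir, "permanova.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  for (st in names(result$diff_metabolites))
    write_tsv(result$diff_metabolites[[st]],
              file.path(out_dir, paste0("diff_metabolites_", st, ".tsv")))
  for (st in names(result$diff_taxa))
    write_tsv(result$diff_taxa[[st]],
              file.path(out_dir, paste0("diff_taxa_", st, ".tsv")))
  if (!is.null(result$correlations)) {
    write_tsv(result$correlations, file.path(out_dir, "correlations.tsv"))
    hm <- data.frame(taxon = rownames(result$heatmap), result$heatmap,
                     check.names = FALSE, stringsAsFactors = FALSE)
    write_tsv(hm, file.path(out_dir, "heatmap.tsv"))
  }
  summary <- list(
    n_metagenome_samples = sum(result$experiment$metadata$assay == "metagenome"),
    n_exudate_samples = sum(result$experiment$metadata$assay == "exudate"),
    pct_classes_by_stage = lapply(result$diff_metabolites,
                                  function(d) attr(d, "summary")),
    community_fraction_by_stage = lapply(result$diff_taxa,
                                         function(d) attr(d, "community_fraction")),
    community_fraction_denominator = "summed mean relative abundance",
    unique_taxa = result$unique_taxa,
    n_consistent_diff_taxa = length(result$diff_taxa_consistent))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  manifest <- list(package = "rhizoxlink",
                   version = as.character(utils::packageVersion("rhizoxlink")),
                   seed = result$seed,
                   n_permutations = n_permutations,
                   n_pairings = n_pairings)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Validate consistency of feature tables against metadata
#'
#' Checks sample-id coverage, non-negativity, and (for the metagenome assay)
#' design balance. Violations are returned, not raised.
#'
#' @param tables named list of samples x features matrices.
#' @param metadata sample metadata data.frame.
#' @return data.frame report with columns `level` ("error"/"warning"),
#'   `table`, `message`; zero rows when everything is consistent.
#' @export
validate_tables <- function(tables, metadata) {
  rows <- list()
  add <- function(level, table, message)
    rows[[length(rows) + 1L]] <<- data.frame(level = level, table = table,
                                             message = message,
                                             stringsAsFactors = FALSE)
  if (!is.data.frame(metadata) || !"sample_id" %in% names(metadata)) {
    add("error", "(metadata)", "metadata lacks a sample_id column")
  } else {
    for (nm in names(tables)) {
      tab <- tables[[nm]]
      absent <- setdiff(rownames(tab), metadata$sample_id)
      if (length(absent))
        add("error", nm, paste("samples missing from metadata:",
                               paste(absent, collapse = ", ")))
      if (any(tab < 0))
        add("error", nm, "negative abundances")
    }
    if (all(c("genotype", "stage") %in% names(metadata))) {
      for (as_ in unique(metadata$assay)) {
        sub <- metadata[metadata$assay == as_, ]
        cells <- table(sub$genotype, sub$stage)
        if (length(unique(as.vector(cells))) != 1L)
          add("warning", paste0("(design:", as_, ")"),
              paste("unbalanced design; cell sizes:",
                    paste(paste(rownames(cells)[row(cells)],
                                colnames(cells)[col(cells)],
                                as.vector(cells), sep = ":"),
                          collapse = " ")))
      }
    }
  }
  if (length(rows)) do.call(rbind, rows)
  else data.frame(level = character(0), table = character(0),
                  message = character(0), stringsAsFactors = FALSE)
}

#' @export
print.rhizo_run <- function(x, ...) {
  cat("rhizoxlink pipeline run (seed ", x$seed, ")\n", sep = "")
  cat("  samples: ", nrow(x$taxa_ra), " metagenome, ",
      nrow(x$experiment$metabolites), " exudate\n", sep = "")
  for (st in names(x$permanova_by_stage)) {
    p <- x$permanova_by_stage[[st]]
    cat(sprintf("  PERMANOVA %-10s F = %.3f, R2 = %.3f, p = %.3f\n",
                st, p$pseudo_f[1], p$r2[1], p$p[1]))
  }
  cat("  consistent differential taxa: ", length(x$diff_taxa_consistent),
      "\n", sep = "")
  if (!is.null(x$correlations)) {
    above <- sum(abs(x$correlations$mean_r) >= attr(x$correlations, "threshold"),
                 na.rm = TRUE)
    cat("  taxon-ion correlations above display threshold: ", above, "\n",
        sep = "")
  }
  invisible(x)
}
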