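# Two-group differential analysis.
#
# Two modes mirror the two conventions of the field's desktop tools:
#   * volcano mode (metabolite ions): Welch's t on log2(intensity + 1),
#     Benjamini-Hochberg adjustment, features classified increased /
#     decreased / unrelated at adjusted p < alpha;
#   * STAMP mode (taxa, KEGG level-2 functions): relative-abundance input,
#     features below the RA filter excluded before testing, significance at
#     *raw* p < alpha, direction reported as enriched/suppressed in the
#     second (mutant) genotype.

#' Two-group t test
#'
#' Two-sided Welch's (default) or Student's t test. Degenerate inputs are
#' handled explicitly: if both groups have zero variance the p-value is 1
#' for equal means, and the smallest representable double (flagged via the
#' `"degenerate"` attribute) for unequal means.
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @param test `"welch"` or `"student"`.
#' @return List with `statistic`, `df`, `p`.
#' @export
two_group_test <- function(a, b, test = c("welch", "student")) {
  test <- match.arg(test)
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least two values", call. = FALSE)
  va <- stats::var(a); vb <- stats::var(b)
  if (va == 0 && vb == 0) {
    if (mean(a) == mean(b))
      return(list(statistic = 0, df = length(a) + length(b) - 2L, p = 1))
    out <- list(statistic = sign(mean(a) - mean(b)) * Inf,
                df = length(a) + length(b) - 2L, p = .Machine$double.xmin)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  fit <- stats::t.test(a, b, var.equal = (test == "student"))
  list(statistic = unname(fit$statistic), df = unname(fit$parameter),
       p = fit$p.value)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment; order-preserving with the input
#' and capped at one.
#'
#' @param pvals numeric vector of raw p-values in [0, 1].
#' @return Adjusted p-values in input order.
#' @export
bh_adjust <- function(pvals) {
  if (length(pvals) == 0L) return(numeric(0))
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE))
    stop("p-values must be in [0, 1]", call. = FALSE)
  stats::p.adjust(pvals, method = "BH")
}

split_two_groups <- function(table, metadata, stage = NULL) {
  md <- metadata_for(table, metadata)
  if (!is.null(stage)) {
    keep <- md$stage == stage
    if (!any(keep)) stop("no samples at stage ", stage, call. = FALSE)
    table <- table[keep, , drop = FALSE]
    md <- md[keep, , drop = FALSE]
  }
  # group (reference) order follows the metadata's own row order so results
  # are invariant to sample reordering of the table
  groups <- intersect(unique(metadata$genotype), unique(md$genotype))
  if (length(groups) != 2L)
    stop("need exactly two genotypes",
         if (!is.null(stage)) paste0(" at stage ", stage), call. = FALSE)
  list(ref = table[md$genotype == groups[1], , drop = FALSE],
       alt = table[md$genotype == groups[2], , drop = FALSE],
       groups = groups)
}

#' Differential metabolite ions (volcano mode)
#'
#' Per-ion log2 fold change of raw intensity means (second genotype over
#' first), Welch's t test on log2(intensity + pseudocount), BH adjustment,
#' and volcano classification at adjusted p < alpha. All-zero ions are
#' excluded before testing (count reported in the summary).
#'
#' @param table samples x ions intensity matrix (exudate assay).
#' @param metadata sample metadata with `sample_id`, `genotype`, `stage`.
#' @param stage stage label to analyse (NULL pools all stages).
#' @param alpha significance level on adjusted p (default 0.05).
#' @param test `"welch"` (default) or `"student"`.
#' @param pseudocount added before the log transform (default 1).
#' @return data.frame (one row per tested ion) with means per genotype,
#'   `log2fc`, `statistic`, `df`, `p`, `padj`, `direction` in
#'   {increased, decreased, unrelated}; attribute `summary` holds the class
#'   percentages and the number of excluded all-zero ions.
#' @export
differential_metabolites <- function(table, metadata, stage = NULL,
                                     alpha = 0.05, test = "welch",
                                     pseudocount = 1) {
  check_feature_table(table)
  sp <- split_two_groups(table, metadata, stage)
  all_zero <- colSums(sp$ref) == 0 & colSums(sp$alt) == 0
  n_excluded <- sum(all_zero)
  if (n_excluded > 0)
    message(n_excluded, " all-zero ion(s) excluded")
  ions <- colnames(table)[!all_zero]
  la <- log2(sp$ref[, ions, drop = FALSE] + pseudocount)
  lb <- log2(sp$alt[, ions, drop = FALSE] + pseudocount)
  res <- lapply(seq_along(ions), function(j)
    two_group_test(lb[, j], la[, j], test = test))
  mean_ref <- colMeans(sp$ref[, ions, drop = FALSE])
  mean_alt <- colMeans(sp$alt[, ions, drop = FALSE])
  out <- data.frame(
    feature = ions,
    mean_ref = mean_ref, mean_alt = mean_alt,
    log2fc = log2((mean_alt + pseudocount) / (mean_ref + pseudocount)),
    statistic = vapply(res, `[[`, numeric(1), "statistic"),
    df = vapply(res, `[[`, numeric(1), "df"),
    p = vapply(res, `[[`, numeric(1), "p"),
    row.names = NULL, stringsAsFactors = FALSE)
  names(out)[names(out) == "mean_ref"] <- paste0("mean_", sp$groups[1])
  names(out)[names(out) == "mean_alt"] <- paste0("mean_", sp$groups[2])
  out$padj <- bh_adjust(out$p)
  out$direction <- ifelse(out$padj < alpha,
                          ifelse(out$log2fc > 0, "increased", "decreased"),
                          "unrelated")
  n <- nrow(out)
  attr(out, "summary") <- list(
    pct_increased = 100 * sum(out$direction == "increased") / n,
    pct_decreased = 100 * sum(out$direction == "decreased") / n,
    pct_unrelated = 100 * sum(out$direction == "unrelated") / n,
    n_excluded_all_zero = n_excluded)
  out
}

#' Differentially abundant taxa or functions (STAMP mode)
#'
#' Expects relative abundances. Features whose mean relative abundance
#' across the analysed samples is not above `min_ra` are excluded before
#' testing. Each remaining feature is tested at level `alpha` on the *raw*
#' p-value; significant features are labelled enriched or suppressed in the
#' second genotype, and the summed mean relative abundance of the
#' significant set (the fraction of the community it represents) is
#' reported.
#'
#' @param table samples x features relative-abundance matrix.
#' @param metadata sample metadata.
#' @param stage stage label to analyse (NULL pools all stages).
#' @param min_ra relative-abundance filter, default 1e-4 (0.01%); features
#'   kept when mean RA > min_ra.
#' @param alpha significance level on raw p (default 0.05).
#' @param test `"welch"` (default) or `"student"`.
#' @return data.frame of tested features with means, `log2fc`, `statistic`,
#'   `df`, `p`, `padj` (BH, reported for reference), `significant`,
#'   `direction` in {enriched, suppressed, unrelated}; attributes
#'   `community_fraction` (summed mean RA of the significant set),
#'   `n_filtered` (features removed by the RA filter), and `groups`.
#' @export
differential_features <- function(table, metadata, stage = NULL,
                                  min_ra = 1e-4, alpha = 0.05,
                                  test = "welch") {
  check_feature_table(table)
  if (any(rowSums(table) > 1 + 1e-6))
    warning("input does not look like relative abundances (row sums > 1)")
  sp <- split_two_groups(table, metadata, stage)
  pooled_mean <- colMeans(rbind(sp$ref, sp$alt))
  keep <- pooled_mean > min_ra
  n_filtered <- sum(!keep)
  feats <- colnames(table)[keep]
  if (length(feats) == 0L)
    stop("no features pass the relative-abundance filter", call. = FALSE)
  res <- lapply(feats, function(f)
    two_group_test(sp$alt[, f], sp$ref[, f], test = test))
  mean_ref <- colMeans(sp$ref[, feats, drop = FALSE])
  mean_alt <- colMeans(sp$alt[, feats, drop = FALSE])
  out <- data.frame(
    feature = feats,
    mean_ref = mean_ref, mean_alt = mean_alt,
    log2fc = log2(mean_alt / mean_ref),
    statistic = vapply(res, `[[`, numeric(1), "statistic"),
    df = vapply(res, `[[`, numeric(1), "df"),
    p = vapply(res, `[[`, numeric(1), "p"),
    row.names = NULL, stringsAsFactors = FALSE)
  names(out)[names(out) == "mean_ref"] <- paste0("mean_", sp$groups[1])
  names(out)[names(out) == "mean_alt"] <- paste0("mean_", sp$groups[2])
  out$padj <- bh_adjust(out$p)
  out$significant <- out$p < alpha
  out$direction <- ifelse(out$significant,
                          ifelse(mean_alt > mean_ref, "enriched", "suppressed"),
                          "unrelated")
  attr(out, "community_fraction") <-
    sum(pooled_mean[feats][out$significant])
  attr(out, "n_filtered") <- n_filtered
  attr(out, "groups") <- sp$groups
  out
}

#' Genotype-unique features per stage
#'
#' A feature is "present" in a genotype x stage cell when its abundance
#' exceeds `presence_threshold` in at least one replicate. For each stage,
#' counts features present in exactly one genotype, and shared features.
#'
#' @param table samples x features abundance matrix.
#' @param metadata sample metadata.
#' @param presence_threshold presence cut-off (default 0, i.e. strictly
#'   positive abundance).
#' @return data.frame with one row per stage: counts unique to each
#'   genotype and shared.
#' @export
unique_features <- function(table, metadata, presence_threshold = 0) {
  check_feature_table(table)
  if (presence_threshold < 0)
    stop("presence_threshold must be >= 0", call. = FALSE)
  md <- metadata_for(table, metadata)
  genotypes <- unique(md$genotype)
  if (length(genotypes) != 2L)
    stop("need exactly two genotypes", call. = FALSE)
  stages <- unique(md$stage)
  rows <- lapply(stages, function(st) {
    present <- lapply(genotypes, function(g) {
      sub <- table[md$stage == st & md$genotype == g, , drop = FALSE]
      apply(sub > presence_threshold, 2, any)
    })
    data.frame(stage = st,
               unique_a = sum(present[[1]] & !present[[2]]),
               unique_b = sum(present[[2]] & !present[[1]]),
               shared = sum(present[[1]] & present[[2]]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  names(out)[2:3] <- paste0("unique_", genotypes)
  out
}
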