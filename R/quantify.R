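# Gene-abundance quantification from read-to-gene mapping tables.
#
# Shotgun reads mapped against a non-redundant gene catalogue fall into two
# classes: reads with a single candidate gene ("unique") and reads with
# several ("multi-mapped"). Unique reads contribute 1/l to their gene, where
# l is the gene length in base pairs. Each multi-mapped read carries one unit
# of read mass that is redistributed over its candidate genes proportionally
# to the genes' unique-read abundances, through the coefficient
#   Co_g = Ab(U)_g / sum over the read's candidates of Ab(U),
# and contributes Co_g / l_g to each candidate. Total gene abundance is
#   Ab(S) = Ab(U) + Ab(M).
# The redistribution is single pass: Co is computed from unique-read
# abundances only, with no iterative refinement.

#' Validate a gene catalog
#'
#' A gene catalog is a data.frame with columns `gene_id`, `length_bp`
#' (positive integer), `taxon` (species-level lineage label) and `ko`
#' (KEGG ortholog id, `NA` when unannotated).
#'
#' @param catalog data.frame as described above.
#' @return The catalog, invisibly, after validation.
#' @export
check_catalog <- function(catalog) {
  if (!is.data.frame(catalog))
    stop("catalog must be a data.frame", call. = FALSE)
  need <- c("gene_id", "length_bp", "taxon")
  missing_cols <- setdiff(need, names(catalog))
  if (length(missing_cols))
    stop("catalog lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(catalog$gene_id))
    stop("catalog gene ids are not unique", call. = FALSE)
  if (any(!is.finite(catalog$length_bp)) || any(catalog$length_bp <= 0))
    stop("catalog gene lengths must be strictly positive", call. = FALSE)
  if (is.null(catalog$ko)) catalog$ko <- NA_character_
  invisible(catalog)
}

# Parse one sample's mapping data.frame (read_id, gene_ids comma-separated)
# into a list of deduplicated candidate-gene character vectors.
parse_candidates <- function(mapping) {
  if (!is.data.frame(mapping) || !all(c("read_id", "gene_ids") %in% names(mapping)))
    stop("mapping must be a data.frame with columns read_id, gene_ids",
         call. = FALSE)
  cand <- strsplit(as.character(mapping$gene_ids), ",", fixed = TRUE)
  lapply(cand, unique)
}

check_candidates_in_catalog <- function(cands, catalog) {
  genes <- unique(unlist(cands, use.names = FALSE))
  unknown <- setdiff(genes, catalog$gene_id)
  if (length(unknown))
    stop("gene(s) in mapping absent from catalog: ",
         paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
  invisible(genes)
}

#' Unique-read gene abundance Ab(U)
#'
#' Each uniquely mapped read (candidate set of size one after deduplication)
#' contributes `1 / length_bp` to its gene.
#'
#' @param mapping data.frame with columns `read_id` and `gene_ids`
#'   (comma-separated candidate gene ids) for one sample.
#' @param catalog gene catalog, see [check_catalog()].
#' @return Named numeric vector of Ab(U), one entry per catalog gene
#'   (zero for genes without unique reads).
#' @export
unique_abundance <- function(mapping, catalog) {
  check_catalog(catalog)
  if (nrow(catalog) == 0L) stop("catalog is empty", call. = FALSE)
  cands <- parse_candidates(mapping)
  check_candidates_in_catalog(cands, catalog)
  len <- stats::setNames(catalog$length_bp, catalog$gene_id)
  ab <- stats::setNames(numeric(nrow(catalog)), catalog$gene_id)
  is_unique <- lengths(cands) == 1L
  if (any(is_unique)) {
    genes <- unlist(cands[is_unique], use.names = FALSE)
    counts <- table(genes)
    ab[names(counts)] <- as.numeric(counts) / len[names(counts)]
  }
  ab
}

#' Multi-mapped-read gene abundance Ab(M)
#'
#' Redistributes each multi-mapped read over its candidate genes with weight
#' `Co = Ab(U)_g / sum(Ab(U) over candidates)`, contributing `Co / l` to each
#' candidate. When no candidate of a read has unique-read support the
#' coefficient is undefined (0/0); the read mass is then split uniformly over
#' the candidates (1/N each) so that read mass is conserved, and the number of
#' such fallback reads is reported via the `"n_uniform_fallback"` attribute.
#'
#' @inheritParams unique_abundance
#' @param abU named Ab(U) vector computed from the same mapping,
#'   see [unique_abundance()].
#' @return Named numeric vector of Ab(M) over catalog genes, with attribute
#'   `n_uniform_fallback`.
#' @export
multiread_abundance <- function(mapping, abU, catalog) {
  check_catalog(catalog)
  cands <- parse_candidates(mapping)
  check_candidates_in_catalog(cands, catalog)
  len <- stats::setNames(catalog$length_bp, catalog$gene_id)
  abM <- stats::setNames(numeric(nrow(catalog)), catalog$gene_id)
  multi <- cands[lengths(cands) > 1L]
  n_fallback <- 0L
  if (length(multi)) {
    genes_flat <- unlist(multi, use.names = FALSE)
    read_idx <- rep.int(seq_along(multi), lengths(multi))
    u_flat <- abU[genes_flat]
    denom_by_read <- rowsum(u_flat, read_idx, reorder = TRUE)[, 1L]
    denom_flat <- denom_by_read[read_idx]
    n_cand_flat <- lengths(multi)[read_idx]
    co <- ifelse(denom_flat > 0, u_flat / denom_flat, 1 / n_cand_flat)
    n_fallback <- sum(denom_by_read == 0)
    contrib <- co / len[genes_flat]
    add <- rowsum(contrib, genes_flat, reorder = FALSE)
    abM[rownames(add)] <- abM[rownames(add)] + add[, 1L]
  }
  attr(abM, "n_uniform_fallback") <- n_fallback
  abM
}

#' Total gene abundance Ab(S) = Ab(U) + Ab(M) for one sample
#'
#' @inheritParams unique_abundance
#' @return data.frame with columns `gene_id`, `abU`, `abM`, `abS` (one row per
#'   catalog gene) and attribute `n_uniform_fallback`.
#' @export
gene_abundance <- function(mapping, catalog) {
  abU <- unique_abundance(mapping, catalog)
  abM <- multiread_abundance(mapping, abU, catalog)
  out <- data.frame(gene_id = names(abU), abU = as.numeric(abU),
                    abM = as.numeric(abM), abS = as.numeric(abU + abM),
                    stringsAsFactors = FALSE)
  attr(out, "n_uniform_fallback") <- attr(abM, "n_uniform_fallback")
  out
}

#' Gene abundance table for a set of samples
#'
#' Applies [gene_abundance()] to every sample of a read-mapping set and
#' assembles the Ab(S) values into a samples x genes feature table.
#'
#' @param mappings named list of per-sample mapping data.frames.
#' @param catalog gene catalog.
#' @return Numeric matrix (samples x genes) of Ab(S).
#' @export
gene_abundance_table <- function(mappings, catalog) {
  check_catalog(catalog)
  if (is.null(names(mappings)) || anyDuplicated(names(mappings)))
    stop("mappings must be a uniquely named list of per-sample tables",
         call. = FALSE)
  rows <- lapply(mappings, function(m) gene_abundance(m, catalog)$abS)
  out <- do.call(rbind, rows)
  dimnames(out) <- list(names(mappings), catalog$gene_id)
  out
}

#' Aggregate a gene table to taxon or KEGG-ortholog features
#'
#' Sums Ab(S) over all member genes of each annotation. Genes lacking an
#' annotation at the requested level are dropped; their number is reported
#' via the `"n_unannotated"` attribute and a message.
#'
#' @param gene_table samples x genes matrix of Ab(S),
#'   see [gene_abundance_table()].
#' @param catalog gene catalog.
#' @param level `"taxon"` or `"ko"`.
#' @return samples x annotations abundance matrix.
#' @export
aggregate_by_annotation <- function(gene_table, catalog, level = c("taxon", "ko")) {
  level <- match.arg(level)
  check_catalog(catalog)
  shared <- intersect(colnames(gene_table), catalog$gene_id)
  if (length(shared) == 0L)
    stop("no genes shared between table and catalog", call. = FALSE)
  ann <- catalog[[if (level == "taxon") "taxon" else "ko"]]
  names(ann) <- catalog$gene_id
  ann <- ann[shared]
  keep <- !is.na(ann) & ann != ""
  n_drop <- sum(!keep)
  if (n_drop > 0)
    message(n_drop, " gene(s) without ", level, " annotation dropped")
  sub <- gene_table[, shared[keep], drop = FALSE]
  grouped <- rowsum(t(sub), group = ann[keep], reorder = TRUE)
  out <- t(grouped)
  attr(out, "n_unannotated") <- n_drop
  out
}

#' Convert a feature table to per-sample relative abundances
#'
#' @param table samples x features non-negative matrix.
#' @return Matrix of the same shape whose rows sum to one.
#' @export
relative_abundance <- function(table) {
  check_feature_table(table)
  totals <- rowSums(table)
  if (any(totals <= 0))
    stop("sample(s) with zero total abundance: ",
         paste(utils::head(rownames(table)[totals <= 0], 5), collapse = ", "),
         call. = FALSE)
  sweep(table, 1, totals, "/")
}
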