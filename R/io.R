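# Plain-text I/O. All tables are tab-separated with a header row and floats
# serialized at full precision (17 significant digits) so that identical
# runs produce byte-identical files.

fmt_num <- function(x) {
  if (is.double(x)) sprintf("%.17g", x) else as.character(x)
}

write_tsv <- function(df, path) {
  out <- as.data.frame(df, stringsAsFactors = FALSE)
  for (j in seq_along(out)) if (is.double(out[[j]])) out[[j]] <- fmt_num(out[[j]])
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "NA")
  invisible(path)
}

#' Write a feature table as TSV (samples in rows)
#'
#' @param table samples x features matrix.
#' @param path output file path.
#' @export
write_feature_table <- function(table, path) {
  df <- data.frame(sample_id = rownames(table), table, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' Read a feature table written by [write_feature_table()]
#'
#' @param path TSV path with a `sample_id` column.
#' @return samples x features numeric matrix.
#' @export
read_feature_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, setdiff(names(df), "sample_id"), drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df$sample_id
  m
}

#' Write a synthetic experiment to a directory
#'
#' Produces `mappings/<sample>.tsv`, `catalog.tsv`, `metabolites.tsv`,
#' `metadata.tsv` and `truth.json`.
#'
#' @param experiment a `rhizo_experiment`, see [generate_experiment()].
#' @param dir output directory (created if needed).
#' @export
write_experiment <- function(experiment, dir) {
  stopifnot(inherits(experiment, "rhizo_experiment"))
  dir.create(file.path(dir, "mappings"), recursive = TRUE, showWarnings = FALSE)
  for (s in names(experiment$mappings))
    write_tsv(experiment$mappings[[s]],
              file.path(dir, "mappings", paste0(s, ".tsv")))
  write_tsv(experiment$catalog, file.path(dir, "catalog.tsv"))
  write_feature_table(experiment$metabolites, file.path(dir, "metabolites.tsv"))
  write_tsv(experiment$metadata, file.path(dir, "metadata.tsv"))
  truth <- experiment$truth
  truth$gene_ra <- NULL  # bulky; regenerate from the config when needed
  truth$taxa_ra <- NULL
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(dir)
}

#' Read a mappings directory into a named list
#'
#' @param dir directory containing `<sample>.tsv` mapping files.
#' @return Named list of mapping data.frames.
#' @export
read_mappings <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.tsv$", full.names = TRUE))
  if (length(files) == 0L)
    stop("no mapping files in ", dir, call. = FALSE)
  out <- lapply(files, function(f)
    utils::read.delim(f, colClasses = "character", stringsAsFactors = FALSE))
  names(out) <- sub("\\.tsv$", "", basename(files))
  out
}
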