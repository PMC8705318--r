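#' @keywords internal
"_PACKAGE"

# Shared validation helpers. Feature tables throughout the package are plain
# numeric matrices with samples in rows and features in columns (the vegan
# convention); sample metadata travels alongside as a data.frame with columns
# sample_id, assay, genotype, stage, replicate.

check_feature_table <- function(table, what = "table") {
  if (!is.matrix(table) || !is.numeric(table))
    stop(what, " must be a numeric matrix (samples x features)", call. = FALSE)
  if (is.null(rownames(table)) || is.null(colnames(table)))
    stop(what, " must have sample rownames and feature colnames", call. = FALSE)
  if (anyDuplicated(rownames(table)))
    stop(what, " has duplicated sample ids", call. = FALSE)
  if (anyDuplicated(colnames(table)))
    stop(what, " has duplicated feature ids", call. = FALSE)
  if (any(!is.finite(table)))
    stop(what, " contains non-finite values", call. = FALSE)
  if (any(table < 0))
    stop(what, " contains negative values", call. = FALSE)
  invisible(table)
}

check_metadata <- function(metadata, sample_ids = NULL,
                           required = c("sample_id", "genotype", "stage")) {
  if (!is.data.frame(metadata))
    stop("metadata must be a data.frame", call. = FALSE)
  missing_cols <- setdiff(required, names(metadata))
  if (length(missing_cols))
    stop("metadata lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (!is.null(sample_ids)) {
    absent <- setdiff(sample_ids, metadata$sample_id)
    if (length(absent))
      stop("samples absent from metadata: ",
           paste(utils::head(absent, 5), collapse = ", "), call. = FALSE)
  }
  invisible(metadata)
}

# Align a metadata data.frame to the rows of a table, in table order.
metadata_for <- function(table, metadata) {
  check_metadata(metadata, rownames(table))
  metadata[match(rownames(table), metadata$sample_id), , drop = FALSE]
}

# Deterministic per-stage seed derivation: a single pipeline seed fans out to
# stage seeds through a fixed multiplicative counter scheme, kept below 2^31.
derive_seed <- function(seed, counter) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  as.integer((as.double(seed) * 48271 + counter * 9973) %% 2147483647)
}
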