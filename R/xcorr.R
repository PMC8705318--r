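# Random-pairing resampled correlation between unpaired assays.
#
# The microbiome and the exudate metabolome were measured on different
# plants, so replicates cannot be matched. The linkage statistic therefore
# repeatedly (a) subsamples, within every genotype x stage condition, as many
# microbiome replicates as the metabolome has, (b) pairs them with the
# metabolome replicates through a uniformly random bijection, (c) pools the
# paired samples across all conditions and computes the Pearson correlation
# for every (taxon, metabolite) pair on transformed values, and reports the
# Monte-Carlo average (and SD) over many such pairings. Because the pairing
# within a condition is arbitrary, only correlation carried by the
# condition-mean profiles survives the averaging; replicate-level coupling
# (which the design cannot observe) averages out. In the limit of zero
# within-condition variance the mean correlation equals the Pearson
# correlation of the condition means exactly, for any seed.
#
# Records are classified against the taxon's differential direction:
#   suppressed in the mutant (higher in WT) + r > 0  -> type i
#   suppressed in the mutant               + r < 0  -> type ii
#   enriched in the mutant                 + r > 0  -> type iii
#   enriched in the mutant                 + r < 0  -> type iv
# with |mean r| below the display threshold -> "none".

transform_table <- function(table, transform, log_offset) {
  switch(transform,
         identity = table,
         log = log(table + log_offset),
         hellinger = hellinger(table),
         stop("unknown transform: ", transform, call. = FALSE))
}

#' Random-pairing averaged Pearson correlation
#'
#' @param taxa samples x taxa matrix (typically relative abundances of the
#'   metagenome assay).
#' @param metab samples x ions matrix (exudate intensities).
#' @param metadata metadata covering the samples of both tables, with
#'   columns `sample_id`, `assay`, `genotype`, `stage`.
#' @param taxa_ids,metab_ids feature subsets to correlate (typically the
#'   differentially abundant taxa passing the RA filter, and the
#'   differential ions).
#' @param n_pairings Monte-Carlo iterations (default 10000).
#' @param subsample replicates drawn per condition from the larger assay
#'   (default: the number of replicates of the smaller assay).
#' @param transform_taxa,transform_metab value transform per assay:
#'   `"hellinger"` (default for taxa), `"log"` (default for metabolites) or
#'   `"identity"`. The Hellinger transform is applied to the full table
#'   before subsetting; `"log"` is `log(x + offset)`.
#' @param log_offset_taxa,log_offset_metab offsets for the log transform.
#' @param threshold display threshold on |mean r| (default 0.5, inclusive).
#' @param directions optional named vector (`"enriched"`/`"suppressed"` per
#'   taxon) used to classify records, see [classify_type()].
#' @param min_valid minimum number of iterations with a defined correlation
#'   for a record to be reported as defined (default 3).
#' @param seed integer seed.
#' @return data.frame of class `correlation_records`: `taxon`, `metabolite`,
#'   `mean_r`, `sd_r`, `n_valid`, `type`.
#' @export
random_pairing_correlation <- function(taxa, metab, metadata,
                                       taxa_ids = colnames(taxa),
                                       metab_ids = colnames(metab),
                                       n_pairings = 10000L,
                                       subsample = NULL,
                                       transform_taxa = "hellinger",
                                       transform_metab = "log",
                                       log_offset_taxa = 1e-6,
                                       log_offset_metab = 1,
                                       threshold = 0.5,
                                       directions = NULL,
                                       min_valid = 3L,
                                       seed = 1L) {
  check_feature_table(taxa); check_feature_table(metab)
  if (n_pairings < 1L) stop("n_pairings must be >= 1", call. = FALSE)
  if (threshold < 0 || threshold > 1)
    stop("threshold must be in [0, 1]", call. = FALSE)
  missing_t <- setdiff(taxa_ids, colnames(taxa))
  missing_m <- setdiff(metab_ids, colnames(metab))
  if (length(missing_t) || length(missing_m))
    stop("unknown feature id(s): ",
         paste(c(missing_t, missing_m), collapse = ", "), call. = FALSE)

  md_t <- metadata_for(taxa, metadata)
  md_m <- metadata_for(metab, metadata)
  cond_t <- interaction(md_t$genotype, md_t$stage, drop = FALSE)
  cond_m <- interaction(md_m$genotype, md_m$stage, drop = FALSE)
  conds <- sort(intersect(levels(droplevels(cond_t)),
                          levels(droplevels(cond_m))))
  if (length(conds) < 2L)
    stop("need at least two shared genotype x stage conditions", call. = FALSE)
  idx_t <- lapply(conds, function(cc) which(cond_t == cc))
  idx_m <- lapply(conds, function(cc) which(cond_m == cc))
  n_m <- lengths(idx_m)
  k <- if (is.null(subsample)) min(lengths(idx_t), n_m) else as.integer(subsample)
  short <- lengths(idx_t) < k | n_m < k
  if (any(short))
    stop("condition(s) with fewer than ", k, " replicates: ",
         paste(conds[short], collapse = ", "), call. = FALSE)
  if (any(n_m != k))
    stop("subsample size (", k, ") must equal the replicate count of the ",
         "smaller assay in every condition", call. = FALSE)

  X <- transform_table(taxa, transform_taxa, log_offset_taxa)[, taxa_ids,
                                                              drop = FALSE]
  Y <- transform_table(metab, transform_metab, log_offset_metab)[, metab_ids,
                                                                 drop = FALSE]
  p <- length(taxa_ids); q <- length(metab_ids)
  sum_r <- matrix(0, p, q); sum_r2 <- matrix(0, p, q)
  n_valid <- matrix(0L, p, q)
  run <- function() {
    for (it in seq_len(n_pairings)) {
      rows_t <- integer(0); rows_m <- integer(0)
      for (ci in seq_along(conds)) {
        pick <- if (length(idx_t[[ci]]) == k) idx_t[[ci]]
                else idx_t[[ci]][sample.int(length(idx_t[[ci]]), k)]
        rows_t <- c(rows_t, pick[sample.int(k)])   # random bijection
        rows_m <- c(rows_m, idx_m[[ci]])
      }
      r <- suppressWarnings(stats::cor(X[rows_t, , drop = FALSE],
                                       Y[rows_m, , drop = FALSE]))
      ok <- is.finite(r)
      r[!ok] <- 0
      sum_r <<- sum_r + r
      sum_r2 <<- sum_r2 + r * r
      n_valid <<- n_valid + ok
    }
  }
  withr::with_seed(seed, run())

  mean_r <- ifelse(n_valid > 0, sum_r / n_valid, NA_real_)
  var_r <- ifelse(n_valid > 1,
                  pmax(0, (sum_r2 - n_valid * mean_r^2) / (n_valid - 1)), NA_real_)
  defined <- n_valid >= min_valid
  mean_r[!defined] <- NA_real_
  out <- data.frame(
    taxon = rep(taxa_ids, times = q),
    metabolite = rep(metab_ids, each = p),
    mean_r = as.vector(mean_r),
    sd_r = as.vector(sqrt(var_r)),
    n_valid = as.vector(n_valid),
    stringsAsFactors = FALSE)
  out$type <- "none"
  if (!is.null(directions)) {
    out$type <- mapply(classify_type, out$mean_r,
                       directions[out$taxon],
                       MoreArgs = list(threshold = threshold))
  }
  out$type[is.na(out$mean_r)] <- NA_character_
  structure(out, class = c("correlation_records", "data.frame"),
            threshold = threshold, n_pairings = n_pairings, seed = seed)
}

#' Classify a taxon-metabolite association
#'
#' Crosses the taxon's differential direction with the sign of the mean
#' correlation: WT-higher (suppressed in the mutant) with r > 0 is type i,
#' with r < 0 type ii; mutant-higher (enriched) with r > 0 is type iii,
#' with r < 0 type iv. Below-threshold or undefined correlations give
#' `"none"`.
#'
#' @param mean_r averaged Pearson correlation.
#' @param direction `"suppressed"` (higher in WT) or `"enriched"` (higher in
#'   the mutant).
#' @param threshold display threshold on |mean_r| (inclusive).
#' @return One of `"i"`, `"ii"`, `"iii"`, `"iv"`, `"none"`.
#' @export
classify_type <- function(mean_r, direction, threshold = 0.5) {
  if (is.na(mean_r) || is.na(direction) || abs(mean_r) < threshold)
    return("none")
  if (!direction %in% c("enriched", "suppressed"))
    stop("direction must be 'enriched' or 'suppressed'", call. = FALSE)
  if (direction == "suppressed") {
    if (mean_r > 0) "i" else "ii"
  } else {
    if (mean_r > 0) "iii" else "iv"
  }
}

#' Correlation heat-map matrix
#'
#' Arranges mean correlations as a taxa x metabolites matrix with entries
#' below the display threshold masked (NA). Taxa are ordered suppressed
#' block first, then enriched, each alphabetically; metabolites
#' alphabetically.
#'
#' @param records output of [random_pairing_correlation()].
#' @param directions optional named direction vector used for the row
#'   blocks; taxa without a direction sort last.
#' @param threshold masking threshold on |mean r| (defaults to the records'
#'   threshold attribute).
#' @return Numeric matrix with masked entries NA.
#' @export
correlation_heatmap_table <- function(records, directions = NULL,
                                      threshold = NULL) {
  if (is.null(threshold)) threshold <- attr(records, "threshold")
  if (is.null(threshold)) threshold <- 0.5
  if (nrow(records) == 0L) return(matrix(numeric(0), 0, 0))
  taxa <- sort(unique(records$taxon))
  if (!is.null(directions)) {
    blk <- match(directions[taxa], c("suppressed", "enriched"))
    blk[is.na(blk)] <- 3L
    taxa <- taxa[order(blk, taxa)]
  }
  metab <- sort(unique(records$metabolite))
  m <- matrix(NA_real_, length(taxa), length(metab),
              dimnames = list(taxa, metab))
  keep <- !is.na(records$mean_r) & abs(records$mean_r) >= threshold
  sub <- records[keep, , drop = FALSE]
  m[cbind(sub$taxon, sub$metabolite)] <- sub$mean_r
  m
}
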