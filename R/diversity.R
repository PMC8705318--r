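# Community statistics: Hellinger transform, alpha diversity, Bray-Curtis
# dissimilarity, PCA, and one-/two-way PERMANOVA. All heavy lifting is done
# by vegan (decostand, diversity, vegdist, adonis2) and stats::prcomp; the
# wrappers add the input validation, deterministic seeding, and result
# shapes used across this package.

#' Hellinger transform
#'
#' Square root of per-sample relative abundance; per sample the squares of
#' the transformed values sum to one.
#'
#' @param table samples x features non-negative matrix.
#' @return Transformed matrix of the same shape.
#' @export
hellinger <- function(table) {
  check_feature_table(table)
  if (any(rowSums(table) <= 0))
    stop("sample(s) with zero total abundance: ",
         paste(utils::head(rownames(table)[rowSums(table) <= 0], 5),
               collapse = ", "), call. = FALSE)
  vegan::decostand(table, method = "hellinger")
}

#' Shannon diversity (natural log)
#'
#' @param table samples x features non-negative matrix.
#' @return Named per-sample Shannon index H = -sum p log p. All-zero samples
#'   get H = 0 with a warning.
#' @export
shannon <- function(table) {
  check_feature_table(table)
  zero <- rowSums(table) <= 0
  if (any(zero))
    warning("all-zero sample(s), Shannon set to 0: ",
            paste(rownames(table)[zero], collapse = ", "))
  h <- vegan::diversity(table, index = "shannon", base = exp(1))
  h[zero] <- 0
  h
}

#' Species richness
#'
#' @param table samples x features non-negative matrix.
#' @return Named per-sample count of features with abundance > 0.
#' @export
richness <- function(table) {
  check_feature_table(table)
  vegan::specnumber(table)
}

#' Bray-Curtis dissimilarity matrix
#'
#' d(x, y) = sum |x - y| / sum (x + y), bounded in [0, 1].
#'
#' @param table samples x features non-negative matrix.
#' @return A `dist` object over samples.
#' @export
bray_curtis <- function(table) {
  check_feature_table(table)
  zero <- rowSums(table) <= 0
  if (sum(zero) >= 2)
    stop("Bray-Curtis undefined for pairs of all-zero samples: ",
         paste(rownames(table)[zero], collapse = ", "), call. = FALSE)
  vegan::vegdist(table, method = "bray")
}

#' Principal component analysis of a feature table
#'
#' Column-centred (unscaled) PCA via singular value decomposition. For
#' reproducibility across platforms each component's loading vector is
#' flipped, if necessary, so that its largest-magnitude entry is positive.
#'
#' @param table samples x features matrix (usually Hellinger-transformed).
#' @param n_components number of components to keep; clipped with a warning
#'   to `min(n_samples - 1, n_features)`.
#' @return List of class `pca_result` with `scores` (samples x components),
#'   `loadings` (features x components) and `explained` (proportion of
#'   variance per component).
#' @export
pca_ordination <- function(table, n_components = 2L) {
  if (!is.matrix(table) || nrow(table) < 2L)
    stop("need a matrix with at least 2 samples", call. = FALSE)
  max_k <- min(nrow(table) - 1L, ncol(table))
  if (n_components > max_k) {
    warning("n_components clipped to ", max_k)
    n_components <- max_k
  }
  fit <- stats::prcomp(table, center = TRUE, scale. = FALSE)
  explained <- fit$sdev^2 / sum(fit$sdev^2)
  k <- seq_len(n_components)
  flip <- vapply(k, function(j) {
    l <- fit$rotation[, j]
    sign(l[which.max(abs(l))])
  }, numeric(1))
  flip[flip == 0] <- 1
  structure(list(scores = sweep(fit$x[, k, drop = FALSE], 2, flip, "*"),
                 loadings = sweep(fit$rotation[, k, drop = FALSE], 2, flip, "*"),
                 explained = explained[k],
                 sdev = fit$sdev[k]),
            class = "pca_result")
}

permanova_frame <- function(fit, n_permutations, seed) {
  out <- data.frame(term = rownames(fit), df = fit$Df, ss = fit$SumOfSqs,
                    r2 = fit$R2, pseudo_f = fit$F, p = fit$`Pr(>F)`,
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(out, class = c("permanova_result", "data.frame"),
            n_permutations = n_permutations, seed = seed)
}

#' One-way PERMANOVA on a distance matrix
#'
#' Permutational multivariate analysis of variance (Anderson partitioning of
#' squared inter-point distances) with the pseudo-F statistic
#' `F = (SS_A / (a - 1)) / (SS_W / (N - a))` and permutation p-value
#' `(1 + #permuted F >= observed) / (1 + n_permutations)`, computed with
#' `vegan::adonis2`.
#'
#' @param dm `dist` object or square symmetric matrix of dissimilarities.
#' @param grouping factor (or coercible) of group labels, one per sample,
#'   at least two groups with at least two samples each.
#' @param n_permutations number of permutations (default 999).
#' @param seed integer seed for the permutation stream.
#' @return A `permanova_result` data.frame with one row per term
#'   (group factor, residual, total): df, sums of squares, R2, pseudo-F, p.
#' @export
permanova <- function(dm, grouping, n_permutations = 999L, seed = 1L) {
  dm <- stats::as.dist(dm)
  grouping <- factor(grouping)
  n <- attr(dm, "Size")
  if (length(grouping) != n)
    stop("grouping length does not match distance matrix", call. = FALSE)
  if (nlevels(grouping) < 2L)
    stop("need at least two groups", call. = FALSE)
  sizes <- table(grouping)
  if (any(sizes < 2L))
    stop("singleton group(s): ",
         paste(names(sizes)[sizes < 2], collapse = ", "), call. = FALSE)
  df <- data.frame(group = grouping)
  fit <- withr::with_seed(seed,
    vegan::adonis2(dm ~ group, data = df, permutations = n_permutations,
                   by = "terms"))
  permanova_frame(fit, n_permutations, seed)
}

#' Two-way crossed PERMANOVA (balanced designs)
#'
#' Partitions the distance-based sums of squares into the two main effects,
#' their interaction, and residual, testing each term against the residual
#' mean square with unrestricted permutation of sample identities. Only
#' balanced crossed designs are supported: with equal cell sizes sequential
#' and marginal sums of squares coincide, so no Type-I/II/III choice arises.
#' A factor with a single level is dropped, reducing to the one-way model.
#'
#' @param dm distance matrix (`dist` or square matrix).
#' @param factor_a,factor_b factors, one value per sample.
#' @param n_permutations,seed as in [permanova()].
#' @return A `permanova_result` data.frame with rows for each fitted term,
#'   residual and total.
#' @export
permanova_twoway <- function(dm, factor_a, factor_b, n_permutations = 999L,
                             seed = 1L) {
  dm <- stats::as.dist(dm)
  a <- factor(factor_a); b <- factor(factor_b)
  n <- attr(dm, "Size")
  if (length(a) != n || length(b) != n)
    stop("factor length does not match distance matrix", call. = FALSE)
  terms <- c(if (nlevels(a) > 1) "A", if (nlevels(b) > 1) "B")
  if (length(terms) == 0L)
    stop("both factors are constant", call. = FALSE)
  if (length(terms) == 2L) {
    cell_sizes <- table(a, b)
    if (any(cell_sizes == 0L) || length(unique(as.vector(cell_sizes))) != 1L)
      stop("unbalanced or incomplete design: cell sizes ",
           paste(as.vector(cell_sizes), collapse = "/"),
           "; only balanced crossed designs are supported", call. = FALSE)
  }
  df <- data.frame(A = a, B = b)
  rhs <- if (length(terms) == 2L) "A * B" else terms
  fml <- stats::as.formula(paste("dm ~", rhs))
  environment(fml) <- environment()
  fit <- withr::with_seed(seed,
    vegan::adonis2(fml, data = df, permutations = n_permutations,
                   by = "terms"))
  out <- permanova_frame(fit, n_permutations, seed)
  # report terms under the caller's factor names
  out$term <- sub("^A:B$", "interaction", out$term)
  out
}
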