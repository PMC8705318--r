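# Transforms, alpha diversity, distances, PCA, PERMANOVA.

named_mat <- function(x, nr, nc) {
  matrix(x, nr, nc, byrow = TRUE,
         dimnames = list(paste0("s", seq_len(nr)), paste0("f", seq_len(nc))))
}

test_that("Hellinger transform closed forms and unit row sum of squares", {
  expect_equal(unname(hellinger(named_mat(5, 1, 1))[1, 1]), 1)
  expect_equal(unname(hellinger(named_mat(c(1, 1, 1, 1), 1, 4))[1, ]),
               rep(0.5, 4), ignore_attr = TRUE)
  expect_equal(unname(hellinger(named_mat(c(1, 4), 1, 2))[1, ]),
               c(sqrt(0.2), sqrt(0.8)), ignore_attr = TRUE)
  set.seed(2)
  m <- named_mat(rexp(60), 6, 10)
  expect_equal(unname(rowSums(hellinger(m)^2)), rep(1, 6))
  m[2, ] <- 0
  expect_error(hellinger(m), "s2")
})

test_that("Shannon and richness match their closed forms", {
  expect_equal(unname(shannon(named_mat(c(1, 1, 1, 1), 1, 4))[1]), log(4))
  expect_equal(unname(shannon(named_mat(c(0, 7, 0), 1, 3))[1]), 0)
  expect_equal(unname(shannon(named_mat(c(0.5, 0.25, 0.25), 1, 3))[1]),
               1.5 * log(2))
  expect_equal(unname(richness(named_mat(c(0, 7, 2), 1, 3))[1]), 2)
  expect_warning(h <- shannon(named_mat(c(0, 0), 1, 2)), "all-zero")
  expect_equal(unname(h[1]), 0)
})

test_that("Bray-Curtis closed forms, bounds and symmetry", {
  m <- named_mat(c(1, 1, 1, 1), 2, 2)
  expect_equal(as.numeric(bray_curtis(m)), 0)
  disj <- named_mat(c(1, 0, 0, 2), 2, 2)
  expect_equal(as.numeric(bray_curtis(disj)), 1)
  xy <- named_mat(c(1, 1, 1, 3), 2, 2)
  expect_equal(as.numeric(bray_curtis(xy)), 1 / 3)
  set.seed(3)
  r <- named_mat(rexp(40), 4, 10)
  d <- as.matrix(bray_curtis(r))
  expect_true(all(d >= 0 & d <= 1))
  expect_equal(d, t(d))
  expect_equal(unname(diag(d)), rep(0, 4))
  zz <- named_mat(c(1, 1, 0, 0, 0, 0), 3, 2)
  expect_error(bray_curtis(zz), "all-zero")
})

test_that("PCA explains a single axis fully and is rotation invariant", {
  line <- named_mat(c(0, 0, 1, 1, 2, 2, 3, 3), 4, 2)
  p <- pca_ordination(line, 2)
  expect_equal(p$explained[1], 1)
  # rotating the cloud 90 degrees leaves the spectrum unchanged
  set.seed(4)
  x <- named_mat(rnorm(40), 10, 4)
  rot <- x[, c(2, 1, 4, 3)] * rep(c(-1, 1), each = 2)[col(x)]
  colnames(rot) <- colnames(x)
  expect_equal(pca_ordination(x, 3)$explained,
               pca_ordination(rot, 3)$explained)
  # deterministic sign convention: dominant loading entry positive
  for (j in seq_len(ncol(p$loadings)))
    expect_gte(p$loadings[which.max(abs(p$loadings[, j])), j], 0)
})

test_that("full-rank PCA reconstructs the centred input", {
  set.seed(5)
  m <- named_mat(rnorm(120), 6, 20)
  p <- pca_ordination(m, n_components = 5)
  centred <- scale(m, center = TRUE, scale = FALSE)
  rec <- p$scores %*% t(p$loadings)
  expect_equal(unname(rec), unname(centred)[, ], tolerance = 1e-10)
  expect_warning(pca_ordination(m, 10), "clipped")
})

test_that("one-way PERMANOVA reproduces the Anderson partitioning", {
  pts <- c(0, 1, 2, 10, 11, 12)
  d <- dist(pts)
  g <- rep(c("a", "b"), each = 3)
  res <- permanova(d, g, n_permutations = 99, seed = 1)
  expect_equal(res$ss[res$term == "Total"], 154)
  expect_equal(res$pseudo_f[1], 150)
  expect_equal(res$r2[1], 150 / 154)
  # agreement with the loop-based oracle on random data
  set.seed(6)
  for (i in 1:5) {
    m <- named_mat(rexp(36), 9, 4)
    dd <- bray_curtis(m)
    gg <- rep(c("x", "y", "z"), each = 3)
    want <- manual_permanova_F(dd, gg)
    got <- permanova(dd, gg, n_permutations = 9, seed = i)
    expect_equal(got$pseudo_f[1], want$pseudo_f, tolerance = 1e-10)
    expect_equal(got$r2[1], want$r2, tolerance = 1e-10)
    expect_equal(got$ss[got$term == "Total"], want$ss_total,
                 tolerance = 1e-10)
  }
})

test_that("PERMANOVA is invariant to label names and sample order", {
  set.seed(7)
  m <- named_mat(rexp(48), 8, 6)
  d <- bray_curtis(m)
  g <- rep(c("ctrl", "mut"), each = 4)
  f1 <- permanova(d, g, 19, seed = 1)$pseudo_f[1]
  f2 <- permanova(d, ifelse(g == "ctrl", "B", "A"), 19, seed = 2)$pseudo_f[1]
  expect_equal(f1, f2)
  perm <- sample(8)
  d2 <- as.dist(as.matrix(d)[perm, perm])
  f3 <- permanova(d2, g[perm], 19, seed = 3)$pseudo_f[1]
  expect_equal(f1, f3)
})

test_that("permutation p agrees with exhaustive enumeration and is in (0, 1]", {
  set.seed(8)
  m <- named_mat(rexp(30), 6, 5)
  d <- bray_curtis(m)
  g <- rep(c("a", "b"), each = 3)
  p_exact <- exact_permutation_p(d, g)
  res <- permanova(d, g, n_permutations = 999, seed = 4)
  # (b+1)/(m+1) estimator vs exact enumeration over the 20 assignments
  mc_sd <- sqrt(p_exact * (1 - p_exact) / 999)
  expect_lt(abs(res$p[1] - p_exact), max(3 * mc_sd, 0.01))
  expect_gt(res$p[1], 0)
  expect_lte(res$p[1], 1)
})

test_that("PERMANOVA rejects degenerate groupings", {
  d <- dist(1:5)
  expect_error(permanova(d, c("a", "a", "a", "a", "b")), "singleton")
  expect_error(permanova(d, rep("a", 5)), "two groups")
})

test_that("two-way PERMANOVA reduces to one-way and partitions SS", {
  set.seed(9)
  m <- named_mat(rexp(72), 12, 6)
  d <- bray_curtis(m)
  a <- rep(c("WT", "Nr"), each = 6)
  b <- rep("x", 12)
  two <- permanova_twoway(d, a, b, 99, seed = 1)
  one <- permanova(d, a, 99, seed = 1)
  expect_equal(two$pseudo_f[two$term == "A"], one$pseudo_f[1])
  # full crossed design: term SS add up to the total
  b2 <- rep(rep(c("s1", "s2", "s3"), each = 2), 2)
  full <- permanova_twoway(d, a, b2, 99, seed = 2)
  ss <- full$ss
  expect_equal(sum(ss[full$term != "Total"]), ss[full$term == "Total"],
               tolerance = 1e-8)
  expect_true(all(full$r2 >= 0 & full$r2 <= 1))
  b_unbal <- b2
  b_unbal[1] <- "s2"
  expect_error(permanova_twoway(d, a, b_unbal, 9, 1), "unbalanced")
})

test_that("two-way PERMANOVA p-values are uniform under the null", {
  set.seed(10)
  n_sim <- 120
  pv <- matrix(NA_real_, n_sim, 3)
  a <- rep(c("WT", "Nr"), each = 6)
  b <- rep(rep(c("s1", "s2", "s3"), each = 2), 2)
  for (i in seq_len(n_sim)) {
    m <- named_mat(rexp(72), 12, 6)
    res <- permanova_twoway(bray_curtis(m), a, b, 99, seed = 1000 + i)
    pv[i, ] <- res$p[1:3]
  }
  for (j in 1:3)
    expect_gt(suppressWarnings(ks.test(pv[, j], "punif"))$p.value, 0.01)
})
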