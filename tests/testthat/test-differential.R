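# Two-group tests, BH adjustment, volcano and STAMP-style analyses,
# genotype-unique features.

test_that("two-group t tests behave at the boundaries", {
  same <- two_group_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
  for (tst in c("welch", "student")) {
    shifted <- two_group_test(c(1, 2, 3), c(11, 12, 13), test = tst)
    expect_lt(shifted$p, 0.01)
  }
  # matches the reference implementation
  set.seed(11)
  a <- rnorm(6); b <- rnorm(6, 1)
  expect_equal(two_group_test(a, b, "welch")$p,
               t.test(a, b)$p.value)
  expect_equal(two_group_test(a, b, "student")$p,
               t.test(a, b, var.equal = TRUE)$p.value)
  # equal sizes and variances: Welch df equals Student df
  w <- two_group_test(c(1, 2, 3), c(2, 3, 4), "welch")
  s <- two_group_test(c(1, 2, 3), c(2, 3, 4), "student")
  expect_equal(w$df, s$df)
  expect_equal(w$statistic, s$statistic)
  # degenerate variance handling
  flat <- two_group_test(c(1, 1, 1), c(1, 1, 1))
  expect_equal(flat$p, 1)
  apart <- two_group_test(c(1, 1, 1), c(2, 2, 2))
  expect_equal(apart$p, .Machine$double.xmin)
  expect_true(isTRUE(attr(apart, "degenerate")))
  expect_error(two_group_test(1, c(1, 2)), "at least two")
})

test_that("BH adjustment matches the definitional step-up", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(numeric(0)), numeric(0))
  set.seed(12)
  for (i in 1:25) {
    p <- runif(sample(1:40, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, bh_brute(p), tolerance = 1e-12)
    expect_true(all(adj >= p))
    expect_true(all(adj <= 1))
    # monotone with the raw ranks
    expect_true(all(diff(adj[order(p)]) >= -1e-12))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("volcano analysis recovers a planted intensity shift", {
  set.seed(13)
  n_ions <- 60
  wt <- matrix(exp(rnorm(3 * n_ions, log(1e4), 0.1)), 3, n_ions)
  nr <- matrix(exp(rnorm(3 * n_ions, log(1e4), 0.1)), 3, n_ions)
  nr[, 1] <- nr[, 1] * 4    # +2 log2 planted
  wt[, 2] <- wt[, 2] * 4    # -2 log2 in the mutant
  fx <- two_group_table(wt, nr)
  d <- differential_metabolites(fx$table, fx$metadata, stage = "seedling")
  expect_equal(d$direction[1], "increased")
  expect_equal(d$direction[2], "decreased")
  expect_equal(d$log2fc[1], 2, tolerance = 0.35)
  s <- attr(d, "summary")
  expect_equal(s$pct_increased + s$pct_decreased + s$pct_unrelated, 100)
  # all-zero ions are excluded, with a count
  wt[, 3] <- nr[, 3] <- 0
  fx0 <- two_group_table(wt, nr)
  expect_message(d0 <- differential_metabolites(fx0$table, fx0$metadata,
                                                stage = "seedling"),
                 "all-zero")
  expect_false("f3" %in% d0$feature)
  expect_equal(attr(d0, "summary")$n_excluded_all_zero, 1L)
  # a stage with one genotype only is an error
  md_bad <- fx$metadata[fx$metadata$genotype == "WT", ]
  expect_error(differential_metabolites(
    fx$table[md_bad$sample_id, ], md_bad, stage = "seedling"),
    "two genotypes")
})

test_that("STAMP-style analysis applies the RA filter before testing", {
  set.seed(14)
  n <- 40
  base <- rexp(n) + 0.5
  mk <- function(shift1) {
    m <- matrix(rep(base, each = 6), 6, n) *
      matrix(exp(rnorm(6 * n, 0, 0.15)), 6, n)
    m[, 1] <- m[, 1] * shift1
    m[, 2] <- 1e-5          # tiny feature with a huge planted effect below
    m
  }
  wt <- mk(1); nr <- mk(4)
  nr[, 2] <- wt[1, 2] * 50  # would be wildly significant, but RA-filtered
  fx <- two_group_table(wt / rowSums(wt), nr / rowSums(nr))
  d <- differential_features(fx$table, fx$metadata, stage = "seedling",
                             min_ra = 1e-4)
  expect_false("f2" %in% d$feature)
  expect_gte(attr(d, "n_filtered"), 1L)
  expect_equal(d$direction[d$feature == "f1"], "enriched")
  expect_equal(attr(d, "community_fraction"),
               sum(colMeans(fx$table)[d$feature[d$significant]]))
  # identical groups: nothing significant, zero community fraction
  fx2 <- two_group_table(wt / rowSums(wt), wt / rowSums(wt))
  d2 <- differential_features(fx2$table, fx2$metadata, stage = "seedling",
                              alpha = 1e-6)
  expect_equal(sum(d2$significant), 0L)
  expect_equal(attr(d2, "community_fraction"), 0)
})

test_that("STAMP-style results do not depend on sample order", {
  set.seed(15)
  wt <- matrix(rexp(6 * 10) + 0.1, 6, 10)
  nr <- matrix(rexp(6 * 10) + 0.1, 6, 10)
  fx <- two_group_table(wt / rowSums(wt), nr / rowSums(nr))
  d1 <- differential_features(fx$table, fx$metadata, stage = "seedling")
  perm <- sample(nrow(fx$table))
  d2 <- differential_features(fx$table[perm, ], fx$metadata,
                              stage = "seedling")
  expect_equal(d1, d2, ignore_attr = TRUE)
})

test_that("unique-feature counts match brute-force set arithmetic", {
  set.seed(16)
  fx <- two_group_table(matrix(rbinom(4 * 12, 1, 0.5), 4, 12),
                        matrix(rbinom(4 * 12, 1, 0.5), 4, 12))
  got <- unique_features(fx$table, fx$metadata)
  md <- fx$metadata
  pres <- function(g) colSums(fx$table[md$genotype == g, , drop = FALSE] > 0) > 0
  expect_equal(got$unique_WT, sum(pres("WT") & !pres("Nr")))
  expect_equal(got$unique_Nr, sum(pres("Nr") & !pres("WT")))
  expect_equal(got$shared, sum(pres("Nr") & pres("WT")))
  # identical tables share everything
  fx2 <- two_group_table(fx$table[1:4, ], fx$table[1:4, ])
  same <- unique_features(fx2$table, fx2$metadata)
  expect_equal(same$unique_WT + same$unique_Nr, 0)
  # a feature present only in the mutant is unique to it
  wt0 <- matrix(0, 2, 1); nr1 <- matrix(3, 2, 1)
  fx3 <- two_group_table(wt0, nr1)
  expect_equal(unique_features(fx3$table, fx3$metadata)$unique_Nr, 1)
})
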