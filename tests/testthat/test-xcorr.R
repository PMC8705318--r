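# Random-pairing correlation: exact limits, enumeration, classification.

test_that("zero within-condition variance gives the condition-mean Pearson, any seed", {
  ct <- c(1, 3, 2, 5, 4, 6)
  cm <- c(2, 5, 5, 9, 8, 13)
  fx <- pairing_fixture(ct, cm, n_reps_taxa = 6, n_reps_metab = 3, noise = 0)
  want <- cor(ct, cm)
  for (sd_ in c(1, 99)) {
    rec <- random_pairing_correlation(
      fx$taxa, fx$metab, fx$metadata, "tax1", "ion1",
      n_pairings = 50, transform_taxa = "identity",
      transform_metab = "identity", seed = sd_)
    expect_equal(rec$mean_r, want, tolerance = 1e-12)
    expect_equal(rec$sd_r, 0, tolerance = 1e-6)  # two-pass variance round-off
    expect_equal(rec$n_valid, 50L)
  }
})

test_that("a constant feature is reported as undefined", {
  fx <- pairing_fixture(c(1, 2, 3, 4, 5, 6), c(2, 4, 5, 7, 9, 12),
                        noise = 0.1, seed = 3)
  taxa <- cbind(fx$taxa, flat = 1)
  rec <- random_pairing_correlation(
    taxa, fx$metab, fx$metadata, c("tax1", "flat"), "ion1",
    n_pairings = 20, transform_taxa = "identity",
    transform_metab = "identity", seed = 1)
  flat <- rec[rec$taxon == "flat", ]
  expect_true(is.na(flat$mean_r))
  expect_equal(flat$n_valid, 0L)
  expect_true(is.na(flat$type))
})

test_that("Monte-Carlo mean matches exhaustive enumeration of pairings", {
  # 2 conditions x 2 replicates in both assays: 2 x 2 = 4 assignments
  fx <- pairing_fixture(c(1, 4), c(2, 7), n_reps_taxa = 2, n_reps_metab = 2,
                        noise = 0.5, seed = 7)
  md <- fx$metadata
  mg <- md[md$assay == "metagenome", ]
  ex <- md[md$assay == "exudate", ]
  conds <- unique(paste(mg$genotype, mg$stage))
  perms2 <- list(1:2, 2:1)
  rs <- c()
  for (p1 in perms2) for (p2 in perms2) {
    ord <- list(p1, p2)
    rows_t <- unlist(lapply(seq_along(conds), function(ci) {
      idx <- which(paste(mg$genotype, mg$stage) == conds[ci])
      idx[ord[[ci]]]
    }))
    rows_m <- unlist(lapply(conds, function(cc)
      which(paste(ex$genotype, ex$stage) == cc)))
    rs <- c(rs, cor(fx$taxa[mg$sample_id[rows_t], "tax1"],
                    fx$metab[ex$sample_id[rows_m], "ion1"]))
  }
  rec <- random_pairing_correlation(
    fx$taxa, fx$metab, fx$metadata, "tax1", "ion1",
    n_pairings = 10000, transform_taxa = "identity",
    transform_metab = "identity", seed = 5)
  expect_equal(rec$mean_r, mean(rs), tolerance = 0.01)
})

test_that("records are reproducible under a fixed seed", {
  fx <- pairing_fixture(c(1, 3, 2, 6, 4, 7), c(1, 4, 3, 7, 6, 9),
                        noise = 0.3, seed = 11)
  args <- list(fx$taxa, fx$metab, fx$metadata, "tax1", "ion1",
               n_pairings = 200, transform_taxa = "identity",
               transform_metab = "identity", seed = 42)
  r1 <- do.call(random_pairing_correlation, args)
  r2 <- do.call(random_pairing_correlation, args)
  expect_identical(r1, r2)
})

test_that("Monte-Carlo error of the mean shrinks like 1/sqrt(n_pairings)", {
  fx <- pairing_fixture(c(1, 4), c(2, 7), n_reps_taxa = 2, n_reps_metab = 2,
                        noise = 0.8, seed = 13)
  mean_at <- function(n, s)
    random_pairing_correlation(fx$taxa, fx$metab, fx$metadata, "tax1", "ion1",
                               n_pairings = n, transform_taxa = "identity",
                               transform_metab = "identity", seed = s)$mean_r
  m100 <- vapply(1:10, function(s) mean_at(100, s), numeric(1))
  m10k <- vapply(1:10, function(s) mean_at(10000, s), numeric(1))
  ratio <- sd(m100) / sd(m10k)
  expect_gt(ratio, 2.5)   # expected ratio 10, wide band for 10-seed noise
  expect_lt(ratio, 40)
})

test_that("too few replicates in a condition is an informative error", {
  fx <- pairing_fixture(c(1, 2, 3, 4, 5, 6), c(2, 3, 4, 5, 6, 7),
                        n_reps_taxa = 2, n_reps_metab = 3, noise = 0.1)
  expect_error(random_pairing_correlation(
    fx$taxa, fx$metab, fx$metadata, "tax1", "ion1", n_pairings = 5,
    subsample = 3,
    transform_taxa = "identity", transform_metab = "identity"),
    "fewer than")
})

test_that("type classification covers the direction x sign grid", {
  expect_equal(classify_type(0.7, "suppressed"), "i")
  expect_equal(classify_type(-0.6, "suppressed"), "ii")
  expect_equal(classify_type(0.7, "enriched"), "iii")
  expect_equal(classify_type(-0.6, "enriched"), "iv")
  expect_equal(classify_type(0.49, "enriched", threshold = 0.5), "none")
  expect_equal(classify_type(0.5, "enriched", threshold = 0.5), "iii")
  expect_equal(classify_type(NA_real_, "enriched"), "none")
  expect_error(classify_type(0.9, "sideways"), "direction")
})

test_that("heat-map table masks below threshold with deterministic layout", {
  expect_equal(dim(correlation_heatmap_table(
    data.frame(taxon = character(0), metabolite = character(0),
               mean_r = numeric(0)))), c(0L, 0L))
  rec <- data.frame(
    taxon = c("t_b", "t_a", "t_c"),
    metabolite = c("m1", "m1", "m2"),
    mean_r = c(0.8, -0.2, -0.7), stringsAsFactors = FALSE)
  dirs <- c(t_a = "enriched", t_b = "suppressed", t_c = "enriched")
  hm <- correlation_heatmap_table(rec, dirs, threshold = 0.5)
  expect_equal(rownames(hm), c("t_b", "t_a", "t_c"))  # suppressed block first
  expect_equal(hm["t_b", "m1"], 0.8)
  expect_true(is.na(hm["t_a", "m1"]))
  expect_equal(sum(!is.na(hm)), sum(abs(rec$mean_r) >= 0.5))
})
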