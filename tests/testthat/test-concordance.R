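# Agreement statistics: concordance decomposition, r2, weighted kappa,
# low-agreement flags.

pair_from_vectors <- function(tg, cg) {
  list(seq = toy_geno(matrix(tg, nrow = 1)),
       arr = toy_geno(matrix(cg, nrow = 1)))
}

test_that("concordance decomposition matches direct counting", {
  p <- pair_from_vectors(c(0L, 1L, 2L, 1L), c(0L, 1L, 1L, 2L))
  cc <- concordance_counts(p$seq, p$arr, axis = "sample")
  expect_equal(cc$n_compared, 4)
  expect_equal(cc$n_match, 2)
  expect_equal(cc$n_diff1, 2)
  expect_equal(cc$n_diff2, 0)
  expect_equal(cc$concordance, 0.5)
  # maximal disagreement
  p2 <- pair_from_vectors(c(0L, 2L), c(2L, 0L))
  cc2 <- concordance_counts(p2$seq, p2$arr, axis = "sample")
  expect_equal(cc2$concordance, 0)
  expect_equal(cc2$n_diff2, 2)
  # identity
  p3 <- pair_from_vectors(c(0L, 1L, 2L), c(0L, 1L, 2L))
  cc3 <- concordance_counts(p3$seq, p3$arr, axis = "sample")
  expect_equal(cc3$concordance, 1)
  expect_equal(cc3$n_diff1 + cc3$n_diff2, 0)
  # missing entries are excluded from the denominator
  p4 <- pair_from_vectors(c(0L, NA, 2L), c(0L, 1L, NA))
  expect_equal(concordance_counts(p4$seq, p4$arr, "sample")$n_compared, 1)
})

test_that("per-sample and per-SNP r2 equal the squared Pearson correlation", {
  p <- pair_from_vectors(c(0L, 0L, 1L, 2L), c(0L, 1L, 1L, 2L))
  expect_equal(unname(r2_per_sample(p$seq, p$arr)), 8 / 11, tolerance = 1e-12)
  # same numbers arranged site-wise (4 samples, 1 site)
  ps <- list(seq = toy_geno(matrix(c(0L, 0L, 1L, 2L), ncol = 1)),
             arr = toy_geno(matrix(c(0L, 1L, 1L, 2L), ncol = 1)))
  expect_equal(unname(r2_per_snp(ps$seq, ps$arr)), 8 / 11, tolerance = 1e-12)
  # perfect and sign-reversed correlations give 1
  expect_equal(unname(r2_per_sample(pair_from_vectors(0:2, 0:2)$seq,
                                    pair_from_vectors(0:2, 0:2)$arr)), 1)
  rev <- pair_from_vectors(c(0L, 1L, 2L), c(2L, 1L, 0L))
  expect_equal(unname(r2_per_sample(rev$seq, rev$arr)), 1)
  # constant vector -> undefined
  mono <- pair_from_vectors(c(1L, 1L, 1L), c(0L, 1L, 2L))
  expect_true(is.na(r2_per_sample(mono$seq, mono$arr)))
})

test_that("r2 and concordance are symmetric in the two platforms", {
  cfg <- tiny_cfg(n_autosomal_sites = 300)
  tr <- simulate_truth(cfg)
  a <- observe_array(tr, cfg, seed = 1)
  b <- observe_array(tr, cfg, seed = 2)
  expect_equal(r2_per_sample(a, b), r2_per_sample(b, a))
  ca <- concordance_counts(a, b, "site")
  cb <- concordance_counts(b, a, "site")
  expect_equal(ca$n_match, cb$n_match)
  expect_equal(ca$n_diff1, cb$n_diff1)
})

test_that("squared-weight kappa reproduces hand-computed values", {
  expect_equal(weighted_kappa(c(0L, 1L, 2L, 0L), c(0L, 1L, 2L, 1L)), 0.8,
               tolerance = 1e-12)
  expect_equal(weighted_kappa(0:2, 0:2), 1)
  expect_equal(suppressMessages(weighted_kappa(c(1L, 1L), c(1L, 1L))), 1)
  # kappa <= 1 and equals 1 only at perfect agreement
  set.seed(4)
  x <- sample(0:2, 200, TRUE); y <- sample(0:2, 200, TRUE)
  expect_lte(weighted_kappa(x, y), 1)
})

test_that("kappa of independent raters sits inside its permutation null band", {
  set.seed(9)
  x <- sample(0:2, 2000, TRUE, prob = c(0.4, 0.4, 0.2))
  y <- sample(0:2, 2000, TRUE, prob = c(0.3, 0.5, 0.2))
  k_obs <- weighted_kappa(x, y)
  k_null <- replicate(200, weighted_kappa(x, sample(y)))
  band <- stats::quantile(k_null, c(0.005, 0.995))
  expect_gte(k_obs, band[[1]])
  expect_lte(k_obs, band[[2]])
})

test_that("mean per-sample concordance matches the pooled rate at equal weights", {
  cfg <- tiny_cfg(arr_missing = 0)   # equal n_compared across samples
  tr <- simulate_truth(cfg)
  a <- observe_array(tr, cfg, seed = 5)
  auto <- which(tr$genotypes$sites$compartment == "auto")
  rep <- concordance_report(subset_geno(tr$genotypes, sites = auto),
                            subset_geno(a, sites = auto))
  expect_equal(rep$summary[["mean_sample_concordance"]],
               rep$summary[["overall_concordance"]], tolerance = 1e-12)
})

test_that("low-agreement flags apply strict thresholds and skip undefined r2", {
  by_site <- data.frame(id = c("a", "b", "c", "d"),
                        concordance = c(0.89, 0.90, 1, 1),
                        r2 = c(0.9, 0.79, NA, 1))
  fl <- flag_low_agreement(by_site)
  expect_identical(fl$low_concordance, "a")
  expect_identical(fl$low_r2, "b")
  expect_identical(sort(fl$union), c("a", "b"))
  expect_equal(fl$n_r2_undefined, 1)
})
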