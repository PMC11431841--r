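# Generator properties: HWE, pedigree construction, sex chromosomes,
# platform observation models, depth model.

test_that("truth simulation is deterministic under a seed", {
  cfg <- tiny_cfg()
  t1 <- simulate_truth(cfg)
  t2 <- simulate_truth(cfg)
  expect_identical(t1$genotypes$calls, t2$genotypes$calls)
  expect_identical(t1$sexes, t2$sexes)
  expect_identical(t1$trios, t2$trios)
})

test_that("founder autosomal genotypes follow Hardy-Weinberg at p = 0.5", {
  cfg <- tiny_cfg(n_samples = 40, n_trios = 0, n_autosomal_sites = 4000,
                  n_x_nonpar_sites = 0, n_y_sites = 0, n_par_sites = 0,
                  maf_low = 0.5, maf_high = 0.5)
  tr <- simulate_truth(cfg)
  n <- length(tr$genotypes$calls)
  het <- mean(tr$genotypes$calls == 1L)
  se <- sqrt(0.5 * 0.5 / n)
  expect_lt(abs(het - 0.5), 3 * se)
})

test_that("trio offspring are Mendelian-consistent at every autosomal site", {
  tr <- simulate_truth(tiny_cfg())
  auto <- tr$genotypes$sites$compartment == "auto"
  for (t in seq_len(nrow(tr$trios))) {
    ok <- mendelian_consistent(tr$genotypes$calls[tr$trios$sire[t], auto],
                               tr$genotypes$calls[tr$trios$dam[t], auto],
                               tr$genotypes$calls[tr$trios$offspring[t], auto])
    expect_true(all(ok))
  }
})

test_that("sex-chromosome construction: male hemizygosity, female Y missing", {
  tr <- simulate_truth(tiny_cfg())
  xs <- tr$genotypes$sites$compartment == "x_nonpar"
  ys <- tr$genotypes$sites$compartment == "y"
  males <- names(tr$sexes)[tr$sexes == "male"]
  females <- names(tr$sexes)[tr$sexes == "female"]
  expect_false(any(tr$genotypes$calls[males, xs] == 1L, na.rm = TRUE))
  expect_true(all(is.na(tr$genotypes$calls[females, ys])))
  expect_true(all(!is.na(tr$genotypes$calls[males, ys])))
})

test_that("array observation: identity at zero error, calibrated missingness, adjacency", {
  cfg0 <- tiny_cfg(arr_error = 0, arr_missing = 0)
  tr <- simulate_truth(cfg0)
  expect_identical(observe_array(tr, cfg0)$calls, tr$genotypes$calls)

  cfgm <- tiny_cfg(n_samples = 40, n_trios = 0, n_autosomal_sites = 3000,
                   arr_error = 0, arr_missing = 0.02)
  trm <- simulate_truth(cfgm)
  obs <- observe_array(trm, cfgm)
  n <- sum(!is.na(trm$genotypes$calls))
  miss_frac <- sum(is.na(obs$calls) & !is.na(trm$genotypes$calls)) / n
  expect_lt(abs(miss_frac - 0.02), 3 * sqrt(0.02 * 0.98 / n))

  # forced errors move exactly one allele step
  cfge <- tiny_cfg(arr_error = 1, arr_missing = 0)
  tre <- simulate_truth(cfge)
  obse <- observe_array(tre, cfge)
  tc <- tre$genotypes$calls
  expect_true(all(obse$calls[!is.na(tc) & tc == 0L] == 1L))
  expect_true(all(obse$calls[!is.na(tc) & tc == 2L] == 1L))
  expect_true(all(obse$calls[!is.na(tc) & tc == 1L] %in% c(0L, 2L)))
})

test_that("sequencing observation: het allele balance, female Y empty, depth calibrated", {
  cfg <- sim_config(n_samples = 20, n_males = 4, n_trios = 0,
                    n_autosomal_sites = 10000, n_x_nonpar_sites = 100,
                    n_y_sites = 5, n_par_sites = 10, seed = 11)
  tr <- simulate_truth(cfg)
  so <- observe_sequencing(tr)
  het <- !is.na(tr$genotypes$calls) & tr$genotypes$calls == 1L
  alt <- sum(so$allele_depth$alt[het])
  tot <- sum(so$allele_depth$ref[het] + so$allele_depth$alt[het])
  expect_lt(abs(alt / tot - 0.5), 3 * sqrt(0.25 / tot))

  females <- names(tr$sexes)[tr$sexes == "female"]
  ys <- tr$genotypes$sites$compartment == "y"
  expect_true(all(so$allele_depth$ref[females, ys] == 0L))
  expect_true(all(so$allele_depth$alt[females, ys] == 0L))

  # mean realized SNP depth across non-outlier sites within 5% of target
  ok <- so$site_stats$sim_outlier == "none"
  expect_lt(abs(mean(so$site_stats$depth_snp[ok]) - cfg$mean_depth),
            0.05 * cfg$mean_depth)
})

test_that("noise-free saturating observation reproduces truth on both platforms", {
  cfg <- tiny_cfg(arr_error = 0, arr_missing = 0, seq_read_error = 0,
                  depth_shape = Inf, frac_low_outlier = 0,
                  frac_high_outlier = 0, frac_offcentre = 0)
  tr <- simulate_truth(cfg)
  expect_identical(observe_array(tr, cfg)$calls, tr$genotypes$calls)
  so <- observe_sequencing(tr, cfg)
  expect_identical(so$genotypes$calls, tr$genotypes$calls)
})
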