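# VanRaden GRM, GRM correlation, opposing homozygotes, parentage, sex.

test_that("GRM reproduces the hand-computed 2x2 example", {
  g <- toy_geno(matrix(c(0L, 2L, 2L, 0L), nrow = 2))
  G <- compute_grm(g)$values
  expect_equal(unname(G), matrix(c(2, -2, -2, 2), 2), tolerance = 1e-12)
})

test_that("GRM is symmetric and duplicated samples coincide", {
  cfg <- tiny_cfg(n_trios = 0, n_x_nonpar_sites = 0, n_y_sites = 0,
                  n_par_sites = 0, n_autosomal_sites = 500)
  tr <- simulate_truth(cfg)
  g <- tr$genotypes
  dup <- geno_matrix(rbind(g$calls, g$calls[1, , drop = FALSE]),
                     c(g$samples, "dup1"), g$sites)
  G <- suppressMessages(compute_grm(dup))$values
  expect_equal(G, t(G), tolerance = 1e-10)
  n <- nrow(G)
  expect_equal(G[1, n], G[1, 1], tolerance = 1e-10)
  expect_equal(G[n, n], G[1, 1], tolerance = 1e-10)
})

test_that("GRM diagonal averages near 1 for HWE founders", {
  cfg <- sim_config(n_samples = 30, n_males = 4, n_trios = 0,
                    n_autosomal_sites = 20000, n_x_nonpar_sites = 0,
                    n_y_sites = 0, n_par_sites = 0, seed = 13)
  tr <- simulate_truth(cfg)
  G <- suppressMessages(compute_grm(tr$genotypes))$values
  expect_lt(abs(mean(diag(G)) - 1), 0.05)
})

test_that("GRM correlation: exact self-agreement, affine invariance, sample checks", {
  g <- toy_geno(matrix(c(0L, 2L, 1L, 2L, 0L, 1L, 1L, 1L, 0L), nrow = 3))
  G <- compute_grm(g)
  expect_identical(grm_correlation(G, G)$r, 1)
  G2 <- G
  G2$values <- 3 * G$values + 0.5
  expect_equal(grm_correlation(G, G2)$r, 1, tolerance = 1e-12)
  G3 <- G
  rownames(G3$values)[1] <- "other"
  expect_error(grm_correlation(G, G3), "differ")
})

test_that("opposing-homozygote rate counts correctly and matches the HWE closed form", {
  r <- opposing_homozygote_rate(c(0L, 2L, 1L), c(2L, 2L, 0L))
  expect_equal(r$rate, 1 / 3)
  expect_equal(r$n_opposing, 1)
  # parent-offspring pairs on error-free truth have rate zero
  tr <- simulate_truth(tiny_cfg())
  auto <- tr$genotypes$sites$compartment == "auto"
  for (t in seq_len(nrow(tr$trios))) {
    expect_equal(opposing_homozygote_rate(
      tr$genotypes$calls[tr$trios$offspring[t], auto],
      tr$genotypes$calls[tr$trios$sire[t], auto])$rate, 0)
  }
  # unrelated HWE pair at p = 0.3: expected rate 2 p^2 (1-p)^2
  cfg <- sim_config(n_samples = 2, n_males = 0, n_trios = 0,
                    n_autosomal_sites = 30000, n_x_nonpar_sites = 0,
                    n_y_sites = 0, n_par_sites = 0,
                    maf_low = 0.3, maf_high = 0.3, seed = 21)
  t2 <- simulate_truth(cfg)
  expected <- 2 * 0.3^2 * 0.7^2
  obs <- opposing_homozygote_rate(t2$genotypes$calls[1, ], t2$genotypes$calls[2, ])
  expect_lt(abs(obs$rate - expected),
            3 * sqrt(expected * (1 - expected) / obs$n_compared))
})

test_that("parentage assignment recovers true parents and ranks them first", {
  cfg <- sim_config(n_samples = 30, n_males = 5, n_trios = 6,
                    n_autosomal_sites = 5000, n_x_nonpar_sites = 50,
                    n_y_sites = 5, n_par_sites = 10, seed = 31)
  tr <- simulate_truth(cfg)
  arr <- observe_array(tr)
  pa <- assign_parents(arr, tr$trios$offspring, arr$samples, tau = 0.01,
                       sexes = tr$sexes)
  for (t in seq_len(nrow(tr$trios))) {
    tab <- pa[[tr$trios$offspring[t]]]
    acc <- tab$candidate[tab$accepted]
    expect_setequal(acc, c(tr$trios$sire[t], tr$trios$dam[t]))
    expect_identical(attr(tab, "sire"), tr$trios$sire[t])
    expect_identical(attr(tab, "dam"), tr$trios$dam[t])
  }
  # tau = 1 lists everyone; true parents still rank in the top two
  pa_all <- assign_parents(arr, tr$trios$offspring[1], arr$samples, tau = 1)
  tab <- pa_all[[1]]
  expect_true(all(tab$accepted))
  expect_setequal(tab$candidate[1:2], c(tr$trios$sire[1], tr$trios$dam[1]))
  # no candidate below an impossibly small tau -> empty acceptance
  pa_none <- assign_parents(arr, tr$trios$offspring[1],
                            setdiff(arr$samples, unlist(tr$trios[1, ])),
                            tau = 1e-6)
  expect_equal(sum(pa_none[[1]]$accepted), 0)
})

test_that("sex assignment is driven by Y presence and non-PAR X heterozygosity", {
  cfg <- tiny_cfg()
  tr <- simulate_truth(cfg)
  arr <- observe_array(tr)
  y <- which(tr$genotypes$sites$compartment == "y")
  x <- which(tr$genotypes$sites$compartment == "x_nonpar")
  sx <- assign_sex(arr, y, x)
  expect_identical(sx$assigned_sex, unname(tr$sexes[sx$sample]))
  # conflicting evidence is ambiguous, never silently male
  g <- arr
  f1 <- names(tr$sexes)[tr$sexes == "female"][1]
  g$calls[f1, y] <- 0L                 # female with Y calls present
  sx2 <- assign_sex(g, y, x)
  expect_identical(sx2$assigned_sex[sx2$sample == f1], "ambiguous")
  expect_error(assign_sex(arr, integer(0), x), "Y site")
  expect_error(assign_sex(arr, y, x[1:5]), "non-PAR X")
})
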