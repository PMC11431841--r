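# Trio screening, call-rate exclusion, depth/quality flags, region
# detection and the problematic-SNP table.

test_that("Mendelian predicate agrees with the gamete-set oracle on all 27 combinations", {
  combos <- expand.grid(f = 0:2, m = 0:2, c = 0:2)
  got <- mendelian_consistent(combos$f, combos$m, combos$c)
  want <- mapply(oracle_mendelian, combos$f, combos$m, combos$c)
  expect_identical(unname(got), unname(want))
  expect_equal(sum(!got), 12)
  # spot checks
  expect_false(mendelian_consistent(0L, 0L, 2L))
  expect_true(all(mendelian_consistent(1L, 1L, 0:2)))
  expect_true(is.na(mendelian_consistent(NA, 1L, 0L)))
})

test_that("MI rates use informative trios only and the filter honours its threshold", {
  # 3 trios at 2 sites; site 1: one inconsistent of two informative (third
  # has a missing parent); site 2: all consistent.
  samples <- c("o1", "f1", "d1", "o2", "f2", "d2", "o3", "f3", "d3")
  calls <- matrix(c(2L, 0L, 0L,  1L, 1L, 0L,  0L, NA, 0L,
                    1L, 1L, 1L,  0L, 0L, 0L,  2L, 2L, 2L),
                  nrow = 9)
  g <- geno_matrix(calls, samples,
                   data.frame(chrom = "1", pos = c(100L, 200L), ref = "A",
                              alt = "G", snp_id = c("s1", "s2")))
  trios <- data.frame(offspring = c("o1", "o2", "o3"),
                      sire = c("f1", "f2", "f3"), dam = c("d1", "d2", "d3"))
  mi <- mendelian_inconsistency(g, trios)
  expect_equal(mi$n_informative, c(2L, 3L))
  expect_equal(mi$mi_rate, c(0.5, 0))
  kept <- suppressMessages(mi_filter(g, trios, threshold = 0.05))
  expect_identical(kept$sites$snp_id, "s2")
  # threshold 1 removes nothing; threshold 0 removes any site with >= 1 hit
  expect_equal(nrow(suppressMessages(mi_filter(g, trios, 1))$sites), 2)
  expect_identical(suppressMessages(mi_filter(g, trios, 0))$sites$snp_id, "s2")
})

test_that("X/Y sites are excluded from trio testing", {
  samples <- c("o1", "f1", "d1")
  g <- geno_matrix(matrix(c(2L, 0L, 0L, 2L, 0L, 0L), nrow = 3), samples,
                   data.frame(chrom = c("1", "X"), pos = c(1L, 2L), ref = "A",
                              alt = "G", snp_id = c("a", "x")))
  mi <- mendelian_inconsistency(g, data.frame(offspring = "o1", sire = "f1",
                                              dam = "d1"))
  expect_equal(mi$mi_rate[1], 1)
  expect_true(is.na(mi$mi_rate[2]))
})

test_that("sample call-rate filter drops below-threshold samples only", {
  calls <- rbind(rep(0L, 100),
                 c(rep(NA_integer_, 11), rep(1L, 89)))  # 89% call rate
  g <- toy_geno(calls)
  kept <- suppressMessages(sample_call_rate_filter(g, 0.90))
  expect_identical(kept$samples, "s1")
  expect_identical(attr(kept, "removed"), "s2")
  expect_identical(sample_call_rate_filter(g, 0)$samples, g$samples)
  full <- toy_geno(matrix(1L, 2, 4))
  expect_identical(sample_call_rate_filter(full, 0.9)$samples, full$samples)
  expect_error(sample_call_rate_filter(g, 1.1), "below threshold")
})

test_that("site pass flags use depth >= 100 and QUAL strictly > 20", {
  stats <- data.frame(depth_snp = c(260, 80, 260), qual = c(60, 60, 20))
  expect_identical(site_pass_flags(stats), c(TRUE, FALSE, FALSE))
})

test_that("IQR outlier flags reproduce hand-derived results and invariances", {
  depths <- c(rep(100, 8), 5, 900)
  fl <- iqr_depth_outliers(depths)
  expect_identical(as.character(fl), c(rep("none", 8), "low", "high"))
  # degenerate constant vector: bounds collapse, nothing flagged
  expect_true(all(iqr_depth_outliers(rep(7, 10)) == "none"))
  # translation invariance
  expect_identical(iqr_depth_outliers(depths + 123), fl)
  # order invariance
  perm <- c(10, 9, 1:8)
  expect_identical(iqr_depth_outliers(depths[perm]), fl[perm])
  expect_error(iqr_depth_outliers(c(1, 2, 3)), ">= 4")
})

test_that("central-capture flags compare SNP depth to region depth (>= at the boundary)", {
  stats <- data.frame(depth_snp = c(300, 100, 250, 50),
                      depth_ave = c(250, 250, 250, 0))
  fl <- suppressMessages(central_capture_flags(stats))
  expect_identical(fl, c(TRUE, FALSE, TRUE, NA))
})

test_that("low-MQ regions are maximal runs above the minimum length", {
  stats <- data.frame(chrom = "5", pos = (1:5) * 1e6,
                      mq = c(60, 30, 30, 30, 60))
  reg <- detect_low_mq_regions(stats, mq_threshold = 50, min_run = 3)
  expect_equal(nrow(reg), 1)
  expect_equal(reg$start, 2e6)
  expect_equal(reg$end, 4e6)
  expect_equal(reg$n_sites, 3)
  # an isolated low site is not a region
  one <- data.frame(chrom = "5", pos = (1:5) * 1e6, mq = c(60, 60, 30, 60, 60))
  expect_equal(nrow(detect_low_mq_regions(one)), 0)
  # position-unsorted input is sorted internally
  shuf <- stats[c(3, 1, 5, 2, 4), ]
  expect_equal(detect_low_mq_regions(shuf), reg)
})

test_that("problematic table takes the union of the three criteria without double counting", {
  stats <- data.frame(chrom = "1", pos = 1:4 * 100L,
                      snp_id = paste0("s", 1:4),
                      depth_snp = c(260, 20, 20, 260),
                      depth_ave = c(250, 250, 250, 250),
                      maf = c(0.1, 0.2, 0.3, 0.4))
  conc <- c(0.4, 1, 1, 1)
  dfl <- factor(c("none", "low", "low", "none"), levels = c("none", "low", "high"))
  cen <- c(TRUE, FALSE, TRUE, TRUE)
  tab <- build_problematic_table(stats, conc, dfl, cen)
  expect_equal(nrow(tab), 3)             # union of {1}, {2,3}, {2}
  expect_identical(tab$reasons[tab$snp_id == "s1"], "low_concordance")
  expect_identical(tab$reasons[tab$snp_id == "s2"],
                   "depth_outlier_low;non_central")
  # clean input -> empty table
  clean <- build_problematic_table(stats, c(1, 1, 1, 1),
                                   factor(rep("none", 4), levels = c("none", "low", "high")),
                                   rep(TRUE, 4))
  expect_equal(nrow(clean), 0)
})
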