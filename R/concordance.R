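# Cross-platform agreement statistics: concordance with one-/two-allele
# mismatch decomposition, per-sample and per-SNP squared Pearson
# correlation, squared-weight Cohen's kappa, and low-agreement flags.
# All statistics use pairwise-complete deletion: only positions where both
# platforms have a call enter the computation.

check_paired <- function(g_seq, g_arr) {
  if (!identical(dim(g_seq$calls), dim(g_arr$calls)) ||
      !identical(g_seq$samples, g_arr$samples) ||
      !identical(g_seq$sites$snp_id, g_arr$sites$snp_id))
    fail("paired statistics need identically indexed matrices; run intersect_common_sites() first")
}

#' Concordance counts and rates along one axis
#'
#' For every sample (axis = "sample") or site (axis = "site"): the number of
#' pairwise-complete calls, matches, one-allele differences (|delta| = 1)
#' and two-allele differences (|delta| = 2), plus the concordance rate.
#'
#' @param g_seq,g_arr aligned [geno_matrix] pair (sequencing, array).
#' @param axis `"sample"` or `"site"`.
#' @return data.frame with `id`, `n_compared`, `n_match`, `n_diff1`,
#'   `n_diff2`, `concordance` (NA where nothing was comparable).
#' @export
concordance_counts <- function(g_seq, g_arr, axis = c("sample", "site")) {
  axis <- match.arg(axis)
  check_paired(g_seq, g_arr)
  d <- abs(g_seq$calls - g_arr$calls)      # NA where either call missing
  margin <- if (axis == "sample") 1L else 2L
  n_cmp <- apply(d, margin, function(z) sum(!is.na(z)))
  n_d1 <- apply(d, margin, function(z) sum(z == 1L, na.rm = TRUE))
  n_d2 <- apply(d, margin, function(z) sum(z == 2L, na.rm = TRUE))
  n_match <- n_cmp - n_d1 - n_d2
  ids <- if (axis == "sample") g_seq$samples else g_seq$sites$snp_id
  data.frame(id = ids, n_compared = n_cmp, n_match = n_match,
             n_diff1 = n_d1, n_diff2 = n_d2,
             concordance = ifelse(n_cmp > 0, n_match / n_cmp, NA_real_),
             stringsAsFactors = FALSE, row.names = NULL)
}

# Squared Pearson correlation of two paired vectors over complete pairs;
# NA when fewer than 2 complete pairs or either vector is constant.
r2_pair <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2) return(NA_real_)
  x <- x[ok]; y <- y[ok]
  if (stats::var(x) == 0 || stats::var(y) == 0) return(NA_real_)
  stats::cor(x, y)^2
}

#' Per-sample squared correlation between platforms
#'
#' The squared Pearson correlation between the two platforms' B-allele
#' counts across sites, one value per sample.
#'
#' @param g_seq,g_arr aligned [geno_matrix] pair.
#' @return named numeric vector (NA where undefined: < 2 complete pairs or
#'   a constant vector).
#' @export
r2_per_sample <- function(g_seq, g_arr) {
  check_paired(g_seq, g_arr)
  out <- vapply(seq_along(g_seq$samples), function(k)
    r2_pair(g_seq$calls[k, ], g_arr$calls[k, ]), numeric(1))
  stats::setNames(out, g_seq$samples)
}

#' Per-SNP squared correlation between platforms
#'
#' As [r2_per_sample()] with the roles of samples and sites exchanged.
#' @param g_seq,g_arr aligned [geno_matrix] pair.
#' @return named numeric vector over sites.
#' @export
r2_per_snp <- function(g_seq, g_arr) {
  check_paired(g_seq, g_arr)
  out <- vapply(seq_len(nrow(g_seq$sites)), function(i)
    r2_pair(g_seq$calls[, i], g_arr$calls[, i]), numeric(1))
  stats::setNames(out, g_seq$sites$snp_id)
}

#' Cohen's kappa with squared weights for two genotype vectors
#'
#' Agreement between two raters over the ordinal categories \{0, 1, 2\}
#' using squared disagreement weights d_ij = (i - j)^2 / (K - 1)^2:
#' kappa = 1 - observed weighted disagreement / expected weighted
#' disagreement under marginal independence. When the expected disagreement
#' is zero (both raters constant and equal) kappa is 1 by convention.
#'
#' @param x,y genotype vectors in \{0, 1, 2, NA\}; pairwise-complete pairs
#'   are used.
#' @return kappa in \[-1, 1\]; NA if no complete pair exists.
#' @export
weighted_kappa <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  if (!any(ok)) return(NA_real_)
  x <- factor(x[ok], levels = 0:2)
  y <- factor(y[ok], levels = 0:2)
  n <- length(x)
  tab <- table(x, y) / n
  d <- outer(0:2, 0:2, function(i, j) (i - j)^2 / 4)
  obs <- sum(tab * d)
  expd <- sum(outer(rowSums(tab), colSums(tab)) * d)
  if (expd == 0) {
    log_info("weighted_kappa: zero expected disagreement (both raters constant); kappa = 1 by convention")
    return(1)
  }
  1 - obs / expd
}

#' Per-sample squared-weight kappa between platforms
#'
#' @param g_seq,g_arr aligned [geno_matrix] pair.
#' @return named numeric vector, one kappa per sample.
#' @export
kappa_per_sample <- function(g_seq, g_arr) {
  check_paired(g_seq, g_arr)
  out <- vapply(seq_along(g_seq$samples), function(k)
    weighted_kappa(g_seq$calls[k, ], g_arr$calls[k, ]), numeric(1))
  stats::setNames(out, g_seq$samples)
}

#' Full concordance report for an aligned platform pair
#'
#' Bundles the per-sample and per-site concordance decompositions, r2 and
#' kappa, plus summary means. Undefined (NA) r2/kappa entries are excluded
#' from the summary means and counted.
#'
#' @param g_seq,g_arr aligned [geno_matrix] pair.
#' @return object of class `concordance_report`: list with `by_sample`,
#'   `by_site` (data.frames), `kappa_pooled` (kappa over all calls pooled)
#'   and `summary` (named numeric vector).
#' @export
concordance_report <- function(g_seq, g_arr) {
  by_sample <- concordance_counts(g_seq, g_arr, "sample")
  by_sample$r2 <- unname(r2_per_sample(g_seq, g_arr))
  by_sample$kappa <- unname(kappa_per_sample(g_seq, g_arr))
  by_site <- concordance_counts(g_seq, g_arr, "site")
  by_site$r2 <- unname(r2_per_snp(g_seq, g_arr))
  kp <- weighted_kappa(as.vector(g_seq$calls), as.vector(g_arr$calls))
  total_cmp <- sum(by_sample$n_compared)
  summary <- c(
    n_samples = nrow(by_sample), n_sites = nrow(by_site),
    n_compared = total_cmp,
    overall_concordance = if (total_cmp > 0) sum(by_sample$n_match) / total_cmp else NA_real_,
    mean_sample_concordance = mean(by_sample$concordance, na.rm = TRUE),
    mean_site_concordance = mean(by_site$concordance, na.rm = TRUE),
    mean_sample_r2 = mean(by_sample$r2, na.rm = TRUE),
    mean_site_r2 = mean(by_site$r2, na.rm = TRUE),
    mean_sample_kappa = mean(by_sample$kappa, na.rm = TRUE),
    kappa_pooled = kp,
    n_sample_r2_undefined = sum(is.na(by_sample$r2)),
    n_site_r2_undefined = sum(is.na(by_site$r2)))
  structure(list(by_sample = by_sample, by_site = by_site,
                 kappa_pooled = kp, summary = summary),
            class = "concordance_report")
}

#' @exportS3Method base::print
print.concordance_report <- function(x, ...) {
  s <- x$summary
  cat("Cross-platform concordance report\n")
  cat(sprintf("  %d samples x %d sites, %d genotype pairs compared\n",
              s[["n_samples"]], s[["n_sites"]], s[["n_compared"]]))
  cat(sprintf("  overall concordance: %.2f%%\n", 100 * s[["overall_concordance"]]))
  cat(sprintf("  mean per-sample R2:  %.4f   kappa (pooled): %.4f\n",
              s[["mean_sample_r2"]], s[["kappa_pooled"]]))
  invisible(x)
}

#' Flag sites with low agreement
#'
#' @param by_site per-site data.frame from [concordance_report()].
#' @param conc_min concordance cutoff (strict `<`, default 0.90).
#' @param r2_min r2 cutoff (strict `<`, default 0.8).
#' @return list with `low_concordance`, `low_r2` (snp_id vectors), `union`,
#'   and `n_r2_undefined` (sites whose r2 could not be computed; they are
#'   in neither list).
#' @export
flag_low_agreement <- function(by_site, conc_min = 0.90, r2_min = 0.8) {
  lc <- by_site$id[!is.na(by_site$concordance) & by_site$concordance < conc_min]
  lr <- by_site$id[!is.na(by_site$r2) & by_site$r2 < r2_min]
  list(low_concordance = lc, low_r2 = lr, union = union(lc, lr),
       n_r2_undefined = sum(is.na(by_site$r2)))
}
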