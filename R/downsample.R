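# Coverage down-sampling by binomial thinning of allele depths, a minimal
# biallelic likelihood caller, and the full-vs-thinned re-evaluation.

#' Thin allele depths to a target coverage
#'
#' Entries with total depth d > target keep each read independently with
#' probability target/d (reference and alternate counts thinned as
#' independent binomials); entries with d <= target are unchanged.
#'
#' @param ad an [allele_depth] matrix pair.
#' @param target target mean depth (> 0), e.g. 30.
#' @param seed RNG seed.
#' @return a thinned [allele_depth].
#' @export
thin_depths <- function(ad, target, seed = 1L) {
  if (target <= 0) fail("thin_depths: target must be > 0")
  r <- ad$ref; a <- ad$alt
  d <- r + a
  with_seed(seed, {
    thin <- !is.na(d) & d > target
    p <- target / d[thin]
    r[thin] <- stats::rbinom(sum(thin), r[thin], p)
    a[thin] <- stats::rbinom(sum(thin), a[thin], p)
  })
  allele_depth(r, a)
}

#' Call genotypes from allele depths with a flat-prior likelihood model
#'
#' Per entry with r reference and a alternate reads (d = r + a), genotype
#' likelihoods under per-read error probability e are
#' L(0) proportional to e^a (1-e)^r, L(1) to 0.5^d, L(2) to e^r (1-e)^a.
#' The call is the maximum-likelihood genotype (exact ties call the
#' heterozygote); QUAL is 10 log10 of the flat-prior posterior odds of the
#' best genotype against the rest, capped at 99. Entries with d below
#' `min_depth` are no-calls.
#'
#' @param ad an [allele_depth], or a numeric vector/matrix of reference
#'   counts (then `alt` must be given).
#' @param alt alternate counts when `ad` is not an [allele_depth].
#' @param error_rate per-read error probability e, in (0, 0.5).
#' @param min_depth minimum depth to emit a call (default 4).
#' @return list with `genotype` (same shape as input, values 0/1/2/NA) and
#'   `qual` (phred, NA where no call).
#' @export
call_genotype_from_ad <- function(ad, alt = NULL, error_rate = 0.01,
                                  min_depth = 4) {
  if (error_rate <= 0 || error_rate >= 0.5)
    fail("call_genotype_from_ad: error_rate must be in (0, 0.5)")
  if (inherits(ad, "allele_depth")) {
    r <- ad$ref; a <- ad$alt
  } else {
    r <- ad; a <- alt
    if (is.null(a)) fail("call_genotype_from_ad: alt counts required")
  }
  dm <- dim(r)
  dn <- dimnames(r)
  r <- as.numeric(r); a <- as.numeric(a)
  d <- r + a
  nocall_na <- is.na(d)
  r[nocall_na] <- 0; a[nocall_na] <- 0; d[nocall_na] <- 0
  e <- error_rate
  l0 <- a * log(e) + r * log1p(-e)
  l1 <- d * log(0.5)
  l2 <- r * log(e) + a * log1p(-e)
  L <- cbind(l0, l1, l2)
  best <- max.col(L, ties.method = "first")
  lmax <- L[cbind(seq_along(d), best)]
  # exact tie in likelihoods -> heterozygote
  tie <- (L[, 1] == lmax) + (L[, 2] == lmax) + (L[, 3] == lmax) > 1
  best[tie] <- 2L
  post <- exp(L - lmax)
  psum <- rowSums(post)
  pbest <- post[cbind(seq_along(d), best)] / psum
  qual <- ifelse(pbest >= 1, 99, pmin(99, 10 * log10(pbest / (1 - pbest))))
  geno <- best - 1L
  nocall <- nocall_na | d < min_depth
  geno[nocall] <- NA_integer_
  qual[nocall] <- NA_real_
  shape <- function(x) { dim(x) <- dm; dimnames(x) <- dn; x }
  list(genotype = shape(as.integer(geno)), qual = shape(qual))
}

#' Closed-form heterozygote miscall probability of the likelihood caller
#'
#' For a true heterozygote sequenced at fixed depth d, the alternate read
#' count is Binomial(d, 1/2); the caller misses the heterozygote exactly
#' when the count falls outside the likelihood-ratio decision band. This
#' returns the binomial tail mass outside that band (the oracle used to
#' check the empirical miscall rate).
#'
#' @param depth fixed read depth d.
#' @param error_rate caller error probability e.
#' @return probability of calling a true het as a homozygote.
#' @export
het_miscall_probability <- function(depth, error_rate) {
  a <- 0:depth
  calls <- call_genotype_from_ad(depth - a, a, error_rate = error_rate,
                                 min_depth = 0)$genotype
  sum(stats::dbinom(a[calls != 1L], depth, 0.5))
}

#' Re-evaluate concordance and relatedness at a reduced coverage
#'
#' Runs the down-sampling experiment on simulated sequencing observations:
#' thin allele depths to `target`, re-call genotypes, and compare both the
#' full-coverage and thinned call sets against the array platform, plus the
#' GRM correlation between the two coverage levels.
#'
#' @param seqobs an [observe_sequencing()] result (full coverage).
#' @param arr the array [geno_matrix] aligned to the same truth.
#' @param target target coverage (default 30).
#' @param cfg the [sim_config()] used (for caller parameters).
#' @param seed thinning seed.
#' @return object of class `coverage_comparison`: list with `full`
#'   and `thinned` [concordance_report()]s against the array,
#'   `concordance_delta` (full minus thinned overall concordance),
#'   `grm_r` (GRM correlation between full and thinned sequencing calls)
#'   and `thinned_mean_depth`.
#' @export
reevaluate_at_coverage <- function(seqobs, arr, target = 30,
                                   cfg = sim_config(), seed = 1L) {
  ad30 <- thin_depths(seqobs$allele_depth, target, seed = seed)
  called <- call_genotype_from_ad(ad30, error_rate = max(cfg$seq_read_error, 1e-3),
                                  min_depth = cfg$min_call_depth)
  g30 <- seqobs$genotypes
  g30$calls <- called$genotype
  pair_full <- intersect_common_sites(seqobs$genotypes, arr)
  pair_thin <- intersect_common_sites(g30, arr)
  rep_full <- concordance_report(pair_full$seq, pair_full$arr)
  rep_thin <- concordance_report(pair_thin$seq, pair_thin$arr)
  auto_full <- subset_geno(seqobs$genotypes,
                           sites = which(!(seqobs$genotypes$sites$chrom %in% c("X", "Y"))))
  auto_thin <- subset_geno(g30, sites = which(!(g30$sites$chrom %in% c("X", "Y"))))
  grm_r <- grm_correlation(compute_grm(auto_full), compute_grm(auto_thin))$r
  structure(list(full = rep_full, thinned = rep_thin,
                 concordance_delta = rep_full$summary[["overall_concordance"]] -
                   rep_thin$summary[["overall_concordance"]],
                 grm_r = grm_r,
                 thinned_mean_depth = mean(ad30$ref + ad30$alt, na.rm = TRUE)),
            class = "coverage_comparison")
}

#' @exportS3Method base::print
print.coverage_comparison <- function(x, ...) {
  cat(sprintf("Coverage comparison: full %.2f%% vs thinned %.2f%% concordance (delta %.3f pp)\n",
              100 * x$full$summary[["overall_concordance"]],
              100 * x$thinned$summary[["overall_concordance"]],
              100 * x$concordance_delta))
  cat(sprintf("  thinned mean depth %.1fX; GRM r(full, thinned) = %.4f\n",
              x$thinned_mean_depth, x$grm_r))
  invisible(x)
}
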