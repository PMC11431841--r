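# Genotype QC: trio Mendelian screening, call-rate exclusion, depth/quality
# site flags, IQR depth outliers, off-centre capture flags, low-MQ region
# detection, and the problematic-SNP table. Filtering order follows the
# evaluation protocol: duplicate resolution -> Mendelian filter -> sample
# call-rate filter.

#' Mendelian consistency of a single trio genotype combination
#'
#' A trio (sire f, dam m, offspring c) of B-allele counts is consistent when
#' c can be formed from one allele of each parent: parent 0 transmits only
#' the A allele, parent 2 only B, parent 1 either.
#'
#' @param f,m,c genotypes in \{0, 1, 2\} (vectorized; NA propagates to NA).
#' @return logical; NA where any member is missing (the trio is
#'   uninformative there, not an error).
#' @export
mendelian_consistent <- function(f, m, c) {
  # transmissible B-allele set per parent: 0 -> {0}, 1 -> {0,1}, 2 -> {1}
  lo <- (f == 2L) + (m == 2L)          # minimum B alleles the child can get
  hi <- (f >= 1L) + (m >= 1L)          # maximum
  ok <- c >= lo & c <= hi
  ok[is.na(f) | is.na(m) | is.na(c)] <- NA
  ok
}

#' Per-site Mendelian-inconsistency rates over a trio set
#'
#' @param g a [geno_matrix].
#' @param trios data.frame with `offspring`, `sire`, `dam` sample ids, all
#'   present in `g`.
#' @return data.frame per site: `snp_id`, `n_informative` (trios with all
#'   three calls non-missing), `n_inconsistent`, `mi_rate` (NA when no trio
#'   is informative). X/Y sites are not assessed (`mi_rate` NA) since the
#'   autosomal transmission rule does not apply there.
#' @export
mendelian_inconsistency <- function(g, trios) {
  ids <- unique(unlist(trios[, c("offspring", "sire", "dam")]))
  missing_ids <- setdiff(ids, g$samples)
  if (length(missing_ids))
    fail("mendelian_inconsistency: trio sample(s) absent from matrix: %s",
         paste(utils::head(missing_ids, 5), collapse = ", "))
  n_site <- nrow(g$sites)
  n_inf <- integer(n_site)
  n_bad <- integer(n_site)
  for (t in seq_len(nrow(trios))) {
    ok <- mendelian_consistent(g$calls[trios$sire[t], ],
                               g$calls[trios$dam[t], ],
                               g$calls[trios$offspring[t], ])
    inf <- !is.na(ok)
    n_inf <- n_inf + inf
    n_bad <- n_bad + (inf & !ok)
  }
  mi <- ifelse(n_inf > 0, n_bad / n_inf, NA_real_)
  sex_site <- g$sites$chrom %in% c("X", "Y")
  mi[sex_site] <- NA_real_
  data.frame(snp_id = g$sites$snp_id, n_informative = ifelse(sex_site, 0L, n_inf),
             n_inconsistent = ifelse(sex_site, 0L, n_bad), mi_rate = mi,
             stringsAsFactors = FALSE)
}

#' Remove sites with high Mendelian inconsistency
#'
#' @param g a [geno_matrix].
#' @param trios trio data.frame (see [mendelian_inconsistency()]).
#' @param threshold sites with `mi_rate` strictly above this are removed
#'   (default 0.05, i.e. MI > 5\%).
#' @return the filtered [geno_matrix]; attributes `mi` (the per-site MI
#'   table) and `removed` (snp_ids dropped). Sites with no informative trio
#'   are kept and counted in the message.
#' @export
mi_filter <- function(g, trios, threshold = 0.05) {
  if (!NROW(trios)) fail("mi_filter: no trios supplied")
  mi <- mendelian_inconsistency(g, trios)
  drop <- !is.na(mi$mi_rate) & mi$mi_rate > threshold
  n_uninf <- sum(is.na(mi$mi_rate) & !(g$sites$chrom %in% c("X", "Y")))
  log_info("mi_filter: removed %d site(s) with MI > %.2f; %d autosomal site(s) had no informative trio (kept)",
           sum(drop), threshold, n_uninf)
  out <- subset_geno(g, sites = which(!drop))
  attr(out, "mi") <- mi
  attr(out, "removed") <- g$sites$snp_id[drop]
  out
}

#' Drop samples below a call-rate threshold
#'
#' @param g a [geno_matrix].
#' @param threshold samples with call rate strictly below this are removed
#'   (default 0.90).
#' @return filtered [geno_matrix]; attribute `removed` lists dropped ids.
#' @export
sample_call_rate_filter <- function(g, threshold = 0.90) {
  cr <- sample_call_rate(g)
  keep <- cr >= threshold
  if (!any(keep)) fail("sample_call_rate_filter: all samples below threshold %.2f", threshold)
  if (any(!keep))
    log_info("sample_call_rate_filter: dropped %d sample(s) with call rate < %.2f: %s",
             sum(!keep), threshold, paste(g$samples[!keep], collapse = ", "))
  out <- subset_geno(g, samples = which(keep))
  attr(out, "removed") <- g$samples[!keep]
  out
}

#' Site pass flags from depth and quality
#'
#' A site passes when its mean SNP depth is at least `dp_min` and its QUAL
#' strictly exceeds `qual_min`. Flags annotate; they never remove sites.
#'
#' @param stats site-stats data.frame with `depth_snp` and `qual`.
#' @param dp_min minimum depth (default 100).
#' @param qual_min QUAL must be strictly greater (default 20).
#' @return logical vector `site_pass`.
#' @export
site_pass_flags <- function(stats, dp_min = 100, qual_min = 20) {
  stats$depth_snp >= dp_min & stats$qual > qual_min
}

#' IQR depth-outlier flags
#'
#' Flags sites whose mean depth lies outside
#' \[Q1 - k IQR, Q3 + k IQR\]; quartiles use linear interpolation
#' (`stats::quantile` type 7).
#'
#' @param depths per-site mean depth vector (length >= 4).
#' @param k whisker multiplier (default 1.5).
#' @return factor per site with levels `none`, `low`, `high`.
#' @export
iqr_depth_outliers <- function(depths, k = 1.5) {
  if (length(depths) < 4) fail("iqr_depth_outliers: need >= 4 sites")
  q <- stats::quantile(depths, c(0.25, 0.75), na.rm = TRUE, type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  flag <- rep("none", length(depths))
  flag[depths < q[1] - k * iqr] <- "low"
  flag[depths > q[2] + k * iqr] <- "high"
  factor(flag, levels = c("none", "low", "high"))
}

#' Central-capture flags
#'
#' A SNP is judged captured centrally when its depth at the SNP base is at
#' least the mean depth of its ~250 bp target region; `depth_snp <
#' depth_ave` marks off-centre capture.
#'
#' @param stats site-stats data.frame with `depth_snp` and `depth_ave`.
#' @return logical `central` per site; NA (with a message) where
#'   `depth_ave` is zero or missing.
#' @export
central_capture_flags <- function(stats) {
  bad <- is.na(stats$depth_ave) | stats$depth_ave <= 0
  if (any(bad))
    log_info("central_capture_flags: %d site(s) with depth_ave <= 0 or missing (central undefined)",
             sum(bad))
  central <- stats$depth_snp >= stats$depth_ave
  central[bad] <- NA
  central
}

#' Detect low mapping-quality regions
#'
#' Scans each chromosome in position order for maximal runs of at least
#' `min_run` consecutive sites with MQ below `mq_threshold`; the reported
#' interval starts at the first such SNP and ends at the last.
#'
#' @param stats site-stats data.frame with `chrom`, `pos`, `mq`.
#' @param mq_threshold MQ cutoff (default 50, strict `<`).
#' @param min_run minimum run length to report (default 3).
#' @return data.frame `chrom`, `start`, `end` (1-based closed), `n_sites`,
#'   `mean_mq`.
#' @export
detect_low_mq_regions <- function(stats, mq_threshold = 50, min_run = 3) {
  out <- list()
  for (ch in unique(stats$chrom)) {
    s <- stats[stats$chrom == ch, ]
    s <- s[order(s$pos), ]
    low <- !is.na(s$mq) & s$mq < mq_threshold
    r <- rle(low)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values & r$lengths >= min_run)) {
      idx <- starts[j]:ends[j]
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start = s$pos[starts[j]], end = s$pos[ends[j]],
        n_sites = length(idx), mean_mq = mean(s$mq[idx]),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), n_sites = integer(0),
                      mean_mq = numeric(0)))
  do.call(rbind, out)
}

#' Write detected regions as BED
#'
#' Internal coordinates are 1-based closed; BED is 0-based half-open, so
#' `start` is decremented (stated in the header comment of the file).
#' @param regions data.frame from [detect_low_mq_regions()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_regions_bed <- function(regions, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# BED (0-based half-open) converted from 1-based closed intervals", con)
  if (nrow(regions))
    utils::write.table(data.frame(regions$chrom, regions$start - 1L, regions$end,
                                  sprintf("lowMQ_%.1f", regions$mean_mq)),
                       con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Assemble the problematic-SNP table
#'
#' A site is problematic when its cross-platform concordance is at or below
#' `conc_threshold`, when it is an IQR depth outlier (either direction), or
#' when it was not captured centrally. One row per problematic site; the
#' `reasons` column lists every criterion that fired.
#'
#' @param stats site-stats data.frame (`chrom`, `pos`, `snp_id`,
#'   `depth_snp`, `depth_ave`, `maf`).
#' @param concordance per-site concordance vector aligned with `stats`
#'   (NA allowed for sites never compared).
#' @param depth_flag factor from [iqr_depth_outliers()].
#' @param central logical from [central_capture_flags()].
#' @param mi_rate optional per-site MI rates to carry along.
#' @param both_callers optional logical marker column.
#' @param conc_threshold low-concordance cutoff (default 0.50, `<=`).
#' @return data.frame of problematic sites with a semicolon-joined
#'   `reasons` column drawn from \{low_concordance, depth_outlier_low,
#'   depth_outlier_high, non_central\}.
#' @export
build_problematic_table <- function(stats, concordance, depth_flag, central,
                                    mi_rate = NULL, both_callers = NULL,
                                    conc_threshold = 0.50) {
  n <- nrow(stats)
  stopifnot(length(concordance) == n, length(depth_flag) == n,
            length(central) == n)
  low_conc <- !is.na(concordance) & concordance <= conc_threshold
  dlow <- depth_flag == "low"
  dhigh <- depth_flag == "high"
  noncen <- !is.na(central) & !central
  any_problem <- low_conc | dlow | dhigh | noncen
  idx <- which(any_problem)
  if (!length(idx)) {
    return(data.frame(chrom = character(0), pos = integer(0),
                      snp_id = character(0), reasons = character(0),
                      concordance = numeric(0), mi_rate = numeric(0),
                      maf = numeric(0), depth_snp = numeric(0),
                      depth_ave = numeric(0), central = logical(0),
                      both_callers = logical(0), stringsAsFactors = FALSE))
  }
  reasons <- vapply(idx, function(i) {
    paste(c(if (low_conc[i]) "low_concordance",
            if (dlow[i]) "depth_outlier_low",
            if (dhigh[i]) "depth_outlier_high",
            if (noncen[i]) "non_central"), collapse = ";")
  }, character(1))
  out <- data.frame(chrom = stats$chrom[idx], pos = stats$pos[idx],
                    snp_id = stats$snp_id[idx], reasons = reasons,
                    concordance = concordance[idx],
                    mi_rate = if (is.null(mi_rate)) NA_real_ else mi_rate[idx],
                    maf = stats$maf[idx],
                    depth_snp = stats$depth_snp[idx],
                    depth_ave = stats$depth_ave[idx],
                    central = central[idx],
                    both_callers = if (is.null(both_callers)) NA else both_callers[idx],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
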