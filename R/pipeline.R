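# End-to-end orchestration: io -> qc -> concordance -> relatedness ->
# downsample, with a run manifest that mirrors the filter accounting
# (targeted, called, duplicate-dropped, MI-removed, sample-dropped, common,
# compared).

#' Evaluation configuration
#'
#' Bundles input paths, thresholds and the root seed for a full run. All
#' thresholds default to the evaluation protocol's values.
#'
#' @param vcf,array,trios,probes input file paths (probes optional, "" to
#'   skip; trios optional, "" to skip the Mendelian filter and parentage).
#' @param outdir report directory ("" for no file output).
#' @param mi_threshold Mendelian-inconsistency removal cutoff (default 0.05).
#' @param sample_call_rate sample call-rate cutoff (default 0.90).
#' @param conc_flag,r2_flag low-agreement flag cutoffs (default 0.90 / 0.8).
#' @param conc_problem problematic-SNP concordance cutoff (default 0.50).
#' @param iqr_k IQR whisker multiplier (default 1.5).
#' @param mq_threshold,min_run low-MQ region rule (default MQ < 50, run >= 3).
#' @param dp_min,qual_min site pass thresholds (default depth >= 100,
#'   QUAL > 20).
#' @param tau parentage opposing-homozygote acceptance threshold (0.01).
#' @param het_max,y_min_frac sex-assignment thresholds (0.05, 0.5).
#' @param par_start X positions at or above this are treated as
#'   pseudoautosomal and excluded from sex inference (default
#'   [SIM_PAR_START]).
#' @param downsample_target coverage for the thinning experiment (30; 0
#'   disables it).
#' @param caller_error,min_call_depth likelihood-caller parameters for
#'   re-calling thinned depths.
#' @param seed root seed; stage seeds are derived from it.
#' @return object of class `evaluation_config`.
#' @export
evaluation_config <- function(vcf, array, trios = "", probes = "",
                              outdir = "",
                              mi_threshold = 0.05, sample_call_rate = 0.90,
                              conc_flag = 0.90, r2_flag = 0.8,
                              conc_problem = 0.50, iqr_k = 1.5,
                              mq_threshold = 50, min_run = 3,
                              dp_min = 100, qual_min = 20,
                              tau = 0.01, het_max = 0.05, y_min_frac = 0.5,
                              par_start = SIM_PAR_START,
                              downsample_target = 30,
                              caller_error = 0.01, min_call_depth = 4,
                              seed = 1L) {
  cfg <- as.list(environment())
  rng <- c(mi_threshold = mi_threshold, sample_call_rate = sample_call_rate,
           conc_flag = conc_flag, conc_problem = conc_problem, tau = tau,
           het_max = het_max, y_min_frac = y_min_frac)
  if (any(rng < 0 | rng > 1))
    fail("evaluation_config: fraction thresholds must lie in [0,1]")
  if (iqr_k < 0 || min_run < 1 || dp_min < 0)
    fail("evaluation_config: invalid qc thresholds")
  structure(cfg, class = "evaluation_config")
}

#' Run the full cross-platform evaluation
#'
#' Executes the whole pipeline: read both platforms; resolve duplicate
#' sites; Mendelian-filter and call-rate-filter the array; align on common
#' SNPs; concordance/r2/kappa; depth and MQ quality control with the
#' problematic-SNP table; per-platform VanRaden GRMs and their correlation;
#' sex assignment and (when trios are given) parentage verification; and the
#' down-sampling re-evaluation when allele depths are present. Reports are
#' written to `cfg$outdir` when set.
#'
#' @param cfg an [evaluation_config()].
#' @return object of class `genotype_evaluation`: list with `concordance`
#'   (a [concordance_report()]), `flags`, `site_qc` (site-stats with QC
#'   columns), `problematic`, `regions`, `grm` (list seq/arr/correlation),
#'   `sex`, `parentage`, `downsample`, `manifest`.
#' @export
run_evaluation <- function(cfg) {
  stopifnot(inherits(cfg, "evaluation_config"))
  manifest <- list(seed = cfg$seed)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      fail("run_evaluation: stage '%s' failed: %s", name, conditionMessage(e)))
  }

  vcfdat <- stage("read_vcf", read_vcf_genotypes(cfg$vcf))
  g_seq <- vcfdat$genotypes
  arr_raw <- stage("read_array", read_array_matrix(cfg$array))
  manifest$input_md5 <- unname(tools::md5sum(c(cfg$vcf, cfg$array)))
  manifest$n_seq_sites_called <- nrow(g_seq$sites)
  manifest$n_seq_records_skipped <- vcfdat$n_skipped
  manifest$n_array_sites <- nrow(arr_raw$sites)

  arr <- stage("resolve_duplicates", resolve_duplicate_sites(arr_raw, seed = cfg$seed + 11L))
  manifest$n_array_duplicates_dropped <- length(attr(arr, "dropped"))
  g_seq <- stage("resolve_duplicates", resolve_duplicate_sites(g_seq, seed = cfg$seed + 12L))

  trios <- NULL
  if (nzchar(cfg$trios)) {
    trios <- stage("read_trios", read_trios(cfg$trios))
    present <- trios$offspring %in% arr$samples & trios$sire %in% arr$samples &
      trios$dam %in% arr$samples
    trios <- trios[present, , drop = FALSE]
  }
  mi_tab <- NULL
  if (!is.null(trios) && nrow(trios)) {
    arr <- stage("mi_filter", mi_filter(arr, trios, threshold = cfg$mi_threshold))
    mi_tab <- attr(arr, "mi")
    manifest$n_mi_removed <- length(attr(arr, "removed"))
  } else {
    manifest$n_mi_removed <- 0L
  }
  arr <- stage("sample_call_rate", sample_call_rate_filter(arr, cfg$sample_call_rate))
  manifest$samples_dropped_call_rate <- attr(arr, "removed")

  pair <- stage("intersect", intersect_common_sites(g_seq, arr))
  manifest$n_common_sites <- nrow(pair$seq$sites)
  manifest$n_common_samples <- length(pair$seq$samples)
  manifest$n_allele_swapped <- pair$n_swapped
  manifest$n_allele_mismatch_dropped <- pair$n_mismatch

  conc <- stage("concordance", concordance_report(pair$seq, pair$arr))
  manifest$n_compared <- conc$summary[["n_compared"]]
  flags <- flag_low_agreement(conc$by_site, cfg$conc_flag, cfg$r2_flag)

  # site QC on the sequencing platform's called sites
  stats <- vcfdat$site_stats
  stats <- stats[match(g_seq$sites$snp_id, stats$snp_id), , drop = FALSE]
  stats$depth_flag <- iqr_depth_outliers(stats$depth_snp, k = cfg$iqr_k)
  stats$central <- central_capture_flags(stats)
  stats$site_pass <- site_pass_flags(stats, cfg$dp_min, cfg$qual_min)
  regions <- detect_low_mq_regions(stats, cfg$mq_threshold, cfg$min_run)
  site_conc <- conc$by_site$concordance[match(stats$snp_id, conc$by_site$id)]
  mi_aligned <- if (!is.null(mi_tab)) mi_tab$mi_rate[match(stats$snp_id, mi_tab$snp_id)]
  problematic <- build_problematic_table(stats, site_conc, stats$depth_flag,
                                         stats$central, mi_rate = mi_aligned,
                                         conc_threshold = cfg$conc_problem)
  manifest$n_problematic <- nrow(problematic)
  manifest$n_low_mq_regions <- nrow(regions)

  auto <- which(!(pair$seq$sites$chrom %in% c("X", "Y")))
  grm <- NULL
  if (length(auto) >= 2) {
    grm_seq <- stage("grm", compute_grm(subset_geno(pair$seq, sites = auto)))
    grm_arr <- stage("grm", compute_grm(subset_geno(pair$arr, sites = auto)))
    grm <- list(seq = grm_seq, arr = grm_arr,
                correlation = grm_correlation(grm_seq, grm_arr))
  }

  x_np <- which(g_seq$sites$chrom == "X" & g_seq$sites$pos < cfg$par_start)
  y_idx <- which(g_seq$sites$chrom == "Y")
  sex <- NULL
  if (length(y_idx) >= 1 && length(x_np) >= 10)
    sex <- stage("sex", assign_sex(g_seq, y_idx, x_np, cfg$het_max, cfg$y_min_frac))

  parentage <- NULL
  if (!is.null(trios) && nrow(trios)) {
    sexes <- if (!is.null(sex)) stats::setNames(sex$assigned_sex, sex$sample)
    keep_off <- trios$offspring[trios$offspring %in% pair$seq$samples]
    if (length(keep_off))
      parentage <- stage("parentage",
        assign_parents(pair$seq, keep_off, pair$seq$samples, tau = cfg$tau,
                       sexes = sexes))
  }

  downsample <- NULL
  if (cfg$downsample_target > 0 && any(!is.na(vcfdat$allele_depth$ref))) {
    seqobs <- list(allele_depth = vcfdat$allele_depth,
                   genotypes = vcfdat$genotypes, site_stats = vcfdat$site_stats)
    class(seqobs) <- "seq_observation"
    downsample <- stage("downsample",
      reevaluate_at_coverage(seqobs, arr, target = cfg$downsample_target,
                             cfg = sim_config(seq_read_error = cfg$caller_error,
                                              min_call_depth = cfg$min_call_depth),
                             seed = cfg$seed + 30L))
  }

  chrom_summary <- summarize_per_chromosome(stats)
  res <- structure(list(concordance = conc, flags = flags, site_qc = stats,
                        problematic = problematic, regions = regions,
                        grm = grm, sex = sex, parentage = parentage,
                        downsample = downsample,
                        chrom_summary = chrom_summary,
                        manifest = manifest, config = cfg),
                   class = "genotype_evaluation")
  if (nzchar(cfg$outdir)) write_evaluation_reports(res, cfg$outdir)
  res
}

#' Per-chromosome summary of called sites
#'
#' @param stats site-stats data.frame with `chrom`, `pos`, `maf`,
#'   `depth_snp`, `mq` and (optionally) QC flag columns.
#' @return data.frame per chromosome: `n_sites`, `mean_maf` (over
#'   non-missing MAF), `mean_spacing` (mean successive position difference;
#'   NA for single-site chromosomes), `mean_depth`, `mean_mq`, `n_flagged`
#'   (depth outliers or off-centre sites, 0 when flags absent).
#' @export
summarize_per_chromosome <- function(stats) {
  out <- lapply(split(stats, stats$chrom), function(s) {
    pos <- sort(s$pos)
    data.frame(chrom = s$chrom[1], n_sites = nrow(s),
               mean_maf = mean(s$maf, na.rm = TRUE),
               mean_spacing = if (nrow(s) > 1) mean(diff(pos)) else NA_real_,
               mean_depth = mean(s$depth_snp, na.rm = TRUE),
               mean_mq = mean(s$mq, na.rm = TRUE),
               n_flagged = sum((if ("depth_flag" %in% names(s)) s$depth_flag != "none" else FALSE) |
                               (if ("central" %in% names(s)) !is.na(s$central) & !s$central else FALSE)),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, out)
  tab <- tab[order(match(tab$chrom, c(as.character(1:29), "X", "Y"))), ]
  rownames(tab) <- NULL
  tab
}

write_evaluation_reports <- function(res, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(x, name) utils::write.table(x, file.path(outdir, name),
                                             sep = "\t", quote = FALSE,
                                             row.names = FALSE)
  wt(res$concordance$by_sample, "concordance_by_sample.tsv")
  wt(res$concordance$by_site, "concordance_by_site.tsv")
  wt(res$problematic, "problematic_snps.tsv")
  wt(res$chrom_summary, "chromosome_summary.tsv")
  write_regions_bed(res$regions, file.path(outdir, "low_mq_regions.bed"))
  if (!is.null(res$grm)) {
    write_grm(res$grm$seq, file.path(outdir, "grm_seq.tsv"))
    write_grm(res$grm$arr, file.path(outdir, "grm_array.tsv"))
  }
  if (!is.null(res$sex)) wt(res$sex, "sex_assignment.tsv")
  if (!is.null(res$parentage)) {
    ptab <- do.call(rbind, lapply(names(res$parentage), function(o) {
      tab <- res$parentage[[o]]
      data.frame(offspring = o, tab, stringsAsFactors = FALSE)
    }))
    wt(ptab, "parentage.tsv")
  }
  m <- res$manifest
  lines <- vapply(names(m), function(k)
    paste0(k, "\t", paste(m[[k]], collapse = ",")), character(1))
  writeLines(lines, file.path(outdir, "manifest.tsv"))
  invisible(outdir)
}

#' @exportS3Method base::print
print.genotype_evaluation <- function(x, ...) {
  cat("Cross-platform genotype evaluation\n")
  print(x$concordance)
  if (!is.null(x$grm))
    cat(sprintf("  GRM correlation (seq vs array): %.4f (off-diagonal %.4f)\n",
                x$grm$correlation$r, x$grm$correlation$r_offdiag))
  cat(sprintf("  problematic SNPs: %d; low-MQ regions: %d\n",
              nrow(x$problematic), nrow(x$regions)))
  if (!is.null(x$downsample))
    cat(sprintf("  down-sampling to %gX: concordance delta %.3f pp\n",
                x$config$downsample_target, 100 * x$downsample$concordance_delta))
  invisible(x)
}

#' @export
summary.genotype_evaluation <- function(object, ...) {
  s <- object$concordance$summary
  out <- c(s,
           grm_r = if (!is.null(object$grm)) object$grm$correlation$r else NA_real_,
           grm_r_offdiag = if (!is.null(object$grm)) object$grm$correlation$r_offdiag else NA_real_,
           n_problematic = nrow(object$problematic),
           n_low_mq_regions = nrow(object$regions),
           n_flag_low_concordance = length(object$flags$low_concordance),
           n_flag_low_r2 = length(object$flags$low_r2),
           downsample_concordance_delta =
             if (!is.null(object$downsample)) object$downsample$concordance_delta else NA_real_,
           downsample_grm_r =
             if (!is.null(object$downsample)) object$downsample$grm_r else NA_real_)
  class(out) <- "summary.genotype_evaluation"
  out
}

#' @exportS3Method base::print
print.summary.genotype_evaluation <- function(x, ...) {
  y <- unclass(x)
  for (k in names(y)) cat(sprintf("%-32s %s\n", k, format(y[[k]], digits = 6)))
  invisible(x)
}
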