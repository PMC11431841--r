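# Reading/writing both platforms and aligning them on common SNPs.
# Array TSV layout: columns snp_id, chrom, pos, ref, alt, then one column per
# sample with calls in {0,1,2,NA}. Coordinates are 1-based throughout (VCF
# convention); region spans are closed intervals.

#' Read an array-platform genotype matrix from TSV
#'
#' The expected layout is one row per SNP: columns `snp_id`, `chrom`, `pos`,
#' `ref`, `alt`, then one column per sample holding B-allele counts in
#' \{0, 1, 2\} or `NA` for a no-call.
#'
#' @param path path to a tab-separated file.
#' @return a [geno_matrix] (samples x sites).
#' @export
read_array_matrix <- function(path) {
  if (!file.exists(path)) fail("read_array_matrix: no such file: %s", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("snp_id", "chrom", "pos", "ref", "alt")
  if (!all(need %in% names(tab)))
    fail("read_array_matrix: header must contain %s", paste(need, collapse = ", "))
  sample_cols <- setdiff(names(tab), need)
  if (!length(sample_cols)) fail("read_array_matrix: no sample columns")
  if (anyNA(tab$pos) || !is.numeric(tab$pos))
    fail("read_array_matrix: malformed pos at line %d",
         which(is.na(tab$pos) | !is.finite(tab$pos))[1] + 1L)
  calls <- as.matrix(tab[, sample_cols, drop = FALSE])
  suppressWarnings(storage.mode(calls) <- "integer")
  bad <- which(!is.na(calls) & !(calls %in% 0:2), arr.ind = TRUE)
  raw_bad <- which(is.na(calls) & !is.na(tab[, sample_cols, drop = FALSE]),
                   arr.ind = TRUE)
  bad <- rbind(bad, raw_bad)
  if (nrow(bad))
    fail("read_array_matrix: call outside {0,1,2,NA} at line %d (sample %s)",
         bad[1, 1] + 1L, sample_cols[bad[1, 2]])
  g <- geno_matrix(t(calls), sample_cols,
                   tab[, c("chrom", "pos", "ref", "alt", "snp_id")])
  g
}

#' Write an array-platform genotype matrix to TSV
#'
#' Inverse of [read_array_matrix()]; missing calls are written as `NA`.
#' @param g a [geno_matrix].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_array_matrix <- function(g, path) {
  tab <- data.frame(snp_id = g$sites$snp_id, chrom = g$sites$chrom,
                    pos = g$sites$pos, ref = g$sites$ref, alt = g$sites$alt,
                    t(g$calls), check.names = FALSE)
  colnames(tab)[-(1:5)] <- g$samples
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sequencing-platform genotypes from a VCF
#'
#' Parses a VCF (v4.x) with per-sample GT and, when present, AD/DP, plus
#' per-site MQ (INFO) and QUAL. Diploid GT is converted to B-allele counts
#' (0/0 -> 0, 0/1 -> 1, 1/1 -> 2, ./. -> NA). Multiallelic or symbolic
#' records are skipped and counted, as are records whose GT is not diploid.
#' The optional INFO key `DPA` (mean capture-region depth) feeds
#' `depth_ave`; absent annotations yield `NA` columns.
#'
#' @param path path to a VCF file (plain or bgzipped).
#' @return a list with elements:
#'   \describe{
#'     \item{genotypes}{a [geno_matrix]}
#'     \item{site_stats}{data.frame: `chrom`, `pos`, `snp_id`, `depth_snp`
#'       (mean per-sample depth at the SNP base), `depth_ave`, `mq`, `qual`,
#'       `maf`, `call_rate`}
#'     \item{allele_depth}{an [allele_depth] matrix pair (NA where AD absent)}
#'     \item{n_skipped}{count of records excluded (multiallelic/symbolic or
#'       non-diploid GT)}
#'   }
#' @export
read_vcf_genotypes <- function(path) {
  if (!file.exists(path)) fail("read_vcf_genotypes: no such file: %s", path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  alt <- fix[, "ALT"]
  ref <- fix[, "REF"]
  biallelic <- !grepl(",", alt) & !grepl("[<>*]", alt) & !grepl(",", ref) &
    nzchar(alt) & !is.na(alt)
  gt_raw <- vcfR::extract.gt(vcf, element = "GT")
  # Normalize separators; flag non-diploid records for skipping.
  gt_chr <- gsub("\\|", "/", gt_raw)
  ploidy_ok <- apply(gt_chr, 1, function(z) {
    z <- z[!is.na(z) & z != "." & z != "./."]
    if (!length(z)) return(TRUE)
    all(vapply(strsplit(z, "/"), length, 1L) == 2L)
  })
  keep <- biallelic & ploidy_ok
  n_skipped <- sum(!keep)
  if (n_skipped) log_info("read_vcf_genotypes: skipped %d record(s) (multiallelic/symbolic/non-diploid)", n_skipped)
  if (!any(keep)) fail("read_vcf_genotypes: no usable biallelic records in %s", path)

  gt_chr <- gt_chr[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  calls_site <- matrix(NA_integer_, nrow(gt_chr), ncol(gt_chr))
  calls_site[gt_chr == "0/0"] <- 0L
  calls_site[gt_chr %in% c("0/1", "1/0")] <- 1L
  calls_site[gt_chr == "1/1"] <- 2L
  # Hemizygous single-allele records (X/Y) encode as 0 or 2.
  calls_site[gt_chr == "0"] <- 0L
  calls_site[gt_chr == "1"] <- 2L

  snp_id <- fix[, "ID"]
  noid <- is.na(snp_id) | snp_id == "."
  snp_id[noid] <- paste0(fix[noid, "CHROM"], ":", fix[noid, "POS"])
  sites <- data.frame(chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
                      ref = fix[, "REF"], alt = fix[, "ALT"], snp_id = snp_id,
                      stringsAsFactors = FALSE)
  samples <- colnames(gt_chr)
  g <- geno_matrix(t(calls_site), samples, sites)

  ad_raw <- tryCatch(vcfR::extract.gt(vcf, element = "AD")[keep, , drop = FALSE],
                     error = function(e) NULL)
  nsite <- nrow(sites)
  ref_ct <- matrix(NA_integer_, length(samples), nsite,
                   dimnames = list(samples, snp_id))
  alt_ct <- ref_ct
  if (!is.null(ad_raw)) {
    parts <- strsplit(as.vector(ad_raw), ",", fixed = TRUE)
    r <- suppressWarnings(as.integer(vapply(parts, function(p) p[1] %||% NA_character_, "")))
    a <- suppressWarnings(as.integer(vapply(parts, function(p) if (length(p) >= 2) p[2] else NA_character_, "")))
    ref_ct[] <- t(matrix(r, nsite, length(samples)))
    alt_ct[] <- t(matrix(a, nsite, length(samples)))
  }
  dp_raw <- tryCatch(vcfR::extract.gt(vcf, element = "DP", as.numeric = TRUE)[keep, , drop = FALSE],
                     error = function(e) NULL)
  # mean depth over covered samples (depth 0 marks an absent chromosome,
  # e.g. female Y, and would bias the site mean downwards)
  mean_pos <- function(z) { z <- z[!is.na(z) & z > 0]; if (!length(z)) 0 else mean(z) }
  depth_snp <- if (!is.null(dp_raw)) {
    apply(dp_raw, 1, mean_pos)
  } else if (!is.null(ad_raw)) {
    apply(ref_ct + alt_ct, 2, mean_pos)
  } else {
    rep(NA_real_, nsite)
  }
  mq <- suppressWarnings(as.numeric(vcfR::extract.info(vcf, element = "MQ")[keep]))
  dpa <- suppressWarnings(as.numeric(vcfR::extract.info(vcf, element = "DPA")[keep]))
  qual <- suppressWarnings(as.numeric(fix[, "QUAL"]))

  stats <- data.frame(chrom = sites$chrom, pos = sites$pos, snp_id = sites$snp_id,
                      depth_snp = as.numeric(depth_snp), depth_ave = dpa,
                      mq = mq, qual = qual, maf = site_maf(g),
                      call_rate = unname(site_call_rate(g)),
                      stringsAsFactors = FALSE)
  list(genotypes = g, site_stats = stats,
       allele_depth = allele_depth(ref_ct, alt_ct), n_skipped = n_skipped)
}

#' Per-sample per-site allele read depths
#'
#' @param ref_count,alt_count integer matrices (samples x sites) of reference
#'   and alternate read counts; `NA` marks entries with no depth information.
#' @return object of class `allele_depth`: list with `ref`, `alt`.
#' @export
allele_depth <- function(ref_count, alt_count) {
  ref_count <- as.matrix(ref_count); alt_count <- as.matrix(alt_count)
  if (!identical(dim(ref_count), dim(alt_count)))
    fail("allele_depth: ref/alt dimensions differ")
  if (any(ref_count < 0, na.rm = TRUE) || any(alt_count < 0, na.rm = TRUE))
    fail("allele_depth: negative read counts")
  storage.mode(ref_count) <- "integer"
  storage.mode(alt_count) <- "integer"
  structure(list(ref = ref_count, alt = alt_count), class = "allele_depth")
}

#' @exportS3Method base::print
print.allele_depth <- function(x, ...) {
  cat(sprintf("allele_depth: %d samples x %d sites, mean depth %.1f\n",
              nrow(x$ref), ncol(x$ref), mean(x$ref + x$alt, na.rm = TRUE)))
  invisible(x)
}

#' Read a trio pedigree table
#'
#' @param path TSV with columns `offspring`, `sire`, `dam`.
#' @return data.frame of trios.
#' @export
read_trios <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("offspring", "sire", "dam")
  if (!all(need %in% names(tab)))
    fail("read_trios: columns must be %s", paste(need, collapse = ", "))
  tab[, need]
}

#' Read the probe/target-region table
#'
#' @param path TSV with columns `chrom`, `pos`, `region_start`, `region_end`
#'   (1-based, closed intervals).
#' @return data.frame of target regions.
#' @export
read_probes <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "region_start", "region_end")
  if (!all(need %in% names(tab)))
    fail("read_probes: columns must be %s", paste(need, collapse = ", "))
  if (any(tab$region_start > tab$region_end))
    fail("read_probes: region_start > region_end")
  tab
}

#' Resolve duplicated sites at the same position
#'
#' Where several SNPs share one (chrom, pos), the SNP with the higher call
#' rate is kept; exact ties are broken by a seeded uniform draw. Dropped
#' snp_ids are reported via the `"dropped"` attribute and a message.
#'
#' @param g a [geno_matrix].
#' @param seed integer seed for the tie-break draw.
#' @return a [geno_matrix] with one site per (chrom, pos), original order
#'   preserved; attribute `dropped` lists removed snp_ids.
#' @export
resolve_duplicate_sites <- function(g, seed = 1L) {
  key <- paste(g$sites$chrom, g$sites$pos, sep = ":")
  if (!anyDuplicated(key)) {
    attr(g, "dropped") <- character(0)
    return(g)
  }
  cr <- site_call_rate(g)
  keep <- with_seed(seed, {
    tie_u <- stats::runif(length(key))
    unlist(lapply(split(seq_along(key), key), function(idx) {
      best <- idx[cr[idx] == max(cr[idx])]
      if (length(best) > 1L) best <- best[which.max(tie_u[best])]
      best
    }), use.names = FALSE)
  })
  keep <- sort(keep)
  dropped <- g$sites$snp_id[-keep]
  out <- subset_geno(g, sites = keep)
  log_info("resolve_duplicate_sites: dropped %d duplicate site(s): %s",
           length(dropped), paste(utils::head(dropped, 10), collapse = ", "))
  attr(out, "dropped") <- dropped
  out
}

#' Align two platforms on their common samples and SNPs
#'
#' Both matrices are restricted to shared sample ids and shared (chrom, pos)
#' keys, in identical order. Where ref/alt are swapped between platforms the
#' second matrix's calls are recoded 0 <-> 2; sites whose allele pairs are
#' neither equal nor swapped are dropped and counted. Strand flips are not
#' resolved (both platforms are assumed to report plus-strand alleles).
#'
#' @param g_seq,g_arr two [geno_matrix] objects (sequencing and array).
#' @return list with `seq`, `arr` (aligned [geno_matrix] pair, identical
#'   sample and site indexes), `n_swapped` (allele-swap recodes) and
#'   `n_mismatch` (sites dropped for incompatible alleles).
#' @export
intersect_common_sites <- function(g_seq, g_arr) {
  shared_samples <- intersect(g_seq$samples, g_arr$samples)
  if (!length(shared_samples)) fail("intersect_common_sites: no shared samples")
  key_seq <- paste(g_seq$sites$chrom, g_seq$sites$pos, sep = ":")
  key_arr <- paste(g_arr$sites$chrom, g_arr$sites$pos, sep = ":")
  if (anyDuplicated(key_seq) || anyDuplicated(key_arr))
    fail("intersect_common_sites: resolve duplicate sites first")
  shared_keys <- intersect(key_seq, key_arr)
  if (!length(shared_keys)) fail("intersect_common_sites: no shared sites")
  i_seq <- match(shared_keys, key_seq)
  i_arr <- match(shared_keys, key_arr)
  same <- g_seq$sites$ref[i_seq] == g_arr$sites$ref[i_arr] &
    g_seq$sites$alt[i_seq] == g_arr$sites$alt[i_arr]
  swapped <- g_seq$sites$ref[i_seq] == g_arr$sites$alt[i_arr] &
    g_seq$sites$alt[i_seq] == g_arr$sites$ref[i_arr] & !same
  ok <- same | swapped
  n_mismatch <- sum(!ok)
  if (n_mismatch)
    log_info("intersect_common_sites: dropped %d site(s) with incompatible alleles",
             n_mismatch)
  i_seq <- i_seq[ok]; i_arr <- i_arr[ok]; swapped <- swapped[ok]
  if (!length(i_seq)) fail("intersect_common_sites: no shared sites with compatible alleles")
  out_seq <- subset_geno(g_seq, samples = shared_samples, sites = i_seq)
  out_arr <- subset_geno(g_arr, samples = shared_samples, sites = i_arr)
  if (any(swapped)) {
    sw <- which(swapped)
    out_arr$calls[, sw] <- 2L - out_arr$calls[, sw]
    # Adopt the sequencing platform's ref/alt orientation for the pair.
    out_arr$sites$ref[sw] <- out_seq$sites$ref[sw]
    out_arr$sites$alt[sw] <- out_seq$sites$alt[sw]
    log_info("intersect_common_sites: recoded %d allele-swapped site(s)", length(sw))
  }
  # Present both in the sequencing matrix's site naming for traceability.
  list(seq = out_seq, arr = out_arr, n_swapped = sum(swapped),
       n_mismatch = n_mismatch)
}
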