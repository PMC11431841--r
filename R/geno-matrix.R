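#' B-allele-count genotype matrix
#'
#' The common representation for both genotyping platforms: an integer matrix
#' of alternate ("B") allele copy counts with samples in rows and SNP sites in
#' columns. Calls are 0 (homozygous reference, AA), 1 (heterozygous, AB) or
#' 2 (homozygous alternate, BB); `NA` is a no-call and is never conflated
#' with 0. Site metadata travels alongside the calls.
#'
#' @param calls integer matrix, samples x sites, values in \{0, 1, 2, NA\}.
#' @param samples character vector of sample ids (length `nrow(calls)`).
#' @param sites data.frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `snp_id` (one row per column of `calls`). Positions are 1-based.
#' @return An object of class `geno_matrix`: a list with elements `calls`,
#'   `samples`, `sites`.
#' @examples
#' g <- geno_matrix(matrix(c(0L, 1L, 2L, NA), 2, 2),
#'                  samples = c("s1", "s2"),
#'                  sites = data.frame(chrom = "1", pos = c(100L, 200L),
#'                                     ref = "A", alt = "G",
#'                                     snp_id = c("snp1", "snp2")))
#' site_call_rate(g)
#' @export
geno_matrix <- function(calls, samples, sites) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (length(samples) != nrow(calls))
    fail("geno_matrix: %d samples but %d call rows", length(samples), nrow(calls))
  if (nrow(sites) != ncol(calls))
    fail("geno_matrix: %d sites but %d call columns", nrow(sites), ncol(calls))
  need <- c("chrom", "pos", "ref", "alt", "snp_id")
  miss <- setdiff(need, names(sites))
  if (length(miss)) fail("geno_matrix: sites table lacks column(s) %s",
                         paste(miss, collapse = ", "))
  bad <- calls[!is.na(calls) & !(calls %in% 0:2)]
  if (length(bad)) fail("geno_matrix: calls outside {0,1,2,NA}: %s",
                        paste(unique(bad), collapse = ", "))
  sites <- as.data.frame(sites)[, need, drop = FALSE]
  sites$chrom <- as.character(sites$chrom)
  sites$pos <- as.integer(sites$pos)
  if (any(sites$pos < 1L)) fail("geno_matrix: positions must be >= 1")
  if (any(sites$ref == sites$alt))
    fail("geno_matrix: ref equals alt at %s", sites$snp_id[sites$ref == sites$alt][1])
  rownames(calls) <- samples
  colnames(calls) <- sites$snp_id
  rownames(sites) <- NULL
  structure(list(calls = calls, samples = as.character(samples), sites = sites),
            class = "geno_matrix")
}

#' @exportS3Method base::print
print.geno_matrix <- function(x, ...) {
  cat(sprintf("geno_matrix: %d samples x %d sites\n",
              length(x$samples), nrow(x$sites)))
  cat(sprintf("  chromosomes: %s\n",
              paste(unique(x$sites$chrom), collapse = " ")))
  cr <- sample_call_rate(x)
  cat(sprintf("  mean sample call rate: %.4f\n", mean(cr)))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$calls)

#' Per-site call rate
#'
#' Fraction of samples with a non-missing call at each site.
#' @param g a [geno_matrix].
#' @return numeric vector in \[0, 1\], one entry per site, named by snp_id.
#' @export
site_call_rate <- function(g) {
  colMeans(!is.na(g$calls))
}

#' Per-sample call rate
#'
#' Fraction of sites with a non-missing call for each sample.
#' @param g a [geno_matrix].
#' @return numeric vector in \[0, 1\], one entry per sample.
#' @export
sample_call_rate <- function(g) {
  rowMeans(!is.na(g$calls))
}

#' Subset a genotype matrix
#'
#' @param g a [geno_matrix].
#' @param samples sample ids or row indices to keep (default all).
#' @param sites site column indices or snp_ids to keep (default all).
#' @return a [geno_matrix] restricted (and reordered) to the selection.
#' @export
subset_geno <- function(g, samples = NULL, sites = NULL) {
  si <- seq_along(g$samples)
  vi <- seq_len(nrow(g$sites))
  if (!is.null(samples)) {
    si <- if (is.character(samples)) match(samples, g$samples) else samples
    if (anyNA(si)) fail("subset_geno: unknown sample id(s)")
  }
  if (!is.null(sites)) {
    vi <- if (is.character(sites)) match(sites, g$sites$snp_id) else sites
    if (anyNA(vi)) fail("subset_geno: unknown site(s)")
  }
  geno_matrix(g$calls[si, vi, drop = FALSE], g$samples[si],
              g$sites[vi, , drop = FALSE])
}

#' Minor-allele frequency per site
#'
#' Allele frequencies are estimated from the non-missing calls of the matrix
#' itself (B-allele dosage mean / 2, folded to the minor allele).
#' @param g a [geno_matrix].
#' @return numeric vector in \[0, 0.5\]; NA for sites with no calls.
#' @export
site_maf <- function(g) {
  p <- colMeans(g$calls, na.rm = TRUE) / 2
  p[is.nan(p)] <- NA_real_
  pmin(p, 1 - p)
}
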