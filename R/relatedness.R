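# VanRaden genomic relationship matrices, GRM correlation, parentage by
# opposing homozygotes, and sex assignment from sex-chromosome markers.

#' VanRaden genomic relationship matrix (method 1)
#'
#' G = Z Z' / (2 * sum_i p_i (1 - p_i)) where M is the samples x sites
#' B-allele-count matrix, p_i the alternate-allele frequency at site i and
#' Z = M - 2p. Allele frequencies are estimated from the matrix itself;
#' missing calls are mean-imputed with 2 p_i (so they contribute zero to Z);
#' monomorphic sites carry no information and are dropped with a message.
#'
#' @param g a [geno_matrix] with at least 2 samples and 2 polymorphic sites.
#' @return object of class `grm`: list with `values` (symmetric matrix,
#'   dimnames = sample ids), `p` (allele frequencies used) and
#'   `n_sites_used`.
#' @export
compute_grm <- function(g) {
  if (length(g$samples) < 2) fail("compute_grm: need >= 2 samples")
  p <- colMeans(g$calls, na.rm = TRUE) / 2
  poly <- !is.na(p) & p > 0 & p < 1
  if (sum(poly) < 2) fail("compute_grm: fewer than 2 polymorphic sites")
  if (any(!poly))
    log_info("compute_grm: dropped %d monomorphic/empty site(s)", sum(!poly))
  M <- g$calls[, poly, drop = FALSE]
  p <- p[poly]
  Z <- sweep(M, 2, 2 * p)
  Z[is.na(Z)] <- 0                       # mean imputation: M_ij <- 2 p_j
  denom <- 2 * sum(p * (1 - p))
  G <- tcrossprod(Z) / denom
  dimnames(G) <- list(g$samples, g$samples)
  structure(list(values = G, p = p, n_sites_used = sum(poly)), class = "grm")
}

#' @exportS3Method base::print
print.grm <- function(x, ...) {
  cat(sprintf("VanRaden GRM: %d samples, %d sites; mean diagonal %.3f\n",
              nrow(x$values), x$n_sites_used, mean(diag(x$values))))
  invisible(x)
}

#' Pearson correlation between two GRMs
#'
#' Correlates corresponding elements of two relationship matrices built on
#' the same samples: by default the upper triangle including the diagonal.
#' The off-diagonal-only correlation is also returned, since diagonal
#' elements can inflate agreement.
#'
#' @param g1,g2 [compute_grm()] results with identical sample sets/order.
#' @return list with `r` (upper triangle incl. diagonal) and `r_offdiag`.
#' @export
grm_correlation <- function(g1, g2) {
  if (!identical(rownames(g1$values), rownames(g2$values)))
    fail("grm_correlation: sample sets/order differ")
  ut <- upper.tri(g1$values, diag = TRUE)
  off <- upper.tri(g1$values, diag = FALSE)
  # identical inputs correlate exactly, without floating-point residue
  r <- if (identical(g1$values, g2$values)) 1 else
    stats::cor(g1$values[ut], g2$values[ut])
  r_off <- if (identical(g1$values, g2$values)) 1 else
    stats::cor(g1$values[off], g2$values[off])
  list(r = r, r_offdiag = r_off)
}

#' Opposing-homozygote rate between two individuals
#'
#' Fraction of pairwise-complete sites where one individual is homozygous
#' reference and the other homozygous alternate (genotype pair \{0,2\}),
#' which is impossible between parent and offspring barring genotyping
#' error or mutation.
#'
#' @param x,y genotype vectors in \{0, 1, 2, NA\} (e.g. rows of a
#'   [geno_matrix] restricted to autosomes).
#' @return list with `rate` (NA when no comparable site), `n_opposing`,
#'   `n_compared`.
#' @export
opposing_homozygote_rate <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  n <- sum(ok)
  opp <- sum((x[ok] == 0L & y[ok] == 2L) | (x[ok] == 2L & y[ok] == 0L))
  list(rate = if (n > 0) opp / n else NA_real_, n_opposing = opp, n_compared = n)
}

#' Parentage assignment by opposing-homozygote screening
#'
#' For each offspring, every candidate's opposing-homozygote rate is
#' computed over autosomal sites; candidates with rate below `tau` are
#' accepted and ranked ascending. When candidate sexes are supplied, the
#' best male (sire) and best female (dam) among the accepted candidates are
#' reported.
#'
#' @param g a [geno_matrix]; only autosomal sites (chrom not X/Y) are used.
#' @param offspring_ids character vector of offspring sample ids.
#' @param candidate_ids character vector of candidate parent ids.
#' @param tau acceptance threshold on the rate (default 0.01, strict `<`).
#' @param sexes optional named vector ("male"/"female") for candidates.
#' @return list per offspring (named): data.frame `candidate`, `rate`,
#'   `n_compared`, `accepted`, sorted by rate; attributes `sire`/`dam` give
#'   the best accepted candidate of each sex when sexes are known.
#' @export
assign_parents <- function(g, offspring_ids, candidate_ids, tau = 0.01,
                           sexes = NULL) {
  auto <- !(g$sites$chrom %in% c("X", "Y"))
  if (!any(auto)) fail("assign_parents: no autosomal sites")
  calls <- g$calls[, auto, drop = FALSE]
  out <- list()
  for (o in offspring_ids) {
    cands <- setdiff(candidate_ids, o)
    res <- lapply(cands, function(cand)
      opposing_homozygote_rate(calls[o, ], calls[cand, ]))
    tab <- data.frame(candidate = cands,
                      rate = vapply(res, `[[`, numeric(1), "rate"),
                      n_compared = vapply(res, `[[`, numeric(1), "n_compared"),
                      stringsAsFactors = FALSE)
    tab$accepted <- !is.na(tab$rate) & tab$rate < tau
    tab <- tab[order(tab$rate), ]
    rownames(tab) <- NULL
    if (!is.null(sexes)) {
      acc <- tab[tab$accepted, ]
      attr(tab, "sire") <- acc$candidate[match("male", sexes[acc$candidate])]
      attr(tab, "dam") <- acc$candidate[match("female", sexes[acc$candidate])]
    }
    out[[o]] <- tab
  }
  out
}

#' Sex assignment from Y-marker presence and non-PAR X heterozygosity
#'
#' A sample is called male when a sufficient fraction of Y-chromosome sites
#' yield a call (`y_present`) and its heterozygosity over non-PAR X sites is
#' below `het_max`; female when Y markers are absent and X heterozygosity is
#' at or above `het_max`. Conflicting evidence yields `ambiguous`, never a
#' silent call. PAR sites must be excluded from `x_nonpar_sites` by the
#' caller (they are diploid in both sexes).
#'
#' @param g a [geno_matrix].
#' @param y_sites site indices (or snp_ids) of Y-chromosome markers (>= 1).
#' @param x_nonpar_sites site indices (or snp_ids) of non-PAR X markers
#'   (>= 10).
#' @param het_max X-heterozygosity threshold (default 0.05).
#' @param y_min_frac minimum fraction of Y sites with a non-missing call to
#'   count Y as present (default 0.5).
#' @return data.frame per sample: `sample`, `y_called_frac`, `y_present`,
#'   `x_het_rate`, `assigned_sex` in \{male, female, ambiguous\}.
#' @export
assign_sex <- function(g, y_sites, x_nonpar_sites, het_max = 0.05,
                       y_min_frac = 0.5) {
  if (is.character(y_sites)) y_sites <- match(y_sites, g$sites$snp_id)
  if (is.character(x_nonpar_sites))
    x_nonpar_sites <- match(x_nonpar_sites, g$sites$snp_id)
  if (length(y_sites) < 1) fail("assign_sex: need >= 1 Y site")
  if (length(x_nonpar_sites) < 10) fail("assign_sex: need >= 10 non-PAR X sites")
  ycalls <- g$calls[, y_sites, drop = FALSE]
  xcalls <- g$calls[, x_nonpar_sites, drop = FALSE]
  y_frac <- rowMeans(!is.na(ycalls))
  x_het <- apply(xcalls, 1, function(z) {
    z <- z[!is.na(z)]
    if (!length(z)) NA_real_ else mean(z == 1L)
  })
  y_present <- y_frac >= y_min_frac
  sex <- rep("ambiguous", length(g$samples))
  sex[y_present & !is.na(x_het) & x_het < het_max] <- "male"
  sex[!y_present & !is.na(x_het) & x_het >= het_max] <- "female"
  data.frame(sample = g$samples, y_called_frac = unname(y_frac),
             y_present = unname(y_present), x_het_rate = unname(x_het),
             assigned_sex = sex, stringsAsFactors = FALSE, row.names = NULL)
}

#' Write a GRM to TSV (square and long formats)
#'
#' @param grm a [compute_grm()] result.
#' @param path output path for the square matrix (header = sample ids); a
#'   companion `<path>.long.tsv` holds row/col/value triplets of the upper
#'   triangle.
#' @return `path`, invisibly.
#' @export
write_grm <- function(grm, path) {
  utils::write.table(data.frame(sample = rownames(grm$values), grm$values,
                                check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  ut <- which(upper.tri(grm$values, diag = TRUE), arr.ind = TRUE)
  long <- data.frame(sample1 = rownames(grm$values)[ut[, 1]],
                     sample2 = colnames(grm$values)[ut[, 2]],
                     value = grm$values[ut])
  utils::write.table(long, paste0(path, ".long.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
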