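# Dual-platform simulator: truth genotypes (HWE founders, trios, sex
# chromosomes) plus array and capture-sequencing observation models. The
# defaults mirror the study design being emulated: 56 animals (8 males),
# ~260X mean capture depth over ~250 bp target regions, array call rate
# ~0.98, and a sprinkling of depth outliers, off-centre captures and a
# low-mapping-quality block.

#' Position where the X pseudoautosomal region starts in the simulated map
#' @export
SIM_PAR_START <- 133e6

#' Simulation configuration
#'
#' @param n_samples total animals, founders plus trio offspring.
#' @param n_males number of male founders (males are always founders).
#' @param n_trios number of trio offspring; each has a sire drawn from the
#'   male founders (with replacement) and a distinct dam.
#' @param n_autosomal_sites,n_x_nonpar_sites,n_y_sites,n_par_sites site
#'   counts per compartment. PAR sites are diploid in both sexes.
#' @param maf_low,maf_high bounds of the uniform allele-frequency draw.
#' @param arr_error per-genotype array error probability (errors move to an
#'   adjacent genotype: 0 <-> 1, 2 <-> 1; from 1 to 0 or 2 equiprobably).
#' @param arr_missing array no-call probability.
#' @param seq_read_error per-read base miscall probability `e`.
#' @param mean_depth target mean capture depth (X coverage).
#' @param depth_shape gamma shape for site-level depth variation; `Inf`
#'   gives constant site depth.
#' @param frac_offcentre fraction of sites captured off-centre
#'   (depth at the SNP base below the region average).
#' @param frac_low_outlier,frac_high_outlier fractions of sites whose region
#'   depth is multiplied by 0.1 / 4 to create IQR outliers.
#' @param lowmq_regions data.frame `chrom`, `start`, `end`, `mq`: blocks in
#'   which simulated site MQ takes the given value instead of 60.
#' @param min_call_depth minimum read depth for the likelihood caller.
#' @param seed root seed; observation functions derive child seeds from it.
#' @return object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_samples = 56, n_males = 8, n_trios = 10,
                       n_autosomal_sites = 20000, n_x_nonpar_sites = 2500,
                       n_y_sites = 5, n_par_sites = 100,
                       maf_low = 0.05, maf_high = 0.5,
                       arr_error = 0.005, arr_missing = 0.02,
                       seq_read_error = 0.01,
                       mean_depth = 260, depth_shape = 20,
                       frac_offcentre = 0.002,
                       frac_low_outlier = 0.03, frac_high_outlier = 0.0015,
                       lowmq_regions = data.frame(chrom = "12", start = 70e6,
                                                  end = 76e6, mq = 35),
                       min_call_depth = 4, seed = 1L) {
  cfg <- as.list(environment())
  probs <- c(arr_error = arr_error, arr_missing = arr_missing,
             seq_read_error = seq_read_error, frac_offcentre = frac_offcentre,
             frac_low_outlier = frac_low_outlier,
             frac_high_outlier = frac_high_outlier)
  if (any(probs < 0 | probs > 1))
    fail("sim_config: probabilities must lie in [0,1] (%s)",
         paste(names(probs)[probs < 0 | probs > 1], collapse = ", "))
  if (mean_depth <= 0) fail("sim_config: mean_depth must be > 0")
  if (maf_low <= 0 || maf_high > 0.5 || maf_low > maf_high)
    fail("sim_config: maf bounds must satisfy 0 < maf_low <= maf_high <= 0.5")
  if (seq_read_error < 0 || seq_read_error >= 0.5)
    fail("sim_config: seq_read_error must be in [0, 0.5)")
  n_founders <- n_samples - n_trios
  if (n_trios > 0 && (n_males < 1 || (n_founders - n_males) < n_trios))
    fail("sim_config: %d trios need >= 1 male founder and >= %d female founders (have %d)",
         n_trios, n_trios, n_founders - n_males)
  if (n_males > n_founders) fail("sim_config: more males than founders")
  structure(cfg, class = "sim_config")
}

# Simulated genome layout: 29 autosomes of 1e8 bp each (positions uniform),
# X non-PAR in [1e6, 1.3e8], X PAR above SIM_PAR_START, Y in [1e6, 4e7].
sim_site_table <- function(cfg) {
  mk <- function(n, chroms, lo, hi) {
    if (n == 0) return(NULL)
    chrom <- sort(sample(chroms, n, replace = TRUE))
    data.frame(chrom = chrom,
               pos = as.integer(round(stats::runif(n, lo, hi))),
               stringsAsFactors = FALSE)
  }
  auto <- mk(cfg$n_autosomal_sites, as.character(1:29), 1, 1e8)
  xnp  <- mk(cfg$n_x_nonpar_sites, "X", 1e6, 1.3e8)
  par  <- mk(cfg$n_par_sites, "X", SIM_PAR_START + 1, SIM_PAR_START + 5e6)
  y    <- mk(cfg$n_y_sites, "Y", 1e6, 4e7)
  sites <- rbind(auto, xnp, par, y)
  sites$compartment <- rep(c("auto", "x_nonpar", "par", "y"),
                           c(NROW(auto), NROW(xnp), NROW(par), NROW(y)))
  o <- order(match(sites$chrom, c(as.character(1:29), "X", "Y")), sites$pos)
  sites <- sites[o, ]
  # Deduplicate positions drawn twice (rare); nudge by +1.
  key <- paste(sites$chrom, sites$pos)
  while (anyDuplicated(key)) {
    dup <- duplicated(key)
    sites$pos[dup] <- sites$pos[dup] + 1L
    key <- paste(sites$chrom, sites$pos)
  }
  n <- nrow(sites)
  alle <- t(vapply(seq_len(n), function(i) sample(c("A", "C", "G", "T"), 2), character(2)))
  sites$ref <- alle[, 1]; sites$alt <- alle[, 2]
  sites$snp_id <- sprintf("snp%06d", seq_len(n))
  rownames(sites) <- NULL
  sites
}

#' Simulate truth genotypes, sexes and pedigree
#'
#' Founder autosomal genotypes are Hardy-Weinberg draws given a per-site
#' allele frequency p ~ Uniform(maf_low, maf_high). Each trio offspring
#' receives one gamete per parent chosen uniformly. Males are hemizygous on
#' non-PAR X and Y (genotype coded 0 or 2, never 1); females have no Y
#' calls. PAR sites are diploid in both sexes. Trio offspring are simulated
#' female so that every male is a founder.
#'
#' @param cfg a [sim_config()].
#' @return object of class `truth_set`: list with `genotypes` (a
#'   [geno_matrix] including a `compartment` column in its site table),
#'   `sexes` (named "male"/"female" vector), `trios` (data.frame
#'   offspring/sire/dam), `p` (per-site truth allele frequency) and `config`.
#' @export
simulate_truth <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    sites <- sim_site_table(cfg)
    n_site <- nrow(sites)
    n_f <- cfg$n_samples - cfg$n_trios
    founders <- sprintf("founder_%03d", seq_len(n_f))
    kids <- if (cfg$n_trios > 0) sprintf("offspring_%03d", seq_len(cfg$n_trios)) else character(0)
    samples <- c(founders, kids)
    sexes <- stats::setNames(rep("female", cfg$n_samples), samples)
    males <- if (cfg$n_males > 0) sample(founders, cfg$n_males) else character(0)
    sexes[males] <- "male"
    female_founders <- setdiff(founders, males)

    p <- stats::runif(n_site, cfg$maf_low, cfg$maf_high)
    comp <- sites$compartment
    G <- matrix(NA_integer_, cfg$n_samples, n_site,
                dimnames = list(samples, sites$snp_id))
    diploid <- comp %in% c("auto", "par")
    hemi_x <- comp == "x_nonpar"
    ychr <- comp == "y"
    for (s in founders) {
      male <- sexes[s] == "male"
      g <- integer(n_site)
      g[diploid] <- stats::rbinom(sum(diploid), 2, p[diploid])
      g[hemi_x] <- if (male) 2L * stats::rbinom(sum(hemi_x), 1, p[hemi_x])
                   else stats::rbinom(sum(hemi_x), 2, p[hemi_x])
      g[ychr] <- if (male) 2L * stats::rbinom(sum(ychr), 1, p[ychr]) else NA_integer_
      G[s, ] <- g
    }
    trios <- NULL
    if (cfg$n_trios > 0) {
      sires <- sample(males, cfg$n_trios, replace = TRUE)
      dams <- sample(female_founders, cfg$n_trios)
      trios <- data.frame(offspring = kids, sire = sires, dam = dams,
                          stringsAsFactors = FALSE)
      transmit <- function(g, n) stats::rbinom(n, 1, g / 2)
      for (j in seq_len(cfg$n_trios)) {
        gs <- G[sires[j], ]; gd <- G[dams[j], ]
        g <- integer(n_site)
        g[diploid] <- transmit(gs[diploid], sum(diploid)) +
          transmit(gd[diploid], sum(diploid))
        # female offspring: paternal X is the sire's hemizygous allele
        g[hemi_x] <- (gs[hemi_x] / 2L) + transmit(gd[hemi_x], sum(hemi_x))
        g[ychr] <- NA_integer_
        G[kids[j], ] <- g
      }
    }
    gm <- geno_matrix(G, samples, sites[, c("chrom", "pos", "ref", "alt", "snp_id")])
    gm$sites$compartment <- comp
    structure(list(genotypes = gm, sexes = sexes, trios = trios, p = p,
                   config = cfg), class = "truth_set")
  })
}

#' @exportS3Method base::print
print.truth_set <- function(x, ...) {
  cat(sprintf("truth_set: %d samples (%d male), %d sites, %d trios\n",
              length(x$sexes), sum(x$sexes == "male"),
              nrow(x$genotypes$sites), NROW(x$trios)))
  invisible(x)
}

#' Observe the truth through the array platform
#'
#' Each true call is independently a no-call with probability `arr_missing`,
#' otherwise erroneous with probability `arr_error`; errors move to an
#' adjacent genotype (0 -> 1, 2 -> 1, 1 -> 0 or 2 equiprobably). Female Y
#' entries stay missing. Under a fixed seed the error locations are nested
#' across error rates (the same uniform draw is thresholded), so lowering
#' `arr_error` can only remove errors.
#'
#' @param truth a [simulate_truth()] result.
#' @param cfg a [sim_config()]; `arr_error`/`arr_missing` are read from it.
#' @param seed observation seed (default derived from `cfg$seed`).
#' @return a [geno_matrix] of observed array calls.
#' @export
observe_array <- function(truth, cfg = truth$config, seed = cfg$seed + 101L) {
  g <- truth$genotypes
  calls <- g$calls
  with_seed(seed, {
    n <- length(calls)
    u_miss <- stats::runif(n)
    u_err <- stats::runif(n)
    u_dir <- stats::runif(n)
    out <- calls
    err <- !is.na(calls) & u_miss >= cfg$arr_missing & u_err < cfg$arr_error
    out[err & calls == 0L] <- 1L
    out[err & calls == 2L] <- 1L
    het_err <- err & calls == 1L
    out[het_err] <- ifelse(u_dir[het_err] < 0.5, 0L, 2L)
    out[!is.na(calls) & u_miss < cfg$arr_missing] <- NA_integer_
    obs <- g
    obs$calls <- out
    obs
  })
}

#' Observe the truth through the capture-sequencing platform
#'
#' Region mean depth per site is Gamma(depth_shape) scaled to `mean_depth`,
#' multiplied by 0.1 / 4 for designated low/high outlier sites; off-centre
#' sites have SNP-base depth u * region depth with u ~ Uniform(0.2, 0.9).
#' Per-sample depths are Poisson around the site SNP depth; alternate read
#' counts are Binomial(depth, mu_g) with mu_0 = e, mu_1 = 0.5, mu_2 = 1 - e.
#' Genotypes and QUAL come from the likelihood caller
#' ([call_genotype_from_ad()]). Site MQ is 60 outside the configured low-MQ
#' blocks. Female samples have zero depth at Y sites. All count draws are
#' inverse-CDF transforms of uniforms drawn before the error rate enters, so
#' runs at different `seq_read_error` under one seed are coupled.
#'
#' @param truth a [simulate_truth()] result.
#' @param cfg a [sim_config()].
#' @param seed observation seed (default derived from `cfg$seed`).
#' @return object of class `seq_observation`: list with `allele_depth`,
#'   `site_stats` (as in [read_vcf_genotypes()]), `genotypes` (called
#'   [geno_matrix]), `qual` (per-sample phred matrix).
#' @export
observe_sequencing <- function(truth, cfg = truth$config, seed = cfg$seed + 202L) {
  g <- truth$genotypes
  n_site <- nrow(g$sites)
  n_samp <- length(g$samples)
  with_seed(seed, {
    # Coverage peaks at the probe centre, so for a centrally captured SNP the
    # depth at the SNP base exceeds the ~250 bp region average by a factor
    # c ~ Uniform(1.05, 1.3); the region average is scaled so that the mean
    # realized SNP depth stays at mean_depth (E[c] = 1.175).
    peak_mean <- mean(c(1.05, 1.3))
    depth_ave <- if (is.infinite(cfg$depth_shape)) rep(cfg$mean_depth / peak_mean, n_site)
                 else stats::rgamma(n_site, shape = cfg$depth_shape,
                                    rate = cfg$depth_shape * peak_mean / cfg$mean_depth)
    n_low <- round(cfg$frac_low_outlier * n_site)
    n_high <- round(cfg$frac_high_outlier * n_site)
    n_off <- round(cfg$frac_offcentre * n_site)
    outlier_idx <- sample(n_site, n_low + n_high)
    low_idx <- outlier_idx[seq_len(n_low)]
    high_idx <- setdiff(outlier_idx, low_idx)
    depth_ave[low_idx] <- depth_ave[low_idx] * 0.1
    depth_ave[high_idx] <- depth_ave[high_idx] * 4
    off_idx <- sample(setdiff(seq_len(n_site), outlier_idx), n_off)
    depth_snp <- stats::runif(n_site, 1.05, 1.3) * depth_ave
    depth_snp[off_idx] <- stats::runif(n_off, 0.2, 0.9) * depth_ave[off_idx]

    u_depth <- matrix(stats::runif(n_samp * n_site), n_samp, n_site)
    u_alt <- matrix(stats::runif(n_samp * n_site), n_samp, n_site)
    lam <- matrix(depth_snp, n_samp, n_site, byrow = TRUE)
    female_y <- outer(truth$sexes == "female",
                      g$sites$compartment == "y", `&`)
    lam[female_y] <- 0
    d <- matrix(stats::qpois(u_depth, lam), n_samp, n_site)
    e <- cfg$seq_read_error
    mu <- matrix(0.5, n_samp, n_site)
    tc <- g$calls
    mu[!is.na(tc) & tc == 0L] <- e
    mu[!is.na(tc) & tc == 2L] <- 1 - e
    mu[is.na(tc)] <- 0          # no true allele to sequence (female Y)
    a <- matrix(stats::qbinom(u_alt, d, mu), n_samp, n_site)
    r <- d - a
    dimnames(r) <- dimnames(a) <- dimnames(g$calls)
    ad <- allele_depth(r, a)

    # The caller needs a strictly positive read-error assumption; a noise-free
    # simulation is still called under a small error floor.
    called <- call_genotype_from_ad(ad, error_rate = max(e, 1e-3),
                                    min_depth = cfg$min_call_depth)
    gm <- g
    gm$calls <- called$genotype
    mq <- rep(60, n_site)
    lr <- cfg$lowmq_regions
    if (NROW(lr)) {
      for (b in seq_len(nrow(lr))) {
        hit <- g$sites$chrom == as.character(lr$chrom[b]) &
          g$sites$pos >= lr$start[b] & g$sites$pos <= lr$end[b]
        mq[hit] <- lr$mq[b]
      }
    }
    site_qual <- apply(called$qual, 2, function(q) {
      q <- q[!is.na(q)]
      if (!length(q)) 0 else stats::median(q)
    })
    sim_outlier <- rep("none", n_site)
    sim_outlier[low_idx] <- "low"
    sim_outlier[high_idx] <- "high"
    sim_offcentre <- seq_len(n_site) %in% off_idx
    # site mean depth over covered samples only: zero-depth entries mark a
    # chromosome the sample lacks (female Y), not capture failure
    mean_covered <- apply(d, 2, function(z) {
      z <- z[z > 0]
      if (!length(z)) 0 else mean(z)
    })
    stats <- data.frame(chrom = g$sites$chrom, pos = g$sites$pos,
                        snp_id = g$sites$snp_id,
                        depth_snp = mean_covered, depth_ave = depth_ave,
                        mq = mq, qual = as.numeric(site_qual),
                        maf = site_maf(gm),
                        call_rate = unname(site_call_rate(gm)),
                        sim_outlier = sim_outlier,
                        sim_offcentre = sim_offcentre,
                        stringsAsFactors = FALSE)
    structure(list(allele_depth = ad, site_stats = stats, genotypes = gm,
                   qual = called$qual), class = "seq_observation")
  })
}

#' @exportS3Method base::print
print.seq_observation <- function(x, ...) {
  cat(sprintf("seq_observation: %d samples x %d sites, mean SNP depth %.1fX\n",
              nrow(x$allele_depth$ref), ncol(x$allele_depth$ref),
              mean(x$site_stats$depth_snp)))
  invisible(x)
}

#' Inject Mendelian-violating offspring calls at designated sites
#'
#' Testing aid for the trio QC: at each chosen site the offspring call of a
#' fixed fraction of trios is overwritten with a genotype that cannot arise
#' from the (observed) parental calls. Trios whose parents are missing or
#' both heterozygous at a site (every offspring genotype consistent) are not
#' eligible there.
#'
#' @param g a [geno_matrix] (typically array observations).
#' @param trios trio data.frame (offspring, sire, dam).
#' @param site_idx site column indices to corrupt.
#' @param frac_trios fraction of trios to violate at each site.
#' @param seed seed for trio selection.
#' @return `g` with corrupted offspring calls; attribute `injected` is a
#'   data.frame (site index, offspring, old, new).
#' @export
inject_trio_errors <- function(g, trios, site_idx, frac_trios = 0.1, seed = 1L) {
  n_want <- max(1L, round(frac_trios * nrow(trios)))
  inj <- vector("list", length(site_idx))
  with_seed(seed, {
    for (k in seq_along(site_idx)) {
      i <- site_idx[k]
      f <- g$calls[trios$sire, i]
      m <- g$calls[trios$dam, i]
      eligible <- which(!is.na(f) & !is.na(m) & !(f == 1L & m == 1L))
      if (length(eligible) < n_want)
        fail("inject_trio_errors: only %d eligible trios at site %d (need %d)",
             length(eligible), i, n_want)
      pick <- sample(eligible, n_want)
      for (t in pick) {
        allowed <- which(vapply(0:2, function(c)
          mendelian_consistent(f[t], m[t], c), logical(1))) - 1L
        new <- sample(rep(setdiff(0:2, allowed), 2), 1)
        inj[[k]] <- rbind(inj[[k]],
                          data.frame(site = i, offspring = trios$offspring[t],
                                     old = g$calls[trios$offspring[t], i],
                                     new = new))
        g$calls[trios$offspring[t], i] <- new
      }
    }
  })
  attr(g, "injected") <- do.call(rbind, inj)
  g
}

#' Write a simulated data set to disk in exchange formats
#'
#' Emits the sequencing platform as a VCF (GT:AD:DP per sample, MQ and DPA
#' in INFO, QUAL per site), the array platform as the TSV layout of
#' [read_array_matrix()], the pedigree and probe tables, sample sexes, and a
#' truth TSV (true calls plus the generating allele frequency) for oracles.
#'
#' @param truth a [simulate_truth()] result.
#' @param arr array observation ([geno_matrix]).
#' @param seqobs sequencing observation ([observe_sequencing()] result).
#' @param outdir output directory (created if needed).
#' @return named character vector of file paths.
#' @export
write_simulation <- function(truth, arr, seqobs, outdir) {
  ok <- dir.exists(outdir) || dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!ok || file.access(outdir, 2) != 0)
    fail("write_simulation: cannot write to %s", outdir)
  paths <- c(vcf = file.path(outdir, "sequencing.vcf"),
             array = file.path(outdir, "array.tsv"),
             trios = file.path(outdir, "trios.tsv"),
             probes = file.path(outdir, "probes.tsv"),
             truth = file.path(outdir, "truth.tsv"),
             sexes = file.path(outdir, "sexes.tsv"))
  write_vcf_genotypes(seqobs, paths[["vcf"]])
  write_array_matrix(arr, paths[["array"]])
  trios <- truth$trios %||% data.frame(offspring = character(0),
                                       sire = character(0), dam = character(0))
  utils::write.table(trios, paths[["trios"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  st <- truth$genotypes$sites
  probes <- data.frame(chrom = st$chrom, pos = st$pos,
                       region_start = pmax(1L, st$pos - 125L),
                       region_end = st$pos + 124L)
  utils::write.table(probes, paths[["probes"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  tru <- data.frame(snp_id = st$snp_id, chrom = st$chrom, pos = st$pos,
                    ref = st$ref, alt = st$alt,
                    compartment = st$compartment, p = truth$p,
                    t(truth$genotypes$calls), check.names = FALSE)
  utils::write.table(tru, paths[["truth"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(data.frame(sample = names(truth$sexes), sex = truth$sexes),
                     paths[["sexes"]], sep = "\t", quote = FALSE, row.names = FALSE)
  paths
}

# Plain-text VCF v4.2 serializer for simulated observations.
write_vcf_genotypes <- function(seqobs, path) {
  g <- seqobs$genotypes
  st <- seqobs$site_stats
  ad <- seqobs$allele_depth
  gt_code <- c("0/0", "0/1", "1/1")
  gt <- matrix("./.", nrow(g$calls), ncol(g$calls))
  ok <- !is.na(g$calls)
  gt[ok] <- gt_code[g$calls[ok] + 1L]
  d <- ad$ref + ad$alt
  field <- matrix(paste0(gt, ":", ad$ref, ",", ad$alt, ":", d),
                  nrow(g$calls), ncol(g$calls))
  body_samples <- apply(field, 2, paste, collapse = "\t")
  info <- sprintf("MQ=%.2f;DPA=%.2f", st$mq, st$depth_ave)
  rows <- paste(st$chrom, st$pos, st$snp_id, g$sites$ref, g$sites$alt,
                sprintf("%.2f", st$qual), "PASS", info, "GT:AD:DP",
                body_samples, sep = "\t")
  hdr <- c("##fileformat=VCFv4.2",
           "##source=genoconcord-simulator",
           "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"RMS mapping quality\">",
           "##INFO=<ID=DPA,Number=1,Type=Float,Description=\"Mean capture-region depth\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", g$samples), collapse = "\t"))
  writeLines(c(hdr, rows), path)
  invisible(path)
}
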