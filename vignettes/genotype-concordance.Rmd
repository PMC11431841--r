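---
title: "Evaluating genotype agreement between target capture sequencing and a SNP array"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating genotype agreement between target capture sequencing and a SNP array}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Target capture sequencing (TCS) enriches ~250 bp regions around known SNPs
with hybridisation probes and sequences them deeply (hundreds of X), offering
a flexible alternative to fixed SNP arrays for livestock genotyping. Before a
breeding program trusts TCS calls, it needs to know how well they agree with
the array calls it already uses, on the same animals: per-sample and per-SNP
agreement, which SNPs or genomic regions misbehave, whether relationship
matrices built from the two platforms coincide, and whether sex, parentage
and key trait markers are reproduced. genoconcord implements that evaluation
as a reusable pipeline, together with a synthetic dual-platform simulator so
that every stage is testable without access to proprietary animal data.

## Data representation

Both platforms are reduced to a common **B-allele-count matrix**: samples in
rows, SNPs in columns, entries 0 (homozygous reference, AA), 1 (heterozygous,
AB), 2 (homozygous alternate, BB), or `NA` for a no-call. `NA` is a distinct
sentinel and never conflates with 0. Coordinates are 1-based (VCF
convention) and region spans are closed intervals. Array B alleles are
mapped to the VCF alternate allele; when the two platforms report the same
(chrom, pos) with ref/alt swapped, the array calls are recoded 0 <-> 2.
Strand flips (e.g. A/G vs T/C) are **not** resolved: the simulator emits
plus-strand alleles on both platforms, and real-data strand harmonisation is
a documented limitation of this package. Sites whose allele pairs are
neither equal nor swapped are dropped and counted.

Duplicated array SNPs at one position are resolved by keeping the higher
call-rate SNP, with exact ties broken by a seeded uniform draw, so a given
seed always reproduces the same choice.

## Agreement statistics

For the aligned pair, with `tg` the sequencing call and `cg` the array call:

* **Concordance** is the fraction of pairwise-complete calls that match,
  with mismatches decomposed into one-allele (|tg - cg| = 1) and two-allele
  (|tg - cg| = 2) differences.
* **R²** per sample (over SNPs) and per SNP (over samples) is the squared
  Pearson correlation of the two B-allele-count vectors. A printed formula
  for this quantity is ambiguous about where the square applies; the squared
  Pearson correlation is the only reading bounded by [0, 1], which is how
  the statistic is used, and is what is implemented.
* **Cohen's kappa with squared weights** treats the three genotypes as
  ordinal categories with disagreement weights d(i,j) = (i-j)^2/(K-1)^2,
  K = 3: kappa = 1 - observed weighted disagreement / expected weighted
  disagreement under marginal independence. When the expected disagreement
  is zero (both raters constant and equal) kappa is reported as 1 by
  convention, with a message. Kappa is computed per sample and pooled over
  all calls; both are reported.

All statistics use pairwise-complete deletion; summary means exclude
undefined entries (monomorphic vectors make R² undefined) and report the
exclusion count.

## Quality control

* **Trio Mendelian screening.** A trio (sire, dam, offspring) is consistent
  when the offspring genotype can be formed from one allele of each parent;
  of the 27 genotype combinations exactly 12 are inconsistent. The per-site
  MI rate uses only *informative* trios (all three calls present) as the
  denominator — the alternative (all trios) is not stated by the protocol
  this mirrors, and the informative denominator is the estimable one. Sites
  with MI > 5% are removed; X/Y sites are excluded from trio testing because
  the autosomal transmission rule does not apply there. Filtering order is
  duplicates -> MI -> sample call rate (< 90% drops the sample).
* **Depth flags.** Per-site mean SNP depth (over covered samples; zero-depth
  entries mark an absent chromosome such as female Y, not capture failure)
  is screened with the IQR rule: outside [Q1 - 1.5 IQR, Q3 + 1.5 IQR].
  Quartiles use linear interpolation (`quantile` type 7); this matters for
  sites near the bounds, so it is fixed and stated. A SNP with
  depth_snp < depth_ave (region average) is judged not captured centrally;
  the boundary depth_snp = depth_ave counts as central.
* **Site pass annotation** records depth_snp >= 100 AND QUAL > 20 (the QUAL
  bound read strictly). It annotates; it never removes sites.
* **Low-MQ regions.** Maximal runs of at least `min_run = 3`
  position-consecutive sites with MQ < 50, reported from the first such SNP
  to the last. The run-length rule formalises what was originally done by
  visual inspection; `min_run` is configurable and the default of 3 is the
  smallest run that cannot be a single-site artefact.
* **Problematic-SNP table.** The union of sites with concordance <= 50%,
  IQR depth outliers, and non-central capture; one row per site with every
  reason that fired, plus MI, MAF and depth columns.

## Relatedness, sex and parentage

The genomic relationship matrix is VanRaden method 1:
G = ZZ' / (2 Σ p(1-p)) with Z = M - 2p, allele frequencies estimated from
the analysed matrix itself and missing calls mean-imputed as 2p (so they
contribute zero to Z). Monomorphic sites are dropped with a message. The
original workflow imputed genotypes against an external reference panel
before building GRMs; imputation is out of scope here, so GRMs are computed
on the observed matrices — a stated divergence. GRM agreement is the Pearson
correlation over upper-triangle elements including the diagonal; since
diagonals can inflate agreement, the off-diagonal-only correlation is also
reported. Identical matrices short-circuit to exactly 1.

Parentage uses opposing homozygotes: sites where the two individuals are
homozygous for different alleles, impossible between parent and offspring
barring error. Candidates with rate < tau = 0.01 are accepted and ranked;
under Hardy-Weinberg an unrelated pair at frequency p has expected rate
2p²(1-p)² (several percent for common SNPs), while a true parent's rate is
error-driven (order arr_error/2), so the threshold separates the two by an
order of magnitude. The mechanism is this package's formalisation; the
protocol it mirrors reports only the outcome.

Sex is assigned from two signals: presence of calls at Y-chromosome markers
(at least half the Y sites called) and heterozygosity across non-PAR X
sites (male if < 5%). The pseudoautosomal region recombines and is diploid
in both sexes, so PAR sites are excluded. Conflicting evidence yields
`ambiguous`, never a silent call.

## Down-sampling

To emulate cheaper sequencing, allele depths are thinned binomially: an
entry with total depth d > target keeps each read independently with
probability target/d; shallower entries are untouched. Genotypes are then
re-called with a minimal biallelic likelihood caller: with r reference and
a alternate reads and per-read error e, L(0) ∝ e^a (1-e)^r, L(1) ∝ 0.5^d,
L(2) ∝ e^r (1-e)^a; the call is the maximum-likelihood genotype, exact ties
call the heterozygote, QUAL is the flat-prior posterior odds on the phred
scale capped at 99, and entries with d < 4 are no-calls. The original
experiment down-sampled reads and re-ran external callers; thinning allele
depths and re-calling with this caller is the same mechanism class at desk
scale, and makes the depth-accuracy relationship mechanistic: the
heterozygote miscall probability at fixed depth has a closed binomial-tail
form that the tests check against simulation. The caller's flat genotype
prior keeps it platform-neutral (no allele-frequency feedback); it is
config-exposed.

## The simulator

`sim_config()` defaults are the emulated study conditions: 56 animals of
which 8 males, 10 trios, ~70K-panel-like site mix scaled to desk size
(20,000 autosomal, 2,500 non-PAR X, 100 PAR, 5 Y sites), allele frequencies
uniform on [0.05, 0.5], array error 0.005 and no-call rate 0.02 (array call
rate ~0.98), per-read error 0.01, mean capture depth 260X. Founder
genotypes are Hardy-Weinberg; trio offspring receive one gamete per parent;
males are hemizygous (coded 0/2) on non-PAR X and Y; females have no Y
calls; PAR sites are diploid in both sexes and excluded from sex inference.
Trio offspring are simulated female so every male is a founder, matching a
design in which the males are a separate confirmation batch.

Sequencing depth: each site's region depth is Gamma(shape 20) scaled so the
realized SNP depth averages `mean_depth`; capture peaks at the probe
centre, so central sites have SNP-base depth c × region average with
c ~ U(1.05, 1.3), while planted off-centre sites (fraction 0.002) use
u ~ U(0.2, 0.9). Planted outlier sites multiply region depth by 0.1
(fraction 0.03) or 4 (0.0015) — these fractions mirror the reported
prevalence of low/high coverage outliers and off-centre SNPs. Per-sample
depth is Poisson; alternate reads are Binomial(depth, mu) with mu = e, 0.5,
1-e by true genotype. Site MQ is 60 except in configured low-MQ blocks
(default: one ~6 Mb block on chromosome 12, echoing the kind of low-MQ
stretch such panels show). The gamma shape of 20 (CV ≈ 0.22) keeps ordinary
site-to-site depth variation inside the IQR whiskers so that the planted
×0.1/×4 artifacts are what the outlier screen should find; `Inf` gives
constant depth for exact-recovery checks.

Array errors are adjacent-state (0 <-> 1, 2 <-> 1; a heterozygote errs to
either homozygote equiprobably) because two-allele array errors are rare;
this also exercises the one-/two-allele mismatch decomposition
asymmetrically. Sequencing genotype errors are *not* injected directly —
they emerge from read sampling through the caller. Error locations are
nested across error rates under a fixed seed (a uniform draw is
thresholded), and count draws are inverse-CDF transforms of
uniforms drawn before the error rate enters, so runs at different error
rates are coupled; this makes monotonicity properties (e.g. GRM agreement
rising as error rates shrink) testable at moderate problem sizes.

What the simulator does **not** emulate: linkage disequilibrium (all sites
independent — sufficient for every statistic in scope, but not for
imputation, which is out of scope), read-level artefacts (alignment error,
index hopping, reference bias), batch effects between male and female
sequencing runs, strand-ambiguous array reporting, and reduced male X
coverage (male X sites are simulated at full depth). Passing tests
therefore demonstrate correctness of the statistics and the pipeline's
behaviour under a faithful error model, not performance on any real data
set.

## Numerical and policy choices

* Genotypes are stored as integers; statistics are computed in double
  precision. GRM correlations of identical inputs return exactly 1.
* The likelihood caller works in log space; ties are resolved to the
  heterozygote and documented.
* Exported stochastic functions take an explicit `seed` and restore the
  caller's RNG state; the pipeline derives per-stage seeds from one root
  seed recorded in the manifest, so a config plus seed reproduces reports
  byte for byte.
* With only a handful of in-sample trios (default 10), a single
  inconsistent trio at a site exceeds the 5% MI threshold, so the Mendelian
  screen is deliberately conservative at desk scale; the emulated protocol
  had hundreds of trios and correspondingly finer MI resolution.
* Degenerate inputs: constant depth vectors produce no IQR flags (the
  whiskers collapse onto the value); depth_ave = 0 makes centrality
  undefined (NA, logged); sites with no informative trio keep their place
  and are counted; a site monomorphic on either platform has undefined R²
  and is excluded from means with a count.

## Problem sizes

The unit tests run on small simulations (hundreds of sites, ~24 animals);
the validation suite uses study-scale simulations of 50-56 samples by
~20,000-22,600 sites, 10 observation seeds for the down-sampling
comparison, and 100 trios by 2,000 sites for the Mendelian-recovery check —
sizes at which the binomial standard errors of the asserted quantities are
small enough for 3-sigma bands to be meaningful. `scripts/acceptance.R`
runs the full default-scale pipeline end to end (including the file
round-trip through VCF/TSV) and reports the headline quantities it
computes.

## Known limitations

* Strand harmonisation and Illumina TOP/BOT final-report parsing are not
  implemented; inputs must already be plus-strand with array B = VCF ALT.
* Multiallelic sites and indels are skipped (counted), so indel proxy
  markers must be evaluated upstream.
* GRMs are built on unimputed matrices with 2p mean-imputation; with
  substantial missingness this shrinks relationships toward the mean.
* X-chromosome trio inheritance is not checked (autosomes only), and
  single-parent (duo) checks are not implemented.
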