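---
title: "Marker-based heritability and GWAS of horn size from harvest records"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Marker-based heritability and GWAS of horn size from harvest records}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hornherit)
```

## The problem

Mountain sheep rams grow massive horns under sexual selection, and in
most North American jurisdictions every legally harvested ram passes
through a compulsory inspection at which horn length, per-annulus
("annuli") growth segments and base circumferences are recorded. Because
horn growth stops each winter, the annuli are a built-in longitudinal
record: the horn dimensions at the end of each past growing season can
be reconstructed from a single harvested horn. Combined with SNP-chip
genotypes from the same animals, these registries support a full
quantitative-genetic analysis — narrow-sense heritability of horn size
and a genome-wide association scan — in a wild population that was never
part of a long-term pedigree study.

`hornherit` implements that analysis end to end: horn-record quality
control and reconstruction, genotype quality control from PLINK text
files, a genomic relationship matrix (GRM), a five-component
repeated-measures animal model fitted by average-information REML, and a
covariance-aware single-SNP Wald scan with genomic control. A
first-class simulation module generates data of the same shape with
known ground truth, so that every stage of the pipeline can be validated
by parameter recovery rather than by eye.

## From annuli to repeated measures

For a ram harvested at age $T$ the record holds annual segment lengths
$s_1, \dots, s_T$ (lamb tip first) and per-annulus base circumferences
$c_1, \dots, c_T$. Lamb tips are frequently worn or broken and a missed
first annulus shifts every age, so reconstruction applies the standard
corrections:

* records with implausible early growth are excluded — year-1 growth
  above 160 mm, or year-1 plus year-2 growth above 420 mm;
* all year-1 measures are dropped and year-1 growth is subtracted from
  cumulative lengths;
* no volume is computed for the lamb tip.

For ages $j = 2, \dots, T$ this yields cumulative length
$\sum_{i=2}^{j} s_i$, circumference $c_j$, and volume
$\sum_{i=2}^{j} \tfrac{1}{3}\pi s_i (r_i^2 + r_i r_{i-1} + r_{i-1}^2)$
with $r_i = c_i / 2\pi$ — each year's growth treated as a conical
frustum with circular cross-sections. Volumes are reported in cm³,
lengths and circumferences in mm.

Two readings of the exclusion rule are defensible: we exclude when
*either* bound is violated (each describes an implausibility on its
own); the conjunctive variant is available via `rule = "both"`. The
first-annulus circumference is retained solely as the inner frustum
boundary of the age-2 volume and never emitted as a trait value.

## The animal model

Each trait is analysed with the repeated-measures animal model

$$y_{iat} = \mu_a + a_i + pe_i + b_{\mathrm{birth}(i)} + m_t + e_{iat},$$

with age class $a$ as a fixed categorical factor (horn growth is
strongly nonlinear in age, so a linear age term would leak age variance
into the random effects; a linear option exists behind
`age_effect = "linear"`). The random effects are additive genetic
($V_a$, covariance $\sigma^2_a G$ with $G$ the GRM), permanent
environment ($V_{pe}$, identity over individuals — the non-genetic
covariance among one ram's repeated records), birth-year cohort
($V_{yb}$), year of measurement ($V_{ym}$), and residual ($V_r$).
Phenotypic variance is $V_p = V_a + V_{pe} + V_{yb} + V_{ym} + V_r$ and
narrow-sense heritability $h^2 = V_a / V_p$.

The GRM is the centered-and-standardized allele-sharing estimator,

$$G_{ij} = \frac{1}{L_{ij}} \sum_k
  \frac{(x_{ik} - 2p_k)(x_{jk} - 2p_k)}{2 p_k (1 - p_k)},$$

summed over loci where both calls are observed. Sample allele
frequencies are used, as appropriate for a single-population analysis;
this gives off-diagonals a known expected offset of $-1/(n-1)$, which is
absorbed by the fixed intercept and is immaterial at $n \approx 180$. A
raw identity-by-state variant (`method = "ibs"`) is available for
sensitivity analysis. `stabilize_grm()` adds a diagonal ridge only when
the smallest eigenvalue falls below $10^{-8}$, and never touches
off-diagonals.

### REML numerics

Variance components are estimated by average-information (AI) REML with
five expectation-maximization warm-up iterations, convergence when the
restricted log-likelihood changes by less than $10^{-6}$, a cap of 200
iterations, and components projected to $10^{-10} V_p$ — components
pinned at that floor with a downhill gradient are dropped from the AI
system, which prevents boundary oscillation. All products with
$V^{-1}$ go through a Woodbury factorization
$V = \sigma^2_r (I + WW')$, so a fit at 180 individuals and ~1,500
records takes about a second; the test suite verifies the factorized
log-likelihood against a dense-matrix evaluation to $10^{-6}$.
Standard errors of components come from the inverse AI matrix at the
optimum, and standard errors of $h^2$ and the other variance ratios by
the first-order delta method. Degenerate inputs (a constant response)
return an all-zero fit flagged `degenerate`; a GRM that is numerically
an identity matrix triggers a warning that $V_a$ and $V_{pe}$ are
confounded, since without relatedness contrast the two are not
separately identifiable.

## The association scan

The scan is two-step: the null animal model (no SNP effects) is fitted
once, and each SNP's observation-level allele count (the individual's
genotype expanded over its repeated records) is then tested by
generalized least squares with $V$ *fixed* at the null REML estimate,
using Wald statistics against $\chi^2(1)$. $V$ is factorized once and
reused across all loci, so a 6,635-locus scan takes a few seconds.
Using the fitted covariance accounts simultaneously for relatedness
(through the GRM) and the correlation of repeated measures (through the
permanent-environment term). Loci monomorphic among the phenotyped
individuals are reported with missing statistics; observations with a
missing call are dropped for that locus only.

Calibration is summarized by the genomic inflation factor $\lambda$,
the zero-intercept regression slope of the sorted observed statistics
on expected $\chi^2(1)$ order statistics (the median-ratio variant is
reported alongside as a diagnostic; whether one regresses statistics or
log p-values is a convention, and we fix the $\chi^2$ scale). With
genomic control enabled, statistics are divided by $\lambda$ before
p-values and threshold comparison. Significance thresholds follow the
standard per-genome rules: genome-wide $0.05/n_{\mathrm{SNPs}}$
(Bonferroni) and suggestive $1/n_{\mathrm{SNPs}}$ (one expected false
positive per scan).

## What the simulator emulates

`sim_config()` defaults define the study conditions used throughout the
tests:

* **Design**: a two-generation polygynous half-sib scheme — 30 sires
  each mated to 3 unrelated dams, 2 offspring per dam — giving 180
  phenotyped, genotyped rams with full-sib (1/2), half-sib (1/4) and
  unrelated pairs. This relatedness contrast is what makes $V_a$ and
  $V_{pe}$ separately identifiable. Parents are pedigree scaffolding
  and are not phenotyped.
* **Markers**: 6,635 unlinked biallelic SNPs across 26 autosomes,
  founder allele frequencies uniform on (0.01, 0.5), genotypes dropped
  through the pedigree by independent Mendelian sampling per locus.
  After marker QC in the phenotyped cohort, slightly fewer loci
  (typically ~6,570) survive, exactly as a real panel would behave.
* **Records**: ages at harvest uniform on 6–13 years, one record per
  year of life from age 2 (year-1 measures do not survive horn QC), so
  8.5 usable records per ram on average, matching the ~9 observations
  per ram of harvest registries of full-curl-regulated populations.
* **Variance decomposition**: generating proportions follow the
  published estimates for the three traits — horn length
  $(V_a, V_{pe}, V_{ym}, V_{yb}, V_r)/V_p = (0.33, 0.35, 0.02, 0.01,
  0.29)$ with $V_p = 2926$ mm², base circumference $(0.36, 0.29, 0.06,
  0.01, 0.28)$ with $V_p = 542$ mm², volume $(0.36, 0.31, 0.01, 0.01,
  0.34)$ renormalized by its printed sum of 1.03, with $V_p = 796{,}253$
  cm⁶. Breeding values are drawn from the *pedigree* numerator
  relationship matrix, keeping the true $h^2$ exactly controllable and
  independent of the marker panel; causal SNPs are added only on
  request.
* **Age means**: a von Bertalanffy curve
  $\mu(a) = L_\infty (1 - e^{-ka})$ per trait (length
  $L_\infty = 720$ mm, $k = 0.16$; circumference 300 mm, 0.55; volume
  9000 cm³, 0.15), chosen so that post-correction trait values and
  year-over-year increments sit in the realistic range for Dall's sheep
  — in particular, about 3% of plausible records graze the 420 mm
  two-year bound, similar to the exclusion rate seen in real
  registries. Only the curve's values at integer ages matter, since the
  model fits age as a factor.

All randomness flows from a single master seed with fixed per-stage
derived streams; identical configurations reproduce bit-identical data.

What the simulator deliberately does **not** model: linkage and LD
(inference is single-SNP plus a genome-wide GRM), genotyping error,
mutation, and — most importantly — phenotype-dependent sampling. Real
harvest records are truncated by the full-curl legality rule, which
preferentially removes fast-growing young rams; passing recovery tests
here therefore shows the estimator is correct under random sampling,
not that harvest selection bias is absent in real data.

## Validation strategy and problem sizes

The test suite validates each fast path against an independent
brute-force oracle: the Woodbury REML log-likelihood against dense
matrices, per-SNP GLS against $(X'V^{-1}X)^{-1}X'V^{-1}y$ on a
six-observation fixture (to $10^{-10}$), the exact
Hardy–Weinberg test (Levene–Haldane conditional distribution, no mid-p)
against full enumeration with binomial coefficients for samples up to
50, the two-component reduction against a profiled grid search over
$h^2$, and the gene-dropper against Mendelian ratios and pedigree
expectations.

End-to-end recovery runs the full pipeline (simulate → QC → GRM → REML
→ scan) at the default 180-ram design: across 10 replicate seeds the
mean $\hat h^2$ must land within ±0.06 of the generating value for horn
length (0.33) and base circumference (0.36); the per-replicate sampling
standard deviation of $\hat h^2$ at this design is ~0.13, so the
±0.06 band on a 10-seed mean is a genuine statistical requirement, not
a formality. Null scans must show $\lambda \in [0.9, 1.1]$ in at least
9 of 10 seeds, and a scan run with $V = \sigma^2 I$ on the same related
repeated-measures data must inflate ($\lambda > 1.1$) — the directional
check that modelling the covariance is what keeps the test calibrated.

For signal detection, the spiked causal SNP explains 30% of $V_p$ — the
scale of known major-effect horn loci in sheep (in feral domestic sheep
a single region explains most of the additive variance in horn size). A
locus at 5% of $V_p$ has theoretical power of only ~35% against a
$1/6{,}635$ suggestive threshold at $n = 180$, so a detection check at
that size would mostly measure luck; at 30% the per-seed power is ~97%
and the 9-of-10 requirement is meaningful.

## Worked example

```{r example, eval = FALSE}
library(hornherit)

cfg <- sim_config(seed = 1)
sim <- simulate_horn_study(cfg, traits = "length")

qc  <- qc_genotypes(sim$genotypes)
grm <- stabilize_grm(compute_grm(qc$genotypes))
fit <- animal_model(sim$phenotypes, grm, trait = "length")
summary(fit)
heritability(fit)

scan <- gwas_scan(fit, qc$genotypes)
summary(scan)
plot(scan, "qq")
```

On file-based inputs the same analysis is one call:
`run_pipeline(list(genotypes = "geno", phenotypes = "phenos.tsv",
out_dir = "out"))`, which writes per-stage TSVs, a QC accounting log
and a JSON manifest sufficient to reproduce the run.

## Known limitations

* Cluster-quality (GC-score) filtering of raw chip intensities is out
  of scope; the QC report reserves a stage for it so real-data
  accounting can mirror a full chip pipeline.
* With ~180 individuals and ~6,600 informative markers, heritability
  estimates carry sampling errors of ~0.13 per dataset, and SNP effect
  sizes at suggestive significance are upwardly biased (winner's
  curse); both are properties of the design, not the implementation.
* A marker-estimated GRM is the true relatedness plus noise of order
  $1/\sqrt{L}$ per entry; at ~6,600 markers this attenuates $\hat V_a$
  (and hence $\hat h^2$) by a few percent — the familiar downward bias
  of medium-density marker panels relative to pedigree estimates.
* The exact allele-sharing weighting used by chip-era GRM software
  varies; the default here is the standard centered estimator with the
  correct pedigree expectation, and the IBS variant exists for
  comparison.
* Harvest (full-curl) selection bias is not modelled; see above.
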