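---
title: "Models and methods behind the pleiotropy scan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the pleiotropy scan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pleioscan)
```

# The problem

Carcass and meat quality in beef cattle — marbling (MARB), ribeye area
(REA), the sensory panel traits tenderness (TEND), juiciness (JUIC) and
flavor (FLAV), and the visual traits color (COLOR), texture (TEXT) and
firmness (FIRM) — are expensive to measure and only available late or after
harvest, which makes them prime candidates for genomic selection. In
multibreed populations (e.g. Angus x Brahman crosses), a prerequisite is
knowing whether the same genomic regions drive several of these traits at
once. `pleioscan` implements the full inference chain for that question:
single-step genomic BLUP (ssGBLUP) with AI-REML variance components, an
iterative weighted single-step GWAS per trait with all other traits fitted
as covariates, 1-Mb window variance partitioning, cross-trait overlap
classification into pleiotropic regions, and candidate-gene flagging from
a local annotation.

# The animal model and the single-step machinery

Every trait is analysed under the linear mixed animal model

$$y = Xb + Zu + e, \qquad u \sim N(0,\, H\sigma^2_u), \qquad
  e \sim N(0,\, I\sigma^2_e),$$

with year of birth as a class effect and age at slaughter as a covariate
(omitted for TEND and FLAV, where it carries no signal). `H` is the joint
pedigree–genomic relationship matrix; its inverse — the only form the mixed
model equations need — is

$$H^{-1} = A^{-1} +
  \begin{bmatrix} 0 & 0 \\ 0 & G^{-1} - A_{22}^{-1} \end{bmatrix},$$

where `A` is the pedigree relationship matrix (tabular method, with
inbreeding in the Meuwissen–Luo set-up of $A^{-1}$), $A_{22}$ its genotyped
sub-block, and

$$G = \frac{Z D Z'}{2\sum_i p_i (1 - p_i)}$$

the (optionally weighted) genomic relationship matrix built from genotype
codes centered at the current population's allele frequencies, missing
codes mean-imputed (so they contribute exactly zero). `G` is blended as
$0.95\,G + 0.05\,A_{22}$ before inversion to avoid singularity; both blend
weights are arguments of `blend_and_invert_G()`.

Two-trait models share the fixed effects and assume
$u \sim MVN(0,\, T \otimes H)$ and $e \sim MVN(0,\, R \otimes I)$, from
which genetic and phenotypic correlations derive as
$r_g = T_{12}/\sqrt{T_{11}T_{22}}$ and
$r_p = (T_{12}+R_{12})/\sqrt{(T_{11}+R_{11})(T_{22}+R_{22})}$.

# AI-REML: how the likelihood is actually evaluated

`aireml_single()` and `aireml_bivariate()` maximize the restricted
likelihood by Newton steps on the average-information (AI) matrix, with an
exact EM-REML step (single-trait) or a damped fallback (two-trait general
path) whenever an AI update would leave the parameter space or decrease the
likelihood; candidate steps are halved until the likelihood is
non-decreasing. Standard errors come from the inverse AI matrix at
convergence, and `se(h2)` / `se(r_g)` by the delta method; both are
approximate and reported as such.

Because every record maps to a distinct animal in these models, the
likelihood is evaluated in the eigenbasis of the relationship block over
recorded animals: with $K = U\Lambda U'$, the single-trait covariance
$\sigma^2_u K + \sigma^2_e I$ rotates to a diagonal matrix and the
two-trait complete-case covariance to 2x2 blocks $\lambda_i T + R$. This is
the identical REML problem — the eigendecomposition is done once per
dataset and each iteration costs O(n) — and it is what makes the
parameter-recovery suites run at full scale (pedigrees of ~2,000 animals)
in seconds per fit. Two-trait data with *differing* missingness patterns
cannot be jointly diagonalized; they fall back to a dense general path
(records enter trait-wise; residual covariance only ties animals observed
for both traits) that is exact but quadratic in storage, intended for up to
a few thousand records. The two paths agree to machine precision on
complete data (this is asserted in the test suite).

Numerical choices: variances are floored at $10^{-8}\times$ the phenotypic
variance (keeping $h^2$ defined at the zero boundary), covariances are
pulled inside the positive-definite cone when rounding pushes a correlation
past $\pm 1$ (with a warning), starting values are half the phenotypic
variance per component with zero covariances, and convergence requires a
relative parameter change below `tol = 1e-9` (default; 200 rounds cap).
One practical caveat found while validating against the closed-form
balanced half-sib ANOVA estimators: when the realized between-family
variance is large, the REML maximum in the *animal-model* parameterization
can sit at $\sigma^2_e \le 0$; the optimizer then runs to the boundary, as
it should, and flags slow convergence.

# The weighted single-step GWAS

`run_wssgblup()` implements the iterative scan, per trait:

1. start with identity marker weights, $D = I$;
2. build the weighted blended $G^*$ and $H^{-1}$, solve the mixed model
   equations at the AI-REML variance components (components are *not*
   re-estimated between rounds — they come from the one-time
   variance-component stage);
3. backsolve marker effects from the genotyped animals' GEBVs,
   $\hat a = \lambda D Z' (G^*)^{-1} \hat u$ with
   $\lambda = 1/(2\sum p_i(1-p_i))$, the constant that makes
   $Z\hat a = \hat u$ exact in the unblended full-rank case;
4. update nonlinearA weights
   $d_i = 1.05^{\,|\hat a_i|/\sigma(\hat a) - 2}$, cap raw weights at 10,
   then normalize so $\sum_i d_i$ equals the marker count (keeping the
   additive variance constant); the cap is applied *before* normalization,
   reading the "maximum change in variance" as a bound on the raw update;
5. iterate — three rounds by default, all rounds retained, the third being
   the reporting default (which round a study reports is a convention; all
   are available).

The association statistic is the percentage of direct additive genetic
variance explained by a genomic window,
$\mathrm{Var}(\sum_{j \in w} Z_j \hat a_j)\, /\, \sigma^2_u \times 100$,
with the variance taken *across individuals* as a population variance
(divide by n — a variance-share reading; a sample variance would scale all
windows by n/(n-1) alike). Two window schemes are available:
a fixed 1-Mb grid per chromosome (default; 1-based closed bins) and
non-overlapping windows of adjacent markers spanning at most 1 Mb, whose
boundaries then depend on the marker set under analysis — which is why
per-trait window counts can differ when marker sets differ.

For the pleiotropy scan proper, each trait's model additionally carries the
phenotypes of all *other* traits as covariates (complete cases only). This
conditional adjustment removes indirect, mediated signal: a window that
affects trait B only through trait A loses its share in B's conditional
scan while keeping it in the unconditional one — a property asserted by
simulation in the test suite.

# Classification and gene flagging

Windows explaining more than 1% of the direct additive genetic variance are
associated; those between 0.9 and 1% form a suggestive band. Overlapping
associated windows of two or more traits merge into a pleiotropic region;
an associated window overlapping only a suggestive-band window of a
*different* trait yields a suggestive region (windows of the same trait
never corroborate each other). Region bounds are reported as the
intersection of the windows that define the call — associated members for
pleiotropic regions, associated plus band members for suggestive ones —
with the union retained alongside; if chained overlaps empty the
intersection, the union is reported instead. Within a region, markers are
ranked by their largest standardized effect $|\hat a|/\sigma(\hat a)$
across member traits (per-trait standardization puts traits with different
units on one scale), the top 20 are kept with ties at the cut broken by
position, and a candidate gene hit requires the marker to sit inside the
gene's span (1-based closed; BED input is converted from 0-based
half-open).

# The synthetic-data generator

The generator emulates the statistical skeleton of a multibreed
beef-cattle study — ~2,400 animals born over multiple years with breed
fractions spanning 0 to 100%, a genotyped subset (44% by default, matching
a 1,038/2,384 design), eight traits with the reported additive/residual
(co)variance structure, year-of-birth class effects and an age-at-slaughter
covariate — so every downstream stage is testable without external data.

* **Pedigree** (`simulate_pedigree()`): discrete generations; each
  generation mates only animals of the previous one (precluding
  parent–offspring pairs), with balanced sexes and `floor(n/2)` random
  pairs. Founders' breed fractions are uniform with 15% forced to each
  purebred endpoint. The paper-scale herd's actual mating design is not
  public; this one is deliberately generic.
* **Genotypes** (`simulate_genotypes()`): founder haplotypes drawn
  per-marker from a frequency range (default 0.05–0.5, a chip-like
  spectrum), descendants by gene dropping with Haldane recombination at
  1 cM/Mb — the simplest defensible linkage model. Founders carry no
  linkage disequilibrium; see the limitations below.
* **Traits** (`simulate_traits()`): founder breeding values
  $MVN(0, T)$; a non-founder is the parental mean plus a Mendelian
  sampling deviation with covariance $T \cdot (0.5 - 0.25(F_s + F_d))$,
  using inbreeding from the pedigree module so simulated values are
  exactly consistent with `A` (this keeps REML recovery tests unbiased).
  Year effects default to N(0, (0.3 sd_P)^2) per year and trait; age at
  slaughter is N(550, 60) days. Ordinal traits are simulated as continuous
  liabilities; `discretize_scores()` maps them onto the recording scales
  (MARB 100–999, COLOR 1–8, TEXT 1–7, FIRM 1–5) purely for fixture
  realism — the analyses treat scores as continuous throughout, following
  the linear models used at study scale.
* **QTL planting** (`plant_qtl()`): one marker per window receives an
  allele-substitution effect sized so its genotypic variance equals the
  target share of $\sigma^2_u$; the polygenic part is rescaled so the total
  additive variance is unchanged, and `update_phenotypes()` carries the new
  breeding values into existing phenotypes while keeping residuals fixed
  (a zero-effect plant leaves phenotypes bit-identical).

All randomness flows from one top-level seed through a deterministic
splitting scheme, so fixtures are reproducible.

# What the recovery suites do and do not show

The study's real phenotypes are not public, so acceptance is
parameter recovery on synthetic data using the reported components as
simulation truth: single-trait heritabilities for the marbling-, ribeye-,
tenderness- and firmness-like component pairs (3176.10/3317.30, 1.05/0.94,
0.28/0.36, 0.08/0.34), and the two-trait genetic correlation implied by a
genetic covariance of 6.26 between the marbling- and tenderness-like
traits. The suites run five (ten for the low-heritability trait in the
acceptance script) replicate pedigrees of 2,004 animals over five
generations per case; `scripts/acceptance.R` reproduces them end to end.
These tests show the estimation machinery is calibrated; they cannot
certify anything about the real herd's data quality or model adequacy.

A genuine limitation surfaced by the end-to-end power suite: with founders
drawn in linkage equilibrium and an infinitesimal polygenic background (the
generator's faithful design), a planted QTL at 5% of $\sigma^2_u$ is tagged
by exactly one marker, and the GEBV-to-marker backsolve shrinks that
marker's effect by roughly
$z'z / (z'z + 2\sum p q \cdot \sigma^2_e/\sigma^2_u)$ — about 0.1–0.25 at
500 animals and 2,000 markers — so its *estimated* window share lands near
0.03–0.3%, below the polygenic smear of ordinary multi-marker windows. The
nonlinearA weight of such a marker saturates near 1.1 rather than
cascading. Real populations put dozens of chip markers in LD with a causal
variant inside a 1-Mb window, and it is that aggregation which lifts
estimated shares past 1%; sequence-level or coalescent LD simulation is
out of scope here. Consequently the desk-scale pipeline detects planted
QTL reliably at the *marker rank* level (the QTL marker ranks near the top
and holds or improves its rank across weighting iterations) but not at the
1%-of-variance window threshold, and the window-threshold power suite is
expected to fail at this scale. Scans on data with genuine LD are
unaffected by this limitation of the fixture generator.

# Worked example

```{r example, eval = FALSE}
set.seed(1)
ds <- simulate_dataset(seed = 1, n_founders = 128, n_generations = 3,
                       n_markers = 2000, n_chromosomes = 10,
                       T_true = diag(4), R_true = diag(4) * 1.04,
                       genotyped_rate = 1,
                       qtl = list(list(window = list(chrom = "5",
                                                     start = 5e7 + 1, end = 5.5e7),
                                       target_pct = 5, traits = c("T1", "T2"))))
scan <- run_pleiotropy_scan(ds$ped, ds$geno, ds$traits, verbose = TRUE)
scan$vc$T1          # variance components per trait
scan$regions        # pleiotropic / suggestive calls
plot_windows(scan$windows$T1)
```

The same driver accepts real inputs: a pedigree TSV, PLINK-RAW or VCF
genotypes plus a marker map, a phenotype table (scores collapsed with
`collapse_scores()`, panel scores averaged with `average_panel_scores()`),
and BED/GFF3 gene annotation through `read_annotation()`.
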