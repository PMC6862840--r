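---
title: "QTL mapping by combined LDLA with principal-component compression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{QTL mapping by combined LDLA with principal-component compression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The mapping problem

`ldlapca` maps quantitative trait loci (QTL) in populations structured as
large paternal half-sib families, the typical design of dairy sheep and
cattle resource populations: genotyped sires, genotyped daughters with
repeated lactation records, and mostly ungenotyped dams. In such data two
complementary sources of identity-by-descent (IBD) information coexist:

* **Linkage analysis (LA)** — recombinations observed within the genotyped
  families trace each *replicated haplotype* (RH, a gamete inherited from a
  genotyped parent) back to the *base haplotypes* (BH, gametes inherited
  from ungenotyped or unknown parents).
* **Linkage disequilibrium (LD)** — historical recombinations make
  identity-by-state (IBS) sharing around a position informative about IBD
  between the base haplotypes themselves.

A combined LDLA model uses both. The computational obstacle is the
per-locus gametic IBD matrix: it is large, dense and frequently not
positive definite. This package follows the principal-component route: the
IBD information is compressed into a small set of orthogonal covariates and
the QTL and polygenic effects are estimated as *fixed* effects by weighted
least squares, so no variance-component machinery is needed inside the
genome scan.

## Model

At every SNP position $l$ the phenotype vector $y$ (one average
performance deviation, APD, per ewe) is modelled as

$$ y = 1\mu + Z V_l \beta_l + Z V_g \alpha_l + \varepsilon,
   \qquad \varepsilon \sim N(0, \sigma^2_\varepsilon R^{-1}), $$

where $Z$ ($n_P \times n_{RH}$) links each ewe to her two gametes, $R$ is
the diagonal matrix of APD reliabilities, $V_l$ holds the locus-level PC
scores of the RH and $V_g$ the genome-level scores. The per-locus
ingredients are:

* $H_l$ ($n_{RH} \times n_{BH}$): LA descent probabilities, row-stochastic;
  $f_l = H_l' 1$ counts the replicates of each BH and $F_l =
  \mathrm{diag}(f_l)$.
* $U_l$ ($n_{BH} \times n_{BH}$): LD-based IBD probabilities between BH,
  unit diagonal, exactly zero across breed pools.
* $U_l^w = F_l^{1/2} U_l F_l^{1/2}$, the replicate-weighted matrix whose
  eigendecomposition replaces that of the full gametic matrix
  $G_l = H_l U_l H_l'$: for 0/1 $H_l$ the nonzero eigenvalues coincide and
  the PC scores transfer as $V_l = H_l F_l^{-1/2} V_l^w$ (this equivalence
  is asserted numerically in the test suite at tolerance $10^{-8}$).
* Retention: within each breed block, the smallest leading set of
  components explaining more than 99% of the block trace.

At the genome level the same construction is applied to the across-loci
averages $U_g$, $H_g$, $f_g$. Because genome-average IBD between BH is
moderate, $U_g^w$ compresses poorly; the model therefore first selects the
*high-impact* subset $BH_h$ — the smallest set with
$\sum f_{g_h}/n_{RH} > 0.99$ where $f_{g_h} = W'f_g$ and
$W = U_{g\_h} U_{g\_hh}^{-1}$ — and decomposes
$U_{g\_hh}^w = F_{g\_h}^{1/2} U_{g\_hh} F_{g\_h}^{1/2}$, giving
$V_g = H_g W F_{g\_h}^{-1/2} V^w_{g\_hh}$, constant across loci.

Three null hypotheses are tested per SNP by partial F-tests:
$\beta_l = 0$, $\beta_l^S = 0$ and $\beta_l^L = 0$ (the two breed blocks);
the breed-S block is the primary reported statistic. Genome-wide
significance uses within-trait permutations of the reduced-model residuals
($y = 1\mu + ZV_g\alpha + \varepsilon$): the genome-wide maxima of
$-\log_{10} p$ form the null distribution and the $(1-\alpha)$ empirical
quantile is the threshold. Significant positions are clustered into QTL
regions by the correlation of their fitted locus-effect vectors
$ZV_l\beta_l$ (new peaks must correlate below 0.15 in absolute value with
all existing peaks; remaining significant SNPs join the peak they correlate
with most; overlapping regions of different traits merge).

Per-BH allelic effects are recovered from a fitted locus as
$\beta_l^{BH} = F_l^{-1/2} V_l^w \beta_l$ and rank the base haplotypes
driving a peak.

## Parameters that matter

| parameter | default | role |
|---|---|---|
| `window` | 21 SNPs | IBS window (10 per side) conditioning LD-IBD |
| `prior_ibd` | 0.1 | prior same-breed IBD of the window estimator |
| `pc_threshold` | 0.99 | variance share retained per PC block |
| `bhh_coverage` | 0.99 | replicate coverage of the BH_h subset |
| `phase_certainty` | 0.99 | minimum origin probability kept in phasing |
| `call_rate`, `maf` | 0.95, 0.01 | SNP editing before phasing |
| `n_perm`, `alpha` | 2000, 0.05 | permutation null and threshold level |
| `qtlr_corr` | 0.15 | correlation cut-off separating QTL-region peaks |

Map positions assume 1 Mb = 1 cM throughout, and recombination follows the
Haldane model (Poisson crossovers, no interference) — the simplest model
consistent with that assumption; no interference model is imposed anywhere
else in the method, so this choice only affects the simulator and the
conversion of flanking distances into recombination fractions.

## The windowed IBD estimator

The exact coalescent prediction of IBD from IBS status is not prescribed
here; the package ships an **IBS-run posterior** as its default, pluggable
estimator (`estimator` argument of `ld_ibd_locus()`). For a pair of
haplotypes sharing the focal allele, let $q$ be the probability of the
observed uninterrupted IBS run around the focal SNP under independence,
computed from the within-breed expected homozygosity
$c_k = p_k^2 + (1-p_k)^2$ of each SNP in the run. Then

$$ P(\text{IBD}) = \frac{\pi}{\pi + (1-\pi)\, q}, $$

with prior $\pi$ = `prior_ibd`. Pairs differing at the focal SNP get 0;
missing alleles neither extend nor break a run; runs stop at chromosome
ends. Long shared runs drive the posterior towards 1 and a broken run
towards $\pi/(\pi + (1-\pi)c)$, which reproduces the characteristic
trimodal IBD distribution of closed populations (a large mass at exactly 0,
a mode near 1, and a thin band of intermediate values).

## The simulator and what it emulates

`sim_population()` generates the study conditions used by the tests and
the acceptance script:

* **Pedigree** — genotyped sires (a configurable number of F1 sires whose
  ungenotyped father is of the second breed), generation-1 ewes out of
  distinct ungenotyped dams, later generations with dams sampled from the
  previous ewe generation. All ewes are phenotyped.
* **Base gametes** — each breed pool derives from a small set of ancestral
  haplotypes (defaults: 8 for breed S, 4 for breed L), and every base
  gamete is a recombinant **mosaic** of that pool: ancestry switches along
  the chromosome as a Poisson process with mean segment length 15 cM, plus
  a per-SNP copying-error rate of 0.005. The mosaic structure is essential:
  it makes *local* IBD classes differ from *genome-average* kinship, which
  is exactly the contrast the LDLA model exploits (with whole-haplotype
  copies the locus term would be confounded with the polygenic term). The
  ancestral-pool size reproduces the strong locus-level compressibility of
  a closed nucleus flock — a couple of dozen effective haplotypes locally —
  while keeping genome-average IBD between base gametes moderate (about
  `1/n_ancestral`, plus the prior floor of the window estimator). Breed
  pools use independent frequency draws, so cross-breed LD-IBD is
  effectively zero, and the model sets it to exactly zero.
* **Phenotypes** — repeated records $y_{ij} = q_i + a_i + e_{ij}$ collapsed
  to the APD mean, with the balanced closed-form reliability
  $r = n\sigma^2_a/(n\sigma^2_a + \sigma^2_e)$. Defaults
  $\sigma^2_a = 0.3$, $\sigma^2_e = 0.7$, four records per ewe. The
  polygene is iid normal by default (a clean null for calibration
  studies); `polygenic_model = "genomic"` instead builds it from many small
  SNP effects so that genome-wide IBD can track it — used when the
  polygenic adjustment itself is under test. QTL effects are additive per
  allele copy; `qtl_effect_for_variance()` converts a target fraction of
  the APD phenotypic variance into an allele substitution effect.

What the simulator does **not** emulate: genotyping error, selection over
generations, dominance and epistasis, pedigree errors, and a realistic
site-frequency spectrum (allele frequencies are uniform in the MAF range).
Passing tests therefore demonstrate correctness of the machinery and
calibration under the stated conditions, not performance on any particular
real data set.

## Phasing and descent tracing

Population-level LD is deliberately ignored in phasing — family information
suffices in this design. The deterministic phaser works in three passes:
homozygous and Mendelian-exclusion phasing; progeny-based phasing of parent
heterozygous sites by majority vote with origin tracking along the
chromosome (ties leave the site unphased); and a flanking-linkage rule that
assigns remaining heterozygous sites from the nearest informative positions
of the same meiosis, keeping assignments whose origin probability

$$ p = \frac{l_1 r_1}{l_1 r_1 + (1-l_1)(1-r_1)} $$

(with $l_1$, $r_1$ the flank-implied origin-1 probabilities under Haldane)
reaches 0.99. Everything below that threshold is missing. Individuals with
both parents ungenotyped get arbitrary paternal/maternal labels; with the
progeny-vote pass the label is also arbitrary per chromosome, so the two
base gametes of such a founder may swap identity between chromosomes. This
only blurs genome-average IBD entries involving those pairs and is a known
limitation.

LA descent uses the same origin machinery: certain where the transmitting
parent is phased-heterozygous and the child allele known, interpolated from
the nearest informative flanks elsewhere, and composed down the pedigree by
the gametic recursion (one vectorized update per generation layer). Rows
are renormalized after zeroing entries below $10^{-12}$; BH with $f_l = 0$
at a locus are dropped from that locus's basis.

## Numerical choices

* Any LAPACK symmetric eigensolver satisfies the reconstruction tolerance;
  eigenvectors get a deterministic sign (largest-magnitude element
  positive).
* Weighted least squares go through pivoted QR; collinear columns are
  dropped, the numerator df of a partial F-test is the rank difference and
  the denominator df is $n_P - \mathrm{rank}$. $-\log_{10}p$ is capped at
  300. Residual sums of squares are clamped at zero to avoid cancellation
  artifacts in near-perfect fits.
* `select_bh_h()` is an exact greedy search on the marginal gain in
  $\sum f_{g_h}$, vectorized over candidates with block-inverse updates;
  ties break to the lowest BH index. A numerically singular $U_{g\_hh}$
  falls back to a $10^{-8}$ diagonal ridge with a warning.
* Reliability variance components come from the one-way ANOVA method of
  moments — deterministic and entirely adequate for regression weights.
* Permutations standardize the reduced-model residuals by $R^{1/2}$,
  permute, de-standardize and re-add fitted values, preserving both the
  null structure and the heteroskedastic weighting; permutation $i$ draws
  its order under seed $s + i$, so results are independent of evaluation
  order. Thresholds use the type-7 empirical quantile.
* Region peaks use absolute correlations (the conservative reading of the
  0.15 rule); cross-trait merging requires bp-interval overlap, a single
  shared bp sufficing.

## Problem sizes used in the checks

The bundled checks run at desk scale, chosen to finish in minutes while
preserving the structure of the design: a 10-family population of 40 ewes
per family over two generations (400 ewes, roughly 220 base haplotypes) on
a 2 x 100 Mb genome with 400 SNPs for QTL recovery; a 5-family version
with 500 SNPs, 200 permutations and 200 independent null scans for
threshold calibration; 20 replicates for the position-recovery and
monotonicity studies. The QTL-region study instead uses a 40-family
design of 5 daughters each (same 400 ewes): with few families the fitted
locus-effect vectors of even unlinked positions share a between-family
component exceeding the 0.15 correlation cut-off, whereas the many-family
design — the regime of a real nucleus flock with over a hundred sire
families — decorrelates unlinked positions as the region procedure
presumes. The real-data regime this emulates is one order of
magnitude larger in every direction; the statistical behaviour
(calibration, compression, equivalence identities) is scale-free, whereas
detection power of course is not.

## Worked example

```{r example}
library(ldlapca)

sim <- sim_population(
  n_sires = 10, daughters_per_sire = 20, n_generations = 2,
  n_snps = 400, n_chr = 2, chr_length_mb = 100,
  qtl_frac = 0.10, seed = 1
)
model <- ldla_prepare(sim$genotypes, sim$pedigree, sim$map)
ctx <- design_context(model, sim$phenotypes)
scan <- scan_genome(ctx, model)
null <- gw_threshold(ctx, model, n_perm = 200, alpha = 0.05, seed = 2)
regions <- cluster_regions(scan, null$threshold)

glance(scan)
autoplot(scan, threshold = null$threshold)
```

## Known limitations

* RH-pair covariance created by uncertain transmissions is not modelled
  (the weighted-BH construction deliberately routes all covariance through
  the base haplotypes); the approximation degrades when many descent
  probabilities are far from 0/1.
* The per-breed 99% retention rule is applied block by block; a joint rule
  could retain slightly different components.
* The region procedure can undercount QTL when several causal genes share
  a region; no correction is attempted.
* Founder-label ambiguity across chromosomes (see above).
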