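# ldlapca

Combined linkage and linkage-disequilibrium (LDLA) QTL mapping with
principal-component compression of identity-by-descent (IBD) matrices.

## What it does, and for whom

`ldlapca` is aimed at geneticists mapping quantitative trait loci in
livestock populations organized as large paternal half-sib families —
genotyped sires and daughters, mostly ungenotyped dams, repeated records
per ewe collapsed to average performance deviations (APD). In that design,
within-family linkage analysis (LA) traces every *replicated haplotype*
(RH; a gamete inherited from a genotyped parent) back to the *base
haplotypes* (BH; gametes inherited from ungenotyped parents), while
population linkage disequilibrium (LD) predicts IBD between the base
haplotypes themselves from marker windows. Combining the two gives the
per-locus gametic IBD matrix

$$ G_l = H_l U_l H_l', $$

with $H_l$ ($n_{RH} \times n_{BH}$) the LA descent probabilities and
$U_l$ ($n_{BH} \times n_{BH}$) the LD-based IBD between BH. $G_l$ is
large, dense and often not positive definite; this package sidesteps it by
decomposing the small replicate-weighted matrix
$U_l^w = F_l^{1/2} U_l F_l^{1/2}$ (with $F_l = \mathrm{diag}(H_l'1)$),
whose nonzero eigenvalues equal those of $G_l$ for certain transmissions,
and by carrying the retained principal components into the fixed-effects
model

$$ y = 1\mu + Z V_l \beta_l + Z V_g \alpha_l + \varepsilon, \qquad
   \varepsilon \sim N(0, \sigma^2_\varepsilon R^{-1}), $$

where $V_l = H_l F_l^{-1/2} V_l^w$ are the locus PC scores of the RH
(split into breed blocks $[V_l^S\; V_l^L]$), $V_g$ the analogous
genome-wide scores built over the high-impact BH subset
($W = U_{g\_h}U_{g\_hh}^{-1}$), and $R$ the diagonal matrix of APD
reliabilities. Each SNP is tested by partial F-tests of
$\beta_l = 0$, $\beta_l^S = 0$, $\beta_l^L = 0$ — weighted least squares
only, no per-locus variance-component estimation. Genome-wide thresholds
come from within-trait permutations of the reduced-model residuals, and
significant positions are clustered into QTL regions by the correlation of
their fitted locus effects $ZV_l\beta_l$ (cut-off 0.15). A family-structured
population simulator (`sim_population()`) provides ground truth for every
stage. See `vignettes/ldla-pca-methods.Rmd` for the full model account.

## Worked example

```r
library(ldlapca)

sim <- sim_population(
  n_sires = 10, daughters_per_sire = 20, n_generations = 2,
  n_snps = 400, n_chr = 2, chr_length_mb = 100,
  qtl_frac = 0.10, seed = 1
)
model <- ldla_prepare(sim$genotypes, sim$pedigree, sim$map)
model
#> LDLA model components
#>   374 SNPs on 2 chromosome(s); 220 BH (218 S, 2 L); 800 RH
#>   BH_h: 19 members covering 99.2% of replicates; n_PC_g = 19

ctx  <- design_context(model, sim$phenotypes)
scan <- scan_genome(ctx, model)
null <- gw_threshold(ctx, model, n_perm = 200, alpha = 0.05, seed = 2)
glance(scan)
#> # A tibble: 1 × 7
#>   trait n_loci mean_n_pc_l peak_snp peak_chrom peak_mb peak_minus_log10_p_S
#> 1 y        374        12.5 snp1_98           1    45.7                 6.90
null
#> Permutation null (200 permutations, S test): 95% GW threshold = 3.721

cluster_regions(scan, null$threshold)
#>   region chrom n_snps peak_snp peak_mb start_mb end_mb max_minus_log10_p traits
#> 1      1     1     26  snp1_98    45.7     41.8   53.1              6.90      y
#> 2      2     1      1 snp1_186    92.6     92.6   92.6              4.66      y

autoplot(scan, threshold = null$threshold)   # Manhattan plot
```

The planted QTL explains 10% of the phenotypic variance and sits at
46.9 Mb on chromosome 1; the scan's top signal (`snp1_98`,
$-\log_{10}p = 6.9$) lands 1.2 Mb away, well above the permutation
threshold of 3.72, and the 26 significant positions around it collapse
into one QTL region. `fit_locus()` + `bh_effects()` then rank the base
haplotypes driving the peak
($\beta_l^{BH} = F_l^{-1/2} V_l^w \beta_l$).

A thin command-line wrapper is installed as `exec/ldlapca`
(`ldlapca simulate`, `ldlapca run`) for file-based pipelines
(PLINK .ped/.map genotypes, TSV pedigree/phenotypes).

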