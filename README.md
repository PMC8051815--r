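# varbatch

Variant-level batch effect diagnostics for case/control sequencing
association studies.

## The problem

Multi-center sequencing studies split their samples across exome capture
kits. The conventional defenses — genotype PCA plus a batch covariate in
the association model — operate at the *sample* level. They miss a
variant-level failure mode: when one kit captures templates carrying the
alternative allele less efficiently than reference templates, that
variant's alternative allele fraction (AAF) is depressed in that kit,
heterozygotes drop out as homozygous-reference calls, the kit's cohort
minor allele frequency (MAF) collapses, and the association signal comes
exclusively from the other kit even with center in the model. Discarding
every batch-discordant variant then throws away real signals whenever the
discordance is a *quality* difference.

`varbatch` is for analysts of such studies. It implements, end to end:

* a read-level synthetic-cohort generator (two kits, three centers,
  Balding–Nichols substructure, logistic case/control phenotype, planted
  causal and kit-biased variants) so the whole workflow is testable
  without controlled-access data;
* VCF 4.2 / metadata / reference-MAF input-output for the supported
  biallelic-SNP subset;
* sample QC (call rate > 95%, depth ≥ 10x at ≥ 90% of calls, Ti/Tv >
  2.75) and variant filters (VQSLOD > 0, control-sample exact
  Hardy–Weinberg p ≥ 1e-6, ≥ 10 alt-supporting reads cohort-wide);
* pruned-set genotype PCA (MAF ≥ 5%, HWE p ≥ 1e-4, r² ≤ 0.2 in 0.1 Mb
  windows), eigenvalue-above-1 PC retention, and a k-means/silhouette
  subpopulation surrogate;
* per-variant additive logistic association (Wald test), full-cohort and
  stratified by center or kit, with Bonferroni thresholding
  (`alpha / n_tests`) and *batch-exclusive* flagging;
* variant-level diagnostics: per-kit mean GQ/DP/AAF and their log2
  ratios with 5% tails, subset-PCA kit-separation silhouettes, AAF
  bimodality (Gaussian mixture), reference-MAF concordance, and a direct
  estimator of allelic capture efficiency
  `c = AAF/(1 - AAF)` over heterozygous carriers.

The core model: capture efficiency `c` is the relative probability that
an alt-carrying template is captured versus a reference template. A
heterozygote's expected AAF is `c/(1+c)`; depth scales by `1`, `(1+c)/2`,
`c` for dosage 0/1/2. One parameter reproduces both the depressed-AAF
mode and allele dropout. See `vignettes/variant-batch-effects.Rmd` for
the full account.

## Worked example

```r
library(varbatch)

cfg <- sim_config(seed = 1)          # default study conditions
rep <- run_pipeline(cfg, strata = c("full", "KitA", "KitB"))
print(summarize(rep))
```

```
2000 variants tested; Bonferroni threshold 2.5e-05
exclusions: vqsr=0, hwe=0, alt_support=0
flags: concordant=2, exclusive_KitA=7, not_significant=1991
ratio tails: any_tail=516, aaf_left=100, aaf_right=100
top variants by full-cohort p:
     variant_id            p   maf_case   maf_ctrl            flag
 1:19880000:T:A 6.105339e-27 0.13823529 0.05660377      concordant
 1:15400000:T:C 7.868754e-22 0.11307190 0.04492188      concordant
  1:6730000:G:A 4.840772e-14 0.07643944 0.03067885  exclusive_KitA
  1:4510000:T:C 5.448395e-13 0.05497038 0.01860313  exclusive_KitA
  1:2630000:G:A 7.834993e-12 0.05157687 0.01920573  exclusive_KitA
  1:7030000:C:T 6.304393e-10 0.04515491 0.01756669  exclusive_KitA
  1:3500000:C:T 3.065010e-09 0.04503616 0.01725260  exclusive_KitA
  1:6930000:C:G 2.088109e-08 0.04966887 0.02149837  exclusive_KitA
  1:7380000:T:C 5.051016e-07 0.04068241 0.01919323  exclusive_KitA
  1:7580000:A:G 7.485886e-05 0.35784314 0.40598569 not_significant
```

Reading the output: all simulated sites survive the variant filters, so
the Bonferroni cutoff is 0.05/2000 = 2.5e-5. The nine significant
variants are planted risk variants (MAF ~0.08, OR 3.5; this seed planted
two unbiased and eight KitB-biased causal variants, of which seven are
recovered as exclusive). The `exclusive_KitA` flags mark the planted
KitB capture-bias variants — their KitB stratum shows no evidence because
the biased kit lost the alternative alleles during capture, which is why
their pooled control MAF is roughly half the kit-A value. The diagnostics
stages then adjudicate these flags (AAF ratio tails, concordance with the
reference panel, capture-efficiency estimates).

The same analysis, stage by stage with intermediate tables on disk, is in
`analysis/01_simulate.R` … `analysis/06_summary.R` (run from the
repository root in order; outputs land under `results/`).

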