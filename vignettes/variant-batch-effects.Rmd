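---
title: "Detecting variant-level capture-kit batch effects in case/control sequencing studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting variant-level capture-kit batch effects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Large sequencing-based association studies spread their samples across
sequencing centers and exome capture kits. Conventional batch handling —
inspect genotype PCA, add the batch as a covariate — operates at the
*sample* level and treats every variant that survived site-level quality
control as equal. But capture chemistry can differ between kits at the
level of an *individual variant*: if one kit captures templates carrying
the alternative allele less efficiently than reference templates, that
variant's alternative allele fraction (AAF) is depressed in that kit,
heterozygotes are mis-called homozygous reference (allele dropout), the
cohort minor allele frequency (MAF) in that kit collapses, and an
association signal can appear to come exclusively from the other kit —
even with the sequencing center in the model. Such variants are easy to
discard as batch artifacts; when the discordance is driven by a *quality*
difference, discarding them is a false negative.

`varbatch` implements the full adjudication workflow: simulate (or load) a
two-kit, three-center case/control cohort; apply the standard sample- and
variant-level QC; run genotype PCA and stratified additive logistic
association; flag batch-exclusive signals; and interrogate them with
variant-level diagnostics — per-kit quality-metric ratios and their tails,
AAF bimodality, subset-PCA kit separation, reference-MAF concordance, and
a direct estimator of allelic capture efficiency.

## The capture-bias model

One parameter per variant and kit drives everything: the capture
efficiency $c \in (0, 1]$, the relative probability that a template
carrying the alternative allele is captured and sequenced versus a
reference template. For a genotype with alternative dosage $g$:

* capture weight (expected depth scale): $1$, $(1+c)/2$, $c$ for
  $g = 0, 1, 2$;
* per-read alternative probability with base error $\varepsilon$:
  $\pi(0) = \varepsilon$,
  $\pi(1) = \dfrac{c(1-\varepsilon) + \varepsilon}{1 + c}$,
  $\pi(2) = 1 - \varepsilon$.

At $c = 1$ a heterozygote's reads are balanced ($\pi = 1/2$); at small
$c$ its AAF collapses to $c/(1+c)$ and the depth of homozygous-alternative
carriers shrinks by $c$. A single parameter therefore reproduces both the
depressed AAF mode and the allele dropout that destroys genotype calls.
The same algebra gives the estimator used by the diagnostics: among
heterozygous carriers, alt reads over ref reads estimates $c$
($\mathrm{AAF}/(1-\mathrm{AAF}) = c$ when $\varepsilon = 0$).

The contract between the module's post-conditions and its design note is
read as the coherent template-sampling model above: the post-condition's
"depth scaled by $c$ for alt-carrying genotypes" applies in full to
homozygous-alternative carriers, while heterozygotes scale by $(1+c)/2$,
which is what per-template weights 1 (ref) and $c$ (alt) imply.

Genotypes are re-called from the simulated reads by flat-prior maximum
binomial likelihood over expected alternative fractions
$\{\varepsilon, 1/2, 1-\varepsilon\}$ — a deliberately simple stand-in for
a production caller that produces the same FORMAT fields (GT, AD, DP, GQ,
with GQ the phred-scaled probability the call is wrong, capped at 99).
Calls below the depth floor are set missing. The VQSLOD-style site score
is drawn positive unless the configuration injects failures; the pipeline
only thresholds this score, it never fits a recalibration model.

## The synthetic cohort: what it emulates, what it does not

`sim_config()` defaults define the study conditions:

| parameter | default | rationale |
|---|---|---|
| samples per center | 1475 / 1085 / 740 | one third of the motivating cohort's census, same proportions; C1 uses KitA, C2/C3 use KitB |
| variants | 2,000 | biallelic exome SNPs, one per 10 kb |
| subpopulations, $F_{ST}$ | 3, 0.01 | mild within-continental substructure (Balding–Nichols) |
| prevalence | 0.5 | balanced case/control design |
| causal variants | 10 at MAF 0.08, OR 3.5 | matches the case/control MAF contrast of the study's top table (case ~0.08 vs control ~0.025) |
| biased variants | 8 (causal first), $c = 0.02$ in KitB | $\log_2(c/(1+c)) \approx -5.7$, the reported low AAF mode near $-6$ |
| depth | 60x, NB dispersion 8 | typical exome coverage |
| base error $\varepsilon$ | 0.005 | post-filter per-read error |
| missing-call depth floor | 6 | minimum depth for a usable call |
| Ti/Tv mix | 0.76 transitions | cohort Ti/Tv ≈ 3.2, typical of exonic regions |

Two deliberate consequences of these choices: causal MAF and OR sit where
the motivating study's novel variants sat, which keeps the planted
variants *past* the control-sample HWE filter — at common MAF (0.2+) the
kit-mixture of frequencies (a Wahlund-style homozygote excess) would
itself trip the HWE exclusion, which is exactly why capture bias at
common variants is less insidious; and the biased-kit efficiency 0.02
reproduces the reported second AAF mode near $\log_2 = -6$ rather than a
merely depressed-but-called AAF.

Age is drawn confounded with phenotype (cases older), so the optional
age-adjusted model (M3) loses the genetic signal, mirroring the design
confound described for the motivating cohort.

Not emulated: read alignment and BAM-level artifacts, indels and
multi-allelic sites, relatedness, contamination, sex-linked effects, LD
beyond chance correlation (variants are drawn independently, so the LD
pruning stage mostly removes nothing on synthetic data — its logic is
exercised by constructed fixtures), and any real VQSR model. Passing
tests therefore show the *procedure* is correct and calibrated, not that
real exomes behave this simply.

## QC stages and their thresholds

Defaults reproduce the published values end to end
(`qc_thresholds()`): per-sample SNP call rate > 95%, depth ≥ 10x at ≥ 90%
of called variants, Ti/Tv > 2.75; per-variant VQSLOD > 0, control-sample
HWE exact p ≥ 1e-6, ≥ 10 alternative-supporting reads cohort-wide;
pruning MAF ≥ 5%, HWE p ≥ 1e-4, pairwise $r^2 \le 0.2$ in 0.1 Mb windows,
plus an excluded-regions table (empty by default — the hypervariable
regions the published filter lists are build-specific coordinates, so on
synthetic genomes the mechanism is configurable rather than preloaded).

The HWE test is the conditional exact test on heterozygote counts given
allele counts, with the two-sided "probability ≤ observed" summation (not
mid-p; conventional and conservative). It is checked against a full
enumeration oracle for every table with up to 100 alleles. The HWE filter
uses all control samples (founder status is not modelled).

LD pruning scans each chromosome left to right and drops the *later*
variant of any pair within the window whose mean-imputed dosage
correlation squared exceeds the ceiling — deterministic and
position-stable.

## PCA, PC retention, clustering

Dosages are mean-imputed per variant, centered at $2\hat p$ and scaled by
$\sqrt{2\hat p(1-\hat p)}$ (unscaled dosages would let common variants
dominate). The sample-space covariance is eigendecomposed; when the
variant subset is smaller than the sample count the equivalent
variant-side problem is solved instead. Signs follow a fixed convention
(largest-magnitude loading positive) so coordinates are exactly
reproducible.

PCs are retained by the eigenvalue-above-1 rule, capped at `max_pcs`
(default 10): under the sample-covariance scaling the null eigenvalue
bulk extends above 1 (Marchenko–Pastur), so the uncapped rule would
retain a long tail of noise components on homogeneous data. The cap is
this package's guard; the rule itself is as published. Stratified
association fits recompute PC scores within the stratum by default
(configurable), since a stratum's substructure need not match the
cohort's.

Subpopulation *labels* come from k-means over the retained PCs with the
cluster count chosen by maximum mean silhouette — a deliberately simple
surrogate for model-based admixture estimation, justified because labels
are only used for visualization and sanity checks; the association
covariates are the PCs themselves.

## Association and batch-exclusive flagging

Each variant is tested under an additive logistic model (IRLS, tolerance
1e-8, ≤ 50 iterations; Wald p-value, as in the cited PLINK default; the
engine is `stats::glm.fit`). Model M1 adjusts for center and retained
PCs; M2 adds sex and the major-locus genotype covariate; M3 adds age.
Constant dosages are flagged rather than fitted; separation is flagged as
non-converged, not rescued (no Firth correction — a logged limitation).
Significance uses the Bonferroni threshold $\alpha / \#\text{tests}$.

"Batch-exclusive" is formalized as: full-cohort significant, *and* below
the per-stratum threshold in one kit's stratum, *and* above a null floor
(default p > 0.05) in the other. The per-stratum threshold defaults to
the full-cohort Bonferroni cutoff (configurable, since the visual
analysis it formalizes did not state one). A stratum fit whose dosage is
constant — the signature of complete allele dropout — counts as "no
evidence" (p treated as 1); only a variant genuinely missing from a
stratum table is `indeterminate`.

## Variant-level diagnostics

* **Per-kit metrics and ratios** — per-variant mean GQ, DP and AAF per
  kit and their $\log_2$ A/B ratios. The AAF averaging set is ambiguous
  in the source material (variant-wide mean vs per-carrier balance), so
  both are implemented: `aaf_mode = "carriers"` (default; samples with at
  least one alternative read, making the statistic read as allelic
  balance) and `"all"` (every called sample with reads).
* **Tails** — per metric, the 5% empirical tails of the ratio
  distribution (strict inequalities, so degenerate distributions have
  empty tails); a variant is a "largest-difference" variant if it is in
  either tail of *any* metric (the union rule).
* **Subset PCA separation** — genotype PCA restricted to a variant
  subset, scored by the mean silhouette of the kit labels on the first
  two PCs: a quantitative stand-in for "clear separation by kit" in an
  eigenvector plot.
* **AAF bimodality** — one- vs two-component Gaussian mixtures (EM via
  `mclust`, unequal variances) on $\log_2$ mean AAF; bimodal iff the
  two-component fit wins by BIC, both weights ≥ 0.05 and the modes are
  > 2 pooled SD apart.
* **Reference MAF concordance** — per variant, which kit's control MAF
  is closer (absolute distance after minor-allele folding; absolute
  rather than log-fold because biased-kit MAFs sit near zero) to an
  external reference frequency; summarized by winner counts and a sign
  test. On simulated data the truth frequencies serve as a synthetic
  reference panel. The null split is ~50/50 only when the kits have
  comparable sample sizes — with very unequal cohorts the larger kit
  wins more often through smaller sampling error alone, which is why the
  null-calibration checks use balanced kits.
* **Capture efficiency** — mean over heterozygous carriers of alt/ref
  reads, per variant; from called or truth heterozygotes. Under strong
  dropout called heterozygotes are a biased (ascertained) subset, so
  truth-het estimates are used for parameter-recovery checks and
  called-het estimates for real-data style diagnostics.

The planted-bias adjudication — the analogue of calling a
batch-discordant signal "likely real" — is the conjunction: AAF-ratio
tail membership, exclusive-kit association flag, and concordance winner
equal to the unbiased kit.

## Numerical choices and degenerate inputs

* HWE probabilities via log-gamma closed form, normalized in place; ties
  in the "≤ observed" rule use a $1 + 10^{-10}$ relative slack.
* Logistic fits drop per-variant missing dosages; covariate columns that
  are constant within a stratum (center inside a single center) are
  dropped automatically.
* PCA drops zero-variance variants after imputation with a message;
  eigenvalues are clipped at 0; null-space eigenvectors are excluded from
  reproducibility guarantees.
* k-means on identical points cannot split: the clusterer falls back to
  a single cluster. Ties in silhouette resolve to the smaller k.
* Tail quantiles use strict inequalities so an all-equal ratio vector
  yields zero-width tails.
* All randomness flows from one master seed; each stage derives a fixed
  sub-seed (`cohort`, `calls`, `kmeans`, ...), so stages are individually
  reproducible and the pipeline is byte-identical under a fixed
  configuration.

## Problem sizes used by the checks

The packaged studies run at desk scale, chosen to keep the full suite in
the tens of minutes while leaving the measured quantities well inside
their tolerances: null calibration at 2,000 samples × 20,000 variants
(one seed); planted-bias recovery at the default study conditions
(3,300 samples × 2,000 variants, five seeds, 8 biased variants each);
confounding control at 1,200 samples × 4,000 variants with two
subpopulations at $F_{ST} = 0.1$ and ±0.6 phenotype log-odds offsets.
The published-scale quantities that need no data (the Bonferroni worked
example, the center census) are computed directly.

## Known limitations

* The genotype caller and the VQSLOD stand-in are simplified; absolute GQ
  distributions are not calibrated against any production caller.
* No Firth or exact logistic fallback under separation; such variants are
  flagged and excluded from inference rather than rescued.
* The batch-exclusivity rule is a formalization of a visual analysis; its
  null floor and per-stratum threshold are conventions exposed as
  configuration, not estimated quantities.
* Simulated variants are unlinked; LD-pruning behaviour on real, linked
  data is exercised only by constructed fixtures.
* The concordance sign test assumes variants are independent; on real
  data, LD would make its p-value anticonservative.
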