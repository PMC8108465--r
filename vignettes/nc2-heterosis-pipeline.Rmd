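---
title: "Models and methods of the NC-II heterosis pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods of the NC-II heterosis pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hybridforge)
options(hybridforge.verbose = FALSE)
```

hybridforge implements the analysis chain of an NC-II factorial testcross
study: a panel of inbred maternal lines crossed to a small set of elite
testers, the resulting half-sibling F1 populations phenotyped in multiple
environments, unphenotyped hybrids predicted genomically, and the genetic
architecture of the traits (including heterosis) dissected by GWAS and QTL
classification. This vignette documents the models, the parameters that
matter, the numerical choices, and what the package's own synthetic checks
do and do not demonstrate.

## Genotype representation and filtering

Genotypes are biallelic SNP dosages (0/1/2 alt-allele copies, `NA` missing)
with variants sorted by (chromosome, position); positions are 1-based and all
intervals closed, the VCF convention. Inbred parents are assumed homozygous
at retained sites; residual heterozygous calls are never resolved by
sampling a gamete — they are handled deterministically by the cell-level
filter rule, which marks the derived hybrid call missing.

The parental filter applies five criteria in a fixed order: (1) heterozygous
parental calls flag the corresponding F1 cells missing (cells, not variants);
(2) variants with heterozygote rate at or above 10% among maternal lines
*or* 1/30 among testers are removed — the two pool thresholds reflect the
very different pool sizes, and either pool tripping the rule is treated as
disqualifying; (3) variants monomorphic within either pool are removed
(they carry no information about within-pool variation or cross
combinations); (4) variants with MAF below 0.02 across all parents jointly
are removed — the MAF is computed over the pooled panel because the rare
allele's information content depends on the whole parental set; (5) variants
whose minor homozygous genotype would occur in fewer than 0.5% of the
hybrids of the *full factorial* are removed. Criterion 5 deliberately uses
the full factorial rather than the training crosses: filtering precedes
hybrid inference and must not depend on which crosses happen to be
phenotyped. For homozygous parents the count is exact from parental
homozygote tallies (`n0_maternal * n0_paternal` etc.), which the test suite
verifies against per-cross enumeration. The filter is idempotent, and every
step logs counts in and out.

F1 dosages are the mid-parent dosage; missing hybrid calls are imputed by
the modal dosage among hybrids sharing the same tester at that variant, with
ties broken toward the lower dosage (a fixed, documented tie-break rather
than a coin flip). The mode imputer is a deterministic device: it restores
the common within-family genotype and never fabricates recombination.

## Phenotype processing

Multi-environment records are reduced to one value per line by the mixed
model `value = mu + location + year + line + e` with location and year fixed
and line random (REML via lme4). The line BLUP is the shrunken line effect
plus the grand fixed-effect mean, so in balanced data the BLUP ranking
equals the line-mean ranking and, as residual variance vanishes, BLUPs
converge to line means. Genotype-by-environment interaction is deliberately
omitted: with the handful of environments typical of such trials the
interaction variance is poorly identified, and the downstream analyses need
a single line value. Fixed terms with one observed level are dropped so
small fixtures remain estimable.

Check-row adjustment subtracts the local-minus-global mean of a repeated
check entry within a row window (default 25 rows). The formula is a simple
moving-check correction; it removes smooth spatial trends captured by the
checks and nothing else.

Mid-parent heterosis is computed on BLUP values, before any z-scoring:
`MPH = (y_h - mid) / mid` with `mid` the parental mean. MPH is
dimensionless, symmetric in the parents and invariant to rescaling; a zero
mid-parent value leaves it undefined (flagged `NA`). z-score normalisation
is estimated within one F1 population (one tester's hybrids), because
tester-driven population stratification would otherwise leak into genomic
prediction; transforms are kept alongside the values so predictions can be
mapped back to absolute units exactly.

## gBLUP and the REML kernel

Prediction uses `y = X beta + u + e`, `u ~ N(0, K sigma_u^2)`,
`e ~ N(0, I sigma_e^2)`, with `K = W W' / p` the centered genomic
relationship matrix (missing dosages mean-filled only inside this
computation) and `X` an intercept plus the maternal and paternal BLUPs of
the same trait. Parental phenotypes enter as fixed covariates to absorb
population stratification; BLUPs (not raw means) are used because they are
the package's best estimate of the parental genetic value.

REML is profiled on `lambda = sigma_u^2 / sigma_e^2`: one symmetric
eigendecomposition of `K`, rotation of `y` and `X`, then a grid search over
`log10(lambda)` in [-6, 6] (0.5 steps) refined by Brent optimisation in the
bracketing interval. `beta` and `sigma_e^2` are profiled out analytically.
Two numerical choices matter. Small negative eigenvalues (roundoff) are
clipped at zero, and a matrix whose smallest eigenvalue is materially
negative is rejected rather than repaired. When the profile is flat — with
`K = I` the ratio is unidentifiable — ties break toward the pure-noise
boundary (`lambda -> 0`), a parsimony rule that makes the estimator return
near-zero heritability instead of an arbitrary interior point. The reported
heritability is `sigma_u^2 mean(diag K) / (sigma_u^2 mean(diag K) +
sigma_e^2)`, i.e. the average model variance attributable to the random
effect, which makes simulation truth and estimate directly comparable.

Candidate hybrids are predicted as `K[cand, train] %*% alpha` plus the
covariate term, `alpha` being the rotated-residual weights of the fit; a
candidate genetically identical to a training sample receives its
prediction exactly. Two evaluation schemes mirror the study design:
leave-one-tester-out (train on all other testers' hybrids, predict the
held-out population) and the tester swap (base block of a maternal subset
across all testers, plus one tester's extension, predicting the other
tester's extension). Pearson correlations are computed per fold; fold
correlations on the z scale equal those on the absolute scale within one
population because the transform is linear.

## GWAS

The scan fits the null mixed model once per (population, trait) — the
population-parameters-previously-determined approximation — and tests every
variant by generalized least squares in the rotated space with Wald t
p-values (df = n - covariates - 1). With identity kinship and no covariates
this is *exactly* the simple-regression t-test, which the suite verifies to
1e-6 relative error; re-optimising the variance components per variant
would change third-decimal p-values at hundred-fold cost. The kinship matrix
is the single cGRM over all retained variants, including the tested one (no
leave-one-chromosome-out); this matches the single-GRM practice the pipeline
emulates and is documented because it shrinks signals at very strong loci
(proximal contamination). Monomorphic variants are reported at `p = 1`
rather than dropped so result rows stay aligned with the variant panel.

Conditional scans split on the two homozygous classes of a tag SNP
(heterozygotes and missing excluded — the maternal panel is inbred),
re-fitting kinship and null model within each class; classes under
`min_subgroup` (default 30) are skipped with a warning. The battery runs the
maternal population for each base trait and every F1 population for each
base and MPH trait, giving `T + P (T + T_mph)` scans.

## QTL calling and classification

Seed loci are maximal runs of significant SNPs (`p <= 1e-6`) with
consecutive gaps under 800 kbp — the LD decay length at `r^2 = 0.1` in the
kind of dense maize panel emulated here. Adjacent loci merge when any
cross-locus SNP pair exceeds `r^2 = 0.1` and the peaks are under 5 Mbp
apart, repeating until no pair qualifies. Because a merged locus re-derives
its peak (minimum p, ties to the lower position), the fixed point can depend
on merge order; the order is therefore part of the algorithm's definition:
loci are kept sorted by (chromosome, start) and the first qualifying pair is
merged at each step. The test suite checks this against an independently
coded exhaustive merge over 200 random fixtures. LD is computed on the same
population whose scan produced the loci, since that is the sample in which
the clumping question is posed.

Loci with at least 10 significant SNPs are QTLs with `significant` support.
Smaller loci receive one symmetric 400 kbp extension (half the LD length)
collecting SNPs at `p <= 1e-4`; reaching 10 total yields `suggestive`
support, otherwise the locus is dropped. The extension is applied once by
default — repeated extension would let a locus crawl arbitrarily far — with
`max_extensions` exposed for users who read the rule the other way.

Cross-population merging is the transitive closure of closed-interval
overlap (union-find with an interval sweep), recording contributing
populations and per-population peaks. Classification is a pure function of
the (maternal, F1, MPH) detection pattern: (1,1,0) additive, (1,0,1)
dominant, (0,1,0) epistatic DxA, (0,0,1) epistatic DxD. The remaining
patterns are completed deterministically: (0,1,1) is epistatic with
ambiguous subtype (reported DxA, flagged); (1,1,1) additive with a
dominance component (flagged); (1,0,0) — maternal-only detection, the
dominant scenario minus its MPH confirmation — maps to dominant, flagged;
(0,0,0) is unclassified. Flags are carried in an `ambiguous` column so no
information is destroyed. Cumulative class effects sum `|beta|` at the peak
SNP, averaging each merged QTL over the populations detecting it first so a
QTL found in many populations is not over-counted.

## Simulation studies

The FDR/power study spikes 20 QTNs with effects `beta_i = 0.96^i` into
variants drawn from the 0.25–0.35 MAF stratum, builds the purely genetic
phenotype `y = sum x_i beta_i` (no residual noise — the "observed" phenotype
is the genetic value, so accuracy degradation is attributable to the
prediction-noise model alone), corrupts it with
`e ~ N(0, var(y) (1 - r^2) / r^2)`, scans, and scores FDR at `p <= 1e-5`
and per-class detection power at permutation thresholds (alpha-quantile of
the per-permutation minimum p). QTN contributions are classed by
`PVE_i = beta_i f_i (1 - f_i)` *normalised to sum to one* before applying
the 7% and 4.5% thresholds: the raw product is not a variance fraction and
the class boundaries are only meaningful on the normalised scale; `mode =
"raw"` and a variance-based alternative (`beta^2 2f(1-f)`) are exposed. A
detected QTN is one contained in, or linked at `r^2 > 0.1` to, a
significant-SNP cluster formed by the QTL grouping rule; unlinked clusters
are false discoveries. Simulation scans omit the kinship term: the simulated
trait has no polygenic background, so the mixed model would only add cost.

The effect-gradient study shifts a base phenotype by `± effect * SD` on the
two homozygous classes of a randomly drawn mid-frequency SNP and counts the
fraction of 100 such SNPs passing `p = 2.2e-7`, per effect gradient
(0.1–1.9) and population size. Only the spiked SNP's own p-value decides
detection, so the scan reduces to one regression per SNP.

Desk-scale presets (reduced grids: 2,000 variants, sizes 207/600, r² levels
1.0/0.6/0.2, 50 repetitions, 100 permutations) are the package's own
checking conditions; the full-scale settings (100,000 variants, six sizes,
six levels, 500 repetitions) are config defaults for users with the
corresponding compute. These sizes were chosen so the qualitative contrasts
(power monotone in n and r², FDR not rising as accuracy falls) are resolved
well above Monte-Carlo noise — the checks allow 0.03 slack on power and
0.05 on FDR for 50-repetition grids.

## The synthetic study generator

`gen_inbred_genotypes()` emulates a resequenced inbred panel: dosages 0/2
with a 0.5% residual heterozygote rate, allele indicators from a Gaussian
copula whose latent process is AR(1) within blocks (so each variant keeps
its marginal frequency exactly while r² decays with distance), and
block-coherent allele frequencies (a shared base frequency per block with
0.01 jitter, coherent minor-allele orientation) — markers on one haplotype
block really do carry similar frequencies, and without this the binary
correlation between neighbours is artificially attenuated. Chromosome names
are zero-padded so lexicographic and numeric order agree.

`gen_full_study()` assembles a complete scaled-down study: 300 maternal
lines x 5 testers, 1,200 markers on 10 chromosomes at 50 kbp spacing with
40-marker LD blocks (`rho = 0.985`) — a marker-density-to-LD-length ratio
matching dense resequencing panels, so each causal locus is tagged by tens
of markers as the >= 10-SNP support rule presumes. Three traits emulate the
canonical architectures: DTT with three additive QTLs (2.0/1.5/1.0 days per
allele); PH with a 12 cm dominant QTL (dwarfing-gene scale; every tester
carries the complementing allele, so the locus segregates in the maternal
panel and in MPH but is flat in hybrids) and an 8 cm epistatically masked
QTL (the masker fixed repressive in the maternal pool, activating in all
testers); EW with six small masked effects plus one small additive QTL.
Environments add location and year main effects and per-plot noise over 3
locations x 2 years; line-level polygenic deviates are drawn independently
of the markers so they behave as extra noise rather than confounding
structure. Purely additive loci cancel exactly in expected MPH — the
algebra `(m + t)/2 - (m + t)/2 = 0` — which is what makes the additive
pattern (detected in maternal and F1, absent in MPH) emerge rather than
being imposed.

What the passing checks show: the pipeline recovers a planted epistatically
masked locus as epistatic-class in at least 4 of 5 seeds, end to end from
raw multi-environment phenotypes. What they do not show: performance on
real data with pervasive G×E, kinship confounding between causal loci and
background, allele-frequency spectra skewed toward rare variants, or
assembly/genotyping error — none of which the generator emulates. The
dominant planted QTL is recovered less reliably than the masked one, an
honest reflection of single-GRM shrinkage at strong loci and of the general
difficulty of detecting dominant QTLs at stringent thresholds.

## Molecular design breeding

Haplotype groups partition the samples homozygous and non-missing at all
selected loci, labelled `Hap1..HapK` in lexicographic order of the allele
combination — canonical, but not guaranteed to match any external figure's
numbering. Group comparisons use Welch's t-test against a designated
reference (robust to unequal variances, which differ systematically between
haplotype groups). "Not significantly reduced" is operationalised as *not*
(mean below reference *and* p < 0.05), so a group is only excluded when
both the direction and the evidence are against it. Ranking of the
survivors is lexicographic in the minimised trait means with ties broken by
group label, making the selection deterministic and stable under input
reordering. The two-locus epistasis table reports homozygous cell means and
the interaction contrast `(AA,BB) - (AA,bb) - (aa,BB) + (aa,bb)` with a
plug-in standard error; an empty or singleton corner leaves the contrast
undefined rather than silently extrapolated.

## Known limitations

- Haplotype-based imputation is out of scope; the within-tester mode
  imputer is deterministic and family-aware but cannot recover recombinant
  haplotypes.
- The scan reuses null variance components across variants; very strong
  loci are slightly conservative, and `fit_null_lmm()` + per-subset scans
  are the tool for users needing exact per-variant REML on small panels.
- The single-GRM kinship (no LOCO) shrinks signals at major loci; this is a
  faithful design choice, not an oversight.
- The QTL merge order is canonicalised; other orders can yield different
  (equally defensible) fixed points on adversarial inputs.
- Pipeline-level checks run at desk scale; full-scale simulation presets
  exist in the configs but are not exercised by the test suite.
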