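---
title: "Methods and design notes for phenodiv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for phenodiv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(phenodiv)
```

`phenodiv` analyses a replicated berry germplasm trial on two axes — the
phenolic/antioxidant phenotype measured by five colorimetric assays, and
the genetic structure measured by diploid SSR markers — and bridges them
with a Mantel permutation test. This vignette records the statistical
models, the tunable parameters, and the design decisions behind the
implementation, including those points where more than one reasonable
choice existed.

## 1. Assay quantification

All five assays share one extraction context: `sampleMass` grams of tissue
(berries: 5 g, leaves: 2.5 g) extracted into `extractVolume` mL of 80%
ethanol (30 mL). The cuvette concentration obtained from a calibration
curve, multiplied by the record's dilution factor, gives the extract
concentration; scaling by extract volume and sample mass yields the
reported unit.

* **Calibration** is ordinary least squares with intercept
  (`fitStandardCurve`). An intercept is retained because reagent blanks
  rarely sit at exactly zero absorbance; r² is reported so that poor
  curves can be rejected by the analyst. Inverse predictions outside the
  calibrated standard range are returned but flagged as extrapolation —
  a warning, not an error, because dilution-series endpoints routinely
  drift a few percent outside the calibrated window.
* **TPC/TFC** (Folin–Ciocalteau; aluminium-chloride flavonoids): one
  reading each, expressed as mg gallic acid / rutin equivalents per 100 g.
* **TAC** (pH-differential anthocyanins): four readings; the differential
  absorbance uses the cyanidin-3-glucoside constants ε = 26,900 L mol⁻¹
  cm⁻¹ and MW = 449.2 g mol⁻¹ with a 1-cm path length (the standard cuvette;
  the path length is fixed rather than exposed because every published
  variant of this protocol uses 1 cm). A negative differential — possible
  for near-colourless (yellow-fruited) samples under replicate noise —
  clamps to zero with a warning rather than erroring, since a hard error
  would make whole yellow-fruit panels unprocessable.
* **ABTS**: percent inhibition of the blank, converted through a Trolox
  inhibition curve. The 20–80% inhibition window is a *flag* on the output
  (`inhibition_out_of_range`), not a rejection: the analyst decides whether
  to re-dilute. A blank outside 0.70 ± 0.02 AU raises a configuration
  warning because the working solution is titrated to that absorbance.
* **FRAP**: Trolox curve in mM at 593 nm; µmol TE per g.
* **Dry weight**: per-100-g-FW concentrations divide by 100 and by the
  tissue dry-matter fraction (strictly inside (0, 1)); per-g-FW activities
  divide by the fraction only.

Dilution factors are per-record inputs; the package defaults
(`defaultDilutionFactors()`: 10× except TFC read neat) encode the usual
mixing ratios (e.g. 0.2 mL sample into 1.8 mL buffer) but are not
hard-wired, because the factor actually applied varies sample by sample in
practice.

## 2. Genotype statistics

Replicate summaries report mean ± SE (SE = sd/√n; undefined and reported
missing at n = 1). The trial design this package targets is balanced at
n = 3 replicates.

**Duncan's multiple range test** (`duncanTest`) follows the classical
definition: means ranked; a range spanning *p* ordered means is tested
against `R_p = q(α_p, p, df_e)·√(MSE/n)`, with studentized-range quantiles
at Duncan's protection levels `α_p = 1 − (1−α)^(p−1)`; the step-down rule
declares every range inside a non-significant range non-significant without
testing. At span 2 the critical range coincides with the plain studentized
range at α — Duncan is never more conservative there. With unequal group
sizes the harmonic mean of the n's replaces n, with a warning. `qtukey`
can fail to converge for low probabilities at large group counts (spans
above ~20); the implementation then inverts `ptukey` numerically
(bisection via `uniroot`, tolerance 1e-9), which is slower but stable.
Compact letters are assigned by insert-and-absorb; ties in the mean
ranking keep input order, so output is deterministic.

**Correlation matrices** are computed across *genotype means*, not the
replicate observations. A mean-level correlation is the standard reading
when a study publishes only means ± SE, and it is what the packaged panel
reproduces; replicate-level correlations would mix within- and
between-genotype variation. Deviations of a few hundredths from published
coefficients are expected when recomputing from rounded published means.
Variables with zero variance yield `NA` with a warning rather than an
error, so one degenerate assay does not invalidate a whole matrix.

## 3. SSR diversity

Allele identity is the integer fragment size in bp; sizes are assumed
pre-binned by the caller (no binning window is applied). Missing calls
drop from the affected locus's denominators only — genotypes are never
list-wise deleted. Per locus: `He = 1 − Σp²` (plain gene diversity,
matching the usual reporting convention; the small-sample `2n/(2n−1)`
correction is available behind `corrected = TRUE` because software
differs on this point), `Ho` = fraction of typed heterozygotes, and
`PIC = 1 − Σp² − Σ_{i<j} 2p_i²p_j²`. Monomorphic loci carry zero
diversity and are excluded from panel summaries by default
(`polymorphicOnly = TRUE`), mirroring the convention of reporting genetic
statistics for polymorphic markers only.

## 4. Distances, UPGMA and the Mantel test

**Biochemical distance** is Euclidean over z-scored assay means by
default. The assays live on very different scales (total phenolics in the
hundreds of mg/100 g, anthocyanins in the tens, FRAP/ABTS in the tens of
µmol/g); an unstandardized distance would be dominated by the
largest-scaled variable. `standardize = FALSE` disables z-scoring.

**Genetic distance** offers two metrics because the encoding of "locus
size values" into a distance is genuinely open:

* `allele_size_euclidean` — per locus the call is the sorted two-allele
  size vector (sorting makes heterozygote order deterministic); Euclidean
  over the concatenation, with pairs missing loci rescaled by
  `√(L/L_used)` so distances stay on the full-panel scale. A per-locus
  mean-size encoding is available (`encoding = "mean"`). This metric is
  sensitive to fragment-length differences, i.e. it treats allele size as
  a quantitative character.
* `shared_allele` — `D = 1 − mean(shared alleles / 2)`, counting shared
  alleles as multisets. This is the metric of choice for marker panels
  where size differences carry no dosage meaning, and it is the package
  default in `runPipeline`.

**UPGMA** (`upgmaTree`) is the textbook unweighted average-linkage
agglomeration, written out rather than delegated so that two contracts
hold exactly: node heights are *half* the merge distance (hence the tree
is ultrametric and cophenetic distances equal merge distances — running
UPGMA on its own cophenetic matrix is a fixed point), and ties in the
minimum inter-cluster distance break deterministically by the smallest
contained leaf index (tie tolerance 1e-12), giving bit-reproducible
Newick output. The test suite cross-checks merge heights and cophenetic
structure against `stats::hclust(method = "average")` on tie-free random
matrices. Newick export goes through `ape`; leaf labels are sanitised
(Newick syntax characters become underscores) because germplasm names
contain spaces and parentheses.

**Mantel test** (`mantelTest`): Pearson correlation of off-diagonal
entries, matrices aligned by label (never by position), one-sided upper
tail with the +1 permutation correction, default 9,999 permutations, and
an optional seed that leaves the caller's RNG state untouched. The test
suite verifies the sampled p against full enumeration of all 4! = 24
relabelings of a four-object pair, and the statistic against
`vegan::mantel`.

## 5. The synthetic-data generator

The generator reproduces the statistical structure the analysis assumes,
at the scale of the study design it targets: 25 genotypes (24 in the SSR
panel), 3 replicates, 7 polymorphic SSR loci with 2,3,2,2,3,7,2 alleles.

* **Truth table**: per-genotype assay means default to the packaged panel
  means, so simulated data inherit realistic scales and between-genotype
  correlation structure.
* **Replicate noise**: multiplicative, `Normal(truth, cv·truth)` truncated
  at zero, default CV = 0.08 — chosen to match the magnitude of the
  published standard errors (SE/mean mostly 0.03–0.13 at n = 3). Truncation
  only matters for near-zero anthocyanin truths.
* **Absorbance emission**: each replicate value is pushed backwards
  through the quantification chain with the default curves and dilution
  factors, so `quantifyAssays` on generator output recovers the replicate
  values exactly; at CV = 0 the two modules are exact inverses. This is
  what makes the quantification chain testable end-to-end.
* **Genotypes**: Hardy–Weinberg draws, loci unlinked, frequencies chosen
  to reproduce the packaged panel's per-locus He (all deliberately
  non-uniform — real germplasm frequencies never are, and exactly uniform
  frequencies are a degenerate point for variance formulas).
* **Association**: the dosage (0/1/2) of one designated allele shifts
  assay truths by `effect · dosage · sd(trait means)`. Two design points
  were genuinely open and were settled by pilot simulation *before* the
  validation thresholds were frozen:
  1. *Which traits shift.* A pathway-regulatory allele moves the whole
     phenolic pool, and the panel's own correlation structure (TPC, TFC,
     FRAP, ABTS inter-correlated at 0.76–0.92) says these traits co-vary;
     the default therefore couples all four, leaving anthocyanins (a
     distinct sub-pool) uncoupled. Coupling only two traits caps the
     attainable matrix correlation near 0.28 regardless of effect size,
     because z-scoring caps each trait's variance share.
  2. *Which locus is designated.* A biallelic locus (default FaFS01,
     minor-allele frequency 0.27): there the dosage determines the
     genotype, so the per-locus shared-allele distance is a deterministic
     monotone function of the dosage difference. Designating the
     seven-allele locus instead mostly adds distance noise unrelated to
     dosage.
  Effect presets: `"none"` = 0, `"moderate"` = 2, `"strong"` = 4 SD per
  allele copy. Strong is a major-gene effect — of the order of the
  anthocyanin difference between yellow- and red-fruited genotypes — and
  under it the Mantel test at n = 24 rejects in well over 80% of runs.

**What the generator does not emulate**: linkage between loci, null
alleles and genotyping error, genotype-by-environment interaction,
non-normal replicate error, and pedigree structure among genotypes
(real breeding lines are related; HWE draws are not). Passing tests on
simulated data therefore validate the estimators and the pipeline
plumbing, not robustness to those real-data complications.

## 6. Validation choices and problem sizes

The test suite validates operating characteristics at sizes chosen to
keep the full run around a minute: Mantel type-I error on 1,000
independent random matrix pairs at n = 15 (99 permutations — at that count
the +1-corrected threshold p ≤ 0.05 is exact); Mantel power over 100
seeded studies at n = 24 with the strong preset; Duncan letters against a
brute-force all-pairs oracle on 500 random instances of 2–8 groups;
He/Ho/PIC recovery over 200 Hardy–Weinberg panels of n = 200 genotypes.
For the recovery check, "theoretical SE" is the binomial-theory
`√(θ(1−θ)/n)` over typed individuals applied to each statistic — the
classical proportion standard error. First-order delta-method and
exact-moment variances were evaluated in piloting and found to give 2-SE
normal intervals with coverage just under 95% (the normal-tail
approximation consumes the nominal margin), which would conflate
approximation error with estimator defects; the binomial form is mildly
conservative and makes the 95% recovery bar meaningful.

## 7. Known limitations

* Duncan's test controls error only through its protection levels; no
  additional multiple-testing control is applied across assays.
* `pearsonMatrix` uses pairwise-complete observations; matrices from very
  patchy data need not be positive semi-definite.
* The UPGMA implementation is O(n³) — ample for germplasm panels
  (tens of genotypes), not for thousands of leaves.
* Mantel tests have known low power against nonlinear association; the
  power figures here are specific to the generator's linear dosage
  mechanism.
* The shared-allele distance treats loci equally; no weighting by locus
  information content is offered.
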