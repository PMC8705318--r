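---
title: "Linking rhizosphere microbiome shifts to root-exudate chemistry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking rhizosphere microbiome shifts to root-exudate chemistry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhizoxlink)
```

## The analysis problem

A plant genotype (here, a tomato line carrying a disrupted ethylene receptor,
compared to its isogenic wild type) can reshape its rhizosphere microbiome
indirectly, by changing what the roots exude. Establishing that chain
computationally requires four stages, each of which this package implements:

1. **Quantification** — turn read-to-gene mappings from shotgun metagenomes
   into gene, taxon and KEGG-ortholog abundance tables, handling reads that
   map to several genes.
2. **Community statistics** — alpha diversity, Hellinger-based PCA, and
   Bray-Curtis PERMANOVA (one-way per developmental stage, two-way over the
   genotype × stage design).
3. **Differential features** — genotype-differential metabolite ions
   (volcano-style, adjusted p) and taxa / functional categories
   (STAMP-style, raw p with a relative-abundance filter).
4. **Cross-assay linkage** — a random-pairing resampled Pearson correlation
   that associates differential taxa with differential ions even though the
   two assays were measured on *different plants*.

A synthetic-data generator emulating the study design (two genotypes × three
stages; six metagenome and three exudate replicates per condition, i.e. 36
and 18 samples) provides ground truth for every stage.

## Gene abundance with multi-mapped reads

For one sample, each *uniquely* mapped read of gene $g$ (length $l_g$ base
pairs) contributes $1/l_g$:

$$\mathrm{Ab}(U)_g = \sum_{\text{unique reads of } g} \frac{1}{l_g}.$$

A *multi-mapped* read with candidate set $C$ carries one unit of read mass,
redistributed over its candidates proportionally to their unique-read
abundances through

$$\mathrm{Co}_g = \frac{\mathrm{Ab}(U)_g}{\sum_{j \in C}\mathrm{Ab}(U)_j},
\qquad
\mathrm{Ab}(M)_g = \sum_{\text{multireads} \ni g} \frac{\mathrm{Co}_g}{l_g},
\qquad
\mathrm{Ab}(S) = \mathrm{Ab}(U) + \mathrm{Ab}(M).$$

Numerical choices worth stating explicitly:

* **Single pass.** $\mathrm{Co}$ is computed once, from unique-read
  abundances only; there is no EM-style iteration. This is the literal
  reading of the printed equations and keeps the estimator deterministic.
* **Uninformative multireads.** If no candidate of a read has unique-read
  support, $\mathrm{Co}$ is $0/0$; the read's mass is then split uniformly
  ($1/|C|$ each), so total read mass is always conserved
  ($\sum_g \mathrm{Ab}(M)_g\, l_g$ equals the number of multireads — a
  property the tests assert on every synthetic run). The number of fallback
  reads is reported per sample.
* **"Unique" means a candidate set of size one after deduplication**; a read
  listed as `g1,g1` is a unique read of `g1`.
* Lengths are taken from the catalog in base pairs; no effective-length
  correction is applied.

Aggregation to taxa or KEGG orthologs sums $\mathrm{Ab}(S)$ over member
genes; unannotated genes are dropped with a reported count.

## Community statistics

These stages wrap vegan, the toolchain this analysis style comes from:
`decostand` (Hellinger), `diversity`/`specnumber` (Shannon with natural
logarithm — the ecology default — and richness), `vegdist` (Bray-Curtis) and
`adonis2` (PERMANOVA, pseudo-$F$ from the Anderson partitioning of squared
inter-point distances, $p = (b + 1)/(m + 1)$ over $m$ permutations so a
permutation p-value is never exactly zero). The test suite checks the
wrappers against independent loop-based evaluations of the partitioning
formulas and against exhaustive label enumeration at $n = 6$, not against
vegan itself.

Two deliberate interpretation choices:

* PCA is run on Hellinger-transformed relative abundances; PERMANOVA on
  Bray-Curtis of untransformed relative abundances. Both inputs are plain
  matrices, so a user can pass either transform to either test.
* The two-way PERMANOVA supports **balanced crossed designs only** and
  permutes raw sample identities (unrestricted). With equal cell sizes,
  sequential and marginal sums of squares coincide, so no Type-I/II/III
  choice arises; restricted permutation schemes are out of scope. A factor
  with a single level is dropped, which reduces the model to the one-way
  case exactly — a property the tests assert. Unbalanced designs are
  rejected rather than silently approximated.
* PCA components are sign-fixed (largest-magnitude loading positive) for
  reproducibility across BLAS implementations.

## Differential features

Metabolite ions use Welch's $t$ on $\log_2(\text{intensity} + 1)$ with
Benjamini–Hochberg adjustment and the volcano classes
increased / decreased / unrelated at adjusted $p < 0.05$. The
negative-binomial GLM machinery sometimes used for ion counts is *not*
re-implemented here: the package's focus is the downstream linkage, the
two-group Welch test on logged intensities is a transparent, calibrated
substitute (the null-calibration test verifies its size), and externally
computed results can be substituted since all downstream stages take plain
feature subsets.

Taxa and KEGG level-2 categories use the STAMP convention: relative
abundances, features with mean RA $\le$ 0.01% excluded *before* testing,
significance at **raw** $p < 0.05$ (BH-adjusted values are still reported).
The summed mean RA of the significant set — "what fraction of the community
is genotype-responsive" — is reported; the denominator is summed relative
abundance, not feature count. Genotype-unique features ("present" meaning
abundance above a threshold, default strictly positive, in at least one
replicate of a genotype × stage cell) give Venn-style counts.

## Random-pairing correlation between unpaired assays

The metagenome (6 replicates/condition) and the exudate metabolome
(3 replicates/condition) come from different plants, so no replicate-level
pairing exists. The linkage statistic therefore repeats, 10,000 times by
default:

1. within each genotype × stage condition, draw 3 of the 6 metagenome
   replicates without replacement (redrawn independently every iteration);
2. pair them with the 3 exudate replicates by a uniformly random bijection;
3. pool the paired samples across all 6 conditions (18 points) and compute
   Pearson correlations per (taxon, ion) pair on transformed values —
   Hellinger-transformed taxa RA and log intensities by default, both
   configurable;
4. report the mean and SD of $r$ across iterations. Iterations where a pair
   has zero variance contribute nothing and are counted; pairs with fewer
   than 3 valid iterations are reported as undefined rather than averaged.

The key statistical point, which the generator and the tests encode: random
pairing destroys any replicate-level coupling, so **only correlation carried
by the condition-mean profiles is recoverable**. In the limit of zero
within-condition variance the mean $r$ equals the Pearson correlation of the
six condition means exactly, independent of the seed — an assertable
identity. Associations with $|\bar r| \ge 0.5$ (inclusive) are displayed and
classified by crossing the taxon's differential direction with the sign of
$\bar r$: WT-higher with $r > 0$ is type i, WT-higher with $r < 0$ type ii,
mutant-higher with $r > 0$ type iii, mutant-higher with $r < 0$ type iv.

What this statistic is *not*: it is not a causal claim, not a partial
correlation, and the quantity correlated (pooled transformed abundances
across all conditions) is one defensible reading of a procedure that could
also be run per stage; the pooled form is the default because 6 condition
means give the correlation room to be estimated at all.

## The synthetic generator

The generator is first-class, tested code, not a fixture. Its model:

* **Taxa.** Baseline log-abundances $\mathcal{N}(0, \sigma_\text{base}^2)$
  ($\sigma_\text{base} = 1$), condition-level shifts of $\pm 2\ \log_2$
  units on 20 planted genotype-differential taxa (half enriched in the
  mutant, half suppressed, drawn from taxa above the lower baseline quartile
  so planted features sit above the RA detection filter) and $+1\ \log_2$ on
  20 stage-responsive taxa, plus log-normal replicate noise
  ($\sigma_\text{rep} = 0.3$). Reads are then drawn multinomially with
  probability proportional to abundance × gene length. The log-normal ×
  multinomial compound gives overdispersed counts (the standard microbiome
  assumption) while keeping the per-sample read total fixed.
* **Metabolites.** Log-normal intensities around condition means;
  10 planted ions at $\pm 2\ \log_2$; replicate noise
  $\sigma_\text{rep} = 0.1$ (a 10% CV, the low-noise regime of
  quality-controlled LC-MS intensity data). Power matters here: with
  $n = 3$ per genotype and BH correction over 300 ions, a $2\ \log_2$ shift
  is only reliably detected when replicate CVs are near this level — a
  limitation of the *design*, not of the test, and the reason the default
  emulates low-noise replicates. At biological CVs of 30% and more, this
  design has little adjusted-power, which the null-calibration and recovery
  tests make visible if defaults are changed.
* **Planted correlation.** Five (taxon, ion) pairs with target
  condition-mean correlation $\rho = 0.9$, realized by an *empirically
  exact* Gaussian-copula construction: the random profile components vary at
  the stage level only (constant across genotypes within a stage, so
  planting a correlation never perturbs the within-stage genotype contrast
  that makes the features differential), are orthogonalized against the
  planted effect profiles, and the latent mixing coefficient is solved so
  the realized 6-point condition-mean Pearson equals $\rho$ exactly. The
  target is infeasible when the planted effects already impose a stronger
  opposite correlation than $\rho$; this raises an error naming the pair.
  Pairs sharing a feature fall back to a Cholesky draw of the implied joint
  correlation (distributional rather than exact; a non-positive-definite
  specification is an error naming the offending pairs).

What the generator does **not** emulate: phylogenetic correlation among
taxa, compositional coupling beyond the shared softmax denominator,
sequencing error or mapping ambiguity beyond uniform decoy genes,
ion-intensity heteroscedasticity, batch effects, or missing values. Passing
recovery tests on this generator therefore shows the pipeline is correct and
calibrated under its stated model — not that real rhizosphere data will be
as kind.

## Determinism and problem sizes

Every stochastic step takes a seed; the pipeline derives per-stage seeds
from one global seed through a fixed integer scheme, so stages rerun
individually reproduce the pipeline's results, and identical-seed runs
produce byte-identical output files (floats are serialized at 17
significant digits). The test suite runs the full default design (36 + 18
samples, 200 taxa, 300 ions, 10,000 pairings), 1000-replicate null
calibrations of the one-way PERMANOVA at $n = 12$ with 199 permutations,
and 100-replicate recovery simulations for the two-way PERMANOVA at
$n = 36$ — sizes chosen so the whole suite completes in about a minute on
one core while keeping Monte-Carlo intervals tight enough to be meaningful.

## A short example

```{r example, eval = FALSE}
cfg <- design_config(seed = 11)
experiment <- generate_experiment(cfg)
result <- run_all(experiment)
print(result)
result$correlations[!is.na(result$correlations$mean_r) &
                      abs(result$correlations$mean_r) >= 0.5, ]
```
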