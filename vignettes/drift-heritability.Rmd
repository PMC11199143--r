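---
title: "Heritability of polygenic traits under bottlenecks, migration and growth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Heritability of polygenic traits under bottlenecks, migration and growth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The question

Isolated sub-populations founded through a bottleneck (Ashkenazi Jews,
Finns, Icelanders, or on a larger scale all non-Africans after the
out-of-Africa contraction) are prized in GWAS because drift can push
otherwise-rare large-effect variants to workable frequencies. But the same
drift acts on *every* causal SNP of a polygenic trait at once, so the
trait's heritability and its whole genetic architecture in the bottlenecked
population differ from those in the source population where the trait
evolved. `driftherit` simulates this process forward and asks two
questions: how do bottleneck severity, age, migration and post-founding
growth move the distribution of heritability, and how much of the change
survives the power-limited view a real GWAS has of the SNP set?

## Model

**Demography.** An ancestral population of `N0` diploids splits `T`
generations ago. The Reference population keeps size `N0`; the Bottlenecked
population is founded with `N` diploids and grows exponentially forward in
time at rate `g`, reaching `N e^{gT}` today (with `g = 0.015` and `T = 200`
that is a nearly 20-fold expansion). Optionally a fraction `m` of the
bottlenecked population is replaced by migrants from the Reference
population every generation. Genealogies with recombination are generated
by the msprime coalescent simulator (sequentially Markovian-exact ancestry
with a uniform recombination map), and mutations are superimposed under the
infinite-sites model with no restriction on when they occur. The model is
neutral: selection is assumed to have shaped the architecture in the
ancestral past and to be ineffective (or absent) after the contraction, so
drift is the only force moving frequencies.

**Trait.** Every simulated SNP is causal — the mutation rate is interpreted
as already scaled by the polygenicity fraction. Writing `f_j` for the
derived-allele frequency of SNP `j` in the *Reference sample*, effect sizes
are drawn once per trait as

    beta_j ~ N(0, [f_j (1 - f_j)]^s)

with selection parameter `s`. The default `s = -1` encodes negative
selection on the trait: large effects are confined to rare alleles (the
LDAK-style frequency coupling). Genetic values are `Y_i = sum_j X_ij
beta_j` with genotypes coded 0/1/2, phenotypes add `N(0, Ve)` environmental
noise, and heritability is

    h2 = Vg / (Vg + Ve),   Vg = Var(Y)

with `Var` the population-convention variance over the sampled individuals.
`Ve` is calibrated once, in the Reference sample, so that `h2_ref` equals
the target (0.5 by default), and is then held fixed — the
constant-environment assumption. Re-evaluating `Vg` in the bottleneck
sample with the *same* effect sizes and the same `Ve` gives the bottleneck
heritability. Nothing is estimated from phenotype data; effect sizes are
known by construction, which isolates the demographic signal from
estimation noise.

**Thresholding.** A GWAS only sees SNPs it has power to detect. The
detectability score of SNP `j` in the bottleneck population is either its
variance explained `v_j = f_j (1 - f_j) beta_j^2` (frequencies taken in the
bottleneck sample) or its marginal-regression p-value from a simulated
bottleneck GWAS. Scores from 200 independent calibration traits sharing the
demography are pooled, and the cutoff is placed so the top `1/2^n` of the
pooled distribution survives. Fresh evaluation traits are then filtered at
that fixed cutoff and their heritability recomputed from the surviving SNPs
only (same betas, same `Ve`). The calibration batch is never reused for
evaluation, so the cutoff is independent of the traits being scored.

## Parameters that matter

| parameter | meaning | default | why |
|---|---|---|---|
| `N0` | Reference diploid size | 10,000 | standard human-scale effective size |
| `N` | founding bottleneck size | 1,000 | severe but recoverable contraction |
| `T` | split time (generations) | 200 | ~6 kya, Ashkenazi-founding scale |
| `m` | migration fraction/generation | 0 | isolation; 0.01 already offsets much drift |
| `g` | growth rate/generation | 0 | 0.015 gives ~20-fold growth over 200 generations |
| map length | Morgans | 0.1 | one short chromosome; replicates stand in for more genome |
| physical length | bp | 1e7 | puts the map at the human-typical 1e-8/bp |
| `causal_mutation_rate` | per bp per generation | 4e-10 | theta = 160: a few hundred to ~2000 causal SNPs per sample; not a printed value, chosen for realistic polygenicity, and all qualitative results should be robust to it |
| samples | diploids per population | 500 + 500 | large enough that sample variance tracks population variance |
| `s` | selection parameter | -1 | negative selection on the trait |
| `h2_target` | Reference heritability | 0.5 | the calibrated control condition |

Ploidy is diploid with 0/1/2 coding (the standard GWAS convention); `N0`
and `N` count diploid individuals and the coalescent backend is configured
in the same units.

## What the generator emulates — and what it does not

The synthetic-data stage reproduces exactly the stated world: a clean
two-population split with constant `N0`, instantaneous founding at size
`N`, exponential growth, continuous one-way migration, a single uniform
recombination map, and every SNP causal with a Gaussian frequency-coupled
effect. Real data differ in ways that are deliberately out of scope: no
selection acts during the simulated epoch, there is no dominance or
epistasis, no gene–environment interaction, the environment has equal
variance in both populations, non-causal markers and linkage-based
fine-mapping are absent, and the genome is one short chromosome rather
than a genome-wide mosaic of variable recombination. A green test
therefore establishes that the *drift mechanics and their bookkeeping* are
right, not that any particular human trait behaves quantitatively this
way.

Each replicate is an independent (genealogy, trait) pair: new genealogies
and new effect sizes every time, so the spread across replicates mixes
genealogical and architectural randomness, as intended. Averages over 200
replicates of a 0.1 Morgan genome can be read as one 20 Morgan genome's
worth of independent trait realisations.

## Numerical and design choices

* **Variance convention.** Genetic variances divide by `n`, not `n - 1`
  (`Var(.)` over the simulated sample; at `n >= 250` the distinction is
  negligible but the calibration identity is kept exact). Across-replicate
  summaries (variance of heritability, bootstrap) use the usual sample
  variance.
* **Quantile convention for thresholds.** The cutoff is the k-th most
  favourable pooled score with `k = floor(pool_size / 2^n)`, and retention
  is by weak inequality on the favourable side. This makes the worked
  example "pool = {1..32}, n = 5 retains exactly the top value" true, keeps
  the all-scores-equal case fully retained, and makes `n = 0` the
  degenerate retain-everything threshold. A pool too small for even one
  survivor raises an explicit empty-retention error at calibration time; an
  *evaluation* trait in which no SNP passes simply reports thresholded
  heritability 0.
* **Scoring population.** Thresholding scores are always computed in the
  bottleneck population (its frequencies, its phenotypes) — the population
  in which the hypothetical GWAS runs. Effect sizes, in contrast, are
  always the Reference-drawn ones.
* **`T = 0`.** A split at the sampling instant is degenerate for the
  coalescent backend; it is simulated as a single panmictic population of
  size `N0` from which both samples are drawn, which is also the natural
  limit (frequency differences reduce to binomial sampling noise).
* **Empty traits.** A scenario with no Reference-segregating site raises a
  typed condition (`driftherit_empty_trait`); batch drivers record such
  replicates as missing rows rather than aborting a sweep.
* **Bootstrap flavour.** "Empirical bootstrap" is read as the basic/pivot
  interval `[2 vhat - q_{1-a/2}, 2 vhat - q_{a/2}]`; the percentile interval
  is available via `type = "percentile"`. No BCa.
* **Fisher-z standard errors.** `se_z = 1/sqrt(n - 3)` back-transformed to
  the correlation scale symmetrically; at `|r| = 1` (within 1e-12, to
  absorb floating error on collinear input) the standard error is reported
  as 0.
* **Regression direction.** The Fig.-4-style coefficient regresses
  thresholded heritability *on* simulated heritability, so "1" means the
  thresholded view tracks the truth one-for-one.
* **Error bars.** Sweep summaries report the standard error of the mean,
  and the column is named `se_mean_h2_bot` so the choice is explicit.
* **Seed discipline.** Every replicate's seeds derive from one master seed
  by sampling distinct integers in `[1, 2^31 - 2]` without replacement
  under that master seed: reproducible, collision-free, and parallelisable.
  msprime's ancestry seed is the replicate seed; its mutation seed is a
  fixed multiplicative step away so layers never collide across replicates.
* **Decorrelated-columns check.** Dropping SNPs cannot raise the genetic
  variance when columns are truly independent, but shuffled columns are
  independent only in expectation; empirical cross-covariances perturb
  `Vg` by `O(Vg/sqrt(n))`. The property test therefore allows a 0.01 slack
  on the heritability scale rather than asserting the exact inequality.

## Desk scale

Full-scale sweeps (0.1 Morgan on 10 Mb, 500 + 500 samples, hundreds of
replicates per grid point) are minutes-per-replicate work. The test suite
and the acceptance script instead run a *desk scale* fixed in advance: 1 Mb
/ 0.01 Morgan (identical per-bp rates), causal rate 1.6e-9 (theta = 64,
roughly 400–500 causal SNPs per 250-diploid Reference sample), 250 + 250
diploids, and 100–500 replicates per setting. Most qualitative claims are
scale-free statements about drift and thresholding, and the package
defaults remain the full-scale values. Two claims are not scale-free and
the test design reflects that:

* A strict pooled quantile retains about `L / 2^n` SNPs per trait, so the
  behaviour of the `n = 9` threshold depends on the causal SNP count `L`.
  The thresholding experiments therefore run on a genome with the
  full-scale theta of 160 (2.5 Mb at rate 1.6e-9, ~1100 causal SNPs),
  keeping ~2 retained SNPs per trait at `n = 9` as at full scale.
* Mean-heritability contrasts shrink with weak drift: at `T = 50` the
  no-migration deficit is of order 0.01, at the Monte-Carlo resolution of
  a 100-replicate mean, so the migration comparisons run at `T = 200` and
  `T = 500` where the measured deficits (~0.05, ~0.10) are resolvable. For the
  same reason the `N`-sweep monotonicity is asserted within two standard
  errors of each adjacent mean difference, the split-time variance trend
  uses 500 replicates per point (a variance estimate carries
  `sqrt(2/(R-1))` relative error), and the growth contrast pairs its three
  arms on common seeds.

One behaviour worth knowing: at these demographies roughly half the
Reference SNPs are lost from the bottleneck sample, so their detectability
scores are degenerate (variance explained 0, p-value 1). The pooled
`n = 1` cutoff then sits at that degenerate mass and retains every SNP in
both modes — the n = 1 threshold is a no-op, exactly as the retention rule
dictates. Relatedly, the regression coefficient of thresholded on
simulated heritability approaches 1 from *below* in variance-explained
mode but from *above* in p-value mode (traits collapsing to zero pivot the
fitted line steeper than the identity), so "approaches 1" is meaningful as
`|slope - 1|`, not as a one-sided slope ordering.

## Known limitations

Single chromosome, uniform map, no selection during the simulated epoch,
no dominance/epistasis, constant environmental variance across populations,
causal-only SNP universe (sites private to the bottleneck carry no
effect), and no attempt at the inverse problem (inferring the ancestral
architecture from the drifted one). Linkage disequilibrium is present in
the genotypes but the thresholding analysis makes no attempt to clump or
fine-map correlated SNPs; thresholded heritability can consequently sit
slightly above the all-SNP value through covariance with dropped SNPs.
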