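---
title: "Modeling CRISPR toxin-antidote gene drives: assumptions, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling CRISPR toxin-antidote gene drives}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tadrive)
```

## The model

`tadrive` models split CRISPR toxin-antidote drives at three unlinked,
independently assorting autosomal loci: the drive insertion (DsRed-marked,
carrying gRNAs and a recoded rescue element), a separate supporting Cas9
allele (EGFP-marked), and the diploid target gene.  Treating the loci as
unlinked is deliberate even though, in the experimental system the package
emulates, one 2-gRNA drive and its target sit on opposite arms of the same
chromosome: observed transmission was Mendelian (51–54%), consistent with
free recombination across the centromere, so linkage would add state
without adding signal.

A target allele is in one of three states, following the field's
resistance-allele nomenclature: `wt` (functional, cleavable), `r1`
(functional recoded — formed here by homology-directed repair using the
drive's rescue element as template), `r2` (disrupted, nonfunctional).
Viability is a pure dosage rule: an individual survives iff its count of
functional target alleles, plus one dose per drive copy when the rescue
element works, meets the required dosage (2 for a haplolethal TADE target,
1 for a haplosufficient TARE target).  Dosage is uncapped: drive
homozygotes with functional rescue contribute two doses with no
over-expression penalty, because the experiments found no fitness
phenotype in drive homozygotes.  Rescue is all-or-nothing
(`rescue_functional`); the experiments could not distinguish
under-expression at one versus both copies, and "no partial rescue" was
the observed outcome of every distant-site construct tested.

### Cutting and repair

Cutting happens at two points, gated by genotype and parent sex:

* **Germline** (`c_germline`, per transmitted allele): active only in a
  parent carrying at least one drive *and* one Cas9 allele.  Conditional
  on modification, repair yields `r1` with probability `p_hdr_functional`
  (only when the architecture's rescue element can template HDR), restores
  `wt` with probability `p_hdr_wt`, and otherwise yields `r2`.  Applying
  the rate per transmitted allele is equivalent, under independence, to
  cutting both alleles pre-meiotically and then segregating.
* **Embryo** (`c_embryo`, per wild-type allele of the zygote): maternal
  deposition of Cas9/gRNA, active only when the *mother* carries drive and
  Cas9.  Both the maternally and the paternally inherited wild-type
  alleles are exposed, independently.  This two-allele convention is load
  bearing: it is what makes the published viability triple (72%, 75%, 83%)
  invert to a ~2% per-allele embryo rate rather than ~4%, and it is the
  package's canonical convention.

`p_hdr_wt` (seamless repair off the homolog) defaults to 0.  It is
observationally confounded with a lower `c_germline` — only the product of
cut rate and non-wt repair is identifiable from viability data — so the
parameter is exposed but not resolved; fits should leave it fixed.

Two further selection terms act after hatching: leaky somatic Cas9
expression removes drive+Cas9 carriers of a haplolethal target with
probability `somatic_cut_rate` (modeling the larval death observed with a
*vasa* promoter), and each drive copy multiplies survival by
`drive_fitness`.

### From crosses to rates

For a drive/Cas9 heterozygote crossed to wild type under the
any-cut-lethal model (failed rescue, no HDR), expected viabilities are
`v_male = v0 (1 - c_g)` and `v_female = v0 (1 - c_g)(1 - c_e)^2`; the
closed-form estimators in `estimate_germline_rate()` and
`estimate_embryo_rate()` are exact inverses of the forward model, and the
package tests verify the round trip to 1e-12.  The embryo-resistance
estimator generalizes the one-allele lethality to `n_cut_sites`
independent sites per allele; the site count enters *only* this estimator
— the cross model works per allele, which is the level at which the
underlying arithmetic operates.

`fit_ml()` maximizes the product over vials of
`Binomial(adults | eggs, absolute viability)` plus marker-count binomials,
with the per-cross viability always computed by the forward cross model.
Confidence intervals are 95% profile-likelihood intervals (chi-square,
1 df): Wald intervals misbehave for the small rates of interest, which sit
near the [0, 1] boundary.  Two-sided exact tests use the
minimum-likelihood convention (sum all outcomes no more probable than the
observed one), matching the common implementations; the alternative
"double the smaller tail" convention differs and is not used.

### The batch-effect substitution

The original analysis fitted a binomial GLMM with per-vial random
intercepts (adaptive Gauss–Hermite quadrature).  That model is *not*
reimplemented.  Instead `overdispersion = TRUE` fits a beta-binomial with
intra-class correlation `rho`, the matched approximate likelihood of the
logit-normal batch effect the synthetic generator produces.  The original
report notes the GLMM moved estimates only slightly while widening
standard errors; the beta-binomial captures exactly that effect.  As
`rho -> 0` the beta-binomial likelihood converges to the binomial one
(tested).

## The synthetic-data generator

`generate_dataset()` emulates the statistical structure of the fly
experiments: per-vial egg counts (Poisson mean 50 by default — no egg
count is published, and ~50 eggs over a multi-day lay is a realistic vial;
this is a design knob, chosen once), binomial egg-to-adult survival at the
cross model's predicted viability, a per-vial `Normal(0, batch_sd)`
perturbation on the logit scale (the random-intercept structure a binomial
GLMM assumes), and binomial marker counts among adults.  It does **not**
simulate fluorescence-scoring or sexing error, egg-count miscounting, or
viability differences between vials of the *same* batch beyond the single
logit-normal term.  A green parameter-recovery test therefore establishes
that the inference machinery is consistent with the package's own
generative model — not that the model captures every feature of real vial
data.  The recovery study itself (100 datasets of 2 crosses x 10 vials at
c_g = 0.10, c_e = 0.02) is generated with `batch_sd = 0` so the binomial
likelihood is correctly specified for the coverage claim being tested;
overdispersed paths are exercised separately.

## The population recursion

`step_population()` iterates nonoverlapping generations on pooled genotype
frequencies (1:1 sex ratio, identical genotype distributions between sexes
at birth — valid because no locus is sex-linked): sterile females (drive
homozygotes under a suppression architecture) are removed from the
maternal gamete pool; germline gametes come from the same per-genotype
machinery as the cross model; mothers are paired with the paternal pool
*before* maternal deposition, partitioned by the deposition indicator
(deposition depends on the mother only through drive+Cas9 carriage, so
the two-class partition is exact, not an approximation); then viability,
somatic and fitness selection.  Stochastic mode multinomially resamples to
the census size each generation under a stated seed.

Suppression is reported as **genetic load** — one minus the product of the
fertile-female fraction and the mean relative survival of the offspring
pool the current state would produce — not as demographic extinction; no
density dependence is modeled.

### Split versus complete drives

A design question the package had to resolve: the qualitative claims about
toxin-antidote dynamics ("no introduction threshold without fitness costs,
a threshold with them"; "suppression once the drive is common") come from
the complete-drive modeling literature, but the experimental constructs
are *split* drives.  In a wild-type background the separate Cas9 allele is
itself selected against — broods of Cas9-carrying parents lose offspring —
and it dissociates from the drive within a few generations, so cutting
decays and the drive stalls.  The simulator reproduces this (and tests
assert it).  To study the complete-drive limit, fix Cas9 in the resident
population via `background_genotype = genotype(0, 2)`: with the toxin
always present, cutting is gated by drive carriage alone, which is exactly
the complete-drive model.  The threshold and suppression properties are
tested in that limit.

`find_introduction_threshold()` bisects on the release frequency with
spread defined as "drive allele frequency at the horizon above its initial
value, or extinction".  One numerical subtlety: a drive with fitness costs
settles at an internal equilibrium, so a release *above* the equilibrium
ends below where it started while the drive persists.  The upper bisection
bracket is therefore found by scanning candidate releases downward for the
largest one that spreads, rather than assuming 0.99 spreads.

## Numerical choices

* Distribution invariants are enforced to 1e-12 (cross model) and 1e-9
  (population recursion); both are tested.
* The cross kernel runs on a precomputed 54-genotype index (3 drive x 3
  Cas9 x 6 unordered allele pairs), with gamete union as a single matrix
  multiply and maternal deposition as a quadratic matrix polynomial in
  `c_embryo`; the data-frame interface is a thin view over this kernel.
* ML optimization is box-constrained Nelder–Mead with a one-dimensional
  coordinate polish, on the raw probability scale clamped to
  [1e-9, 1 - 1e-9]; boundary estimates are flagged in the result.
* A zero-survivor cross reports its inheritance rate as `NA` with an
  explicit `inheritance_defined = FALSE` flag — never 0/0.
* `zero_survivor_bound()` uses the exact (Clopper–Pearson) one-sided
  inversion, which for zero successes has the closed form
  `kill >= (1 - confidence)^(1/n)`.
* Binomial log-densities use the lgamma form of the coefficient so that
  noiseless expected-count fixtures (non-integer "counts") are handled
  exactly.

## Known limitations

* No spatial structure, migration, age structure, density dependence, or
  overlapping generations.
* Sequence-level design (gRNA choice, recoding extent, promoter identity)
  appears only through architecture flags and rate parameters.
* `c_embryo` is weakly identified from viability data alone when female
  and male drive-cross viabilities are statistically indistinguishable;
  the profile intervals make this visible (they are wide and typically
  touch 0) rather than resolving it.
* The beta-binomial is an approximation to, not a reimplementation of,
  the logit-normal GLMM; with very large batch effects the two diverge.
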