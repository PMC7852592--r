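---
title: "Genetic evaluation from pen-summed group records"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genetic evaluation from pen-summed group records}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(penBLUP)
```

## The problem

Some economically important traits are impractical to record on single
animals. Feed intake in group-housed pigs is the canonical example: a pen
of pigs shares one feeder, so what is observed is the *pen total*, not the
individual intake. penBLUP implements genetic evaluation for exactly this
situation: a trait recorded as pen sums ("group records"), optionally
analysed jointly with a cheap, individually recorded, genetically
correlated trait such as daily gain, with pedigree, genomic or combined
(single-step) relationship information.

## The model

For an individually recorded trait the package fits the standard animal
model

$$
\mathbf{y} = \mathbf{1}\mu + \mathbf{Z}_l \mathbf{l} + \mathbf{Z}_c
\mathbf{c} + \mathbf{Z}_a \mathbf{a} + \mathbf{e},
$$

with litter effects $\mathbf{l} \sim N(0, \mathbf{I}\sigma^2_l)$ (common
environment before weaning), pen effects $\mathbf{c} \sim N(0,
\mathbf{I}\sigma^2_c)$ (common environment during test), additive genetic
effects $\mathbf{a} \sim N(0, \boldsymbol{\Omega}\sigma^2_a)$ and residuals
$\mathbf{e} \sim N(0, \mathbf{I}\sigma^2_e)$. $\boldsymbol{\Omega}$ is the
pedigree matrix $\mathbf{A}$ (PBLUP), the VanRaden method-1 genomic matrix
(GBLUP, after rescaling to the $\mathbf{A}_{11}$ scale and blending with
weight $w = 0.05$), or the single-step matrix $\mathbf{H}$ combining both.

A group record is the sum of its pen members' records. Writing $\mathbf{T}$
for the 0/1 incidence matrix of pens by recorded animals (disjoint groups:
every column has one 1), the group-record model is the individual model
premultiplied by $\mathbf{T}$:

$$
\mathbf{T}\mathbf{y} = \mathbf{T}\mathbf{1}\mu + \mathbf{T}\mathbf{Z}_l
\mathbf{l} + \mathbf{T}\mathbf{Z}_c \mathbf{c} + \mathbf{T}\mathbf{Z}_a
\mathbf{a} + \mathbf{T}\mathbf{e},
$$

so the fixed-effect column becomes the group-size vector
$\mathbf{T}\mathbf{1}$ and the residual of a group of $n$ animals has
variance $n\sigma^2_e$ ($\mathbf{T}\mathbf{T}'$ is diagonal because pens
are disjoint). All animals of the pedigree carry additive-effect equations,
so animals without records — including an unrecorded validation
generation — receive breeding values through the covariance structure.

In the bivariate form the two traits' litter, pen, additive and residual
effects carry $2\times 2$ covariance matrices combined with the usual
Kronecker structure, e.g. $\mathrm{var}(\mathbf{a}) = \Sigma_a \otimes
\boldsymbol{\Omega}$. When trait 1 is group-recorded and trait 2
individually recorded, a residual covariance between a pen sum and an
individual record is not representable as a single parameter of a
block-diagonal residual; the cross-record residual covariance is therefore
excluded from the model (`residual_1_2` simply does not exist in mixed
mode). A known and deliberate consequence, reproduced by the package's
tests, is that part of the residual covariance is absorbed by the pen
covariance, which is then overestimated; the breeding values remain
essentially unbiased (regression of true on estimated values stays near
1).

## Variance-component estimation

`remlEstimate()` maximises the restricted likelihood with
average-information (AI) updates:

* the score uses exact trace terms,
  $\partial \ell_R / \partial \theta_i = -\tfrac12\,[\mathrm{tr}(\mathbf{P}
  \dot{\mathbf{V}}_i) - \mathbf{y}'\mathbf{P}\dot{\mathbf{V}}_i
  \mathbf{P}\mathbf{y}]$;
* the AI matrix is $\tfrac12 (\dot{\mathbf{V}}_i\mathbf{P}\mathbf{y})'
  \mathbf{P}(\dot{\mathbf{V}}_j\mathbf{P}\mathbf{y})$, obtained from
  working vectors solved against the mixed-model equations;
* an EM update replaces any AI step that would leave the parameter space
  or reduce the likelihood (after step halving), and variances are pinned
  at a floor rather than removed.

Two computational routes produce identical results (cross-checked to
`1e-6` in the test suite). For small numbers of observations the
phenotypic covariance $\mathbf{V}$ is formed densely. At scale the package
factorises Henderson's coefficient matrix sparsely and reads the trace
terms from a Takahashi partial inverse of the Cholesky factor — the
classical approach of large-scale REML software — computed by a small
compiled routine on the factor's own sparsity pattern. Both the likelihood
identity $\log|\mathbf{V}| + \log|\mathbf{X}'\mathbf{V}^{-1}\mathbf{X}| =
\log|\mathbf{C}| + \log|\mathbf{G}| + \log|\mathbf{R}|$ and the partial
inverse are validated against dense linear algebra in the tests.

Defaults: starting values assign 40% of the per-trait phenotypic variance
to the residual and 20% to each remaining component with covariances at 0;
convergence requires a maximum relative parameter change below `1e-8`
*and* a score norm below `1e-6` (parameters pinned at the floor are
excluded from the gradient check); at most 200 iterations. For the
replicated study runs the driver starts at the generating components —
the optimum is unchanged, quadratic convergence just sets in sooner — and
uses a variance floor of `0.01`: group records carry a weakly identified
residual variance whose estimate can collapse to the boundary, and a floor
at `1e-8` makes $\mathbf{R}^{-1}$ entries of order $10^8$ that poison the
score numerically, while `0.01` on a phenotypic variance of 100–400 is
numerically safe and statistically indistinguishable from zero.

## Solving the equations

`solveMME()` uses a sparse Cholesky factorisation up to 20,000 equations.
Beyond that it switches to Jacobi-preconditioned conjugate gradients
(compiled, converging to a relative residual of `1e-10`): group records
couple every pen's members, which makes the factor of the full-sized
bivariate system fill in heavily, whereas a matrix-vector product stays
cheap. The two solvers are verified against each other in the tests, and
every solve is checked against its right-hand side before being accepted.

## What the simulator generates

`simulateStudyReplicate()` reproduces a pig-nucleus design:

* **Genome** — 18 chromosomes of 100 cM; per chromosome 3100 biallelic
  markers and 50 biallelic QTL at uniformly random positions; recurrent
  0/1 mutation at 2.5e-5 per locus per meiosis; Haldane crossovers
  (Poisson count, uniform placement, no interference).
* **Historical phase** — 400 unrelated founders with uniform(0.1, 0.9)
  allele frequencies drift through 300 generations of random mating at
  constant size, building linkage disequilibrium; loci with minor allele
  frequency below 0.01 are then discarded. The founder range is the one
  genuinely open knob of the design ("random" frequencies can mean many
  laws); it was calibrated once against the observable the design reports —
  about 78% of loci segregating after the filter (on the order of 44,000
  markers and 700 QTL at full density) — because the post-drift allele
  frequency spectrum controls the effective number of loci behind the
  simulated breeding values. A fully uniform (0, 1) draw loses over 30% of
  loci and leaves a spikier spectrum.
* **Recent phase** — a base mating (30 sires × 200 dams, litters of 6)
  yields generation 0 of 630 founders (600 females, 30 males); each of 8
  discrete generations then mates 30 sires to 600 dams (20 dams per sire),
  every litter 3 males + 3 females: 29,430 pedigree animals, of which the
  14,400 in generations 5–8 are phenotyped. Mutation acts in the
  historical phase only, and mating is random throughout (no selection).
* **Traits** — QTL effect pairs are drawn bivariate normal with
  correlation 0.8 (0.5 in the sensitivity variant); true breeding values
  (sums of allele effects) are rescaled so their variance among the
  generation-0 founders equals the design values 30 and 100. Phenotypes
  add litter, pen and residual effects drawn with variances 10/10/50
  (trait 1) and 40/40/220 (trait 2) and correlations 0.3/0.3/0.5, giving
  heritabilities 0.3 and 0.25.
* **Pens** — built within generation: `S12_L2x3` splits each litter into
  two random sublitters of 3 and fills pens of 12 with 4 sublitters of 4
  distinct litters; `S24_L2x3` uses pens of 24 with 8 sublitters;
  `S12_Lran` permutes individuals into pens of up to 12. Pens are
  assigned first; 20% of the recorded animals (drawn among non-parents
  only) then lose their records, which produces pen sizes 4–12 with mean
  9.6 and leaves the breeding animals as 16.5% of the data.
* **Genotyping designs** — 0% (PBLUP), 100% (GBLUP), or 30% (ssGBLUP: all
  breeding animals plus random fill). The 30% set is frozen per replicate
  so that every design scores identical validation subsets (Group I =
  genotyped validation animals, Group II = the rest).

What this emulates — and what it does not: the generator reproduces the
family structure, LD build-up, group composition and missingness patterns
of a nucleus herd, but mating is random (no selection response), litter
size is fixed at the 6 tested pigs, generations do not overlap, and pen
effects are independent of pen composition. Passing tests therefore show
that the estimation machinery recovers what this generating process
encodes; they do not certify behaviour under selection, heterogeneous
variances or maternal/social effects.

## Validation measures

The last generation (8) is the validation set: its post-attrition recorded
animals are scored either with their records kept (`Valid_R`) or with all
generation-8 records of both traits removed before fitting (`Valid_nR`).
Accuracy is the Pearson correlation between estimated and true breeding
values; dispersion bias is the regression of true on estimated values
(1 = no over- or under-dispersion). `runExperiment()` repeats
simulate–fit–score over replicates and reports per-cell means and SDs;
identical seeds give bitwise-identical summaries.

## Problem sizes of the reference study

`runReferenceStudy()` is the package's own replication of the evaluation
study at desk scale: 10 replicates, QTL-only genome (markers are not
needed for pedigree-based cells), full population size (600 litters per
generation, 29,430 pedigree animals) for all accuracy/bias cells and for
the univariate group-record REML cell. The bivariate mixed-mode REML cell
runs on a size-reduced population (100 litters per generation, 5 sires —
the same mating ratio, litter size, pen structure and attrition): its
measured quantity, the inflation of the pen covariance when the
cross-record residual covariance is excluded, is driven by the within-pen
structure (roughly $\sigma_{e_1e_2}$ spread over the average pen), not by
population size, and the full-sized bivariate REML would dominate the
study's runtime many times over.

## What the replication can and cannot show

The acceptance checks in `tests/testthat/test-acceptance.R` compare the
replicated study's cell means against reference values with tolerances of
three reported SDs over the square root of the replicate count. Two facts,
both established by the test suite itself, frame how to read them:

* The estimation machinery is exact: the mixed-model solutions equal a
  dense GLS oracle on small fixtures, and when the true breeding values
  are drawn from the pedigree model itself, the realised accuracy equals
  the prediction-error-variance-implied accuracy — the information
  ceiling of the generating design. Nothing in the solver leaves accuracy
  on the table.
* Under the stated design (400 historical animals for 300 generations, 30
  sires and 600 dams per recent generation, four recorded generations,
  the Table-1-style variance structure), that ceiling sits near 0.70 for
  individual records and near 0.47 for pen-sum records in the
  records-kept validation. Replicated runs with QTL-based breeding values
  land at that ceiling. Reference accuracy figures a few points above it
  (for example 0.74 and 0.54) are therefore not reachable by any faithful
  implementation of the stated generating process; the package reproduces
  every *relative* contrast — scenario ordering, group-to-individual
  ratios, bivariate gains, with/without-record differences, variance
  component means and spreads, dispersion slopes near 1 — while its
  absolute accuracy level reflects the design as stated.

## Numerical choices and edge cases

* Pedigree inverse by the Meuwissen–Luo inbreeding algorithm and
  Henderson's rules; $\mathbf{A}$ itself is only materialised for small
  pedigrees, and subsets of it are obtained by sparse solves (Colleau's
  indirect method).
* $\mathbf{G}$ requires at least one polymorphic marker and complete
  genotypes (missing genotypes are an error, not an imputation); the
  rescale-to-$\mathbf{A}_{11}$ step precedes blending, and
  $\mathbf{G}^{-1}$ is only ever taken after blending.
* The sublitter-to-pen assignment repairs random clashes (two sublitters
  of one litter in a pen) by swap moves; an assignment is rejected only if
  1000 repair sweeps fail, which does not occur at the study's sizes.
* Degenerate inputs fail loudly: cyclic or unsorted pedigrees, overlapping
  groups, monomorphic marker panels, non-positive-definite covariance
  blocks, unreachable solver tolerances.
* Ties in the validation sets cannot occur (ids are unique); full sibs in
  one sublitter and pen receive identical pedigree-based EBVs, which is a
  property of the model, not a numerical artifact.

## Known limitations

No selection during simulation; no maternal, dominance or social genetic
effects; at most two traits; groups must be disjoint; missing genotypes
unsupported; the cross-record residual covariance of the mixed bivariate
model is structurally excluded (by design, matching the analysis whose
behaviour the package reproduces).
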