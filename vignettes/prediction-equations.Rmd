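---
title: "Deterministic accuracy of multi-population genomic prediction with two GRMs"
author: "gpacc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deterministic accuracy of multi-population genomic prediction with two GRMs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gpacc)
```

## The problem

Genomic prediction in a numerically small population is limited by the size
of its training population. Two remedies can be combined: add training
individuals from a second, genetically correlated population, and split the
SNP panel into a small pre-selected set (markers with prior evidence of
causality) and the remaining genome-wide set, each carried by its own
genomic relationship matrix (GRM) so the model can weight them differently.
This package implements deterministic selection-index equations that predict
the accuracy of the four resulting models before any phenotype is collected:

* **WPSG** — within-population training, one GRM;
* **WPMG** — within-population training, two GRMs;
* **MPSG** — combined two-population training, one GRM;
* **MPMG** — combined two-population training, two GRMs;

together with the machinery needed to apply and validate them: GRM
construction with population-specific allele frequencies, estimation of the
effective number of independent chromosome segments ($M_e$), a
two-population simulator, and a bivariate two-GRM GBLUP cross-validation
harness.

## The equations

All predictors descend from the classical deterministic accuracy of genomic
prediction with a single GRM,

$$r = \sqrt{\rho^2\,\frac{h^2 N}{h^2 N + M_e}},$$

where $h^2$ is the trait heritability, $N$ the training size, $M_e$ the
effective number of independently segregating chromosome segments the model
must estimate, and $\rho^2$ the proportion of the total genetic variance in
the validation population that the SNPs capture. `wpsgAccuracy()` evaluates
this directly.

When two GRMs are fitted jointly within one population, the two sets of
estimated genomic values (EGV) are uncorrelated, each set explains its
partial variance $\rho_s^2$, and the selection index combining them has
accuracy (`wpmgAccuracy()`)

$$r = \sqrt{\rho_1^2\,\frac{h^2_A N_A}{h^2_A N_A + M_{e_{A_1}}}
          + \rho_2^2\,\frac{h^2_A N_A}{h^2_A N_A + M_{e_{A_2}}}}.$$

For a combined training population the index gains two more information
sources: the EGV of the candidates obtained from the population-B part of
training. Per SNP set $s$, writing $a_s = h_A^2 / M_{e_{A_s}}$ and
$b_s = h_B^2 / M_{e_{AB_s}}$, the source covariances are

$$\mathbf g_s = \begin{pmatrix}\rho_s\sqrt{a_s}\\ \rho_s r_g\sqrt{b_s}\end{pmatrix},
\qquad
\mathbf P_s = \begin{pmatrix}a_s + 1/N_A & r_g\sqrt{a_s b_s}\\
r_g\sqrt{a_s b_s} & b_s + 1/N_B\end{pmatrix},$$

with $r_g$ the genetic correlation between the populations. The four-source
index of the MPMG model is block diagonal in the two SNP sets
(`buildMpmgIndex()`), and its accuracy is
$r = \sqrt{\mathbf g' \mathbf P^{-1} \mathbf g}$
(`selectionIndexAccuracy()`). `mpmgAccuracy()` evaluates either this matrix
form or the algebraically identical scalar closed form; a property test
holds them together to $10^{-10}$ over a thousand random parameter sets.
With one SNP set the same index is the established two-population
single-GRM predictor (`mpsgAccuracy()`); the general equation reduces to it
exactly at $\rho_2^2 = 0$ and to the within-population equation at
$r_g = 0$.

### Parameters that matter

| Parameter | Meaning | Typical value here |
|---|---|---|
| $h^2_A$, $h^2_B$ | trait heritability per population | 0.3 or 0.8 |
| $N_A$, $N_B$ | training individuals per population | 476 / 5553 |
| $\rho_1^2$, $\rho_2^2$ | genetic variance captured by each SNP set | 0.4 / 0.4 |
| $r_g$ | genetic correlation between populations | 0.4–1 |
| $M_{e_{A_s}}$ | segments within A per SNP set | 159 (pre-selected), 280 (remaining) |
| $M_{e_{AB_s}}$ | segments across A and B per SNP set | 463 / 32,970 |

The benchmark baselines bundled in `caseBaseline()` describe a small
dairy-cattle target population supported by a large distantly related one,
with $M_e$ values estimated from a genome-wide bovine SNP panel. A few
hundred pre-selected SNPs keep both $M_{e_{A_1}}$ and, crucially,
$M_{e_{AB_1}}$ small (its upper bound is the number of pre-selected SNPs),
which is why the two-GRM multi-population model can extract information
from a distantly related population even when the genome-wide
$M_{e_{AB_2}}$ runs to tens of thousands. The interface also accepts
per-set genetic correlations (`rg1`, `rg2`), defaulting to a single value,
since pre-selected SNPs may be more consistent across populations than the
remainder.

`runCase(1:4)` sweeps, in turn, $r_g$, $\rho_1^2$ (with
$\rho_2^2 = 1 - \rho_1^2$), $M_{e_{AB_2}}$, and a fractional
underestimation $u$ of the within-A $M_e$ values (each multiplied by
$1-u$ while the across-population values stay fixed), reporting every
model's accuracy and its percent change against WPSG.

## GRMs and the effective number of segments

`buildGRM()` centres genotype codes with the allele frequencies of each
individual's own population and scales per population by
$\sum_j 2p_{kj}(1-p_{kj})$; the across-population block uses the geometric
mean of the two scaling sums. $M_e$ is estimated as the inverse of the
variance of genomic relationships: over the off-diagonal elements of a
within-population block (`meWithin()`; diagonals measure inbreeding, not
segment sharing, and are excluded — the variance uses the unbiased $n-1$
denominator), and over all elements of the across-population block
(`meAcross()`). SNPs monomorphic in one population are retained as long as
the other population is polymorphic; missing codes are mean-imputed per
population before centring.

## The simulator

`simulateGenotypes()` draws unlinked loci under the Balding–Nichols model:
an ancestral frequency uniform on `mafRange` (default 0.05–0.5), then
per-population frequencies
$\mathrm{Beta}\!\left(p\frac{1-F_{st}}{F_{st}},\,(1-p)\frac{1-F_{st}}{F_{st}}\right)$
and binomial genotypes. The default `simulationConfig()` mirrors the
benchmark design: 595 + 5553 individuals, a 48,912-SNP panel with 500
causal SNPs shared by both populations, bivariate normal causal effects
with unit variance and correlation $r_g$, heritability 0.3, 100
replicates, and an $F_{st}$ of 0.1 typical of distantly related cattle
breeds. Phenotypes add per-population Gaussian residuals with variance
$\sigma^2_{g_k}(1/h^2 - 1)$, where $\sigma^2_{g_k}$ is the realized
variance of the true genomic values (TGV) in population $k$, so realized
heritability targets $h^2$. Replicate $r$ derives every stage's seed from
`seed + r`, so stages re-run independently.

What the simulator deliberately does **not** emulate is linkage
disequilibrium: loci are independent, so the remaining (non-causal) SNPs
carry no information about causal SNPs that are left out of both GRMs. Two
consequences follow. First, `partitionCausal()` defaults to excluding
non-selected causal SNPs from both sets, but the validation grid runs with
`includeUnselectedCausal = TRUE` so that the second GRM genuinely tags the
remaining genetic variance and the analytic split
$\rho_1^2 = \text{level}/n_\text{causal}$,
$\rho_2^2 = 1 - \rho_1^2$ applies. Second, synthetic $M_e$ values sit near
the SNP counts rather than at the benchmark values, so the validation
compares predictions parameterised with $M_e$ estimated from the synthetic
GRMs themselves. Passing tests therefore demonstrate the internal
consistency of equations, GRM machinery and GBLUP on structured but
LD-free data — not that the equations capture every property of real
livestock genomes.

## The validation harness

`predictEgv()` computes best linear predictions at known variance
components: the phenotype covariance is
$\sum_s \mathbf K_s \circ \mathbf{GRM}_s + \mathbf R$ (the per-population
genetic (co)variance matrix applied elementwise to the matching GRM block,
plus diagonal residuals), fixed per-population means are estimated by
generalized least squares, and validation individuals keep their GRM rows
while contributing no phenotypes. A test pins this path to an
independently coded mixed-model-equations oracle to $10^{-8}$.
Variance-component estimation by REML is intentionally out of scope:
`truthComponents()` supplies the simulation-truth components, because the
equations under study concern accuracy *given* a variance structure, and
estimation noise would blur exactly the comparison the harness exists to
make. `crossValidate()` holds out only population-A individuals (fivefold
by default), and `empiricalAccuracy()` is the correlation between pooled
held-out EGV and TGV.

`runValidationGrid()` runs 30 replicates of a reduced design — 300 + 1000
individuals, 2000 SNPs, 200 causal, $F_{st} = 0.05$ — across
$r_g \in \{0.4, 0.8\}$, $h^2 \in \{0.3, 0.8\}$ and pre-selection of half or
all causal SNPs, sizes chosen so the whole grid solves in a few minutes of
dense linear algebra on one CPU while leaving replicate standard
deviations small enough to be informative.

## Numerical choices and degenerate inputs

* $\mathbf P$ is factorised by Cholesky before inversion; failure raises a
  degeneracy error rather than falling back to a pseudo-inverse, because a
  singular $\mathbf P$ means the information sources are redundant and the
  index weights are not identifiable.
* A squared accuracy within $10^{-8}$ above 1 is clamped to 1 (floating
  point); a larger excess raises an error to surface inconsistent
  $M_e$/$\rho^2$ combinations instead of hiding them.
* Zero-variance situations (monomorphic panels, flat GRM blocks, constant
  EGV) raise explicit degenerate-data errors.
* All stochastic stages take explicit seeds; reports re-run byte-identical.

## Known limitations

* The within-population reliability $h^2N/(h^2N + M_e)$ is an
  approximation that weakens as $h^2N/M_e$ approaches and exceeds 1. In
  the validation grid the prediction lies within two replicate standard
  deviations of the measured accuracy in six of the eight cells; the two
  cells that pair full causal pre-selection with $h^2 = 0.8$ under-predict
  the measured accuracy (by about 0.08–0.11), because there GBLUP runs on
  an exactly correct kernel with $h^2N/M_e \approx 1$ and the replicate
  standard deviations are only about 0.01–0.02. With real genomes this
  bias is partly masked by the opposite bias of GRM-based $M_e$
  estimates, which linkage disequilibrium pushes downward.
* No linkage disequilibrium, pedigree structure or selection in the
  simulator, and no REML: conclusions about real data should rest on real
  genotypes.
* Dense solvers only; the harness is intended for at most a few thousand
  individuals.
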