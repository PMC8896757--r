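---
title: "Thermodynamic environment profiling: models, choices and limits"
author: "thermoenv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Thermodynamic environment profiling: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermoenv)
```

This vignette is the package's own account of the science it implements:
the models and their assumptions, the tunable parameters and why their
defaults are what they are, what the synthetic generator emulates and what
it does not, and the numerical choices made where the design was genuinely
open.

## The TE alphabet and the assignment metric

A residue's thermodynamic state is summarized by a 4-vector of descriptors
{ΔG, ΔH~apolar~, ΔH~polar~, TΔS~conf~}, in kJ/mol, computed separately for
the native state and for a locally unfolded denatured state. "Native" and
"denatured" here mean subensembles in which that residue is folded or
locally unfolded — not the fully folded versus fully unfolded protein.
Empirically, such vectors cluster into eight recurrent environments per
state; the package takes the cluster centers as given (a
`TECenters` object) and assigns each residue to the environment whose
center is nearest in weighted Manhattan distance:

$$\mathrm{TE}_j = \arg\min_k \sum_{m=1}^{4} w_m\,
 \bigl|\bar{c}_{k,m} - x_{j,m}\bigr|$$

with $w = (1,1,1,3)$ for the native state — the conformational-entropy
deviation is counted three-fold — and $w = (1,1,1,1)$ for the denatured
state. Both weight vectors are configurable (`TECenters()` arguments); the
defaults implement the published assignment rule exactly as printed, since
no justification for the factor is available to second-guess. Environments
are indexed by stability: TE1 has the least negative mean ΔG, TE8 the most
negative, and the class validity check enforces that ordering.

Numerical choices:

* **Ties** go to the lowest environment index. An argmin over eight
  distances is silent about ties; a deterministic rule is required for
  reproducibility, and "lowest index" is the simplest one.
* **Units.** Assignment is invariant under a common rescaling of centers
  and descriptors, but not under rescaling one without the other, so
  everything internal is kJ/mol and `readCenterTable(units = "kcal")`
  converts on load (x 4.184).
* The real center values live in published supplementary material and are
  not hard-coded here; `genCenterTable()` provides a synthetic,
  well-separated stand-in so the package is testable without them
  (see below).

## Proteome profiles, clustering, PCA

A proteome is summarized by the vector of native TE frequencies
$T_n / \sum_{n=1}^{8} T_n$, pooled over all residues of all proteins.
Pooling residue counts (rather than averaging per-protein frequencies) is a
choice the underlying description leaves open; the pooled form weights
proteins by length, matches the residue-level census semantics, and the
`perProtein = TRUE` flag gives the alternative.

`upgmaCluster()` is average-linkage agglomerative clustering under
Euclidean distance on those vectors, via `stats::hclust` and `ape`. The
height convention: a node sits at *half* the average pairwise distance
between the clusters it joins, so the cophenetic (patristic) distance
between two leaves equals the UPGMA average distance. Trees are therefore
ultrametric by construction, which the tests verify over all leaf triples.

`pcaDecompose()` mean-centers but does **not** variance-scale, matching the
common default of standard decomposition tooling for this analysis; a
frequency of 0.2 in TE4 and in TE8 should weigh equally, which scaling
would destroy. Two consequences of compositional closure (rows sum to 1)
are handled explicitly: the covariance has rank at most 7, so a trailing
near-zero eigenvalue is expected and retained rather than treated as error;
and no analysis should request eight "meaningful" components. PCA signs are
arbitrary, so each loading is flipped to make its largest-magnitude entry
positive, making scores reproducible across platforms.

Trait regressions (`regressPCTrait`) are ordinary least squares of a trait
(growth temperature in °C, disorder fraction in [0,1], or the configurable
"fraction of most stable residues", default the TE8 frequency — whether
that set should be {8} or {7,8} is genuinely open, hence the argument) on a
component score, reporting slope, Pearson r and the two-sided zero-slope
p-value. Organisms missing a trait are dropped and counted, never imputed.
`kingdomSlopeTest` asks whether kingdoms share a slope via an ANCOVA with a
full kingdom x score interaction, using the F-test of the interaction
against the additive model; no specific test is canonical for "a
significantly different slope", so the standard one is used and per-kingdom
slopes are reported alongside.

## Secondary-structure enrichment

DSSP codes group as helix (H, G, I), strand (E, B), turn (T, S) and coil
(anything else — applied literally, so unassigned residues are coil). For
each of the 32 (class, TE) cells the score is

$$\ln \frac{N_{j|k}/N_k}{N_j/N},$$

symmetric in class and environment. Zero-count handling is explicit because
small synthetic runs (unlike a ~10⁸-residue census) can produce zeros: a
cell with a zero *marginal* is undefined and reported `NA`; a zero joint
count with live marginals is a genuine $-\infty$; an optional
Haldane-style `pseudocount = 0.5` makes everything finite. No pseudocount
is added by default since the score definition is exact at nonzero counts.
A useful internal identity — for each class,
$\sum_k (N_k/N)\,e^{\text{score}} = 1$ over defined cells — follows from
the definition and is asserted in the tests at 1e-9.

## The additive stability model

$$\Delta G \;=\; \sum_{i=1}^{8} w^N_i\,\mathrm{NTE}_i
 \;+\; \sum_{j=1}^{8} w^D_j\,\mathrm{DTE}_j \;-\; L\,R\,T\ln Z$$

with R = 0.0083145 kJ/(mol K) and T fixed at 298.15 K (standard
conditions; configurable but defaulted). The first two terms act as a
per-environment solvation free energy; the last is a uniform per-residue
unfolded-state entropy penalty, Z being the effective number of unfolded
conformations per residue (RT ln 20 ≈ 7.43 kJ/mol).

**Identifiability.** Because $\sum_i \mathrm{NTE}_i = \sum_j \mathrm{DTE}_j
= L$, shifting every native weight by $a$, every denatured weight by $b$
and $\ln Z$ by $(a+b)/(RT)$ changes no prediction. All quality claims are
therefore about predictions, never raw parameters. `fitStabilityModel`
defaults to the unconstrained fit (reporting the degeneracy through
`gaugeTransform`, which makes it explicit and testable); `gauge = TRUE`
pins mean(w^N) = mean(w^D) = 0 afterwards — a pure reparameterization, so
the pinned Z is allowed outside the optimizer's search box.

**Optimizer.** Bounded multi-start quasi-Newton (L-BFGS-B, analytic
gradient) over the 16 weights and ln Z: 8 seeded uniform starts, weights in
[-20, 20] kJ/mol, Z in (1, 1000]; best objective wins; fully deterministic
given the seed. Because the model is linear in the weights at fixed Z, the
winner is polished by the closed-form minimum-norm least-squares solution
of the weights (accepted when it respects the bounds and does not worsen
the objective); this is what makes noiseless recovery exact to ~1e-12
rather than optimizer-tolerance. On the gauge-flat objective the
optimizer's convergence codes are uninformative, so a leave-one-out fold
counts as converged when its polished objective is finite. Whether the
original objective was unweighted least squares is unstated; unweighted is
implemented.

**Leave-one-out bootstrapping** produces one fit per left-out record;
weights are averaged element-wise and Z on the log scale (it enters the
model only through ln Z). Held-out predictions are pinned by the data only
when the training design spans the 15 identifiable weight directions, i.e.
from about 16 records up; below that the per-fold null spaces differ and
held-out predictions are not fold-invariant even without noise.
Classification (`classifyStructured`) calls a protein disordered when its
predicted ΔG exceeds a threshold, default 0 kJ/mol.

## Per-protein profiles

Hydropathy profiles use the Kyte-Doolittle scale (replaceable by any named
per-residue vector) with a centered moving average, default window 17.
Terminal windows shrink symmetrically rather than padding — the published
convention is unstated, and shrinking keeps the operator linear and
mass-preserving. TE delta profiles are positionwise mutant-minus-wild-type
native label differences; window averaging of a compensating +2/−2
adjacent pair zeroes the center and pushes the effect to the window edges,
which the tests demonstrate. Substitution-consequence distributions sum the
signed TE change over the mutated site ± 3 flanking residues by default,
because local stability changes land on sequence neighbors as well as the
site itself; the flank is configurable since the exact aggregation behind
the published census is unstated.

## The synthetic generator: what it emulates, and what it does not

The generator replaces two things the package deliberately does not ship:
the sequence-based TD predictor and the proteome downloads. Its defaults
*are* the study conditions of the test suite and acceptance script, chosen
once on field-plausibility grounds:

* **Centers** (`genCenterTable`): a deterministic ladder, adjacent centers
  10 kJ/mol apart in the assignment metric, with 70% of the separation
  carried by ΔG and 15% by each enthalpy. The native entropy column is flat
  across centers: its triple metric weight would otherwise triple the
  scatter noise in the discriminant while adding nothing to the test's
  purpose. Native ΔG means decrease strictly with the index, per the TE
  nomenclature.
* **Descriptor scatter** (`genProteinTD`): isotropic Gaussian, sd 1 kJ/mol
  — a tenth of the center separation, at which label recovery exceeds 99%.
* **Proteomes** (`genProteomeSet`): organism TE targets from
  kingdom-specific Dirichlet distributions with concentration 400 around a
  base composition peaked at TE4/TE5 (the two median-stability environments
  dominate real usage, with the extremes rarest). Bacteria and eukaryotes
  tilt by ∓0.8 log-units along a stability contrast, archaea by 0.35 along
  an alternating contrast, so the first two principal components carry a
  kingdom structure qualitatively like the real one without copying its
  numbers. Growth temperature is planted as 20 + 60 x (alternating
  contrast) + N(0, 4) °C and disorder as 0.25 + 0.35 x (stability
  contrast) + N(0, 0.03), clipped to [0, 1].
* **Secondary structure** (`genSSLabels`): class labels are sampled from
  per-TE conditionals constructed so that every *planted* cell of the
  log-odds matrix is realized **exactly** against the realized marginals,
  with free (`NA`) cells absorbing the compensation through per-row and
  per-column factors found by fixed-point iteration. Exactness matters: a
  naive "multiply the conditional by e^score" construction biases the
  realized score by the marginal shift (a ~0.3 error for a factor-2
  enrichment of a 0.35-probability class), which would defeat recovery
  tests. Not every matrix is feasible — each planted row and column needs
  compensating mass — and infeasible patterns raise an error rather than
  being silently renormalized. The full realized score matrix is returned
  as ground truth.
* **Stability records** (`genStabilityRecords`): class-specific Dirichlet
  compositions (structured tilted toward the stable end, disordered the
  mirror), denatured counts from the background shape, and ΔG from a known
  model (native ladder +2..−3, flat denatured 7.7 kJ/mol per residue,
  Z = 20) plus Gaussian noise, sd 2 kJ/mol. The truth weights put a typical
  structured protein near −0.25 kJ/mol per residue and a disordered one
  near +0.8, i.e. realistic two-state stabilities for the structured class
  and a clean sign separation for classification.

Every generator flows from one seed and returns its ground truth; same
seed, same bytes.

**What passing these tests shows — and does not.** The synthetic data are
Gaussian around well-separated centers, compositionally Dirichlet, and
linear in their planted traits. Real descriptor predictions are none of
these: environments overlap, proteome compositions are phylogenetically
autocorrelated, traits are noisy and confounded, and real stability data
carry experimental heterogeneity the generator does not model. Recovery
here validates the *implementation* (the estimators find what was planted,
at the planted magnitude), not the biological claims, and says nothing
about the accuracy of any upstream TD predictor.

## Problem sizes

The test suite and acceptance script use 10⁴ vectors for oracle-agreement
and recovery checks, 3 x 30 organisms x 20 proteins for the kingdom study,
500 replicates of n = 200 for regression calibration, 10⁵ residues for
log-odds recovery, and 35-record training sets with 50+50 length-matched
classification — sizes at which every sampling-error band in the checks is
comfortably resolved while the full suite runs in well under a minute.

## Known limitations

* The shipped centers are synthetic; analyses of real data require the
  published center values as a `readCenterTable()` input.
* The additive stability model's parameters are gauge-degenerate by
  construction; fitted Z values are comparable only within a fixed gauge.
* The denatured-state PCA variant (`states = "both"`) concatenates the two
  frequency blocks into a 16-vector; whether the original analysis used a
  concatenated or separate construction is unstated.
* No phylogenetic correction is applied in trait regressions: organisms
  are treated as independent, as in the analysis this package reimplements.
* Melting temperatures, salt and pH dependence are out of scope; T is a
  constant of the model, not a variable.
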