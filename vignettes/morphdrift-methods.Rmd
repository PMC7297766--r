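---
title: "Methods: from landmarks to an evolutionary-mode verdict"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from landmarks to an evolutionary-mode verdict}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(morphdrift)
```

# Overview

`morphdrift` analyses temporal samples of a single population measured by
3D landmarks — typically historic and contemporary museum skulls — and asks
whether the shape change between periods is attributable to genetic drift
or requires directional selection.  The chain is: landmark IO and
validation → missing-landmark imputation → view merging → generalized
Procrustes analysis (GPA) with object symmetry → RRPP shape ANCOVA and PCA
→ interlandmark-distance P-matrices → random skewers → multivariate drift
test.  This vignette documents the model at each stage, the parameters that
matter, the synthetic world the tests rely on, and the numerical choices.

# Superimposition

**Centroid size** of a configuration $X \in \mathbb{R}^{p\times 3}$ is
$CS = \sqrt{\sum_i \lVert x_i - \bar x\rVert^2}$, computed on the raw mm
coordinates before any scaling, and kept as the allometry covariate
($\log CS$).

**GPA** centers every configuration, optionally scales to unit centroid
size (the default; this is the partial-Procrustes convention standard in
geometric morphometrics), and iterates rotate-to-consensus /
recompute-consensus until the total residual changes by less than $10^{-10}$
or 100 passes.  The per-pass residual log is stored and is non-increasing;
non-convergence warns rather than fails.  The rotation subproblem is solved
in closed form by SVD with the determinant constrained to $+1$ (no
reflections).  The procedure is deterministic — no RNG anywhere in
alignment.  Analyses use the Procrustes shape variables directly
(coordinates relative to the consensus) without an explicit tangent-space
projection: at the shape-variation scale of within-population skull data
the projection changes nothing at the tolerances used here, and omitting it
keeps shapes interpretable as configurations.

**Object symmetry.**  Skulls are internally bilaterally symmetric, so each
configuration is paired with its reflected-relabeled copy (one coordinate
axis negated, left/right landmark rows swapped, midline rows fixed), GPA is
run on the doubled sample of $2n$ configurations, and each specimen's
*symmetric component* is the mean of its two aligned copies (the
asymmetric component is the half-difference; it is computed and returned
but not analysed further).  The decomposition is exact:
symmetric + asymmetric reconstructs the aligned original, and the doubled
set's variance splits additively between components.

**Missing landmarks** are imputed with a 3D thin-plate spline using the
biharmonic kernel $U(r) = r$ plus a full affine part, fit from a complete
reference (the rigidly aligned mean of the complete specimens) to each
incomplete specimen's observed landmarks; missing positions are the images
of the reference positions.  Because the affine part is exact, any specimen
that is an affine deformation of the reference is recovered to machine
precision — the key property test.  At least 4 non-coplanar observed
landmarks are required; a coplanar or coincident observed set raises a
singular-system error rather than returning garbage.

**View merging.**  When dorsal and ventral digitizing passes share a set of
common landmarks (5 in the shipped cranium template: 18 dorsal + 30
ventral − 5 common = 43), the ventral view is superimposed onto the dorsal
frame by rotation + translation only — both views are mm measurements of
one rigid object, so scaling is forbidden — and the common landmarks are
averaged across the two fitted copies.  Averaging (rather than keeping the
dorsal copy) is a declared assumption; the historical merging tool's exact
rule is undocumented.  A configurable RMSD threshold on the common-landmark
fit catches digitizing blunders.

# RRPP linear models

Shape responses are the flattened symmetric Procrustes shape variables.
Sums of squares are **sequential (type I)**: $SS_k$ is the drop in residual
sum of squared Procrustes distances when term $k$ joins terms
$1,\dots,k-1$, implemented with orthonormal bases of the nested design
matrices so each permutation costs three projections.  Goodall's
$F_k = (SS_k/df_k)/(SS_{res}/df_{res})$ pools over all response columns.

The RRPP null for term $k$ permutes the residuals of the reduced model
(terms $1..k-1$) and adds them back to the reduced fitted values; a single
permutation per iteration is shared by all terms, drawn from one seeded
stream.  The observed arrangement counts as one of the `n_perm`
permutations, so $p \ge 1/n_{perm}$ — with the conventional 1,000
iterations the smallest reportable p-value is 0.001.  The effect size $Z$
is computed on the F distribution itself, $(F_{obs} - \bar F^*)/sd(F^*)$;
implementations in the wild have switched between $F$ and $\log F$
conventions across versions, so Z values are explicitly not comparable
across packages and are not used for any decision here.

Factors use treatment contrasts with alphabetical level order ("1890s"
before "2010s", "F" before "M"); under unbalanced designs this affects the
term-wise sequential SS, which is why the fitting order is user-visible and
preserved exactly as entered.  On balanced univariate designs the machinery
reduces exactly to the classical ANOVA table (tested against the closed
form), and its type-I error at $\alpha = 0.05$ is calibrated to
$[0.03, 0.07]$ over 1,000 null simulations.

Companion tests follow the same RRPP logic: full-vs-reduced model
comparison (F from the SS difference, reduced-model residuals permuted),
pairwise homogeneity of slopes (statistics: $|\,\lVert b_i\rVert -
\lVert b_j\rVert\,|$ and the angle $\arccos(b_i \cdot b_j /
\lVert b_i\rVert \lVert b_j\rVert)$, null: the common-slope model), and the
digitizing-error percentage ($100 \cdot SS_{res}/SS_{tot}$ with specimen
identity as the sole factor on replicated measurements).

**PCA** is the SVD of the mean-centered flattened shape variables;
eigenvalues sum to the total shape variance, scores reproduce pairwise
shape distances, and each axis carries consensus ± extreme-score
reconstructions for wireframe-style display (rendering itself is out of
scope).

# Traits, P-matrices, random skewers

Interlandmark distances are computed from the **raw digitized
coordinates**, never the aligned ones: Euclidean distances are invariant to
rigid motion, so superimposition is unnecessary, and mm units keep
biological effects (a fraction-of-a-millimetre tooth-row change) readable.
Left/right copies of a bilaterally symmetric distance are declared via a
reciprocal `mirror_of` relation and averaged into one trait.  Distances are
not log-transformed by default (a `log` flag exists); the choice matters
only if trait scales differ by orders of magnitude, which interlandmark
distances on one skull do not.

Each period's **P-matrix** is the unbiased $(n-1)$ sample covariance of its
trait rows.  With typical museum sample sizes ($n \approx 25$) and
$m \approx 20$–30 traits, P can be singular; the package warns (and all
downstream operations tolerate PSD-singular matrices) rather than
silently regularizing.

**Random skewers** draws selection vectors $\beta$ uniformly on the unit
sphere (normalized iid Gaussians; a uniform-cube option exists for
historical fidelity), computes responses $\Delta z_i = P_i\beta$, and
reports the mean cosine between response pairs over `n_vectors = 1000`
draws.  The p-value uses the closed-form null for the cosine of two
independent uniform unit vectors in $m$ dimensions,
$(1+X)/2 \sim \mathrm{Beta}(\tfrac{m-1}{2}, \tfrac{m-1}{2})$, rather than a
Monte-Carlo null — exact, fast, and verified against simulation in the
tests.  No repeatability (t-)adjustment is applied to the correlation.

# The multivariate drift test

Under pure drift for $t$ generations at effective size $N_e$, the
between-period mean shift is a draw from $\mathrm{MVN}(0, D)$ with
divergence matrix $D = P_{anc}\, t/N_e$, the ancestral-period P-matrix
standing in for the G-matrix.  The test simulates `n_sim` such draws, takes
the $(\alpha/2, 1-\alpha/2)$ quantiles of their norms as the **drift
envelope**, bootstraps the observed divergence norm by resampling specimens
within each population (`n_boot` resamples), and **rejects drift only when
the observed CI lies entirely above the envelope** — a deliberately
conservative rule.

**Sampling-error correction (a design decision).**  The raw statistic
$\lVert \bar z_2 - \bar z_1 \rVert$ confounds drift with the noise of
estimating two mean vectors, whose contribution
$\mathrm{tr}(S_1)/n_1 + \mathrm{tr}(S_2)/n_2$ dwarfs the drift signal in
the regime this test targets ($t/N_e \approx 0.015$ against
$1/n_1 + 1/n_2 = 0.08$): the uncorrected statistic would reject drift on
pure noise most of the time.  The default observed statistic is therefore
$\sqrt{\max(0, \lVert\Delta\bar z\rVert^2 - \mathrm{tr}(S_1)/n_1 -
\mathrm{tr}(S_2)/n_2)}$, applied identically inside every bootstrap
replicate; `correct_sampling = FALSE` restores the literal norm.  With the
correction the test is calibrated (pure-drift rejection rate well under
0.10 in the target regime) while retaining essentially full power against
directional shifts of 5× the median drift norm — both properties are
exercised at full scale in the acceptance tests.  A consequence worth
knowing: divergence smaller than the sampling noise is indistinguishable
from zero, so the infinite-$N_e$ limit rejects drift only for divergence
that actually exceeds noise.

The simulated norms themselves remain pure $\mathrm{MVN}(0, P\,t/N_e)$
draws, so their median scales as $\sqrt{t/N_e}$ (for $P = \sigma^2 I$ it
equals $\sigma\sqrt{t/N_e}$ times the median of a $\chi_m$ distribution),
the distribution is invariant to simultaneous orthogonal rotation of $P$
and the trait basis, and the whole result is bit-reproducible under a fixed
seed.  Generation counts come from `generations_count()`: for windows
1889–1895 and 2014–2016 at 3 generations/year the span is 357–381 with
arithmetic mean 369 (the source study quotes 370 for this span; the
difference is their rounding, and $t$ is a user input in any case).
Estimating $N_e$ itself (from genomic data) is out of scope; $t$ and $N_e$
are user-supplied.

# The synthetic world

`make_template(n_pairs, n_midline)` builds a bilaterally symmetric template
(midline on the $x{=}0$ plane, pairs mirrored in $x$) with distance
definitions covering all midline–midline pairs plus one mirrored bilateral
distance per pair; `19 + 5` reproduces the 43-landmark cranium structure.
The shipped `cranium_template()` / `mandible_template()` are **documented
synthetic stand-ins**: they have the study's correct counts (43 with an
18/30/5 dorsal/ventral/common split; 15 left-side mandible landmarks) but
not the real anatomy, whose definitions live in unpublished supplementary
tables.

`simulate_shapes()` draws each specimen as
$\text{base} + \log(s)\,A + \mathbb{1}(\text{2010s})\,T +
\mathbb{1}(\text{M})\,X + \varepsilon$, scales to its drawn centroid size
$s \sim U(\text{size\_range})$, and adds iid Gaussian digitizing noise per
coordinate per replicate.  Defaults describe a rat-skull-like regime chosen
once: 12 specimens per period × sex cell ($n = 48$, near the study's 49
crania), centroid sizes 40–55 mm, digitizing noise 0.05 mm, isotropic
individual shape sd 0.005 (Procrustes units).  Because effects are defined
at unit centroid size, a configuration with all effects and noise zeroed
and `size_range = c(1, 1)` reproduces the base shape exactly — the
degenerate-case contract the tests pin down.  The generator emulates the
additive linear-model structure the ANCOVA assumes; it does **not** emulate
integration/modularity structure, measurement outliers, allometric
curvature, or realistic anatomy, so a green recovery test establishes
correctness of the machinery, not anatomical realism.

`simulate_trait_divergence()` draws the ancestral sample from
$\mathrm{MVN}(\mu, P)$, one drift shift $\delta \sim
\mathrm{MVN}(0, P\,t/N_e)$, and the descendant sample from
$\mathrm{MVN}(\mu + \delta + s, P)$ with $s$ the selection vector (zero
under drift).  Defaults: $m = 20$ traits, $P = 0.25(0.3J + 0.7I)$ mm²
(variances 0.25 mm², correlations 0.3 — typical of mm-scale skull
distances), $\mu = 10 + 0.5(1{:}m)$ mm, $n_1 = n_2 = 25$, and
$t/N_e = 370/24905 \approx 0.0149$, the regime of a ~120-year, 3
generations/year rodent series.

# Numerical choices and edge cases

- GPA convergence $10^{-10}$ on the total residual, max 100 passes;
  rank-deficient (collinear) configurations abort the rotation solve.
- TPS systems are solved exactly; singularity (coincident/coplanar support
  points) is an error, not a warning.
- Permutation p-values use $\ge$ with a $10^{-12}$ slack so ties (exact
  refits of the observed data) count toward the null.
- PSD checks tolerate eigenvalues down to $-10^{-8}\cdot\mathrm{trace}$ to
  absorb symmetric-eigensolver noise.
- The missing-data sentinel is all-9999 rows in TPS files and blank
  coordinate fields in CSV; round-trips preserve masks exactly.
- Aliased model terms (no rank added) raise an error naming the term.
- `mirror_of` relations must be reciprocal; the averaged trait takes the
  alphabetically first member's name.

# Limitations

- The real landmark/distance definitions of the motivating study are not
  public; its headline numbers (ANCOVA R², PCA percentages, skewers
  correlations, drift CIs) therefore cannot be reproduced without the
  archived primary data, and the shipped templates are structural stand-ins.
- The drift test treats $t/N_e$ as known; uncertainty in either is not
  propagated.
- P-for-G substitution is a biological assumption, not a statistical one;
  with low trait heritability the drift envelope is misscaled.
- Sliding semilandmarks, 2D pipelines, mixed models, and non-sequential SS
  types are out of scope.
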