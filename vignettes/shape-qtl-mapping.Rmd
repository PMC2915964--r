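---
title: "Mapping shape QTLs: model, algorithms, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping shape QTLs: model, algorithms, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shapeqtl)
```

# The problem

A backcross segregates two genotypes, QQ and Qq, at every locus. If a
locus influences organ shape, progeny carrying different QTL genotypes
have systematically different silhouettes, blurred by segregation
elsewhere in the genome and by environment. shapeqtl treats the whole
silhouette as the phenotype — every pixel of a signed-distance
embedding — rather than a handful of landmarks or ratios, so shape
differences anywhere in the outline contribute to the mapping signal.

The workflow has four stages, each exposed as ordinary functions:
alignment (`align_shapes`), embedding (`build_phenotypes`), the mixture
fit (`run_em`), and the genome scan with permutation calibration
(`qtl_scan`, `permutation_threshold`).

# Alignment

Shape, in Kendall's sense, is what remains after location, scale and
rotation are removed. We estimate a pose p = [a, b, h, θ] per image and
minimise the joint pairwise energy

$$E=\sum_{i<j}\frac{\sum_\Omega(\tilde I^i-\tilde I^j)^2}{\sum_\Omega(\tilde I^i+\tilde I^j)^2}$$

by steepest descent with backtracking line search. Design choices a
user should know about:

* **Normalised energy.** The denominator removes the degenerate
  minimum at h → 0 in which every shape shrinks to nothing; the raw
  sum-of-squares variant stays available (`normalized = FALSE`) for
  sensitivity checks.
* **Gauge fixing.** A common pose applied to all images leaves E
  unchanged, so the optimum is a ridge. We freeze shape 1
  (`reference_index`) at the identity; recovered poses are therefore
  relative to that reference frame.
* **Centering.** Scaling and rotation act about the image center
  ((L+1)/2, (L+1)/2). Origin-centered similarity transforms on 1..L
  grids swing shapes out of the domain.
* **Differentiability.** Binary images have no spatial derivatives, so
  gradients are evaluated on Gaussian-smoothed copies (σ = 1 px,
  `smoothing.sigma`). Transformed images are pull-sampled bilinearly —
  output(x, y) = input(T[p]⁻¹(x, y)) — and the analytic gradient flows
  through the exact derivative of the bilinear interpolant and the
  Jacobian of the inverse coordinates. The test suite checks it against
  central finite differences at off-lattice poses; on the lattice lines
  the interpolant has kinks where one-sided derivatives are expected.
* **Parameterisation.** Scale is optimised as log h (positivity for
  free, and a step of 0.01 means "one percent" at any scale); rotation
  in radians; translations in pixels. The first line-search trial is
  scaled so the largest component moves `step0` = 0.1 units; the step
  doubles after an immediately accepted move and halves on
  backtracking, so the trace is non-increasing by construction.
* **Initialisation.** Translations start at foreground-centroid
  differences, scale at the square-rooted area ratio, rotation at zero.
  This moment-based warm start places optimisation inside the
  attraction basin for the pose ranges we target (a few pixels, ±10 %
  scale, ±15°); larger rotations of nearly symmetric shapes can still
  fall into a symmetry-related local minimum, which joint alignment
  cannot distinguish from the truth.
* **Stopping.** |ΔE|/E < 10⁻⁶ or 500 iterations; hitting the cap
  records a warning on the result rather than failing, since pose
  recovery is typically already inside tolerance while E creeps along
  a flat valley.

# Signed-distance phenotypes

Each aligned image is binarised (threshold 0.5 of the interpolated
intensity) and embedded as an exact Euclidean signed distance map:
background pixels carry the distance to the nearest foreground pixel,
foreground pixels minus the distance to the nearest background pixel.
Distances are pixel-center to pixel-center, so magnitudes are ≥ 1, the
zero level set lies between pixels, and thresholding the field at zero
reproduces the binary image exactly — which is also how estimated
genotype means are rendered back into shapes (`reconstruct_shape`).
The exactness matters because these values enter a likelihood;
a chamfer approximation would bias parameter recovery. The transform is
delegated to `EBImage::distmap` and verified in the test suite against
a brute-force all-pairs oracle.

Columns of the L×L field are stacked (column-major) into a length-m
vector, m = L², giving the n×m phenotype matrix. At L = 256 this is
already m = 65,536 variables per progeny; the default simulation grid
of L = 75 gives m = 5,625.

# The mixture model and EM

At a test position, flanking markers at recombination fractions r₁ and
r₂ (Haldane, r = r₁ + r₂ − 2r₁r₂) determine each progeny's prior
probability ω_{1|i} of carrying QQ via the standard backcross
conditional-probability table; at a marker the prior collapses to that
marker's genotype indicator. The phenotype density is the two-component
mixture ω_{1|i} f(Y_i; μ₁, σ²I) + ω_{2|i} f(Y_i; μ₂, σ²I).

Working assumptions, and why:

* **Σ = σ²I, shared between genotypes.** With m in the thousands an
  unstructured m×m covariance is hopeless at n = 200; the independence
  working model keeps the likelihood well defined and the M step closed
  form. Smooth spatial correlation in real SDFs is thereby ignored —
  the LR is then a quasi-likelihood statistic, which is one reason
  significance comes from permutation rather than asymptotics.
* **Unstructured means.** μ₁ and μ₂ are free m-vectors; no basis or
  smoothness penalty is imposed on them.

The EM alternates the posterior update
Π_{j|i} ∝ ω_{j|i} f_j(Y_i) with weighted means per genotype and the
pooled variance σ² = (nm)⁻¹ ΣᵢΣₖΣⱼ Π_{j|i}(y_{ik} − μ_{jk})².
Numerical choices:

* All density arithmetic is in log space with log-sum-exp; raw
  densities underflow catastrophically at these dimensions.
* Initialisation hard-assigns each progeny to its larger prior weight
  (ties to component 1) — deterministic and genetics-informed. If a
  component empties, one restart perturbs the means by ±0.1σ before
  failing.
* Convergence: absolute log-likelihood change < 10⁻⁶, cap 200
  iterations; a variance floor of 10⁻¹² guards noiseless data.
* The log-likelihood trace is asserted non-decreasing (EM ascent) on
  every fit in the test suite.

# Scan and permutation test

`qtl_scan` computes LR = 2(ℓ̂_mix − ℓ̂₀) on a position grid (default:
every 1 cM plus all markers; coarser grids via `scan_grid(map, by)`),
with the one-component null fitted once in closed form. Two guards keep
the profile nonnegative: positions whose prior leaves a component with
essentially no mass are scored LR = 0 (a single effective component is
the null), and whenever the genetics-informed EM start ends below the
null likelihood, the EM is re-seeded from the null solution and the
better fit kept.

`permutation_threshold` shuffles whole phenotype rows against the
genotype matrix — preserving within-shape correlation, breaking only
the marker-phenotype link — reruns the scan per permutation, and takes
the type-7 empirical (1 − α) quantile of the max-LR draws. The
permutation stream is an explicit function of `seed`, so thresholds are
replayable. Defaults: 1000 permutations in production, α = 0.05.

One behaviour worth understanding: when the phenotypes are strongly
bimodal (a large QTL effect), the mixture can rediscover the two
clusters even after permutation wherever the priors are soft (interior
test positions), so permuted max-LR values are themselves large and the
detection margin is carried by the linkage information. At marker
positions the indicator priors pin the posteriors, permuted LRs stay
small, and margins are wide. Either way the threshold is conditional on
the observed data, so it is recomputed per dataset — reusing a
threshold across replicate simulations is not valid, and the package's
own validation computes one per replicate.

# The synthetic simulator

`simulate_population` replicates the simulation design used to
validate the method: n = 200 backcross progeny, one linkage group of 11
equally spaced markers (10 cM spacing chosen as the conventional
default; the spacing is configurable), a shape QTL on the third marker
interval (25 cM, mid-interval), and phenotypes drawn as
Y_i = ξ_i μ₁ + (1 − ξ_i) μ₂ + e_i with e_i ~ N(0, σ²I), σ² = 1.
Marker and QTL genotypes are simulated as one Markov chain over the
augmented locus list, so the indicator ξ_i and the QTL genotype agree
by construction. Noise is added in SDF space — the additive
multivariate-normal model is only coherent for continuous phenotypes —
and noisy silhouettes are obtained by thresholding the noisy fields at
zero.

The genotype mean shapes come from a parametric leaf: polar boundary
ρ(φ) = r₀L(1 − d·cos(kφ))(1 + s·cos(12φ)) with y-scaling for
elongation. Three named presets fix the effect sizes as reproducible
constants rather than free knobs: `"big"` (deeply lobed round wild
type vs nearly unlobed elongated cultivar), `"small-wild"` (lobe depth
0.45 vs 0.35), `"small-cultivar"` (elongation 1.3 vs 1.15), plus
`"null"` (identical shapes, for calibration). What the simulator does
*not* emulate: photographic segmentation error, within-genotype
biological shape variation beyond iid pixel noise (real leaves vary
smoothly, not independently per pixel), asymmetry, petioles, and
multi-QTL or epistatic architectures. Passing tests therefore
demonstrate correct inference under the stated generative model, not
robustness to violations of it.

# Problem sizes used in validation

The package's own test suite runs the replication schemes at L = 32
(m = 1,024) with per-replicate 100-permutation thresholds on the 10 cM
marker grid, 20 replicate seeds per scheme; EM correctness is checked
against exact small-instance oracles; alignment recovery uses six
copies of one L = 48 leaf under ±3 px, ±10 % scale, ±15° perturbations;
and type-I error is estimated from 100 null simulations at n = 60,
L = 16 over a 6-marker map. These are the package's chosen validation
scales; production analyses would typically use L = 75–256 grids, the
1 cM scan grid, and 1000 permutations.

# Known limitations

* Backcross only; F2/RIL designs need different genotype priors.
* Missing marker genotypes are rejected rather than integrated over.
* The σ²I working covariance understates spatial correlation; the
  permutation test protects the size of the QTL test, but posterior
  probabilities and density summaries inherit the approximation.
* Joint alignment is O(n²L²) per energy evaluation — fine for tens of
  shapes, impractical for hundreds; for simulated populations (born
  aligned) the pipeline's alignment stage can be disabled.
* Single-QTL scan; no multiple-QTL or epistasis modelling.
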