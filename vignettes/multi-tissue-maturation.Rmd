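---
title: "Modelling white-matter maturation with multi-tissue spherical deconvolution"
author: "neomti"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling white-matter maturation with multi-tissue spherical deconvolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neomti)
```

## The problem

Diffusion MRI of the neonatal brain changes dramatically over the weeks
around term: white matter sharpens its orientation signature and slows its
signal decay across b-values as premyelination and myelination proceed,
overall water content falls, and the brain grows and reshapes. A single
"adult-style" white-matter/grey-matter/CSF decomposition does not work in
neonates — cortical grey matter is spectrally indistinguishable from much
of the white matter at this age — but the white-matter signal itself
carries a strong, approximately linear age trend.

`neomti` implements a complete analysis chain built around that
observation:

1. decompose the multi-shell HARDI signal into **three components** — an
   isotropic, CSF-derived compartment (*Iso*) and two anisotropic
   compartments whose kernels are the white-matter signatures of the
   **youngest** (*Ay*) and **oldest** (*Ao*) ends of the age range — by
   multi-shell multi-tissue constrained spherical deconvolution (MSMT-CSD);
2. normalise the components so densities are quantitatively comparable
   across subjects;
3. align subjects with a symmetric diffeomorphic ODF registration that
   reorients fibre orientation distributions, driven by two contrasts
   (CSF + the subject's native WM component) with equal weights;
4. build unbiased, leave-one-out groupwise templates on a coarse-to-fine
   schedule, organise them into weekly templates in one common space; and
5. extract per-region time courses of the component densities, in which
   the balance between *Ay* and *Ao* reads out local maturation.

Everything is exercised on synthetic multi-shell phantoms with known
three-tissue ground truth; no clinical data ships with the package.

## Signal model

A tissue's **response function** is the axially symmetric signal kernel of
a canonically oriented fibre population, stored as per-shell zonal (m = 0)
coefficients of the real even spherical-harmonics (SH) basis. For a voxel
containing tissue ODFs $f_i$ with responses $R_i$, the predicted signal is
the sum of spherical convolutions

$$ S(b, \mathbf{g}) \;=\; \sum_i (f_i \ast R_i)(b, \mathbf{g}), \qquad
   (f \ast R)_{\ell m} \;=\; \sqrt{\tfrac{4\pi}{2\ell+1}}\; R_{\ell}(b)\, f_{\ell m}. $$

MSMT-CSD inverts this per voxel as a linear least-squares problem subject
to nonnegativity of every tissue's ODF amplitude on 300 near-uniform
directions — a convex quadratic program solved to machine precision
(dual-method active set; Tikhonov $10^{-12}$ on the normal matrix makes the
objective strictly convex; unconstrained interior solutions take a direct
path). `shell_residuals()` reports per-shell misfit in percent of the mean
b = 0 signal; on phantoms the three-component model fits at least as well
as any two-component alternative on every shell.

The maturation model treats any white-matter response $R_{\mathrm{WM},t}$
as a linear mixture of the two age-extremal kernels,

$$ \operatorname*{argmin}_{\alpha, \beta}\;
   \lVert \alpha R_{\mathrm{WM,y}} + \beta R_{\mathrm{WM,o}} -
   R_{\mathrm{WM},t} \rVert^2, $$

fitted by unconstrained least squares over all stacked coefficients
(`fit_response_mixture()`; weights may be negative). The quantity
$\beta - \alpha$ increases monotonically with age and is the package's
scalar maturation read-out. Age curves of such quantities are fitted with
a cubic polynomial under the Huber loss (`fit_age_curves()`, IRLS with
$\delta = 1.345\,\mathrm{MAD}$, reducing to ordinary least squares for
well-behaved data).

## Conventions that other tools may choose differently

* **SH basis**: real, even degrees only, orthonormal on the sphere;
  coefficients ordered by ascending $\ell = 0, 2, \dots$ and, within each
  degree, $m = -\ell \dots \ell$. 4-D NIfTI SH volumes store coefficients
  in this order on the fourth axis.
* **Density vs amplitude**: the *density* of an ODF is its integral over
  the sphere, $c_{00}\sqrt{4\pi}$; the *DC (mean) amplitude* is
  $c_{00}/\sqrt{4\pi}$. The normalisation target — mean summed DC
  amplitude $= 1/(4\pi)$ — is identical to *unit mean summed density*.
* **Shells**: volumes within ±50 s/mm² of a shell centre belong to that
  shell; the representative b is the member mean.
* **Geometry**: NIfTI affines are authoritative; voxel indices are
  0-based; displacement fields live in world millimetres and follow the
  pull-back convention (an image resampled through $\varphi(x) = x + u(x)$
  takes its value at $\varphi(x)$).

## Response estimation

`select_csf_voxels()` keeps the fastest-decaying 10% of a dilated brain
mask (ratio of mean b = 0 to mean highest-shell signal), above a noise
floor of twice the background SD. `select_single_fibre_voxels()`
iterates: deconvolve the highest shell with the current kernel
(initialised with a sharp axially symmetric tensor), rank voxels by peak
dominance, keep the best, re-estimate the kernel from the kept voxels
(signals rotated so each voxel's fibre axis maps to +z, then projected on
the zonal basis), and stop when the kept set is stable (Jaccard ≥ 0.99,
at most 10 iterations; a damped kernel update stabilises the ranking).

Three details matter at realistic noise and were settled empirically on
the phantom:

* **Dominance score.** Ranking by the *ratio* of first to second ODF peak
  is scale-invariant, so weak, noise-dominated ODFs whose second peak
  happens to vanish outrank strong coherent fibres. The package instead
  ranks by the amplitude **margin** `peak1 - max(peak2, 0)`, and the
  ranking deconvolution carries a Laplace–Beltrami penalty (relative
  weight 0.1) strong enough to suppress noise peaks on the high-b shell
  while leaving 90° crossings — the sharpest structure the score must
  reject — clearly resolved. With this score essentially all selected
  voxels fall in true single-fibre bundles across the whole age range.
* **Fibre axes.** The realignment axis for response estimation is the
  tensor fit's principal eigenvector, which pools the high-SNR low-b
  shells; on immature subjects its median axis error is ≈ 3° where the
  high-b ODF peak errs by ≈ 30°. ODF peaks still drive the dominance
  ranking.
* **FA gate.** Instead of the manual mask editing used for young brains
  in practice, candidates are gated at the in-mask upper FA quartile with
  an absolute floor of 0.15. The moving quartile follows parenchymal FA
  as it rises with maturation; the floor protects immature brains, whose
  deep white matter reaches only FA ≈ 0.17–0.21 once intra-voxel
  dispersion is accounted for, while neonatal grey matter and free water
  stay below ≈ 0.1. Deep-white-matter restriction comes from eroding the
  brain mask by 2 voxels (configurable; the erosion depth is not
  prescribed anywhere and 2 voxels removes the cortex-like rim on the
  phantom).

## Normalisation and the two-pass protocol

`mt_normalise()` estimates one smooth multiplicative field shared by all
components — an order-3 trivariate polynomial of the log summed DC
amplitude, alternating field and scale updates — plus a single global
scale, so that after correction the in-mask mean summed DC amplitude is
exactly $1/(4\pi)$. Voxels with non-positive summed amplitude are excluded
from the field fit and flagged. Doubling all inputs changes only the
scale, not the output.

`two_pass_decompose()` implements the full protocol: (1) subject-native
CSF + WM estimation, two-tissue decomposition and normalisation, with the
global scale propagated back onto the subject's responses (multiplied by
the scale, so normalised responses reproduce normalised densities — this
is what makes responses comparable across subjects); then (2) a
three-tissue decomposition with fixed group kernels, normalised again.

## Registration and template construction

`register_rigid_affine()` optimises the multi-contrast SSD cost (squared
L2 difference of SH coefficients, channels combined as a weighted average)
over rigid then affine parameters, moving both images symmetrically into
the midway space (matrix square root of the affine). `register_nonlinear()`
is a symmetric demons-type scheme: both images carry half-warps toward the
midway space; per iteration the SSD force is smoothed (σ = 2.0 × voxel),
applied with an adaptive step (halved on cost increase, so accepted
iterations never increase the cost), and the accumulated displacement is
smoothed (σ = 1.0 × voxel). The derivative of the reorientation term is
ignored in the force — the standard approximation — while the returned
warps carry numerically exact inverses (composition error ≈ 0.01 voxel).

ODF reorientation uses apodized deltas: the ODF is decomposed onto 300
fixed directions, the directions are pushed through the local Jacobian
(inverse of the pull-back Jacobian), and the SH coefficients are
recomposed. For affine maps this collapses to a single precomputed
SH-space matrix.

`build_template()` follows leave-one-out averaging: per schedule stage,
each subject registers to the mean of all *other* transformed subjects,
then transforms are updated and the average rebuilt. After every
rigid/affine stage the element-wise mean transform is removed, and after
every nonlinear stage the voxel-wise mean displacement is subtracted
(warp demeaning) — these two demeaning steps are the concrete mechanism
behind "unbiased" here, since leave-one-out registration alone lets the
template drift. Each subject is resampled exactly once per evaluation,
through its composed transform. The full 28-stage schedule (6 rigid + 6
affine from 3.3 mm to 1 mm, lmax 2 then 4; 16 nonlinear, 8 from 3.3 mm to
1 mm at lmax 2 then 8 at 1 mm with lmax 4) is `default_schedule()`;
`desk_schedule()` — two rigid, one affine, three nonlinear stages at
resolutions suited to the 24 × 24 × 16 phantom — is the default for
`build_template()` and is what the test suite exercises.
`build_weekly_and_common()` builds one common template from all subjects
and averages each weekly group's transformed images, so weekly templates
share the common space and each subject is interpolated once end-to-end.

## The phantom: what it emulates, and what it does not

`phantom_truth()` / `render_phantom()` / `make_cohort()` generate the
study conditions: four shells at b = 0/400/1000/2600 s/mm² with
20/64/88/128 volumes, 1.5 mm voxels, on a 24 × 24 × 16 grid. The anatomy
comprises an ellipsoidal brain mask, a central CSF block (≈ 24% of the
mask, a deliberately generous neonatal ventricle/CSF fraction), two
orthogonal unit-density fibre bundles crossing at 90° with a 50/50 split,
a thin cortex-like rim with radial fibres, and background parenchyma made
of two balanced orthogonal weak fibres (0.3 + 0.3) plus 40% free water —
anisotropic enough not to decay like CSF, yet never single-fibre
dominant. Summed density is 1 everywhere in the mask, matching the
normalisation model. The maturation weight is a power-law ramp
$t = \mathrm{age}_{\!f}^{\,2.5 - 1.8\, y_{\mathrm{post}}}$ with
$\mathrm{age}_{\!f}$ linear in postmenstrual age from 33 to 44 weeks and
$y_{\mathrm{post}} \in [0, 1]$ the anterior-to-posterior coordinate:
maturation rises strictly with age everywhere and reaches 1 at 44 weeks
in every voxel, but posterior voxels (concave exponent 0.7) rise early
while anterior voxels (convex exponent 2.5) lag — regional time courses
differ in onset, not just amplitude. Fibre ODFs are *apodized* deltas — the sharpest band-limited Watson
lobe that stays strictly positive at lmax 8 — so the ground truth never
sits on the deconvolution's nonnegativity constraints and noiseless
recovery is exact. Tissue kernels are axially symmetric tensors
(young: λ∥ = 1.9, λ⊥ = 1.2; old: λ∥ = 1.7, λ⊥ = 0.4, all ×10⁻³ mm²/s;
free water 3.0 ×10⁻³ mm²/s), chosen to reproduce the qualitative trend of
sharpening with slower cross-shell decay. Noise is Rician at SNR 30
(referenced to b = 0), and a smooth multiplicative bias field
(order-2 log-polynomial, ±10% in-mask) emulates residual
coil-sensitivity modulation. Cohorts deform one base anatomy per age by
random smooth diffeomorphic warps (velocity-field exponentials, so exact
inverses are known) with a 2 mm default peak amplitude.

What the phantom does **not** emulate: realistic anatomy or partial
voluming, EPI distortion, motion, gyrification, multiple crossing angles,
spatially varying SNR, or exchange between compartments. Passing tests
therefore demonstrate the correctness and self-consistency of the
algorithms under the stated model — not clinical performance on real
neonatal data. Estimated responses on the phantom recover the
*dispersion-convolved* kernel (`phantom_effective_response()`), exactly as
in-vivo estimates absorb intra-voxel orientation dispersion.

## Numerical choices and degenerate inputs

* Quadrature oracles use equal-weight Fibonacci samplings with ≥ 4096
  nodes; SH code is validated against them (orthonormality to 10⁻³ on
  10 000 nodes, convolution theorem to 10⁻⁴ relative).
* The per-voxel QP is `quadprog` with a pre-factorised Cholesky; failed
  solves zero the voxel and set a QC flag. An independent check solves the
  dual as an NNLS (own Lawson–Hanson) — strong duality makes it exact.
* Peak finding evaluates 300 hemisphere directions and refines each peak
  on shrinking spherical caps to sub-degree precision.
* Trilinear interpolation zero-pads outside the field of view for images
  and clamps for displacement fields; field inversion is fixed-point
  (20 iterations), adequate for the smooth fields produced here.
* Degenerate inputs error early and descriptively: empty masks, all-zero
  images, mismatched gradient tables, ragged response files, collinear
  mixture kernels, zero axes.
* Problem sizes in the tests (24 × 24 × 16 grids, lmax ≤ 8, cohorts of
  2–12 subjects, reduced schedules) are the package's desk-scale defaults;
  every algorithm accepts larger inputs unchanged.

## Known limitations

* The demons-style registration is first-order and, like the framework it
  follows, ignores the reorientation derivative in the force; very large
  rotations of anisotropic structure converge more slowly.
* Affine demeaning in template building is element-wise (exact for
  translations, first-order for rotations/scalings).
* The single-fibre selection degrades gracefully but measurably in mature,
  noisy data when balanced crossings dominate the candidate pool
  (~75–80% in-bundle on warped mature subjects at n_keep = 80); the
  response average tolerates this contamination, and the maturation
  read-out remains monotone.
* `mt_normalise()` assumes near-unit summed density in brain tissue, as
  its real-world counterpart does; strong true density gradients would be
  partially absorbed into the field.
* On the desk-scale grid, template "sharpness" (mean ODF peak amplitude in
  bundle cores) is dominated by trilinear-interpolation blur rather than by
  residual misalignment — bundle cores are only 3–4 voxels wide — so
  sharpening across template stages is not measurable there; template
  quality is instead validated through ground-truth warp recovery and
  exact unbiasedness.
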