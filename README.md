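# neomti

Multi-component spherical deconvolution and orientation-distribution
template building for neonatal diffusion MRI, in R.

Between roughly 33 and 44 weeks postmenstrual age, the white-matter (WM)
diffusion signal changes shape continuously: it sharpens around the fibre
axis and its decay across b-values slows. A WM/GM/CSF decomposition that
works in adults fails in neonates (cortical grey matter is spectrally
inside the white-matter spectrum at this age), but the WM trend itself is
the signal of interest. `neomti` is for researchers who want to exploit
that: it decomposes multi-shell HARDI data into one CSF-derived isotropic
component and **two anisotropic components whose kernels are the WM
signatures of the age extremes** — so the local balance between the
"young" and "old" components reads out maturation, fibre population by
fibre population.

## The model

Each tissue has a response function $R_\ell(b)$ (per-shell zonal SH
coefficients of an axially symmetric kernel). The voxel signal is a sum of
spherical convolutions, which in SH coefficients reads

$$ S_{\ell m}(b) = \sqrt{\tfrac{4\pi}{2\ell+1}}\; R_\ell(b)\, f_{\ell m}, $$

and MSMT-CSD inverts this per voxel under nonnegativity of all tissue ODF
amplitudes (a convex QP). WM maturation is modelled as a mixture of the
age-extremal kernels,

$$ \operatorname*{argmin}_{\alpha,\beta}
   \lVert \alpha R_{\mathrm{WM,y}} + \beta R_{\mathrm{WM,o}}
   - R_{\mathrm{WM},t} \rVert^2 , $$

with $\beta - \alpha$ increasing monotonically with age. Components are
normalised so the summed ODF density averages 1 (mean summed DC amplitude
$1/(4\pi)$) with a shared smooth bias field. Alignment uses symmetric
diffeomorphic ODF registration with apodized-delta reorientation, driven
by two contrasts (CSF + native WM) with equal weights; unbiased leave-one-
out template building follows a 28-stage coarse-to-fine schedule (a
reduced 6-stage schedule is the desk-scale default). Everything is
validated on synthetic multi-shell phantoms (four shells,
b = 0/400/1000/2600 s/mm², 20/64/88/128 volumes, Rician noise, bias
fields, known warps and per-voxel ground truth).

## Worked example

```r
library(neomti)

spec   <- acquisition_spec()            # the default four-shell protocol
scheme <- default_scheme(spec, seed = 1)
scheme
#> gradient_scheme: 300 volumes, 4 shells
#>   b = 0/400/1000/2600 (n = 20/64/88/128)

truth <- phantom_truth(spec, age_weeks = 38)
dwi   <- render_phantom(truth, scheme, seed = 1)   # SNR 30 + bias field
dwi
#> phantom_dwi: 24 x 24 x 16 x 300 volumes, sigma = 0.0333

bv      <- scheme$shell_bvalues
tissues <- three_tissue_set(analytic_responses(0, bv)$iso,   # Iso (CSF)
                            analytic_responses(0, bv)$aniso, # Ay (young WM)
                            analytic_responses(1, bv)$aniso) # Ao (old WM)
fit  <- msmt_csd(dwi, scheme, tissues, truth$mask)
fit
#> msmt_fit: iso/ay/ao on 3552 voxels; 0 flagged

norm <- mt_normalise(fit$components, truth$mask)
norm
#> mt_normalisation: scale = 0.9986, field range [0.833, 1.11], 0 flagged
S <- Reduce(`+`, lapply(norm$components, \(x) dc_amplitude(x, "mean")))
mean(S[truth$mask]) * 4 * pi
#> [1] 1

shell_residuals(dwi, scheme, fit, truth$mask)
#> shell_residuals (% of mean b0): b0 = 2.68, b400 = 2.7, b1000 = 2.57, b2600 = 2.41

mix <- fit_response_mixture(analytic_responses(0, bv)$aniso,
                            analytic_responses(1, bv)$aniso,
                            analytic_responses(0.4, bv)$aniso)
tidy(mix)
#> # A tibble: 1 × 3
#>   alpha  beta residual_norm
#>   <dbl> <dbl>         <dbl>
#> 1 0.600 0.400      1.63e-15
```

Reading the numbers: the per-voxel deconvolution flags no failures; after
normalisation the in-mask mean summed density is exactly 1 and the
recovered field spans the rendered ±10% bias; per-shell residuals sit at
the 2–3% level expected at SNR 30; and a 40%-mature kernel decomposes into
the extremal kernels with weights (0.6, 0.4) and numerically zero
residual.

Registration, template building and ROI extraction follow the same
pattern; see `?register_nonlinear`, `?build_template`,
`?build_weekly_and_common` and `?roi_timecourses`, or the methods
vignette (`vignettes/multi-tissue-maturation.Rmd`). A command-line front
end (`exec/neomti`) exposes `phantom`, `response`, `decompose`,
`register`, `template` and `roi-stats` subcommands.

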