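# crackdic

Detection and quantification of surface micro-cracks from speckle image
pairs by subset-based digital image correlation (DIC), motivated by the
diagnosis of cracked tooth syndrome: incomplete fractures of the tooth
crown are sub-visible, yet under a masticatory-scale compressive load the
crack faces move apart by a few micrometres — enough to localize the
crack from full-field surface deformation and to measure its opening,
without contact or radiation. The package is aimed at researchers in
experimental mechanics and dental imaging who work with speckle-painted
surfaces imaged before and after loading (at roughly 20 µm/pixel in the
motivating setup), and at anyone who wants a fully synthetic,
ground-truth-controlled DIC test bench.

## Method

Given a reference image *T* and a deformed image *I* of a random speckle
texture, a square subset of *T* centred at each lattice point is matched
within a search region of *I* by maximizing the normalized
cross-correlation

```
C(x, y) = Σ T(x′, y′) I(x + x′, y + y′) / sqrt( Σ T² · Σ I² ),
```

with exhaustive integer search followed by subpixel refinement against
bilinearly interpolated grey levels (a Gaussian prefilter suppresses
interpolation peak-locking). The displacement components u (horizontal)
and v (vertical) are the matched offsets. Strains come from windowed
least-squares plane fits `u ≈ a₀ + a₁x + a₂y`, `v ≈ b₀ + b₁x + b₂y`:

```
εx = a₁,  εy = b₂,  γxy = a₂ + b₁,
ε1,2 = (εx + εy)/2 ± sqrt( ((εx − εy)/2)² + (γxy/2)² ).
```

The maximum principal strain ε₁ highlights the crack regardless of its
orientation; hysteresis thresholding (seed at a high threshold, grow
8-connected at a low one), morphological cleaning and topology-preserving
thinning reduce it to a one-pixel crack skeleton. Finally, crack
kinematics: around each skeleton point the two crack faces A and B are
fitted with rigid motions, the relative displacement is

```
δ = δ_B − δ_A,   δ_S = δ_S1 + (I₂ − R_S) s₁   (S = A, B),
```

and the crack opening displacement (COD) is the component of δ normal to
the local crack tangent, `δn = sin(αr) ‖δ‖`, with αr the inclination
angle between δ and the tangent estimated over a fitting window of
w = 7 grid points.

A synthetic-data module generates speckle textures (anti-aliased dark
dots on a bright background), warps them by analytic translation, affine
or piecewise-rigid crack fields with prescribed opening/slip/rotation,
and adds seeded sensor noise — so every stage is testable against exact
ground truth.

## Worked example

```r
library(crackdic)

# a 256x256 speckle pair with a vertical crack at x = 128 opened by
# 0.4 px (8 um at 20 um/px), 1% sensor noise
path <- cbind(128, seq(0, 255, 2))
spec <- deformation_spec("crack", path = path, opening = 0.4,
                         noise_sigma = 0.01, seed = 7)
pair <- simulate_speckle_pair(256, 256, spec, seed = 42)

cfg <- pipeline_config(subset_size = 39, search_size = 49, step = 4,
                       low_quantile = 0.75)
res <- run_pipeline(pair$reference, pair$deformed, cfg)
print(res)
#> <pipeline_result>
#>   grid 55 x 55, 2401 valid points, mean |d| 0.1662 px
#>   max eps_1 0.02311, main crack length 157.0 px
#>   COD: max 0.367 px (7.34 um), mean 0.361 px
print(res$cod)
#> <cod_profile> 39 skeleton point(s), 39 with COD estimate
#>   opening delta_n: max 0.367 px (7.34 um), mean 0.361 px; slip delta_t: max 0.144 px
```

The matcher sees each face of the 0.4 px crack as a ±0.2 px displacement
(`u in [-0.215, 0.195]` px across the field); the principal-strain ridge
is skeletonized into a 157 px crack path, and the opening profile along
it recovers the prescribed 0.4 px/8 µm opening as 0.37 px/7.3 µm —
within the subpixel accuracy of the matcher. `plot(res$strain)`,
`plot(res$skeleton)` and `plot(res$cod)` draw the strain map, the crack
path and the opening profile.

A command-line front end wrapping the same functions lives at
`inst/cli/crackdic.R`:

```sh
Rscript inst/cli/crackdic.R simulate --size 256 --opening 0.5 --out sim
Rscript inst/cli/crackdic.R run --reference sim/reference.png \
        --deformed sim/deformed.png --out results
Rscript inst/cli/crackdic.R self-test
```

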