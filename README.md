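# morphofrill

Morphoelastic finite-element simulation of ridge formation in the embryonic
neck frill of the frilled dragon (*Chlamydosaurus kingii*), and the
two-layer nanoindentation model used to estimate the skin-to-substrate
stiffness ratio that the simulations take as input.

## The scientific problem

Each lobe of the frilled dragon's erectile ruff always folds into three
convex ridges. The package simulates the hypothesis that this robust
pattern requires no molecular pre-pattern: it emerges as an **elastic
instability** when the frill's anterior skin grows homogeneously while
frustrated by its attachment to the neck (whose boundary grows far more
slowly) and by the much softer connective tissue beneath it.

The kinematics are morphoelastic: each tetrahedron's deformation gradient
factors as `A = F G`, with the growth tensor

```
G = Gs Gc,   Gs = gs I + (1 - gs) N N',   Gc = I + (gc - 1) C C'
```

(`N` = reference surface normal, `C` = crease direction), growth factors
attenuated with tissue depth by a generalized logistic, and a
nearly-incompressible neo-Hookean energy

```
W = mu/2 [Tr(F F') J^(-2/3) - 3] + K/2 (J - 1)^2,   K = (2+2nu)/(3-6nu) mu .
```

Equilibria are found by damped second-order dynamic relaxation of the
traction-assembled nodal forces (`s_i = -sigma n_i` per deformed face,
shared equally by its vertices). Morphometrics (ridge counts per sampling
band, middle-ridge amplitude, wrinkle wavelengths, realized surface growth)
quantify the converged states. The apparent indentation modulus of the
skin-on-substrate composite is modeled as
`E(d) = E_sub (E_skin/E_sub)^(1/(1 + A (d/T)^B))` and fitted across a
skin-thickness range.

Default parameters are the embryonic measurements: skin thickness
T = 47 um, T/L = 0.014, Poisson ratio 0.45, surface growth 1.3, crease
growth 2.2, and skin-to-substrate stiffness ratios of order 50-160.

## Worked example

```r
library(morphofrill)

# bilayer frill lobe (stiff skin on 100x softer substrate) grown by the
# measured factors g_s = 1.3, g_c = 2.2, then relaxed to equilibrium
res <- run_simulation("bilayer_ratio_sweep")
res$report
#> ridge report (prominence threshold 10%):
#>   ridges per lobe: 3 (bands: 2, 3, 3, 2, 3 )
#>   middle ridge amplitude: 0.1001 mm ( 2.98 % of L)
#>   mean wavelength: 2.019 +/- 1.3 mm
#>   realized linear surface growth: 1.278

# stiffness ratio recovered from a noisy synthetic indentation profile
fit <- fit_two_layer(
  make_indentation_profile(two_layer_params(11440, 220, 1, 1.5, 47),
                           noise_cv = 0.05, seed = 1),
  thickness_range = c(27, 72))
stiffness_ratio(fit)
#> $raw
#> [1] 54.71322
#> $rounded
#> [1] 55
```

The bilayer lobe reproduces the three convex ridges of the real frill at
the measured stiffness ratio; the realized linear surface growth of 1.278
for an applied growth of 1.3 quantifies the (small) elastic compression,
and the middle-ridge amplitude of ~3% of the neck-boundary length falls in
the range reported for the full-scale simulations. The fitted stiffness
ratio of ~55 recovers the generating value 52 from a 5%-noise profile.
Ridge counts are always reported with the per-band counts and the
prominence threshold that produced them.

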