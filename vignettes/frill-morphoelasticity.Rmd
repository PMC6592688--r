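---
title: "Morphoelastic ridge formation in the frilled-dragon neck frill"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Morphoelastic ridge formation in the frilled-dragon neck frill}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(morphofrill)
```

## The model

The erectile neck frill of the frilled dragon (*Chlamydosaurus kingii*)
develops, on each of its two lobes, a robust pattern of three convex ridges
during embryogenesis. `morphofrill` simulates the hypothesis that this
pattern needs no localized growth or molecular pre-pattern: it emerges as an
elastic instability when the frill's anterior skin sheet grows homogeneously
while being frustrated by (i) its attachment to the neck, whose boundary
grows much more slowly, and (ii) its adhesion to the much softer underlying
loose connective tissue.

The kinematics are morphoelastic: the deformation gradient of every
tetrahedral element factors multiplicatively,

$$A \;=\; F\,G,$$

where $G$ is a growth tensor (stress-free shape change of locally added
material) and $F$ the elastic accommodation that keeps the grown elements
compatible. Growth is anisotropic and built from two rank-one updates:

$$G = G_s G_c, \qquad
  G_s = g_s I + (1 - g_s)\,N N^T, \qquad
  G_c = I + (g_c - 1)\,C C^T,$$

with $N$ the reference surface normal (so $G_s$ expands by $g_s$ in the two
tangential directions) and $C$ the crease direction (so $G_c$ stretches the
sagittal crease strip by $g_c$). Local factors are attenuated with depth by
a generalized logistic,

$$g_i = 1 + \frac{g^{(i)} - 1}{1 + 0.25\,e^{-s\,(T - x_i)}},$$

where $T$ is the skin thickness, $x_i$ the distance of the element centroid
to the anterior surface (for $g_s$) or to the crease plane (for $g_c$), and
$s$ a sharpness constant. The tissue is neo-Hookean and nearly
incompressible,

$$W = \tfrac{\mu}{2}\left[\operatorname{Tr}(F F^T)\,J^{-2/3} - 3\right]
    + \tfrac{K}{2}(J - 1)^2,
  \qquad K = \alpha\mu,\ \ \alpha = \frac{2 + 2\nu}{3 - 6\nu},$$

with $\nu = 0.45$ for both skin and substrate. Equilibria are found with
damped second-order dynamic relaxation: the Cauchy stress
$\sigma = \mu J^{-5/3}\operatorname{dev}(F F^T) + K(J-1)I$ yields a traction
$s_i = -\sigma n_i$ on each deformed element face, distributed equally to
the three face vertices; for linear tetrahedra this equals exactly minus
the gradient of the total elastic energy (the test suite verifies both the
stress and the forces against finite differences).

## Measured inputs

The default parameters are the embryonic measurements for the
ridge-forming period: skin thickness $T = 47\,\mu m$, thickness-to-boundary
ratio $T/L = 0.014$, tangential surface growth $g_s \approx 1.3$, crease
growth $g_c \approx 2.2$, outer-edge growth $\approx 1$ (so no edge tensor
is applied), and a skin-to-substrate stiffness ratio of order
$50\text{--}160$ estimated by depth-dependent nanoindentation. The
developmental growth schedule interpolates these with a linear surface ramp
and a quadratic crease ramp fixed by its three anchors
$(\tau, g_c) = (0, 1), (1/3, 1.5), (1, 2.2)$, i.e.
$g_c(\tau) = 1 + 1.65\tau - 0.45\tau^2$; the surface ramp passes 1.1 at
$\tau = 1/3$, the growth observed a third of the way through the period.

## Design choices

Several aspects are not pinned down by the underlying measurements and are fixed here as
package conventions:

- **Geometry.** The real embryonic frill geometry is not available as a
  mesh; it is replaced by parametric stand-ins that preserve what the
  mechanics depends on: the ratio $T/L$, the curvature of the fixed inner
  boundary, the sagittal crease, and (for the bilayer) a substrate about
  two orders of magnitude softer. The lobe is an annular sector with a
  120 degree inner arc of length $L$ and radial extent $1.0\,L$; the crease
  lies in the $y$-$z$ plane. The substrate depth defaults to $10\,T$
  (graded element layers, finer near the interface). Meshes are structured
  hexahedral lattices split into 6 consistently oriented tetrahedra per
  cell.
- **Single-sheet growth.** For single-sheet runs the whole sheet is growing
  skin, so growth is uniform through the thickness ("uniform" mode); the
  logistic depth attenuation ("attenuated" mode) is used for the bilayer,
  where it confines tangential growth to the skin. The gel-analog runs use
  isotropic swelling $G = gI$. When the crease is declared to grow at the
  surface rate (single-sheet runs), the crease tensor is applied literally
  with $g_c = g_s$: the crease strip receives extra radial growth on top of
  its tangential growth. This is what the formulas state, and the extra
  material at the sagittal plane is what nucleates the crease-adjacent
  ridge; treating the crease as carrying no separate tensor delays the
  first ridge well past the growth at which embryos show it.
- **Units and sharpness.** Lengths are mm and stresses are normalized to
  the skin shear modulus ($\mu_{skin} = 1$). The logistic sharpness is
  interpreted as $100\,mm^{-1}$, giving a skin/substrate growth transition
  of width $\sim 10\,\mu m$ around depth $T$ for the measured thickness.
- **Constraints.** Fixed-boundary nodes are clamped. Crease nodes may move
  only along $C$ in single-sheet runs; in multi-layer runs they are
  confined to the sagittal plane. Film-on-substrate validation strips
  confine the two end faces to their planes so the film cannot shed its
  growth by elongating.

## The solver and its numerical choices

Relaxation uses $v \leftarrow v + (f - \gamma v)\,\Delta t/m$,
$x \leftarrow x + v\,\Delta t$ with node mass $m = a^3$ ($a$ = mean node
spacing). The pseudo-time step is $\Delta t = c\,a/\sqrt{K_{max}}$ — the
stable explicit scaling for nodal stiffness $\sim K a$ — with an automatic
halving-and-restart guard on inverted elements or non-finite energy.
Damping starts at $10\,m$ and is halved at the end of every convergence
window in which the elastic energy failed to drop by half, floored at
$0.1\,m$ (near-critical damping of the slow modes; a constant large
damping converges an order of magnitude slower).

Convergence requires the energy to change by less than `energy_rel_tol`
over `energy_window` iterations *and* the per-step displacement to fall
below `disp_tol * a` — and, additionally, the damping schedule to have
reached its floor. The last condition matters: while the system is
overdamped, a slowly growing unstable mode produces per-step displacements
below any reasonable tolerance and a flat (unstable) configuration can
masquerade as a steady state.

Because the flat grown state is an exact equilibrium of the discretized
problem, every run applies a seeded random normal perturbation of the
anterior surface (amplitude $10^{-3}\,T$ by default, zero on constrained
nodes) before stepping. Reported ridge counts are checked for stability
across perturbation seeds in the acceptance runs. Ridges that are marginal
at a given problem size (the bilayer's third ridge at the smallest standard
mesh, or any count read exactly at its onset growth) can depend on the
perturbation realization; the reproduction script therefore reports such
counts as the mode over three perturbation seeds, and reports the onset as
the growth at which a count first appears rather than the count at one
exact growth value.

## Resolution

Film-on-substrate wrinkling imposes a resolution requirement: linear
tetrahedra lock in bending when the in-plane spacing exceeds the sheet
thickness, which stiffens the sheet artificially, lengthens the selected
wavelength and eventually suppresses the instability. Package experiments
with the strip geometry show wrinkling is lost at in-plane spacing
$\sim 2T$ and the wavelength stabilizes for spacing $\lesssim T$. Because
the wrinkles of interest run along the frill's bands, meshes resolve the
along-band direction at about the sheet thickness while the inradial and
width directions are coarser; the skin always carries at least 2 element
layers through its thickness.

The problem sizes used by the test-suite and acceptance runs (tens of
thousands of tetrahedra, convergence windows of a few thousand iterations,
displacement tolerance $10^{-4}a$) are the package's standard desk-scale
configuration; they reproduce ridge counts and wavelengths but not
fine-amplitude details, for which the full configuration (spacing
$\sim T/2$ everywhere, window $10^5$, tolerance $10^{-6}a$) is exposed
through [solver_config()].

## What the synthetic data do and do not emulate

All inputs are generated in-package: parametric geometries, seeded
perturbations, fixture surfaces with known morphometrics (for validating
the ridge counting), and noisy two-layer indentation profiles (lognormal
multiplicative noise, CV 5% by default, matching the positive,
scale-spanning character of modulus estimates). The synthetic geometry does
not emulate the real frill's irregular outline, the posterior skin sheet,
fixation shrinkage of measured amplitudes, or HREM imaging noise — so
passing tests validate the mechanism (ridge counts, their transitions and
parameter trends, wavelength scaling) rather than exact amplitudes on real
embryos.

## Morphometrics conventions

Ridges are counted on 5 concentric bands (geodesic fractions 0.2-0.8 from
the fixed boundary): the normal surface displacement is smoothed over
$3a$, local maxima with topographic prominence of at least 10% of the band
range count as ridges, bands with range below $0.05\,T$ are flat, and the
per-lobe count is the modal band count (ties resolve toward mid-frill).
The threshold is reported with every count and counts are required to be
stable for thresholds 5-20%. The middle-ridge amplitude is peak-to-trough
(not peak-to-baseline), read from the raw profile at peaks located on the
smoothed one. Wavelengths are successive peak-to-peak arc distances in
reference coordinates; the quoted spread is the standard deviation across
band means.

## The two-layer indentation fit

The apparent modulus of an indented two-layer tissue mixes skin and
substrate as the depth grows:

$$E(d) = E_{sub}\left(\frac{E_{skin}}{E_{sub}}\right)^{\ell(d)},
 \qquad \ell(d) = \frac{1}{1 + A\,(d/T)^B}.$$

The fit runs in log-modulus space (balanced residuals across two decades),
multi-started over $(A, B) \in \{0.5, 1, 2\}^2$, and is repeated across a
skin-thickness grid (default 27-72 um) because $T$ is only known to a
range; reported parameters are means across that grid, and the quoted
uncertainty is their spread — a stated convention, not a claim about the
original error bars. Note $A$ and $T$ are not jointly identifiable (only
$A T^{-B}$ is), so $E_{skin}$, $E_{sub}$ and $B$ are stable across the
grid while $A$ rescales.

## What the desk-scale runs reproduce, and what they do not

With the standard problem sizes, the package reproduces: the onset of the
two-ridge state of the single-sheet lobe at growth close to the value at
which embryos show two ridges (g about 1.07-1.10); three ridges on the
bilayer lobe at the measured stiffness ratio of 100 with realized linear
surface growth about 1.28 for applied 1.3; pleating of the swollen
gel-analog sheet with wavelength increasing toward the free edge; and the
monotone trends of ridge count with growth and relative thickness.

Several published outcomes are *not* reached at these sizes, and the
corresponding acceptance tests are expected to fail rather than being
weakened:

- The single-sheet lobe saturates at two ridges up to the largest meshes
  exercised (along-arc spacing down to 1.6 sheet thicknesses, 58k
  tetrahedra); the reported third single-sheet ridge above g = 1.15 does
  not appear. Arc angle (120 vs 180 degrees) and lobe extent (0.7 vs 1.0 L)
  do not change this. Linear tetrahedra are over-stiff in bending at these
  spacings, which biases fold counts downward.
- On the bilayer stand-in, the inverse relation between ridge count and
  stiffness ratio holds only at its upper end: at ratio 20 the whole
  skin-plus-substrate slab, whose lower face is free in this parametric
  geometry, buckles into a single global fold instead of film wrinkles.
  For the same reason ridge counts are sensitive to the assumed substrate
  depth (a 15 T slab folds globally where a 5 T one wrinkles). The real
  frill's substrate is bounded by the posterior skin sheet, which the
  stand-in omits (its geometry is not quantified).
- On flat film-on-substrate strips the measured wrinkle wavelength is
  within ~10-15% of the analytic law (the law predicting slightly larger
  values, as in the original comparison), but a regular strip's
  band-to-band wavelength spread is small, so a "within two standard
  deviations" check passes at stiffness ratio 10 and fails at 50.

## Known limitations

- Strictly elastic: no viscous flow, contact, or self-avoidance of deep
  folds.
- Parametric geometry only; the posterior sheet bounding the substrate is
  not modeled (see above).
- Coarse meshes under-resolve bending; geometries resolve the along-band
  (wrinkle) direction at roughly the sheet thickness while the inradial
  direction is coarser.
- Amplitudes on real embryos include fixation shrinkage and are not
  reproduced quantitatively.

## A worked example

```{r example}
library(morphofrill)

res <- run_simulation("single_lobe", g = 1.2)
res$report

fit <- fit_two_layer(
  make_indentation_profile(two_layer_params(11440, 220, 1, 1.5, 47),
                           noise_cv = 0.05, seed = 1),
  thickness_range = c(27, 72))
stiffness_ratio(fit)
```
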