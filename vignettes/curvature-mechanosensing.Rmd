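---
title: "Curvature mechanosensing on ultrasoft hydrogels: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curvature mechanosensing on ultrasoft hydrogels: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(curvmech)
```

`curvmech` studies a deliberately minimal question: if a hydrogel is so soft
(~700 Pa) that stiffness-based mechanosensing is off the table, what does
surface *curvature* alone do to a cell's cytoskeleton? The package supplies
the three ingredients needed to ask that question quantitatively — substrate
geometry, a mechanical model of the stress-fiber architecture, and
image-level orientation statistics — plus synthetic generators that stand in
for the experimental surfaces, so the whole chain is testable end to end.
This vignette records the models, the tunable parameters, the numerical
choices, and the places where the design was genuinely open.

## 1. Geometry of substrates

Substrates are height fields $z(x,y)$ on regular grids (μm everywhere).
Curvature comes from the first and second fundamental forms via the shape
operator; per-node output is $\kappa_1 \le \kappa_2$, principal direction,
$H = (\kappa_1+\kappa_2)/2$, $K_G = \kappa_1\kappa_2$, and an area weight
$dx\,dy\sqrt{1+|\nabla z|^2}$. The sign convention is fixed package-wide:
**convex toward the cell side is positive** (ridge tops $+$, troughs $-$;
convex-outward for microgel meshes). Derivatives are second-order central
differences; the boundary ring has no full stencil and is flagged invalid
rather than estimated one-sided, which would bias areal statistics.

Normal sections — the vertical cutting plane rotated by azimuth $\theta$
around the surface normal — are the geometric substrate of the energy
model. Three numerical choices matter:

* **Interpolation is bicubic (Catmull–Rom), not bilinear.** Bilinear
  profiles are piecewise linear, so second differences at sub-grid steps
  alias toward zero (we measured a −14% curvature bias on a
  $\lambda = 80$ μm sinusoid sampled at 0.5 μm). Catmull–Rom reproduces
  quadratic patches exactly, making the section-versus-pointwise Euler
  relation check exact to discretization.
* **Profile derivatives use a one-grid-cell stride.** Central differences
  whose physical half-width equals the grid spacing cancel the remaining
  interpolation bias; a 3-sample moving average then suppresses sub-cell
  ripple.
* **Signed profile curvature** is $\kappa(s) = -z''/(1+z'^2)^{3/2}$, so
  ridge tops are positive, matching the surface convention.

Microgel meshes get per-vertex curvature from a local quadric fit in the
tangent frame (neighbours within 2.6 mean edge lengths; at least 6
required, otherwise the vertex is flagged invalid). Quadric fitting was
chosen over discrete-Laplacian estimators because the classification and
morphometry stages need principal *directions*, not just $H$. On an
icosphere the estimator recovers $H = 2/d$ to well under 1% at subdivision
4; accuracy degrades if the fit radius grows (quadric truncation), which is
why the multiplier is committed at 2.6.

## 2. The two-layer stress-fiber model

Stress fibers are idealized as Euler–Bernoulli beams with an active
contractile force $F_{a0}$, anchored at both ends by focal adhesions. Two
populations are modelled separately.

**Basal fibers** conform to the substrate section of contour length
$L_f$:

$$U^b_{\text{total}} = \underbrace{\tfrac{B^b_f}{2}\!\int\!\kappa(s)^2\,ds}_{\text{bending}}
 + \underbrace{F_{a0}\,(\text{contour}-\text{chord})}_{\text{active}}
 + \underbrace{-\,N_{FA}\,\varepsilon_{FA}}_{\text{adhesion}},$$

with the adhesion count driven by the pressing load
$P = F_{a0}\int\kappa(s)\,ds$: convex sections press the fiber onto the gel
and recruit units, $N_{FA} = \max(N^b_0 + P/f_c,\,0)$; concave sections
peel it, floored at zero. **Apical fibers** form an actin cap spanning $W$
between adhesions and arching over the nucleus (height $h_N$) as a
parabolic arc of deflection $\delta = \max(h_N + g(\theta), 0)$, where the
sagitta $g$ is read from the substrate profile
($g = z(\text{centre}) - \overline{z(\text{ends})}$):

$$U^a_{\text{total}} = \frac{32 B^a_f \delta^2}{W^3}
 + F_{a0}\frac{8\delta^2}{3W} - N^a_0\varepsilon_{FA}
 + \frac{(N^a_f F_v)^2}{2 k_{nuc}},
 \qquad F_v = \frac{8 F_{a0}\delta}{W}.$$

These are the minimal closed forms consistent with the qualitative
structure the model must reproduce: each is one documented function behind
the `basal_energy()` / `apical_energy()` interface so alternative
functionals can be swapped. The nuclear term is quadratic (an effective
compression spring); nuclear indentation does not feed back into $\delta$
(with defaults the indentation is ≈ 0.04 μm ≪ δ — a documented one-way
coupling). Fibers follow planar normal sections, not geodesics, matching
the cutting-plane construction of the landscape.

### Parameters, units, defaults

All lengths μm, forces pN, energies pN·μm (= 10⁻¹⁸ J).

| parameter | meaning | default |
|---|---|---|
| $B^b_f$, $B^a_f$ | fiber bending rigidity (basal / apical cap) | 2, 20 pN·μm² |
| $L_f$, $W$ | basal contour length / apical span | 20, 30 μm |
| $F_{a0}$ | active force per fiber | 10 pN |
| $N^a_f$, $N^b_f$ | fiber counts | 10, 5.5 |
| $h_N$, $k_{nuc}$ | nucleus height / compression stiffness | 5 μm, 5000 pN/μm |
| $\varepsilon_{FA}$ | adhesion unit binding energy (≈ 25 k_BT) | 0.1 pN·μm |
| $N^b_0$, $N^a_0$, $f_c$ | baseline adhesion units / recruitment force | 10, 10, 0.05 pN |

$F_{a0} = 10$ pN and $N^a_f = 10$ are the two printed model values; the
apical cap is stiffer than single basal fibers (thick perinuclear bundles);
$N^b_f = 5.5$ sets the control basal population fraction to 0.355, the
printed control value. The defaults must satisfy two calibration
inequalities, checked at construction and in tests:

* **C1 (basal decrease)** $\varepsilon_{FA}/f_c > \kappa_{max}(L_f^2/12 +
  B^b_f/F_{a0})$ with $\kappa_{max} = 0.04$ μm⁻¹ — adhesion recruitment
  outpaces bending + contraction penalties, so $U^b_{\text{total}}$ falls
  monotonically with curvature and basal fibers favour the
  maximal-curvature direction.
* **C2 (apical adhesion dominance at zero curvature)**
  $N^a_0\varepsilon_{FA} > 32 B^a_f h_N^2/W^3$ — on flat gel the adhesion
  term dominates; with curvature the deflection grows and bending takes
  over at $\kappa^* = \big(\sqrt{N^a_0\varepsilon_{FA}W^3/32B^a_f} -
  h_N\big)\,8/W^2 \approx 0.013$ μm⁻¹ for the defaults, which is why apical
  fibers seek the minimal-curvature direction.

Orientation landscapes evaluate both layers on sections at
$\theta = 0, \ldots, 180°-\Delta\theta$; minima are located under
180°-periodicity and filtered by topographic prominence (10% of the
landscape relief, floor $10^{-3}$ pN·μm) so grid-sampling ripple does not
spawn spurious orientations; a relief below $10^{-3}$ pN·μm flags the
layer degenerate (flat gel). Nuclear-energy curves use the osculating
paraboloid sagitta $g = KW^2/8$ for an isotropic cap of curvature $K$.

Cytoskeletal drugs are committed parameter maps (YAML in
`inst/extdata/presets.yaml`): CN03 doubles $F_{a0}$ and moves the basal
fraction to 0.68; Y-27632 ablates the apical cap and halves $F_{a0}$;
blebbistatin scales $F_{a0}$ by 0.1; latrunculin B scales both fiber counts
by 0.05. These reproduce the observed directions: less nuclear strain
energy under actin/myosin disruption, lower CPI under Rho activation.

## 3. Synthetic topographies

The generators emulate the *morphology* produced by solvent-induced
buckling, not the buckling mechanics (no swelling model is attempted —
downstream analyses only consume geometry). All generators are pure
functions of (spec, seed).

* **Wrinkle fields**: seeded white noise filtered on an annular Gaussian
  band at $k_c = 2\pi/\lambda_c$ (relative width = `bandwidth`), with a von
  Mises directional weight $\exp[\kappa_{vm}(\cos 2(\phi-\phi_0)-1)]$,
  $\kappa_{vm} = (2a/(1-a))^2$ mapping anisotropy $a \in [0,1]$; $a = 1$
  keeps only the modes perpendicular to the groove direction. The field is
  rescaled to peak-to-trough $2A$.
* **Grooves**: $z = A\cos(2\pi y/\lambda)$ (axis along $x$, so θ = 0° is
  the axial direction), ridge-top $K_\perp = A(2\pi/\lambda)^2$; presets
  commit $K_\perp = 0.011$ and $0.018$ μm⁻¹ at $\lambda = 60$ μm.
* **Multiaxial test surface**: superposed oblique cosine waves, phases
  chosen so all waves crest at the evaluation point. The committed
  `constructed-multiaxial` preset uses three equal waves at 0/60/120°,
  $\lambda = 40$ μm — *below* the fiber spans on purpose: at the crest the
  pointwise normal curvature is isotropic (the three $\cos^2$ terms sum to
  a constant), so the multiple, non-orthogonal landscape minima arise from
  finite-fiber-length sampling of the surrounding terrain, the regime of
  interest. Grid spacing 0.5 μm keeps estimator ripple below the landscape
  relief.
* **Microgels**: icospheres with a seeded radial perturbation from a
  spherical-harmonic degree band, rescaled to a maximum displacement;
  subdivision is committed per preset (4 for the 97.2 μm microgel, 5 for
  203.8/532.4 μm) so the band is resolved by the mesh.
* **Synthetic cells**: per-layer fiber orientations drawn from Boltzmann
  weights $p(\theta) \propto \exp[-(U(\theta)-U_{min})/U_{scale}]$ on the
  1° landscape grid. $U_{scale}$ (default 1 pN·μm, the order of the basal
  landscape relief) is a disorder knob, not a physical temperature. Fiber
  midpoints scatter anisotropically: the s.d. *along* a fiber's own axis
  grows with its layer's population share. This is the footprint model
  that lets the Curvature Polarization Index respond to population shifts —
  maximal projection extents are insensitive to fiber counts, so a cell
  must physically extend along the dominant layer's axis, as spread cells
  do. Rendering uses Gaussian line-spread segments (σ = 0.5 px), adequate
  for structure-tensor closure tests.

### Preset calibration and what it does not show

The `C100`/`C70` presets (pure-ethanol and 70%-ethanol treatments) were
calibrated once against the printed substrate statistics and committed to
`inst/extdata/presets.yaml`. A band-limited Gaussian random field cannot
match depth (155 μm), width (85.9 μm) *and* mean curvature (0.019 μm⁻¹)
simultaneously — real wrinkles are cusped, decoupling width from
wavelength, while a smooth spectral field ties them together. We match the
mean |H| statistic (the quantity the classification and acceptance sweep
consume) and the peak-to-trough depth exactly ($2A$), and accept ~50 μm
widths for C100 instead of 85.9 μm. Passing tests therefore demonstrate
that the analysis chain reproduces the *curvature statistics and their
ordering* across conditions, not that the generator is a faithful sample
of SICE morphology; sharp-crease geometry, long-range correlations, and
imaging noise of real substrates are all absent. Groove "width" is
measured at half depth (the definition is not fixed by the source
measurements; ours is committed and used consistently). The reported mean
curvature is the area-weighted mean of $|H|$ — a signed mean would be
near zero on wrinkles; the dominant-principal-curvature variant is
available as a switchable statistic.

Classification thresholds default to $\tau_{flat} = 0.003$ μm⁻¹ (an order
below the observed curvature scale) and $\kappa_{split} = 0.0145$ μm⁻¹
(midpoint of the two groove exemplars); they are declared defaults, not
measured constants, and the headline areal proportions are taken over
convex (cell-adhesive) regions, with the full breakdown also emitted.

## 4. Orientation analysis

The structure tensor uses Scharr 3×3 gradients (plain central differences
carry a ~1.3° direction-dependent bias on fine textures; the committed
criterion is ≤ 1° on stripes) after Gaussian pre-smoothing
($\sigma_g$, default 1 px), with tensor averaging at $\sigma_w \ge
\sigma_g$ (default 4 px). Coherence is $(\lambda_{max}-\lambda_{min}) /
(\lambda_{max}+\lambda_{min})$; pixels under a coherence floor (0.05) are
masked. Histograms over [0°, 180°) are coherence-and-intensity-weighted for
fields and length-weighted for segments (count and coherence weightings are
also available — the appropriate polar-diagram weighting is not uniquely
determined, so all are emitted). The circumferential alignment band is
±15° by default and configurable. CPI uses maximal projected extents
(Feret-style) onto the fixed axial/circumferential axes; swapping the axes
maps CPI to 1/CPI exactly.

## 5. Numerical sizes and determinism

Committed problem sizes keep the full suite under a minute on one core:
161×161 grids at 1 μm for groove presets, 160×160 at 4 μm for wrinkle
presets, 321×321 at 0.5 μm for the multiaxial preset, 128×128 at 3 μm for
the nine-surface acceptance sweep, icospheres at subdivision 3–5, and
200-fiber synthetic cells at 0.5 μm/px. Landscape scans use 1–2° steps; a
0.1° rescan changes argmins by < 1°. All stochastic stages route their
randomness through a seed saved in specs and manifests; `run_pipeline()`
reruns are byte-identical, and every run directory carries a manifest with
package version, full configuration, and md5 hashes of its artifacts.

## 6. Known limitations

* The energy functionals are minimal constructions behind stable
  interfaces; absolute energy scales are not calibrated against
  experiments (only printed model inputs such as $F_{a0}$ and $N^a_f$ are
  used), so only orderings, monotonicities and minima locations are
  scientifically load-bearing.
* Basal fibers are assumed to conform to the substrate rather than bridge
  chords; on deeply concave sections conformity plus the adhesion floor is
  a coarse treatment of detachment.
* Mesh landscapes are not implemented — energy landscapes operate on
  height fields, matching the cutting-plane construction; microgels get
  curvature statistics only.
* No segmentation of real confocal data: the orientation tools accept any
  grayscale matrix, but validation is entirely against synthetic
  renderings.
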