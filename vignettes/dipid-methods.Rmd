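---
title: "Models and methods behind dipidr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind dipidr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dipidr)
```

dipidr models membranes self-assembled from "Dipids": radially symmetric
DNA origami barrels whose flexible, weak, isotropic binding strands make
them behave like lipids. A single monomer type, programmed with a cone
angle, assembles into planar membranes, tubes, or closed containers whose
diameter is set by that angle. This vignette documents the models, the
parameters that matter, the numerical choices, and what the synthetic-data
tests do and do not demonstrate.

## From curvature to sequences

Each 30-nm-class monomer (barrel diameter $w = 28.5$ nm, height $h = 18$
nm) carries 30 binding strands arranged in six groups of two and six
groups of three. A strand is, 5' to 3', an oligo-dT *curvature* domain
($n$T, 0–52 nt), an oligo-dT *flex* domain ($m$T $\in \{2,4,8,16\}$ nt)
and a weak palindromic *sticky* domain ($x$N $\in \{4,6,8\}$ nt). The
physical strand length uses the worm-like-chain RMS end-to-end distance
for the single-stranded part (rise 0.63 nm/nt, persistence length
$L_p = 1.5$ nm) plus half the contour of the hybridized sticky duplex
(0.34 nm/bp), shared between the two bound strands:

$$ l_\mathrm{strand} = \sqrt{2L_p^2\left(\frac{L_c}{L_p} - 1 +
   e^{-L_c/L_p}\right)} + \tfrac12 L_c(\mathrm{dsDNA}). $$

**Cone model.** The monomer plus its half-gaps is treated as an annular
wedge of radial extent $h$. With per-face gaps $g = 2\,l_\mathrm{strand}$
(each bound neighbour contributes one strand), the wedge angle is
$\alpha = 2\,\mathrm{atan}\!\big((g_\mathrm{out}-g_\mathrm{in})/(2h)\big)$
and the mid-height assembly radius is $r = s_\mathrm{mid}/\alpha$ with
$s_\mathrm{mid} = w + (g_\mathrm{in}+g_\mathrm{out})/2$. This trapezoid
construction is the package's normative choice; its exact inverse
(`invertDiameterToAngle`) converts measured minor diameters back to
experimental cone angles, so angle errors are reproducible from the same
geometry.

**Strand layout.** The curvature domain is applied to a fixed subset of
24 of the 30 strands — both strands of each pair and two of three in each
triple — and these 24 are the outer-face strands; the 6 remaining
inner-face strands carry no curvature domain. That makes the cone
asymmetry one-sided and means converting one variant class into another
exchanges exactly 24 strands, the property the class system is designed
around. The authors' exact subset is not published; this one is the
package's documented convention.

**Variant classes.** The experimentally characterized classes are known
by their measured diameters; the designed (naive) targets behind them are
not published. dipidr therefore fixes the class definitions itself: XS and S use naive
targets equal to the measured means they reproduced (119 and 166 nm); M,
L, XL and XXL use package-chosen naive targets of 250, 350, 500 and 700
nm, which the two-regime calibration then maps onto the larger measured
sizes. The 60-nm classes reuse the layout on the 57-nm barrel with flex
8T (M60, L60) and 16T (XL60, XXL60); their binding-strand count is not
printed and defaults to the 30-nm layout (flagged as an assumption).
Curvature-domain lengths are solved by exhaustive search over integer
$n$T with ties broken toward the smaller (cheaper) extension.

**Calibration.** `fitCalibration` fits a continuous two-regime
piecewise-linear map from naive to measured diameters, scanning candidate
breakpoints on a 10-nm grid and solving each candidate by least squares
with a hinge basis. The fits are deliberately heuristic — separate curves
for containers and tubes — because the deviation from the naive model
grows roughly linearly but with geometry-specific scaling.

## Bead-spring growth simulation

The simulator follows the capsid-assembly bead-spring model class:
vertices of a triangulated mesh are monomer centres (rest spacing
$l_0 = w + g_\mathrm{mid} = 37.7$ nm for the 30-nm class), edges are
harmonic springs, and adjacent triangles pay a bending penalty

$$ E = \sum_\mathrm{edges} \tfrac12 k_s (l-l_0)^2 +
   \sum_\mathrm{hinges} k_b\,(1 - \cos(\theta - \theta_0)), $$

with the preferred dihedral $\theta_0$ set equal to the simulated cone
angle $\alpha_\mathrm{sim}$ (adjacent subunits meet at the cone angle).
Exact moduli are not published for the adapted model; the default
stiffness ratio is $k_s l_0^2 / k_b = 10$, overridable in
`elasticParams`. A relaxed closed shell then sits near
$R \approx l_0 / (2\sqrt3 \sin(\theta_0/2))$, which the test suite checks
within 15%.

**Growth rules.** Growth starts from a single triangle and adds one
triangle per step at the rim:

* *Bond completion.* Rim wedges with opening angle $\beta$ below 70°
  close unconditionally — the two rim edges are then within binding range
  (chord $\lesssim 1.15\,l_0$). These closures complete hexamers.
* *Pentamer closure.* A rim vertex already carrying four triangles closes
  below the pentagon corner angle of 108°, creating a 5-fold
  disclination. A single lower threshold cannot create disclinations at
  all: a 4-triangle wedge on a smooth cap subtends at least
  $\approx 108°$, so the pentagon angle is the geometrically meaningful
  eligibility bound. Wedges are closed smallest-first.
* *Placement.* Otherwise a new monomer is added on the rim edge where it
  forms the most bonds (existing rim vertices within $1.35\,l_0$ of the
  relaxed trial position), with local elastic energy as tie-break
  weighted by a per-bond binding energy ($0.05\,k_s l_0^2$ by default).
  Purely elastic scoring is degenerate on a growth front — every site
  relaxes to nearly zero added energy — and produces unphysical fingered
  growth; maximal-bond placement is the compact-growth rule of the model
  class. With probability `pRandom` (default 5%) the monomer is placed on
  a uniformly random rim edge instead, which reproduces polymorphism at
  fixed cone angle.

**Relaxation.** Gradient descent with backtracking line search and
analytic hinge gradients (validated against finite differences in the
tests). After each addition the neighbourhood of the change (graph
distance 2) is relaxed for up to 60 iterations; a full-mesh sweep of 150
iterations runs every 10 additions and a final full relaxation of up to
3000 iterations (tolerance $10^{-6}$) ends each run. This schedule is
the package's accuracy/throughput compromise for sweeps of hundreds of
runs; single runs can be re-relaxed to arbitrary tolerance with
`relaxMesh` (iteration cap 5000 by default).

**Morphology.** A run ends at closure (rim shrunk to a triangle) or at
the monomer budget. Principal extents come from the eigenvectors of the
vertex covariance tensor (extents are projection ranges, so a cylinder of
length $3d$ reports $a \approx 3$ exactly). Classification: closed with
$a \le 1.6$ is a *spheroid*; closed and elongated, or open with
$a > 1.6$ (rolled cylinders), is a *tube*; anything else is *open*. The
1.6 threshold is a configurable choice. The RNG is a counter-based
splitmix64 generator inside the compiled core, so identical seeds give
bitwise identical trajectories.

**Desk-scale sweeps.** `sweepAlpha` runs seeded replicates per cone angle
and `transitionAngle` reports the smallest angle at which closed
spheroids appear. At the default budget of 300 monomers, closure is
geometrically possible only for $\alpha \gtrsim 7.3°$ (a closed shell of
$N$ monomers needs $N \approx 4.84/\alpha_\mathrm{rad}^2$), so the
desk-scale transition is budget-limited rather than dynamics-limited;
the dynamical onset of pentamer formation — the full-scale mechanism
separating tubes from containers — sits near 5.5–6° in this
implementation. Both numbers are visible in the sweep output: below
$\approx 5.5°$ no disclinations form at all and growth stays sheet- or
tube-like; between 6 and 7.3° shells curve and facet but cannot close
within budget.

## Morphometry of collapsed containers

Containers flatten on the grid; flattening preserves circumference, so
the collapsed width along each axis is half the corresponding 3D
circumference. `segmentContainers` runs normalized cross-correlation
against a soft-edged monomer-sized dark-disc template (threshold 0.5),
closes over the monomer lattice spacing, fills holes and labels
components; border-touching regions are flagged and excluded from
statistics. For each region the outline is refined at the stain step
(Otsu threshold) and fitted with the numerically stable direct
least-squares (Fitzgibbon) ellipse method on the marching contour (pixel
centres at half-integer coordinates). Then

$$ d_\mathrm{minor} = \frac{4\,r_\mathrm{minor,2D}}{\pi}, \qquad
   P\!\left(\frac{d_\mathrm{major}}{2}, \frac{d_\mathrm{minor}}{2}\right)
   = 4\,r_\mathrm{major,2D}, $$

where $P$ is Ramanujan's perimeter approximation (accurate to well below
0.1% for $a \le 4$, verified against quadrature); the major diameter is
found by bracketed root finding on $[d_\mathrm{minor},\, 8
r_\mathrm{major,2D}/3.9]$ to $10^{-6}$ relative tolerance, assuming equal
minor diameters (prolate spheroid). Widths inconsistent with that model
($r_\mathrm{major,2D} < r_\mathrm{minor,2D}$) are flagged and clamped.
The same circumference rule gives tube diameters $d = 2w_\mathrm{2D}/\pi$
from flattened widths. Size distributions are reported as mean ± SD plus
a Gaussian KDE with Silverman's bandwidth. Monomer counts and container
masses come from the prolate-spheroid surface area divided by the
hexagonal packing footprint $(\sqrt3/2)\,s_\mathrm{mid}^2$, at a default
monomer mass of 2873 bp × 650 Da.

## Pore analysis

Monomer centres (from simulation output, synthetic shells, or template
matching upstream) become hard discs of the barrel radius (14.25 nm;
electrostatic screening can be represented by an optional radius
inflation, default 0 assuming high salt). Neighbours are centres within
1.35 barrel diameters. A junction pore is the largest inscribed circle:
cycle members are projected onto their best-fit plane and the minimal
distance to any disc edge is maximized by Nelder-Mead from the cycle
centroid ($10^{-4}$ nm scale tolerance). Closed forms fix the geometry:
three touching discs give $2R(2/\sqrt3 - 1) \approx 4.41$ nm and a
regular five-ring of side $2R$ gives $2R(1/\sin 36° - 1) \approx 20.0$
nm at $R = 14.25$ nm. At the default lattice spacing of 37.7 nm the
trimeric pore evaluates to 15.0 nm. The census enumerates 3-cycles
(trimeric), rings around 5-coordinated disclinations (pentagonal;
measured with the central monomer excluded, emulating the open-pentagon
binding geometry seen at deformed disclinations) and chordless 4–9-rings
that enclose no monomer (vacancy holes); pores above 30 nm are
re-labelled missing-monomer defects.

## Synthetic data: what it shows and what it does not

The generators are pure functions of their arguments including the seed.
Collapsed-container micrographs use the same forward collapse model the
morphometry inverts, render the packed-barrel texture as a hexagonal
carpet of monomer discs at the 37.7-nm lattice spacing, a darker rim
(negative-stain polarity, one barrel-height thick) on a bright
background, Gaussian blur and additive noise; placements enforce a
minimum separation (no overlaps), and impossible packings raise an
error. Shell layouts are icosadeltahedral spheres — general $(h,k)$
classes with $10T+2$ sites and exactly 12 disclinations — rolled
hexagonal-lattice tubes, and planar sheets, with optional vacancies.
Membrane images draw a smooth curve with A/B/AB domain arcs, dye signals
(488 for B, 565 for A), channel gains, bleed-through and noise.

Passing the recovery benchmarks therefore shows that the measurement
chain inverts its own forward model without bias under realistic noise,
texture and discretization — it does not show robustness to the things
real TEM adds (CTF, uneven stain, aggregates, focus gradients), which
are explicitly out of scope. Recovery at the stated tolerances needs the
monomer texture resolved at roughly 3 pixels per barrel radius or
better; the benchmark images use 3–5 nm/px accordingly.

## Problem sizes used in the checks

The test suite uses desk-scale versions of every experiment: WLC
Monte-Carlo cross-checks with 2000 discrete chains at three contour
lengths; exhaustive monotonicity over all 636 menu combinations;
six-class morphometry with 4–6 containers per class; growth runs capped
at 300 monomers with ~10 seeds per condition; and an alpha sweep over
4–12° in 0.3° steps with 10 seeds per angle for the morphology
transition. These sizes were chosen as the smallest that exercise each
claim with meaningful statistics.

## Known limitations

* The naive cone model ignores strand-length fluctuations and the
  short-strand breakdown of the WLC approximation — the reason the
  experimental calibration exists.
* The growth simulator has no thermal dynamics, no disassembly, and no
  explicit DNA; it cannot produce the amorphous packing of the smallest
  containers, and at small cone angles it grows open spirals rather than
  the closed tubes found experimentally.
* The 300-monomer default budget caps the shells that can close; the
  reported desk-scale transition angle is therefore an upper bound on
  the dynamical one.
* Pentagonal pore sizes around occupied disclinations are estimates with
  the central monomer removed, not measurements of a physical void.
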