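---
title: "From endoscopic OCT pullbacks to airflow-based obstruction localization"
author: "airwayflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From endoscopic OCT pullbacks to airflow-based obstruction localization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(airwayflow)
```

# The problem and the pipeline

Obstructive sleep apnea (OSA) is treated far more effectively when the
anatomical site of airway collapse is known. Endoscopic optical coherence
tomography (OCT) offers a quantitative route: a rotating fiber-optic
catheter inside a transparent sheath is pulled back through the upper
airway, producing a stack of 360° cross-sectional images (B-scans) of the
lumen, once while the patient is awake and once during natural sleep. From
these stacks one can reconstruct the three-dimensional airway, compare the
awake and asleep lumen, simulate the respiratory airflow through both, and
rank candidate obstruction sites by how sharply the cross-section-averaged
pressure bends along the airway axis.

`airwayflow` implements this entire computational chain at desk scale, with
a synthetic airway phantom standing in for patient data (no raw clinical
stacks are publicly deposited). The stages are:

1. **phantom** — analytic awake/asleep airway geometries, rendered polar
   B-scan stacks, electromagnetic-tracker coordinates, and exact ground
   truth for every downstream stage;
2. **imaging** — polar↔Cartesian conversion, sheath-artifact masking,
   rotational frame alignment;
3. **segmentation** — automated lumen-wall detection producing closed
   per-frame contours with per-sector validity flags;
4. **reconstruction** — tracker-path smoothing, rotation-minimizing frames,
   lofting of the contours into a watertight surface, per-station areas and
   awake/asleep regional comparison;
5. **flow_lbm** — a D3Q19 lattice-Boltzmann solver (SRT and MRT collision
   operators) driven at a stated flow rate;
6. **obstruction** — station pressures, axial pressure derivatives, and the
   ranked obstruction sites.

`runPipeline()` chains everything from one seed and one configuration list.

# The synthetic phantom: what it emulates and what it does not

The phantom mimics the acquisition protocol: 25 B-scans/s with 2000 A-lines
per rotation, 12.5 mm/s pullback (hence exactly 0.5 mm between B-scans),
12.8 mm radial imaging range, and a 10 µm axial point-spread function. The
airway is a tube of circular cross-section along a gently curved 3D
centerline spanning 150 mm of arc length, with a 6 mm baseline lumen
radius in the pharyngeal segments. Five named arc-length windows stand in
for the anatomical regions (nasopharynx 10–38 mm, velopharynx 44–68 mm,
base of tongue 74–100 mm, epiglottis 110–126 mm, hypopharynx 132–146 mm).
In the asleep state the cross-sectional **area** is scaled by 0.92, 0.44
and 0.68 in the nasopharynx, base-of-tongue and epiglottis windows
(8%, 56% and 32% area loss; radius scales by the square root), with
half-cosine ramps of width 4 mm placed immediately *outside* the window
edges so that within-window area means equal the nominal factors exactly.
This makes the constriction factors themselves the oracle for the
end-to-end area-comparison test.

Per A-line, the rendered signal is a Gaussian wall echo at the
catheter-to-wall distance (the catheter meanders up to 0.5 mm off the
lumen axis), a tissue tail decaying over ~1.2 mm beyond the wall, both
multiplied by axially correlated Rayleigh speckle of unit mean, plus a
rectified-Gaussian noise floor and a bright specular ring at the 0.9 mm
sheath radius. Lumen ranging uses refractive index 1 (air); the tissue
index affects only the axial resolution quoted for tissue, not the
distance to the wall. A-lines whose wall lies beyond 12.8 mm carry no echo
and are flagged truth-missing.

What the phantom deliberately does **not** emulate: irregular (non-convex,
non-circular) real lumen shapes, swallowing or breathing motion between
frames, non-uniform rotational distortion, catheter whip, mucus and
specular highlights on tissue, or genuinely unknown anatomy. Passing the
packaged tests therefore demonstrates that the *computational chain* is
correct and self-consistent under realistic noise, eccentricity and
range-clipping — not that the segmentation would handle every clinical
image.

Circular sections were chosen because they give closed-form areas and
volumes for testing; an elliptical or lobed section generator would
exercise the same code paths but without exact oracles.

# Segmentation choices

The wall detector returns the depth of the first run of at least `m = 5`
consecutive samples exceeding `noise median + 4·MAD` beyond a 1.3 mm
exclusion zone (past the sheath ring). First-crossing rather than
peak-maximum detection is used because the lumen boundary is the *near
edge* of the wall echo; a peak detector would bias outward by half the
echo width. The noise floor is estimated robustly (median and MAD over the
whole A-line beyond the exclusion zone) so that a wall sitting near the
end of the imaging range does not contaminate the estimate.

Contours smooth the radius signature with a periodic 9-A-line moving
average applied to valid runs only. Frames with more than 50% of sectors
missing are flagged unusable, mirroring the original workflow's image-set
triage; the threshold is configurable because the source protocol states
only qualitative criteria. Missing sectors are filled by linear
interpolation *in frame index* from the nearest valid same-angle
neighbors within ±10 frames, falling back to angular interpolation within
the frame; filled vertices stay flagged so that every area report carries
the fraction of extrapolated boundary.

# Reconstruction choices

The tracked catheter path is smoothed per coordinate by a cross-validated
smoothing spline against arc length and resampled at the 0.5 mm frame
spacing. Frames along the path are **rotation-minimizing** (double
reflection), not Frenet: Frenet frames twist uncontrollably wherever the
curvature is small, while the double-reflection transport keeps spurious
twist below 1° per 100 mm on planar curves (verified by test). Contours
are placed rigidly in the normal plane at their station, roll-registered
to the previous ring by the cyclic vertex shift minimizing the summed
vertex distance (computed by FFT cross-correlation), stitched with
triangle strips and capped, giving a watertight, outward-oriented mesh.
Rigid placement preserves each contour's area exactly, so per-station
areas are measured on the 2D contours — matching how per-B-scan areas are
measured in practice — rather than by slicing the mesh. Whether areas
should instead be measured perpendicular to the anatomical centerline is
an open representational question; the catheter-plane convention is used
and stated.

The default trim removes 5 mm from each end of the loft (the "excess"
ends; the source workflow trims without quantifying).

# The lattice-Boltzmann solver

The solver is a standard D3Q19 lattice-Boltzmann method: second-order
Maxwellian equilibrium, BGK (single-relaxation-time, SRT) and
multi-relaxation-time (MRT) collisions, halfway bounce-back walls, a
non-equilibrium bounce-back (Zou–He-type) velocity inlet with a plug
profile ramped over the first ~1000 steps, a fixed-density outlet, and
optional Guo forcing for body-force-driven validation cases. The MRT
moment basis is the standard orthogonal polynomial set; equilibrium
moments are obtained by transforming the equilibrium distribution, which
makes equal-rate MRT reduce to SRT *exactly* (a packaged test holds this
to 1e-12 per collision). Default MRT rates: 0 for conserved moments,
`1/tau` for the five shear moments, 1.2 for the rest.

**Unit bookkeeping** is the classic LBM pitfall, so every run records it:
lattice spacing `dx` (mm), time step `dt` (s), relaxation time `tau`,
lattice viscosity, the velocity scale (m/s per lattice unit), the pressure
scale (Pa per lattice pressure unit, using air density 1.204 kg/m³), and
the Reynolds number. The inlet plug speed is set so the volumetric flux
through the discrete inlet plane equals the requested flow rate
(9.45 L/min by default); the Reynolds number is defined on the inlet
hydraulic diameter.

**Desk-scale Reynolds.** Physiological pharyngeal flow at 9.45 L/min has
Re of several thousand; resolving it by direct numerical simulation is a
cluster-scale computation. The package instead preserves geometric
similarity and runs at Re = 200 (target range 100–500) by inflating the
fluid viscosity — the standard similarity-scaling compromise — and says so
in every report. Results quantify *where* the pressure gradient
concentrates, not absolute physiological pressures.

**Numerical operating point.** The asleep base-of-tongue constriction
halves the local diameter, so the local Mach number, not the shear
resolution, limits the solver: with an inlet speed of 0.06 lattice units
the throat jet approaches a third of the lattice sound speed and the run
destabilizes. The default operating point is therefore `uLat = 0.03`,
`dx = 0.75 mm` (≥10 voxels across the narrowest asleep lumen), MRT
collisions, and up to 16–20k steps with a 1000-step inlet ramp; the field
is time-averaged over the final 1000 steps whether or not the 1e-6
steady-state criterion has been met (separated jets at Re 200 retain slow
unsteadiness, which the averaging absorbs).

**Validation and its limits.** Body-force plane-channel flow matches the
parabolic profile to <0.1%; a lattice-centered circular pipe at 21 nodes
per diameter matches Poiseuille to ≤5% (max-norm) and Hagen–Poiseuille
pressure drop to within 10%. Spatial convergence is second order, with the
order measured on the *channel* (flat walls resolved by the lattice, error
ratio ≈4 when dx halves); on the staircase-walled pipe, halfway
bounce-back degrades the observed order to ~1–1.5, a well-known property
of staircase boundaries. Mass is conserved to machine precision.

**Flow domain.** Airway flow runs use a straight-axis loft of the measured
contours (arc length and per-station areas preserved) so that the inlet
and outlet are the flat trimmed end planes of the voxel grid. Curvature
affects secondary flows but enters the obstruction statistic only through
the per-arc-length area profile, which is preserved; the anatomically
curved loft is still produced, validated, and exported for visualization.

The respiratory cycle (~5 s; normal breathing is about 7 breaths/min,
~8.6 s per breath) is available as a sinusoidally modulated inflow with
the cycle mapped to a stated number of lattice steps and fields averaged
over the final inspiratory half cycle; the steady mode is the default and
is what the packaged localization tests use, because the source analysis
is ambiguous about which mode produced its figures.

# The obstruction statistic

At each of (by default) seven stations A–G along the trimmed arc length,
the pressure is averaged over the fluid voxels of a one-voxel-thick slab
and referenced to the first station ("pressure difference"; the absolute
offset is unrecoverable and irrelevant to derivatives). First and second
axial derivatives use three-point Lagrange stencils, exact for quadratics
and valid on non-uniform stations; `d²p/dz²` is undefined at the end
stations. Sites are ranked by `|d²p/dz²|`, with ties broken by lower mean
pressure and then the more distal position; each site's lumen area is
reported alongside as corroboration but never enforced. An essentially
linear pressure profile is flagged as "no focal obstruction".

Because the statistic is a curvature, it peaks where the pressure *slope
changes* — the entrance and exit of a constriction — not automatically at
the geometric throat center. Station layout therefore matters: a
constriction that is compact relative to the station spacing deposits its
whole pressure drop between the stations flanking the throat, and the
curvature maximum lands on the station nearest the throat; a constriction
wider than the spacing resolves its entrance and exit knees onto separate
stations, which still bracket the site. With the default seven stations
(~23 mm apart) and the 26-mm base-of-tongue window, the flanking stations
fall inside the window and the dominant site lands there.

# Problem sizes used by the packaged tests

The test suite and the acceptance script run on desk-scale sampling chosen
as the package's default study conditions: 360 A-lines × 512 depth pixels
per frame for the end-to-end area analysis (301 frames per state; wall
quantization 25 µm ≈ 0.4% of the 6 mm radius), 96-vertex contours for
lofting, `dx = 0.75 mm` voxel grids (~15–30k fluid nodes) and 14–16k-step
MRT runs for the flow stages. The full 2000 × 1024 acquisition remains the
constructor default and runs identically, only slower.

# Known limitations

- Circular-section phantoms cannot probe segmentation on concave or lobed
  lumina; real stacks would also need motion handling that is out of scope.
- Staircase bounce-back limits near-wall accuracy on curved walls; a
  wall-fitted (interpolated) boundary would restore second-order wall
  placement at the cost of link-distance bookkeeping.
- Desk-scale Reynolds similarity preserves the *location* of pressure-drop
  concentration, not turbulent transition physics; absolute pressures are
  not physiological.
- The oscillatory mode time-averages the inspiratory half cycle only; a
  full phase-resolved analysis (per-phase obstruction ranking) is not
  implemented.
- Region windows are configuration; on real data they are anatomical
  landmarks a clinician must supply.

# Reproducing the analysis

```{r pipeline}
library(airwayflow)
report <- runPipeline(list(seed = 0L, flow = list(enabled = FALSE)))
report$reductions
```

The flow and localization stages:

```{r flow}
g <- acquisitionGeometry(alinesPerFrame = 360L, depthPixels = 512L)
ph <- makePhantom("asleep", seed = 0L, curved = FALSE)
gt <- groundTruth(ph, g, nVertices = 96, straighten = TRUE, trim = c(5, 5))
lat <- voxelize(gt$surface, 0.75)
fl <- runSimulation(lat, inflowLpm = 9.45, Re = 200, collision = "mrt")
prof <- rankObstructions(obstructionProfile(stationPressures(fl, 7L)))
prof
```

`scripts/acceptance.R` recomputes the acquisition timing and the three
regional reductions from scratch and writes them as JSON; see the README.
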