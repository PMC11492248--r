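---
title: "Membrane curvature, contacts and clustering from CG trajectories: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Membrane curvature, contacts and clustering from CG trajectories: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memcurv)
```

memcurv analyses coarse-grained membrane/protein trajectories: membrane
curvature from a fitted height surface, protein–lipid contacts and
occupancy, DBSCAN lipid clustering, lipid-density/height correlation,
and rigid-body orientation.  This vignette is the package's account of
the underlying models and of the numerical and design choices; the
README shows the day-to-day workflow.

## The curvature model

A nearly planar bilayer can be written as a Monge patch, a height
function $z(x,y)$ over the membrane plane.  Per frame, the upper-leaflet
PO4 beads are fitted with a parametric family; the default,
`gauss_dimple`, is a tilted plane plus one anisotropic Gaussian
depression,

$$z(x,y) = c_0 + c_1 x + c_2 y +
  A\,\exp\!\left(-\frac{(x-x_0)^2}{2 s_x^2}-\frac{(y-y_0)^2}{2 s_y^2}\right),$$

chosen because it is the simplest smooth shape resembling a plasma
membrane with a single protein-induced dimple ($A<0$ points the dimple
into the cell).  The family is a registry entry
(`surface_forms()`, `register_surface_form()`): a biquadratic
polynomial and a separable cosine bump are built in, and new forms only
need a height function, its analytic first/second partials, a parameter
Jacobian and an initialisation rule.

From the fitted surface, each bead's curvature is evaluated
analytically along the box axes,

$$\kappa_x = \frac{z_{xx}}{(1+z_x^2)^{3/2}}, \qquad
  \kappa_y = \frac{z_{yy}}{(1+z_y^2)^{3/2}},$$

and the unsigned Gaussian curvature $|K| = |\kappa_x\,\kappa_y|$
(units Å$^{-2}$) is averaged over beads to give the per-frame
observable.  Treating the box axes as the principal directions is the
usual convention for nearly planar membranes, where the fitted surface
is axis-aligned by construction; the full shape-operator
eigendecomposition is available as
`shape_operator_curvatures()` for strongly tilted patches.  The mean is
taken over beads (not over a uniform grid): curvature is a per-bead
assignment, so bead-dense regions weigh proportionally to the lipids
actually present.

### Fitting

Nonlinear forms are minimised with Levenberg–Marquardt
(`minpack.lm::nls.lm`) using the analytic parameter Jacobian;
convergence is declared at a relative cost change below $10^{-10}$
(up to 1024 iterations, the optimiser's ceiling — all tested fixtures
converge within a few dozen).  Forms linear in their parameters (plane,
biquadratic) are solved exactly by QR, which *is* the least-squares
minimiser.  Initialisation is deterministic: plane at the mean height,
zero tilt, dimple centred on the lowest bead with amplitude
$\min z - \bar z$, and widths of one sixth of the box edge — a
basin-reasonable start for a single-depression membrane.  Per-frame
fits are independent (no warm start) so each frame stands on its own;
`warm_start = TRUE` is available for long, smooth trajectories.
Degenerate inputs (fewer points than parameters, collinear $(x,y)$)
are refused with an error, and fitted widths are reported with positive
sign (the model is even in them).

## Contacts and occupancy

A contact is two reference points strictly closer than the cutoff
(default 10 Å; a pair exactly at the cutoff is *not* in contact).
Reference points are the backbone (BB) bead for a protein residue and
the centre of geometry for a lipid molecule, except GM3, whose centre
of geometry is buried in the membrane and which therefore uses the
carboxyl-group D bead on its second sugar ring.  Distances honour the
minimum-image convention in the membrane plane ($x$, $y$) by default —
in-plane periodicity is physically required near box edges — and are
raw in $z$; `convention = "raw"` reproduces naive behaviour.  Neighbour
search uses spatial binning with bin width equal to the cutoff, and its
correctness is defined by (and tested against) a brute-force all-pairs
oracle, not by the acceleration.  Both per-pair frame counts and
per-residue totals are reported, since either may be wanted for
B-factor visualisation; occupancy is the fraction of frames in a window
in which a residue touches at least one molecule of the species of
interest.

## Lipid clustering

Molecules are assigned to leaflets once, from the first frame (midplane
= mean PO4 height; the assignment is frozen afterwards, so a lipid that
later crosses the midplane keeps its original stratum).  Clustering
uses an in-package DBSCAN (eps 28 Å, minimum 5 molecules including the
point itself) on per-species reference points — centres of geometry for
*every* species in this analysis, including GM3: clustering asks where
molecules are, not where their binding epitope is.  DBSCAN is
implemented in the package rather than delegated so that the
minimum-image option and the oracle test are possible.  One deliberate
deviation from the classic scan-order algorithm: a border point
reachable from several clusters joins its *nearest* core neighbour
(ties to the lower label), making the partition deterministic and
independent of input order; the classic algorithm's answer depends on
expansion order, which would make permutation invariance untestable.
The parameter pair (28 Å, 5) can be re-derived on one frame with
`tune_cluster_params()`, which scans a grid and reports the
non-clustered ("noise") count per setting — the minimum-noise criterion
for a species of interest.

The 2D height map uses a planar Delaunay triangulation (deldir) of the
upper-leaflet PO4 beads, each triangle coloured by the mean height of
its three vertices.

## Density–height correlation

The membrane plane is tiled from the box origin with squares of edge
18 Å; a final partial row/column is kept as smaller squares so molecule
counts are conserved.  Per square $i$: $L_i$, the number of molecules
of the species of interest (by reference point), and $\Delta z_i$, the
deviation of the mean PO4 height in the square from the frame's overall
mean.  The per-frame statistic is the population Pearson correlation

$$\rho = \frac{1}{N}\sum_i
  \frac{(L_i - \langle L\rangle)(\Delta z_i - \langle\Delta z\rangle)}
       {\sigma_L\,\sigma_{\Delta z}},$$

over the $N$ squares that contain at least one PO4 bead (squares with
beads but zero molecules of the species still contribute $L_i = 0$ —
they carry signal; squares with no height information cannot).  The
$1/N$ versus $1/(N-1)$ choice cancels in $\rho$.  When either field has
zero variance $\rho$ is undefined and reported as missing rather than
zero.  $\Delta z$ uses upper-leaflet PO4 beads by default, matching the
curvature definition; `dz_source = "all"` uses both leaflets.  Species
are stratified by their first-frame leaflet.

## Orientation

Rigid-body reorientation is tracked through one body-fixed vector
between two chosen residues' BB beads, normalised per frame and
compared with its first-frame direction:
$\theta_t = \arccos(\hat v_t \cdot \hat v_0)$ in degrees.  The
implementation evaluates the equivalent
$\operatorname{atan2}(\lVert \hat v_t \times \hat v_0\rVert,\,
\hat v_t \cdot \hat v_0)$, which is exact at $0^\circ$ and stable near
$0^\circ$/$180^\circ$ where $\arccos$ loses precision; the dot product
is clamped to $[-1, 1]$ so round-off can never leave the domain.  The
residue pair should span the body (approximately a diameter): rotation
about the axis parallel to $\hat v_0$ is invisible to a single-vector
measure — a documented limitation, not a defect.  No minimum-image
correction is applied within the capsid, which is assumed
whole-molecule wrapped.

## Smoothing and the pipeline

Time series are smoothed with a trailing 200-frame rolling mean whose
start-up entries average all available preceding points, so output
length equals input length.  `run_pipeline()` executes the stages in
dependency order from a YAML/R config whose defaults are the standard
parameters above (10 Å, 28 Å/5, 18 Å, 200 frames), writes one CSV per
stage plus a JSON manifest (config echo, package version, seed), and is
bit-reproducible: identical config and inputs give identical files.

## The synthetic-scene generator

The generator is first-class, tested code, not a fixture dump.  It
emulates the simulated study systems: a bilayer patch in a 50 nm box
(default 500 × 500 × 500 Å) with the asymmetric plasma-membrane
composition POPC/DOPC/POPE/DOPE/CHOL/DPG3 = 25:25:8:7:25:10 (upper
leaflet) and POPC/DOPC/POPE/DOPE/CHOL/POPS/DOPS/POP2 =
5:5:20:20:25:8:7:10 (lower), apportioned exactly by largest remainder;
an icosahedral capsid shell of default radius 125 Å (the ~25 nm virus
diameter); and scripted trajectories with known rigid rotations and
surface schedules.  Design choices:

- **In-plane placement** is blue-noise-like dart throwing with a
  minimum spacing of 8 Å, a realistic CG area per lipid; it prevents
  accidental sub-eps packings that would confound clustering tests.
- **Bilayer thickness** defaults to 40 Å (typical CG bilayer); only the
  relative leaflet separation matters for leaflet assignment.
- **Lipid geometry** is minimal: a PO4 bead exactly on the surface, a
  body bead 5 Å toward the midplane (centre-of-geometry proxy), and for
  GM3 a D bead 3 Å above the head group.
- **Planted clusters** relocate molecules into disks whose radius is
  capped just below eps/2, so every planted blob is mutually within the
  neighbourhood distance and recoverable as one cluster by
  construction whenever its size reaches `min_pts`; blob centres are
  separated by more than $2(\text{spread} + \text{eps})$ and leftover
  molecules are isolated beyond eps from everything, so they are noise
  by construction.
- **The default dimple form equals the default fit family**, so
  zero-residual fixtures exist and parameter recovery is a meaningful
  test.
- Species use the CG residue names (DPG3, POP2, ...) with a GM3/PIP2
  alias table, so selections written for real data work on fixtures.

What the generator does *not* emulate: thermal roughness beyond
optional Gaussian $z$-jitter, lipid diffusion, area-per-lipid
fluctuations, protein flexibility, or solvent.  Passing tests therefore
demonstrate correctness of the *analysis machinery* on scenes with
known answers — not that a real membrane satisfies the fitted model.
On real trajectories the RMS residual column is the honesty check: a
residual comparable to the dimple amplitude means the single-dimple
family is underfitting that frame.

Frames are constructed, not simulated; all randomness is seeded and
scenes are bit-reproducible.

## Verification scales

The checks in `tests/` and `scripts/acceptance.R` run on desk-scale
scenes chosen to finish in seconds while still exercising every code
path: 2,500-bead noise-free surfaces for parameter recovery (machine
precision in practice, asserted at $10^{-4}$ relative), 200 random
100 × 100-point scenes against the brute-force contact oracle, 100
random 300-point scenes against the textbook DBSCAN, planted-cluster
grids up to 3 × 40 molecules in 1,300-lipid patches, 100-seed nulls for
the correlation, and a 20-frame end-to-end determinism run.  These
sizes are the package's own verification conditions — real
production trajectories are orders of magnitude larger, and the
per-frame algorithms scale linearly (binned neighbour search) or as the
fit's $O(M)$ residual evaluations.

## Input/output conventions and limitations

Internally everything is Å and ps; GRO and TRR files (nm) are converted
at the boundary.  GRO (single and concatenated multi-frame), PDB
(single and multi-MODEL, read via bio3d) and TRR (a self-contained
big-endian XDR reader/writer) are supported; XTC is not — its
compressed-integer coordinate codec is out of scope, and TRR or
multi-frame GRO cover the uncompressed cases.  On reading, molecules
are identified with residues (the CG convention of one residue per
lipid).  Coordinates are assumed wrapped into the primary box; no
unwrapping is performed, and analyses use minimum-image distances where
physically required.  Per-residue scores export to the PDB B-factor
column at the format's two-decimal precision, clamped to the
six-character field with a warning on overflow.

Not provided, by design: signed mean curvature or mesh-based curvature
estimators, energetic interaction scoring, Voronoi area-per-lipid,
flip-flop detection, three-angle orientation estimation, and any
physical dynamics in the generator.
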