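# memcurv

Analysis of coarse-grained (CG) molecular-dynamics trajectories of
membrane–protein systems — the kind produced when a ~25 nm virus capsid
is simulated on a ~50 nm plasma-membrane patch.  The package quantifies
how much the protein bends the membrane, which residues touch which
lipids, whether specific lipid species (such as the ganglioside GM3)
cluster underneath the protein, how lipid density co-varies with local
membrane height, and how the rigid body reorients over time.

It is aimed at structural bioinformaticians and molecular modellers who
have CG trajectories (GRO/PDB coordinates, TRR or multi-frame
GRO/multi-MODEL PDB trajectories) and want tested, scriptable versions
of these five standard analyses — plus a synthetic-scene generator that
builds membrane/capsid fixtures with exact analytic ground truth, so
every stage can be verified at desk scale before being trusted on real
data.

## The model at the core

The membrane surface is treated as a Monge patch: the upper-leaflet
phosphate (PO4) beads of each frame are fitted with a parametric height
function, by default a plane plus an anisotropic Gaussian dimple

    z(x, y) = c0 + c1 x + c2 y + A exp(-( (x - x0)^2 / (2 sx^2) + (y - y0)^2 / (2 sy^2) ))

by Levenberg–Marquardt least squares.  Normal curvatures along the box
axes are evaluated analytically from the fit,

    kappa_x = z_xx / (1 + z_x^2)^{3/2},   kappa_y = z_yy / (1 + z_y^2)^{3/2},

and each bead is assigned the unsigned Gaussian curvature
|K| = |kappa_x * kappa_y| (Å⁻²); the per-frame mean of |K| is the
curvature observable.  Around this sit:

- **contacts** — two reference points (protein backbone bead; lipid
  centre of geometry, or the D bead for GM3) are in contact when closer
  than 10 Å; per-residue occupancy is the fraction of frames with at
  least one contact to a species of interest;
- **lipid clustering** — in-package DBSCAN (eps 28 Å, minimum 5
  molecules) on per-species reference points, stratified by the leaflet
  each molecule occupied in the first frame;
- **density–curvature correlation** — an 18 Å grid over the membrane
  plane; per frame, the population Pearson correlation between
  per-square molecule counts L_i and height deviations Δz_i;
- **orientation** — the angle between a body-fixed residue-pair vector
  and its first-frame direction, in degrees.

## Worked example

```r
library(memcurv)

## a 50 x 50 nm membrane patch dimpled by a capsid-sized depression
surf  <- surface_params("gauss_dimple", c0 = 150, A = -30,
                        x0 = 250, y0 = 250, sx = 80, sy = 80)
scene <- make_membrane_frame(surf, n_per_leaflet = 400,
                             box = c(500, 500, 300), seed = 1)

fit <- surface_fit(scene)
print(fit)
#> Monge-patch surface fit (form 'gauss_dimple', 386 beads)
#>  c0  c1  c2   A  x0  y0  sx  sy
#> 150   0   0 -30 250 250  80  80
#> RMS residual: 0 A
```

The fit recovers the generating surface exactly (noise-free beads), and
`summary()` adds the curvature observable — here 4.8 × 10⁻⁷ Å⁻², the
mean |K| over the 386 upper-leaflet PO4 beads of this dimple:

```r
summary(fit)
#> mean |K| over 386 beads: 4.826e-07 A^-2

capsid <- make_capsid_shell(center = c(250, 250, 245), radius = 125,
                            beads_per_face = 10, seed = 1, box = scene$box)
sc <- merge_frames(scene, capsid)
attr(sc, "truth") <- scene_truth(scene)
traj <- make_trajectory(sc, 5, angles = seq(0, 40, by = 10),
                        axis = c(1, 0, 0),
                        dimple_schedule = replicate(5, surf, simplify = FALSE),
                        seed = 2)

curvature_series(traj)
#>   frame time_ps   mean_abs_K rms_residual_A
#> 1     1       0 4.826018e-07              0
#> ...   (constant: the dimple schedule holds the surface fixed)

mats <- contact_trajectory(traj, species_a = "CAPS")
fq   <- contact_frequency(mats)
head(sort(fq$residue, decreasing = TRUE), 3)
#> 32 33 35
#>  2  2  2          # contact counts over the 5 frames
occupancy(mats, 32)
#> [1] 0.4           # residue 32 touches a lipid in 2 of 5 frames

orientation_angles(traj, residue_a = 1, residue_b = 31)$angle_deg
#> [1]  0 10 20 30 40   # the scripted rotation, recovered exactly
```

Contact counts can be painted onto a structure for visualisation with
`write_score_structure(frame, scores, "contacts.pdb")`, which writes
them into the PDB B-factor column.  A YAML-configurable end-to-end run
(`run_pipeline()`, or `inst/cli/memcurv run --config cfg.yaml`) writes
one CSV per stage plus a JSON manifest, and is bit-reproducible for a
fixed config and seed.

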