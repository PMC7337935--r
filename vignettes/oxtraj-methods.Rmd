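---
title: "oxtraj: models, parameters and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{oxtraj: models, parameters and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of what it computes, which knobs
matter, and where genuinely open design choices were resolved. It states no
empirical result that the test suite does not itself compute.

## The data model

A **topology** holds what is constant along a trajectory: strand membership,
base identity and the 3'/5' backbone links of every nucleotide. Links must be
mutual, and each strand must form a single path (or a single cycle —
circularity is *derived* from closed connectivity, never declared). Global
nucleotide ids are 0-based throughout, matching the on-disk dialect, index
files and viewer selections; frame indices are 1-based, matching R. Base
symbols outside `A, C, G, T, U` are carried opaquely and treated as
non-complementary.

A **configuration** is one frame: per-nucleotide positions plus the versor
pair `a1` (towards the base site) and `a3` (stacking axis). On construction
we require `|a1| = |a3| = 1` within 1e-5 and `a1 · a3 = 0` within 1e-4; the
third axis `a2 = a3 × a1` is computed on demand and never stored. The file
reader re-normalises versors off by up to 1e-3 (printing at 8 decimals
perturbs them by ~1e-8; anything worse than 1e-3 indicates a corrupt file
and is rejected).

Internal math uses simulation length units; user-facing distances are nm via
the model's convention 1 unit = 0.8518 nm. Energies stay in simulation units
(of order k~B~T) everywhere. The base-site offset along `a1` defaults to the
DNA-model value 0.4; the RNA model's offset is not published in a single
authoritative place, so it is a parameter (`pos_base`) rather than a second
hard-coded constant.

Trajectory files are indexed in one pass by recording the byte offset of
every `t =` header; frames are parsed on demand. This keeps memory flat for
long trajectories and lets the chunked parallel scheme hand workers frame
ranges without ever holding the file in memory.

## Mean structures, RMSF and the collapse problem

The primary mean-structure route aligns every frame to a reference with the
Kabsch algorithm (SVD of the cross-covariance, smallest singular direction
sign-flipped so the rotation is always proper) and averages positions. Two
choices deserve comment:

* **Reference.** Default is frame 1; `reference = "random"` (seeded) and
  external configurations are supported. The suite checks that RMSF is
  insensitive to this choice on rigid planted-noise fixtures (2% tolerance)
  rather than assuming it.
* **Mean orientations.** Whether the original tools average orientations at
  all is unstated. We average the aligned `a1`/`a3` fields and
  re-orthonormalise by Gram–Schmidt (`a3` first), which keeps the mean a
  valid, viewer-loadable configuration. This is documented as this package's
  choice, not asserted as anyone else's.

`RMSF_i = sqrt(mean_f |x_{i,f} − mean_i|²)`, converted to nm. For isotropic
per-axis noise σ the expectation is σ√3 (in nm, ×0.8518); alignment absorbs
six rigid degrees of freedom, biasing the estimate slightly low — visible in
the README example and tolerated at 5% in the acceptance suite.

Full-structure alignment fails informatively on floppy systems: flexible
regions collapse towards a centre line and bending structures show spurious
low-RMSF rings at oscillation nodes. The remedy implemented here is the
contact-map route below, not any attempt to "fix" the SVD mean.

## MDS mean structures

`mean_distance_map()` keeps pairs whose trajectory-mean centre-of-mass
distance is at most `r_cut` (default 2.07 nm — about the interhelix gap in
an origami, so neighbouring helices stay coupled while long-range pairs,
whose mean distances are the noisiest and least structural, drop out).
`mds_embed()` then minimises the raw stress `Σ (⟨δ_ij⟩ − d_ij)²` over
retained pairs only (weight 0 beyond the cutoff).

Numerically this is done in three deterministic stages:

1. **Initialisation**: classical MDS (`cmdscale`) of the geodesic completion
   of the sparse map — shortest-path distances through the contact graph via
   `igraph`. A disconnected graph is a hard error listing fragment sizes,
   since fragments are mutually unconstrained.
2. **SMACOF majorisation** (up to 300 iterations, relative stress tolerance
   1e-6) with the weighted-Laplacian pseudo-inverse computed once.
3. **Quasi-Newton polish**: L-BFGS on the stress with its analytic gradient.
   This stage is a deliberate deviation from a majorisation-only design:
   measured on a noiseless 200-nt helix, pure SMACOF stalls around stress
   1.7e-2 (coordinate RMSD ≈ 0.1) even after 2000 iterations, because
   elongated structures relax through slow long-wavelength bending modes;
   the polish reaches stress ~1e-14 in about two seconds. Hyperparameters of
   the solver are not part of the method's published description, so this is
   an implementation choice, documented here.

The embedding is defined only up to rigid transforms *and reflection*
(distances carry no chirality); all fidelity tests therefore compare after a
reflection-allowed best fit. The documented large-scale failure mode — every
particle at the origin — is detected (bounding-box diagonal < 1e-4 × the
largest map distance) and warned about rather than silently returned.
Orientation data is lost by construction; MDS means are visualised as
spheres.

**Local deviation**: per retained pair, the per-frame distance spread is
summarised by the standard deviation (default) or mean absolute deviation
(`method = "mad"`), then averaged over each nucleotide's partners. "Mean
deviation" is ambiguous in prose; std is the default because it matches the
planted-variance calibration tests exactly, and the alternative is one flag
away. Values are left in simulation units (the overlay is a relative map;
RMSF is the calibrated nm-valued quantity).

## Duplex geometry

Duplexes are maximal runs of consecutive base pairs `(i, j), (i+1, j−1), …`
walked along mutual backbone links (so the logic is connectivity-driven and
survives arbitrary id layouts, nicks and junctions). Runs shorter than
`min_len` (default 4 bp — short enough to keep junction arms, long enough
that an axis fit is meaningful) are dropped.

Two axis estimators: for B-form, the first principal direction of the
base-pair midpoints (they are nearly collinear); for A-form, where the helix
axis misses the base-pair centres, the normal of the least-squares plane
through successive backbone displacement vectors of both strands — for any
regular helix those displacements have a fixed axial component and a
rotating in-plane component, so their plane's normal *is* the axis. The
plane fit degenerates when all displacements are parallel (a straight
ladder); that is reported as an error, not a guess. Axis signs point from
the first towards the last base pair of the run.

Because fitted axes carry arbitrary sign in general, the interduplex angle
defaults to the unsigned `acos(|u · v|) ∈ [0°, 90°]`; `signed = TRUE` keeps
the strand-order sign convention for users studying reflex junction angles.
Per-frame bonded pairs can come from the designed-pair list (assume intact)
or from the bond detector (default when analysing a trajectory, since the
question is what is present *in each configuration*). The co-occurrence
fraction — frames where both probed duplexes exist / frames analysed — is
reported alongside mean/median/std, as a stability indicator.

## Hydrogen bonds and occupancy

The full coarse-grained force field is deliberately **not** reimplemented:
its functional forms belong to the model papers, and re-deriving them would
make occupancy untestable against anything but itself. Instead:

* **Energy mode** consumes an engine-produced interaction table (TSV:
  `frame, i, j, kind, energy`) and applies the conventional threshold:
  hydrogen-bonded iff the HB pair potential is below −0.1 simulation energy
  units (about 10% of the equilibrium base-pairing energy). The threshold is
  a parameter because the unit system of external tables is the producer's
  responsibility.
* **Geometric mode** declares a bond when base sites are within 0.85 length
  units, bases are Watson–Crick complementary (wobble optional for RNA), and
  `a1 · a1' < −0.7` (antiparallel). These defaults are calibrated so the
  ideal synthetic duplex is detected exactly, with zero false
  positives/negatives across 100 perturbed frames at σ = 0.05 — stacked
  neighbours pass the distance test but fail antiparallelism.

One bond per base is enforced (occupancy presumes an involution); ties go to
the most negative energy or smallest site distance. Occupancy is an exact
ratio of integers — the suite asserts `occupancy × frame_count` is integral —
and nucleotides with no designed complement are exactly 0, never NA.

## PCA of motion modes

Frames are aligned to the mean, positional deviations flattened to
3N-vectors (orientations excluded: modes describe where mass moves), and the
covariance about the empirical deviation mean is diagonalised. Alignment
removes six rigid degrees of freedom, so at most 3N − 6 eigenvalues are
materially nonzero — asserted at 1e-6 relative in the suite. Eigenvector
signs are fixed (largest-magnitude component positive) so overlays are
reproducible. Overlay weighting uses the eigenvalue per the tool's
description, with `weight = "sqrt"` (modal amplitude, same units as
displacement) one flag away. Above 3N = 4000 the spectrum comes from the
SVD of the F × 3N deviation matrix — identical nonzero eigenvalues, far
cheaper when F < 3N, at the cost of a truncated basis.

The synthetic generator's planted mode is projected onto the complement of
the six rigid-body modes before use: a "planted mode" with a rigid component
is unrecoverable by construction (alignment removes it), so ground truth is
only well-defined for internal deformations. This is why noiseless planted
modes are recovered with |cos| > 0.999 rather than ≈ 0.99.

## Clustering

DBSCAN is implemented directly (standard semantics; a point counts itself
towards `min_samples`; labels −1/0.., numbered by first-seen frame) and is
checked exactly against an independent brute-force
neighbourhood-graph-plus-BFS reference over a grid of `(eps, min_samples)`
on 500-point fixtures. Defaults for trajectory clustering are heuristics and
say so: order parameters are the leading PCA projections reaching 90%
explained variance (capped at 10), and `eps` comes from the elbow
(max-distance-to-chord) of the sorted k-distance curve. Both should be
overridden when the system is understood — the published applications chose
order parameters per system, and no universal `eps` exists. Border points
attach to the first core point (in index order) that reaches them, making
output deterministic; per-cluster trajectory files preserve frame order and
feed unchanged back into every other analysis.

## Rigid-body relaxation

Blocks (from spatial DBSCAN, noise particles becoming singleton groups so
nothing is left immobile, or from user index files) move as rigid bodies
under two forces: springs `f_spr = c_spr (l − l_r)` at every backbone bond
crossing groups, applied at the attachment nucleotides, and a central
repulsion `f_rep = max(c_rep (1 − d/(r_a + r_b)), 0)` between group centres
(zero torque). Integration is damped first-order motion — momentum-style
updates `v ← damping·v + step·F` — because the goal is a relaxed
*arrangement*, not kinetics; whether the original interactive implementation
applies torques or uses another integrator is unstated, so this is the
package's own choice. Rotations are applied by axis-angle exponentiation,
keeping intra-group geometry rigid to 1e-8 across the entire run (asserted,
not assumed). Termination: largest per-group net force below `tol`
(default 1e-4) or the iteration cap; a potential-energy rise across 100
consecutive checkpoints aborts with a diagnostic. Defaults
(`c_spr = 1, l_r = 0.76` — the model's relaxed backbone length —
`c_rep = 10, step = 0.05, damping = 0.95`) are all exposed, since none are
published. `pinned` substitutes for interactive dragging.

## The synthetic world

`build_duplex()` constructs ideal straight helices: B form with rise 0.3897
units (≈0.34 nm), twist 34.3°/bp, backbone radius 0.6, base-pair midpoints
exactly on the axis; A form with rise ≈0.28 nm-equivalent, twist 32.7°/bp
and midpoints displaced 0.25 units off-axis, so the plane-fit axis route is
genuinely exercised rather than degenerating to the midpoint fit. These are
canonical helix parameters; nothing in the analysed method depends on their
exact values. `build_interrupted_duplex()` defaults to a 50-nt strand-1
pattern (segments 15/15/10 bp, two 5-nt gaps) mirroring the flexible
gapped-duplex motif used to demonstrate the SVD-mean collapse.
`perturb()` adds iid Gaussian positional noise and commensurate orientation
noise (random axis, angle ~ N(0, (σ/rise)²)); `planted_mode_trajectory()`
and `two_state_trajectory()` plant a known covariance spike and a known
bimodal mixture. All generators are pure functions of their arguments
including the seed.

What the generators do **not** emulate: thermodynamically faithful ensembles,
sequence-dependent structure, correlated (hydrodynamic) noise, fraying
kinetics. A green test therefore establishes that the *estimators* recover
planted statistical structure at the stated tolerances — not that any real
nanostructure behaves like the fixture.

## Parallelisation

`plan_chunks()` splits frames into ≤ n_cpus contiguous ranges differing by
at most one frame. Workers (forked via `parallel::mclapply`) only *compute*
per-frame results; all reduction happens on the calling process in frame
order, so results are independent of worker count — the suite asserts
serial/parallel agreement at 1e-12 for RMSF, contact maps and covariance
spectra.

## Known limitations

* MDS means do not scale to origami-size structures (thousands of
  particles): mean-distance data is noisy and the embedding collapses — the
  detector warns, but the method is the wrong tool at that scale.
* The geometric bond detector is calibrated on ideal geometry; heavily
  distorted duplexes should use energy mode with an engine table.
* `dbscan()` builds a dense distance matrix: fine for the intended
  F ≲ 10^4 frames, wrong for millions of points.
* Angle statistics treat frames as independent; no autocorrelation
  correction is applied to the reported std.
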