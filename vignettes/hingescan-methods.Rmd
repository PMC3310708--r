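---
title: "Quasi-rigid domains and hinge axes: models, parameters, design"
author: "hingescan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quasi-rigid domains and hinge axes: models, parameters, design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the models it
implements, the parameters that matter, the numerical choices, what the
synthetic-data generator does and does not emulate, and the known
limitations.

## The multiscale picture

Large proteins rarely move as elastic continua. Their internal dynamics
is often well described at three scales: per-residue-pair flexibility
(which distances fluctuate), per-residue mechanical strain (whose
contact neighbourhood deforms), and domain-scale motion (a few
quasi-rigid bodies moving relative to each other, connected by hinges).
`hingescan` computes all three from a Cα trajectory, plus a fourth,
comparative one: a *meta-trajectory* pooling the corresponding residues
of several homologous proteins, so one joint decomposition captures the
dynamics they share.

## Distance fluctuations (superposition-free flexibility)

For residues $i, j$ with instantaneous Cα distance $d_{ij}(t)$,
$$A_{ij} = \left\langle \left(d_{ij} - \langle d_{ij}\rangle\right)^2
\right\rangle ,$$
with $\langle\cdot\rangle$ the plain time average over the analysis
frames (population variance; duplicating frames leaves $A$ unchanged).
Because only internal distances enter, $A$ is exactly invariant under
per-frame global roto-translations — no superposition is performed, so
no reference-structure choice can distort it. The implementation streams
over frames in two passes (mean, then variance), which is numerically
stable and keeps memory at one pair-vector per frame. Quasi-rigid
domains appear as near-zero blocks.

`blockSummary()` averages $A$ over two residue ranges (diagonal entries
excluded) to quantify segment-to-segment mobility;
`minDistanceSeries()` reports the closest-pair distance between two
selections per frame with its final and time-average values.

## Geometric strain (hinge detection)

$$p_i = \sum_{j \ne i} A_{ij}\, f(\langle d_{ij}\rangle), \qquad
f(x) = \frac{1}{1 + e^{(x - c)/w}},$$
with cutoff $c = 5$ Å and width $w = 0.5$ Å by default. The weight
restricts the sum to each residue's local (~5 Å) contact network;
residues whose network deforms — hinges between quasi-rigid domains,
mechanically stressed sites — carry high strain. Two choices deserve
comment:

* **Functional form.** Only the ~5 Å scale of the contact weight is
  physically essential; we adopt the least-surprising logistic with its
  midpoint at the cutoff, and expose both parameters. With $w \to 0$
  the profile tends to a hard-cutoff neighbour sum (verified
  numerically in the tests at $w = 10^{-3}$ Å).
* **Weight argument.** $f$ is evaluated at the *time-mean* distance, so
  the neighbour set is fixed over the analysis range and $p_i$ is a
  weighted row sum of $A$. An instantaneous-distance variant (weights
  inside the time average) is available via
  `strainProfile(..., instantaneous = TRUE)` for sensitivity analysis.

`strainTimeResolved()` evaluates the same quantity in non-overlapping
windows (default 10% of the trajectory, at least 2 frames) with
window-local averages; trailing frames that do not fill a window are
dropped.

## Quasi-rigid decomposition

Given a partition of the residues into $q$ domains, the fit error is
$$\varepsilon^2 = \frac{1}{3NF}\sum_{\ell=1}^{q}\sum_{t=1}^{F}
\min_{R,\,\tau}\sum_{i \in \ell}
\left| R\, r_i^{(0)} + \tau - r_i(t) \right|^2 ,$$
each inner minimisation an exact Kabsch superposition with a full
rotation matrix (no small-angle linearisation). The reference
conformation $r^{(0)}$ is the frame closest to the iteratively
superposed mean structure (`selectReference()`: superpose all frames on
the running mean until it moves < 1e-6 Å RMSD; ties to the lowest
index). The equivalent velocity-based formulation (deviation of
instantaneous residue velocity from the domain's rigid-body field) is
implemented in this displacement form, which the full-rotation
refinement requires anyway and which avoids finite-difference noise.

**Normalisation.** $\varepsilon^2$ is the *per-coordinate* mean squared
residual (Å²), so values are comparable across system sizes and
trajectory lengths and so that, for planted rigid motion plus isotropic
coordinate noise of s.d. $\sigma$ (noisy reference, noisy frames), the
floor is $\approx 2\sigma^2(1 - 2/n)$. The conventional per-atom RMSD is
reported alongside (`perFrameRmsd`), with
$\mathrm{mean}(\mathrm{RMSD}^2) = 3\,\varepsilon^2$. The **captured
fraction** is $1 - \varepsilon^2 / \varepsilon^2_{\mathrm{1\,body}}$,
where the baseline superposes the whole molecule as a single body per
frame: it measures what domain-*relative* rigid motion explains beyond a
global fit, and is defined as 1 when the baseline itself is ~0 (a
globally rigid input). A no-superposition baseline would conflate global
drift into the denominator.

**Search.** The optimisation alternates three move classes, all scored
by the same $\varepsilon^2$:

1. *Seeding from essential dynamics.* Frames are superposed on the mean,
   the $3N \times 3N$ covariance is diagonalised, and the trajectory is
   filtered through its top modes (default at most 10, dropping modes
   within 10× of the spectrum's median eigenvalue — the flat tail that
   uncorrelated noise produces). The distance-fluctuation matrix of the
   filtered motion is the clustering dissimilarity for k-medoids (PAM):
   residues of one rigid body have near-zero mutual fluctuation, which
   is the defining property of the decomposition. Raw mode components
   are *not* clusterable — a rigid rotation is a spatially varying
   displacement field — which is why the dissimilarity, not the
   eigenvector, carries the signal. A $10^{-9} \times$ distance term
   breaks the exact ties of ideal rigid blocks (PAM can cycle on tied
   zeros). A spatial k-means partition of the reference is used as a
   second deterministic start; quasi-rigid domains are spatially
   compact, and the residual decides which basin wins.
2. *Simulated annealing* over single-residue relabellings, boundary
   residues preferred (reference contact map, 8 Å), geometric cooling,
   move budget $50\,qN$ by default, driven by R's RNG so a seed fixes
   the whole search.
3. *Settling:* k-means-style alternation (refit all transforms, then
   reassign every residue to the domain whose transforms predict its
   trajectory best — monotone descent that moves coherent blocks) and a
   greedy best-improvement polish. Every candidate start and annealing
   result is settled; the lowest residual wins.

Domains may be sequence-discontiguous (quasi-rigid domains are spatial
objects); a minimum size of 3 non-collinear residues keeps every Kabsch
fit well-posed. `scanQ()` warm-starts $q{+}1$ by splitting the
highest-residual domain of the best $q$ partition (2-means on reference
coordinates), which guarantees the captured fraction is non-decreasing
in $q$; it suggests the smallest $q$ whose marginal gain drops below
0.05 (a stand-in figure of merit — the gain threshold is configurable).

## Fixed hinge axes

The motion of a side domain relative to a core is restricted to pure
rotation about a single time-independent axis, anchored on a Cα and
fixed in the core frame: every frame is first superposed onto the
reference *by the core domain*, making "fixed relative to the core"
literal. For a candidate axis (anchor $a$, unit orientation $u$) the
optimal per-frame angle has a closed form: decomposing each reference
point into axial and perpendicular components turns the residual into
$C - 2(A\cos\theta + B\sin\theta)$, minimised at
$\theta = \mathrm{atan2}(B, A)$ (verified against a 0.01° grid-search
oracle in the tests). The search is the exhaustive product of all Cα
anchors (optionally strided) × `nOrientations` (default 500) uniform
orientations, followed by rounds of continuous orientation refinement
(Nelder–Mead on local sphere coordinates) alternated with anchor
rescans at the refined orientation; the discrete-scan result is kept
alongside. The orientation sign is fixed so the mean angle is
non-negative; reported angles are relative to the reference
conformation. The axis is not constrained to the domain boundary and
need not pass through the domain's centre of mass.

A single `HingeAxis` carries a captured fraction relative to the moving
domain's own displacement in core-fixed coordinates; `fitAllHinges()`
additionally evaluates the restricted whole-molecule model (core at its
reference position, every side domain moved only by its fitted
rotation) against the same single-body baseline as the free fit, so
restricted ≤ free holds by construction and the two numbers are
directly comparable. A side domain that is static in the core frame has
no defined axis: it is flagged with a warning and an NA captured
fraction.

## The synthetic generator (and what passing tests mean)

The generator plants ground truth rather than emulating biophysics:
compact self-avoiding random blobs (minimum pair distance 3.5 Å,
mimicking Cα packing) chained along an axis, adjacent domains joined by
an explicit contact patch of residue pairs facing each other at ~4.4 Å,
with the domain bulks kept > 7.9 Å from the other domain. Cross-domain
distances therefore avoid the 5–7.5 Å band, so the declared interface
set (cross-domain neighbour < 5 Å in the reference) coincides exactly
with the residues that carry appreciable weight under the ~5 Å strain
contact function — with a purely random adjacency the hard 5 Å label
and the soft sigmoid tail disagree and "interface" would be ill-defined.
Each frame applies the scheduled rotations about the planted axes to the
moving domains, then adds i.i.d. Gaussian noise per coordinate.

Kinematic defaults: successive hinges get distinct axis orientations
(z, y, x) and phase-distinct schedules (25° smooth ramp; 20°
there-and-back sweep; …). Two parallel axes sharing one schedule would
collapse into a near-global rotation with almost no relative-motion
signal — an adversarially degenerate rather than typical study system.
The planted axis passes 0.3 Å beside its anchor Cα: an axis exactly
through an atom makes that atom's domain label formally degenerate (the
atom is invariant under both domains' motions), whereas a physical
hinge axis passes between atoms; the Cα-anchored fit is the
approximation under test, and 0.3 Å keeps its error small while making
the planted partition the unique optimum.

What the generator does **not** emulate: chain connectivity, secondary
structure, anharmonic or correlated ("breathing") fluctuations,
solvent, and ligand chemistry. Passing recovery tests therefore
demonstrates the correctness of the estimators and the optimisation
machinery on planted rigid-plus-noise motion — not that any particular
real protein decomposes into clean rigid bodies. On real trajectories
the captured fraction itself reports how good the quasi-rigid idealisation
is.

## Study sizes and numerical choices

The validation study (tests and `scripts/acceptance.R`) uses a
three-body system of 60+50+70 residues over 100 frames, with σ = 0.5 Å
noise for the noisy arm; axis recovery uses a 45+55 two-body system over
60 frames with 500 orientations and a full anchor scan; oracle
equivalence uses 30 residues × 20 frames against brute-force double
loops; exhaustive-search equivalence enumerates all 1969 two-part
partitions of 12 residues. These sizes make every brute-force oracle
exact and keep the full suite comfortably within a desktop run.

Other numerics: population (not sample) variance everywhere; two-pass
variance accumulation; rotations via SVD with a determinant guard
(proper rotations only, checked to 1e-8 in the fit results); collinear
domain geometry rejected at fit time; equilibration discard exposed as
`discardFrames` in the pipeline/CLI (long simulations typically drop an
initial transient, e.g. the first 20 ns); per-protomer fluctuation
matrices by default, with averaging over protomers or sources done
explicitly by the caller.

## Known limitations

* The annealing-plus-sweeps search is stochastic; with a fixed seed it
  is deterministic, but on genuinely ambiguous (noise-dominated)
  boundaries different seeds may settle residues differently — the
  residual, not the labels, is the stable quantity.
* Fixed-axis fitting excludes screw motion (no translation along the
  axis) by design.
* The meta-trajectory weighs every frame equally; sources with more
  frames contribute proportionally more (subsample beforehand to
  equalise if needed).
* Trajectory formats: multi-model PDB, DCD (with a PDB topology) and
  GRO are read; XTC/TRR are not.
* Elastic-network single-structure mode input is not implemented; modes
  always come from the trajectory covariance.
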