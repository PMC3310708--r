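# hingescan

Multiscale analysis of protein internal dynamics from Cα coordinate
trajectories, for structural biologists and simulators who want to know
*how a protein moves*: which residue pairs fluctuate, where the
mechanical strain concentrates, how many quasi-rigid domains explain the
motion, and about which fixed axes those domains rotate. The approach is
built for large-amplitude conformational dynamics (multi-domain
chaperones, motors, transporters) where mode-superposition pictures
distort, and it extends to a *meta-trajectory*: trajectories of several
homologous proteins restricted to corresponding residues and pooled, so
one joint decomposition describes them all.

## The quantities

**Distance-fluctuation matrix.** For residues *i*, *j* with
time-dependent Cα distance *d<sub>ij</sub>(t)*,

&nbsp;&nbsp;&nbsp;&nbsp;*A<sub>ij</sub>* = ⟨(*d<sub>ij</sub>* − ⟨*d<sub>ij</sub>*⟩)²⟩&nbsp;&nbsp;(Å²),

a superposition-free measure of internal flexibility: near-zero inside a
quasi-rigid domain, large across domains.

**Geometric strain.** Per residue,

&nbsp;&nbsp;&nbsp;&nbsp;*p<sub>i</sub>* = Σ<sub>j≠i</sub> *A<sub>ij</sub>* · *f*(⟨*d<sub>ij</sub>*⟩),&nbsp;&nbsp;*f*(x) = 1 / (1 + e^((x−5 Å)/0.5 Å)),

the deformation of the ~5 Å contact network; peaks mark hinges and
mechanically stressed sites.

**Quasi-rigid decomposition.** Residues are partitioned into *q* domains
minimising the rigid-fit error ε²: per frame and domain, the optimal
(Kabsch) rigid placement of the reference conformation onto the frame,
with full rotation matrices — no small-angle approximation. The search
is seeded from the essential dynamical space and refined by simulated
annealing plus block-reassignment sweeps. The *captured fraction*
1 − ε²/ε²(single body) says how much of the mean-square fluctuation
domain-relative rigid motion explains.

**Hinge axes.** A side domain's motion relative to a core domain is
restricted to pure rotation about one time-independent axis anchored on
a Cα; all Cα anchors × 500 uniformly sampled orientations are scanned,
per-frame angles are solved in closed form, and the best axis is refined
continuously.

## Worked example

```r
library(hingescan)

# a synthetic three-body molecule with two planted hinges
spec <- SyntheticSpec(c(60, 50, 70),
  hinges = list(list(moving = 1, core = 2),
                list(moving = 3, core = 2)),
  nFrames = 100, seed = 11)
gen  <- generateTrajectory(spec)
traj <- gen$trajectory

sp <- searchPartition(traj, q = 3, seed = 5)
sp$fit
#> RigidFitResult: q = 3  residualMsf = 3.402e-15 A^2
#>   captured fraction: 1  mean fit RMSD: 8.161e-08 A

axes <- fitAllHinges(traj, sp$partition, core = 2, seed = 9)
axes
#> HingeAxisSet: 2 axes about core domain 2
#>   combined captured fraction: 0.9998  mean RMSD: 0.01642 A
```

The fit recovers the planted partition exactly (residual at machine
precision, captured fraction 1), and restricting both side domains to
single fixed-axis rotations still reproduces the whole trajectory to
0.02 Å — the two rotation angles are the only time-dependent parameters
left. `strainProfile(traj)` puts the highest-strain residues at the
planted domain interfaces, and `scanQ(traj, 1:6)` shows the captured
fraction plateau at q = 3.

For real data: `loadTrajectory("traj.pdb")` (multi-model PDB; DCD or GRO
also supported), `distanceFluctuationMatrix()`, `strainProfile()`,
`buildMetaTrajectory()` with a residue-correspondence TSV
(`group_id protein_tag chain resid`), and `perSourceFitReport()` for
per-protein fit quality. A command-line interface is installed at
`exec/hingescan` with subcommands `pipeline`, `synth`, `dfmat`,
`strain`, `qrd`, `axisfit`, `metatraj`; residue selections use
`tag:<t> chain:<c> resid:<a>-<b>` terms, `|` for alternatives.

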