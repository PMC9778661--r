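---
title: "Dissecting GTPase switch-region ensembles: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting GTPase switch-region ensembles: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhotraj)
```

## The scientific problem

Small GTPases such as RhoA act as molecular switches: the GTP-bound form
interconverts between an *active* conformation, in which the switch I and
switch II loops close over the nucleotide, and *inactive* conformations in
which they open. The closed, active conformation is pinned by two highly
conserved hydrogen bonds from the GTP gamma-phosphate oxygens to the
backbone amides of a switch I threonine (T37 in RhoA numbering) and a
switch II glycine (G62). Constitutively activating mutations such as G14V
and Q63L shift the whole ensemble toward active-like conformations, tighten
nucleotide binding, and bury the catalytic site away from the water
molecules required for hydrolysis.

`rhotraj` implements the analysis layer used to characterize such
ensembles from molecular-dynamics trajectories: per-frame conformational
state classification, hydrogen-bond occupancy statistics, solvent-exposure
metrics of the nucleotide site, conformational clustering, fluctuation
profiles, a reduced secondary-structure assignment, and MM/GBSA energy
bookkeeping. Because real production trajectories are large and
system-specific, the package also ships a synthetic-trajectory generator
that plants known ground truth for every one of those observables; the test
suite validates each stage against that truth or against independent
closed-form and brute-force oracles.

## State classification

The classifier is hydrogen-bond based. For every frame the backbone amide
N-H of T37 and of G62 is tested as a donor against each gamma-phosphate
oxygen (O1G/O2G/O3G) under the geometric criterion below, and the frame is
labelled by the truth table

| T37 bond | G62 bond | label |
|---|---|---|
| yes | yes | `ACTIVE` |
| no | no | `INACTIVE_1` |
| no | yes | `INACTIVE_2` |
| yes | no | `INACTIVE_3` |

The two atom-pair distances d1 = Calpha(T37)-Pbeta and d2 =
Calpha(G62)-Pbeta are carried alongside as descriptive observables (the
literature describes the states by the intervals these distances fall
into), but they never drive the classification: the bonds define the
states, the distances annotate them. `INACTIVE_2` has not been observed in
RhoA ensembles; the classifier still supports it as a reachable label.

## Hydrogen-bond criterion

A bond between acceptor heavy atom A, donor hydrogen H and donor heavy
atom D is formed iff the A-D distance is **strictly** below 3.5 Å and the
angle **at the hydrogen** between A and D is strictly above 120°. Both
defaults are exposed as parameters (`hbond_criterion()`). Two conventions
deserve a note:

* the angle is measured at the hydrogen (A-H-D). Many tools quote the
  D-H...A angle; the vertex is the same atom, so the two are identical.
* when a donor carries several hydrogens, each is tested and the
  heavy-atom pair counts as bonded if any hydrogen satisfies the
  criterion, since occupancy tables are reported per heavy-atom pair.

Occupancy is the fraction of analysis-window frames in which a pair is
bonded; replicate means are arithmetic means of per-replicate fractions,
and the `high_occupancy()` filter keeps a pair when its mean exceeds the
threshold (75% by default) in *any* of the analysed systems. The
symmetric gamma-phosphate oxygens are reported per oxygen by default; the
characteristic-bond helpers collapse them into one any-oxygen test.

## Analysis windows

Production runs typically discard an equilibration prefix:
`analysis_window(traj, fraction)` keeps the trailing
`ceiling(fraction * n_frames)` frames. The default 0.6 mirrors analysing
the last 120 ns of 200 ns runs. Energies, occupancies, SASA and water
counts use the window; fluctuation profiles and clustering use full
trajectories. Both choices are plain parameters.

## Geometry: superposition, RMSD, RMSF

Rigid-body fits use the Kabsch least-squares rotation with the proper-
rotation correction (determinant +1 even for reflective configurations).
"Backbone" means CA, C, N exactly — the carbonyl O is excluded — and
mass-weighted RMSD uses sqrt(sum(m_i d_i^2)/sum(m_i)) with standard atomic
masses looked up from element symbols. RMSF aligns all frames to the first
frame, then takes the square root of the time-mean squared deviation from
the time-mean position per atom; per-residue values are mass-weighted
means over the residue's backbone atoms. With several replicates each run
is aligned and measured independently (per-run alignment) and the profile
reports the across-run mean and standard deviation.

For isotropic Gaussian jitter of width sigma per coordinate the RMSF has
the closed form sigma*sqrt(3); the suite recovers it to within 2% at
10,000 frames. A subtlety worth recording: aligning on the same atoms
whose fluctuations are measured absorbs six rigid degrees of freedom and
biases the recovered RMSF down by roughly 6/(2*3*N_atoms) in relative
terms (about 1% for the ~90-atom backbone used in the test) — well inside
the tolerance, but visible.

## SASA: LCPO with a Shrake-Rupley oracle

The production SASA path is the LCPO approximation (linear combination of
pairwise overlaps): per atom,
A = P1*S1 + P2*sum_j A_ij + P3*sum_jk A_jk + P4*sum_j A_ij sum_k A_jk,
with S1 the full probe-inflated sphere, A_ij pairwise buried areas, and
the P3/P4 sums running over neighbour pairs that are themselves
neighbours. Negative estimates are clamped to zero. Parameters are keyed
on element plus bonded-heavy-neighbour count (bonds inferred from
geometry at 1.9 Å, 2.0 Å when phosphorus or sulfur is involved), with
oxygen sub-typed into hydroxyl/ether/carbonyl/charged-phosphate rows. Two
deliberate extensions of the published table:

* an atom with no bonded heavy neighbour (an isolated atom, a water
  oxygen, a bare ion) has no published row; it gets P1 = 1, i.e. the
  exact isolated-sphere limit;
* elements outside the parameterized organic set (e.g. Mg) fall back to
  that same limit instead of erroring, since they appear only as
  occluders; atoms whose element has no radius at all still raise an
  error naming the atom.

The independent oracle is a Shrake-Rupley quadrature with a deterministic
golden-spiral point set (no randomness, so results are bitwise
reproducible). It reproduces the analytic isolated-sphere and two-sphere
closed forms to quadrature accuracy, and doubling the point count moves
totals by well under 1%. The oracle-vs-LCPO comparison is run on the
synthetic GTP-like molecule *in isolation* and with both algorithms on
the LCPO radius set, so that it isolates algorithmic error from radius-set
differences; agreement is within 10%. Inside the full complex LCPO
systematically overestimates deeply buried atoms — the linear overlap
model is weakest at extreme burial — which is a property of the method,
not of this implementation. Default radii for the numerical path are the
Bondi set with a 1.4 Å probe.

Catalytic-site solvation is measured by counting distinct water molecules
whose oxygen lies strictly within 3.0 Å of any gamma-phosphate atom (PG,
O1G, O2G, O3G); the site selection is configurable down to the Pgamma
atom alone. The reported GTP SASA is the nucleotide's area within the
complex, with the selection likewise configurable.

## Clustering

Frames (strided to one per 40 ps by default, pooled over replicates) are
superposed once onto the reference structure on all CA atoms; pairwise
RMSD over CA is then computed on the aligned coordinates without per-pair
refitting. This "one global alignment" reading matches the common
trajectory-analysis workflow; a per-pair refit mode is available behind a
flag. Average-linkage agglomeration is delegated to `stats::hclust` and
the dendrogram is cut at five clusters by default. `hclust` applies its
own deterministic tie-break rather than a lowest-frame-index rule; on
RMSD matrices of noisy trajectories exact ties have measure zero, and the
suite's exhaustive small-matrix oracle runs on generic (tie-free)
matrices. A cluster's representative ("middle") structure is the member
minimizing the mean RMSD to the other members.

## Secondary structure

A reduced Kabsch-Sander assignment: backbone hydrogen bonds are scored
with E = 0.084 * 332 * (1/d_ON + 1/d_CH - 1/d_OH - 1/d_CN) kcal/mol and
formed below -0.5 kcal/mol; two consecutive i→i+4 turns make an
alpha-helix run (H), two consecutive i→i+3 turns a 3-10 helix run (G),
and the Kabsch-Sander parallel/antiparallel bridge rules mark strands
(E); everything else is coil (C), with precedence H > G > E > C. The full
eight-letter alphabet (bends, turns, pi-helices) is intentionally out of
scope: propensity profiles over {H, G, E, C} are what the switch-region
comparison needs. Amide hydrogens are required; structures stored without
them can be protonated with the idealized bisector placement
(`add_amide_hydrogens()`, N-H 1.01 Å in the C(prev)-N-CA plane).

## MM/GBSA bookkeeping

The gas-phase molecular-mechanics terms and the GB polar solvation term
are *consumed* from per-frame tables, never computed — no force field is
in scope. The module combines them as dG = (dE_int + dE_ele + dE_vdw) +
(dG_pol + dG_nonpol) - TdS, derives the nonpolar term from SASA as
gamma*dSASA + b when not supplied (gamma = 0.0072 kcal/(mol Å^2), b = 0,
the common defaults of the cited scheme), and neglects entropy by default
while recording the term. Totals are means of per-replicate window means;
the SD is reported across replicate means, since the reported triple-run
deviations are of that small magnitude, with a pooled-frame mode behind a
flag. Per-residue decompositions are window means per replicate, sorted
by residue number with the Mg ion as its own row.

## The synthetic generator

`simulate_trajectory()` plants, per frame:

* a **state** drawn from a four-state Markov chain. The default chain is
  `persistence * I + (1 - persistence) * 1 pi^T` with stationary pi =
  (0.70, 0.20, 0.10, 0.00) and persistence 0.2 — a mixing chain whose
  one-step autocorrelation is the persistence, so 5000 frames recover the
  stationary law within ±0.02. Presets emulate the three studied systems
  qualitatively: `wt` INACTIVE_1-dominant with flexible switches, `g14v`
  ACTIVE-dominant and rigid, `q63l` INACTIVE_3-dominant;
* the **characteristic bond geometries**: the T37 and G62 amides are
  re-placed so the donor-acceptor distance follows Normal(2.9, 0.1)
  truncated above 3.4 Å when bonded (with an acceptor-H-donor angle drawn
  uniformly in 150-180°) and Normal(4.5, 0.3) truncated below 3.7 Å when
  broken — cleanly separated from the 3.5 Å / 120° criterion so detector
  and generator agree on every frame by construction. The whole residue
  shifts rigidly with its amide, which makes d1/d2 co-vary with the state
  as they do in real ensembles. In broken frames the donor is additionally
  kept at least 3.7 Å from *all three* gamma-oxygens so no surrogate
  acceptor can fake a bond;
* **isotropic jitter** on all other atoms with per-region sigma (P-loop,
  switch I, switch II, nucleotide, other; 0.35 Å unless overridden —
  backbone fluctuations of a stable fold);
* a **water shell**: a per-state Poisson count (ACTIVE 2, INACTIVE_1 5,
  INACTIVE_2 3, INACTIVE_3 3 — matching the reported roughly two/five/
  three waters for the mutant-active, wild-type and Q63L-like ensembles)
  of water oxygens placed strictly inside the 3.0 Å gamma-phosphate
  shell, the rest of the bath well outside; the counting stage must
  recover the planted integer exactly on every frame.

The single RNG stream is consumed in the fixed order states → bond
geometries → noise → waters. Bond-geometry values are *drawn* before the
noise but *applied* after it (placement must see the jittered acceptor);
drawing order, not application order, is what seed portability needs.
Waters are re-placed independently each frame — their identity carries no
dynamics — so water RMSF is meaningless in this generator, and no test
uses it.

The reference template is a reduced pseudo-complex, not a
stereochemically consistent protein: fragments of the P-loop (12-20),
switch I (32-42) and switch II (60-70) built as ideal extended strands,
a full heavy-atom GTP with correct bond topology, Mg with an exactly
hexahedral (six-oxygen) coordination shell at 2.0-2.2 Å (one oxygen from
each phosphate, T19 OG1, T37 OG1, V35 backbone O), and a ≥20-molecule
water bath. Side-chain atoms beyond CB are placed along
clearance-maximizing directions; a few atoms (the pinned Mg ligands) are
positioned by their role rather than by residue stereochemistry. What
passing tests show about real data is therefore limited to the *analysis*
layer: the geometry, detection, counting, clustering and bookkeeping code
paths are exercised under controlled truth, while force-field realism,
solvent structure and kinetics are explicitly not emulated.

## Problem sizes and numerical choices

The suite and the acceptance script run on one CPU in minutes: 5000-frame
chains for population recovery, 10,000 frames for the RMSF closed form,
960-point quadratures (3840 where a 1% closed-form comparison needs it),
100-500 frames for the brute-force oracle scans, and ≤8-frame matrices
for the exhaustive clustering oracle. Strict inequalities are used at
every geometric threshold (hydrogen-bond distance and angle, water-shell
cutoff, coordination cutoff), half-open bins `[lo, hi)` of 0.2 Å in the
distance histograms, and 1e-9/1e-12 tolerances on the algebraic
identities. Degenerate inputs raise informative errors: superposition
refuses fewer than three or collinear atoms, RMSF a single frame, the
centroid monitor a residue with no side-chain heavy atoms, and the
stationary distribution a reducible chain.

## A worked example

```{r example}
spec <- preset_spec("g14v", n_frames = 400, seed = 1)
sim <- simulate_trajectory(spec)
ss <- state_series(sim$trajectory)
round(state_populations(ss), 3)

at <- sim$trajectory$atoms
gammaO <- which(at$resname == "GTP" & at$name %in% c("O1G", "O2G", "O3G"))
occ <- hbond_occupancy(list(sim$trajectory),
                       which(at$resid == 37 & at$name == "N"),
                       gammaO, window = 0.6)
occ$mean

w <- water_count_summary(list(sim$trajectory), window = 0.6)
round(w$mean, 2)
```

An ACTIVE-dominant ensemble keeps the T37 characteristic bond formed in
nearly every frame and holds only about two waters in the catalytic
shell — the signature the analysis is built to detect.

## Known limitations

* LCPO overestimates deeply buried atoms inside the full complex (method
  property; the Shrake-Rupley path is available wherever accuracy beats
  speed).
* The Shrake-Rupley quadrature is exactly rotation-invariant only when
  its point set co-rotates with the frame; with the fixed laboratory
  point set, totals move by discretization error only.
* The DSSP reduction does not implement bends, turns, pi-helices or
  chirality; bridge detection requires at least three residues of
  separation.
* The synthetic generator controls ensembles and geometries, not physics:
  no force field, no kinetics beyond the Markov chain, no water dynamics.
* Trajectory I/O is multi-model PDB only; binary formats (DCD/XTC) are
  out of scope.
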