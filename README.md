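# rhotraj

Conformational-state and interaction analysis of small-GTPase
molecular-dynamics trajectories, in the style used to dissect the
constitutively activating RhoA mutants G14V and Q63L.

GTP-bound Rho-family GTPases interconvert between an **active** state, in
which the switch I and switch II loops close over the nucleotide, and
**inactive** substates in which they open. The active state is defined by
two conserved hydrogen bonds from the GTP gamma-phosphate oxygens to the
backbone amides of T37 (switch I) and G62 (switch II); losing one or both
bonds defines three inactive substates:

| T37 bond | G62 bond | state |
|---|---|---|
| + | + | ACTIVE |
| − | − | INACTIVE_1 |
| − | + | INACTIVE_2 |
| + | − | INACTIVE_3 |

`rhotraj` classifies every trajectory frame by that scheme (with the
d1 = Cα(T37)–Pβ and d2 = Cα(G62)–Pβ distances as descriptive observables)
and implements the surrounding analysis layer:

* geometric hydrogen-bond detection (A–D < 3.5 Å and A–H–D angle > 120°,
  strict) and occupancy statistics across replicates, with a 75%
  "formed in any system" filter;
* solvent-accessible surface area by the analytical **LCPO**
  approximation with a deterministic **Shrake–Rupley** quadrature as
  numerical oracle, plus catalytic-site water counting within 3.0 Å of
  the gamma-phosphate;
* Kabsch superposition, mass-weighted RMSD and per-residue RMSF profiles
  with replicate mean ± SD;
* average-linkage conformational clustering on pairwise CA RMSD with
  populations and "middle" (representative) structures;
* a reduced Kabsch–Sander secondary-structure assignment
  (E = 0.084·332·(1/d_ON + 1/d_CH − 1/d_OH − 1/d_CN), bond below
  −0.5 kcal/mol; labels H/G/E/C) and per-residue propensities;
* MM/GBSA bookkeeping per
  ΔG = (ΔE_int + ΔE_ele + ΔE_vdW) + (ΔG_pol + ΔG_nonpol) − TΔS with
  ΔG_nonpol = γ·ΔSASA + b, per-residue decomposition and replicate
  statistics (energy terms are consumed from tables, never computed);
* a **synthetic-trajectory generator** that plants a Markov state
  sequence, the two characteristic bond geometries, per-region
  fluctuation amplitudes and a gamma-phosphate water shell, so every
  analysis stage can be validated against known ground truth;
* a configuration-driven pipeline (`run_simulate` / `run_analyze` /
  `run_report`) with a thin CLI at `inst/scripts/rhotraj`.

Trajectories are read and written as multi-model PDB (via bio3d), one
frame per MODEL block.

## Worked example

Simulate an ACTIVE-dominant (G14V-like) synthetic ensemble and recover its
signature:

```r
library(rhotraj)

spec <- preset_spec("g14v", n_frames = 400, seed = 1)
sim  <- simulate_trajectory(spec)

ss <- state_series(sim$trajectory)
round(state_populations(ss), 3)
#>     ACTIVE INACTIVE_1 INACTIVE_2 INACTIVE_3
#>      0.948      0.015      0.000      0.038

at <- sim$trajectory$atoms
gammaO <- which(at$resname == "GTP" & at$name %in% c("O1G", "O2G", "O3G"))
hbond_occupancy(list(sim$trajectory),
                which(at$resid == 37 & at$name == "N"), gammaO,
                window = 0.6)
#>                  pair      rep1      mean
#> 1 THR37.N-O1G/O2G/O3G 0.9791667 0.9791667

round(water_count_summary(list(sim$trajectory), window = 0.6)$mean, 2)
#> [1] 2.07
```

The ensemble sits 95% in the ACTIVE state, keeps the characteristic
T37-amide-to-gamma-phosphate bond formed in 98% of analysis-window frames,
and holds about two waters in the catalytic shell — the solvent-occluded,
bond-locked signature of a constitutively active mutant. A wild-type-like
preset (`preset_spec("wt")`) instead yields an INACTIVE_1-dominant
ensemble with about five shell waters.

Reported reference values for the three RhoA systems (mean GTP SASA,
binding-free-energy totals and per-residue rows, cluster populations) ship
in `inst/extdata/rhoa_reference_values.tsv`:

```r
vals <- read.delim(system.file("extdata", "rhoa_reference_values.tsv",
                               package = "rhotraj"))
sasa <- vals[vals$quantity == "mean_gtp_sasa", ]
round(percent_decrease(sasa$value[sasa$system == "wt"],
                       sasa$value[sasa$system == "g14v"]))
#> [1] 32
bfe_difference(-227.08, -262.51)
#> [1] 35.43
```

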