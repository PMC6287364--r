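# acidbridge

Salt-bridge guided design of acid-stable peroxidase variants.

Lignin peroxidases do their best chemistry below pH 3 — and unfold there
within minutes. Their acid-tolerant relatives, manganese peroxidases,
survive pH 2 in part because of surface salt bridges that persist at high
proton concentrations. `acidbridge` implements the in-silico workflow for
moving that protection onto an acid-labile scaffold: survey the donor's
salt bridges with a pH-aware geometric criterion, map them onto the
acceptor through sequence alignment and rigid superposition, graft the
donor's charged residue types at positions where the acceptor cannot form
the bridge, score each candidate's pH-dependent folding free-energy
change, and classify it with the ±0.5 kcal/mol rule. The package also
carries the downstream validation fits (first-order inactivation
half-lives, Hanes–Woolf Michaelis–Menten kinetics) and synthetic-data
generators with known ground truth so every stage is testable offline.
It is aimed at protein engineers and structural bioinformaticians
prototyping electrostatics-guided stabilization campaigns.

## The model in brief

**Salt bridge.** A positively charged side-chain nitrogen (Lys NZ, Arg
NH1/NH2, doubly protonated His ND1/NE2) within 4.0 Å (closed bound) of a
carboxylate oxygen (Glu OE1/OE2, Asp OD1/OD2); one bridge per residue
pair. On an ensemble, occupancy = fraction of frames the criterion holds.

**Protonation.** Henderson–Hasselbalch charges from effective pKas
computed by a self-consistent mean-field scheme: model pKa + Born-type
burial shift (±1.5 pKa units × burial) + screened Coulomb shifts
(−Σ q·332/(20·r) / (ln10·RT)) from the other sites.

**pH-dependent stability (Wyman linkage).**

    ΔG_unfold(pH₂) − ΔG_unfold(pH₁) = −RT ln10 ∫ [Q_U(pH) − Q_F(pH)] dpH

with Q the net-charge (proton-binding) isotherm of the unfolded (model
pKas) and folded (effective pKas) states.

**Mutation score.** ΔΔG_mut = Wyman term (wt − mutant, pH 7 → 2.5) −
1.0 kcal/mol per bridge gained + 5.0 kcal/mol per steric clash; negative
is stabilizing; classification thresholds at ±0.5 kcal/mol.

**Kinetics.** t½ = ln 2 / kd from OLS of ln(activity) on time;
Hanes–Woolf (S/v on S) for KM and kcat; efficiency kcat/KM in s⁻¹·mM⁻¹.

## Worked example

```r
library(acidbridge)

# a synthetic acid-stable donor with three planted bridges, and an
# acceptor that already has one of them
donor <- make_toy_structure(n_residues = 40, planted_pairs = data.frame(
  basic = c("ARG", "LYS", "ARG"), acidic = c("GLU", "ASP", "GLU"),
  distance = c(3.5, 3.2, 3.8)))
acceptor <- make_toy_structure(n_residues = 40, planted_pairs = data.frame(
  basic = "ARG", acidic = "GLU", distance = 3.5))

report <- run_design_pipeline(donor, acceptor, design_config(target_ph = 2.5))
report
#> <design_report: 3 donor bridges; 1 conserved, 2 incompatible, 0 unmappable; 2 candidates>
report$candidates
#>   candidate mutations n_new_bridges    ddg_mut      effect
#> 1 A10K/A12D A10K/A12D             0 -0.6840915 stabilizing
#> 2 A18R/A20E A18R/A20E             0 -0.3411491     neutral
```

One donor bridge is already present in the acceptor (conserved); the two
missing ones become grafting candidates, of which one clears the
−0.5 kcal/mol stabilization threshold at pH 2.5.

Kinetics side, from measured steady-state constants:

```r
catalytic_efficiency(kcat = 10.0, km = 121.0)   # native enzyme
#> [1] 82.64463
catalytic_efficiency(kcat = 9.4, km = 59.8)     # best combined variant
#> [1] 157.1906
# a 1.9-fold gain in kcat/KM at pH 2.5

fit <- fit_first_order_decay(simulate_decay(half_life = 117.7,
                                            timepoints = seq(0, 480, 30),
                                            noise_sd = 0.03, seed = 1))
fit
#> <decay_fit: kd 0.005922 /min, t1/2 117 min, R2 0.9989>
```

The numbered scripts under `analysis/` run the same stages as a narrative
workflow (01 synthetic scaffolds → 02 titration + bridge survey →
03 design pipeline → 04 flexibility metrics → 05 kinetics tables),
writing tables and PDB files to `results/`.

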