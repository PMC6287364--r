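---
title: "Designing acid-stable peroxidase variants by homologous salt-bridge grafting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing acid-stable peroxidase variants by homologous salt-bridge grafting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acidbridge)
```

## The problem

Lignin peroxidases (LiP) depolymerize lignin most effectively below pH 3,
where the redox potential of the enzyme and the stability of substrate
radical cations are highest — but the enzymes themselves unfold and
inactivate within minutes under those conditions. Homologous manganese
peroxidases (MnP) from the same fold family remain active at pH 2. A large
part of that difference is electrostatic: surface salt bridges that survive
high proton concentrations hold the MnP scaffold together. This package
implements an in-silico workflow for transplanting that protection onto an
acid-labile acceptor scaffold:

1. assign pH-dependent protonation states to the donor structure;
2. survey its salt bridges, on the crystal structure and/or across a
   conformational ensemble (persistence = occupancy);
3. align and superpose donor and acceptor, and map each donor bridge onto
   the acceptor scaffold;
4. at positions where the acceptor cannot form the bridge, graft the donor
   residue types, score the mutation's pH-dependent folding free-energy
   change, and keep candidates classified as stabilizing;
5. validate variants downstream with first-order inactivation (half-life)
   and Michaelis–Menten (Hanes–Woolf) kinetics fits.

## The salt-bridge criterion

A salt bridge is called when a positively charged side-chain nitrogen
(Lys NZ; Arg NH1/NH2; His ND1/NE2 in the doubly protonated imidazolium
form) lies within 4.0 Å of a carboxylate oxygen (Glu OE1/OE2, Asp
OD1/OD2). The bound is closed (≤ 4.0), distances are between heavy atoms
exactly as named, and hydrogens are ignored throughout. Bridges are
counted at residue-pair level: a bidentate Arg–Glu contact is one bridge,
annotated with its minimum atom distance. Histidine only counts as a donor
when its charge at the working pH is at least +0.5, i.e. when the
imidazolium form dominates; with no titration model supplied the solution
pKa (6.3) decides, so His donates at pH 2.5 and not at pH 8.

On an ensemble, the criterion is evaluated per frame and each residue pair
reports the fraction of frames in which it holds. The persistence
threshold for calling a bridge "present" is not pinned down by any
published convention we know of; the default is majority persistence
(occupancy ≥ 0.5), configurable down to 0 (union over frames). Both modes
are exposed because bridge counts quoted for trajectories in the
literature rarely state which rule was used.

## The titration model

Protonation states come from a deliberately simple, openly documented
mean-field model rather than a continuum-electrostatics solver. Each
titratable site (Asp 4.0, Glu 4.4, His 6.3, Lys 10.4, Arg 12.0, Tyr 9.6,
free Cys 8.3, N-terminus 7.5, C-terminus 3.8 — solution model pKas) gets:

* a **burial (Born) shift**: burial `b` is the heavy-atom neighbour count
  within 9 Å of the site's charged-atom centroid, mapped linearly from
  15 (surface) to 40 (buried) onto [0, 1]; acids shift up and bases down
  by `born_scale * b` with `born_scale` = 1.5 pKa units. Desolvation
  destabilizes the charged form of either polarity, which is exactly this
  sign pattern.
* a **charge–charge shift**: `-sum_j q_j * 332 / (eps_eff * r_ij)` kcal/mol
  converted to pKa units by `ln(10) R T`, with partner charges `q_j`
  evaluated at the target pH (default 2.5) from the current effective
  pKas, a uniform screening dielectric `eps_eff` = 20, and centroid
  distances in Å. The scheme iterates to self-consistency (tolerance 0.01
  pKa units, cap 50 iterations; non-convergence is flagged, not hidden).

Cysteine pairs with SG–SG distance under 2.3 Å are treated as disulfides
and excluded. All constants live in `titration_config()`; the defaults are
ordinary textbook values, and the model is validated by its limiting
behaviour (isolated site = model pKa; fully buried acid = model + 1.5; an
adjacent protonated base lowers an acid's pKa by the screened-Coulomb
amount) rather than against any particular solver's output.

Charges close through Henderson–Hasselbalch: θ = 1/(1+10^(pH−pKa)), acid
charge −(1−θ), base charge +θ. The net charge Q(pH) is the proton-binding
isotherm; it is monotone non-increasing by construction.

## pH-dependent stability and the mutation score

The pH dependence of unfolding free energy follows the Wyman linkage
relation: the change of ΔG_unfold between two pH values is
−RT ln10 ∫ [Q_unfolded − Q_folded] dpH. The unfolded reference uses the
model pKas with no environmental shifts — the standard null model for this
kind of calculation. The integral uses composite Simpson quadrature on a
grid of step ≤ 0.01 pH units; against the one-site closed form it agrees
to better than 1e−4 kcal/mol, and it is antisymmetric and additive over
adjacent intervals to quadrature tolerance.

The mutation score is

```
ddG_mut = [dG_unfold(wt) − dG_unfold(mut)]  (Wyman terms, reference pH 7 → target pH 2.5)
          − 1.0 kcal/mol × (bridges gained − bridges lost)
          + 5.0 kcal/mol × clashes introduced
```

negative = stabilizing. The classification rule is the one the wet-lab
selection used: stabilizing below −0.5 kcal/mol, neutral in [−0.5, +0.5],
destabilizing above. We stress that the energy engine is a stand-in with
the right pH-dependent *structure*, not a reimplementation of any
commercial force-field pipeline: published per-variant ΔΔG magnitudes from
such engines are used in the test suite only to check the classifier's
thresholds, never as regression targets for this score. The bridge bonus
(1 kcal/mol) is at the low end of measured surface salt-bridge
contributions; the clash penalty (5 kcal/mol) is simply large enough to
disqualify a sterically impossible graft.

## Homology mapping

Sequences are aligned with a global Needleman–Wunsch/Gotoh affine-gap
aligner (BLOSUM62, gap open 10, extend 0.5, end gaps penalized; a gap of
length L costs open + L·extend). Identity and similarity percentages use
all alignment columns including gaps as denominator — the EMBOSS-needle
convention — because that is the convention behind the published
identity/similarity figures for this enzyme pair; the numbers are
convention-sensitive and are treated as informational. Structures are
superposed with a Kabsch (SVD) least-squares fit on the Cα atoms of
aligned columns with both residues present, reflection-corrected so
det(R) = +1; the test suite cross-checks it against an independent
quaternion (Horn) implementation to 1e−8.

Donor bridges map through the alignment, not through 3D proximity:
deterministic, testable, and correct whenever the scaffolds truly share an
architecture (Cα RMSD below ~1 Å), which is the regime this workflow is
for. A mapped pair is *conserved* if the acceptor already has a
positive-type and a negative-type residue at the two positions,
*incompatible* otherwise (the offending sides become mutation targets),
and *unmappable* if either position falls in a gap column — the three
calls always partition the donor bridge set.

Mutant structures are built by minimal side-chain grafting: the residue is
renamed, the side chain truncated to CB, and the charged atoms placed
along the CA→CB direction at canonical distances from CA (Arg guanidinium
N 4.1 Å, Lys NZ 4.7 Å, His ring N 3.6 Å, Asp carboxyl O 2.9 Å, Glu
3.9 Å). No rotamer search is attempted: only charged-atom geometry enters
the criterion, and a graft whose idealized direction cannot reach the
partner is exactly the situation the bridge-count term should not reward.

## The synthetic generators

Everything above is testable without downloads because the generators
plant known ground truth:

* **Toy structures** are ideal poly-alanine α-helices (rise 1.5 Å, 100°
  twist, Cα radius 2.3 Å) in which selected residue pairs become charged
  types with the basic side chain on its canonical CA→CB ray and the
  acidic partner's carboxylate placed so the minimum N–O distance equals
  the requested target exactly. Planted pairs are spaced 8 residues apart
  so they cannot interfere. What this emulates: arbitrary numbers of
  bridges at controlled distances around the 4.0 Å boundary. What it does
  not: real rotamer distributions, backbone irregularity, buried networks
  — so passing tests certify the *criterion logic*, not detection
  performance on distorted real side chains.
* **Jittered ensembles** displace every atom by i.i.d. isotropic Gaussian
  noise (per-residue σ), giving closed forms the flexibility metrics must
  reproduce: per-residue RMSF → σ√3, mean backbone RMSD (without fitting)
  → σ√3. Real MD has correlated, anisotropic motions; these ensembles
  validate the estimators, not any physics.
* **Decay and rate tables** draw multiplicative Gaussian noise
  (spectrophotometric error scales with signal) around exact first-order
  and Michaelis–Menten curves. The default Michaelis–Menten design mirrors
  the veratryl-alcohol assay: substrate 50–2000 µM, enzyme 0.02 µM.

All generators are pure functions of their arguments and one integer seed;
the same seed gives byte-identical output and no global RNG state leaks.

## Kinetics conventions

Inactivation fits regress ln(residual activity) on time (minutes);
kd = −slope and t½ = ln 2/kd, an identity the fit object maintains to
machine precision. A non-negative slope is flagged "no decay" with t½ = ∞
rather than a spurious number. The Michaelis–Menten estimator is the
Hanes–Woolf linearization — S/v regressed on S, slope 1/Vmax, intercept
KM/Vmax, unweighted OLS — because that is the estimator the reference
assays used; a nonlinear `nls` fit started from the Hanes–Woolf estimates
rides along as a cross-check only. Catalytic efficiency is reported in
s⁻¹·mM⁻¹ (kcat/(KM/1000) with KM in µM). Beer–Lambert conversion of
absorbance slopes uses extinction coefficients in mM⁻¹cm⁻¹ (36.7 for
oxidized ABTS at 420 nm, 9.3 for veratraldehyde at 310 nm, 168 for the
heme Soret band at 409 nm). Times are minutes for decay and seconds for
rates; the unit fields are explicit to prevent silent mixing.

The crystal-packing utility implements the Matthews relation: cell volume
from the general triclinic formula, VM = V/(Z·mass), solvent fraction
1 − 1.66·v̄/VM with v̄ = 0.74 cm³/g for protein. Published solvent
contents for one and the same crystal occasionally disagree between a
report's text and its statistics table because they were computed at
different refinement stages with different masses; the utility computes
the relation and leaves such discrepancies alone.

## Numerical choices and degenerate inputs

* Altloc policy `keep-first` retains, per atom name, the highest-occupancy
  alternate location (ties broken by altloc letter) — deterministic
  single-conformer geometry for bridge detection; `keep-all` is available.
* Waters and ligands are parsed and kept but excluded from every geometric
  operation; the criterion concerns protein side chains only.
* Residue numbering is taken verbatim from the PDB; no renumbering, gaps
  allowed.
* "Within 4.0 Å" is closed (≤); the boundary is covered by tests.
* Coincident titratable-site centroids clamp pairwise distances at
  1e−3 Å instead of dividing by zero.
* Empty structures, mismatched ensemble topologies, coordinates exceeding
  the PDB fixed-width field, non-positive activities, fewer than three
  substrate levels, and collinear superposition inputs all raise distinct
  errors rather than propagating nonsense.

## Problem sizes

The shipped tests and the acceptance script run the whole pipeline on toy
helices of 30–60 residues, ensembles of 50–500 frames, 100-structure
random detection sweeps, and 200-seed Monte-Carlo recovery checks — sizes
chosen so the complete validation battery runs in well under a minute on
one core while still exercising every code path at meaningful statistical
resolution (e.g. a 500-frame RMSF estimate has ~3% sampling error against
its σ√3 target, inside the 5% test band).

## Known limitations

* The titration model is mean-field with a uniform dielectric; it captures
  sign and order of magnitude of environmental pKa shifts, not
  site-specific accuracy. ΔΔG values it produces are rankings, not
  calorimetric predictions.
* Grafted side chains are idealized rays; a real design round would follow
  with rotamer optimization and a physics-based ΔΔG engine on the
  shortlist this pipeline produces.
* Sequence-based position mapping inherits alignment errors in low-identity
  regions; a 3D-proximity mapping mode would be the natural extension.
* The flexibility metrics are estimators only; absolute RMSD/RMSF values
  from real trajectories depend on simulation settings this package does
  not model.
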