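---
title: "Comparing dimer binding tightness with restrained Monte Carlo and constant-force pulling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing dimer binding tightness with restrained Monte Carlo and constant-force pulling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Cytosolic phosphoglucose isomerase (PgiC) functions as a dimer whose
catalytic centres are built from residues of both monomers, so the
tightness of the inter-monomer binding is directly tied to function.
When a grass genome carries two PgiC loci — a native copy and a
horizontally transferred one — three dimers can form: two homodimers and
a heterodimer. `dimermc` implements a desk-scale version of the
computational protocol used to compare such dimers: native-state Monte
Carlo (MC) ensembles under a backbone-RMSD restraint, constant-force
pulling simulations summarised by first-passage dissociation times, and
ensemble-level interface analytics (contacts, typed interactions, a
contact-based binding-affinity model, solvent-accessible surface area,
secondary structure), with the statistical comparisons used to rank the
dimers.

The package deliberately separates three layers:

1. **Structure layer** (`read_dimer_pdb`, `monomer_structure`,
   `backbone_rmsd`, `central_calpha`, `min_image_distance`): two-chain
   all-atom or reduced structures in a periodic cubic box.
2. **Simulation layer** (`build_energy_model`, `run_native_ensemble`,
   `run_pulling`): Metropolis MC over a declared native-contact
   (Gō-type) stand-in energy with two bespoke terms — the monomer-wise
   backbone-RMSD restraint and the constant pulling force.
3. **Analysis layer** (`interface_profile`, `sasa`,
   `secondary_structure`, `fit_two_state`, `anova_tukey`,
   `kruskal_wilcoxon`, `bootstrap_se`): per-conformation metrics,
   ensemble averages with run-aware standard errors, and the
   ANOVA/Tukey and Kruskal–Wallis/Wilcoxon comparison pipelines.

## The energy model

The published protocol runs an all-atom implicit-solvent force field
(`E = E_loc + E_ev + E_hb + E_sc`) that is defined in its own
literature and is out of scope here. `dimermc` replaces it with a
**native-contact (Gō-type) stand-in**: every site pair within 8 Å in
the reference structure (the default native cutoff, a common choice for
Cα-level Gō models) contributes a 12–10 well

$$V(r) = \varepsilon\left[5\left(\tfrac{r_0}{r}\right)^{12} -
6\left(\tfrac{r_0}{r}\right)^{10}\right],$$

with its minimum $-\varepsilon$ at the reference distance $r_0$; all
other pairs interact through a short-range $r^{-12}$ repulsion
(excluded volume radius 4 Å). Sites are the structure's atoms, so a
Cα-only structure yields a Cα-level model. Three well-depth classes
matter:

* `eps_bond` (default 10 kcal/mol) — covalent-like pairs: atoms of the
  same residue and Cα atoms of adjacent residues. These are deep so
  that chain connectivity and side-chain attachment never rupture
  before genuine non-bonded contacts; early experiments without this
  class showed an unphysical failure mode in which the pulled anchor
  atom (or a planted side-chain atom) tore out of its monomer at a
  rate independent of interface strength.
* `eps_intra` (default 2 kcal/mol) — non-bonded intra-monomer contacts.
* `eps_inter` (default 1 kcal/mol; the synthetic generators scale it) —
  inter-monomer contacts, the quantity the pulling experiments probe.

Two bespoke terms complete the energy, both taken directly from the
protocol being reproduced:

* **Backbone-RMSD restraint**: `k_rmsd * (RMSD_A + RMSD_B)`, each
  monomer's backbone RMSD from the reference computed after its own
  optimal superposition (Kabsch), so rigid motions — including the
  relative reorientation of the monomers — cost nothing. The
  coefficient is not printed in the source protocol; the default
  `k_rmsd = 10` kcal/mol/Å was calibrated once so that unforced
  toy-dimer backbone RMSD fluctuates at 1–2 Å, and is exposed in the
  model configuration.
* **Constant pulling force**: the term couples the distance between the
  two central Cα atoms (each the Cα closest to its monomer's
  mass-weighted centre of mass; ties broken by lowest residue index).
  As printed, the added term reads $F\,|x_1 - x_2|$, yet the
  description is of equal and opposite forces pulling the monomers
  *apart*; a positive term of that form would penalise separation, so
  the package implements the separation-favouring sign
  ($-F\,|x_1-x_2|$) by default and exposes `pull_sign` to flip it.
  Unit conversion is computed from constants:
  1 pN·Å = 0.014393 kcal/mol.

Temperature enters through $k_BT$ computed from CODATA constants
(0.5962 kcal/mol at the default 300 K), never hard-coded.

## The MC protocol

One MC cycle is one attempted move per degree of freedom: a Cartesian
displacement per site (default amplitude 0.3 Å per axis) plus four
rigid-body slots (translation and rotation of each monomer; defaults
0.5 Å and 0.08 rad). The published protocol moves torsional degrees of
freedom instead; the cycle definition is kept, with the move-slot count
of this move set as the degree-of-freedom count — a declared deviation.
Rigid-body moves are what allow the relative reorientation and
eventual dissociation of the monomers.

Energies are updated incrementally per move; every `check_stride`
cycles (default 1000) the decomposition is recomputed from scratch and
the absolute drift recorded — the suite asserts it stays below
1e-6 kcal/mol. Randomness comes from R's RNG; per-run streams are
derived from `(master seed, run index)`, so a master seed reproduces
every run bit-for-bit.

Protocol defaults mirror the published study: 300 K, 120 Å periodic
cubic box, 500,000 cycles per run, 200,000 discarded as burn-in, 3,000
evenly spaced snapshots per run (stride 100), 24 independent runs, and
pulling at 368 pN with dissociation declared when the central-Cα
distance D_ca (minimum image) first exceeds 41 Å. The D_ca plateau
after dissociation emerges from the periodic box (at
$\sqrt{3}/2 \times 120 \approx 104$ Å) and is not hard-coded. The worked
examples and tests scale the cycle counts and system sizes down to
desk scale; the protocol logic is unchanged.

## Interface analytics

* **Contacts**: residues from opposite monomers are in contact when any
  heavy-atom pair lies within 5.5 Å. The implementation uses a cell
  list; tests compare it against an O(n²) scan.
* **Interaction typing** (the published analysis delegates to an
  external package without printing rules, so these geometric rules are
  this package's own, all exposed in `interaction_rules()`): hydrogen
  bond = donor–acceptor heavy atoms within 3.5 Å (donor–H…acceptor
  angle ≥ 120° when hydrogens exist), counted per atom pair; ionic =
  oppositely charged side-chain N/O within 4.0 Å, counted per residue
  pair; hydrophobic = side-chain carbons of apolar residues within
  5.0 Å, counted per residue pair (atom-pair counting available as a
  config switch); cation–π = cationic nitrogen within 6.0 Å of an
  aromatic ring centroid, offset ≤ 60° from the ring normal when a
  plane is defined.
* **Binding affinity**: the linear contact-based model
  `dG = Σ w_k IC_k + w_a NIS_apolar% + w_c NIS_charged% + w_0` with
  interface contacts classified by the charged/polar/apolar classes of
  the partners and non-interacting-surface (NIS) percentages from
  per-residue relative SASA (≥ 5% exposure, non-interface). The
  coefficients ship as a versioned data block
  (`affinity_coefficients`), not code.
* **SASA**: Shrake–Rupley with 960 golden-spiral points per atom,
  probe 1.4 Å, ProtOr-style element radii; apolar SASA is the
  carbon-plus-sulfur share (a common convention; the source text does
  not define it). Totals are reported in nm², per-residue values in Å².
* **Secondary structure**: a simplified DSSP-style assignment — amide
  hydrogens rebuilt from the preceding carbonyl, Kabsch–Sander
  electrostatic H-bond energy with the −0.5 kcal/mol threshold, helix
  from consecutive i→i+4 (H) or i→i+3 (G) turns, strand (E) from
  parallel/antiparallel bridge patterns. It is a declared stand-in for
  STRIDE, intended for fraction-level comparisons, with the
  helix-label set a parameter (default {H, G}).

Residue chemistry uses a fixed three-class table (charged D,E,K,R,H;
polar N,Q,S,T,Y; apolar the rest), matching the interface classes of
the contact-based affinity model; it is a single replaceable constant.

## Dissociation kinetics and statistics

`fit_two_state` follows the protocol exactly: the rate is **not**
fitted to the empirical dissociation fraction `P(t)`; it is the inverse
of the mean observed dissociation time. `P(t)` is the pooled fraction
of runs dissociated by time `t`, with censored runs never counted.
`exponentiality_check` turns the qualitative claim that P(t) looks
exponential into a test: a one-sample KS statistic whose p-value is
calibrated by parametric simulation (the rate is estimated from the
same data, so the plain KS null would be wrong). A censoring-aware
exponential MLE is provided because desk-scale runs may be shorter than
every dissociation event.

Group comparisons use one value per independent run — never pooled
snapshots, which are autocorrelated within a run. ANOVA with Tukey's
range test is the parametric branch; Kruskal–Wallis with pairwise
Wilcoxon signed-rank tests (Holm correction by default; the source
protocol names no correction) is the nonparametric branch, gated by
Shapiro–Wilk and a median-centred Levene check at α = 0.05, each branch
also available unconditionally. Bootstrap standard errors of medians
use 10,000 resamples by default and are seeded. Significance stars
follow the `*`/`**`/`***` convention at 0.05/0.01/0.001, with boundary
values assigned to the less significant label.

## Synthetic study systems

The generators produce every input the pipeline needs, with exact
ground truth:

* `make_toy_dimer(n, interface_spec(h, i, b))` builds two ideal
  α-helical Cα traces (rise 1.5 Å, radius 2.3 Å, 100°/residue) facing
  each other across a gap, with single pseudo side-chain atoms planted
  on an interface grid: Ser OG pairs at 3.0 Å (hydrogen bonds), Lys
  NZ/Glu OE1 at 3.8 Å (ionic), Leu CD1 pairs at 4.0 Å (hydrophobic).
  Ionic pairs sit at 3.8 Å — inside the 4.0 Å ionic window but outside
  the 3.5 Å hydrogen-bond window — so planted types never contaminate
  each other; an earlier midpoint placement (3.5 Å) made every salt
  bridge double-count as a hydrogen bond. Slots are one helix turn
  apart on the y = 0 grid, which keeps every cross-slot atom pair
  beyond the 5.5 Å contact cutoff: the planted pair list *is* the
  contact ground truth. Slots are centred on the helix midpoint so the
  interface faces the central-Cα anchors; with a corner-placed
  interface the monomers can scissor open around an intact contact and
  cross the D_ca threshold without unbinding, which an early version
  of the generator exhibited.
* `make_dimer_series` scales planted pair counts and well-depth scales
  with strictly increasing strength factors — the weak/medium/strong
  binding series whose recovery is the package's qualitative
  acceptance bar.
* `perturb_ensemble` (i.i.d. Gaussian coordinate noise) stands in for
  native-state snapshots when testing ensemble analytics without MC.
* `make_sequence_pair` plants substitutions at known positions;
  `synthetic_pgic_pair` is a deterministic 567-residue stand-in for the
  real PgiC1/PgiC2 pair, differing at exactly the 20 published
  positions, with charged residues in the second sequence at 466 and
  521 as published. It is labelled synthetic because the true GenBank
  records are not bundled; residue identities outside those constraints
  are arbitrary, so only position-level conclusions transfer.

What the toys do **not** emulate: real side-chain packing, the
all-atom force field, sequence-dependent folding, or absolute numbers
of contacts and energies. Passing tests therefore demonstrate that the
protocol logic (restraint, pulling, first-passage analysis, ordering
recovery, statistics) is implemented correctly — not that desk-scale
simulations reproduce the published absolute values, which required
cluster-scale sampling of homology-modelled full-size dimers.

## Choosing the pulling study conditions

The 368 pN default is a compromise by design: strong enough that every
run dissociates within a manageable cycle budget, weak enough that the
dimer first survives as a bound complex for an appreciable time. The
same design question reappears at desk scale, with an extra subtlety: a constant force of 368 pN pulls
with 5.3 kcal/mol/Å, so an interface whose maximum restoring force is
below that slides apart deterministically (narrow, drift-dominated
dissociation times), while the two-state picture presumes an activated,
rare event. The package's study conditions therefore use two deliberately
different corners of that design space:

* **Kinetics dimer** (`make_toy_dimer(12, interface_spec(1, 0, 1))`
  with inter-monomer wells of ~5.5 kcal/mol at 368 pN): two deep
  contacts whose combined restoring force well exceeds the pull, so
  dissociation is a rare activated event. Here the dissociation-time
  coefficient of variation approaches 1 and the calibrated
  exponentiality check accepts the two-state model at n = 200. A
  single contact is not enough — one anchoring point lets the monomers
  rotate apart thermally — and shallow wells put the system in the
  drift regime below.
* **Ordering series** (`run_protocol()`: a 30-residue dimer with a
  3 hydrophobic / 1 ionic / 2 hydrogen-bond interface, well depths
  scaled by strength factors 0.8/1.0/1.2 around ~1 kcal/mol at fixed
  architecture): the combined restoring force stays below the pull, so
  every run dissociates quickly with a tight, strength-ordered mean —
  ideal for recovering the weak/medium/strong ordering with separated
  bootstrap confidence intervals. Scaling the pair *counts* instead
  would cross the drift/activated boundary mid-series, where the mean
  dissociation time jumps by orders of magnitude and runs start
  censoring (the generator supports both modes; `scale_counts = FALSE`
  is the protocol default for exactly this reason).

These choices were made on the physical grounds above and are stated
here once; the acceptance experiments run at these defaults.

## Numerical choices and degenerate inputs

* Kabsch superposition uses SVD with the reflection guard in R, and an
  equivalent quaternion (QCP-style) path in the compiled MC inner loop;
  both are tested against a grid-plus-refine brute-force minimiser.
* Contact, SASA and secondary-structure computations are exact
  functions of coordinates: no RNG.
* Degenerate statistics inputs are defined, not errors: identical
  groups give omnibus p = 1; constant values give bootstrap SE 0; a
  single snapshot reports a missing SE; all-censored pulling input is a
  distinct error ("no dissociation observed") mapped to exit status 3
  at the command layer.
* PDB output is a minimal ATOM/TER/END dialect with 3-decimal
  coordinates; reading rejects altloc codes other than blank/'A' and
  skips HETATM and non-standard residues with a message. Round-trips
  are exact at PDB precision.
* Boundary p-values at 0.05/0.01/0.001 take the less significant star.

## Known limitations

* The Gō-type stand-in cannot produce absolute energies, SASA values or
  contact counts comparable to the all-atom published numbers; only
  relative, qualitative conclusions (orderings, significance patterns)
  are meaningful, and that is the level at which the package's
  acceptance suite operates.
* The secondary-structure assignment approximates DSSP/STRIDE; π
  helices are not assigned, and bridge detection uses the standard
  patterns only.
* The desk-scale problem sizes used in the tests and the acceptance
  script (toy dimers of 20–40 residues per monomer, 24 runs, cycle
  budgets of 10⁴–10⁵) were chosen as the package's own study
  conditions; they exercise every code path of the full protocol.
* Sequence comparison requires equal-length inputs by design (the
  study pair is equal-length); there is no alignment step.
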