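# dimermc

Monte Carlo analysis of protein dimer binding tightness.

`dimermc` compares the inter-monomer binding of two-chain protein
dimers the way a biophysical simulation study would: it samples
native-state conformational ensembles with Metropolis Monte Carlo under
a backbone-RMSD restraint, probes mechanical resistance with
constant-force pulling simulations analysed as a first-passage problem,
and profiles the dimer interface conformation by conformation —
heavy-atom residue contacts (5.5 Å rule), geometrically typed
interactions (hydrogen bonds, hydrophobic, ionic, cation–π), a linear
contact-based binding-affinity model with non-interacting-surface
terms, Shrake–Rupley solvent-accessible surface area, and a
hydrogen-bond-based secondary-structure assignment. A statistics layer
implements the comparison protocol: one-way ANOVA with Tukey's range
test, Kruskal–Wallis with corrected pairwise Wilcoxon tests, bootstrap
standard errors of medians, and the star significance convention.

The motivating system is the pair of cytosolic phosphoglucose
isomerase (PgiC) loci in sheep fescue — a native *PgiC1* and a
horizontally transferred *PgiC2* — whose products form two homodimers
and a heterodimer. Because the enzyme's catalytic centres are built
from both monomers, binding tightness is the biophysically meaningful
comparison between them.

## The model in brief

The simulation energy is a native-contact (Gō-type) stand-in: site
pairs within 8 Å in the reference structure get a 12–10 well

    V(r) = eps * [5 (r0/r)^12 − 6 (r0/r)^10]

centred at the reference distance, all other pairs a short-range
repulsion, plus the two terms of the study protocol:

* a restraint `E = k_rmsd (RMSD_A + RMSD_B)` on the monomer-wise
  optimal-superposition backbone RMSD, which keeps monomers native-like
  while leaving rigid-body motion free, and
* a constant pulling term coupling the two central Cα atoms (the Cα
  nearest each monomer's centre of mass) with force `F`
  (1 pN·Å = 0.014393 kcal/mol), used to measure the dissociation time
  `t_dis`: the first MC cycle at which the anchor distance `D_ca`
  (minimum image, 120 Å periodic box) exceeds 41 Å.

Dissociation kinetics are summarised by the two-state model
`P(t) = 1 − exp(−λ t)` with `λ = 1 / mean(t_dis)` — the rate is the
inverse mean first-passage time, not a curve fit.

## Worked example

```r
library(dimermc)

# a toy dimer with a planted interface: 3 hydrophobic, 1 ionic,
# 2 hydrogen-bonding residue pairs across the gap
toy <- make_toy_dimer(30, interface_spec(n_hydrophobic_pairs = 3,
                                         n_ionic_pairs = 1,
                                         n_hbond_pairs = 2))
profile <- interface_profile(toy$conformation)
profile
#> <interface_profile> n_c = 6, dG = -2.63 kcal/mol
#> typed: hbond=2 hydrophobic=3 ionic=1 cation_pi=0

# pulling at 368 pN, 8 short independent runs
model <- build_energy_model(toy$conformation, force = 368,
                            eps_inter = 1)
cfg <- simulation_config(n_cycles = 50000, burn_in = 1, n_snapshots = 1,
                         n_runs = 8, seed = 1)
ps <- run_pulling_set(model, cfg, d_threshold = 41)
fit <- fit_two_state(ps$sample)
fit
#> <two_state_fit> mean t_dis = 136.2 cycles, lambda = 0.007339 /cycle (n = 8)
```

The planted counts are recovered exactly in `profile` (they are the
generator's ground truth: 6 residue contacts, typed 2/3/1), the
estimated binding free energy comes from the linear contact/NIS model
(a toy interface of 6 contacts binds weakly), and `fit$lambda` is by
construction the inverse mean dissociation time. At this shallow well
depth dissociation is force-dominated and fast; the methods vignette
explains how deeper interfaces move the system into the activated
regime where dissociation times become exponential. `run_protocol()` chains the whole
study: generate a weak/medium/strong dimer series, pull each 24 times,
fit the two-state model and compare `ln t_dis` across dimers, returning
the recovered strength ordering with its significance labels.

A thin command-line wrapper over the same functions ships in
`inst/cli/dimermc.R` with subcommands `compare-seqs`,
`analyze-interface`, `simulate`, `dissociation`, `stats`, `synth`.

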