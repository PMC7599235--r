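#' Simulation configuration
#'
#' Defaults follow the study protocol: 300 K, 120 Angstrom periodic cubic
#' box, 500,000 MC cycles per run with the first 200,000 discarded as
#' burn-in, 3,000 snapshots per run, 24 independent runs. One MC cycle is
#' one attempted move per degree of freedom (every site once plus the
#' four rigid-body move slots).
#'
#' @param temperature Kelvin.
#' @param box_side Angstrom.
#' @param periodic Logical.
#' @param n_cycles MC cycles per run.
#' @param burn_in Cycles discarded before snapshotting.
#' @param n_snapshots Snapshots stored per run (evenly spaced after
#'   burn-in).
#' @param n_runs Independent runs.
#' @param seed Master seed; per-run streams are derived from it.
#' @param amp_site Max single-site displacement per axis, Angstrom.
#' @param amp_translate Max rigid monomer translation per axis, Angstrom.
#' @param amp_rotate Max rigid monomer rotation, radians.
#' @param dca_stride Cycles between anchor-distance records in pulling
#'   runs (1 = every cycle).
#' @param stop_margin Extra cycles simulated after the dissociation
#'   threshold is crossed; negative = run to `n_cycles`.
#' @param check_stride Cycles between incremental-vs-full energy
#'   consistency checkpoints.
#' @return List of class `simulation_config`.
#' @export
simulation_config <- function(temperature = 300, box_side = 120,
                              periodic = TRUE, n_cycles = 500000L,
                              burn_in = 200000L, n_snapshots = 3000L,
                              n_runs = 24L, seed = 1L,
                              amp_site = 0.3, amp_translate = 0.5,
                              amp_rotate = 0.08, dca_stride = 1L,
                              stop_margin = 0L, check_stride = 1000L) {
  if (!(burn_in < n_cycles)) stop("burn_in must be < n_cycles")
  if (!(n_snapshots <= n_cycles - burn_in)) {
    stop("n_snapshots must be <= n_cycles - burn_in")
  }
  structure(list(temperature = temperature, box_side = box_side,
                 periodic = periodic, n_cycles = as.integer(n_cycles),
                 burn_in = as.integer(burn_in),
                 n_snapshots = as.integer(n_snapshots),
                 n_runs = as.integer(n_runs), seed = as.integer(seed),
                 amp_site = amp_site, amp_translate = amp_translate,
                 amp_rotate = amp_rotate, dca_stride = as.integer(dca_stride),
                 stop_margin = as.integer(stop_margin),
                 check_stride = as.integer(check_stride)),
            class = "simulation_config")
}

#' Read a simulation configuration from YAML or JSON
#'
#' Unknown keys are an error (listed by name).
#'
#' @param path File path (`.yaml`/`.yml` or `.json`).
#' @return A [simulation_config()].
#' @export
read_simulation_config <- function(path) {
  vals <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- names(formals(simulation_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("invalid config keys: ", paste(bad, collapse = ", "))
  do.call(simulation_config, vals)
}

.derive_seed <- function(master, run) {
  as.integer((as.numeric(master) * 1009 + run * 7919) %% 2147483629)
}

# flat site coordinates: monomer A atoms then monomer B atoms
.conf_coords <- function(conf) {
  rbind(atom_coords(conf$monomer_a), atom_coords(conf$monomer_b))
}

.coords_to_conf <- function(ref_conf, coords) {
  na <- nrow(ref_conf$monomer_a$atoms)
  ma <- ref_conf$monomer_a
  mb <- ref_conf$monomer_b
  ma$atoms[, c("x", "y", "z")] <- coords[seq_len(na), , drop = FALSE]
  mb$atoms[, c("x", "y", "z")] <- coords[-seq_len(na), , drop = FALSE]
  dimer_conformation(ma, mb, box_side = ref_conf$box_side,
                     periodic = ref_conf$periodic)
}

#' Build a native-contact (Go-type) energy model from a reference dimer
#'
#' Every site pair within `native_cutoff` in the reference (intra- and
#' inter-monomer) becomes a native contact with an attractive 12-10 well
#' centred at its reference distance; all other pairs interact through a
#' short-range r^-12 repulsion. A backbone-RMSD restraint (one term per
#' monomer, each proportional to the monomer's optimal-superposition
#' RMSD from the reference) and a constant pulling force acting on the
#' two central C-alpha anchors complete the energy function. The sites
#' are the structure's atoms, so a C-alpha-only structure gives a
#' C-alpha-level model.
#'
#' @param ref Reference [dimer_conformation()].
#' @param native_cutoff Native-contact cutoff in the reference, Angstrom.
#' @param eps_intra Well depth for intra-monomer contacts, kcal/mol.
#' @param eps_inter Well depth for inter-monomer contacts, kcal/mol.
#' @param eps_bond Well depth for covalent-like pairs (atoms of the same
#'   residue, and C-alpha atoms of adjacent residues), kcal/mol; deep so
#'   that chain connectivity never ruptures before non-bonded contacts.
#' @param ev_sigma Excluded-volume radius, Angstrom.
#' @param ev_strength Repulsion strength, kcal/mol.
#' @param k_rmsd Restraint coefficient, kcal/mol per Angstrom of RMSD.
#' @param force Pulling force, pN (0 = no pulling).
#' @param pull_sign -1 favours separation (the default interpretation of
#'   the constant-force term); +1 penalises it.
#' @param anchor_weighting Center-of-mass weighting for anchor selection.
#' @return Object of class `energy_model`.
#' @export
build_energy_model <- function(ref, native_cutoff = 8, eps_intra = 2,
                               eps_inter = 1, eps_bond = 10, ev_sigma = 4,
                               ev_strength = 1, k_rmsd = 10, force = 0,
                               pull_sign = -1,
                               anchor_weighting = c("mass", "geometric")) {
  stopifnot(inherits(ref, "dimer_conformation"))
  anchor_weighting <- match.arg(anchor_weighting)
  na <- nrow(ref$monomer_a$atoms)
  nb <- nrow(ref$monomer_b$atoms)
  if (n_residues(ref$monomer_a) < 3 || n_residues(ref$monomer_b) < 3) {
    stop("reference needs at least 3 sites per monomer")
  }
  coords <- .conf_coords(ref)
  mono <- c(rep(0L, na), rep(1L, nb))
  bb <- c(ref$monomer_a$atoms$is_backbone, ref$monomer_b$atoms$is_backbone)
  pairs <- cpp_pairs_within(coords, native_cutoff)
  inter <- mono[pairs$i] != mono[pairs$j]
  res_of <- c(ref$monomer_a$atoms$res_index, ref$monomer_b$atoms$res_index)
  name_of <- c(ref$monomer_a$atoms$name, ref$monomer_b$atoms$name)
  bonded <- !inter & (
    res_of[pairs$i] == res_of[pairs$j] |
      (name_of[pairs$i] == "CA" & name_of[pairs$j] == "CA" &
         abs(res_of[pairs$i] - res_of[pairs$j]) == 1))
  eps <- ifelse(inter, eps_inter, ifelse(bonded, eps_bond, eps_intra))
  anch_a <- central_calpha(ref$monomer_a, anchor_weighting)
  anch_b <- central_calpha(ref$monomer_b, anchor_weighting)
  structure(list(
    reference = ref,
    ref_coords = coords,
    site_monomer = mono,
    site_backbone = bb,
    contact_sites = cbind(pairs$i, pairs$j),
    contact_r0 = pairs$dist,
    contact_eps = eps,
    contact_inter = inter,
    ev_sigma = ev_sigma,
    ev_strength = ev_strength,
    k_rmsd = k_rmsd,
    force = force,
    pull_sign = pull_sign,
    pull_prefactor = pull_sign * force * dimer_constants$pN_A_to_kcal_mol,
    anchor_sites = c(anch_a$atom_row, na + anch_b$atom_row),
    anchor_res = c(anch_a$res_index, anch_b$res_index),
    box_side = ref$box_side,
    periodic = ref$periodic
  ), class = "energy_model")
}

#' @export
print.energy_model <- function(x, ...) {
  cat(sprintf(paste0(
    "<energy_model> %d sites, %d native contacts (%d inter-monomer)\n",
    "k_rmsd = %g kcal/mol/A, force = %g pN, anchors at residues %d/%d\n"),
    nrow(x$ref_coords), nrow(x$contact_sites), sum(x$contact_inter),
    x$k_rmsd, x$force, x$anchor_res[1], x$anchor_res[2]))
  invisible(x)
}

#' Full energy decomposition of a conformation under a model
#'
#' @param model An [build_energy_model()] result.
#' @param conf A `dimer_conformation` or a site-coordinate matrix.
#' @return List with `contact`, `excluded_volume`, `restraint`,
#'   `pulling`, `total` (kcal/mol), plus monomer RMSDs and the anchor
#'   distance `d_ca`.
#' @export
dimer_energy <- function(model, conf) {
  coords <- if (is.matrix(conf)) conf else .conf_coords(conf)
  cpp_full_energy(unclass(model), coords)
}

#' Backbone-RMSD restraint energy
#'
#' `k_rmsd * (RMSD_A + RMSD_B)`, each monomer RMSD computed after its own
#' optimal superposition, so rigid motions of a whole monomer cost
#' nothing.
#'
#' @param conf,ref `dimer_conformation`s with matching backbones.
#' @param k_rmsd Coefficient, kcal/mol per Angstrom.
#' @return Energy in kcal/mol.
#' @export
restraint_energy <- function(conf, ref, k_rmsd) {
  k_rmsd * (backbone_rmsd(conf$monomer_a, ref$monomer_a) +
              backbone_rmsd(conf$monomer_b, ref$monomer_b))
}

#' Constant-force pulling energy
#'
#' The force acts along the line between the two anchors; with
#' `sign = -1` (default) increasing the anchor separation lowers the
#' energy, i.e. the anchors are pulled apart. Conversion: 1 pN Angstrom
#' = 0.01439 kcal/mol.
#'
#' @param conf A `dimer_conformation`.
#' @param anchors Integer pair of site rows (as in
#'   `energy_model$anchor_sites`), or `NULL` to use the central C-alphas
#'   of `conf` itself.
#' @param force_pN Force in pN.
#' @param sign -1 (separation-favouring) or +1.
#' @return Energy in kcal/mol.
#' @export
pulling_energy <- function(conf, anchors = NULL, force_pN = 368, sign = -1) {
  coords <- .conf_coords(conf)
  if (is.null(anchors)) {
    na <- nrow(conf$monomer_a$atoms)
    anchors <- c(central_calpha(conf$monomer_a)$atom_row,
                 na + central_calpha(conf$monomer_b)$atom_row)
  }
  d <- if (conf$periodic) {
    min_image_distance(coords[anchors[1], ], coords[anchors[2], ],
                       conf$box_side)
  } else {
    sqrt(sum((coords[anchors[1], ] - coords[anchors[2], ])^2))
  }
  sign * force_pN * dimer_constants$pN_A_to_kcal_mol * d
}

# ---- Metropolis -------------------------------------------------------

#' Metropolis acceptance decision
#'
#' Accepts with probability `min(1, exp(-delta_e / kT))`, drawing from
#' R's RNG. Non-finite energy differences are rejected with a warning.
#'
#' @param delta_e Proposed energy change, kcal/mol.
#' @param kT Thermal energy, kcal/mol (see [kT_kcal()]).
#' @return Logical.
#' @export
metropolis_accept <- function(delta_e, kT) {
  if (!is.finite(delta_e)) {
    warning("non-finite energy change; move rejected")
    return(FALSE)
  }
  delta_e <= 0 || runif(1) < exp(-delta_e / kT)
}

#' Initial MC state for a model
#'
#' @param model An `energy_model`.
#' @param conf Starting conformation (default: the model's reference).
#' @param temperature Kelvin.
#' @return Object of class `mc_state` with cached energy terms.
#' @export
mc_state <- function(model, conf = model$reference, temperature = 300) {
  coords <- if (is.matrix(conf)) conf else .conf_coords(conf)
  structure(list(model = model, coords = coords,
                 energy = cpp_full_energy(unclass(model), coords),
                 kT = kT_kcal(temperature), cycle = 0L),
            class = "mc_state")
}

#' One Metropolis step on an MC state
#'
#' Reference implementation with full energy recomputation; the
#' production loop in [run_native_ensemble()]/[run_pulling()] uses the
#' incremental compiled path, which is cross-checked against this one.
#'
#' @param state An [mc_state()].
#' @param move List: `list(type = "site", site, delta)` (3-vector
#'   displacement), `list(type = "translate", monomer, delta)`, or
#'   `list(type = "rotate", monomer, axis, angle)`. `NULL` draws a random
#'   site move of amplitude `amp`.
#' @param amp Amplitude for random moves, Angstrom.
#' @return Updated `mc_state` (identical coordinates if rejected), with
#'   attribute `"accepted"`.
#' @export
metropolis_step <- function(state, move = NULL, amp = 0.3) {
  stopifnot(inherits(state, "mc_state"))
  coords <- state$coords
  n <- nrow(coords)
  if (is.null(move)) {
    move <- list(type = "site", site = sample.int(n, 1),
                 delta = runif(3, -amp, amp))
  }
  prop <- coords
  mono <- state$model$site_monomer
  if (move$type == "site") {
    prop[move$site, ] <- prop[move$site, ] + move$delta
  } else {
    rows <- which(mono == move$monomer)
    if (move$type == "translate") {
      prop[rows, ] <- sweep(prop[rows, , drop = FALSE], 2, -move$delta)
    } else if (move$type == "rotate") {
      ctr <- colMeans(prop[rows, , drop = FALSE])
      ax <- move$axis / sqrt(sum(move$axis^2))
      ang <- move$angle
      K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3)
      R <- diag(3) + sin(ang) * K + (1 - cos(ang)) * (K %*% K)
      prop[rows, ] <- sweep(sweep(prop[rows, , drop = FALSE], 2, ctr) %*% t(R),
                            2, -ctr)
    } else stop("unknown move type: ", move$type)
  }
  e_new <- cpp_full_energy(unclass(state$model), prop)
  dE <- e_new$total - state$energy$total
  accepted <- metropolis_accept(dE, state$kT)
  if (accepted) {
    state$coords <- prop
    state$energy <- e_new
  }
  state$cycle <- state$cycle + 1L
  attr(state, "accepted") <- accepted
  state
}

# ---- protocols --------------------------------------------------------

.snapshot_cycles <- function(config) {
  span <- config$n_cycles - config$burn_in
  stride <- span %/% config$n_snapshots
  if (stride < 1) stop("n_snapshots too large for the cycle budget")
  config$burn_in + stride * seq_len(config$n_snapshots)
}

#' Sample the native-state ensemble of a dimer
#'
#' Runs `config$n_runs` independent Metropolis runs (distinct RNG
#' streams derived from the master seed) of `config$n_cycles` cycles and
#' stores evenly spaced snapshots after burn-in. No inter-monomer
#' constraint is applied: the dimer staying intact is an observable.
#'
#' @param model An [build_energy_model()] result (typically `force = 0`).
#' @param config A [simulation_config()].
#' @return Object of class `native_ensemble`: list with `runs` (each a
#'   list of `dimer_conformation` snapshots), `snapshot_cycles`,
#'   `acceptance`, `rmsd_final`, `energy_drift` (max |incremental-full|
#'   over checkpoints), `config`.
#' @export
run_native_ensemble <- function(model, config = simulation_config()) {
  snap <- .snapshot_cycles(config)
  kT <- kT_kcal(config$temperature)
  runs <- vector("list", config$n_runs)
  acc <- matrix(NA_real_, config$n_runs, 2,
                dimnames = list(NULL, c("site", "rigid")))
  drift <- numeric(config$n_runs)
  rmsd_final <- matrix(NA_real_, config$n_runs, 2)
  for (r in seq_len(config$n_runs)) {
    set.seed(.derive_seed(config$seed, r))
    res <- cpp_run_mc(unclass(model), model$ref_coords, kT,
                      config$n_cycles, as.integer(snap),
                      0L, Inf, -1L,
                      config$amp_site, config$amp_translate,
                      config$amp_rotate, config$check_stride)
    runs[[r]] <- lapply(res$snapshots, function(x)
      .coords_to_conf(model$reference, x))
    acc[r, ] <- res$acceptance
    drift[r] <- if (length(res$energy_drift)) max(res$energy_drift) else 0
    rmsd_final[r, ] <- c(res$rmsd_a, res$rmsd_b)
  }
  structure(list(runs = runs, snapshot_cycles = snap,
                 acceptance = acc, energy_drift = drift,
                 rmsd_final = rmsd_final, config = config),
            class = "native_ensemble")
}

#' @export
print.native_ensemble <- function(x, ...) {
  cat(sprintf("<native_ensemble> %d run(s) x %d snapshot(s)\n",
              length(x$runs), length(x$runs[[1]])))
  invisible(x)
}

#' Constant-force pulling run(s) with first-passage detection
#'
#' Records the central C-alpha anchor distance D_ca (minimum image) and
#' reports the dissociation time `t_dis`, the first cycle at which D_ca
#' exceeds `d_threshold`; runs that never cross are censored.
#'
#' @param model An `energy_model` with `force > 0` for meaningful
#'   dissociation.
#' @param config A [simulation_config()].
#' @param d_threshold Dissociation threshold on D_ca, Angstrom.
#' @param run_index Which run stream to execute (affects the derived
#'   seed).
#' @return Object of class `pulling_trajectory`: `series` (data.frame
#'   cycle, d_ca, energy), `dissociated`, `t_dis` (NA if censored),
#'   `acceptance`, `final` conformation.
#' @export
run_pulling <- function(model, config = simulation_config(),
                        d_threshold = 41, run_index = 1L) {
  if (model$force <= 0) {
    warning("pulling with force <= 0: dissociation is not driven")
  }
  set.seed(.derive_seed(config$seed, run_index))
  kT <- kT_kcal(config$temperature)
  res <- cpp_run_mc(unclass(model), model$ref_coords, kT,
                    config$n_cycles, integer(0),
                    config$dca_stride, d_threshold, config$stop_margin,
                    config$amp_site, config$amp_translate,
                    config$amp_rotate, config$check_stride)
  t_dis <- if (res$t_dis > 0) res$t_dis else NA_integer_
  structure(list(series = res$dca, dissociated = !is.na(t_dis),
                 t_dis = t_dis, acceptance = res$acceptance,
                 energy_drift = res$energy_drift,
                 final = .coords_to_conf(model$reference, res$final_coords),
                 d_threshold = d_threshold, run_index = run_index),
            class = "pulling_trajectory")
}

#' @export
print.pulling_trajectory <- function(x, ...) {
  cat(sprintf("<pulling_trajectory> run %d: %s\n", x$run_index,
              if (x$dissociated) sprintf("dissociated at cycle %d", x$t_dis)
              else "censored (no dissociation)"))
  invisible(x)
}

#' @export
plot.pulling_trajectory <- function(x, ...) {
  plot(x$series$cycle, x$series$d_ca, type = "l",
       xlab = "MC cycle", ylab = "D_ca (Angstrom)", ...)
  abline(h = x$d_threshold, lty = 2)
  invisible(x)
}

#' A set of independent pulling runs
#'
#' @inheritParams run_pulling
#' @param keep_series Keep the full D_ca series of each run (memory).
#' @return List of class `pulling_set`: `trajectories`, and `sample` (a
#'   [dissociation_sample()] of the observed t_dis values).
#' @export
run_pulling_set <- function(model, config = simulation_config(),
                            d_threshold = 41, keep_series = TRUE) {
  traj <- lapply(seq_len(config$n_runs), function(r) {
    tr <- run_pulling(model, config, d_threshold, run_index = r)
    if (!keep_series) tr$series <- tr$series[0, ]
    tr
  })
  times <- vapply(traj, function(t) as.numeric(t$t_dis), numeric(1))
  sample <- dissociation_sample(times[!is.na(times)],
                                censored = sum(is.na(times)))
  structure(list(trajectories = traj, sample = sample),
            class = "pulling_set")
}
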