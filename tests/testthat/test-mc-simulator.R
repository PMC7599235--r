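three_site_dimer <- function(cross_gap = 5) {
  # two rigid 3-site monomers; exactly one cross pair within 8 A
  mk <- function(chain, x0) monomer_structure(chain, data.frame(
    res_index = 1:3, aa = "A", name = "CA", element = "C",
    x = x0, y = c(0, 20, 40), z = 0))
  a <- mk("A", 0)
  b <- mk("B", cross_gap)
  b$atoms$y <- b$atoms$y   # same y: pairs (i,i) at cross_gap, others >= 20
  dimer_conformation(a, b, box_side = 120, periodic = TRUE)
}

test_that("native contacts come from the reference at the declared cutoff", {
  conf <- three_site_dimer(5)
  m <- build_energy_model(conf, native_cutoff = 8, force = 0)
  inter <- m$contact_sites[m$contact_inter, , drop = FALSE]
  expect_equal(nrow(inter), 3)   # the three (i,i) cross pairs at 5 A
  expect_true(all(abs(m$contact_r0[m$contact_inter] - 5) < 1e-12))
  # energy of the reference: each contact at its minimum, no restraint
  e <- dimer_energy(m, conf)
  expect_equal(e$contact, -sum(m$contact_eps), tolerance = 1e-9)
  expect_equal(e$restraint, 0, tolerance = 1e-9)
  expect_equal(e$pulling, 0)
  expect_error(build_energy_model(dimer_conformation(
    random_ca_monomer(2), random_ca_monomer(5, "B"))), "at least 3")
})

test_that("reference contact list equals an O(n^2) scan on a 60+60 toy", {
  set.seed(61)
  a <- random_ca_monomer(60, "A", spread = 30)
  b <- random_ca_monomer(60, "B", spread = 30)
  b$atoms$x <- b$atoms$x + 18
  conf <- dimer_conformation(a, b, box_side = 200)
  m <- build_energy_model(conf, native_cutoff = 8)
  coords <- .conf_coords(conf)
  slow <- 0L
  for (i in 1:119) for (j in (i + 1):120) {
    if (sqrt(sum((coords[i, ] - coords[j, ])^2)) <= 8) slow <- slow + 1L
  }
  expect_equal(nrow(m$contact_sites), slow)
})

test_that("restraint energy is proportional to monomer-wise optimal RMSD", {
  toy <- make_toy_dimer(20, interface_spec(1, 1, 1))
  ref <- toy$conformation
  expect_equal(restraint_energy(ref, ref, 10), 0, tolerance = 1e-9)
  # rigid displacement of one monomer costs nothing
  moved <- ref
  moved$monomer_a <- transform_monomer(ref$monomer_a, angle = 0.6,
                                       shift = c(4, -2, 1))
  expect_equal(restraint_energy(moved, ref, 10), 0, tolerance = 1e-7)
  # deformation: k * (RMSD_A + RMSD_B) with brute-force RMSD oracle
  set.seed(5)
  def <- ref
  def$monomer_a$atoms[, c("x", "y", "z")] <-
    def$monomer_a$atoms[, c("x", "y", "z")] + matrix(
      rnorm(nrow(def$monomer_a$atoms) * 3, 0, 0.8), ncol = 3)
  p <- .matched_backbone(def$monomer_a, ref$monomer_a)
  oracle_a <- rmsd_bruteforce(p$a, p$b)
  expect_equal(restraint_energy(def, ref, 2), 2 * (oracle_a + 0),
               tolerance = 1e-3)
})

test_that("pulling energy uses the pN-Angstrom conversion and is linear", {
  conf <- three_site_dimer(10)
  # anchors: central CA of each monomer (residue 2), 10 A apart
  e <- pulling_energy(conf, force_pN = 368)
  # independent unit conversion: pN*A -> J -> kcal/mol
  kcal_per_pNA <- 1e-12 * 1e-10 * 6.02214076e23 / 4184
  expect_equal(abs(e), 368 * 10 * kcal_per_pNA, tolerance = 1e-9)
  expect_equal(abs(e), 52.96, tolerance = 0.01)
  expect_lt(e, 0)   # separation-favouring by default
  expect_equal(pulling_energy(conf, force_pN = 0), 0)
  expect_equal(pulling_energy(conf, force_pN = 736), 2 * e, tolerance = 1e-12)
  expect_equal(pulling_energy(conf, force_pN = 368, sign = 1), -e)
})

test_that("Metropolis acceptance follows min(1, exp(-dE/kT))", {
  kT <- kT_kcal(300)
  expect_equal(kT, 0.5962, tolerance = 1e-3)
  set.seed(1)
  expect_true(all(replicate(50, metropolis_accept(-0.3, kT))))
  expect_true(all(replicate(50, metropolis_accept(0, kT))))
  # dE = kT: long-run acceptance e^-1 within 3 sigma binomial
  n <- 1e5
  set.seed(2)
  acc <- sum(replicate(n, metropolis_accept(kT, kT)))
  p <- exp(-1)
  expect_lt(abs(acc / n - p), 3 * sqrt(p * (1 - p) / n))
  expect_warning(bad <- metropolis_accept(NaN, kT), "non-finite")
  expect_false(bad)
})

test_that("a 1-D harmonic chain sampled with metropolis_accept obeys equipartition", {
  kT <- kT_kcal(300)
  k <- 5   # kcal/mol/A^2
  set.seed(123)
  x <- 0
  xs <- numeric(1e5)
  for (i in seq_len(1e5)) {
    prop <- x + runif(1, -0.6, 0.6)
    if (metropolis_accept(0.5 * k * (prop^2 - x^2), kT)) x <- prop
    xs[i] <- x
  }
  expect_equal(var(xs[-(1:2000)]), kT / k, tolerance = 0.05 * kT / k)
})

test_that("metropolis_step full-recompute path matches the engine energies", {
  toy <- make_toy_dimer(15, interface_spec(1, 1, 1))
  m <- build_energy_model(toy$conformation, force = 100, k_rmsd = 10,
                          eps_intra = 2)
  st <- mc_state(m)
  expect_lt(st$energy$restraint, 1e-4)   # identity RMSD, numerically zero
  set.seed(9)
  for (i in 1:25) st <- metropolis_step(st)
  # cached energy equals a fresh full evaluation
  fresh <- dimer_energy(m, st$coords)
  expect_equal(st$energy$total, fresh$total, tolerance = 1e-9)
  # rejected proposals restore the state exactly: force rejection with a
  # huge clash
  n <- nrow(st$coords)
  clash <- list(type = "site", site = 1,
                delta = st$coords[2, ] - st$coords[1, ])
  before <- st$coords
  set.seed(10)
  # an exact overlap gives a non-finite energy change: rejected (with a
  # warning) and the state restored exactly
  st2 <- suppressWarnings(metropolis_step(st, clash))
  expect_false(attr(st2, "accepted"))
  expect_identical(st2$coords, before)
})

test_that("the compiled engine is deterministic and conserves its ledger", {
  toy <- make_toy_dimer(15, interface_spec(1, 1, 1))
  m <- build_energy_model(toy$conformation, force = 0, k_rmsd = 10,
                          eps_intra = 2)
  cfg <- simulation_config(n_cycles = 400, burn_in = 100, n_snapshots = 3,
                           n_runs = 2, seed = 77, check_stride = 100)
  e1 <- run_native_ensemble(m, cfg)
  e2 <- run_native_ensemble(m, cfg)
  expect_identical(lapply(e1$runs, lapply, .conf_coords),
                   lapply(e2$runs, lapply, .conf_coords))
  # incremental energy equals full recomputation at every checkpoint
  expect_lt(max(e1$energy_drift), 1e-6)
  # distinct runs differ
  expect_false(identical(.conf_coords(e1$runs[[1]][[3]]),
                         .conf_coords(e1$runs[[2]][[3]])))
})

test_that("snapshot schedule follows the burn-in and stride arithmetic", {
  cfg <- simulation_config()   # 500k cycles, 200k burn-in, 3000 snapshots
  cyc <- .snapshot_cycles(cfg)
  expect_length(cyc, 3000)
  expect_equal(unique(diff(cyc)), 100)
  expect_equal(cyc[1], 200100)
  expect_lte(max(cyc), 500000)
  expect_error(simulation_config(burn_in = 5e5), "burn_in")
  expect_error(simulation_config(n_cycles = 1000, burn_in = 900,
                                 n_snapshots = 200), "n_snapshots")
})

test_that("unforced native runs keep monomers native-like (emergent)", {
  toy <- make_toy_dimer(20, interface_spec(2, 1, 1))
  m <- build_energy_model(toy$conformation, force = 0, k_rmsd = 10,
                          eps_intra = 2)
  cfg <- simulation_config(n_cycles = 1500, burn_in = 500, n_snapshots = 10,
                           n_runs = 2, seed = 5)
  ens <- run_native_ensemble(m, cfg)
  rmsds <- unlist(lapply(ens$runs, function(run) vapply(run, function(s)
    backbone_rmsd(s$monomer_a, toy$conformation$monomer_a), numeric(1))))
  expect_lt(quantile(rmsds, 0.95), 3)
  # and the dimer stays intact: contacts persist without any constraint
  ncs <- unlist(lapply(ens$runs, function(run)
    vapply(run, count_contacts, numeric(1))))
  expect_gt(mean(ncs), 0.5 * toy$ground_truth$n_planted)
})

test_that("pulling runs record D_ca and detect threshold crossing", {
  toy <- make_toy_dimer(20, interface_spec(2, 1, 1))
  cfg <- simulation_config(n_cycles = 20000, burn_in = 1, n_snapshots = 1,
                           n_runs = 1, seed = 42)
  m <- build_energy_model(toy$conformation, force = 368, k_rmsd = 10,
                          eps_intra = 2, eps_inter = 1.5)
  tr <- run_pulling(m, cfg, d_threshold = 41)
  expect_true(tr$dissociated)
  expect_equal(tr$t_dis, tr$series$cycle[which(tr$series$d_ca > 41)[1]])
  # the run stops at threshold + margin (0 by default)
  expect_equal(max(tr$series$cycle), tr$t_dis)
  # F = 0 on a short run: censored
  m0 <- build_energy_model(toy$conformation, force = 0, k_rmsd = 10,
                           eps_intra = 2)
  cfg0 <- simulation_config(n_cycles = 300, burn_in = 1, n_snapshots = 1,
                            n_runs = 1, seed = 42)
  expect_warning(tr0 <- run_pulling(m0, cfg0), "force")
  expect_false(tr0$dissociated)
  expect_true(is.na(tr0$t_dis))
})

test_that("detailed balance: 3-state toy chain reaches Boltzmann occupancy", {
  # explicit 3-state Metropolis chain driven by metropolis_accept
  kT <- kT_kcal(300)
  en <- c(0, 0.4, 1.1)
  set.seed(314)
  state <- 1L
  counts <- integer(3)
  n_steps <- 1e6
  for (i in seq_len(n_steps)) {
    prop <- sample.int(3, 1)
    if (metropolis_accept(en[prop] - en[state], kT)) state <- prop
    counts[state] <- counts[state] + 1L
  }
  p <- exp(-en / kT)
  p <- p / sum(p)
  for (s in 1:3) {
    se <- sqrt(p[s] * (1 - p[s]) / n_steps)
    # allow for autocorrelation (chain mixes in a few steps)
    expect_lt(abs(counts[s] / n_steps - p[s]), 3 * se * 5)
  }
})
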