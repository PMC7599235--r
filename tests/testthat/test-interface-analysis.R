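make_two_res_dimer <- function(gap, aa_a = "L", aa_b = "L",
                               atom_a = "CD1", atom_b = "CD1",
                               elem_a = "C", elem_b = "C") {
  mk <- function(chain, x, aa, nm, el, sign) {
    monomer_structure(chain, data.frame(
      res_index = 1:3, aa = c("G", aa, "G"),
      name = c("CA", "CA", "CA"), element = "C",
      x = c(x, x, x), y = c(-4, 0, 4), z = 0)) -> m
    m$atoms <- rbind(m$atoms, data.frame(
      res_index = 2, aa = aa, name = nm, element = el,
      x = x + sign * 3, y = 0, z = 0,
      is_heavy = el != "H", is_backbone = FALSE))
    m
  }
  a <- mk("A", -(gap / 2 + 3), aa_a, atom_a, elem_a, +1)
  b <- mk("B", +(gap / 2 + 3), aa_b, atom_b, elem_b, -1)
  dimer_conformation(a, b, box_side = 200, periodic = FALSE)
}

test_that("contact rule is a strict 5.5 A heavy-atom cutoff", {
  in_contact <- make_two_res_dimer(5.4)
  ct <- inter_monomer_contacts(in_contact)
  expect_true(any(ct$res_a == 2 & ct$res_b == 2))
  expect_equal(ct$min_dist[ct$res_a == 2 & ct$res_b == 2], 5.4,
               tolerance = 1e-9)
  out <- make_two_res_dimer(10)
  expect_equal(count_contacts(out), 0)
})

test_that("cell-list contacts equal the O(n^2) scan on random dimers", {
  set.seed(2024)
  for (rep in 1:20) {
    a <- random_ca_monomer(50, "A", spread = 25)
    b <- random_ca_monomer(50, "B", spread = 25)
    b$atoms$x <- b$atoms$x + runif(1, 5, 20)
    conf <- dimer_conformation(a, b, box_side = 200, periodic = FALSE)
    fast <- inter_monomer_contacts(conf)
    slow <- contacts_bruteforce(conf)
    expect_equal(nrow(fast), nrow(slow))
    expect_equal(fast$res_a, slow$res_a)
    expect_equal(fast$res_b, slow$res_b)
    expect_equal(fast$min_dist, slow$min_dist, tolerance = 1e-9)
  }
})

test_that("contact set is invariant under monomer swap and rigid motion", {
  toy <- make_toy_dimer(30, interface_spec(3, 2, 2))
  conf <- toy$conformation
  n0 <- count_contacts(conf)
  swapped <- dimer_conformation(conf$monomer_b, conf$monomer_a,
                                conf$box_side, conf$periodic)
  expect_equal(count_contacts(swapped), n0)
  moved <- dimer_conformation(
    transform_monomer(conf$monomer_a, angle = 0.4, shift = c(3, 1, -2)),
    transform_monomer(conf$monomer_b, angle = 0.4, shift = c(3, 1, -2)),
    conf$box_side, conf$periodic)
  expect_equal(count_contacts(moved), n0)
})

test_that("interaction typing follows the geometric rules", {
  # Lys NZ / Glu OE1 at 3.5 A across the interface: one ionic pair
  salt <- make_two_res_dimer(3.5, aa_a = "K", aa_b = "E",
                             atom_a = "NZ", atom_b = "OE1",
                             elem_a = "N", elem_b = "O")
  counts <- classify_interactions(salt)$counts
  expect_equal(counts[["ionic"]], 1)
  expect_equal(counts[["hydrophobic"]], 0)
  # pure Leu interface in van der Waals contact: hydrophobic only
  leu <- make_two_res_dimer(4.5)
  counts <- classify_interactions(leu)$counts
  expect_equal(counts[["ionic"]], 0)
  expect_equal(counts[["hbond"]], 0)
  expect_gte(counts[["hydrophobic"]], 1)
  # planted toy recovers its composition exactly
  toy <- make_toy_dimer(40, interface_spec(5, 2, 3))
  counts <- classify_interactions(toy$conformation)$counts
  expect_equal(unname(counts[c("hbond", "hydrophobic", "ionic")]),
               c(3, 5, 2))
  expect_equal(count_contacts(toy$conformation), 10)
})

test_that("affinity model is exactly linear with the configured weights", {
  # intercept: no contacts, no NIS
  expect_equal(affinity_from_counts(c(cc = 0), 0, 0),
               affinity_coefficients$intercept)
  # one apolar-apolar contact changes dG by exactly the aa coefficient
  base <- affinity_from_counts(c(aa = 10), 30, 20)
  plus <- affinity_from_counts(c(aa = 11), 30, 20)
  expect_equal(plus - base, affinity_coefficients$ic[["aa"]])
  # hand-evaluated dot product on a constructed profile
  ic <- c(cc = 2, ca = 4, pp = 1, pa = 3, aa = 10)
  w <- affinity_coefficients
  by_hand <- 2 * w$ic[["cc"]] + 4 * w$ic[["ca"]] + 1 * w$ic[["pp"]] +
    3 * w$ic[["pa"]] + 10 * w$ic[["aa"]] +
    30 * w$nis_apolar + 20 * w$nis_charged + w$intercept
  expect_equal(affinity_from_counts(ic, 30, 20), by_hand, tolerance = 1e-15)
  # finite differences recover every coefficient to machine precision
  for (k in names(w$ic)) {
    ic0 <- setNames(rep(2, 6), names(w$ic))
    ic1 <- ic0; ic1[k] <- 3
    expect_equal(affinity_from_counts(ic1, 10, 10) -
                   affinity_from_counts(ic0, 10, 10),
                 w$ic[[k]], tolerance = 1e-12)
  }
})

test_that("binding affinity of a separated dimer is intercept plus NIS terms", {
  toy <- make_toy_dimer(20, interface_spec(0, 0, 0))
  expect_equal(count_contacts(toy$conformation), 0)
  nis <- nis_fractions(toy$conformation)
  expect_equal(binding_affinity(toy$conformation),
               affinity_coefficients$intercept +
                 affinity_coefficients$nis_apolar * nis$nis_apolar +
                 affinity_coefficients$nis_charged * nis$nis_charged)
})

test_that("Shrake-Rupley SASA matches closed forms and a dense grid", {
  one <- monomer_structure("A", data.frame(
    res_index = 1, aa = "G", name = "CA", element = "C", x = 0, y = 0, z = 0))
  s1 <- sasa(one)
  exact <- 4 * pi * (1.7 + 1.4)^2
  expect_equal(s1$total * 100, exact, tolerance = 0.005 * exact)
  # far-separated atoms: areas add
  two <- monomer_structure("A", data.frame(
    res_index = 1:2, aa = "G", name = "CA", element = "C",
    x = c(0, 50), y = 0, z = 0))
  expect_equal(sasa(two)$total * 100, 2 * exact, tolerance = 0.01 * exact)
  # 10-atom cluster vs dense-sample oracle within 1%
  set.seed(17)
  xyz <- matrix(runif(30, 0, 6), ncol = 3)
  clus <- monomer_structure("A", data.frame(
    res_index = 1:10, aa = "G", name = "CA", element = "C",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]))
  dense <- sasa_grid_oracle(xyz, rep(1.7, 10), n_samples = 1e5)
  got <- sasa(clus)$total * 100
  expect_equal(got, dense, tolerance = 0.01 * dense)
  expect_error(sasa(monomer_structure("A", data.frame(
    res_index = 1, aa = "G", name = "X1", element = "XX",
    x = 0, y = 0, z = 0))), "radius")
})

test_that("SASA bookkeeping: per-residue sums, apolar bound, burial", {
  toy <- make_toy_dimer(20, interface_spec(2, 1, 1))
  s <- sasa(toy$conformation)
  expect_equal(sum(s$per_residue) / 100, s$total, tolerance = 1e-9)
  expect_lte(s$apolar, s$total)
  sa <- sasa(toy$conformation$monomer_a)
  sb <- sasa(toy$conformation$monomer_b)
  expect_lte(s$total, sa$total + sb$total + 1e-9)
  # separated monomers: no burial, equality
  apart <- make_toy_dimer(20, interface_spec(0, 0, 0))
  s2 <- sasa(apart$conformation)
  sa2 <- sasa(apart$conformation$monomer_a)
  sb2 <- sasa(apart$conformation$monomer_b)
  expect_equal(s2$total, sa2$total + sb2$total, tolerance = 1e-6)
})

test_that("secondary structure finds helices and strands in ideal geometry", {
  helix <- build_peptide_backbone(12, phi = -57, psi = -47)
  ss <- secondary_structure(helix)
  expect_gte(sum(ss$labels == "H"), 8)
  expect_equal(ss$helix_frac + ss$strand_frac +
                 mean(!(ss$labels %in% c("H", "G", "E"))), 1)
  # lone extended chain: no helix, no strand
  ext <- build_peptide_backbone(5, phi = -139, psi = 135)
  ss2 <- secondary_structure(ext)
  expect_equal(sum(ss2$labels %in% c("H", "E")), 0)
  # two ideal antiparallel strands: some rigid placement of the flipped
  # partner at sheet-like separation must register as paired E strands
  s1 <- build_peptide_backbone(8, phi = -139, psi = 135, chain_id = "A")
  base <- build_peptide_backbone(8, phi = -139, psi = 135, chain_id = "A",
                                 res_offset = 20)
  flip <- as.matrix(base$atoms[, c("x", "y", "z")]) %*% diag(c(-1, 1, -1))
  best_e <- 0
  for (dy in seq(3.8, 5.4, by = 0.2)) for (dx in seq(-3, 3, by = 0.25)) {
    for (dz in c(-1, 0, 1)) {
      s2c <- base
      xyz <- flip
      xyz[, 2] <- xyz[, 2] + dy
      xyz[, 1] <- xyz[, 1] - min(xyz[, 1]) + min(s1$atoms$x) + dx
      xyz[, 3] <- xyz[, 3] + dz
      s2c$atoms[, c("x", "y", "z")] <- xyz
      both <- monomer_structure("A", rbind(s1$atoms[, 1:7], s2c$atoms[, 1:7]))
      ss3 <- suppressWarnings(secondary_structure(both))
      best_e <- max(best_e, sum(ss3$labels == "E"))
    }
  }
  expect_gte(best_e, 4)
})

test_that("position decomposition attributes count differences", {
  det <- function(...) data.frame(...)
  px <- det(type = c("ionic", "ionic", "hbond"),
            res_a = c(466, 466, 100), res_b = c(12, 30, 40))
  py <- det(type = "hbond", res_a = 100, res_b = 40)
  pd <- position_decomposition(px, py, c(466, 521))
  expect_equal(pd$total_delta[["ionic"]], 2)
  expect_equal(pd$subset_delta[["ionic"]], 2)
  expect_equal(pd$total_delta[["hbond"]], 0)
  expect_equal(sum(pd$per_position$delta[pd$per_position$type == "ionic"]), 2)
  # identical profiles: all zero
  pd0 <- position_decomposition(px, px, c(466))
  expect_true(all(pd0$total_delta == 0) && all(pd0$subset_delta == 0))
  # empty position set: subset zero, totals unchanged
  pd1 <- position_decomposition(px, py, integer(0))
  expect_true(all(pd1$subset_delta == 0))
  expect_equal(pd1$total_delta[["ionic"]], 2)
})

test_that("per-position deltas bound the subset delta for any set", {
  toyx <- make_toy_dimer(40, interface_spec(5, 2, 3))
  toyy <- make_toy_dimer(40, interface_spec(3, 1, 2))
  ix <- classify_interactions(toyx$conformation)
  iy <- classify_interactions(toyy$conformation)
  pos <- sort(unique(c(ix$detail$res_a, ix$detail$res_b,
                       iy$detail$res_a, iy$detail$res_b)))
  pd <- position_decomposition(ix, iy, pos)
  for (tp in names(pd$subset_delta)) {
    per <- sum(pd$per_position$delta[pd$per_position$type == tp])
    # per-position sums exceed the subset delta exactly by the pairs
    # spanning two distinct set members
    expect_equal(per - pd$double_counted[[tp]], pd$subset_delta[[tp]])
    expect_gte(per, pd$subset_delta[[tp]])
  }
})

test_that("ensemble averages respect run structure", {
  toy <- make_toy_dimer(15, interface_spec(1, 1, 1))
  one <- ensemble_average(list(toy$conformation), "n_c")
  expect_equal(one$mean, count_contacts(toy$conformation))
  expect_true(is.na(one$se))
  # constant metric: zero SE
  runs <- list(rep(list(toy$conformation), 3), rep(list(toy$conformation), 3))
  const <- ensemble_average(runs, "n_c")
  expect_equal(const$se, 0)
  expect_error(ensemble_average(list(toy$conformation), "bogus"),
               "unknown metric")
  # SE over run means of a Gaussian metric tracks sigma/sqrt(n_runs)
  set.seed(88)
  fake_metric <- function(cf) rnorm(1, 0, 2)
  reps <- replicate(60, {
    runs <- replicate(6, rep(list(toy$conformation), 4), simplify = FALSE)
    ensemble_average(runs, fake_metric)$se
  })
  # each run mean has sd 2/sqrt(4) = 1, so se target is 1/sqrt(6)
  expect_equal(mean(reps), 1 / sqrt(6), tolerance = 0.3 / sqrt(6))
})
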