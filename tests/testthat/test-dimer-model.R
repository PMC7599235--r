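test_that("PDB write/read round-trips a synthetic dimer at 3 decimals", {
  toy <- make_toy_dimer(12, interface_spec(1, 1, 1))
  path <- withr::local_tempfile(fileext = ".pdb")
  write_dimer_pdb(toy$conformation, path)
  back <- read_dimer_pdb(path, "A", "B")
  expect_equal(n_residues(back$monomer_a), 12)
  expect_equal(n_residues(back$monomer_b), 12)
  expect_equal(.conf_coords(back), round(.conf_coords(toy$conformation), 3),
               tolerance = 1e-12, ignore_attr = TRUE)
  # fixed point: write the re-read structure again
  path2 <- withr::local_tempfile(fileext = ".pdb")
  write_dimer_pdb(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("PDB reader rejects missing chains and malformed records", {
  toy <- make_toy_dimer(10, interface_spec(1, 0, 1))
  path <- withr::local_tempfile(fileext = ".pdb")
  write_dimer_pdb(toy$conformation, path)
  expect_error(read_dimer_pdb(path, "A", "Q"), "chain not found")
  lines <- readLines(path)
  lines[2] <- substr(lines[2], 1, 40)   # truncate coordinates
  bad <- withr::local_tempfile(fileext = ".pdb")
  writeLines(lines, bad)
  expect_error(read_dimer_pdb(bad, "A", "B"), "malformed ATOM record at line 2")
  expect_error(read_dimer_pdb(withr::local_tempfile(), "A", "B"), "not found")
})

test_that("a 1-atom-per-chain dimer writes 2 ATOM lines and 2 TER", {
  mk <- function(chain, x) monomer_structure(chain, data.frame(
    res_index = 1L, aa = "G", name = "CA", element = "C",
    x = x, y = 0, z = 0))
  conf <- dimer_conformation(mk("A", 0), mk("B", 8), box_side = 50)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_dimer_pdb(conf, path)
  lines <- readLines(path)
  expect_equal(sum(startsWith(lines, "ATOM")), 2)
  expect_equal(sum(startsWith(lines, "TER")), 2)
  expect_identical(lines[length(lines)], "END")
  expect_error(monomer_structure("A", data.frame()), "columns")
})

test_that("residue chemistry table is total and three-valued", {
  expect_identical(classify_residue("D"), "charged")
  expect_identical(classify_residue("L"), "apolar")
  expect_identical(classify_residue("S"), "polar")
  all20 <- classify_residue(.standard_aa)
  expect_length(all20, 20)
  expect_setequal(unique(all20), c("charged", "polar", "apolar"))
  expect_identical(sort(table(all20), decreasing = TRUE)[[1]], 10L) # apolar
  expect_error(classify_residue("B"), "unknown residue")
  expect_identical(classify_residue("d"), "charged")  # case-insensitive
})

test_that("backbone RMSD is zero under congruence and matches brute force", {
  set.seed(42)
  a <- matrix(runif(12, 0, 10), ncol = 3)
  expect_equal(kabsch_rmsd(a, a), 0, tolerance = 1e-12)
  b <- apply_rigid(a, angle = 1.1, axis = c(2, -1, 0.5), shift = c(4, 4, -7))
  expect_lt(kabsch_rmsd(a, b), 1e-9)
  # perturbed copy vs independent grid+refine minimisation over rotations
  set.seed(7)
  b2 <- b + matrix(rnorm(12, 0, 0.4), ncol = 3)
  expect_equal(kabsch_rmsd(a, b2), rmsd_bruteforce(a, b2), tolerance = 1e-4)
  expect_equal(cpp_kabsch_rmsd(a, b2), kabsch_rmsd(a, b2), tolerance = 1e-9)
  expect_error(kabsch_rmsd(a, a[1:3, ]), "incompatible")
})

test_that("RMSD invariance under rigid transforms holds for monomers", {
  mon <- random_ca_monomer(15, seed = 5)
  mon2 <- transform_monomer(mon, angle = 0.35, axis = c(0, 1, 1),
                            shift = c(-2, 9, 3))
  expect_lt(backbone_rmsd(mon, mon2), 1e-9)
  short <- mon
  short$atoms <- short$atoms[1:10, ]
  expect_error(backbone_rmsd(mon, short), "incompatible")
})

test_that("central C-alpha picks the CA nearest the center of mass", {
  # symmetric 3-residue linear chain: middle residue wins
  mon <- monomer_structure("A", data.frame(
    res_index = 1:3, aa = "A", name = "CA", element = "C",
    x = c(0, 5, 10), y = 0, z = 0))
  expect_equal(central_calpha(mon)$res_index, 2)
  # single residue: only candidate
  single <- monomer_structure("A", data.frame(
    res_index = 1, aa = "A", name = "CA", element = "C",
    x = 1, y = 2, z = 3))
  expect_equal(central_calpha(single)$res_index, 1)
  # random 20-residue monomer equals exhaustive scan
  rnd <- random_ca_monomer(20, seed = 99)
  com <- center_of_mass(rnd)
  d <- sqrt(rowSums(sweep(atom_coords(rnd), 2, com)^2))
  expect_equal(central_calpha(rnd)$res_index, unname(which.min(d)))
  noca <- monomer_structure("A", data.frame(
    res_index = 1, aa = "A", name = "CB", element = "C",
    x = 0, y = 0, z = 0))
  expect_error(central_calpha(noca), "no CA")
})

test_that("minimum-image distance matches 27-image enumeration and is a metric", {
  expect_equal(min_image_distance(c(1, 2, 3), c(1, 2, 3), 120), 0)
  expect_equal(min_image_distance(c(0, 0, 0), c(119, 0, 0), 120), 1)
  set.seed(31)
  for (i in 1:25) {
    x1 <- runif(3, 0, 120); x2 <- runif(3, 0, 120)
    expect_equal(min_image_distance(x1, x2, 120),
                 min_image_bruteforce(x1, x2, 120), tolerance = 1e-10)
    expect_lte(min_image_distance(x1, x2, 120), sqrt(3) / 2 * 120 + 1e-12)
  }
  # symmetry and triangle inequality on random triples
  for (i in 1:25) {
    x <- runif(3, 0, 40); y <- runif(3, 0, 40); z <- runif(3, 0, 40)
    expect_equal(min_image_distance(x, y, 40), min_image_distance(y, x, 40))
    expect_lte(min_image_distance(x, z, 40),
               min_image_distance(x, y, 40) + min_image_distance(y, z, 40)
               + 1e-12)
  }
})

test_that("monomer invariants are enforced", {
  expect_error(monomer_structure("A", data.frame(
    res_index = c(2, 1), aa = "A", name = "CA", element = "C",
    x = 0, y = 0, z = 0)), "strictly increasing")
  expect_error(monomer_structure("A", data.frame(
    res_index = 1, aa = "A", name = "CA", element = "C",
    x = NaN, y = 0, z = 0)), "finite")
  mon <- random_ca_monomer(4)
  expect_error(dimer_conformation(mon, mon, box_side = -5), "box_side")
})
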