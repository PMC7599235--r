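#' Specification of a planted dimer interface
#'
#' Controls the composition of a generated toy-dimer interface: how many
#' hydrophobic, ionic and hydrogen-bonding residue pairs face each other
#' across the inter-monomer gap, and a global scale on the inter-monomer
#' well depths of the derived energy model.
#'
#' @param n_hydrophobic_pairs,n_ionic_pairs,n_hbond_pairs Pair counts
#'   (>= 0; at least one positive for a bound dimer).
#' @param well_depth_scale Dimensionless scale (>= 0) on inter-monomer
#'   native-contact well depths.
#' @param seed Integer recorded with the instance.
#' @return List of class `interface_spec`.
#' @export
interface_spec <- function(n_hydrophobic_pairs = 5, n_ionic_pairs = 2,
                           n_hbond_pairs = 3, well_depth_scale = 1,
                           seed = 1L) {
  stopifnot(n_hydrophobic_pairs >= 0, n_ionic_pairs >= 0,
            n_hbond_pairs >= 0, well_depth_scale >= 0)
  structure(list(n_hydrophobic_pairs = as.integer(n_hydrophobic_pairs),
                 n_ionic_pairs = as.integer(n_ionic_pairs),
                 n_hbond_pairs = as.integer(n_hbond_pairs),
                 well_depth_scale = well_depth_scale,
                 seed = as.integer(seed)),
            class = "interface_spec")
}

# ideal alpha-helix C-alpha trace along z (rise 1.5 A, radius 2.3 A,
# 100 degrees per residue), axis at (x0, y0)
.helix_ca <- function(n_res, x0 = 0, y0 = 0, z0 = 0, phase = 0) {
  i <- seq_len(n_res) - 1
  ang <- (i * 100 + phase) * pi / 180
  cbind(x = x0 + 2.3 * cos(ang), y = y0 + 2.3 * sin(ang), z = z0 + 1.5 * i)
}

# planted interaction geometry: atom pair distance, residue and atom
# identities per type. Ionic pairs sit at 3.8 A: inside the 4.0 A ionic
# window but beyond the 3.5 A hydrogen-bond window, so the planted types
# do not contaminate each other.
.plant_geom <- list(
  hbond = list(dist = 3.0, aa = c("S", "S"), atom = c("OG", "OG"),
               elem = c("O", "O")),
  ionic = list(dist = 3.8, aa = c("K", "E"), atom = c("NZ", "OE1"),
               elem = c("N", "O")),
  hydrophobic = list(dist = 4.0, aa = c("L", "L"), atom = c("CD1", "CD1"),
                     elem = c("C", "C"))
)

#' Generate a toy dimer with a planted interface
#'
#' Two ideal alpha-helix C-alpha traces face each other across a gap;
#' selected residues on the facing sides carry single pseudo side-chain
#' atoms placed so that each planted pair satisfies exactly one
#' interaction-typing rule (Ser OG pairs at 3.0 A for hydrogen bonds,
#' Lys NZ / Glu OE1 at 3.8 A for ionic pairs, Leu CD1 pairs at 4.0 A for
#' hydrophobic pairs). All other inter-monomer residue pairs are beyond
#' the 5.5 A contact cutoff, so the planted interface is the exact
#' ground truth for the contact and typing analytics.
#'
#' @param n_res_per_monomer Residues per monomer (>= 10).
#' @param spec An [interface_spec()].
#' @param box_side,periodic Box geometry of the conformation.
#' @return Object of class `toy_dimer`: `conformation`, `sequences`
#'   (a [sequence_pair()]), `ground_truth` (the spec, the planted
#'   contact list and typed detail).
#' @export
make_toy_dimer <- function(n_res_per_monomer = 40,
                           spec = interface_spec(),
                           box_side = 120, periodic = TRUE) {
  n <- as.integer(n_res_per_monomer)
  if (n < 10) stop("need at least 10 residues per monomer")
  types <- rep(c("hbond", "ionic", "hydrophobic"),
               c(spec$n_hbond_pairs, spec$n_ionic_pairs,
                 spec$n_hydrophobic_pairs))
  n_slots <- length(types)
  # one slot per helix turn (3.6 residues); slot k anchors at the
  # residue in turn k whose C-alpha faces the partner monomer
  max_slots <- max(0L, as.integer(floor((n - 1) * 1.5 / 5.4)))
  if (n_slots > max_slots) {
    stop("infeasible spec: ", n_slots, " pairs but only ", max_slots,
         " interface slots for ", n, " residues")
  }
  # monomer B is phase-shifted by 180 degrees so that the residue facing
  # +x in A faces -x in B at the same index
  axis_a <- -8; axis_b <- 8
  ca_a <- .helix_ca(n, x0 = axis_a)
  ca_b <- .helix_ca(n, x0 = axis_b, phase = 180)
  # filler residues carry only a CA atom, so their identity affects the
  # surface (NIS) composition but never contacts or interaction typing;
  # a protein-like class mix (50% apolar, 25% polar, 25% charged)
  filler <- strsplit("AGLSVETKDIPRNFQYAMWV", "")[[1]]
  aa_a <- rep_len(filler, n)
  aa_b <- rep_len(rev(filler), n)
  sc_a <- sc_b <- NULL    # side-chain pseudo atoms
  planted <- NULL
  used <- integer(0)
  z_mid <- mean(range(ca_a[, "z"]))
  for (k in seq_len(n_slots)) {
    # slots are centred on the helix midpoint, one helix turn (5.4 A)
    # apart, so the interface faces the anchor region; pseudo atoms go
    # on the slot grid at y = 0, which keeps every cross-slot atom pair
    # beyond the 5.5 A contact cutoff
    z_slot <- z_mid + (k - (n_slots + 1) / 2) * 5.4
    window <- setdiff(which(abs(ca_a[, "z"] - z_slot) <= 2.8), used)
    if (length(window) == 0L) stop("infeasible spec: no free interface slot")
    ra <- window[which.max(ca_a[window, "x"])]
    used <- c(used, ra)
    rb <- ra
    g <- .plant_geom[[types[k]]]
    aa_a[ra] <- g$aa[1]; aa_b[rb] <- g$aa[2]
    sc_a <- rbind(sc_a, data.frame(
      res_index = ra, aa = g$aa[1], name = g$atom[1], element = g$elem[1],
      x = -g$dist / 2, y = 0, z = z_slot))
    sc_b <- rbind(sc_b, data.frame(
      res_index = rb, aa = g$aa[2], name = g$atom[2], element = g$elem[2],
      x = +g$dist / 2, y = 0, z = z_slot))
    planted <- rbind(planted, data.frame(
      type = types[k], res_a = ra, res_b = rb, dist = g$dist))
  }
  mk <- function(ca, aa, sc, chain) {
    at <- data.frame(res_index = seq_len(n), aa = aa, name = "CA",
                     element = "C", x = ca[, "x"], y = ca[, "y"],
                     z = ca[, "z"], stringsAsFactors = FALSE)
    if (!is.null(sc)) {
      sc$aa <- aa[sc$res_index]   # keep aa consistent
      at <- rbind(at, sc)
      at <- at[order(at$res_index, at$name != "CA"), ]
    }
    monomer_structure(chain, at)
  }
  # center the dimer in the box
  conf <- dimer_conformation(mk(ca_a, aa_a, sc_a, "A"),
                             mk(ca_b, aa_b, sc_b, "B"),
                             box_side = box_side, periodic = periodic)
  shift <- box_side / 2 - mean(c(atom_coords(conf$monomer_a)[, 3],
                                 atom_coords(conf$monomer_b)[, 3]))
  conf$monomer_a$atoms$z <- conf$monomer_a$atoms$z + shift
  conf$monomer_b$atoms$z <- conf$monomer_b$atoms$z + shift
  conf$monomer_a$atoms[, c("x", "y")] <-
    conf$monomer_a$atoms[, c("x", "y")] + box_side / 2
  conf$monomer_b$atoms[, c("x", "y")] <-
    conf$monomer_b$atoms[, c("x", "y")] + box_side / 2
  if (is.null(planted)) {
    planted <- data.frame(type = character(0), res_a = integer(0),
                          res_b = integer(0), dist = numeric(0))
  }
  structure(list(
    conformation = conf,
    sequences = sequence_pair("toy_A", paste(aa_a, collapse = ""),
                              "toy_B", paste(aa_b, collapse = "")),
    ground_truth = list(spec = spec, planted = planted,
                        n_planted = nrow(planted))
  ), class = "toy_dimer")
}

#' @export
print.toy_dimer <- function(x, ...) {
  cat(sprintf("<toy_dimer> %d+%d residues, %d planted pair(s)\n",
              n_residues(x$conformation$monomer_a),
              n_residues(x$conformation$monomer_b),
              x$ground_truth$n_planted))
  invisible(x)
}

#' Series of toy dimers with scaled interface strength
#'
#' Produces dimers identical in architecture whose planted pair counts
#' and well-depth scales grow with the given strength factors, emulating
#' a weak / medium / strong binding series.
#'
#' @param base_spec An [interface_spec()] for strength 1.
#' @param strengths Strictly increasing scale factors (length >= 1).
#' @param n_res_per_monomer Residues per monomer.
#' @param scale_counts Also scale the planted pair counts (rounded); if
#'   `FALSE`, only the well-depth scale grows, keeping the interface
#'   architecture identical across the series.
#' @return List of `toy_dimer`s with `planted_order` attribute.
#' @export
make_dimer_series <- function(base_spec = interface_spec(),
                              strengths = c(1, 1.25, 1.5),
                              n_res_per_monomer = 40,
                              scale_counts = TRUE) {
  if (length(strengths) >= 2 && any(diff(strengths) <= 0)) {
    stop("strengths must be strictly increasing")
  }
  out <- lapply(strengths, function(s) {
    cs <- if (scale_counts) s else 1
    sp <- interface_spec(
      n_hydrophobic_pairs = round(base_spec$n_hydrophobic_pairs * cs),
      n_ionic_pairs = round(base_spec$n_ionic_pairs * cs),
      n_hbond_pairs = round(base_spec$n_hbond_pairs * cs),
      well_depth_scale = base_spec$well_depth_scale * s,
      seed = base_spec$seed)
    make_toy_dimer(n_res_per_monomer, sp)
  })
  attr(out, "planted_order") <- order(strengths)
  attr(out, "strengths") <- strengths
  out
}

#' Gaussian-perturbed conformational ensemble
#'
#' I.i.d. Gaussian displacement of every coordinate; a cheap stand-in
#' for native-state snapshots when testing ensemble analytics without
#' running MC.
#'
#' @param conf A `dimer_conformation`.
#' @param amplitude Per-coordinate standard deviation, Angstrom (>= 0).
#' @param n_snapshots Number of snapshots.
#' @param seed RNG seed.
#' @return List of `dimer_conformation`s.
#' @export
perturb_ensemble <- function(conf, amplitude, n_snapshots, seed = 1L) {
  stopifnot(amplitude >= 0)
  set.seed(as.integer(seed))
  coords <- .conf_coords(conf)
  lapply(seq_len(n_snapshots), function(i) {
    pert <- coords + matrix(rnorm(length(coords), 0, amplitude),
                            ncol = 3)
    .coords_to_conf(conf, pert)
  })
}

#' Random sequence pair with planted substitutions
#'
#' @param length Sequence length.
#' @param n_subs Number of substituted positions (0..length).
#' @param seed RNG seed.
#' @return List: `pair` (a [sequence_pair()]) and `positions` (sorted
#'   planted positions).
#' @export
make_sequence_pair <- function(length, n_subs, seed = 1L) {
  if (n_subs > length) stop("n_subs > length")
  set.seed(as.integer(seed))
  aa <- .standard_aa
  s1 <- sample(aa, length, replace = TRUE)
  pos <- sort(sample.int(length, n_subs))
  s2 <- s1
  for (p in pos) s2[p] <- sample(setdiff(aa, s1[p]), 1)
  list(pair = sequence_pair("seq_a", paste(s1, collapse = ""),
                            "seq_b", paste(s2, collapse = "")),
       positions = pos)
}

#' Printed variable positions of the PgiC1/PgiC2 pair
#'
#' The 20 full-length residue positions at which the two PgiC protein
#' sequences differ, and the four of them near the dimer interface.
#'
#' @format List with `all` (20 positions) and `near_interface` (4).
#' @export
pgic_variant_positions <- list(
  all = c(48L, 49L, 53L, 62L, 85L, 109L, 118L, 121L, 123L, 200L, 210L,
          237L, 266L, 312L, 318L, 372L, 455L, 466L, 521L, 554L),
  near_interface = c(200L, 372L, 466L, 521L)
)

#' Synthetic stand-in for the PgiC1/PgiC2 sequence pair
#'
#' A deterministic 567-residue sequence pair differing at exactly the 20
#' published variable positions, with the second sequence carrying
#' charged residues at positions 466 and 521 (as the real PgiC2 does).
#' This is a synthetic stand-in, not the GenBank records: residue
#' identities outside the documented constraints are arbitrary.
#'
#' @return A [sequence_pair()] with ids marking it as synthetic.
#' @export
synthetic_pgic_pair <- function() {
  set.seed(19054L)
  aa <- .standard_aa
  s1 <- sample(aa, 567, replace = TRUE)
  pos <- pgic_variant_positions$all
  # uncharged in sequence 1, charged in sequence 2 at 466/521
  s1[466] <- "S"; s1[521] <- "T"
  s2 <- s1
  for (p in pos) s2[p] <- sample(setdiff(aa, s1[p]), 1)
  s2[466] <- "K"; s2[521] <- "E"
  sequence_pair("PgiC1_synthetic", paste(s1, collapse = ""),
                "PgiC2_synthetic", paste(s2, collapse = ""))
}

#' Write a toy dimer and its manifest to disk
#'
#' Writes the conformation as PDB, the sequences as FASTA, and a JSON
#' manifest recording the seed and planted ground truth.
#'
#' @param toy A [make_toy_dimer()] result.
#' @param dir Output directory (created if needed).
#' @param name Base file name.
#' @return Invisibly, the manifest path.
#' @export
write_toy_dimer <- function(toy, dir, name = "toy_dimer") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pdb <- file.path(dir, paste0(name, ".pdb"))
  fa <- file.path(dir, paste0(name, ".fasta"))
  manifest <- file.path(dir, paste0(name, "_manifest.json"))
  write_dimer_pdb(toy$conformation, pdb)
  writeLines(c(paste0(">", toy$sequences$id_a), toy$sequences$seq_a,
               paste0(">", toy$sequences$id_b), toy$sequences$seq_b), fa)
  jsonlite::write_json(
    list(spec = unclass(toy$ground_truth$spec),
         planted = toy$ground_truth$planted,
         files = list(pdb = basename(pdb), fasta = basename(fa))),
    manifest, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
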