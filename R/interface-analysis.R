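#' Geometric interaction-typing rules
#'
#' Cutoffs (Angstrom) and counting granularity for the four inter-monomer
#' interaction types. All values are configuration, not code.
#'
#' Counting granularity: hydrogen bonds are counted per donor-acceptor
#' atom pair; hydrophobic interactions per apolar residue pair (group
#' level; set `hydrophobic_granularity = "atom_pair"` for the atom-pair
#' alternative); ionic interactions per oppositely charged residue pair
#' (salt bridge); cation-pi per (cationic residue, aromatic residue) pair.
#'
#' @param hbond_dist Max donor-acceptor heavy-atom distance.
#' @param hbond_angle_min Min donor-H...acceptor angle (degrees), applied
#'   only when hydrogens are present.
#' @param ionic_dist Max distance between oppositely charged side-chain
#'   N/O atoms.
#' @param hydrophobic_dist Max carbon-carbon distance between apolar
#'   side-chain groups.
#' @param cation_pi_dist Max cation-N to ring-centroid distance.
#' @param cation_pi_angle_max Max offset angle from the ring normal
#'   (degrees), applied when the ring plane is defined.
#' @param hydrophobic_granularity `"residue_pair"` or `"atom_pair"`.
#' @return List of rule parameters.
#' @export
interaction_rules <- function(hbond_dist = 3.5, hbond_angle_min = 120,
                              ionic_dist = 4.0, hydrophobic_dist = 5.0,
                              cation_pi_dist = 6.0, cation_pi_angle_max = 60,
                              hydrophobic_granularity = c("residue_pair",
                                                          "atom_pair")) {
  list(hbond_dist = hbond_dist, hbond_angle_min = hbond_angle_min,
       ionic_dist = ionic_dist, hydrophobic_dist = hydrophobic_dist,
       cation_pi_dist = cation_pi_dist,
       cation_pi_angle_max = cation_pi_angle_max,
       hydrophobic_granularity = match.arg(hydrophobic_granularity))
}

# side-chain chemistry tables ------------------------------------------

.positive_atoms <- list(K = "NZ", R = c("NE", "NH1", "NH2"),
                        H = c("ND1", "NE2"))
.negative_atoms <- list(D = c("OD1", "OD2"), E = c("OE1", "OE2"))
.hydroxyl_o <- c("OG", "OG1", "OH")
.ring_atoms <- list(F = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
                    Y = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
                    W = c("CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2"))

# ---- contacts ---------------------------------------------------------

#' Inter-monomer residue contacts at a heavy-atom cutoff
#'
#' A residue pair (one residue per monomer) is in contact if any pair of
#' heavy atoms, one from each residue, lies within `cutoff`. Implemented
#' with a cell list; an O(n^2) scan gives identical results.
#'
#' @param conf A [dimer_conformation()].
#' @param cutoff Heavy-atom distance cutoff in Angstrom (default 5.5).
#' @return data.frame of class `contact_pairs` with columns `res_a`,
#'   `res_b`, `min_dist` (minimum heavy-atom distance).
#' @export
inter_monomer_contacts <- function(conf, cutoff = 5.5) {
  stopifnot(inherits(conf, "dimer_conformation"))
  ha <- conf$monomer_a$atoms[conf$monomer_a$atoms$is_heavy, , drop = FALSE]
  hb <- conf$monomer_b$atoms[conf$monomer_b$atoms$is_heavy, , drop = FALSE]
  out <- cpp_contact_pairs(as.matrix(ha[, c("x", "y", "z")]), ha$res_index,
                           as.matrix(hb[, c("x", "y", "z")]), hb$res_index,
                           cutoff)
  class(out) <- c("contact_pairs", "data.frame")
  out
}

#' Number of inter-monomer residue-pair contacts
#'
#' @inheritParams inter_monomer_contacts
#' @return Integer count n_c (unordered residue pairs).
#' @export
count_contacts <- function(conf, cutoff = 5.5) {
  nrow(inter_monomer_contacts(conf, cutoff))
}

#' Interface residue positions of a dimer
#'
#' Positions (original numbering) of residues participating in at least
#' one inter-monomer contact, in either chain.
#'
#' @inheritParams inter_monomer_contacts
#' @return Sorted integer vector.
#' @export
interface_positions <- function(conf, cutoff = 5.5) {
  ct <- inter_monomer_contacts(conf, cutoff)
  sort(unique(c(ct$res_a, ct$res_b)))
}

# ---- interaction typing ----------------------------------------------

.side_chain <- function(atoms) {
  atoms[!(atoms$name %in% .backbone_names) & atoms$is_heavy, , drop = FALSE]
}

.pairs_within <- function(a, b, cutoff) {
  # all (row_a, row_b) index pairs within cutoff; small inputs only
  if (nrow(a) == 0L || nrow(b) == 0L) {
    return(matrix(integer(0), ncol = 2))
  }
  xa <- as.matrix(a[, c("x", "y", "z")])
  xb <- as.matrix(b[, c("x", "y", "z")])
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * xa %*% t(xb)
  which(d2 <= cutoff^2, arr.ind = TRUE)
}

#' Type the inter-monomer interactions of a dimer conformation
#'
#' Applies the geometric rules of [interaction_rules()] to atom pairs
#' across the interface and returns both counts and the per-interaction
#' table used by [position_decomposition()].
#'
#' @param conf A [dimer_conformation()].
#' @param rules Rule set from [interaction_rules()].
#' @return List of class `typed_interactions`: `counts` (named integer
#'   vector over hbond, hydrophobic, ionic, cation_pi) and `detail`
#'   (data.frame with `type`, `res_a`, `res_b`).
#' @export
classify_interactions <- function(conf, rules = interaction_rules()) {
  stopifnot(inherits(conf, "dimer_conformation"))
  A <- conf$monomer_a$atoms
  B <- conf$monomer_b$atoms
  det <- list()

  first_a <- A[!duplicated(A$res_index), c("res_index", "aa")]
  first_b <- B[!duplicated(B$res_index), c("res_index", "aa")]
  aa_of <- function(tbl, idx) tbl$aa[match(idx, tbl$res_index)]

  # hydrogen bonds: donor (N or hydroxyl O) -- acceptor (O, or His ring N)
  is_donor <- function(at) at$is_heavy &
    (at$element == "N" | (at$element == "O" & at$name %in% .hydroxyl_o))
  is_acceptor <- function(at) at$is_heavy &
    (at$element == "O" | (at$aa == "H" & at$name %in% c("ND1", "NE2")))
  hb_rows <- rbind(
    .hb_atom_pairs(A, B, is_donor, is_acceptor, rules),
    .hb_atom_pairs(B, A, is_donor, is_acceptor, rules)[, c(2, 1), drop = FALSE]
  )
  if (nrow(hb_rows)) {
    hb_rows <- unique(hb_rows)         # atom-pair granularity
    det$hbond <- data.frame(type = "hbond",
                            res_a = A$res_index[hb_rows[, 1]],
                            res_b = B$res_index[hb_rows[, 2]])
  }

  # ionic: oppositely charged side-chain groups (residue-pair level)
  ion <- rbind(
    .charged_pairs(A, B, .positive_atoms, .negative_atoms, rules$ionic_dist),
    .charged_pairs(A, B, .negative_atoms, .positive_atoms, rules$ionic_dist)
  )
  if (nrow(ion)) {
    ion <- unique(ion)
    det$ionic <- data.frame(type = "ionic", res_a = ion[, 1], res_b = ion[, 2])
  }

  # hydrophobic: C-C between apolar side-chain groups
  sa <- .side_chain(A)
  sa <- sa[sa$element == "C" & classify_residue(sa$aa) == "apolar", , drop = FALSE]
  sb <- .side_chain(B)
  sb <- sb[sb$element == "C" & classify_residue(sb$aa) == "apolar", , drop = FALSE]
  hp <- .pairs_within(sa, sb, rules$hydrophobic_dist)
  if (nrow(hp)) {
    pairs <- cbind(sa$res_index[hp[, 1]], sb$res_index[hp[, 2]])
    if (rules$hydrophobic_granularity == "residue_pair") pairs <- unique(pairs)
    det$hydrophobic <- data.frame(type = "hydrophobic",
                                  res_a = pairs[, 1], res_b = pairs[, 2])
  }

  # cation-pi: cationic N near an aromatic ring centroid
  cp <- rbind(
    .cation_pi_pairs(A, B, rules),
    .cation_pi_pairs(B, A, rules)[, c(2, 1), drop = FALSE]
  )
  if (nrow(cp)) {
    cp <- unique(cp)
    det$cation_pi <- data.frame(type = "cation_pi",
                                res_a = cp[, 1], res_b = cp[, 2])
  }

  detail <- if (length(det)) do.call(rbind, det) else
    data.frame(type = character(0), res_a = integer(0), res_b = integer(0))
  rownames(detail) <- NULL
  counts <- c(hbond = sum(detail$type == "hbond"),
              hydrophobic = sum(detail$type == "hydrophobic"),
              ionic = sum(detail$type == "ionic"),
              cation_pi = sum(detail$type == "cation_pi"))
  structure(list(counts = counts, detail = detail),
            class = "typed_interactions")
}

#' @export
print.typed_interactions <- function(x, ...) {
  cat("<typed_interactions>\n")
  print(x$counts)
  invisible(x)
}

# Returns (row in A, row in B) per donor-acceptor atom pair within the
# distance rule (donors drawn from A, acceptors from B).
.hb_atom_pairs <- function(A, B, is_donor, is_acceptor, rules) {
  don_rows <- which(is_donor(A))
  acc_rows <- which(is_acceptor(B))
  don <- A[don_rows, , drop = FALSE]
  acc <- B[acc_rows, , drop = FALSE]
  hits <- .pairs_within(don, acc, rules$hbond_dist)
  if (nrow(hits) == 0L) return(matrix(integer(0), ncol = 2))
  keep <- rep(TRUE, nrow(hits))
  # angle criterion when an H bonded to the donor is present
  hyd <- A[A$element == "H", , drop = FALSE]
  if (nrow(hyd)) {
    for (k in seq_len(nrow(hits))) {
      d <- don[hits[k, 1], ]
      a <- acc[hits[k, 2], ]
      hres <- hyd[hyd$res_index == d$res_index, , drop = FALSE]
      if (nrow(hres) == 0L) next
      dx <- as.numeric(d[c("x", "y", "z")])
      hd2 <- (hres$x - dx[1])^2 + (hres$y - dx[2])^2 + (hres$z - dx[3])^2
      h <- hres[which.min(hd2), ]
      if (min(hd2) > 1.3^2) next           # no covalent H on this donor
      hv <- as.numeric(h[c("x", "y", "z")])
      av <- as.numeric(a[c("x", "y", "z")])
      v1 <- dx - hv
      v2 <- av - hv
      ang <- acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi
      keep[k] <- ang >= rules$hbond_angle_min
    }
  }
  hits <- hits[keep, , drop = FALSE]
  cbind(don_rows[hits[, 1]], acc_rows[hits[, 2]])
}

.charged_group <- function(atoms, table) {
  sc <- atoms[atoms$is_heavy, , drop = FALSE]
  keep <- mapply(function(aa, nm) aa %in% names(table) && nm %in% table[[aa]],
                 sc$aa, sc$name)
  sc[as.logical(keep), , drop = FALSE]
}

.charged_pairs <- function(A, B, table_a, table_b, cutoff) {
  pa <- .charged_group(A, table_a)
  pb <- .charged_group(B, table_b)
  hits <- .pairs_within(pa, pb, cutoff)
  if (nrow(hits) == 0L) return(matrix(integer(0), ncol = 2))
  unique(cbind(pa$res_index[hits[, 1]], pb$res_index[hits[, 2]]))
}

.cation_pi_pairs <- function(A, B, rules) {
  cat_at <- .charged_group(A, .positive_atoms)
  cat_at <- cat_at[cat_at$aa != "H", , drop = FALSE]  # His N not cationic here
  out <- matrix(integer(0), ncol = 2)
  if (nrow(cat_at) == 0L) return(out)
  arom <- B[B$aa %in% names(.ring_atoms), , drop = FALSE]
  for (res in unique(arom$res_index)) {
    ra <- arom[arom$res_index == res, , drop = FALSE]
    ring <- ra[ra$name %in% .ring_atoms[[ra$aa[1]]], , drop = FALSE]
    if (nrow(ring) == 0L) next
    centroid <- colMeans(as.matrix(ring[, c("x", "y", "z")]))
    dv <- sweep(as.matrix(cat_at[, c("x", "y", "z")]), 2, centroid)
    dist <- sqrt(rowSums(dv^2))
    near <- which(dist <= rules$cation_pi_dist)
    if (length(near) == 0L) next
    if (nrow(ring) >= 3) {
      xc <- sweep(as.matrix(ring[, c("x", "y", "z")]), 2,
                  colMeans(as.matrix(ring[, c("x", "y", "z")])))
      normal <- svd(xc)$v[, 3]
      cosang <- abs(dv[near, , drop = FALSE] %*% normal) / dist[near]
      ang <- acos(pmin(1, cosang)) * 180 / pi
      near <- near[ang <= rules$cation_pi_angle_max]
    }
    if (length(near)) {
      out <- rbind(out, cbind(cat_at$res_index[near], res))
    }
  }
  unique(out)
}

# ---- binding affinity -------------------------------------------------

.class_pair_key <- function(ca, cb) {
  code <- c(charged = "c", polar = "p", apolar = "a")
  rank <- c(c = 1, p = 2, a = 3)
  a <- code[ca]; b <- code[cb]
  swap <- rank[a] > rank[b]
  key <- paste0(ifelse(swap, b, a), ifelse(swap, a, b))
  key
}

#' Interface contact counts by residue-class pair
#'
#' @param conf A [dimer_conformation()].
#' @param cutoff Contact cutoff, Angstrom.
#' @return Named integer vector over `cc, cp, ca, pp, pa, aa`.
#' @export
class_contact_counts <- function(conf, cutoff = 5.5) {
  ct <- inter_monomer_contacts(conf, cutoff)
  keys <- c("cc", "cp", "ca", "pp", "pa", "aa")
  out <- setNames(integer(6), keys)
  if (nrow(ct)) {
    fa <- conf$monomer_a$atoms[!duplicated(conf$monomer_a$atoms$res_index), ]
    fb <- conf$monomer_b$atoms[!duplicated(conf$monomer_b$atoms$res_index), ]
    ca <- classify_residue(fa$aa[match(ct$res_a, fa$res_index)])
    cb <- classify_residue(fb$aa[match(ct$res_b, fb$res_index)])
    tab <- table(.class_pair_key(ca, cb))
    out[names(tab)] <- as.integer(tab)
  }
  out
}

#' Evaluate the linear contact-based affinity model
#'
#' `dG = sum_k w_k IC_k + w_a NIS_apolar + w_c NIS_charged + w_0`, with
#' interface contact counts IC by residue-class pair and NIS percentages
#' of the non-interacting surface.
#'
#' @param ic Named counts over `cc, cp, ca, pp, pa, aa`.
#' @param nis_apolar,nis_charged NIS percentages (0-100).
#' @param coefficients Coefficient block, see [affinity_coefficients].
#' @return Predicted binding free energy, kcal/mol.
#' @export
affinity_from_counts <- function(ic, nis_apolar, nis_charged,
                                 coefficients = affinity_coefficients) {
  w <- coefficients$ic[names(coefficients$ic)]
  ic_full <- setNames(numeric(length(w)), names(w))
  ic_full[names(ic)] <- ic
  sum(w * ic_full) +
    coefficients$nis_apolar * nis_apolar +
    coefficients$nis_charged * nis_charged +
    coefficients$intercept
}

#' Non-interacting-surface composition of a dimer
#'
#' Residues outside the interface whose relative SASA in the complex is
#' at least `rel_cutoff` percent form the non-interacting surface (NIS);
#' returns the percentage of NIS residues that are apolar and charged.
#'
#' @param conf A [dimer_conformation()].
#' @param cutoff Interface contact cutoff, Angstrom.
#' @param rel_cutoff Relative SASA threshold (percent) for surface
#'   exposure.
#' @param sasa_result Optional precomputed [sasa()] result for `conf`.
#' @return List with `nis_apolar`, `nis_charged` (percent), `n_nis`.
#' @export
nis_fractions <- function(conf, cutoff = 5.5, rel_cutoff = 5,
                          sasa_result = NULL) {
  if (is.null(sasa_result)) sasa_result <- sasa(conf)
  iface <- interface_positions(conf, cutoff)
  res_tab <- rbind(
    data.frame(chain = "A",
               pos = residue_indices(conf$monomer_a),
               aa = strsplit(monomer_sequence(conf$monomer_a), "")[[1]]),
    data.frame(chain = "B",
               pos = residue_indices(conf$monomer_b),
               aa = strsplit(monomer_sequence(conf$monomer_b), "")[[1]])
  )
  rel <- 100 * sasa_result$per_residue / .max_sasa[res_tab$aa]
  nis <- rel >= rel_cutoff & !(res_tab$pos %in% iface)
  n_nis <- sum(nis)
  if (n_nis == 0L) {
    return(list(nis_apolar = 0, nis_charged = 0, n_nis = 0L))
  }
  cls <- classify_residue(res_tab$aa[nis])
  list(nis_apolar = 100 * mean(cls == "apolar"),
       nis_charged = 100 * mean(cls == "charged"),
       n_nis = n_nis)
}

#' Contact-based binding free energy of a dimer conformation
#'
#' @param conf A [dimer_conformation()].
#' @param coefficients Affinity-model coefficients.
#' @param cutoff Interface contact cutoff, Angstrom.
#' @param nis Optional precomputed [nis_fractions()] result.
#' @return Estimated binding free energy, kcal/mol.
#' @export
binding_affinity <- function(conf, coefficients = affinity_coefficients,
                             cutoff = 5.5, nis = NULL) {
  ic <- class_contact_counts(conf, cutoff)
  if (is.null(nis)) nis <- nis_fractions(conf, cutoff)
  affinity_from_counts(ic, nis$nis_apolar, nis$nis_charged, coefficients)
}

# ---- SASA -------------------------------------------------------------

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Quadrature points on each atom's solvent-expanded sphere are tested
#' for occlusion by neighbouring atoms. Apolar SASA is the carbon plus
#' sulfur contribution.
#'
#' @param x A `dimer_conformation` or `monomer_structure`.
#' @param probe Probe radius, Angstrom.
#' @param n_points Quadrature points per atom.
#' @param radii Named per-element van der Waals radii (Angstrom).
#' @return List of class `sasa_result`: `total` and `apolar` (nm^2),
#'   `per_residue` (Angstrom^2, over chain A then chain B residues),
#'   `per_atom` (Angstrom^2).
#' @export
sasa <- function(x, probe = 1.4, n_points = 960, radii = .vdw_radii) {
  atoms <- if (inherits(x, "dimer_conformation")) {
    rbind(cbind(x$monomer_a$atoms, .chain = "A"),
          cbind(x$monomer_b$atoms, .chain = "B"))
  } else if (inherits(x, "monomer_structure")) {
    cbind(x$atoms, .chain = "A")
  } else stop("need a dimer_conformation or monomer_structure")
  atoms <- atoms[atoms$is_heavy, , drop = FALSE]
  r <- radii[atoms$element]
  if (anyNA(r)) {
    stop("no van der Waals radius for element: ",
         paste(unique(atoms$element[is.na(r)]), collapse = ", "))
  }
  per_atom <- cpp_sasa(as.matrix(atoms[, c("x", "y", "z")]),
                       as.numeric(r), probe, as.integer(n_points))
  key <- paste(atoms$.chain, atoms$res_index)
  per_residue <- tapply(per_atom, factor(key, levels = unique(key)), sum)
  apolar <- sum(per_atom[atoms$element %in% c("C", "S")])
  structure(list(total = sum(per_atom) / dimer_constants$A2_per_nm2,
                 apolar = apolar / dimer_constants$A2_per_nm2,
                 per_residue = as.numeric(per_residue),
                 per_atom = per_atom),
            class = "sasa_result")
}

#' @export
print.sasa_result <- function(x, ...) {
  cat(sprintf("<sasa_result> total %.2f nm^2, apolar %.2f nm^2, %d residues\n",
              x$total, x$apolar, length(x$per_residue)))
  invisible(x)
}

# ---- full profile -----------------------------------------------------

#' Full interface profile of one conformation
#'
#' Bundles contact count, typed interaction counts, class-pair contact
#' counts, NIS composition and the contact-based binding free energy.
#'
#' @param conf A [dimer_conformation()].
#' @param cutoff Contact cutoff, Angstrom.
#' @param rules Interaction-typing rules.
#' @param coefficients Affinity-model coefficients.
#' @param with_sasa Compute SASA/NIS (slower); if `FALSE`, NIS terms are
#'   zero and `dG` is contact-only.
#' @return Object of class `interface_profile`.
#' @export
interface_profile <- function(conf, cutoff = 5.5,
                              rules = interaction_rules(),
                              coefficients = affinity_coefficients,
                              with_sasa = TRUE) {
  contacts <- inter_monomer_contacts(conf, cutoff)
  typed <- classify_interactions(conf, rules)
  ic <- class_contact_counts(conf, cutoff)
  nis <- if (with_sasa) nis_fractions(conf, cutoff) else
    list(nis_apolar = 0, nis_charged = 0, n_nis = 0L)
  dg <- affinity_from_counts(ic, nis$nis_apolar, nis$nis_charged,
                             coefficients)
  structure(list(n_c = nrow(contacts), typed_counts = typed$counts,
                 class_counts = ic, nis_apolar = nis$nis_apolar,
                 nis_charged = nis$nis_charged, dG = dg,
                 contacts = contacts, interactions = typed$detail),
            class = "interface_profile")
}

#' @export
print.interface_profile <- function(x, ...) {
  cat(sprintf("<interface_profile> n_c = %d, dG = %.2f kcal/mol\n",
              x$n_c, x$dG))
  cat("typed:", paste(names(x$typed_counts), x$typed_counts,
                      sep = "=", collapse = " "), "\n")
  invisible(x)
}

# ---- per-position decomposition --------------------------------------

#' Decompose interaction-count differences by residue position
#'
#' Given typed-interaction profiles of two dimers computed with identical
#' rules, reports for each interaction type the total count difference,
#' the difference restricted to interactions involving at least one
#' position in `positions`, and per-position differences. Pairs with both
#' members in the set are counted once in the subset delta but appear in
#' both positions' rows (the double count is reported).
#'
#' @param profile_x,profile_y `typed_interactions` or `interface_profile`
#'   objects (x minus y).
#' @param positions Integer positions of interest.
#' @return List of class `position_decomposition`: `total_delta`,
#'   `subset_delta` (named by type), `per_position` (data.frame),
#'   `double_counted` (named by type).
#' @export
position_decomposition <- function(profile_x, profile_y, positions) {
  getdet <- function(p) {
    if (inherits(p, "interface_profile")) p$interactions
    else if (inherits(p, "typed_interactions")) p$detail
    else p
  }
  dx <- getdet(profile_x)
  dy <- getdet(profile_y)
  types <- c("hbond", "hydrophobic", "ionic", "cation_pi")
  cnt <- function(d, type, pos = NULL) {
    sub <- d[d$type == type, , drop = FALSE]
    if (!is.null(pos)) {
      sub <- sub[sub$res_a %in% pos | sub$res_b %in% pos, , drop = FALSE]
    }
    nrow(sub)
  }
  total <- setNames(vapply(types, function(tp) cnt(dx, tp) - cnt(dy, tp),
                           numeric(1)), types)
  subset <- setNames(vapply(types, function(tp)
    cnt(dx, tp, positions) - cnt(dy, tp, positions), numeric(1)), types)
  per_pos <- do.call(rbind, lapply(sort(unique(positions)), function(p) {
    data.frame(position = p, type = types,
               delta = vapply(types, function(tp)
                 cnt(dx, tp, p) - cnt(dy, tp, p), numeric(1)))
  }))
  if (is.null(per_pos)) {
    per_pos <- data.frame(position = integer(0), type = character(0),
                          delta = numeric(0))
  }
  # an interaction spans two set members only when the two positions
  # differ; res_a == res_b is a single position seen from both chains
  dbl <- setNames(vapply(types, function(tp) {
    both <- function(d) {
      sub <- d[d$type == tp & d$res_a %in% positions &
                 d$res_b %in% positions & d$res_a != d$res_b, , drop = FALSE]
      nrow(sub)
    }
    both(dx) - both(dy)
  }, numeric(1)), types)
  structure(list(total_delta = total, subset_delta = subset,
                 per_position = per_pos, double_counted = dbl),
            class = "position_decomposition")
}

# ---- ensemble averaging ----------------------------------------------

#' Ensemble average of a per-conformation metric
#'
#' Metrics are evaluated conformation by conformation and then averaged.
#' When the snapshots carry run structure (a list of runs, each a list of
#' conformations), the standard error is computed over independent-run
#' means, because snapshots within a run are autocorrelated.
#'
#' @param snapshots List of `dimer_conformation`s, or list of runs (each
#'   a list of conformations).
#' @param metric Function of a conformation returning a scalar, or one of
#'   `"n_c"`, `"dG"`, `"sasa_total"`, `"sasa_apolar"`.
#' @param ... Passed to the metric function.
#' @return List of class `ensemble_average`: `mean`, `se` (NA with a
#'   single run/value), `run_means`, `values`.
#' @export
ensemble_average <- function(snapshots, metric, ...) {
  f <- if (is.function(metric)) metric else switch(
    metric,
    n_c = function(cf, ...) count_contacts(cf, ...),
    dG = function(cf, ...) binding_affinity(cf, ...),
    sasa_total = function(cf, ...) sasa(cf, ...)$total,
    sasa_apolar = function(cf, ...) sasa(cf, ...)$apolar,
    stop("unknown metric: ", metric)
  )
  stopifnot(length(snapshots) >= 1)
  has_runs <- !inherits(snapshots[[1]], "dimer_conformation")
  runs <- if (has_runs) snapshots else list(snapshots)
  vals <- lapply(runs, function(run)
    vapply(run, function(cf) f(cf, ...), numeric(1)))
  run_means <- vapply(vals, mean, numeric(1))
  # SE over independent-run means; with a single run, fall back to the
  # within-run SE over snapshots (NA for a single value)
  se <- if (length(run_means) > 1) {
    sd(run_means) / sqrt(length(run_means))
  } else if (length(vals[[1]]) > 1) {
    sd(vals[[1]]) / sqrt(length(vals[[1]]))
  } else NA_real_
  structure(list(mean = mean(run_means), se = se, run_means = run_means,
                 values = unlist(vals)),
            class = "ensemble_average")
}

#' @export
print.ensemble_average <- function(x, ...) {
  cat(sprintf("<ensemble_average> mean %.4g, se %s (%d run(s), %d values)\n",
              x$mean, ifelse(is.na(x$se), "NA", sprintf("%.3g", x$se)),
              length(x$run_means), length(x$values)))
  invisible(x)
}
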