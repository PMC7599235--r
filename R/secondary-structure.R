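#' Place an atom from internal coordinates (NeRF construction)
#'
#' @param a,b,c Coordinates of the three preceding atoms (3-vectors).
#' @param bond Distance c-new (Angstrom).
#' @param angle Angle b-c-new (degrees).
#' @param torsion Torsion a-b-c-new (degrees).
#' @return 3-vector.
#' @export
place_atom <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d <- c(-bond * cos(ang),
         bond * sin(ang) * cos(tor),
         bond * sin(ang) * sin(tor))
  c + d[1] * bc + d[2] * m + d[3] * n
}

# standard backbone internal coordinates
.bb_geom <- list(
  b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329, b_c_o = 1.231,
  a_n_ca_c = 111.2, a_ca_c_n = 116.2, a_c_n_ca = 121.7, a_ca_c_o = 120.8,
  omega = 180
)

#' Build an ideal peptide backbone from torsion angles
#'
#' Constructs N, CA, C, O coordinates for a chain with the given phi/psi
#' torsions using standard bond lengths and angles (NeRF chain build).
#' An ideal alpha helix is `phi = -57, psi = -47`; an extended strand is
#' about `phi = -139, psi = 135`.
#'
#' @param n_res Number of residues.
#' @param phi,psi Backbone torsions in degrees (recycled).
#' @param aa One-letter residue codes (recycled).
#' @param chain_id Chain identifier.
#' @param res_offset First residue number minus one.
#' @return A [monomer_structure()] with N, CA, C, O per residue.
#' @export
build_peptide_backbone <- function(n_res, phi = -57, psi = -47, aa = "A",
                                   chain_id = "A", res_offset = 0) {
  stopifnot(n_res >= 2)
  phi <- rep_len(phi, n_res)
  psi <- rep_len(psi, n_res)
  aa <- rep_len(aa, n_res)
  g <- .bb_geom
  coords <- matrix(NA_real_, nrow = 4 * n_res, ncol = 3)
  nm <- rep(c("N", "CA", "C", "O"), n_res)
  # seed first residue
  N1 <- c(0, 0, 0)
  CA1 <- c(g$b_n_ca, 0, 0)
  a1 <- g$a_n_ca_c * pi / 180
  C1 <- CA1 + g$b_ca_c * c(-cos(a1), sin(a1), 0)
  coords[1, ] <- N1
  coords[2, ] <- CA1
  coords[3, ] <- C1
  for (i in seq_len(n_res)) {
    base <- (i - 1) * 4
    Ni <- coords[base + 1, ]
    CAi <- coords[base + 2, ]
    Ci <- coords[base + 3, ]
    if (i < n_res) {
      Nn <- place_atom(Ni, CAi, Ci, g$b_c_n, g$a_ca_c_n, psi[i])
      CAn <- place_atom(CAi, Ci, Nn, g$b_n_ca, g$a_c_n_ca, g$omega)
      Cn <- place_atom(Ci, Nn, CAn, g$b_ca_c, g$a_n_ca_c, phi[i + 1])
      coords[base + 5, ] <- Nn
      coords[base + 6, ] <- CAn
      coords[base + 7, ] <- Cn
      # carbonyl O anti to the next N (torsion psi + 180)
      coords[base + 4, ] <- place_atom(Ni, CAi, Ci, g$b_c_o, g$a_ca_c_o,
                                       psi[i] + 180)
    } else {
      coords[base + 4, ] <- place_atom(Ni, CAi, Ci, g$b_c_o, g$a_ca_c_o,
                                       psi[i] + 180)
    }
  }
  monomer_structure(chain_id, data.frame(
    res_index = rep(seq_len(n_res) + res_offset, each = 4),
    aa = rep(aa, each = 4),
    name = nm,
    element = rep(c("N", "C", "C", "O"), n_res),
    x = coords[, 1], y = coords[, 2], z = coords[, 3],
    stringsAsFactors = FALSE
  ))
}

#' Secondary-structure assignment from backbone hydrogen bonds
#'
#' A DSSP-style assignment: amide hydrogens are reconstructed from the
#' preceding carbonyl, backbone hydrogen bonds are scored with the
#' Kabsch-Sander electrostatic energy (hbond when E < -0.5 kcal/mol),
#' helices come from consecutive i -> i+4 (H) or i -> i+3 (G) turn
#' patterns, strands (E) from parallel/antiparallel bridge patterns, T
#' marks remaining turn residues, C the rest.
#'
#' @param mon A `monomer_structure` with backbone N, CA, C, O atoms.
#' @param helix_labels Labels counted as helix in `helix_frac`.
#' @param energy_cutoff Hydrogen-bond energy threshold, kcal/mol.
#' @return Object of class `ss_profile`: `labels` (per residue),
#'   `helix_frac`, `strand_frac`.
#' @export
secondary_structure <- function(mon, helix_labels = c("H", "G"),
                                energy_cutoff = -0.5) {
  stopifnot(inherits(mon, "monomer_structure"))
  a <- mon$atoms
  ridx <- residue_indices(mon)
  n <- length(ridx)
  get_atom <- function(res, name) {
    row <- which(a$res_index == res & a$name == name)
    if (length(row) == 0L) return(NULL)
    as.numeric(a[row[1], c("x", "y", "z")])
  }
  N <- Ca <- C <- O <- matrix(NA_real_, n, 3)
  ok <- rep(TRUE, n)
  aas <- strsplit(monomer_sequence(mon), "")[[1]]
  for (i in seq_len(n)) {
    at <- lapply(c("N", "CA", "C", "O"), function(nm) get_atom(ridx[i], nm))
    if (any(vapply(at, is.null, logical(1)))) {
      ok[i] <- FALSE
      next
    }
    N[i, ] <- at[[1]]; Ca[i, ] <- at[[2]]; C[i, ] <- at[[3]]; O[i, ] <- at[[4]]
  }
  if (!all(ok)) warning("missing backbone atoms; affected residues labelled C")
  # reconstruct amide H: along the previous residue's C=O, flipped
  H <- matrix(NA_real_, n, 3)
  for (i in 2:n) {
    if (!ok[i] || !ok[i - 1]) next
    d <- C[i - 1, ] - O[i - 1, ]
    H[i, ] <- N[i, ] + d / sqrt(sum(d^2))
  }
  # Kabsch-Sander energy, donor i (NH), acceptor j (CO)
  hb <- matrix(FALSE, n, n)
  q1q2f <- 0.084 * 332
  for (i in seq_len(n)) {
    if (!ok[i] || anyNA(H[i, ]) || aas[i] == "P") next
    for (j in seq_len(n)) {
      if (!ok[j] || abs(i - j) < 2) next
      r_on <- sqrt(sum((O[j, ] - N[i, ])^2))
      if (r_on > 5.2) next
      r_ch <- sqrt(sum((C[j, ] - H[i, ])^2))
      r_oh <- sqrt(sum((O[j, ] - H[i, ])^2))
      r_cn <- sqrt(sum((C[j, ] - N[i, ])^2))
      e <- q1q2f * (1 / r_on + 1 / r_ch - 1 / r_oh - 1 / r_cn)
      if (e < energy_cutoff) hb[i, j] <- TRUE
    }
  }
  hbond <- function(acc, don) {                 # CO(acc) ... HN(don)
    acc >= 1 && acc <= n && don >= 1 && don <= n && hb[don, acc]
  }
  turn <- function(i, k) hbond(i, i + k)        # k-turn at i
  labels <- rep("C", n)
  # turns (T), lowest priority, assigned first then overwritten
  for (i in seq_len(n)) {
    for (k in c(3, 4, 5)) {
      if (i + k <= n && turn(i, k)) {
        labels[(i + 1):(i + k - 1)] <- "T"
      }
    }
  }
  # 3-10 helix
  for (i in 2:n) {
    if (i + 3 <= n && turn(i - 1, 3) && turn(i, 3)) {
      labels[i:(i + 2)] <- "G"
    }
  }
  # strand bridges
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (abs(i - j) < 3) next
      par <- (hbond(i - 1, j) && hbond(j, i + 1)) ||
             (hbond(j - 1, i) && hbond(i, j + 1))
      anti <- (hbond(i, j) && hbond(j, i)) ||
              (hbond(i - 1, j + 1) && hbond(j - 1, i + 1))
      if (par || anti) labels[i] <- "E"
    }
  }
  # alpha helix, highest priority
  for (i in 2:n) {
    if (i + 4 <= n && turn(i - 1, 4) && turn(i, 4)) {
      labels[i:(i + 3)] <- "H"
    }
  }
  labels[!ok] <- "C"
  structure(list(labels = labels,
                 helix_frac = mean(labels %in% helix_labels),
                 strand_frac = mean(labels == "E")),
            class = "ss_profile")
}

#' @export
print.ss_profile <- function(x, ...) {
  cat(sprintf("<ss_profile> helix %.1f%%, strand %.1f%%\n",
              100 * x$helix_frac, 100 * x$strand_frac))
  cat(paste(x$labels, collapse = ""), "\n")
  invisible(x)
}
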