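#' @useDynLib dimermc, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats aov TukeyHSD kruskal.test wilcox.test p.adjust sd
#'   rnorm runif rexp quantile shapiro.test setNames median pf
#' @importFrom utils write.table read.table combn
#' @importFrom graphics abline
NULL

.atomic_masses <- c(C = 12.011, N = 14.007, O = 15.999, S = 32.06,
                    H = 1.008, P = 30.974, SE = 78.971)

.backbone_names <- c("N", "CA", "C", "O")

# ---- constructors -----------------------------------------------------

#' Build a monomer structure from an atom table
#'
#' The atom table is the package's flat representation of a chain: one row
#' per atom with original (file) residue numbering. Residue records and
#' the one-letter sequence are derived views.
#'
#' @param chain_id Single chain identifier string.
#' @param atoms data.frame with columns `res_index` (1-based integer,
#'   non-decreasing by residue), `aa` (one-letter code), `name` (atom
#'   name), `element` (element symbol), `x`, `y`, `z` (Angstrom).
#' @return An object of class `monomer_structure`.
#' @export
monomer_structure <- function(chain_id, atoms) {
  stopifnot(is.character(chain_id), length(chain_id) == 1L)
  req <- c("res_index", "aa", "name", "element", "x", "y", "z")
  if (!all(req %in% names(atoms))) {
    stop("atom table must have columns: ", paste(req, collapse = ", "))
  }
  if (nrow(atoms) == 0L) stop("empty chain")
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")])))) {
    stop("non-finite coordinates")
  }
  atoms$element <- toupper(atoms$element)
  atoms$is_heavy <- atoms$element != "H"
  atoms$is_backbone <- atoms$name %in% .backbone_names
  ridx <- unique(atoms$res_index)
  if (any(diff(ridx) <= 0)) stop("residue indices must be strictly increasing")
  if (any(ridx < 1)) stop("residue indices must be >= 1")
  structure(
    list(chain_id = chain_id, atoms = atoms),
    class = "monomer_structure"
  )
}

#' @export
print.monomer_structure <- function(x, ...) {
  cat(sprintf("<monomer_structure> chain %s: %d residues, %d atoms\n",
              x$chain_id, n_residues(x), nrow(x$atoms)))
  invisible(x)
}

#' Number of residues in a monomer
#' @param mon A `monomer_structure`.
#' @return Integer count.
#' @export
n_residues <- function(mon) length(unique(mon$atoms$res_index))

#' Residue indices of a monomer (original numbering)
#' @param mon A `monomer_structure`.
#' @return Integer vector, strictly increasing.
#' @export
residue_indices <- function(mon) unique(mon$atoms$res_index)

#' One-letter sequence of a monomer
#' @param mon A `monomer_structure`.
#' @return Character scalar.
#' @export
monomer_sequence <- function(mon) {
  first <- !duplicated(mon$atoms$res_index)
  paste(mon$atoms$aa[first], collapse = "")
}

#' Per-residue chemical classes of a monomer
#' @param mon A `monomer_structure`.
#' @return Character vector (charged/polar/apolar), one per residue.
#' @export
residue_classes <- function(mon) {
  first <- !duplicated(mon$atoms$res_index)
  classify_residue(mon$atoms$aa[first])
}

#' Coordinate matrix of a monomer
#' @param mon A `monomer_structure`.
#' @param subset Optional: `"heavy"`, `"backbone"` or `"ca"`.
#' @return Numeric matrix n x 3.
#' @export
atom_coords <- function(mon, subset = NULL) {
  a <- mon$atoms
  keep <- switch(
    subset %||% "all",
    all = rep(TRUE, nrow(a)),
    heavy = a$is_heavy,
    backbone = a$is_backbone,
    ca = a$name == "CA",
    stop("unknown subset: ", subset)
  )
  as.matrix(a[keep, c("x", "y", "z")])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build a two-chain dimer conformation
#'
#' @param monomer_a,monomer_b `monomer_structure` objects.
#' @param box_side Side of the cubic simulation box (Angstrom).
#' @param periodic Whether periodic boundary conditions apply.
#' @return Object of class `dimer_conformation`.
#' @export
dimer_conformation <- function(monomer_a, monomer_b, box_side = 120,
                               periodic = TRUE) {
  stopifnot(inherits(monomer_a, "monomer_structure"),
            inherits(monomer_b, "monomer_structure"))
  if (periodic && !(is.numeric(box_side) && box_side > 0)) {
    stop("box_side must be > 0 when periodic")
  }
  structure(
    list(monomer_a = monomer_a, monomer_b = monomer_b,
         box_side = box_side, periodic = periodic),
    class = "dimer_conformation"
  )
}

#' @export
print.dimer_conformation <- function(x, ...) {
  cat(sprintf(
    "<dimer_conformation> chains %s (%d res) + %s (%d res), box %.0f A%s\n",
    x$monomer_a$chain_id, n_residues(x$monomer_a),
    x$monomer_b$chain_id, n_residues(x$monomer_b),
    x$box_side, if (x$periodic) " periodic" else ""))
  invisible(x)
}

# ---- PDB I/O ----------------------------------------------------------

.aa_three_to_one <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLU = "E",
  GLN = "Q", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V"
)
.aa_one_to_three <- setNames(names(.aa_three_to_one), .aa_three_to_one)

.element_from_name <- function(name) {
  stripped <- gsub("[0-9']", "", name)
  ifelse(substr(stripped, 1, 1) == "H", "H", substr(stripped, 1, 1))
}

#' Read a two-chain dimer from a PDB file
#'
#' Parses ATOM records of the two requested chains into a
#' [dimer_conformation()]. Hydrogens are kept but flagged non-heavy;
#' HETATM and non-standard residues are skipped with a message; altloc
#' codes other than blank or 'A' are rejected.
#'
#' @param path Path to a PDB file.
#' @param chain_a,chain_b Chain identifiers to extract.
#' @param box_side,periodic Passed to [dimer_conformation()].
#' @return A `dimer_conformation`.
#' @export
read_dimer_pdb <- function(path, chain_a = "A", chain_b = "B",
                           box_side = 120, periodic = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  atom_lines <- which(startsWith(lines, "ATOM"))
  for (i in atom_lines) {
    ln <- lines[i]
    if (nchar(ln) < 54 ||
        anyNA(suppressWarnings(as.numeric(c(
          substr(ln, 31, 38), substr(ln, 39, 46), substr(ln, 47, 54)))))) {
      stop("malformed ATOM record at line ", i)
    }
  }
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  n_het <- sum(at$type == "HETATM")
  if (n_het > 0) message("skipping ", n_het, " HETATM records")
  at <- at[at$type == "ATOM", , drop = FALSE]
  bad_alt <- !(is.na(at$alt) | at$alt %in% c("", "A"))
  if (any(bad_alt)) stop("alternate location codes other than 'A' present")
  nonstd <- !(at$resid %in% names(.aa_three_to_one))
  if (any(nonstd)) {
    message("skipping ", sum(nonstd), " atoms of non-standard residues")
    at <- at[!nonstd, , drop = FALSE]
  }
  grab <- function(chain) {
    sub <- at[at$chain == chain, , drop = FALSE]
    if (nrow(sub) == 0L) {
      if (!(chain %in% at$chain)) stop("chain not found: ", chain)
      stop("empty chain: ", chain)
    }
    elem <- toupper(sub$elesy)
    missing_elem <- is.na(elem) | elem == ""
    elem[missing_elem] <- .element_from_name(sub$elety[missing_elem])
    monomer_structure(chain, data.frame(
      res_index = sub$resno,
      aa = unname(.aa_three_to_one[sub$resid]),
      name = sub$elety,
      element = elem,
      x = sub$x, y = sub$y, z = sub$z,
      stringsAsFactors = FALSE
    ))
  }
  dimer_conformation(grab(chain_a), grab(chain_b),
                     box_side = box_side, periodic = periodic)
}

#' Write a dimer conformation as a PDB file
#'
#' Emits only ATOM/TER/END records, 3-decimal coordinates, one TER after
#' each chain.
#'
#' @param conf A `dimer_conformation`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_dimer_pdb <- function(conf, path) {
  stopifnot(inherits(conf, "dimer_conformation"))
  serial <- 0L
  fmt_chain <- function(mon) {
    a <- mon$atoms
    out <- character(nrow(a))
    for (i in seq_len(nrow(a))) {
      serial <<- serial + 1L
      nm <- a$name[i]
      nm_field <- if (nchar(nm) >= 4) substr(nm, 1, 4) else sprintf(" %-3s", nm)
      out[i] <- sprintf(
        "ATOM  %5d %4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        serial, nm_field, .aa_one_to_three[a$aa[i]],
        substr(mon$chain_id, 1, 1), a$res_index[i],
        a$x[i], a$y[i], a$z[i], 1.00, 0.00, a$element[i])
    }
    last <- nrow(a)
    ter <- sprintf("TER   %5d      %3s %1s%4d", serial + 1L,
                   .aa_one_to_three[a$aa[last]], substr(mon$chain_id, 1, 1),
                   a$res_index[last])
    serial <<- serial + 1L
    c(out, ter)
  }
  lines <- c(fmt_chain(conf$monomer_a), fmt_chain(conf$monomer_b), "END")
  writeLines(lines, path)
  invisible(path)
}

# ---- geometry ---------------------------------------------------------

#' Optimal-superposition backbone RMSD
#'
#' Root-mean-square deviation between two matched coordinate sets after
#' optimal rigid superposition (Kabsch algorithm: centroid translation
#' plus the rotation from the SVD of the covariance, with the reflection
#' guard). When monomer structures are given, backbone atoms are matched
#' by residue index and atom name.
#'
#' @param conf,ref `monomer_structure` objects or n x 3 coordinate
#'   matrices with rows already matched.
#' @return RMSD in Angstrom (>= 0).
#' @export
backbone_rmsd <- function(conf, ref) {
  p <- .matched_backbone(conf, ref)
  kabsch_rmsd(p$a, p$b)
}

.matched_backbone <- function(conf, ref) {
  if (is.matrix(conf) && is.matrix(ref)) {
    if (!all(dim(conf) == dim(ref))) stop("incompatible structures")
    return(list(a = conf, b = ref))
  }
  key <- function(mon) {
    a <- mon$atoms[mon$atoms$is_backbone, , drop = FALSE]
    list(k = paste(a$res_index, a$name), xyz = as.matrix(a[, c("x", "y", "z")]))
  }
  ka <- key(conf); kb <- key(ref)
  if (length(ka$k) != length(kb$k) || !all(ka$k == kb$k)) {
    m <- match(ka$k, kb$k)
    if (anyNA(m) || length(ka$k) != length(kb$k)) stop("incompatible structures")
    kb$xyz <- kb$xyz[m, , drop = FALSE]
  }
  list(a = ka$xyz, b = kb$xyz)
}

#' Kabsch RMSD between two matched coordinate matrices
#'
#' @param a,b n x 3 matrices, rows matched.
#' @return Minimum RMSD over rigid superposition, Angstrom.
#' @export
kabsch_rmsd <- function(a, b) {
  if (!all(dim(a) == dim(b)) || ncol(a) != 3) stop("incompatible structures")
  n <- nrow(a)
  if (n < 1) stop("incompatible structures")
  ac <- sweep(a, 2, colMeans(a))
  bc <- sweep(b, 2, colMeans(b))
  h <- crossprod(ac, bc)
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  diffs <- bc - ac %*% t(rot)
  sqrt(sum(diffs^2) / n)
}

#' Center of mass of a monomer
#'
#' @param mon A `monomer_structure`.
#' @param weighting `"mass"` (standard atomic masses) or `"geometric"`.
#' @return 3-vector, Angstrom.
#' @export
center_of_mass <- function(mon, weighting = c("mass", "geometric")) {
  weighting <- match.arg(weighting)
  xyz <- atom_coords(mon)
  w <- if (weighting == "mass") {
    m <- .atomic_masses[mon$atoms$element]
    if (anyNA(m)) stop("no atomic mass for element: ",
                       paste(unique(mon$atoms$element[is.na(m)]), collapse = ", "))
    m
  } else rep(1, nrow(xyz))
  colSums(xyz * w) / sum(w)
}

#' Central C-alpha of a monomer
#'
#' Returns the C-alpha atom closest to the monomer's center of mass (ties
#' broken by lowest residue index). This is the anchor on which the
#' pulling force acts.
#'
#' @param mon A `monomer_structure`.
#' @param weighting Passed to [center_of_mass()].
#' @return List with `res_index`, `atom_row` (row in the atom table) and
#'   `coords`.
#' @export
central_calpha <- function(mon, weighting = c("mass", "geometric")) {
  weighting <- match.arg(weighting)
  ca_rows <- which(mon$atoms$name == "CA")
  if (length(ca_rows) == 0L) stop("monomer has no CA atoms")
  com <- center_of_mass(mon, weighting)
  xyz <- as.matrix(mon$atoms[ca_rows, c("x", "y", "z")])
  d2 <- rowSums(sweep(xyz, 2, com)^2)
  best <- ca_rows[order(d2, mon$atoms$res_index[ca_rows])][1]
  list(res_index = mon$atoms$res_index[best], atom_row = best,
       coords = as.numeric(mon$atoms[best, c("x", "y", "z")]))
}

#' Minimum-image distance in a periodic cubic box
#'
#' @param x1,x2 3-vectors, Angstrom.
#' @param box_side Box side, Angstrom (> 0).
#' @return Distance under the minimum-image convention; at most
#'   sqrt(3)/2 * box_side.
#' @export
min_image_distance <- function(x1, x2, box_side) {
  stopifnot(box_side > 0)
  d <- x1 - x2
  d <- d - box_side * round(d / box_side)
  sqrt(sum(d^2))
}
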