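#' Physical constants and unit conversions
#'
#' All energies in the package are kcal/mol, distances in Angstrom, forces
#' in pN, temperatures in K. SASA is Angstrom^2 internally and nm^2 at the
#' report layer. The conversions are derived from CODATA values at load
#' time rather than hard-coded, so that e.g. kT at 300 K is computed, not
#' typed in.
#'
#' @format A list with elements:
#' \describe{
#'   \item{kB_kcal_mol_K}{Boltzmann constant times Avogadro, kcal/mol/K.}
#'   \item{pN_A_to_kcal_mol}{Energy of 1 pN force acting over 1 Angstrom,
#'     in kcal/mol.}
#'   \item{A2_per_nm2}{Angstrom^2 per nm^2.}
#' }
#' @export
dimer_constants <- local({
  kB_J_K <- 1.380649e-23          # exact SI
  N_A <- 6.02214076e23            # exact SI
  J_per_kcal <- 4184              # thermochemical calorie
  list(
    kB_kcal_mol_K = kB_J_K * N_A / J_per_kcal,
    pN_A_to_kcal_mol = 1e-12 * 1e-10 * N_A / J_per_kcal,
    A2_per_nm2 = 100
  )
})

#' Thermal energy kT in kcal/mol
#'
#' @param temperature Temperature in Kelvin.
#' @return kT in kcal/mol (about 0.596 at 300 K).
#' @export
kT_kcal <- function(temperature = 300) {
  dimer_constants$kB_kcal_mol_K * temperature
}

# Residue chemistry table used for interface classification and the
# contact-based affinity model. One configurable constant; His counts as
# charged, consistent with the affinity model's interface classes.
.chem_class_table <- c(
  D = "charged", E = "charged", K = "charged", R = "charged", H = "charged",
  A = "apolar", C = "apolar", G = "apolar", F = "apolar", I = "apolar",
  M = "apolar", L = "apolar", P = "apolar", V = "apolar", W = "apolar",
  N = "polar", Q = "polar", S = "polar", T = "polar", Y = "polar"
)

.standard_aa <- names(.chem_class_table)

# ProtOr-style van der Waals radii by element (Angstrom). Config data, not
# code: sasa() takes a radii table argument defaulting to this one.
.vdw_radii <- c(
  C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20, P = 1.80,
  SE = 1.90
)

# Theoretical maximum per-residue SASA (Angstrom^2), Gly-X-Gly tripeptide
# scale; used for relative SASA when deciding surface exposure.
.max_sasa <- c(
  A = 129, R = 274, N = 195, D = 193, C = 167, E = 223, Q = 225,
  G = 104, H = 224, I = 197, L = 201, K = 236, M = 224, F = 240,
  P = 159, S = 155, T = 172, W = 285, Y = 263, V = 174
)

#' Coefficients of the contact-based binding-affinity model
#'
#' Linear model predicting the binding free energy (kcal/mol) of a
#' protein-protein complex from interface contact counts by residue-class
#' pair (charged/polar/apolar, at a 5.5 Angstrom heavy-atom rule) and the
#' percentage composition of the non-interacting surface (NIS). The
#' coefficients are data, not code, so alternative parameterisations can
#' be supplied to [binding_affinity()].
#'
#' @format Named list: `ic` (named numeric, one weight per unordered class
#'   pair `cc, cp, ca, pp, pa, aa`), `nis_apolar`, `nis_charged`,
#'   `intercept`, and a `version` string.
#' @export
affinity_coefficients <- list(
  ic = c(cc = -0.09459, cp = 0, ca = -0.00826,
         pp = 0.19577, pa = -0.22671, aa = 0),
  nis_apolar = 0.18681,
  nis_charged = 0.13810,
  intercept = -15.9433,
  version = "contact-IC/NIS-2015"
)

#' Classify a residue as charged, polar or apolar
#'
#' Fixed-table classification of the 20 standard amino acids into the three
#' chemical classes used by the interface analytics and the contact-based
#' affinity model: charged = D,E,K,R,H; apolar = A,C,G,F,I,M,L,P,V,W;
#' polar = N,Q,S,T,Y.
#'
#' @param aa One-letter amino-acid code (vectorised).
#' @param table Optional replacement classification table (named character
#'   vector mapping one-letter codes to class names).
#' @return Character vector of classes.
#' @examples
#' classify_residue("D")  # "charged"
#' classify_residue(c("L", "S"))
#' @export
classify_residue <- function(aa, table = .chem_class_table) {
  aa <- toupper(aa)
  bad <- !(aa %in% names(table))
  if (any(bad)) {
    stop("unknown residue: ", paste(unique(aa[bad]), collapse = ", "))
  }
  unname(table[aa])
}
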