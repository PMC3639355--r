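## Residue templates and ideal-geometry peptide construction.
##
## Backbone geometry follows standard values (Engh-Huber-like): N-CA 1.458,
## CA-C 1.525, C-N 1.329, C=O 1.231 Angstrom. Side chains are built from
## internal-coordinate recipes; the template set covers the residue types
## needed for 7TM binding-site fixtures (Ala, Gly, Ser, Asp, Phe, Lys).

BB_GEOM <- list(
  n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231,
  ang_n_ca_c = 111.2, ang_ca_c_n = 116.2, ang_c_n_ca = 121.7,
  ang_ca_c_o = 120.8, omega = 180
)

## Side-chain internal-coordinate recipes. Reference atoms are residue-local
## names; `tors` may be numeric or "chi1"/"chi2" (+offset applied via tadd).
## CB placement (a=N, b=C, c=CA, torsion +122.7 deg) encodes L-chirality.
SIDECHAIN_RECIPES <- list(
  GLY = list(),
  ALA = list(
    list(atom = "CB", el = "C", a = "N", b = "C", c = "CA",
         bond = 1.530, angle = 110.3, tors = 122.7, tadd = 0)
  ),
  SER = list(
    list(atom = "CB", el = "C", a = "N", b = "C", c = "CA",
         bond = 1.530, angle = 110.3, tors = 122.7, tadd = 0),
    list(atom = "OG", el = "O", a = "N", b = "CA", c = "CB",
         bond = 1.417, angle = 110.8, tors = "chi1", tadd = 0),
    list(atom = "HG", el = "H", a = "CA", b = "CB", c = "OG",
         bond = 0.960, angle = 109.5, tors = 180, tadd = 0)
  ),
  ASP = list(
    list(atom = "CB", el = "C", a = "N", b = "C", c = "CA",
         bond = 1.530, angle = 110.3, tors = 122.7, tadd = 0),
    list(atom = "CG", el = "C", a = "N", b = "CA", c = "CB",
         bond = 1.516, angle = 112.6, tors = "chi1", tadd = 0),
    list(atom = "OD1", el = "O", a = "CA", b = "CB", c = "CG",
         bond = 1.249, angle = 118.4, tors = "chi2", tadd = 0),
    list(atom = "OD2", el = "O", a = "CA", b = "CB", c = "CG",
         bond = 1.249, angle = 118.4, tors = "chi2", tadd = 180)
  ),
  PHE = list(
    list(atom = "CB", el = "C", a = "N", b = "C", c = "CA",
         bond = 1.530, angle = 110.3, tors = 122.7, tadd = 0),
    list(atom = "CG", el = "C", a = "N", b = "CA", c = "CB",
         bond = 1.502, angle = 113.8, tors = "chi1", tadd = 0),
    list(atom = "CD1", el = "C", a = "CA", b = "CB", c = "CG",
         bond = 1.390, angle = 120.8, tors = "chi2", tadd = 0),
    list(atom = "CD2", el = "C", a = "CA", b = "CB", c = "CG",
         bond = 1.390, angle = 120.8, tors = "chi2", tadd = 180),
    list(atom = "CE1", el = "C", a = "CB", b = "CG", c = "CD1",
         bond = 1.390, angle = 120.1, tors = 180, tadd = 0),
    list(atom = "CE2", el = "C", a = "CB", b = "CG", c = "CD2",
         bond = 1.390, angle = 120.1, tors = 180, tadd = 0),
    list(atom = "CZ", el = "C", a = "CG", b = "CD1", c = "CE1",
         bond = 1.390, angle = 120.0, tors = 0, tadd = 0)
  ),
  LYS = list(
    list(atom = "CB", el = "C", a = "N", b = "C", c = "CA",
         bond = 1.530, angle = 110.3, tors = 122.7, tadd = 0),
    list(atom = "CG", el = "C", a = "N", b = "CA", c = "CB",
         bond = 1.520, angle = 114.1, tors = "chi1", tadd = 0),
    list(atom = "CD", el = "C", a = "CA", b = "CB", c = "CG",
         bond = 1.520, angle = 111.3, tors = 180, tadd = 0),
    list(atom = "CE", el = "C", a = "CB", b = "CG", c = "CD",
         bond = 1.520, angle = 111.3, tors = 180, tadd = 0),
    list(atom = "NZ", el = "N", a = "CG", b = "CD", c = "CE",
         bond = 1.489, angle = 111.9, tors = 180, tadd = 0)
  )
)

CHI_DEFAULTS <- list(chi1 = -65, chi2 = -20)
## Ring chi2 for Phe is conventionally near 90
CHI_DEFAULTS_BY_RES <- list(PHE = list(chi1 = -65, chi2 = 90))

## Simple fixed partial charges for protein atoms (surrogate force field).
## Backbone amide dipole + charged/polar side-chain groups; apolar atoms 0.
protein_charge <- function(resname, atom) {
  bb <- c(N = -0.35, CA = 0.10, C = 0.45, O = -0.45)
  if (atom %in% names(bb)) return(unname(bb[atom]))
  key <- paste(resname, atom)
  sc <- c("SER OG" = -0.40, "SER HG" = 0.40,
          "ASP CG" = 0.40, "ASP OD1" = -0.70, "ASP OD2" = -0.70,
          "LYS NZ" = 1.00)
  if (key %in% names(sc)) return(unname(sc[key]))
  0
}

## Side-chain torsion axes for Monte Carlo moves: list of c(fixed, axis_from,
## axis_to) atom names; atoms beyond `axis_to` in the recipe order move.
SIDECHAIN_CHI_AXES <- list(
  SER = list(chi1 = c("N", "CA", "CB")),
  ASP = list(chi1 = c("N", "CA", "CB"), chi2 = c("CA", "CB", "CG")),
  PHE = list(chi1 = c("N", "CA", "CB"), chi2 = c("CA", "CB", "CG")),
  LYS = list(chi1 = c("N", "CA", "CB"), chi2 = c("CA", "CB", "CG"),
             chi3 = c("CB", "CG", "CD"), chi4 = c("CG", "CD", "CE")),
  ALA = list(), GLY = list()
)

## Atoms moved by each chi rotation (everything further out on the side chain)
sidechain_downstream <- function(resname, chi_index) {
  rec <- SIDECHAIN_RECIPES[[resname]]
  nm <- vapply(rec, `[[`, "", "atom")
  anchor <- switch(resname,
    SER = c("OG", "HG"), ASP = c("CG", "OD1", "OD2"),
    PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
    LYS = c("CG", "CD", "CE", "NZ"), character(0))
  if (chi_index == 1) return(intersect(nm, anchor))
  ## deeper chis: drop the first (chi_index - 1) chain atoms
  chain <- switch(resname,
    ASP = list(c("OD1", "OD2")), PHE = list(c("CD1", "CD2", "CE1", "CE2", "CZ")),
    LYS = list(c("CD", "CE", "NZ"), c("CE", "NZ"), c("NZ")),
    list(character(0)))
  chain[[chi_index - 1]]
}

#' Build a peptide with specified backbone torsions
#'
#' Constructs an all-heavy-atom (plus serine hydroxyl hydrogen) peptide chain
#' with ideal covalent geometry by internal-coordinate chain extension.
#'
#' @param sequence character vector of three-letter residue names (supported:
#'   ALA, GLY, SER, ASP, PHE, LYS).
#' @param phi,psi backbone torsions in degrees, recycled along the chain.
#'   Defaults are the ideal alpha-helix values (-57, -47).
#' @param chi optional named list `list(resid = list(chi1 = ...))` overriding
#'   side-chain torsion defaults for specific (1-based) residues.
#' @return data.frame with columns resid, resname, atom, element, x, y, z,
#'   charge.
#' @export
build_peptide <- function(sequence, phi = -57, psi = -47, chi = NULL) {
  sequence <- toupper(sequence)
  bad <- setdiff(unique(sequence), names(SIDECHAIN_RECIPES))
  if (length(bad)) stop("unsupported residue type(s): ", paste(bad, collapse = ", "))
  n <- length(sequence)
  phi <- rep_len(phi, n); psi <- rep_len(psi, n)
  g <- BB_GEOM
  rows <- list()
  add <- function(resid, resname, atom, el, xyz) {
    rows[[length(rows) + 1]] <<- data.frame(
      resid = resid, resname = resname, atom = atom, element = el,
      x = xyz[1], y = xyz[2], z = xyz[3],
      charge = protein_charge(resname, atom), stringsAsFactors = FALSE)
  }
  ## first residue backbone in a canonical local frame
  N1 <- c(0, 0, 0)
  CA1 <- c(g$n_ca, 0, 0)
  C1 <- CA1 + g$ca_c * c(-cos(g$ang_n_ca_c * pi / 180),
                         sin(g$ang_n_ca_c * pi / 180), 0)
  bb <- list(list(N = N1, CA = CA1, C = C1))
  for (i in seq_len(n)[-1]) {
    p <- bb[[i - 1]]
    Ni <- place_atom(p$N, p$CA, p$C, g$c_n, g$ang_ca_c_n, psi[i - 1])
    CAi <- place_atom(p$CA, p$C, Ni, g$n_ca, g$ang_c_n_ca, g$omega)
    Ci <- place_atom(p$C, Ni, CAi, g$ca_c, g$ang_n_ca_c, phi[i])
    bb[[i]] <- list(N = Ni, CA = CAi, C = Ci)
  }
  for (i in seq_len(n)) {
    res <- sequence[i]
    p <- bb[[i]]
    add(i, res, "N", "N", p$N)
    add(i, res, "CA", "C", p$CA)
    add(i, res, "C", "C", p$C)
    ## carbonyl O: torsion psi + 180 about N-CA-C
    o_tor <- if (i < n) psi[i] + 180 else psi[i] + 180
    add(i, res, "O", "O", place_atom(p$N, p$CA, p$C, g$c_o, g$ang_ca_c_o, o_tor))
    pos <- list(N = p$N, CA = p$CA, C = p$C)
    chis <- utils::modifyList(
      utils::modifyList(CHI_DEFAULTS,
                        CHI_DEFAULTS_BY_RES[[res]] %||% list()),
      (chi[[as.character(i)]] %||% list()))
    for (rec in SIDECHAIN_RECIPES[[res]]) {
      tors <- if (is.character(rec$tors)) chis[[rec$tors]] + rec$tadd
              else rec$tors + rec$tadd
      xyz <- place_atom(pos[[rec$a]], pos[[rec$b]], pos[[rec$c]],
                        rec$bond, rec$angle, tors)
      pos[[rec$atom]] <- xyz
      add(i, res, rec$atom, rec$el, xyz)
    }
  }
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Intra-residue bonds (pairs of atom names) per residue type
residue_bonds <- function(resname) {
  bb <- list(c("N", "CA"), c("CA", "C"), c("C", "O"))
  sc <- switch(resname,
    GLY = list(),
    ALA = list(c("CA", "CB")),
    SER = list(c("CA", "CB"), c("CB", "OG"), c("OG", "HG")),
    ASP = list(c("CA", "CB"), c("CB", "CG"), c("CG", "OD1"), c("CG", "OD2")),
    PHE = list(c("CA", "CB"), c("CB", "CG"), c("CG", "CD1"), c("CG", "CD2"),
               c("CD1", "CE1"), c("CD2", "CE2"), c("CE1", "CZ"), c("CE2", "CZ")),
    LYS = list(c("CA", "CB"), c("CB", "CG"), c("CG", "CD"), c("CD", "CE"),
               c("CE", "NZ")),
    stop("unsupported residue: ", resname))
  c(bb, sc)
}

## Bond list (2-column matrix of row indices) for a peptide atom table
peptide_bond_list <- function(atoms) {
  idx <- function(resid, atom) {
    w <- which(atoms$resid == resid & atoms$atom == atom)
    if (length(w) != 1) NA_integer_ else w
  }
  out <- list()
  for (r in unique(atoms$resid)) {
    resname <- atoms$resname[atoms$resid == r][1]
    for (b in residue_bonds(resname)) {
      i <- idx(r, b[1]); j <- idx(r, b[2])
      if (!is.na(i) && !is.na(j)) out[[length(out) + 1]] <- c(i, j)
    }
    jn <- idx(r + 1, "N"); jc <- idx(r, "C")
    if (!is.na(jn) && !is.na(jc)) out[[length(out) + 1]] <- c(jc, jn)
  }
  if (!length(out)) return(matrix(integer(0), 0, 2))
  do.call(rbind, out)
}
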