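# Element tables shared across parsing, perception and the detectors.

# Single-bond covalent radii (Angstrom), Cordero-style values for the elements
# that occur in protein-ligand structure files.
COVALENT_RADII <- c(
  H = 0.31, D = 0.31, C = 0.77, N = 0.70, O = 0.66, S = 1.05, P = 1.07,
  F = 0.57, Cl = 0.99, Br = 1.14, I = 1.33, B = 0.84, Se = 1.17,
  Zn = 1.22, Ca = 1.76, Mg = 1.41, Mn = 1.39, Fe = 1.32, Cu = 1.32,
  Ni = 1.24, Co = 1.26, Cd = 1.44, Hg = 1.32, Na = 1.66, K = 2.03
)

# Monoatomic ions recognised as metals/counter-ions by residue or atom name.
# PDB files carry no formal charge column, so identity is by name.
METAL_RESIDUES <- c(
  "ZN", "CA", "MG", "MN", "FE", "CU", "NI", "CO", "CD", "HG",
  "NA", "K", "LI", "CL", "BR", "IOD", "CS", "RB", "SR", "BA", "AL"
)

WATER_RESIDUES <- c("HOH", "WAT", "H2O", "TIP", "TIP3", "SOL", "DOD")

STANDARD_AA <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL"
)

# AutoDock atom types (PDBQT column 78+) -> element, plus an aromatic hint for
# type "A" (aromatic carbon).
AUTODOCK_TYPES <- c(
  A = "C", C = "C", N = "N", NA. = "N", NS = "N", OA = "O", OS = "O",
  S = "S", SA = "S", H = "H", HD = "H", HS = "H", P = "P", F = "F",
  Cl = "Cl", CL = "Cl", Br = "Br", BR = "Br", I = "I",
  Zn = "Zn", ZN = "Zn", Mg = "Mg", MG = "Mg", Ca = "Ca", CA. = "Ca",
  Mn = "Mn", MN = "Mn", Fe = "Fe", FE = "Fe"
)

normalize_element <- function(x) {
  x <- toupper(trimws(x))
  out <- paste0(substr(x, 1, 1), tolower(substr(x, 2, 2)))
  out[x == ""] <- ""
  out
}

covalent_radius <- function(element) {
  r <- COVALENT_RADII[element]
  # unknown elements fall back to a carbon-like radius
  r[is.na(r)] <- 0.77
  unname(r)
}

#' Guess an element symbol from a PDB atom name
#'
#' Used when columns 77-78 of a PDB/PDBQT line are blank. Leading digits are
#' stripped (`"1HB"` is a hydrogen); two-letter symbols are recognised for
#' hetero records whose residue name is a known monoatomic ion, so that a
#' calcium ion `CA` is not confused with an alpha-carbon.
#'
#' @param name Atom name string(s).
#' @param res_name Residue name(s), used to disambiguate metal ions.
#' @param is_hetero Logical; whether the record is HETATM.
#' @return Character vector of element symbols.
#' @keywords internal
guess_element <- function(name, res_name = "", is_hetero = FALSE) {
  stripped <- toupper(gsub("^[0-9']+", "", trimws(name)))
  res_name <- toupper(trimws(res_name))
  first <- substr(stripped, 1, 1)
  two <- substr(stripped, 1, 2)
  el <- first
  metal_hit <- is_hetero & res_name %in% METAL_RESIDUES & two %in%
    toupper(names(COVALENT_RADII))
  el[metal_hit] <- two[metal_hit]
  halogen <- two %in% c("CL", "BR") & is_hetero
  el[halogen] <- two[halogen]
  normalize_element(el)
}
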