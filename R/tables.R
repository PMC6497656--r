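#' BLOSUM62 substitution matrix
#'
#' Returns the standard BLOSUM62 substitution matrix over the 20 amino-acid
#' one-letter codes plus `X` (unknown / nonstandard residue). Scores are the
#' usual half-bit integers; `X` scores -1 against everything (0 against
#' itself by the same convention as EMBOSS EBLOSUM62's `X` row is not used:
#' we keep -1 on the diagonal too so unknown residues never count as
#' identical by score).
#'
#' @return A 21 x 21 integer matrix with dimnames.
#' @export
#' @examples
#' blosum62()["L", "I"] # 2, a conservative substitution
blosum62 <- function() .pc_blosum62

.pc_aa21 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L",
              "K", "M", "F", "P", "S", "T", "W", "Y", "V", "X")

.pc_blosum62 <- matrix(c(
  4, -1, -2, -2, 0, -1, -1, 0, -2, -1, -1, -1, -1, -2, -1, 1, 0, -3, -2, 0, -1,
  -1, 5, 0, -2, -3, 1, 0, -2, 0, -3, -2, 2, -1, -3, -2, -1, -1, -3, -2, -3, -1,
  -2, 0, 6, 1, -3, 0, 0, 0, 1, -3, -3, 0, -2, -3, -2, 1, 0, -4, -2, -3, -1,
  -2, -2, 1, 6, -3, 0, 2, -1, -1, -3, -4, -1, -3, -3, -1, 0, -1, -4, -3, -3, -1,
  0, -3, -3, -3, 9, -3, -4, -3, -3, -1, -1, -3, -1, -2, -3, -1, -1, -2, -2, -1, -1,
  -1, 1, 0, 0, -3, 5, 2, -2, 0, -3, -2, 1, 0, -3, -1, 0, -1, -2, -1, -2, -1,
  -1, 0, 0, 2, -4, 2, 5, -2, 0, -3, -3, 1, -2, -3, -1, 0, -1, -3, -2, -2, -1,
  0, -2, 0, -1, -3, -2, -2, 6, -2, -4, -4, -2, -3, -3, -2, 0, -2, -2, -3, -3, -1,
  -2, 0, 1, -1, -3, 0, 0, -2, 8, -3, -3, -1, -2, -1, -2, -1, -2, -2, 2, -3, -1,
  -1, -3, -3, -3, -1, -3, -3, -4, -3, 4, 2, -3, 1, 0, -3, -2, -1, -3, -1, 3, -1,
  -1, -2, -3, -4, -1, -2, -3, -4, -3, 2, 4, -2, 2, 0, -3, -2, -1, -2, -1, 1, -1,
  -1, 2, 0, -1, -3, 1, 1, -2, -1, -3, -2, 5, -1, -3, -1, 0, -1, -3, -2, -2, -1,
  -1, -1, -2, -3, -1, 0, -2, -3, -2, 1, 2, -1, 5, 0, -2, -1, -1, -1, -1, 1, -1,
  -2, -3, -3, -3, -2, -3, -3, -3, -1, 0, 0, -3, 0, 6, -4, -2, -2, 1, 3, -1, -1,
  -1, -2, -2, -1, -3, -1, -1, -2, -2, -3, -3, -1, -2, -4, 7, -1, -1, -4, -3, -2, -1,
  1, -1, 1, 0, -1, 0, 0, 0, -1, -2, -2, 0, -1, -2, -1, 4, 1, -3, -2, -2, -1,
  0, -1, 0, -1, -1, -1, -1, -2, -2, -1, -1, -1, -1, -2, -1, 1, 5, -2, -2, 0, -1,
  -3, -3, -4, -4, -2, -2, -3, -2, -2, -3, -2, -3, -1, 1, -4, -3, -2, 11, 2, -3, -1,
  -2, -2, -2, -3, -2, -1, -2, -3, 2, -1, -1, -2, -1, 3, -3, -2, -2, 2, 7, -1, -1,
  0, -3, -3, -3, -1, -2, -2, -3, -3, 3, 1, -2, 1, -1, -2, -2, 0, -3, -1, 4, -1,
  -1, -1, -1, -1, -1, -1, -1, -1, -1, -1, -1, -1, -1, -1, -1, -1, -1, -1, -1, -1, -1),
  nrow = 21, byrow = TRUE, dimnames = list(.pc_aa21, .pc_aa21))

# Standard atomic masses (u); used for mass-weighted radius of gyration.
.pc_masses <- c(H = 1.008, D = 2.014, C = 12.011, N = 14.007, O = 15.999,
                S = 32.06, P = 30.974, SE = 78.971, CL = 35.45, F = 18.998,
                BR = 79.904, I = 126.904, FE = 55.845, ZN = 65.38, MG = 24.305)

#' Atomic mass lookup
#'
#' @param element Character vector of element symbols (case-insensitive).
#' @return Numeric vector of atomic masses in u. Unknown elements get the
#'   mass of carbon with a warning, which keeps mass-weighted metrics finite
#'   for exotic heteroatoms.
#' @export
element_mass <- function(element) {
  el <- toupper(trimws(element))
  m <- .pc_masses[el]
  if (anyNA(m)) {
    warning("unknown element(s): ", paste(unique(el[is.na(m)]), collapse = ", "),
            "; using carbon mass")
    m[is.na(m)] <- .pc_masses[["C"]]
  }
  unname(m)
}

# 3-letter -> 1-letter codes for the 20 standard residues. Anything else
# (MSE, PTR, ligands, ...) maps to X by design: nonstandard residues keep
# their heavy atoms in all counts but never score as identical.
.pc_aa3to1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
                GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
                LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
                SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

.pc_aa1to3 <- structure(names(.pc_aa3to1), names = unname(.pc_aa3to1))

aa_three_to_one <- function(res_name) {
  out <- .pc_aa3to1[toupper(res_name)]
  out[is.na(out)] <- "X"
  unname(out)
}
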