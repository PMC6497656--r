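#' @importFrom stats sd setNames aggregate
#' @importFrom utils read.csv write.csv head tail
NULL

# ---------------------------------------------------------------------------
# Structure container
#
# A `pc_structure` is a light S3 wrapper around an atom table:
#   model_id : integer
#   atoms    : data.frame(serial, atom_name, element, chain_id, res_name,
#                         res_seq, ins, x, y, z, occ, is_hetero)
# Residues are publicly identified by author numbering as "chain:res_seq"
# (or "chain:res_seq:ins" when an insertion code is present); no renumbering
# is ever performed, matching how pocket-detection servers report residues.
# ---------------------------------------------------------------------------

new_structure <- function(atoms, model_id = 1L) {
  stopifnot(is.data.frame(atoms))
  need <- c("serial", "atom_name", "element", "chain_id", "res_name",
            "res_seq", "ins", "x", "y", "z", "occ", "is_hetero")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atom table lacks columns: ", paste(miss, collapse = ", "))
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("non-finite coordinates in atom table")
  rownames(atoms) <- NULL
  structure(list(model_id = as.integer(model_id), atoms = atoms),
            class = "pc_structure")
}

#' @export
print.pc_structure <- function(x, ...) {
  poly <- x$atoms[!x$atoms$is_hetero, ]
  cat(sprintf("pc_structure (model %d): %d atoms (%d polymer, %d hetero), %d polymer residues, chains: %s\n",
              x$model_id, nrow(x$atoms), nrow(poly), sum(x$atoms$is_hetero),
              length(unique(residue_key(poly))),
              paste(sort(unique(x$atoms$chain_id)), collapse = " ")))
  invisible(x)
}

# Internal residue key: "chain:res_seq" or "chain:res_seq:ins"
residue_key <- function(atoms) {
  if (!nrow(atoms)) return(character(0))   # paste0 ignores zero-length args
  ins <- ifelse(is.na(atoms$ins) | atoms$ins == "", "", paste0(":", atoms$ins))
  paste0(atoms$chain_id, ":", atoms$res_seq, ins)
}

#' Residue identifiers of a structure
#'
#' @param s A `pc_structure`.
#' @param chain Optional chain id to restrict to.
#' @param polymer If `TRUE` (default) only polymer (ATOM) residues.
#' @return Character vector of residue identifiers (`"A:12"`), in structure
#'   order, one per residue.
#' @export
residue_ids <- function(s, chain = NULL, polymer = TRUE) {
  at <- s$atoms
  if (polymer) at <- at[!at$is_hetero, ]
  if (!is.null(chain)) at <- at[at$chain_id %in% chain, ]
  unique(residue_key(at))
}

is_hydrogen <- function(element) toupper(trimws(element)) %in% c("H", "D")

# ---------------------------------------------------------------------------
# PDB reading / writing
# ---------------------------------------------------------------------------

# Cheap fixed-width sanity check so malformed coordinate lines are reported
# with their line number before the parser proper runs.
validate_pdb_lines <- function(lines) {
  rec <- substr(lines, 1, 6)
  coord <- which(rec %in% c("ATOM  ", "HETATM"))
  for (i in coord) {
    ln <- lines[i]
    if (nchar(ln) < 54)
      stop("PDB parse error at line ", i, ": coordinate record shorter than 54 columns")
    xyz <- suppressWarnings(as.numeric(c(substr(ln, 31, 38), substr(ln, 39, 46),
                                         substr(ln, 47, 54))))
    if (anyNA(xyz))
      stop("PDB parse error at line ", i, ": non-numeric coordinate field")
  }
  invisible(length(coord))
}

#' Read a PDB file
#'
#' Parses a (possibly multi-MODEL) PDB file into a list of structures, one
#' per model. ATOM records become polymer atoms; HETATM records are kept
#' with `is_hetero = TRUE`. Alternate locations are resolved to the highest
#' occupancy conformer (ties: first encountered). Parsing itself is
#' delegated to [bio3d::read.pdb()]; this wrapper adds line-level
#' validation, altloc resolution and the package's atom-table container.
#'
#' @param file Path to a PDB file.
#' @return A list of `pc_structure`, one per MODEL (a single-model file
#'   gives a length-1 list).
#' @export
read_pdb <- function(file) {
  if (!file.exists(file)) stop("no such file: ", file)
  lines <- readLines(file, warn = FALSE)
  n_coord <- validate_pdb_lines(lines)
  if (n_coord == 0L) stop("empty structure: no ATOM or HETATM records in ", file)
  pdb <- suppressWarnings(bio3d::read.pdb(file, multi = TRUE, rm.alt = FALSE,
                                          verbose = FALSE))
  at <- pdb$atom
  atoms <- data.frame(
    serial = as.integer(at$eleno),
    atom_name = trimws(at$elety),
    element = toupper(trimws(ifelse(is.na(at$elesy) | at$elesy == "",
                                    guess_element(at$elety), at$elesy))),
    chain_id = ifelse(is.na(at$chain), " ", at$chain),
    res_name = trimws(at$resid),
    res_seq = as.integer(at$resno),
    ins = ifelse(is.na(at$insert), "", at$insert),
    x = at$x, y = at$y, z = at$z,
    occ = ifelse(is.na(at$o), 1, at$o),
    is_hetero = at$type == "HETATM",
    alt = ifelse(is.na(at$alt), "", at$alt),
    stringsAsFactors = FALSE)
  keep <- resolve_altloc(atoms)
  atoms <- atoms[keep, setdiff(names(atoms), "alt")]
  n_models <- if (is.matrix(pdb$xyz)) nrow(pdb$xyz) else 1L
  out <- vector("list", n_models)
  for (m in seq_len(n_models)) {
    a <- atoms
    if (is.matrix(pdb$xyz) && n_models > 1L) {
      xyz <- matrix(pdb$xyz[m, ], ncol = 3, byrow = TRUE)[keep, , drop = FALSE]
      a$x <- xyz[, 1]; a$y <- xyz[, 2]; a$z <- xyz[, 3]
    }
    out[[m]] <- new_structure(a, model_id = m)
  }
  out
}

# Element from the atom-name columns when the element field is blank
# (old-style PDB): strip digits/primes, handle leading digit (e.g. 1HB).
guess_element <- function(elety) {
  nm <- gsub("[0-9']", "", trimws(elety))
  el <- substr(nm, 1, 1)
  two <- toupper(nm) %in% c("CL", "BR", "FE", "ZN", "MG", "SE", "NA", "MN", "CU")
  el[two] <- substr(nm[two], 1, 2)
  el
}

# Index of atoms to keep after altloc resolution: within each
# (chain, res, ins, resname, atomname) group keep max occupancy, first wins.
resolve_altloc <- function(atoms) {
  key <- paste(atoms$chain_id, atoms$res_seq, atoms$ins, atoms$res_name,
               atoms$atom_name, sep = "|")
  dup_groups <- unique(key[duplicated(key)])
  if (!length(dup_groups)) return(seq_len(nrow(atoms)))
  keep <- rep(TRUE, nrow(atoms))
  for (g in dup_groups) {
    idx <- which(key == g)
    best <- idx[which.max(atoms$occ[idx])]
    keep[setdiff(idx, best)] <- FALSE
  }
  which(keep)
}

#' Write a structure (or list of structures) as PDB
#'
#' Fixed-width PDB v3.3 coordinate records; a list is written as a
#' multi-MODEL file (the trajectory interchange format used throughout).
#'
#' @param s A `pc_structure` or list of them.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_pdb <- function(s, file) {
  if (inherits(s, "pc_structure")) s <- list(s)
  con <- file(file, "w")
  on.exit(close(con))
  multi <- length(s) > 1L
  for (m in seq_along(s)) {
    if (multi) writeLines(sprintf("MODEL     %4d", m), con)
    a <- s[[m]]$atoms
    rec <- ifelse(a$is_hetero, "HETATM", "ATOM  ")
    nm <- ifelse(nchar(a$atom_name) < 4, sprintf(" %-3s", a$atom_name),
                 sprintf("%-4s", a$atom_name))
    lines <- sprintf("%s%5d %s %3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                     rec, a$serial %% 100000L, nm, a$res_name, a$chain_id,
                     a$res_seq, ifelse(a$ins == "", " ", a$ins),
                     a$x, a$y, a$z, a$occ, 0, a$element)
    writeLines(lines, con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(file)
}

# ---------------------------------------------------------------------------
# Sequences
# ---------------------------------------------------------------------------

new_sequence <- function(id, residues, numbering = NULL) {
  residues <- toupper(residues)
  n <- nchar(residues)
  if (is.null(numbering))
    numbering <- data.frame(chain_id = "-", res_seq = seq_len(n), ins = "",
                            stringsAsFactors = FALSE)
  stopifnot(nrow(numbering) == n)
  bad <- setdiff(strsplit(residues, "")[[1]], .pc_aa21)
  if (length(bad)) stop("invalid residue letter(s): ", paste(unique(bad), collapse = ""))
  structure(list(id = id, residues = residues, numbering = numbering),
            class = "pc_sequence")
}

#' @export
print.pc_sequence <- function(x, ...) {
  cat(sprintf("pc_sequence %s (%d aa)\n", x$id, nchar(x$residues)))
  cat(strwrap(x$residues, 60), sep = "\n")
  invisible(x)
}

#' Extract the one-letter sequence of a chain
#'
#' One letter per polymer residue in structure order; residues outside the
#' 20 standard amino acids (MSE, phospho-residues, ...) become `X`. The
#' returned numbering carries the author (chain, res_seq, insertion)
#' identifiers so alignment columns can be projected back onto the
#' structure.
#'
#' @param s A `pc_structure`.
#' @param chain Chain identifier (single character).
#' @return A `pc_sequence`.
#' @export
extract_sequence <- function(s, chain) {
  stopifnot(inherits(s, "pc_structure"))
  at <- s$atoms[!s$atoms$is_hetero, ]
  if (!chain %in% at$chain_id)
    stop("chain '", chain, "' not found; available: ",
         paste(sort(unique(at$chain_id)), collapse = " "))
  at <- at[at$chain_id == chain, ]
  key <- residue_key(at)
  first <- !duplicated(key)
  new_sequence(id = paste0("chain_", chain),
               residues = paste(aa_three_to_one(at$res_name[first]), collapse = ""),
               numbering = data.frame(chain_id = at$chain_id[first],
                                      res_seq = at$res_seq[first],
                                      ins = at$ins[first],
                                      stringsAsFactors = FALSE))
}

#' Count polymer atoms
#'
#' The atom-counting primitive behind the conservation-enrichment statistic:
#' all of T_a (whole protein), P_a (pocket lining) and TC_a (conserved
#' residues) are computed with it. Heavy atoms only by default; hetero
#' (HETATM) atoms are never counted.
#'
#' @param s A `pc_structure`.
#' @param residues Optional character vector of residue identifiers
#'   (`"A:12"`) to restrict to. `NULL` counts the whole polymer; an empty
#'   vector counts nothing.
#' @param include_hydrogens Count hydrogens too? Default `FALSE`.
#' @return Non-negative integer.
#' @export
count_atoms <- function(s, residues = NULL, include_hydrogens = FALSE) {
  stopifnot(inherits(s, "pc_structure"))
  at <- s$atoms[!s$atoms$is_hetero, ]
  if (!include_hydrogens) at <- at[!is_hydrogen(at$element), ]
  if (is.null(residues)) return(nrow(at))
  if (!length(residues)) return(0L)
  known <- unique(residue_key(s$atoms[!s$atoms$is_hetero, ]))
  bad <- setdiff(residues, known)
  if (length(bad)) stop("unknown residue identifier(s): ", paste(bad, collapse = ", "))
  sum(residue_key(at) %in% residues)
}

# ---------------------------------------------------------------------------
# FASTA
# ---------------------------------------------------------------------------

#' Read sequences from a FASTA file
#'
#' @param file Path to a FASTA file.
#' @return A list of `pc_sequence` (sequential numbering).
#' @export
read_fasta <- function(file) {
  lines <- readLines(file, warn = FALSE)
  hdr <- grep("^>", lines)
  if (!length(hdr)) stop("no FASTA records in ", file)
  ends <- c(hdr[-1] - 1L, length(lines))
  lapply(seq_along(hdr), function(i) {
    id <- sub("^>\\s*", "", lines[hdr[i]])
    id <- strsplit(id, "\\s+")[[1]][1]
    seqs <- lines[seq(hdr[i] + 1L, ends[i])]
    new_sequence(id, gsub("\\s", "", paste(seqs, collapse = "")))
  })
}

#' Write sequences to a FASTA file
#'
#' @param seqs A `pc_sequence` or list of them.
#' @param file Output path.
#' @param width Line-wrap width (default 60).
#' @return `file`, invisibly.
#' @export
write_fasta <- function(seqs, file, width = 60) {
  if (inherits(seqs, "pc_sequence")) seqs <- list(seqs)
  con <- file(file, "w")
  on.exit(close(con))
  for (s in seqs) {
    writeLines(paste0(">", s$id), con)
    n <- nchar(s$residues)
    starts <- seq(1, n, by = width)
    writeLines(substring(s$residues, starts, pmin(starts + width - 1, n)), con)
  }
  invisible(file)
}
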