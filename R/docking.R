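# ---------------------------------------------------------------------------
# Docking post-processing: binding free energy <-> inhibition constant, and
# geometric hydrogen-bond detection in docked complexes.
# ---------------------------------------------------------------------------

# Gas constant in kcal mol^-1 K^-1 (CODATA), the AutoDock reporting
# convention together with T = 298.15 K.
GAS_CONSTANT_KCAL <- 1.98720425864083e-3

#' Inhibition constant from binding free energy
#'
#' `Ki = exp(dG / (R T))` with R in kcal/mol/K, so a docking score of
#' -7.41 kcal/mol at 298.15 K corresponds to Ki of about 3.7 uM.
#'
#' @param delta_g Binding free energy in kcal/mol (negative = favourable).
#' @param temperature Temperature in K (default 298.15).
#' @return Inhibition constant in molar units.
#' @export
#' @examples
#' ki_from_energy(-7.41) * 1e6  # micromolar
ki_from_energy <- function(delta_g, temperature = 298.15) {
  if (any(!is.finite(delta_g))) stop("delta_g must be finite")
  if (any(!is.finite(temperature)) || any(temperature <= 0))
    stop("temperature must be positive")
  exp(delta_g / (GAS_CONSTANT_KCAL * temperature))
}

#' Binding free energy from an inhibition constant
#'
#' Inverse of [ki_from_energy()]: `dG = R T log(Ki)`.
#'
#' @param ki Inhibition constant in molar units (> 0).
#' @param temperature Temperature in K (default 298.15).
#' @return Binding free energy in kcal/mol.
#' @export
energy_from_ki <- function(ki, temperature = 298.15) {
  if (any(!is.finite(ki)) || any(ki <= 0)) stop("ki must be positive")
  if (any(!is.finite(temperature)) || any(temperature <= 0))
    stop("temperature must be positive")
  GAS_CONSTANT_KCAL * temperature * log(ki)
}

# ---------------------------------------------------------------------------
# Hydrogen bonds
# ---------------------------------------------------------------------------

# Atom token "chain:res_seq:atom_name" (insertion-coded residues use
# "chain:res_seq:ins:atom_name"); resolves to row indices of s$atoms.
resolve_atom_tokens <- function(tokens, s) {
  at <- s$atoms
  key4 <- paste(at$chain_id, at$res_seq, at$ins, at$atom_name, sep = ":")
  key3 <- paste(at$chain_id, at$res_seq, at$atom_name, sep = ":")
  idx <- match(tokens, key4)
  idx[is.na(idx)] <- match(tokens[is.na(idx)], key3)
  if (anyNA(idx))
    stop("atom token(s) not found in structure: ",
         paste(tokens[is.na(idx)], collapse = ", "))
  idx
}

atom_token <- function(atoms, idx) {
  paste(atoms$chain_id[idx], atoms$res_seq[idx], atoms$atom_name[idx], sep = ":")
}

#' Detect hydrogen bonds by geometric criteria
#'
#' Emits every donor-acceptor pair whose heavy-atom distance is at most
#' `d_max` (closed boundary) and, when a hydrogen is supplied for the
#' donor, whose hydrogen-donor-acceptor angle is at most `angle_max`.
#' Donors without a hydrogen are evaluated in distance-only mode, flagged
#' per record — crystal structures and docked poses commonly lack
#' hydrogens.
#'
#' @param s A `pc_structure` (e.g. a docked receptor-ligand complex).
#' @param donors Character vector of donor atom tokens
#'   (`"chain:res_seq:atom_name"`) or integer row indices into `s$atoms`.
#' @param acceptors Acceptor atoms, same formats.
#' @param d_max Maximum donor-acceptor distance, Angstrom (default 3.5).
#' @param angle_max Maximum H-D-A angle, degrees (default 30).
#' @param hydrogens Optional named vector mapping donor token -> hydrogen
#'   token.
#' @return Data.frame with one row per bond: `donor`, `hydrogen`,
#'   `acceptor`, `distance` (Angstrom), `angle` (degrees, `NA` in
#'   distance-only mode), `distance_only`.
#' @export
detect_hbonds <- function(s, donors, acceptors, d_max = 3.5, angle_max = 30,
                          hydrogens = NULL) {
  stopifnot(inherits(s, "pc_structure"))
  if (!length(donors) || !length(acceptors))
    stop("donor and acceptor sets must be non-empty")
  di <- if (is.numeric(donors)) as.integer(donors) else resolve_atom_tokens(donors, s)
  ai <- if (is.numeric(acceptors)) as.integer(acceptors) else resolve_atom_tokens(acceptors, s)
  xyz <- as.matrix(s$atoms[, c("x", "y", "z")])
  hmap <- NULL
  if (!is.null(hydrogens)) {
    hi <- resolve_atom_tokens(unname(hydrogens), s)
    hmap <- setNames(hi, names(hydrogens))
  }
  rows <- list()
  for (d in di) {
    dtok <- atom_token(s$atoms, d)
    hidx <- if (!is.null(hmap) && dtok %in% names(hmap)) hmap[[dtok]] else NA_integer_
    for (a in ai) {
      if (a == d) next
      dist <- sqrt(sum((xyz[d, ] - xyz[a, ])^2))
      if (dist > d_max) next
      ang <- NA_real_
      if (!is.na(hidx)) {
        v1 <- xyz[hidx, ] - xyz[d, ]
        v2 <- xyz[a, ] - xyz[d, ]
        # angle at the donor between D->H and D->A; 0 deg for perfectly
        # linear D-H...A geometry (the g_hbond convention)
        cosang <- sum(v1 * v2) / (sqrt(sum(v1^2)) * sqrt(sum(v2^2)))
        ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
        if (ang > angle_max) next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        donor = dtok,
        hydrogen = if (is.na(hidx)) NA_character_ else atom_token(s$atoms, hidx),
        acceptor = atom_token(s$atoms, a),
        distance = dist, angle = ang, distance_only = is.na(hidx),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(donor = character(), hydrogen = character(),
                      acceptor = character(), distance = numeric(),
                      angle = numeric(), distance_only = logical(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Load donor/acceptor role assignments
#'
#' Reads a small two/three-column whitespace- or comma-separated text file:
#' atom token, role (`donor`, `acceptor` or `hydrogen`), and for hydrogen
#' rows the donor token they ride on. Lines starting with `#` are ignored.
#'
#' @param file Path.
#' @return List with `donors`, `acceptors` (character vectors) and
#'   `hydrogens` (named vector donor -> hydrogen, possibly empty).
#' @export
load_hbond_roles <- function(file) {
  lines <- readLines(file, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[lines != "" & !startsWith(lines, "#")]
  parts <- strsplit(lines, "[,[:space:]]+")
  role <- vapply(parts, `[`, "", 2)
  tok <- vapply(parts, `[`, "", 1)
  bad <- !role %in% c("donor", "acceptor", "hydrogen")
  if (any(bad)) stop("unknown role '", role[bad][1], "' in ", file)
  hyd <- parts[role == "hydrogen"]
  hydrogens <- setNames(vapply(hyd, `[`, "", 1), vapply(hyd, `[`, "", 3))
  list(donors = tok[role == "donor"], acceptors = tok[role == "acceptor"],
       hydrogens = hydrogens)
}
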