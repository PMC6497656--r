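# ---------------------------------------------------------------------------
# Trajectory container and analysis operators.
#
# Coordinates are carried internally in Angstrom; all reported metrics are
# in nm, following the convention of GROMACS analysis tools. Frames come
# from multi-MODEL PDB files (the package's trajectory interchange format).
# ---------------------------------------------------------------------------

#' Build a trajectory from a topology and coordinate frames
#'
#' @param topology A `pc_structure` carrying the atom metadata.
#' @param frames List of n_atoms x 3 coordinate matrices (Angstrom).
#' @param times Frame times in ps; default 2 ps spacing.
#' @return A `pc_trajectory`.
#' @export
new_trajectory <- function(topology, frames, times = NULL) {
  stopifnot(inherits(topology, "pc_structure"), length(frames) >= 1)
  n <- nrow(topology$atoms)
  for (f in frames)
    if (!is.matrix(f) || nrow(f) != n || ncol(f) != 3)
      stop("every frame must be an n_atoms x 3 matrix matching the topology")
  if (is.null(times)) times <- 2 * (seq_along(frames) - 1)
  if (length(times) != length(frames) || any(diff(times) <= 0))
    stop("times must be strictly increasing, one per frame")
  structure(list(topology = topology, frames = frames, times = times),
            class = "pc_trajectory")
}

#' @export
print.pc_trajectory <- function(x, ...) {
  cat(sprintf("pc_trajectory: %d frames x %d atoms, %g-%g ps\n",
              length(x$frames), nrow(x$topology$atoms),
              min(x$times), max(x$times)))
  invisible(x)
}

#' Read a multi-MODEL PDB file as a trajectory
#'
#' @param file Path to a multi-MODEL PDB file.
#' @return A `pc_trajectory` (model 1 is the topology; 2 ps frame spacing).
#' @export
read_trajectory_pdb <- function(file) {
  models <- read_pdb(file)
  frames <- lapply(models, function(s) unname(as.matrix(s$atoms[, c("x", "y", "z")])))
  new_trajectory(models[[1]], frames)
}

#' Write a trajectory as a multi-MODEL PDB file
#'
#' @param traj A `pc_trajectory`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_trajectory_pdb <- function(traj, file) {
  models <- lapply(seq_along(traj$frames), function(m) {
    s <- traj$topology
    s$atoms$x <- traj$frames[[m]][, 1]
    s$atoms$y <- traj$frames[[m]][, 2]
    s$atoms$z <- traj$frames[[m]][, 3]
    s$model_id <- m
    s
  })
  write_pdb(models, file)
}

#' Atom selections
#'
#' @param s A `pc_structure`.
#' @param selection `"calpha"`, `"backbone"` (N, CA, C, O), `"heavy"`
#'   (all heavy polymer atoms), `"all"`, or an integer vector of atom row
#'   indices used as-is.
#' @return Integer vector of row indices into `s$atoms`.
#' @export
select_atoms <- function(s, selection = "backbone") {
  if (is.numeric(selection)) return(as.integer(selection))
  at <- s$atoms
  poly <- !at$is_hetero
  heavy <- poly & !is_hydrogen(at$element)
  idx <- switch(match.arg(selection, c("calpha", "backbone", "heavy", "all")),
                calpha = which(heavy & at$atom_name == "CA"),
                backbone = which(heavy & at$atom_name %in% c("N", "CA", "C", "O")),
                heavy = which(heavy),
                all = seq_len(nrow(at)))
  if (!length(idx)) stop("empty atom selection")
  idx
}

# ---------------------------------------------------------------------------
# Kabsch superposition
# ---------------------------------------------------------------------------

#' Least-squares superposition (Kabsch algorithm)
#'
#' Finds the proper rotation and translation minimizing the (optionally
#' weighted) sum of squared deviations of `mobile` from `reference`.
#'
#' @param reference,mobile n x 3 coordinate matrices, n >= 3.
#' @param weights Optional non-negative per-atom weights.
#' @return List with `rotation` (3 x 3, det +1), `translation` (length 3),
#'   `fitted` (mobile after transformation; `fitted = mobile %*% t(R) + t`)
#'   and `rmsd` (same length unit as the input).
#' @export
kabsch_superpose <- function(reference, mobile, weights = NULL) {
  reference <- as.matrix(reference); mobile <- as.matrix(mobile)
  if (nrow(reference) != nrow(mobile) || ncol(reference) != 3 || ncol(mobile) != 3)
    stop("reference and mobile must be equal-size n x 3 matrices")
  n <- nrow(reference)
  if (n < 3) stop("superposition needs at least 3 atoms")
  w <- if (is.null(weights)) rep(1, n) else as.numeric(weights)
  if (length(w) != n || any(w < 0) || sum(w) == 0) stop("invalid weights")
  w <- w / sum(w)
  cr <- colSums(reference * w)
  cm <- colSums(mobile * w)
  P <- sweep(mobile, 2, cm)
  Q <- sweep(reference, 2, cr)
  H <- t(P * w) %*% Q
  sv <- svd(H)
  if (sv$d[2] < 1e-10 * max(sv$d[1], 1e-30))
    stop("degenerate geometry: atoms are (near-)collinear, rotation is not unique")
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  fitted <- P %*% t(R)
  fitted <- sweep(fitted, 2, cr, "+")
  rmsd <- sqrt(sum(rowSums((fitted - reference)^2) * w))
  list(rotation = R, translation = as.numeric(cr - R %*% cm),
       fitted = fitted, rmsd = rmsd)
}

#' RMSD time series after superposition
#'
#' Each frame is least-squares fitted to the reference frame on the
#' selection, and the RMSD over the selection is reported in nm.
#'
#' @param traj A `pc_trajectory`.
#' @param selection Passed to [select_atoms()]; default `"backbone"`.
#' @param reference_frame Frame index used as reference (default 1).
#' @return Numeric vector, one RMSD (nm) per frame; zero at the reference.
#' @export
rmsd_series <- function(traj, selection = "backbone", reference_frame = 1) {
  stopifnot(inherits(traj, "pc_trajectory"))
  if (reference_frame < 1 || reference_frame > length(traj$frames))
    stop("reference_frame out of range")
  idx <- select_atoms(traj$topology, selection)
  ref <- traj$frames[[reference_frame]][idx, , drop = FALSE]
  vapply(traj$frames, function(f)
    0.1 * kabsch_superpose(ref, f[idx, , drop = FALSE])$rmsd, 0)
}

#' Radius of gyration time series
#'
#' `Rg = sqrt(sum(m_i ||r_i - r_com||^2) / sum(m_i))`, reported in nm.
#'
#' @param traj A `pc_trajectory`.
#' @param selection Passed to [select_atoms()].
#' @param mass_weighted Weight by atomic mass (default `TRUE`); otherwise
#'   all atoms weigh 1.
#' @return Numeric vector, one Rg (nm) per frame.
#' @export
rg_series <- function(traj, selection = "backbone", mass_weighted = TRUE) {
  stopifnot(inherits(traj, "pc_trajectory"))
  idx <- select_atoms(traj$topology, selection)
  m <- if (mass_weighted)
    suppressWarnings(element_mass(traj$topology$atoms$element[idx]))
  else rep(1, length(idx))
  if (sum(m) <= 0) stop("zero total mass in selection")
  vapply(traj$frames, function(f) {
    x <- f[idx, , drop = FALSE]
    com <- colSums(x * m) / sum(m)
    0.1 * sqrt(sum(m * rowSums(sweep(x, 2, com)^2)) / sum(m))
  }, 0)
}

#' Per-residue RMSF about the time-average structure
#'
#' Frames are superposed on the iterated time-average structure (two
#' fitting passes: fit to the first frame, average, refit to that mean,
#' re-average), then per-residue RMSF is the root mean square, over frames
#' and the residue's selected atoms, of the deviation from the mean
#' position. Reported in nm.
#'
#' @param traj A `pc_trajectory` with at least 2 frames.
#' @param selection `"backbone"` or `"calpha"` (or indices).
#' @return Named numeric vector, one RMSF (nm) per residue in chain order.
#' @export
rmsf_per_residue <- function(traj, selection = "backbone") {
  stopifnot(inherits(traj, "pc_trajectory"))
  if (length(traj$frames) < 2) stop("RMSF needs at least 2 frames")
  idx <- select_atoms(traj$topology, selection)
  sub <- lapply(traj$frames, function(f) f[idx, , drop = FALSE])
  ref <- sub[[1]]
  for (pass in 1:2) {
    fitted <- lapply(sub, function(f) kabsch_superpose(ref, f)$fitted)
    ref <- Reduce(`+`, fitted) / length(fitted)
  }
  mean_xyz <- ref
  dev2 <- Reduce(`+`, lapply(fitted, function(f) rowSums((f - mean_xyz)^2))) /
    length(fitted)
  res <- residue_key(traj$topology$atoms[idx, , drop = FALSE])
  msf <- tapply(dev2, factor(res, levels = unique(res)), mean)
  setNames(0.1 * sqrt(as.numeric(msf)), names(msf))
}

#' Hydrogen-bond time series
#'
#' Applies [detect_hbonds()] to every frame and reports the per-frame bond
#' count plus, per donor-acceptor pair, the occupancy (fraction of frames
#' in which the pair satisfies the criteria; boundaries closed).
#'
#' @param traj A `pc_trajectory`.
#' @param donors,acceptors,d_max,angle_max,hydrogens As [detect_hbonds()].
#' @return List with `count` (integer per frame) and `occupancy`
#'   (data.frame `donor`, `acceptor`, `occupancy`).
#' @export
hbond_series <- function(traj, donors, acceptors, d_max = 3.5, angle_max = 30,
                         hydrogens = NULL) {
  stopifnot(inherits(traj, "pc_trajectory"))
  pair_count <- new.env(parent = emptyenv())
  counts <- integer(length(traj$frames))
  s <- traj$topology
  for (m in seq_along(traj$frames)) {
    s$atoms$x <- traj$frames[[m]][, 1]
    s$atoms$y <- traj$frames[[m]][, 2]
    s$atoms$z <- traj$frames[[m]][, 3]
    hb <- detect_hbonds(s, donors, acceptors, d_max, angle_max, hydrogens)
    counts[m] <- nrow(hb)
    if (nrow(hb)) {
      keys <- paste(hb$donor, hb$acceptor, sep = " -> ")
      for (k in keys)
        assign(k, (if (exists(k, envir = pair_count)) get(k, envir = pair_count) else 0L) + 1L,
               envir = pair_count)
    }
  }
  keys <- ls(pair_count)
  occ <- if (length(keys)) {
    parts <- strsplit(keys, " -> ", fixed = TRUE)
    data.frame(donor = vapply(parts, `[`, "", 1),
               acceptor = vapply(parts, `[`, "", 2),
               occupancy = vapply(keys, function(k) get(k, envir = pair_count), 0L) /
                 length(traj$frames),
               stringsAsFactors = FALSE, row.names = NULL)
  } else {
    data.frame(donor = character(), acceptor = character(),
               occupancy = numeric(), stringsAsFactors = FALSE)
  }
  list(count = counts, occupancy = occ)
}

#' Mean smallest-distance residue matrix
#'
#' For every frame and residue pair, the smallest heavy-atom distance
#' (capped at `truncation`, in nm); entries are averaged over frames. Also
#' returns the mean of the off-diagonal entries and their sum, the two
#' aggregate summaries commonly quoted for such matrices.
#'
#' @param traj A `pc_trajectory`.
#' @param truncation Distance cap in nm (default 1.5).
#' @return List with `matrix` (n_res x n_res, nm, zero diagonal),
#'   `mean_offdiag` and `sum` (sum of all entries of the mean matrix).
#' @export
mean_smallest_distance_matrix <- function(traj, truncation = 1.5) {
  stopifnot(inherits(traj, "pc_trajectory"))
  at <- traj$topology$atoms
  heavy <- which(!at$is_hetero & !is_hydrogen(at$element))
  if (!length(heavy)) stop("no heavy polymer atoms")
  res <- residue_key(at[heavy, , drop = FALSE])
  rlev <- unique(res)
  rfac <- match(res, rlev)
  nr <- length(rlev)
  acc <- matrix(0, nr, nr, dimnames = list(rlev, rlev))
  for (f in traj$frames) {
    x <- f[heavy, , drop = FALSE]
    D <- 0.1 * as.matrix(stats::dist(x))          # nm
    # min over atom pairs within each residue block
    Dmin <- matrix(Inf, nr, nr)
    for (i in seq_len(nr)) {
      ai <- rfac == i
      sub <- D[ai, , drop = FALSE]
      # column mins per residue j
      colmin <- apply(sub, 2, min)
      Dmin[i, ] <- vapply(seq_len(nr), function(j) min(colmin[rfac == j]), 0)
    }
    diag(Dmin) <- 0
    acc <- acc + pmin(Dmin, truncation)
  }
  M <- acc / length(traj$frames)
  list(matrix = M,
       mean_offdiag = mean(M[upper.tri(M) | lower.tri(M)]),
       sum = sum(M))
}
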