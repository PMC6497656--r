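# ---------------------------------------------------------------------------
# Synthetic-data generator: every input the pipeline consumes, with known
# ground truth, so all stages are testable without external downloads.
# All generators are deterministic given `seed` (local RNG state only).
# ---------------------------------------------------------------------------

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate an idealized helical toy structure
#'
#' Builds an alpha-helical backbone (N, CA, C, O plus CB except for
#' glycine) with ideal helix geometry: 1.5 Angstrom rise and 100 degrees
#' rotation per residue on a 2.3 Angstrom radius, giving consecutive
#' CA-CA distances of ~3.8 Angstrom. The sequence is drawn uniformly from
#' the 20 standard residues. The result is a fully valid, PDB-writable
#' structure — geometric scaffolding for the scoring and trajectory
#' machinery, not a physically refined model.
#'
#' @param n_residues Number of residues (>= 3).
#' @param seed Integer seed; the same seed gives a byte-identical structure.
#' @param chain Chain identifier (default `"A"`).
#' @param sequence Optional one-letter sequence overriding the random one.
#' @return A `pc_structure`.
#' @export
make_toy_structure <- function(n_residues = 60, seed = 1, chain = "A",
                               sequence = NULL) {
  if (is.null(sequence)) {
    if (n_residues < 3) stop("n_residues must be >= 3")
    aa <- setdiff(.pc_aa21, "X")
    sequence <- with_seed(seed, paste(sample(aa, n_residues, replace = TRUE),
                                      collapse = ""))
  }
  letters1 <- strsplit(toupper(sequence), "")[[1]]
  n_residues <- length(letters1)
  if (n_residues < 3) stop("n_residues must be >= 3")
  rise <- 1.5; radius <- 2.3; twist <- 100 * pi / 180
  helix_point <- function(t, r = radius) {
    c(r * cos(twist * t), r * sin(twist * t), rise * t)
  }
  rows <- vector("list", n_residues)
  serial <- 0L
  for (i in seq_len(n_residues)) {
    res3 <- if (letters1[i] == "X") "UNK" else .pc_aa1to3[[letters1[i]]]
    # backbone atoms at fractional helix parameters around the CA position;
    # O displaced radially, CB pushed outward
    atoms <- list(
      N  = c(helix_point(i - 0.38), "N"),
      CA = c(helix_point(i), "C"),
      C  = c(helix_point(i + 0.38), "C"),
      O  = c(helix_point(i + 0.45, radius + 1.1), "O"))
    if (res3 != "GLY") atoms$CB <- c(helix_point(i, radius + 1.5), "C")
    df <- do.call(rbind, lapply(names(atoms), function(nm) {
      serial <<- serial + 1L
      v <- atoms[[nm]]
      data.frame(serial = serial, atom_name = nm, element = v[4],
                 chain_id = chain, res_name = res3, res_seq = i, ins = "",
                 x = round(as.numeric(v[1]), 3), y = round(as.numeric(v[2]), 3),
                 z = round(as.numeric(v[3]), 3),
                 occ = 1, is_hetero = FALSE, stringsAsFactors = FALSE)
    }))
    rows[[i]] <- df
  }
  new_structure(do.call(rbind, rows))
}

#' Generate a reference/target homolog sequence pair with known truth
#'
#' Returns a target sequence and a same-length reference sequence with an
#' exact, position-wise conservation truth: `round(n * identity_fraction)`
#' positions identical, `round(n * conserved_fraction)` positions carrying
#' a conservative substitution (different letter, BLOSUM62 score > 0), and
#' every remaining position a non-conservative substitution (score <= 0).
#' Indel-free by default so projecting conservation onto residues is exact;
#' `indel_rate > 0` inserts reference-side deletions for aligner stress
#' tests.
#'
#' @param target A `pc_sequence`, plain string, or integer length (a random
#'   target of that length is drawn).
#' @param identity_fraction Fraction of identical positions.
#' @param conserved_fraction Fraction of conservative substitutions.
#' @param seed Integer seed.
#' @param indel_rate Per-position probability of deleting the reference
#'   residue (default 0).
#' @return List with `reference`, `target` (`pc_sequence`) and `truth`
#'   (character vector per target position: `identical`, `conserved`,
#'   `mismatch`).
#' @export
make_homolog_pair <- function(target = 100, identity_fraction = 0.3,
                              conserved_fraction = 0.2, seed = 1,
                              indel_rate = 0) {
  if (is.numeric(target) && length(target) == 1) {
    aa <- setdiff(.pc_aa21, "X")
    target <- with_seed(seed + 1000L,
                        paste(sample(aa, target, replace = TRUE), collapse = ""))
  }
  tstr <- as_residue_string(target)
  n <- nchar(tstr)
  n_id <- round(n * identity_fraction)
  n_cons <- round(n * conserved_fraction)
  if (n_id + n_cons > n)
    stop("identity_fraction + conserved_fraction exceed 1 for n = ", n)
  tv <- strsplit(tstr, "")[[1]]
  mat <- blosum62()
  aa <- setdiff(.pc_aa21, "X")
  # residues like G or P have no BLOSUM62-positive partner, so conservative
  # substitutions can only be implanted where one exists
  can_conserve <- vapply(tv, function(x) any(aa != x & mat[aa, x] > 0), TRUE)
  with_seed(seed, {
    truth <- rep("mismatch", n)
    elig <- which(can_conserve)
    if (length(elig) < n_cons)
      stop("conserved_fraction infeasible: only ", length(elig),
           " positions admit a conservative substitution")
    cons_pos <- sort(sample(elig, n_cons))
    rest <- setdiff(seq_len(n), cons_pos)
    if (length(rest) < n_id) stop("identity_fraction infeasible")
    id_pos <- sort(sample(rest, n_id))
    truth[id_pos] <- "identical"
    truth[cons_pos] <- "conserved"
    rv <- character(n)
    for (i in seq_len(n)) {
      if (truth[i] == "identical") {
        rv[i] <- tv[i]
      } else if (truth[i] == "conserved") {
        cand <- aa[aa != tv[i] & mat[aa, tv[i]] > 0]
        if (!length(cand))
          stop("no conservative substitution exists for residue ", tv[i])
        rv[i] <- if (length(cand) == 1) cand else sample(cand, 1)
      } else {
        cand <- aa[aa != tv[i] & mat[aa, tv[i]] <= 0]
        rv[i] <- if (length(cand) == 1) cand else sample(cand, 1)
      }
    }
    keep <- if (indel_rate > 0) stats::runif(n) >= indel_rate else rep(TRUE, n)
    list(reference = new_sequence("synthetic_reference_domain",
                                  paste(rv[keep], collapse = "")),
         target = if (inherits(target, "pc_sequence")) target
                  else new_sequence("synthetic_target", tstr),
         truth = truth)
  })
}

#' Generate pocket-detector outputs with an implanted true pocket
#'
#' Emulates two pocket detectors reporting raw scores on incommensurable
#' scales (an alpha-shape-like area in square Angstrom and a small cavity
#' score). One implanted "true" pocket draws its lining residues so that a
#' fraction `min(1, enrichment * rho)` of them are conserved, where `rho`
#' is the background conserved density given by `conserved_residues`;
#' decoy pockets draw conserved residues at exactly the background rate.
#' Conserved counts per pocket are implanted exactly (rounded), so at
#' `enrichment = 1` the true pocket is statistically indistinguishable
#' from the decoys. Pocket identifiers are randomly permuted so tie-breaks
#' cannot systematically favour the implanted pocket.
#'
#' @param structure A `pc_structure` (single chain).
#' @param conserved_residues Character vector of conserved residue ids
#'   (ground truth, e.g. mapped from [make_homolog_pair()]).
#' @param n_pockets Total number of pockets (>= 2; one true + decoys).
#' @param pocket_size Residues per pocket.
#' @param enrichment Conservation density of the true pocket relative to
#'   background (>= 1).
#' @param seed Integer seed.
#' @param rank_noise Probability that each detector swaps the true pocket
#'   out of its top raw-score slot (default 0).
#' @return List with `predictions` (data.frame in the
#'   [load_pocket_predictions()] shape) and `truth_pocket_id`.
#' @export
make_pocket_fixture <- function(structure, conserved_residues, n_pockets = 5,
                                pocket_size = 8, enrichment = 2, seed = 1,
                                rank_noise = 0) {
  stopifnot(inherits(structure, "pc_structure"), n_pockets >= 2, enrichment >= 1)
  all_res <- residue_ids(structure)
  if (pocket_size * n_pockets > length(all_res))
    stop("pocket_size * n_pockets exceeds the number of residues")
  cons <- intersect(all_res, conserved_residues)
  bg <- setdiff(all_res, cons)
  rho <- length(cons) / length(all_res)
  if (rho <= 0) stop("no conserved residues to implant a pocket on")
  k_true <- round(min(1, enrichment * rho) * pocket_size)
  k_decoy <- round(rho * pocket_size)
  if (k_true > length(cons) || pocket_size - k_decoy > length(bg))
    stop("infeasible enrichment for the available conserved/background residues")
  with_seed(seed, {
    draw_pocket <- function(k_cons) {
      c(sample(cons, k_cons), sample(bg, pocket_size - k_cons))
    }
    linings <- c(list(draw_pocket(k_true)),
                 replicate(n_pockets - 1L, draw_pocket(k_decoy), simplify = FALSE))
    ids <- paste0("P", sample.int(n_pockets))   # truth gets a random label
    truth_id <- ids[1]
    # raw scores: truth ranks first in each method unless rank noise flips it
    base_rank <- seq_len(n_pockets)
    methods <- list(
      castp = function(r) 900 - 85 * r + stats::runif(n_pockets, 0, 20),
      activesite = function(r) 12 - 1.1 * r + stats::runif(n_pockets, 0, 0.3))
    rows <- list()
    for (m in names(methods)) {
      r <- base_rank
      if (rank_noise > 0 && stats::runif(1) < rank_noise) r[1:2] <- r[2:1]
      rows[[m]] <- data.frame(method = m, pocket_id = ids,
                              raw_score = methods[[m]](r),
                              residues = vapply(linings, paste, "", collapse = ";"),
                              stringsAsFactors = FALSE)
    }
    pred <- do.call(rbind, rows)
    rownames(pred) <- NULL
    pred$lining_residues <- lapply(pred$residues, parse_residue_tokens)
    pred$residues <- NULL
    list(predictions = pred, truth_pocket_id = truth_id)
  })
}

#' Generate a rigid-motion + Gaussian-noise trajectory
#'
#' Frames are the input structure moved as a rigid body (rotation about a
#' fixed axis by `omega` degrees per frame plus a constant drift) with iid
#' isotropic Gaussian noise of standard deviation `noise_sigma` added to
#' every coordinate. After least-squares fitting the rigid motion is
#' removed exactly, so the expected post-fit RMSD is close to
#' `noise_sigma * sqrt(3)` per atom (slightly less: the fit absorbs 6
#' degrees of freedom and the noisy reference frame contributes its own
#' noise). Frame times use the 2 ps spacing of typical production MD
#' output.
#'
#' @param structure A `pc_structure`.
#' @param n_frames Number of frames (>= 2).
#' @param noise_sigma Coordinate noise sd in Angstrom (>= 0).
#' @param seed Integer seed.
#' @param omega Rotation per frame in degrees (default 1).
#' @param drift Translation per frame in Angstrom (default c(0.05, 0, 0)).
#' @return A `pc_trajectory`.
#' @export
make_trajectory <- function(structure, n_frames = 100, noise_sigma = 0.3,
                            seed = 1, omega = 1, drift = c(0.05, 0, 0)) {
  stopifnot(inherits(structure, "pc_structure"))
  if (n_frames < 2) stop("n_frames must be >= 2")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  xyz <- as.matrix(structure$atoms[, c("x", "y", "z")])
  n <- nrow(xyz)
  axis <- c(1, 1, 1) / sqrt(3)
  rot_about <- function(theta) {
    c1 <- cos(theta); s1 <- sin(theta)
    K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                  -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
    diag(3) + s1 * K + (1 - c1) * (K %*% K)
  }
  with_seed(seed, {
    frames <- lapply(seq_len(n_frames), function(t) {
      R <- rot_about((t - 1) * omega * pi / 180)
      f <- xyz %*% t(R) + matrix((t - 1) * drift, n, 3, byrow = TRUE)
      if (noise_sigma > 0) f <- f + matrix(stats::rnorm(3 * n, sd = noise_sigma), n, 3)
      unname(f)
    })
    new_trajectory(structure, frames)
  })
}

#' Materialize a complete demo workspace
#'
#' Writes every input the pipeline needs into `dir`: the target structure
#' (`target.pdb`), the synthetic reference-domain sequence
#' (`reference.fasta`), two detectors' pocket predictions (`pockets.csv`),
#' a noisy rigid-body trajectory (`trajectory.pdb`) and the generator's
#' ground truth (`truth.json`).
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed driving every stochastic choice.
#' @param n_residues,identity_fraction,conserved_fraction,n_pockets,
#'   pocket_size,enrichment,n_frames,noise_sigma Generator parameters; the
#'   defaults describe a 100-residue single-chain target with 35% identical
#'   + 15% conservatively substituted positions against the reference
#'   domain (a clearly detectable homology, so the alignment stage recovers
#'   the implanted conservation reliably), five candidate pockets of 8
#'   residues with a 2x conservation enrichment in the implanted pocket,
#'   and a 100-frame trajectory with 0.3 Angstrom coordinate noise.
#' @return Invisibly, a list of the generated objects plus `paths`.
#' @export
make_demo_workspace <- function(dir, seed = 1, n_residues = 100,
                                identity_fraction = 0.35,
                                conserved_fraction = 0.15,
                                n_pockets = 5, pocket_size = 8,
                                enrichment = 2, n_frames = 100,
                                noise_sigma = 0.3) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  s <- make_toy_structure(n_residues, seed = seed)
  tseq <- extract_sequence(s, "A")
  hp <- make_homolog_pair(tseq, identity_fraction, conserved_fraction,
                          seed = seed)
  res_ids <- residue_ids(s)
  conserved <- res_ids[hp$truth %in% c("identical", "conserved")]
  pf <- make_pocket_fixture(s, conserved, n_pockets, pocket_size, enrichment,
                            seed = seed)
  traj <- make_trajectory(s, n_frames = n_frames, noise_sigma = noise_sigma,
                          seed = seed)
  paths <- list(structure = file.path(dir, "target.pdb"),
                reference = file.path(dir, "reference.fasta"),
                pockets = file.path(dir, "pockets.csv"),
                trajectory = file.path(dir, "trajectory.pdb"),
                truth = file.path(dir, "truth.json"))
  write_pdb(s, paths$structure)
  write_fasta(hp$reference, paths$reference)
  flat <- pf$predictions
  flat$residues <- vapply(flat$lining_residues, paste, "", collapse = ";")
  flat$lining_residues <- NULL
  write.csv(flat, paths$pockets, row.names = FALSE, quote = TRUE)
  write_trajectory_pdb(traj, paths$trajectory)
  jsonlite::write_json(list(seed = seed,
                            truth_pocket_id = pf$truth_pocket_id,
                            conserved_residues = conserved,
                            truth_classes = hp$truth),
                       paths$truth, auto_unbox = TRUE, pretty = TRUE)
  invisible(list(structure = s, homologs = hp, pockets = pf, trajectory = traj,
                 conserved_residues = conserved, paths = paths))
}
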