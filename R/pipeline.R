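# ---------------------------------------------------------------------------
# Stage orchestration: each runner reads standard-format inputs, calls the
# module functions, writes CSV/JSON outputs and a manifest sufficient to
# reproduce the run (input digests, parameters, package version).
# ---------------------------------------------------------------------------

write_manifest <- function(out_dir, stage, inputs, params) {
  digests <- lapply(inputs, function(p)
    if (!is.null(p) && file.exists(p)) unname(tools::md5sum(p)) else NULL)
  manifest <- list(stage = stage,
                   package = "pocketcons",
                   version = as.character(utils::packageVersion("pocketcons")),
                   inputs = inputs, input_md5 = digests, params = params)
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  invisible(path)
}

#' Run the pocket-nomination pipeline
#'
#' End-to-end: read the target structure and reference-domain sequence,
#' globally align, project conserved columns onto the structure (TC_a),
#' load multi-detector pocket predictions, z-score rank them per method,
#' score the consensus-selected pockets for conservation enrichment and
#' nominate the binding pocket. Writes `conservation_map.csv`,
#' `ranked_pockets.csv`, `pocket_scores.csv`, `selection.json` and
#' `manifest.json` into `out_dir`.
#'
#' @param structure_file Target structure (PDB).
#' @param reference_fasta Reference domain sequence (FASTA; first record).
#' @param pockets_file Pocket predictions CSV
#'   (see [load_pocket_predictions()]).
#' @param out_dir Output directory.
#' @param chain Target chain (default `"A"`).
#' @param gap_open,gap_extend Alignment gap penalties (defaults 10 / 0.5).
#' @param k Pockets selected per detector (default 3).
#' @param pvalue_mode `"pmf"` (default) or `"upper_tail"`.
#' @return Invisibly, a list with `alignment`, `cmap`, `ranked`, `scores`,
#'   `selected` and `paths`.
#' @export
run_pocket_pipeline <- function(structure_file, reference_fasta, pockets_file,
                                out_dir, chain = "A", gap_open = 10,
                                gap_extend = 0.5, k = 3,
                                pvalue_mode = "pmf") {
  for (f in c(structure_file, reference_fasta, pockets_file))
    if (!file.exists(f)) stop("pocket-pipeline: missing input file: ", f)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  s <- tryCatch(read_pdb(structure_file)[[1]],
                error = function(e) stop("pocket-pipeline [structure]: ",
                                         conditionMessage(e), call. = FALSE))
  ref <- read_fasta(reference_fasta)[[1]]
  tseq <- extract_sequence(s, chain)
  aln <- global_align(ref, tseq, gap_open = gap_open, gap_extend = gap_extend)
  cmap <- build_conservation_map(aln, s, chain)
  pred <- tryCatch(load_pocket_predictions(pockets_file),
                   error = function(e) stop("pocket-pipeline [pockets]: ",
                                            conditionMessage(e), call. = FALSE))
  ranked <- zscore_rank(pred, k = k)
  scores <- score_pockets(ranked, cmap, s, pvalue_mode = pvalue_mode)
  sel <- select_binding_pocket(scores)
  winner_res <- ranked$lining_residues[[
    which(ranked$method == sel$method & ranked$pocket_id == sel$pocket_id)[1]]]
  paths <- list(conservation_map = file.path(out_dir, "conservation_map.csv"),
                ranked = file.path(out_dir, "ranked_pockets.csv"),
                scores = file.path(out_dir, "pocket_scores.csv"),
                selection = file.path(out_dir, "selection.json"))
  write.csv(cmap$classes, paths$conservation_map, row.names = FALSE)
  write_ranked_pockets(ranked, paths$ranked)
  write.csv(attr(sel, "ranked"), paths$scores, row.names = FALSE)
  jsonlite::write_json(list(pocket_id = sel$pocket_id, method = sel$method,
                            p_a = sel$p_a, op_c = sel$op_c, ep_c = sel$ep_c,
                            ratio = sel$ratio, poisson_p = sel$poisson_p,
                            residues = sort(winner_res),
                            tc_a = cmap$tc_a, t_a = cmap$t_a),
                       paths$selection, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  write_manifest(out_dir, "pocket-score",
                 list(structure = structure_file, reference = reference_fasta,
                      pockets = pockets_file),
                 list(chain = chain, gap_open = gap_open,
                      gap_extend = gap_extend, k = k,
                      pvalue_mode = pvalue_mode))
  invisible(list(alignment = aln, cmap = cmap, ranked = ranked,
                 scores = attr(sel, "ranked"), selected = sel, paths = paths))
}

#' Run docking post-processing
#'
#' Converts binding free energies to inhibition constants and, when a
#' docked complex plus donor/acceptor roles are supplied, detects
#' receptor-ligand hydrogen bonds. Writes `ki_report.csv`, optionally
#' `hbonds.csv`, and `manifest.json`.
#'
#' @param binding_energy Numeric vector of binding free energies, kcal/mol.
#' @param out_dir Output directory.
#' @param labels Optional labels, one per energy.
#' @param temperature Temperature in K (default 298.15).
#' @param complex_file Optional docked complex PDB.
#' @param roles_file Optional donor/acceptor role file
#'   (see [load_hbond_roles()]).
#' @param d_max,angle_max Hydrogen-bond criteria (3.5 Angstrom / 30 deg).
#' @return Invisibly, list with `ki` (data.frame) and `hbonds` (or `NULL`).
#' @export
run_dock_post <- function(binding_energy, out_dir, labels = NULL,
                          temperature = 298.15, complex_file = NULL,
                          roles_file = NULL, d_max = 3.5, angle_max = 30) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(labels)) labels <- paste0("complex_", seq_along(binding_energy))
  ki <- ki_from_energy(binding_energy, temperature)
  rep <- data.frame(label = labels, binding_energy_kcal_mol = binding_energy,
                    temperature_K = temperature, ki_M = ki, ki_uM = ki * 1e6,
                    stringsAsFactors = FALSE)
  write.csv(rep, file.path(out_dir, "ki_report.csv"), row.names = FALSE)
  hb <- NULL
  if (!is.null(complex_file)) {
    if (!file.exists(complex_file)) stop("dock-post: missing complex file: ", complex_file)
    if (is.null(roles_file) || !file.exists(roles_file))
      stop("dock-post: a roles file is required to detect hydrogen bonds")
    s <- read_pdb(complex_file)[[1]]
    roles <- load_hbond_roles(roles_file)
    hb <- detect_hbonds(s, roles$donors, roles$acceptors, d_max, angle_max,
                        hydrogens = if (length(roles$hydrogens)) roles$hydrogens)
    write.csv(hb, file.path(out_dir, "hbonds.csv"), row.names = FALSE)
  }
  write_manifest(out_dir, "dock-post",
                 list(complex = complex_file, roles = roles_file),
                 list(binding_energy = binding_energy,
                      temperature = temperature, d_max = d_max,
                      angle_max = angle_max))
  invisible(list(ki = rep, hbonds = hb))
}

#' Run trajectory analysis
#'
#' Computes RMSD, radius of gyration, per-residue RMSF, optionally a
#' hydrogen-bond time series, and the mean smallest-distance residue
#' matrix from a multi-MODEL PDB trajectory. Writes per-frame and
#' per-residue CSVs, a `mdmat.csv` matrix, PNG plots and `manifest.json`.
#'
#' @param trajectory_file Multi-MODEL PDB trajectory.
#' @param out_dir Output directory.
#' @param selection `"backbone"` (default) or `"calpha"`.
#' @param truncation mdmat cap in nm (default 1.5).
#' @param roles_file Optional donor/acceptor role file for the H-bond
#'   series.
#' @param plots Write PNG plots (default `TRUE`).
#' @return Invisibly, list with `rmsd`, `rg`, `rmsf`, `hbonds`, `mdmat`.
#' @export
run_traj <- function(trajectory_file, out_dir, selection = "backbone",
                     truncation = 1.5, roles_file = NULL, plots = TRUE) {
  if (!file.exists(trajectory_file))
    stop("traj: missing trajectory file: ", trajectory_file)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  traj <- read_trajectory_pdb(trajectory_file)
  rmsd <- rmsd_series(traj, selection)
  rg <- rg_series(traj, selection)
  rmsf <- rmsf_per_residue(traj, selection)
  md <- mean_smallest_distance_matrix(traj, truncation)
  write.csv(data.frame(time_ps = traj$times, rmsd_nm = rmsd, rg_nm = rg),
            file.path(out_dir, "frame_metrics.csv"), row.names = FALSE)
  write.csv(data.frame(residue = names(rmsf), rmsf_nm = as.numeric(rmsf)),
            file.path(out_dir, "rmsf.csv"), row.names = FALSE)
  write.csv(as.data.frame(md$matrix), file.path(out_dir, "mdmat.csv"))
  hb <- NULL
  if (!is.null(roles_file)) {
    roles <- load_hbond_roles(roles_file)
    hb <- hbond_series(traj, roles$donors, roles$acceptors,
                       hydrogens = if (length(roles$hydrogens)) roles$hydrogens)
    write.csv(data.frame(time_ps = traj$times, n_hbonds = hb$count),
              file.path(out_dir, "hbond_count.csv"), row.names = FALSE)
    write.csv(hb$occupancy, file.path(out_dir, "hbond_occupancy.csv"),
              row.names = FALSE)
  }
  if (plots) {
    png_plot <- function(name, expr) {
      grDevices::png(file.path(out_dir, name), width = 800, height = 500)
      on.exit(grDevices::dev.off())
      expr()
    }
    png_plot("rmsd.png", function()
      graphics::plot(traj$times / 1000, rmsd, type = "l", xlab = "time (ns)",
                     ylab = "RMSD (nm)", main = paste("RMSD,", selection)))
    png_plot("rg.png", function()
      graphics::plot(traj$times / 1000, rg, type = "l", xlab = "time (ns)",
                     ylab = "Rg (nm)", main = paste("Radius of gyration,", selection)))
    png_plot("rmsf.png", function()
      graphics::plot(seq_along(rmsf), as.numeric(rmsf), type = "h",
                     xlab = "residue", ylab = "RMSF (nm)", main = "Per-residue RMSF"))
    png_plot("mdmat.png", function()
      graphics::image(md$matrix, main = "Mean smallest distance (nm)",
                      xlab = "residue", ylab = "residue"))
  }
  write_manifest(out_dir, "traj", list(trajectory = trajectory_file),
                 list(selection = selection, truncation = truncation))
  invisible(list(rmsd = rmsd, rg = rg, rmsf = rmsf, hbonds = hb, mdmat = md))
}
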