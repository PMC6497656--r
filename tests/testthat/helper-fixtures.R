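# Fixture builders and independent oracles shared across tests.
# All fixtures are constructed in code; nothing is read from disk except
# files the tests themselves write to tempdir().

# One fixed-width PDB coordinate line (independent of write_pdb on purpose).
pdb_line <- function(rec, serial, name, res, chain, resno, x, y, z,
                     occ = 1, elem, alt = " ", ins = " ") {
  nm <- if (nchar(name) < 4) sprintf(" %-3s", name) else sprintf("%-4s", name)
  sprintf("%-6s%5d %s%s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          rec, serial, nm, alt, res, chain, resno, ins, x, y, z, occ, 0, elem)
}

# Gly-Ala-Ser tripeptide: 4 + 5 + 6 = 15 heavy atoms.
gas_atom_spec <- function() {
  list(
    list("N", "GLY", 1, "N"), list("CA", "GLY", 1, "C"),
    list("C", "GLY", 1, "C"), list("O", "GLY", 1, "O"),
    list("N", "ALA", 2, "N"), list("CA", "ALA", 2, "C"),
    list("C", "ALA", 2, "C"), list("O", "ALA", 2, "O"),
    list("CB", "ALA", 2, "C"),
    list("N", "SER", 3, "N"), list("CA", "SER", 3, "C"),
    list("C", "SER", 3, "C"), list("O", "SER", 3, "O"),
    list("CB", "SER", 3, "C"), list("OG", "SER", 3, "O"))
}

gas_lines <- function(shift = 0, res2 = "ALA") {
  spec <- gas_atom_spec()
  if (res2 != "ALA")
    spec <- lapply(spec, function(a) { if (a[[3]] == 2) a[[2]] <- res2; a })
  vapply(seq_along(spec), function(i) {
    a <- spec[[i]]
    pdb_line("ATOM", i, a[[1]], a[[2]], "A", a[[3]],
             x = i * 1.3 + shift, y = (i %% 4) * 1.1, z = i * 0.6, elem = a[[4]])
  }, "")
}

write_gas_pdb <- function(path = tempfile(fileext = ".pdb"), nmodels = 1,
                          res2 = "ALA") {
  if (nmodels == 1) {
    writeLines(c(gas_lines(res2 = res2), "END"), path)
  } else {
    body <- unlist(lapply(seq_len(nmodels), function(m)
      c(sprintf("MODEL     %4d", m), gas_lines(shift = (m - 1) * 2, res2 = res2),
        "ENDMDL")))
    writeLines(c(body, "END"), path)
  }
  path
}

# TCDD-like hetero group: C12Cl4O2 -> 18 heavy atoms, no polymer residues.
write_tcdd_pdb <- function(path = tempfile(fileext = ".pdb")) {
  elems <- c(rep("C", 12), rep("CL", 4), rep("O", 2))
  names <- c(paste0("C", 1:12), paste0("CL", 1:4), c("O1", "O2"))
  lines <- vapply(seq_along(elems), function(i)
    pdb_line("HETATM", i, names[i], "TCD", "L", 1,
             x = cos(i) * 3, y = sin(i) * 3, z = i * 0.2, elem = elems[i]), "")
  writeLines(c(lines, "END"), path)
  path
}

# Linear-gap Needleman-Wunsch with free end gaps: independent brute-force
# oracle (score only), penalty d per gap column.
nw_linear_oracle <- function(a, b, mat, d) {
  va <- strsplit(a, "")[[1]]; vb <- strsplit(b, "")[[1]]
  n <- length(va); m <- length(vb)
  F <- matrix(0, n + 1, m + 1)        # free leading gaps
  for (i in seq_len(n)) for (j in seq_len(m)) {
    F[i + 1, j + 1] <- max(F[i, j] + mat[va[i], vb[j]],
                           F[i, j + 1] - d, F[i + 1, j] - d)
  }
  max(F[n + 1, ], F[, m + 1])          # free trailing gaps
}

# Numeric-minimization superposition oracle: optimize 3 Euler angles,
# translation handled by centroiding; returns the minimized RMSD.
rmsd_optim_oracle <- function(ref, mob) {
  n <- nrow(ref)
  rc <- colMeans(ref); mc <- colMeans(mob)
  P <- sweep(mob, 2, mc); Q <- sweep(ref, 2, rc)
  rotmat <- function(ang) {
    cx <- cos(ang[1]); sx <- sin(ang[1])
    cy <- cos(ang[2]); sy <- sin(ang[2])
    cz <- cos(ang[3]); sz <- sin(ang[3])
    Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
    Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE)
    Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE)
    Rz %*% Ry %*% Rx
  }
  obj <- function(ang) mean(rowSums((P %*% t(rotmat(ang)) - Q)^2))
  starts <- list(c(0, 0, 0), c(pi / 2, 0, 0), c(0, pi, 0), c(pi, pi / 2, pi),
                 c(-pi / 2, pi / 4, pi / 2))
  best <- Inf
  for (st in starts) {
    o <- stats::optim(st, obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-15, maxit = 5000))
    o <- stats::optim(o$par, obj, method = "BFGS",
                      control = list(reltol = 1e-15, maxit = 1000))
    best <- min(best, o$value)
  }
  sqrt(best)
}

# Brute-force mean smallest-distance oracle: explicit double loop over
# residues, atoms and frames.
mdmat_oracle <- function(traj, truncation = 1.5) {
  at <- traj$topology$atoms
  heavy <- which(!at$is_hetero & !toupper(at$element) %in% c("H", "D"))
  key <- paste0(at$chain_id[heavy], ":", at$res_seq[heavy],
                ifelse(at$ins[heavy] == "", "", paste0(":", at$ins[heavy])))
  rlev <- unique(key)
  nr <- length(rlev)
  acc <- matrix(0, nr, nr, dimnames = list(rlev, rlev))
  for (f in traj$frames) {
    x <- f[heavy, , drop = FALSE]
    for (i in seq_len(nr)) for (j in seq_len(nr)) {
      if (i == j) next
      ai <- which(key == rlev[i]); aj <- which(key == rlev[j])
      dmin <- Inf
      for (p in ai) for (q in aj)
        dmin <- min(dmin, sqrt(sum((x[p, ] - x[q, ])^2)))
      acc[i, j] <- acc[i, j] + min(0.1 * dmin, truncation)
    }
  }
  acc / length(traj$frames)
}

# Small random rigid transform applied to an n x 3 matrix.
random_rigid <- function(xyz, seed = 1) {
  set.seed(seed)
  ang <- runif(3, -pi, pi)
  cx <- cos(ang[1]); sx <- sin(ang[1])
  cy <- cos(ang[2]); sy <- sin(ang[2])
  cz <- cos(ang[3]); sz <- sin(ang[3])
  R <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE) %*%
    matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE) %*%
    matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
  sweep(xyz %*% t(R), 2, runif(3, -20, 20), "+")
}

# Pocket-prediction CSV writer for consensus tests.
write_pockets_csv <- function(df, path = tempfile(fileext = ".csv")) {
  write.csv(df, path, row.names = FALSE, quote = TRUE)
  path
}

# Poisson pmf reference values computed once with exact rational /
# arbitrary-precision arithmetic (sympy: exp(-ep) * ep^op / op!) and frozen.
poisson_oracle <- list(
  list(op = 0, ep = 0.5, p = 0.60653065971263342),
  list(op = 0, ep = 5.0, p = 0.0067379469990854671),
  list(op = 1, ep = 1.0, p = 0.36787944117144232),
  list(op = 2, ep = 1.0, p = 0.18393972058572116),
  list(op = 2, ep = 3.7, p = 0.16923253868947313),
  list(op = 3, ep = 2.5, p = 0.21376301724973645),
  list(op = 5, ep = 2.0, p = 0.036089408863096718),
  list(op = 5, ep = 8.0, p = 0.091603661592579233),
  list(op = 7, ep = 7.0, p = 0.14900277967433789),
  list(op = 10, ep = 3.0, p = 0.00081015117946814318),
  list(op = 10, ep = 10.5, p = 0.12360552906286463),
  list(op = 17, ep = 20.0, p = 0.075954196370232862),
  list(op = 25, ep = 25.0, p = 0.079522951468065446),
  list(op = 50, ep = 40.0, p = 0.017707017552636247),
  list(op = 60, ep = 75.0, p = 0.010266320338599784),
  list(op = 100, ep = 90.0, p = 0.023320825425141801),
  list(op = 150, ep = 160.0, p = 0.023658482403578863),
  list(op = 250, ep = 240.0, p = 0.020537537794448787),
  list(op = 400, ep = 410.0, p = 0.017635628018117677),
  list(op = 500, ep = 450.0, p = 0.0012227326133173476))
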