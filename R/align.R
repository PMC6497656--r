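# ---------------------------------------------------------------------------
# Needleman-Wunsch global alignment with affine gaps.
#
# Conventions (EMBOSS-Needle-like, frozen as package defaults):
#   * BLOSUM62, gap_open 10, gap_extend 0.5
#   * a gap of length L costs gap_open + gap_extend * L (the opening column
#     pays both the opening charge and one extension; the same convention as
#     Biostrings::pairwiseAlignment, so the two can be compared exactly)
#   * end gaps are free unless penalize_end_gaps = TRUE
#   * deterministic traceback, tie-break diagonal > up (gap in b) > left
#     (gap in a)
# ---------------------------------------------------------------------------

#' Global pairwise alignment (Needleman-Wunsch, affine gaps)
#'
#' Aligns two protein sequences globally, maximizing the summed substitution
#' score minus affine gap costs. With `penalize_end_gaps = FALSE` (the
#' default, matching the EMBOSS Needle default) leading and trailing gaps in
#' either sequence are free, so short domains align into longer targets
#' without penalty.
#'
#' @param a,b `pc_sequence` objects or plain character strings.
#' @param matrix Substitution matrix; default [blosum62()].
#' @param gap_open Gap opening penalty (positive; default 10).
#' @param gap_extend Gap extension penalty per gap column (default 0.5).
#' @param penalize_end_gaps Charge terminal gaps? Default `FALSE`.
#' @return A `pc_alignment`: list with `aligned_a`, `aligned_b` (gapped
#'   strings), `score`, `column_classes` (per column: `identical`,
#'   `conserved`, `mismatch` or `gap`), `pid` (percent identity over the
#'   full alignment length, EMBOSS convention) and the parameters used.
#' @export
#' @examples
#' aln <- global_align("HEAGAWGHEE", "PAWHEAE")
#' aln$score
global_align <- function(a, b, matrix = blosum62(), gap_open = 10,
                         gap_extend = 0.5, penalize_end_gaps = FALSE) {
  sa <- as_residue_string(a)
  sb <- as_residue_string(b)
  if (!nchar(sa) || !nchar(sb)) stop("cannot align an empty sequence")
  va <- strsplit(sa, "")[[1]]
  vb <- strsplit(sb, "")[[1]]
  bad <- setdiff(c(va, vb), rownames(matrix))
  if (length(bad))
    stop("symbol(s) absent from substitution matrix: ", paste(unique(bad), collapse = ""))
  res <- nw_affine(va, vb, matrix, gap_open, gap_extend, penalize_end_gaps)
  cls <- classify_columns(res$aligned_a, res$aligned_b, matrix)
  structure(list(aligned_a = res$aligned_a, aligned_b = res$aligned_b,
                 score = res$score, column_classes = cls,
                 pid = 100 * sum(cls == "identical") / length(cls),
                 gap_open = gap_open, gap_extend = gap_extend,
                 matrix_name = "BLOSUM62",
                 penalize_end_gaps = penalize_end_gaps,
                 id_a = seq_id(a), id_b = seq_id(b)),
            class = "pc_alignment")
}

as_residue_string <- function(x) {
  if (inherits(x, "pc_sequence")) x$residues else toupper(as.character(x))
}
seq_id <- function(x) if (inherits(x, "pc_sequence")) x$id else "seq"

#' @export
print.pc_alignment <- function(x, ...) {
  cat(sprintf("pc_alignment: score %.1f, length %d, identity %.1f%% (%s/%s, gap %g/%g%s)\n",
              x$score, nchar(x$aligned_a), x$pid, x$id_a, x$id_b,
              x$gap_open, x$gap_extend,
              if (x$penalize_end_gaps) "" else ", free end gaps"))
  wa <- strsplit(x$aligned_a, "")[[1]]
  wb <- strsplit(x$aligned_b, "")[[1]]
  mid <- ifelse(x$column_classes == "identical", "|",
                ifelse(x$column_classes == "conserved", ":", " "))
  for (st in seq(1, length(wa), by = 60)) {
    en <- min(st + 59, length(wa))
    cat(paste(wa[st:en], collapse = ""), "\n")
    cat(paste(mid[st:en], collapse = ""), "\n")
    cat(paste(wb[st:en], collapse = ""), "\n\n")
  }
  invisible(x)
}

# Core affine DP. States: M (a_i~b_j), X (a_i~gap, "up"), Y (gap~b_j, "left").
nw_affine <- function(va, vb, mat, open, extend, penalize_end_gaps) {
  n <- length(va); m <- length(vb)
  NEG <- -1e18
  gopen <- open + extend          # cost of the first column of a gap
  S <- mat[va, vb, drop = FALSE]  # n x m substitution scores
  M <- matrix(NEG, n + 1, m + 1); X <- M; Y <- M
  M[1, 1] <- 0
  ecol <- if (penalize_end_gaps) -(gopen + extend * (seq_len(n) - 1)) else rep(0, n)
  erow <- if (penalize_end_gaps) -(gopen + extend * (seq_len(m) - 1)) else rep(0, m)
  X[seq_len(n) + 1, 1] <- ecol
  Y[1, seq_len(m) + 1] <- erow
  # traceback pointers: 0 none; for M: 1=fromM,2=fromX,3=fromY (diagonal step)
  PM <- matrix(0L, n + 1, m + 1); PX <- PM; PY <- PM
  PX[seq_len(n) + 1, 1] <- 2L
  PY[1, seq_len(m) + 1] <- 3L
  for (i in seq_len(n)) {
    Mi1 <- M[i, ]; Xi1 <- X[i, ]; Yi1 <- Y[i, ]
    Mi <- M[i + 1, ]; Xi <- X[i + 1, ]; Yi <- Y[i + 1, ]
    PMi <- PM[i + 1, ]; PXi <- PX[i + 1, ]; PYi <- PY[i + 1, ]
    Srow <- S[i, ]
    for (j in seq_len(m)) {
      # M: diagonal from any state (tie-break M > X > Y)
      cand <- c(Mi1[j], Xi1[j], Yi1[j])
      k <- which.max(cand)
      Mi[j + 1] <- cand[k] + Srow[j]
      PMi[j + 1] <- k
      # X: gap in b, consume a_i (vertical); from M (open) or X (extend) or Y (open)
      cand <- c(Mi1[j + 1] - gopen, Xi1[j + 1] - extend, Yi1[j + 1] - gopen)
      k <- which.max(cand)
      Xi[j + 1] <- cand[k]
      PXi[j + 1] <- k
      # Y: gap in a, consume b_j (horizontal)
      cand <- c(Mi[j] - gopen, Xi[j] - gopen, Yi[j] - extend)
      k <- which.max(cand)
      Yi[j + 1] <- cand[k]
      PYi[j + 1] <- k
    }
    M[i + 1, ] <- Mi; X[i + 1, ] <- Xi; Y[i + 1, ] <- Yi
    PM[i + 1, ] <- PMi; PX[i + 1, ] <- PXi; PY[i + 1, ] <- PYi
  }
  best_state <- function(i, j) {
    v <- c(M[i + 1, j + 1], X[i + 1, j + 1], Y[i + 1, j + 1])
    k <- which.max(v)
    list(score = v[k], state = k)
  }
  if (penalize_end_gaps) {
    start <- c(n, m); bs <- best_state(n, m)
  } else {
    # free trailing gaps: end anywhere on the last row/column
    best <- list(score = -Inf); start <- c(n, m)
    for (i in n:0) {                       # last column, prefer larger i
      b <- best_state(i, m)
      if (b$score > best$score) { best <- b; start <- c(i, m) }
    }
    for (j in m:0) {                       # last row
      b <- best_state(n, j)
      if (b$score > best$score) { best <- b; start <- c(n, j) }
    }
    bs <- best_state(start[1], start[2])
  }
  # traceback
  i <- start[1]; j <- start[2]; st <- bs$state
  ra <- character(0); rb <- character(0)
  # trailing free gaps
  if (i < n) { ra <- c(va[(i + 1):n], ra); rb <- c(rep("-", n - i), rb) }
  if (j < m) { ra <- c(rep("-", m - j), ra); rb <- c(vb[(j + 1):m], rb) }
  while (i > 0 || j > 0) {
    if (st == 1L) {
      if (i == 0 || j == 0) break
      prev <- PM[i + 1, j + 1]
      ra <- c(va[i], ra); rb <- c(vb[j], rb)
      i <- i - 1; j <- j - 1; st <- prev
    } else if (st == 2L) {
      prev <- PX[i + 1, j + 1]
      ra <- c(va[i], ra); rb <- c("-", rb)
      i <- i - 1; st <- prev
    } else {
      prev <- PY[i + 1, j + 1]
      ra <- c("-", ra); rb <- c(vb[j], rb)
      j <- j - 1; st <- prev
    }
  }
  list(aligned_a = paste(ra, collapse = ""),
       aligned_b = paste(rb, collapse = ""),
       score = bs$score)
}

#' Classify alignment columns
#'
#' `identical`: same letter on both sides. `conserved`: different letters
#' with a strictly positive substitution score (the EMBOSS "similar"
#' convention). `gap`: either side gapped. Everything else: `mismatch`.
#'
#' @param aligned_a,aligned_b Equal-length gapped strings (or a
#'   `pc_alignment` as the first argument).
#' @param matrix Substitution matrix.
#' @return Character vector of per-column labels.
#' @export
classify_columns <- function(aligned_a, aligned_b = NULL, matrix = blosum62()) {
  if (inherits(aligned_a, "pc_alignment")) {
    aligned_b <- aligned_a$aligned_b
    aligned_a <- aligned_a$aligned_a
  }
  wa <- strsplit(aligned_a, "")[[1]]
  wb <- strsplit(aligned_b, "")[[1]]
  if (length(wa) != length(wb)) stop("aligned strings differ in length")
  if (any(wa == "-" & wb == "-")) stop("column gapped on both sides")
  out <- character(length(wa))
  gap <- wa == "-" | wb == "-"
  out[gap] <- "gap"
  idn <- !gap & wa == wb
  out[idn] <- "identical"
  rest <- !gap & !idn
  if (any(rest)) {
    sc <- matrix[cbind(wa[rest], wb[rest])]
    out[rest] <- ifelse(sc > 0, "conserved", "mismatch")
  }
  out
}

#' Percent identity of an alignment
#'
#' Identical columns over the full alignment length (gaps included), in
#' percent — the EMBOSS Needle convention.
#'
#' @param aln A `pc_alignment`.
#' @return A number in \[0, 100\].
#' @export
percent_identity <- function(aln) {
  stopifnot(inherits(aln, "pc_alignment"))
  aln$pid
}

#' Project conserved alignment columns onto a target structure
#'
#' Maps every `identical` or `conserved` column of a reference-vs-target
#' alignment to the target residue occupying it, and counts the heavy atoms
#' of those residues (TC_a), the quantity the conservation-enrichment
#' statistic expects per pocket.
#'
#' @param aln A `pc_alignment` whose *b* side is the target sequence.
#' @param target A `pc_structure`.
#' @param target_chain Chain of `target` that was aligned.
#' @return A `pc_conservation_map`: list with `target_id`,
#'   `conserved_residues` (residue identifiers, class attached as names),
#'   `tc_a`, `t_a` and the per-residue class table.
#' @export
build_conservation_map <- function(aln, target, target_chain) {
  stopifnot(inherits(aln, "pc_alignment"), inherits(target, "pc_structure"))
  tseq <- extract_sequence(target, target_chain)
  ungapped <- gsub("-", "", aln$aligned_b)
  if (ungapped != tseq$residues) {
    ref <- strsplit(tseq$residues, "")[[1]]
    got <- strsplit(ungapped, "")[[1]]
    n <- min(length(ref), length(got))
    d <- which(ref[seq_len(n)] != got[seq_len(n)])
    first <- if (length(d)) d[1] else n + 1L
    stop("alignment/structure mismatch for chain ", target_chain,
         ": first discordant position ", first)
  }
  wb <- strsplit(aln$aligned_b, "")[[1]]
  pos_b <- cumsum(wb != "-")          # target residue index per column
  keep <- aln$column_classes %in% c("identical", "conserved") & wb != "-"
  idx <- pos_b[keep]
  if (length(idx)) {
    num <- tseq$numbering[idx, , drop = FALSE]
    ins <- ifelse(num$ins == "", "", paste0(":", num$ins))
    resid <- paste0(num$chain_id, ":", num$res_seq, ins)
    names(resid) <- aln$column_classes[keep]
  } else {
    resid <- character(0)
  }
  tc_a <- count_atoms(target, residues = unique(resid))
  structure(list(target_id = tseq$id,
                 conserved_residues = resid,
                 tc_a = tc_a,
                 t_a = count_atoms(target),
                 classes = data.frame(residue = unname(resid),
                                      class = names(resid),
                                      stringsAsFactors = FALSE)),
            class = "pc_conservation_map")
}

#' @export
print.pc_conservation_map <- function(x, ...) {
  cat(sprintf("pc_conservation_map: %d identical + %d conserved residues, TC_a = %d of T_a = %d heavy atoms\n",
              sum(names(x$conserved_residues) == "identical"),
              sum(names(x$conserved_residues) == "conserved"),
              x$tc_a, x$t_a))
  invisible(x)
}

#' Write an alignment in a pair format
#'
#' Emits a small EMBOSS-pair-style text rendering plus a machine-readable
#' trailer (one line per column: position, letters, class).
#'
#' @param aln A `pc_alignment`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_alignment <- function(aln, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c(
    "########################################",
    sprintf("# Aligned_sequences: 2 (%s, %s)", aln$id_a, aln$id_b),
    sprintf("# Matrix: %s  Gap_penalty: %g  Extend_penalty: %g",
            aln$matrix_name, aln$gap_open, aln$gap_extend),
    sprintf("# Length: %d  Identity: %.1f%%  Score: %.1f",
            nchar(aln$aligned_a), aln$pid, aln$score),
    "########################################",
    aln$aligned_a, aln$aligned_b, "",
    "# column\ta\tb\tclass"), con)
  wa <- strsplit(aln$aligned_a, "")[[1]]
  wb <- strsplit(aln$aligned_b, "")[[1]]
  writeLines(sprintf("%d\t%s\t%s\t%s", seq_along(wa), wa, wb, aln$column_classes), con)
  invisible(file)
}
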