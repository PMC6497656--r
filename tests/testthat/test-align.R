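test_that("self-alignment is perfect: diagonal score, 100% identity, no gaps", {
  set.seed(1)
  aa <- setdiff(rownames(blosum62()), "X")
  for (len in c(1, 7, 40)) {
    s <- paste(sample(aa, len, replace = TRUE), collapse = "")
    aln <- global_align(s, s)
    expect_equal(aln$aligned_a, s)
    expect_equal(aln$aligned_b, s)
    v <- strsplit(s, "")[[1]]
    expect_equal(aln$score, sum(blosum62()[cbind(v, v)]))
    expect_equal(percent_identity(aln), 100)
    expect_true(all(aln$column_classes == "identical"))
  }
})

# Frozen from an independent affine Needleman-Wunsch reference
# (Biostrings::pairwiseAlignment, BLOSUM62, gapOpening 10, gapExtension 0.5,
# free end gaps): optimal score 15 with the shorter sequence end-gapped in.
test_that("the classic two-domain pair reproduces the frozen reference alignment", {
  aln <- global_align("HEAGAWGHEE", "PAWHEAE")
  expect_equal(aln$score, 15)
  expect_equal(aln$aligned_a, "HEAGAWGHEE")
  expect_equal(aln$aligned_b, "---PAWHEAE")
})

test_that("alignment score agrees with Biostrings on random pairs", {
  library(Biostrings)
  mat <- blosum62()
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  set.seed(7)
  aa <- setdiff(rownames(mat), "X")
  for (r in 1:25) {
    a <- paste(sample(aa, sample(4:30, 1), replace = TRUE), collapse = "")
    b <- paste(sample(aa, sample(4:30, 1), replace = TRUE), collapse = "")
    ref <- Biostrings::score(Biostrings::pairwiseAlignment(
      a, b, substitutionMatrix = env$BLOSUM62,
      gapOpening = 10, gapExtension = 0.5, type = "overlap"))
    expect_equal(global_align(a, b)$score, ref)
  }
})

test_that("end gaps are free by default", {
  aln <- global_align("AAAA", "AA")
  expect_equal(aln$score, 2 * blosum62()["A", "A"])
  expect_equal(sum(aln$column_classes == "gap"), 2)
  # with end-gap penalties on, the same pair is charged one affine gap
  aln2 <- global_align("AAAA", "AA", penalize_end_gaps = TRUE)
  expect_equal(aln2$score, 2 * blosum62()["A", "A"] - (10 + 0.5) - 0.5)
})

test_that("degenerate inputs are rejected", {
  expect_error(global_align("", "AA"), "empty")
  expect_error(global_align("AB", "AA"), "absent from substitution matrix")
})

test_that("column classification follows the positive-score convention", {
  expect_equal(classify_columns("L", "L"), "identical")
  expect_equal(classify_columns("L", "I"), "conserved")   # BLOSUM62 s = 2 > 0
  expect_equal(classify_columns("L", "-"), "gap")
  expect_equal(classify_columns("L", "D"), "mismatch")    # s = -4
  # G/A scores 0 (not conserved), W/I scores -3, D/E scores +2
  expect_equal(classify_columns("GLWD-", "ALIEK"),
               c("mismatch", "identical", "mismatch", "conserved", "gap"))
  expect_error(classify_columns("A-", "--"), "both sides")
  expect_error(classify_columns("AA", "A"), "differ in length")
})

test_that("score is invariant under argument swap (symmetric matrix, free end gaps)", {
  set.seed(11)
  aa <- setdiff(rownames(blosum62()), "X")
  for (r in 1:10) {
    a <- paste(sample(aa, sample(3:20, 1), replace = TRUE), collapse = "")
    b <- paste(sample(aa, sample(3:20, 1), replace = TRUE), collapse = "")
    expect_equal(global_align(a, b)$score, global_align(b, a)$score)
  }
})

test_that("degenerate affine gaps reduce to the linear-gap brute-force oracle", {
  # with zero opening charge the affine cost of a length-L gap is extend * L,
  # exactly the linear model the oracle implements
  set.seed(13)
  mat <- blosum62()
  aa <- c("A", "C", "D", "E")
  for (r in 1:60) {
    a <- paste(sample(aa, sample(1:8, 1), replace = TRUE), collapse = "")
    b <- paste(sample(aa, sample(1:8, 1), replace = TRUE), collapse = "")
    expect_equal(global_align(a, b, gap_open = 0, gap_extend = 3)$score,
                 nw_linear_oracle(a, b, mat, 3))
  }
})

test_that("conserved columns project onto target residues with exact atom bookkeeping", {
  s <- read_pdb(write_gas_pdb())[[1]]
  aln <- global_align("GAS", extract_sequence(s, "A"))
  cmap <- build_conservation_map(aln, s, "A")
  expect_equal(unname(cmap$conserved_residues), c("A:1", "A:2", "A:3"))
  expect_equal(cmap$tc_a, 15L)
  expect_equal(cmap$t_a, 15L)

  # reference sharing nothing: G/A/S vs prolines scores <= 0 everywhere
  aln0 <- global_align("PPP", extract_sequence(s, "A"))
  cmap0 <- build_conservation_map(aln0, s, "A")
  expect_length(cmap0$conserved_residues, 0)
  expect_equal(cmap0$tc_a, 0L)
})

test_that("projection rejects an alignment that does not match the structure", {
  s <- read_pdb(write_gas_pdb())[[1]]
  aln <- global_align("GAS", "GCS")    # b side disagrees with the chain at pos 2
  expect_error(build_conservation_map(aln, s, "A"), "discordant position 2")
})

test_that("reclassifying columns upward can only grow TC_a (monotonicity)", {
  s <- make_toy_structure(30, seed = 5)
  tseq <- extract_sequence(s, "A")
  hp <- make_homolog_pair(tseq, 0.4, 0.2, seed = 5)
  aln <- global_align(hp$reference, tseq)
  cmap <- build_conservation_map(aln, s, "A")
  # dropping the 'conserved' class (keeping only identical) cannot increase tc_a
  keep_id <- aln$column_classes == "identical"
  wb <- strsplit(aln$aligned_b, "")[[1]]
  pos_b <- cumsum(wb != "-")
  res_id <- residue_ids(s)[pos_b[keep_id & wb != "-"]]
  expect_lte(count_atoms(s, unique(res_id)), cmap$tc_a)
})

test_that("synthetic homolog pairs carry at least the implanted identity into the map", {
  s <- make_toy_structure(50, seed = 9)
  tseq <- extract_sequence(s, "A")
  hp <- make_homolog_pair(tseq, 0.5, 0.2, seed = 9)
  aln <- global_align(hp$reference, tseq)
  cmap <- build_conservation_map(aln, s, "A")
  k <- sum(hp$truth == "identical")
  expect_gte(length(unique(cmap$conserved_residues)), k)
  expect_equal(cmap$tc_a, count_atoms(s, unique(cmap$conserved_residues)))
})
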