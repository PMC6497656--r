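test_that("pocket atom counts come from lining residues or explicit atom lists", {
  s <- read_pdb(write_gas_pdb())[[1]]
  expect_equal(pocket_atom_count("A:3", s), 6L)
  expect_equal(pocket_atom_count(c("A:1", "A:2", "A:3"), s), count_atoms(s))
  expect_equal(pocket_atom_count(list(lining_atoms = c(1, 2, 3, 5)), s), 4L)
  expect_error(pocket_atom_count("A:9", s), "unknown residue")
})

test_that("expected conservation follows TC_a * P_a / T_a exactly", {
  expect_equal(expected_conservation(100, 50, 1000), 5)
  expect_equal(expected_conservation(0, 30, 100), 0)
  expect_equal(expected_conservation(100, 30, 100), 30)   # fully conserved
  expect_error(expected_conservation(10, 5, 0), "positive")
  expect_error(expected_conservation(101, 5, 100), "<=")
})

test_that("the Poisson p-value matches closed forms and the frozen oracle", {
  expect_equal(poisson_pvalue(0, 2.5), exp(-2.5))
  expect_equal(poisson_pvalue(2, 1), exp(-1) / 2)
  for (case in poisson_oracle) {
    got <- poisson_pvalue(case$op, case$ep)
    expect_lt(abs(got - case$p) / case$p, 5e-13)
  }
  expect_error(poisson_pvalue(3, 0), "positive")
  expect_error(poisson_pvalue(2.5, 1), "integer")
})

test_that("pmf probabilities stay in [0,1]; the upper tail is monotone in op_c", {
  set.seed(2)
  for (r in 1:50) {
    op <- sample(0:300, 1); ep <- runif(1, 0.01, 200)
    p <- poisson_pvalue(op, ep)
    expect_gte(p, 0); expect_lte(p, 1)
  }
  ep <- 12.3
  tails <- poisson_pvalue(0:60, ep, mode = "upper_tail")
  expect_true(all(diff(tails) <= 1e-15))
  expect_equal(tails[1], 1)
})

test_that("the Poisson descriptor gamma-generalizes the pmf to real ratios", {
  expect_equal(poisson_descriptor(1, 1), exp(-1))
  expect_equal(poisson_descriptor(2, 2), 2 * exp(-2))
  # non-integer ratio against a direct gamma-function evaluation
  expect_equal(poisson_descriptor(1.5, 1), exp(-1) / gamma(2.5))
  set.seed(4)
  for (r in 1:20) {
    ratio <- runif(1, 0.05, 12); lam <- runif(1, 0.05, 8)
    expect_equal(poisson_descriptor(ratio, lam),
                 lam^ratio * exp(-lam) / gamma(ratio + 1), tolerance = 1e-12)
  }
  expect_error(poisson_descriptor(0, 1), "positive")
  expect_error(poisson_descriptor(1, -2), "positive")
})

make_score_df <- function(ratio, poisson_p, p_a = NULL, ep_c = 1) {
  n <- length(ratio)
  data.frame(method = "m", pocket_id = paste0("P", seq_len(n)),
             p_a = if (is.null(p_a)) rep(10, n) else p_a,
             op_c = round(ratio * ep_c), ep_c = rep(ep_c, n), ratio = ratio,
             poisson_p = poisson_p, descriptor = NA_real_,
             stringsAsFactors = FALSE)
}

test_that("pocket selection maximizes the ratio with documented tie-breaks", {
  s1 <- select_binding_pocket(make_score_df(c(2, 1), c(0.5, 0.5)))
  expect_equal(s1$pocket_id, "P1")
  s2 <- select_binding_pocket(make_score_df(c(1.5, 1.5), c(1e-6, 1e-2)))
  expect_equal(s2$pocket_id, "P1")
  s3 <- select_binding_pocket(make_score_df(c(1.5, 1.5), c(0.1, 0.1),
                                            p_a = c(5, 50)))
  expect_equal(s3$pocket_id, "P2")       # larger pocket wins the tie
  ranked <- attr(s3, "ranked")
  expect_equal(nrow(ranked), 2L)
  expect_equal(sum(ranked$selected), 1L)

  zero <- make_score_df(c(1, 1), c(0.1, 0.1))
  zero$ep_c <- 0
  expect_error(select_binding_pocket(zero), "no conservation signal")
})

test_that("scoring integrates counts, expectation, ratio and descriptor", {
  s <- make_toy_structure(40, seed = 2)
  res <- residue_ids(s)
  conserved <- res[1:10]
  cmap <- structure(list(target_id = "t",
                         conserved_residues = setNames(conserved,
                                                       rep("identical", 10)),
                         tc_a = count_atoms(s, conserved),
                         t_a = count_atoms(s),
                         classes = data.frame()),
                    class = "pc_conservation_map")
  pockets <- data.frame(method = "m", pocket_id = c("good", "bad"),
                        stringsAsFactors = FALSE)
  pockets$lining_residues <- list(res[1:8], res[31:38])
  sc <- score_pockets(pockets, cmap, s)
  expect_equal(sc$op_c[1], count_atoms(s, res[1:8]))   # fully conserved lining
  expect_equal(sc$op_c[2], 0L)
  expect_equal(sc$ep_c, cmap$tc_a * sc$p_a / cmap$t_a)
  expect_equal(attr(sc, "lambda"), mean(sc$ratio[sc$ratio > 0]))
  expect_equal(select_binding_pocket(sc)$pocket_id, "good")
})

test_that("the enrichment ratio is invariant when op and ep double together", {
  base <- make_score_df(2, 0.1)
  doubled <- base
  doubled$op_c <- base$op_c * 2
  doubled$ep_c <- base$ep_c * 2
  expect_equal(doubled$op_c / doubled$ep_c, base$ratio)
})

test_that("an implanted conserved pocket is recovered across replicates", {
  hits <- 0L
  n_rep <- 25L
  for (r in seq_len(n_rep)) {
    s <- make_toy_structure(80, seed = 100 + r)
    res <- residue_ids(s)
    set.seed(200 + r)
    conserved <- sample(res, 20)         # 25% background density
    pf <- make_pocket_fixture(s, conserved, n_pockets = 5, pocket_size = 8,
                              enrichment = 2, seed = 300 + r)
    cmap <- structure(list(target_id = "t",
                           conserved_residues = setNames(conserved,
                                                         rep("identical", 20)),
                           tc_a = count_atoms(s, conserved),
                           t_a = count_atoms(s), classes = data.frame()),
                      class = "pc_conservation_map")
    sc <- score_pockets(pf$predictions, cmap, s, selected_only = FALSE)
    if (select_binding_pocket(sc)$pocket_id == pf$truth_pocket_id)
      hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.95)
})
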