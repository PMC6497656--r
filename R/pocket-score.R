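# ---------------------------------------------------------------------------
# Conservation-enrichment scoring of candidate pockets.
#
# For a pocket lining P_a heavy atoms on a protein of T_a heavy atoms, of
# which TC_a belong to residues identical/conserved against a reference
# ligand-binding domain, the expected number of conserved pocket atoms under
# uniform placement is EP_c = TC_a * P_a / T_a. The observed count OP_c is
# compared to it through the ratio OP_c/EP_c, the Poisson probability mass
# at OP_c with mean EP_c, and a gamma-generalized Poisson descriptor of the
# ratio itself. The pocket with the highest ratio (ties: lowest p-value)
# is nominated as the ligand-binding pocket.
# ---------------------------------------------------------------------------

#' Heavy atoms lining a pocket (P_a)
#'
#' @param lining_residues Character vector of residue identifiers
#'   (`"A:12"`), or a list with elements `lining_residues` and optionally
#'   `lining_atoms` (explicit atom serial numbers, counted directly).
#' @param s A `pc_structure`.
#' @return Non-negative integer count of heavy polymer atoms.
#' @export
pocket_atom_count <- function(lining_residues, s) {
  if (is.list(lining_residues) && !is.null(lining_residues$lining_atoms)) {
    serials <- lining_residues$lining_atoms
    at <- s$atoms[!s$atoms$is_hetero & !is_hydrogen(s$atoms$element), ]
    return(sum(serials %in% at$serial))
  }
  if (is.list(lining_residues)) lining_residues <- lining_residues$lining_residues
  count_atoms(s, residues = lining_residues)
}

#' Expected conserved atoms in a pocket (EP_c)
#'
#' `EP_c = TC_a * P_a / T_a`: the conserved-atom count a pocket of P_a
#' atoms would contain if conserved atoms were spread uniformly over the
#' protein's T_a atoms.
#'
#' @param tc_a Heavy atoms of all identical/conserved residues.
#' @param p_a Heavy atoms lining the pocket.
#' @param t_a Total heavy atoms of the protein (> 0).
#' @return Non-negative real.
#' @export
expected_conservation <- function(tc_a, p_a, t_a) {
  if (!isTRUE(t_a > 0)) stop("t_a must be positive")
  if (tc_a < 0 || p_a < 0 || tc_a > t_a || p_a > t_a)
    stop("counts must satisfy 0 <= tc_a, p_a <= t_a")
  tc_a * p_a / t_a
}

#' Poisson probability of the observed conserved-atom count
#'
#' `mode = "pmf"` (default) returns the Poisson probability mass at `op_c`
#' with mean `ep_c`, `exp(-ep_c) * ep_c^op_c / op_c!`, evaluated in log
#' space so large counts do not overflow. This is the quantity the pocket
#' ranking uses; note it is a point probability, not a calibrated tail
#' probability. `mode = "upper_tail"` returns `P(X >= op_c)` for
#' `X ~ Poisson(ep_c)`.
#'
#' @param op_c Observed conserved atom count (non-negative integer).
#' @param ep_c Expected count (> 0).
#' @param mode `"pmf"` or `"upper_tail"`.
#' @return Probability in \[0, 1\].
#' @export
#' @examples
#' poisson_pvalue(2, 1)   # exp(-1)/2
poisson_pvalue <- function(op_c, ep_c, mode = c("pmf", "upper_tail")) {
  mode <- match.arg(mode)
  if (any(!is.finite(ep_c)) || any(ep_c <= 0)) stop("ep_c must be positive")
  if (any(op_c < 0) || any(op_c != round(op_c))) stop("op_c must be a non-negative integer")
  if (mode == "pmf") {
    stats::dpois(op_c, lambda = ep_c)
  } else {
    stats::ppois(op_c - 1, lambda = ep_c, lower.tail = FALSE)
  }
}

#' Poisson descriptor of the conservation ratio
#'
#' Evaluates `lam^ratio * exp(-lam) / gamma(ratio + 1)`: the Poisson
#' probability mass generalized to a non-integer "count" — here the
#' enrichment ratio OP_c/EP_c — via the gamma function. `lam` is the
#' population mean of the ratios over the candidate pocket set.
#'
#' @param ratio Positive real (OP_c/EP_c).
#' @param lam Positive real rate parameter.
#' @return Positive real.
#' @export
poisson_descriptor <- function(ratio, lam) {
  if (any(!is.finite(ratio)) || any(ratio <= 0)) stop("ratio must be positive")
  if (any(!is.finite(lam)) || any(lam <= 0)) stop("lam must be positive")
  exp(ratio * log(lam) - lam - lgamma(ratio + 1))
}

#' Score candidate pockets for conservation enrichment
#'
#' Computes, for every pocket, the lining heavy-atom count P_a, the
#' observed conserved-atom count OP_c (heavy atoms of lining residues that
#' are identical/conserved in the reference alignment), the expectation
#' EP_c, the enrichment ratio, the Poisson p-value and the descriptor
#' (with `lam` = the mean ratio over the scored set, recomputed per call).
#'
#' @param pockets Data.frame with `method`, `pocket_id` and list-column
#'   `lining_residues` ([load_pocket_predictions()] / [zscore_rank()]
#'   output; only rows with `selected == TRUE` are scored if a `selected`
#'   column is present and `selected_only = TRUE`).
#' @param cmap A `pc_conservation_map` from [build_conservation_map()].
#' @param s The target `pc_structure` the map was built against.
#' @param pvalue_mode Passed to [poisson_pvalue()].
#' @param selected_only Score only consensus-selected pockets? Default
#'   `TRUE` when a `selected` column is present.
#' @return Data.frame with one row per scored pocket: `method`,
#'   `pocket_id`, `p_a`, `op_c`, `ep_c`, `ratio`, `poisson_p`,
#'   `descriptor`.
#' @export
score_pockets <- function(pockets, cmap, s,
                          pvalue_mode = c("pmf", "upper_tail"),
                          selected_only = "selected" %in% names(pockets)) {
  pvalue_mode <- match.arg(pvalue_mode)
  stopifnot(inherits(cmap, "pc_conservation_map"), inherits(s, "pc_structure"))
  if (isTRUE(selected_only) && "selected" %in% names(pockets))
    pockets <- pockets[pockets$selected, , drop = FALSE]
  if (!nrow(pockets)) stop("no pockets to score")
  conserved <- unique(unname(cmap$conserved_residues))
  t_a <- cmap$t_a
  p_a <- integer(nrow(pockets)); op_c <- integer(nrow(pockets))
  for (i in seq_len(nrow(pockets))) {
    lining <- unique(pockets$lining_residues[[i]])
    p_a[i] <- pocket_atom_count(lining, s)
    op_c[i] <- count_atoms(s, residues = intersect(lining, conserved))
  }
  ep_c <- vapply(p_a, function(p) expected_conservation(cmap$tc_a, p, t_a), 0)
  ratio <- ifelse(ep_c > 0, op_c / ep_c, NA_real_)
  pois <- ifelse(ep_c > 0, poisson_pvalue(op_c, pmax(ep_c, .Machine$double.xmin),
                                          mode = pvalue_mode), NA_real_)
  lam <- mean(ratio[is.finite(ratio) & ratio > 0])
  desc <- rep(NA_real_, length(ratio))
  ok <- is.finite(ratio) & ratio > 0 & is.finite(lam) & lam > 0
  if (any(ok)) desc[ok] <- poisson_descriptor(ratio[ok], lam)
  out <- data.frame(method = pockets$method, pocket_id = pockets$pocket_id,
                    p_a = p_a, op_c = op_c, ep_c = ep_c, ratio = ratio,
                    poisson_p = pois, descriptor = desc,
                    stringsAsFactors = FALSE)
  attr(out, "lambda") <- lam
  out
}

#' Nominate the binding pocket
#'
#' Selects the pocket with the highest enrichment ratio OP_c/EP_c; ties are
#' broken by lowest Poisson p-value, then largest P_a, then lexicographic
#' `pocket_id`. The full table, ordered by that ranking with a `selected`
#' flag on the winner, is attached as attribute `"ranked"`.
#'
#' @param scores Data.frame from [score_pockets()].
#' @return The winning row (single-row data.frame) with attribute
#'   `"ranked"` carrying the ordered table.
#' @export
select_binding_pocket <- function(scores) {
  stopifnot(is.data.frame(scores), nrow(scores) >= 1)
  if (all(!is.finite(scores$ep_c) | scores$ep_c == 0))
    stop("no conservation signal: EP_c is zero for every pocket ",
         "(reference domain shares nothing with the target)")
  ratio <- ifelse(is.finite(scores$ratio), scores$ratio, -Inf)
  pval <- ifelse(is.finite(scores$poisson_p), scores$poisson_p, Inf)
  ord <- order(-ratio, pval, -scores$p_a, scores$pocket_id)
  ranked <- scores[ord, , drop = FALSE]
  rownames(ranked) <- NULL
  ranked$selected <- c(TRUE, rep(FALSE, nrow(ranked) - 1L))
  winner <- ranked[1, , drop = FALSE]
  attr(winner, "ranked") <- ranked
  winner
}
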