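# ---------------------------------------------------------------------------
# Pocket-detector ingestion and Metapocket-style z-score consensus ranking.
#
# Different pocket detectors (alpha-shape area/volume servers, grid cavity
# scanners, solvent mapping) score pockets in incommensurable units. The
# consensus step standardizes each detector's raw scores to z-scores and
# takes the top-k pockets per detector forward.
# ---------------------------------------------------------------------------

#' Load pocket predictions from a CSV file
#'
#' Schema (one row per pocket): `method`, `pocket_id`, `raw_score`,
#' `residues`, where `residues` is a semicolon-separated list of residue
#' tokens `chain:number` (optionally `chain:number:insertion`). A missing
#' column is a schema error; an empty `raw_score` value is allowed and
#' loads as `NA` (detectors such as solvent-mapping servers emit no
#' comparable score) — such pockets are excluded from z-ranking.
#'
#' @param file Path to the CSV file.
#' @return A data.frame with columns `method`, `pocket_id`, `raw_score`
#'   and list-column `lining_residues`.
#' @export
load_pocket_predictions <- function(file) {
  df <- read.csv(file, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("method", "pocket_id", "raw_score", "residues")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("pocket schema error: missing column(s) ", paste(miss, collapse = ", "))
  if (!nrow(df)) stop("pocket schema error: no records in ", file)
  for (col in c("method", "pocket_id", "residues")) {
    empty <- which(is.na(df[[col]]) | df[[col]] == "")
    if (length(empty))
      stop("pocket schema error: record ", empty[1], " lacks field '", col, "'")
  }
  key <- paste(df$method, df$pocket_id, sep = "/")
  if (anyDuplicated(key))
    stop("duplicate (method, pocket_id): ", key[duplicated(key)][1])
  raw <- suppressWarnings(as.numeric(df$raw_score))
  bad <- which(!is.na(df$raw_score) & df$raw_score != "" & is.na(raw))
  if (length(bad))
    stop("pocket schema error: record ", bad[1], " has non-numeric raw_score")
  if (any(is.infinite(raw))) stop("pocket schema error: non-finite raw_score")
  out <- data.frame(method = df$method, pocket_id = df$pocket_id,
                    raw_score = raw, stringsAsFactors = FALSE)
  out$lining_residues <- lapply(df$residues, parse_residue_tokens)
  n_res <- vapply(out$lining_residues, length, 1L)
  if (any(n_res == 0L))
    stop("pocket schema error: record ", which(n_res == 0L)[1], " has no lining residues")
  out
}

# "A:169" -> "A:169"; validates chain:number[:insertion]
parse_residue_tokens <- function(x) {
  toks <- trimws(strsplit(x, ";")[[1]])
  toks <- toks[toks != ""]
  ok <- grepl("^[A-Za-z0-9 ]:-?[0-9]+(:[A-Za-z])?$", toks)
  if (any(!ok)) stop("malformed residue token: '", toks[!ok][1], "'")
  toks
}

#' Rank pocket predictions by within-method z-score
#'
#' Standardizes each detector's raw scores separately — z = (raw - mean) /
#' sd with the sample (n-1) standard deviation — ranks by descending
#' z-score within the method and flags the top `k` as selected. Because the
#' transform is within-method and affine-invariant, selection depends only
#' on each detector's internal ordering, never on its units. Pockets with
#' `NA` raw score are dropped (with a message). A detector with a single
#' pocket gets z = 0 and rank 1; zero-variance scores get all z = 0 with a
#' warning and are ordered by the tie-break.
#'
#' Ties in z are broken by larger lining-residue count, then lexicographic
#' `pocket_id`.
#'
#' @param predictions Data.frame from [load_pocket_predictions()] (columns
#'   `method`, `pocket_id`, `raw_score`, list-column `lining_residues`).
#' @param k Number of pockets to select per method (default 3).
#' @return The input rows plus `zscore`, `rank_in_method` and `selected`,
#'   ordered by method then rank.
#' @export
zscore_rank <- function(predictions, k = 3) {
  stopifnot(is.data.frame(predictions), k >= 1)
  pred <- predictions
  if (anyNA(pred$raw_score)) {
    drop <- is.na(pred$raw_score)
    message(sum(drop), " pocket(s) without a raw score excluded from z-ranking (",
            paste(unique(pred$method[drop]), collapse = ", "), ")")
    pred <- pred[!drop, , drop = FALSE]
  }
  if (!nrow(pred)) stop("no scored pockets to rank")
  out <- lapply(split(pred, pred$method), function(g) {
    n <- nrow(g)
    if (n == 1L) {
      g$zscore <- 0
    } else {
      s <- sd(g$raw_score)
      if (!is.finite(s) || s == 0) {
        warning("zero-variance raw scores for method '", g$method[1],
                "'; all z-scores set to 0")
        g$zscore <- rep(0, n)
      } else {
        g$zscore <- (g$raw_score - mean(g$raw_score)) / s
      }
    }
    nres <- vapply(g$lining_residues, length, 1L)
    ord <- order(-g$zscore, -nres, g$pocket_id)
    g <- g[ord, , drop = FALSE]
    g$rank_in_method <- seq_len(n)
    g$selected <- g$rank_in_method <= k
    g
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Write a ranked pocket table as CSV
#'
#' @param ranked Data.frame from [zscore_rank()].
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_ranked_pockets <- function(ranked, file) {
  flat <- ranked
  flat$residues <- vapply(flat$lining_residues, paste, "", collapse = ";")
  flat$lining_residues <- NULL
  write.csv(flat, file, row.names = FALSE, quote = TRUE)
  invisible(file)
}
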