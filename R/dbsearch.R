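#' Candidate set for one database-search query
#'
#' @param query_id query compound id.
#' @param fingerprints 0/1 matrix: one row per candidate structure,
#'   rownames = candidate structure keys (unique), columns aligned to the
#'   model's labels.
#' @param molecular_formula optional formula string (candidates are usually
#'   retrieved by formula).
#' @param correct_key structure key of the true structure, if known.
#' @return object of class `candidate_set`.
#' @export
candidate_set <- function(query_id, fingerprints, molecular_formula = NULL,
                          correct_key = NULL) {
  fingerprints <- as.matrix(fingerprints)
  if (is.null(rownames(fingerprints)))
    stop("candidate fingerprints need rownames (structure keys)")
  if (anyDuplicated(rownames(fingerprints)))
    stop("duplicate candidate structure keys")
  if (!all(fingerprints %in% c(0, 1)))
    stop("candidate fingerprints must be 0/1")
  structure(list(query_id = query_id, fingerprints = fingerprints,
                 molecular_formula = molecular_formula,
                 correct_key = correct_key),
            class = "candidate_set")
}

#' Per-label log-likelihood score of a candidate fingerprint
#'
#' Treats the predicted probabilities as independent per-label Bernoulli
#' parameters and scores a candidate by its log-likelihood
#' `sum_i f_i log p_i + (1 - f_i) log(1 - p_i)` — a diagonal (independence)
#' approximation of covariance-aware scoring. Probabilities must be
#' clamped away from \{0, 1\} (see [predict_probabilities()]).
#'
#' @param probs per-label predicted probabilities.
#' @param candidate_fp binary candidate fingerprint of the same length.
#' @return log-likelihood (<= 0).
#' @export
loglikelihood_score <- function(probs, candidate_fp) {
  p <- as.numeric(probs); f <- as.numeric(candidate_fp)
  if (length(p) != length(f))
    stop("probability / fingerprint length mismatch: ", length(p), " vs ",
         length(f))
  sum(f * log(p) + (1 - f) * log(1 - p))
}

#' Probabilistic Tanimoto score of a candidate fingerprint
#'
#' Expected intersection over expected union under independent Bernoulli
#' labels: `sum(p*f) / sum(p + f - p*f)`. Uses the full probability vector
#' rather than a 0.5-thresholded one; see [tanimoto_compound()] for the
#' thresholded variant.
#'
#' @param probs per-label predicted probabilities.
#' @param candidate_fp binary candidate fingerprint.
#' @return score in `[0, 1]`.
#' @export
tanimoto_score <- function(probs, candidate_fp) {
  p <- as.numeric(probs); f <- as.numeric(candidate_fp)
  if (length(p) != length(f))
    stop("probability / fingerprint length mismatch")
  union <- sum(p + f - p * f)
  if (union == 0) {
    warning("all-zero candidate against near-zero probabilities; score 0")
    return(0)
  }
  sum(p * f) / union
}

#' Rank candidate structures for a query
#'
#' Scores every candidate fingerprint against the predicted probability
#' vector and sorts descending. The rank of the correct structure uses
#' pessimistic tie handling: every candidate scoring greater than *or equal
#' to* the correct one (other than itself) ranks ahead of it, so tied
#' scores never flatter the identification rate.
#'
#' @param cs a [candidate_set()].
#' @param probs per-label predicted probabilities for the query.
#' @param scoring `"loglik"` (default) or `"tanimoto"`; alternatively a
#'   function `(probs, candidate_fp) -> score` for external scorings.
#' @return object of class `ranked_result`: data.frame `ranking`
#'   (structure_key, score, descending), `rank_of_correct` (NA when the
#'   correct key is unknown or absent) and `query_id`.
#' @export
rank_candidates <- function(cs, probs, scoring = c("loglik", "tanimoto")) {
  stopifnot(inherits(cs, "candidate_set"))
  if (nrow(cs$fingerprints) == 0) stop("empty candidate set")
  score_fun <- if (is.function(scoring)) scoring
  else switch(match.arg(scoring),
              loglik = loglikelihood_score,
              tanimoto = tanimoto_score)
  scores <- apply(cs$fingerprints, 1, function(f) score_fun(probs, f))
  ord <- order(-scores)
  rank_of_correct <- NA_integer_
  if (!is.null(cs$correct_key) &&
      cs$correct_key %in% rownames(cs$fingerprints)) {
    sc <- scores[[cs$correct_key]]
    rank_of_correct <- 1L +
      sum(scores > sc) + sum(scores == sc & names(scores) != cs$correct_key)
  }
  structure(list(query_id = cs$query_id,
                 ranking = data.frame(structure_key = names(scores)[ord],
                                      score = unname(scores[ord]),
                                      row.names = NULL),
                 rank_of_correct = rank_of_correct),
            class = "ranked_result")
}

#' @export
print.ranked_result <- function(x, ...) {
  cat(sprintf("<ranked_result %s> %d candidates, correct at rank %s\n",
              x$query_id, nrow(x$ranking),
              if (is.na(x$rank_of_correct)) "?" else x$rank_of_correct))
  invisible(x)
}

#' Identification rate at k
#'
#' Fraction of queries whose correct structure ranks within the top `k`;
#' queries with unknown/absent correct rank count as misses.
#'
#' @param results list of [rank_candidates()] results.
#' @param k cutoff rank (>= 1).
#' @return fraction in `[0, 1]`.
#' @export
identification_rate <- function(results, k = 1L) {
  if (k < 1) stop("k must be >= 1")
  ranks <- vapply(results, `[[`, numeric(1), "rank_of_correct")
  sum(!is.na(ranks) & ranks <= k) / length(ranks)
}

#' Read / write candidate sets as TSV
#'
#' One file per query: columns `structure_key` and `fingerprint` (a 0/1
#' bitstring). The correct key, when known, is marked with a `correct`
#' column holding 1.
#'
#' @param path file path.
#' @param query_id id for the loaded set (default: file base name).
#' @return [candidate_set()] for the reader; `path` invisibly for the
#'   writer.
#' @export
read_candidates_tsv <- function(path, query_id = NULL) {
  df <- utils::read.delim(path, colClasses = "character")
  fps <- do.call(rbind, lapply(strsplit(df$fingerprint, ""), as.integer))
  rownames(fps) <- df$structure_key
  correct <- if ("correct" %in% names(df) && any(df$correct == "1"))
    df$structure_key[df$correct == "1"][1]
  candidate_set(query_id %||% sub("\\.tsv$", "", basename(path)),
                fps, correct_key = correct)
}

#' @rdname read_candidates_tsv
#' @param cs a [candidate_set()] to serialize.
#' @export
write_candidates_tsv <- function(cs, path) {
  df <- data.frame(
    structure_key = rownames(cs$fingerprints),
    fingerprint = apply(cs$fingerprints, 1, paste, collapse = ""),
    correct = as.integer(rownames(cs$fingerprints) %in% cs$correct_key))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
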