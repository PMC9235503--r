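#' Confusion counts for one binary label
#'
#' @param pred logical or 0/1 vector of predictions.
#' @param truth logical or 0/1 vector of ground truth, same length.
#' @return object of class `confusion_counts` with fields `tp`, `fp`, `fn`,
#'   `tn`.
#' @export
confusion_counts <- function(pred, truth) {
  pred <- as.logical(pred); truth <- as.logical(truth)
  if (length(pred) != length(truth))
    stop("pred and truth length mismatch: ", length(pred), " vs ",
         length(truth))
  structure(list(tp = sum(pred & truth), fp = sum(pred & !truth),
                 fn = sum(!pred & truth), tn = sum(!pred & !truth)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion> tp=%d fp=%d fn=%d tn=%d\n", x$tp, x$fp, x$fn, x$tn))
  invisible(x)
}

add_counts <- function(a, b) {
  structure(list(tp = a$tp + b$tp, fp = a$fp + b$fp,
                 fn = a$fn + b$fn, tn = a$tn + b$tn),
            class = "confusion_counts")
}

#' Matthews correlation coefficient (Yule's phi)
#'
#' `(tp*tn - fp*fn) / sqrt((tp+fp)(tp+fn)(tn+fp)(tn+fn))`; zero for a
#' random classifier. When any marginal is empty the value is undefined and
#' `NA` is returned — undefined values are a value state, not an error, and
#' are excluded from means downstream.
#'
#' @param c a [confusion_counts()].
#' @return value in `[-1, 1]`, or `NA` when undefined.
#' @export
mcc <- function(c) {
  den <- prod(sqrt(c(c$tp + c$fp, c$tp + c$fn, c$tn + c$fp, c$tn + c$fn)))
  if (den == 0) return(NA_real_)
  (c$tp * c$tn - c$fp * c$fn) / den
}

#' Bookmaker informedness (Youden's J)
#'
#' Sensitivity + specificity - 1; undefined (`NA`) when either class is
#' absent. Behaves well under heavy class imbalance.
#'
#' @param c a [confusion_counts()].
#' @return value in `[-1, 1]`, or `NA` when undefined.
#' @export
bm <- function(c) {
  pos <- c$tp + c$fn; neg <- c$tn + c$fp
  if (pos == 0 || neg == 0) return(NA_real_)
  c$tp / pos + c$tn / neg - 1
}

#' Pool rare labels for micro averaging
#'
#' Labels with fewer than `min_positives` positive examples in the
#' evaluation ground truth give noisy or undefined per-label metrics; their
#' confusion counts are summed into a single pooled pseudo-label and one
#' metric is computed for the pool (micro averaging). Remaining labels are
#' reported individually.
#'
#' @param per_label_counts named list of [confusion_counts()], one per
#'   label.
#' @param min_positives pooling threshold on `tp + fn` (default 10).
#' @return list with `pooled` (a `confusion_counts`, or NULL when no label
#'   is rare), `pooled_labels`, and `retained` (the non-pooled sublist).
#' @export
micro_average_pool <- function(per_label_counts, min_positives = 10L) {
  stopifnot(min_positives >= 0)
  positives <- vapply(per_label_counts, function(c) c$tp + c$fn, numeric(1))
  rare <- positives < min_positives
  pooled <- NULL
  if (any(rare))
    pooled <- Reduce(add_counts, per_label_counts[rare])
  list(pooled = pooled,
       pooled_labels = names(per_label_counts)[rare],
       retained = per_label_counts[!rare])
}

#' Tanimoto (Jaccard) index between two binary fingerprints
#'
#' A per-compound metric: intersection over union of the positive
#' positions. Two all-zero vectors compare as identical empty sets (1.0,
#' with a warning — no real fingerprint is all-zero).
#'
#' @param pred_binary,truth_binary logical or 0/1 vectors of equal length.
#' @return value in `[0, 1]`.
#' @export
tanimoto_compound <- function(pred_binary, truth_binary) {
  p <- as.logical(pred_binary); t <- as.logical(truth_binary)
  if (length(p) != length(t)) stop("fingerprint length mismatch")
  u <- sum(p | t)
  if (u == 0) {
    warning("both fingerprints all-zero; Tanimoto defined as 1")
    return(1)
  }
  sum(p & t) / u
}

#' Structure-disjoint k-fold assignment
#'
#' Data from the same 2D structure must never be split across training and
#' evaluation: folds are assigned to *structures* (shuffled, then dealt
#' round-robin so fold sizes differ by at most one), and every compound of
#' a structure inherits its fold.
#'
#' @param structure_keys character vector (one entry per compound;
#'   duplicates allowed).
#' @param k number of folds (>= 2).
#' @param seed integer seed.
#' @return named integer vector structure_key -> fold index in `0:(k-1)`,
#'   over the distinct structures.
#' @export
structure_disjoint_folds <- function(structure_keys, k = 5L, seed = 1L) {
  stopifnot(k >= 2)
  structs <- unique(structure_keys)
  if (length(structs) < k)
    stop("need at least k = ", k, " distinct structures, got ",
         length(structs))
  withr::with_seed(seed, {
    shuffled <- sample(structs)
  })
  stats::setNames(rep_len(seq_len(k) - 1L, length(shuffled)), shuffled)
}

#' Evaluate a probability matrix against ground truth
#'
#' Binarizes predictions at `threshold` (default 0.5), computes per-label
#' confusion counts, MCC and BM with micro averaging of rare labels, and
#' the per-compound Tanimoto. Undefined MCC/BM values are excluded from the
#' means and reported as counts.
#'
#' @param probs n x L probability matrix.
#' @param truth [fingerprint_matrix()] or 0/1 matrix aligned with `probs`.
#' @param threshold binarization threshold.
#' @param min_positives micro-averaging pooling threshold.
#' @return list with `mean_mcc`, `mean_bm`, `mean_tanimoto`,
#'   `n_undefined_mcc`, `n_undefined_bm`, a `per_label` data.frame
#'   (label, tp, fp, fn, tn, mcc, bm, positives, pooled flag) and
#'   `per_compound_tanimoto`.
#' @export
evaluate_predictions <- function(probs, truth, threshold = 0.5,
                                 min_positives = 10L) {
  Ym <- as_label_matrix(truth)
  stopifnot(all(dim(probs) == dim(Ym)))
  pred <- probs >= threshold
  labels <- colnames(Ym)
  if (is.null(labels)) labels <- sprintf("L%05d", seq_len(ncol(Ym)))
  counts <- lapply(seq_len(ncol(Ym)),
                   function(l) confusion_counts(pred[, l], Ym[, l]))
  names(counts) <- labels
  pool <- micro_average_pool(counts, min_positives)
  eval_set <- pool$retained
  if (!is.null(pool$pooled)) eval_set <- c(eval_set, list(pooled = pool$pooled))
  mccs <- vapply(eval_set, mcc, numeric(1))
  bms <- vapply(eval_set, bm, numeric(1))
  tani <- vapply(seq_len(nrow(Ym)), function(i)
    suppressWarnings(tanimoto_compound(pred[i, ], Ym[i, ])), numeric(1))
  per_label <- data.frame(
    label = names(counts),
    tp = vapply(counts, `[[`, numeric(1), "tp"),
    fp = vapply(counts, `[[`, numeric(1), "fp"),
    fn = vapply(counts, `[[`, numeric(1), "fn"),
    tn = vapply(counts, `[[`, numeric(1), "tn"),
    mcc = vapply(counts, mcc, numeric(1)),
    bm = vapply(counts, bm, numeric(1)),
    positives = vapply(counts, function(c) c$tp + c$fn, numeric(1)),
    pooled = names(counts) %in% pool$pooled_labels,
    row.names = NULL)
  list(mean_mcc = mean(mccs, na.rm = TRUE),
       mean_bm = mean(bms, na.rm = TRUE),
       mean_tanimoto = mean(tani),
       n_undefined_mcc = sum(is.na(mccs)),
       n_undefined_bm = sum(is.na(bms)),
       per_label = per_label,
       per_compound_tanimoto = tani)
}

#' Write an evaluation report
#'
#' Per-label TSV plus a JSON summary of the mean metrics.
#'
#' @param ev an [evaluate_predictions()] result.
#' @param tsv_path,json_path output paths (NULL skips either).
#' @return `ev` invisibly.
#' @export
write_metric_report <- function(ev, tsv_path = NULL, json_path = NULL) {
  if (!is.null(tsv_path))
    utils::write.table(ev$per_label, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(
      list(mean_mcc = ev$mean_mcc, mean_bm = ev$mean_bm,
           mean_tanimoto = ev$mean_tanimoto,
           n_undefined_mcc = ev$n_undefined_mcc,
           n_undefined_bm = ev$n_undefined_bm),
      json_path, auto_unbox = TRUE, digits = NA)
  invisible(ev)
}
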