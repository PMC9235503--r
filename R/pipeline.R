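#' Run the kernel pipeline on a benchmark
#'
#' Convenience wrapper over the full chain: probability product kernel on
#' the training ("landmark") compounds, cosine normalization, Nystroem
#' projection, embedding of train and evaluation compounds, head training
#' and evaluation. The landmark set is the full training compound list.
#'
#' @param train_records,eval_records lists of `compound_record`s.
#' @param fingerprints [fingerprint_matrix()] covering all structures.
#' @param head `"nystrom_svm"` or `"deep_kernel"`.
#' @param cfg a [train_config()].
#' @param sigma_m probability-product-kernel mass bandwidth (Da).
#' @param eig_floor relative eigenvalue floor for [fit_projection()].
#' @param min_label_count training-label selection threshold; labels with
#'   fewer positive training structures are dropped (default 1 keeps all
#'   learnable labels at desk scale).
#' @return list with `model`, `projection`, `probs` (eval probabilities),
#'   `evaluation` ([evaluate_predictions()] output on the evaluation set),
#'   `labels` (retained label ids) and the two embeddings.
#' @export
run_kernel_pipeline <- function(train_records, eval_records, fingerprints,
                                head = c("nystrom_svm", "deep_kernel"),
                                cfg = train_config(), sigma_m = 0.01,
                                eig_floor = 1e-10, min_label_count = 1L) {
  head <- match.arg(head)
  train_keys <- vapply(train_records, `[[`, character(1), "structure_key")
  fp_train <- fingerprint_matrix(
    fingerprints$values[intersect(fingerprints$structures, train_keys), ,
                        drop = FALSE])
  fp_sel <- select_labels(fp_train, min_label_count)
  # the 0/1 degenerate columns are constant-flagged by the SVM head and
  # carry ~no gradient for the DNN head; select_labels removes all-zero ones
  K_AA <- normalize_kernel(compute_kernel(train_records,
                                          spec = kernel_spec("ppk",
                                            params = list(sigma_m = sigma_m))))
  proj <- fit_projection(K_AA, eig_floor)
  X_train <- nystrom_embed(K_AA, proj)
  diag_tr <- vapply(train_records, function(r) ppk(r$spectrum, r$spectrum,
                                                   sigma_m), numeric(1))
  diag_ev <- vapply(eval_records, function(r) ppk(r$spectrum, r$spectrum,
                                                  sigma_m), numeric(1))
  K_ev <- compute_kernel(eval_records, train_records,
                         spec = kernel_spec("ppk",
                                            params = list(sigma_m = sigma_m)))
  K_ev <- normalize_kernel(K_ev, diag_row = diag_ev, diag_col = diag_tr)
  X_eval <- nystrom_embed(K_ev, proj)
  Y_train <- labels_for_records(fp_sel, train_records)
  weights <- vapply(train_records, `[[`, numeric(1), "sample_weight")
  model <- switch(head,
    nystrom_svm = train_nystrom_svm(X_train, Y_train, weights, cfg),
    deep_kernel = train_deep_kernel(X_train, Y_train, weights, cfg))
  probs <- predict_probabilities(model, X_eval)
  eval_keys <- vapply(eval_records, `[[`, character(1), "structure_key")
  Y_eval <- fingerprints$values[eval_keys, fp_sel$labels, drop = FALSE]
  ev <- evaluate_predictions(probs, Y_eval)
  list(model = model, projection = proj, probs = probs, evaluation = ev,
       labels = fp_sel$labels, X_train = X_train, X_eval = X_eval,
       K_AA = K_AA, eval_keys = eval_keys)
}

#' Rank benchmark candidate sets from predicted probabilities
#'
#' @param pipeline a [run_kernel_pipeline()] result.
#' @param candidates list of [candidate_set()] objects (query_id must match
#'   an evaluation structure key).
#' @param scoring passed to [rank_candidates()].
#' @return list of `ranked_result`s, one per candidate set.
#' @export
rank_benchmark_candidates <- function(pipeline, candidates,
                                      scoring = "loglik") {
  lapply(candidates, function(cs) {
    i <- match(cs$query_id, pipeline$eval_keys)
    if (is.na(i)) stop("no prediction for query ", cs$query_id)
    fps <- cs$fingerprints
    lab_idx <- match(pipeline$labels, colnames(fps))
    if (anyNA(lab_idx))
      stop("candidate fingerprints do not cover the model labels for ",
           cs$query_id)
    cs$fingerprints <- fps[, lab_idx, drop = FALSE]
    rank_candidates(cs, pipeline$probs[i, ], scoring)
  })
}
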