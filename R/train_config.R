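#' Training configuration
#'
#' Shared hyperparameter container for the three predictor heads. Defaults
#' are the production settings of the deep kernel head: hidden layers of
#' 2500 and 8000 rectified-linear units, 50% dropout, l2 regularization on
#' the output layer with lambda = 1e-7, Adam with learning rate 1e-3,
#' minibatches of 200 and 25 epochs. The SVM head ignores `hidden_sizes`
#' and `dropout_rate` and uses plain minibatch SGD with `svm_C` as the
#' hinge-loss regularization parameter.
#'
#' @param hidden_sizes integer vector of hidden-layer widths (DNN heads).
#' @param dropout_rate dropout probability on hidden activations, in \[0,1).
#' @param l2_output l2 penalty weight (lambda) on the output layer.
#' @param learning_rate positive step size.
#' @param batch_size minibatch size (>= 1).
#' @param epochs number of passes over the training data (>= 0).
#' @param seed integer seed; training is deterministic given it.
#' @param loss `"sigmoid_cross_entropy"` (DNN heads) or `"hinge"` (SVM).
#' @param svm_C positive SVM regularization parameter; may be a per-label
#'   vector (see [tune_svm_C()]).
#' @return object of class `train_config`.
#' @export
train_config <- function(hidden_sizes = c(2500L, 8000L), dropout_rate = 0.5,
                         l2_output = 1e-7, learning_rate = 1e-3,
                         batch_size = 200L, epochs = 25L, seed = 1L,
                         loss = c("sigmoid_cross_entropy", "hinge"),
                         svm_C = 1) {
  loss <- match.arg(loss)
  stopifnot(dropout_rate >= 0, dropout_rate < 1, l2_output >= 0,
            learning_rate > 0, batch_size >= 1, epochs >= 0,
            all(svm_C > 0))
  structure(list(hidden_sizes = as.integer(hidden_sizes),
                 dropout_rate = dropout_rate, l2_output = l2_output,
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 loss = loss, svm_C = svm_C),
            class = "train_config")
}

as_feature_matrix <- function(X) {
  if (inherits(X, "nystrom_embedding")) return(X$features)
  as.matrix(X)
}

as_label_matrix <- function(Y) {
  Y <- if (inherits(Y, "fingerprint_matrix")) Y$values else as.matrix(Y)
  if (is.null(colnames(Y))) colnames(Y) <- sprintf("L%05d", seq_len(ncol(Y)))
  Y
}

#' Align fingerprint rows to a list of compound records
#'
#' @param fp a [fingerprint_matrix()].
#' @param records list of `compound_record`s (or character structure keys).
#' @return 0/1 matrix with one row per record, in record order.
#' @export
labels_for_records <- function(fp, records) {
  keys <- if (is.character(records)) records else
    vapply(records, `[[`, character(1), "structure_key")
  missing_keys <- setdiff(keys, fp$structures)
  if (length(missing_keys))
    stop("structures missing from fingerprint matrix: ",
         paste(utils::head(missing_keys, 5), collapse = ", "))
  fp$values[keys, , drop = FALSE]
}
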