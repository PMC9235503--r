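## Multilayer perceptron with ReLU hidden layers and sigmoid outputs,
## trained by minibatch Adam on sigmoid cross-entropy. Written against base
## matrix ops so training is bit-reproducible from the R RNG seed.

mlp_init <- function(layer_dims) {
  nl <- length(layer_dims) - 1L
  W <- vector("list", nl); b <- vector("list", nl)
  for (k in seq_len(nl)) {
    din <- layer_dims[k]; dout <- layer_dims[k + 1L]
    if (k < nl) {
      s <- sqrt(6 / din)                    # scaled-uniform fan-in
      W[[k]] <- matrix(stats::runif(din * dout, -s, s), din, dout)
    } else {
      W[[k]] <- matrix(0, din, dout)        # zero output layer: p0 = 0.5
    }
    b[[k]] <- numeric(dout)
  }
  list(W = W, b = b)
}

mlp_forward <- function(par, X, dropout_rate = 0, train = FALSE) {
  nl <- length(par$W)
  A <- X
  cache <- list(A0 = X, Z = vector("list", nl), A = vector("list", nl),
                mask = vector("list", nl))
  for (k in seq_len(nl)) {
    Z <- A %*% par$W[[k]] + rep(par$b[[k]], each = nrow(A))
    if (k < nl) {
      A <- pmax(Z, 0)
      if (train && dropout_rate > 0) {
        m <- matrix(stats::runif(length(A)) >= dropout_rate,
                    nrow(A), ncol(A))
        A <- A * m / (1 - dropout_rate)     # inverted dropout
        cache$mask[[k]] <- m
      }
    } else {
      A <- 1 / (1 + exp(-Z))
    }
    cache$Z[[k]] <- Z; cache$A[[k]] <- A
  }
  cache
}

# mean over batch of per-sample weighted sigmoid cross-entropy, plus
# l2_output * ||W_out||^2
mlp_loss <- function(par, X, Y, w, l2_output, eps = 1e-12) {
  P <- mlp_forward(par, X)$A[[length(par$W)]]
  ce <- -rowSums(Y * log(P + eps) + (1 - Y) * log(1 - P + eps))
  mean(w * ce) + l2_output * sum(par$W[[length(par$W)]]^2)
}

mlp_grad <- function(par, X, Y, w, dropout_rate, l2_output, train = TRUE) {
  nl <- length(par$W)
  cache <- mlp_forward(par, X, dropout_rate, train = train)
  n <- nrow(X)
  P <- cache$A[[nl]]
  delta <- (P - Y) * (w / n)                 # dL/dZ_out for mean weighted CE
  gW <- vector("list", nl); gb <- vector("list", nl)
  for (k in nl:1) {
    Aprev <- if (k == 1L) cache$A0 else cache$A[[k - 1L]]
    gW[[k]] <- crossprod(Aprev, delta)
    if (k == nl) gW[[k]] <- gW[[k]] + 2 * l2_output * par$W[[k]]
    gb[[k]] <- colSums(delta)
    if (k > 1L) {
      delta <- delta %*% t(par$W[[k]])
      if (train && dropout_rate > 0 && !is.null(cache$mask[[k - 1L]]))
        delta <- delta * cache$mask[[k - 1L]] / (1 - dropout_rate)
      delta <- delta * (cache$Z[[k - 1L]] > 0)
    }
  }
  list(gW = gW, gb = gb)
}

adam_state <- function(par) {
  zero_like <- function(p) lapply(p, function(x) x * 0)
  list(mW = zero_like(par$W), vW = zero_like(par$W),
       mb = zero_like(par$b), vb = zero_like(par$b), t = 0L)
}

adam_update <- function(par, grad, st, lr, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-8) {
  st$t <- st$t + 1L
  c1 <- 1 - beta1^st$t; c2 <- 1 - beta2^st$t
  for (k in seq_along(par$W)) {
    st$mW[[k]] <- beta1 * st$mW[[k]] + (1 - beta1) * grad$gW[[k]]
    st$vW[[k]] <- beta2 * st$vW[[k]] + (1 - beta2) * grad$gW[[k]]^2
    par$W[[k]] <- par$W[[k]] -
      lr * (st$mW[[k]] / c1) / (sqrt(st$vW[[k]] / c2) + eps)
    st$mb[[k]] <- beta1 * st$mb[[k]] + (1 - beta1) * grad$gb[[k]]
    st$vb[[k]] <- beta2 * st$vb[[k]] + (1 - beta2) * grad$gb[[k]]^2
    par$b[[k]] <- par$b[[k]] -
      lr * (st$mb[[k]] / c1) / (sqrt(st$vb[[k]] / c2) + eps)
  }
  list(par = par, st = st)
}

train_mlp <- function(X, Ym, weights, cfg, kind) {
  n <- nrow(X); d <- ncol(X); L <- ncol(Ym)
  stopifnot(nrow(Ym) == n)
  if (is.null(weights)) weights <- rep(1, n)
  stopifnot(length(weights) == n, all(weights > 0))
  hidden <- cfg$hidden_sizes
  if (!length(hidden))
    warning("empty hidden_sizes: model degenerates to a linear classifier")
  dims <- c(d, hidden, L)
  withr::with_seed(cfg$seed, {
    par <- mlp_init(dims)
    st <- adam_state(par)
    for (ep in seq_len(cfg$epochs)) {
      idx <- sample.int(n)
      for (start in seq(1, n, by = cfg$batch_size)) {
        bi <- idx[start:min(start + cfg$batch_size - 1L, n)]
        g <- mlp_grad(par, X[bi, , drop = FALSE], Ym[bi, , drop = FALSE],
                      weights[bi], cfg$dropout_rate, cfg$l2_output)
        upd <- adam_update(par, g, st, cfg$learning_rate)
        par <- upd$par; st <- upd$st
      }
    }
    par
  }) -> par
  structure(list(kind = kind, par = par, layer_dims = dims,
                 label_ids = colnames(Ym), platt_params = NULL,
                 constant_prob = rep(NA_real_, L), cfg = cfg),
            class = "predictor_model")
}

#' Train the deep kernel head
#'
#' A deep neural network on the Nystroem feature embedding: the kernel
#' framework supplies the representation, the network learns non-linear,
#' label-coupled decision boundaries on top of it. Architecture and
#' defaults: two rectified-linear hidden layers (2500 and 8000 units), 50%
#' dropout, sigmoid outputs (one per label) trained with sigmoid
#' cross-entropy, l2 regularization on the output layer (lambda = 1e-7),
#' Adam with learning rate 1e-3, minibatch 200, 25 epochs. Training is
#' deterministic given `cfg$seed`; dropout is disabled at inference.
#'
#' @param X [nystrom_embed()] result or numeric feature matrix.
#' @param Y [fingerprint_matrix()] or 0/1 matrix, rows aligned to `X`.
#' @param weights per-compound sample weights.
#' @param cfg a [train_config()].
#' @return `predictor_model` of kind `"deep_kernel"`.
#' @export
train_deep_kernel <- function(X, Y, weights = NULL, cfg = train_config()) {
  train_mlp(as_feature_matrix(X), as_label_matrix(Y), weights, cfg,
            kind = "deep_kernel")
}

#' Train the spectrum DNN baseline
#'
#' Same network and training contract as [train_deep_kernel()], but the
#' input is the concatenation of the binned spectrum vectors
#' ([bin_spectrum_features()]) and the normalized molecular-formula vector
#' ([formula_feature_vector()]) instead of the kernel embedding.
#'
#' @param features numeric or [Matrix::sparseMatrix] feature matrix
#'   (rows = compounds); all rows must share one dimension.
#' @param Y,weights,cfg as in [train_deep_kernel()].
#' @return `predictor_model` of kind `"spectrum_dnn"`.
#' @export
train_spectrum_dnn <- function(features, Y, weights = NULL,
                               cfg = train_config()) {
  train_mlp(as.matrix(features), as_label_matrix(Y), weights, cfg,
            kind = "spectrum_dnn")
}

#' Predict per-label probabilities
#'
#' DNN heads return their sigmoid outputs directly; the SVM head maps
#' decision values through the per-label Platt sigmoid. Single-class labels
#' return their stored constant prior. Dropout is never applied at
#' inference, so repeated calls are identical. Probabilities are clamped to
#' `[1e-4, 1 - 1e-4]` so downstream log-likelihood scoring is finite.
#'
#' @param model a `predictor_model`.
#' @param inputs embedding / feature matrix matching the model input dim.
#' @param clamp clamp bounds (set `c(0, 1)` to disable).
#' @return n x L matrix of probabilities in `[0, 1]`.
#' @export
predict_probabilities <- function(model, inputs, clamp = c(1e-4, 1 - 1e-4)) {
  stopifnot(inherits(model, "predictor_model"))
  X <- as_feature_matrix(inputs)
  if (ncol(X) != model$layer_dims[1])
    stop("input dimension ", ncol(X), " does not match model input ",
         model$layer_dims[1])
  L <- length(model$label_ids)
  if (model$kind == "nystrom_svm") {
    if (is.null(model$platt_params))
      stop("SVM model has no Platt parameters; train with ",
           "fit_platt_params = TRUE")
    dec <- decision_values(model, X)
    P <- matrix(NA_real_, nrow(X), L)
    for (l in seq_len(L)) {
      if (!is.na(model$constant_prob[l])) {
        P[, l] <- model$constant_prob[l]
      } else {
        P[, l] <- platt_probability(dec[, l], model$platt_params["A", l],
                                    model$platt_params["B", l])
      }
    }
  } else {
    P <- mlp_forward(model$par, X)$A[[length(model$par$W)]]
  }
  colnames(P) <- model$label_ids
  pmin(pmax(P, clamp[1]), clamp[2])
}

#' Count trainable parameters of a layered model
#'
#' Sum of weight-matrix entries over consecutive layer pairs, optionally
#' plus biases. The production models: deep kernel
#' `[28000, 2500, 8000, 5220]` has 131,760,000 weights; the linear
#' (Nystroem / kernel) SVM `[28000, 5220]` has 146,160,000; the spectrum
#' DNN `[102093, 2500, 8000, 5220]` has 316,992,500.
#'
#' @param layer_dims integer vector of at least 2 positive layer sizes.
#' @param include_bias add one bias per non-input unit.
#' @return integer-valued numeric count.
#' @export
count_parameters <- function(layer_dims, include_bias = FALSE) {
  dims <- as.numeric(layer_dims)
  if (length(dims) < 2) stop("need at least input and output dims")
  if (any(dims <= 0) || any(dims != round(dims)))
    stop("layer dims must be positive integers")
  n <- sum(dims[-length(dims)] * dims[-1])
  if (include_bias) n <- n + sum(dims[-1])
  n
}
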