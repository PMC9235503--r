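#' Train the Nystroem linear SVM head
#'
#' One linear SVM per fingerprint label, trained jointly by minibatch
#' stochastic gradient descent on the Nystroem feature embedding. The
#' objective per label is the weighted hinge loss plus `(1/C) ||w||^2`:
#' \deqn{\frac{1}{n}\sum_i s_i \max(0, 1 - y_i (x_i w + b)) + \frac{1}{C}\|w\|^2}
#' with per-compound sample weights `s_i`. Plain SGD with a fixed learning
#' rate; weights and biases are zero-initialized, so `epochs = 0` returns
#' the initialization. Labels with a single class in training are flagged
#' and predicted as a constant prior probability.
#'
#' @param X [nystrom_embed()] result or numeric feature matrix (n x d).
#' @param Y [fingerprint_matrix()] or 0/1 matrix with rows aligned to `X`
#'   (use [labels_for_records()] to align structures to compounds).
#' @param weights per-compound sample weights (default 1).
#' @param cfg a [train_config()]; `svm_C` may be scalar or per-label.
#' @param fit_platt_params fit per-label Platt calibration on the training
#'   decision values after training (default TRUE).
#' @return object of class `predictor_model`, kind `"nystrom_svm"`, holding
#'   the weight matrix `W` (d x L), intercepts `b`, per-label Platt
#'   parameters and per-label constant probabilities for single-class
#'   labels.
#' @export
train_nystrom_svm <- function(X, Y, weights = NULL, cfg = train_config(),
                              fit_platt_params = TRUE) {
  X <- as_feature_matrix(X); Ym <- as_label_matrix(Y)
  n <- nrow(X); d <- ncol(X); L <- ncol(Ym)
  stopifnot(nrow(Ym) == n)
  if (is.null(weights)) weights <- rep(1, n)
  stopifnot(length(weights) == n, all(weights > 0))
  Cvec <- rep_len(cfg$svm_C, L)
  Ypm <- 2 * Ym - 1                      # {0,1} -> {-1,+1}
  pos <- colSums(Ym)
  single_class <- pos == 0 | pos == n
  if (any(single_class))
    warning(sum(single_class), " label(s) with a single class trained as ",
            "constant predictors")
  W <- matrix(0, d, L); b <- numeric(L)
  lr <- cfg$learning_rate
  withr::with_seed(cfg$seed, {
    for (ep in seq_len(cfg$epochs)) {
      idx <- sample.int(n)
      for (start in seq(1, n, by = cfg$batch_size)) {
        bi <- idx[start:min(start + cfg$batch_size - 1L, n)]
        Xb <- X[bi, , drop = FALSE]
        Yb <- Ypm[bi, , drop = FALSE]
        sw <- weights[bi]
        marg <- Yb * (Xb %*% W + rep(b, each = length(bi)))
        act <- (marg < 1) * Yb * sw      # subgradient mask * label * weight
        nb <- length(bi)
        gW <- -crossprod(Xb, act) / nb +
          W * rep(2 / Cvec, each = d)
        gb <- -colSums(act) / nb
        if (any(single_class)) { gW[, single_class] <- 0; gb[single_class] <- 0 }
        W <- W - lr * gW
        b <- b - lr * gb
      }
    }
  })
  colnames(W) <- colnames(Ym)
  constant_prob <- rep(NA_real_, L)
  constant_prob[single_class] <- (pos[single_class] + 1) / (n + 2)
  platt <- NULL
  if (fit_platt_params) {
    dec <- X %*% W + rep(b, each = n)
    platt <- matrix(NA_real_, 2, L, dimnames = list(c("A", "B"), colnames(Ym)))
    for (l in which(!single_class))
      platt[, l] <- fit_platt(dec[, l], Ym[, l], weights)
  }
  structure(list(kind = "nystrom_svm", W = W, b = b,
                 layer_dims = c(d, L), label_ids = colnames(Ym),
                 platt_params = platt, constant_prob = constant_prob,
                 cfg = cfg),
            class = "predictor_model")
}

#' @export
print.predictor_model <- function(x, ...) {
  cat(sprintf("<predictor_model kind=%s> dims [%s], %d labels\n", x$kind,
              paste(x$layer_dims, collapse = ", "),
              length(x$label_ids)))
  invisible(x)
}

#' SVM decision values
#'
#' @param model a `predictor_model` of kind `"nystrom_svm"`.
#' @param X embedding or feature matrix.
#' @return n x L matrix of signed decision values.
#' @export
decision_values <- function(model, X) {
  stopifnot(model$kind == "nystrom_svm")
  X <- as_feature_matrix(X)
  X %*% model$W + rep(model$b, each = nrow(X))
}

#' Per-label C selection on an inner validation split
#'
#' Grid search bracketing C = 1; for each label the C with the highest
#' validation MCC (ties towards smaller C) is chosen.
#'
#' @param X,Y,weights as in [train_nystrom_svm()].
#' @param cfg base [train_config()].
#' @param grid candidate C values.
#' @param val_fraction fraction of rows held out for validation.
#' @return numeric vector of per-label C values.
#' @export
tune_svm_C <- function(X, Y, weights = NULL, cfg = train_config(),
                       grid = c(0.125, 0.5, 2, 8), val_fraction = 0.25) {
  X <- as_feature_matrix(X); Ym <- as_label_matrix(Y)
  n <- nrow(X)
  if (is.null(weights)) weights <- rep(1, n)
  val <- withr::with_seed(cfg$seed,
                          sample.int(n, max(1, round(val_fraction * n))))
  tr <- setdiff(seq_len(n), val)
  scores <- matrix(-Inf, length(grid), ncol(Ym))
  for (g in seq_along(grid)) {
    cfg_g <- cfg; cfg_g$svm_C <- grid[g]
    m <- train_nystrom_svm(X[tr, , drop = FALSE], Ym[tr, , drop = FALSE],
                           weights[tr], cfg_g, fit_platt_params = FALSE)
    pred <- decision_values(m, X[val, , drop = FALSE]) > 0
    for (l in seq_len(ncol(Ym))) {
      v <- mcc(confusion_counts(pred[, l], Ym[val, l]))
      scores[g, l] <- if (is.na(v)) -Inf else v
    }
  }
  grid[apply(scores, 2, which.max)]
}

#' Convert the primal Nystroem SVM to dual (kernel) form
#'
#' Multiplying the projection matrix Gamma with the learned primal weight
#' matrix gives support-vector coefficients over the landmark compounds, so
#' prediction needs only kernel rows against the landmarks — identical to a
#' classical kernel SVM. The coefficient matrix is centered per label
#' (column mean subtracted); the induced term is carried in the intercept
#' via the row sum of the kernel vector, so dual decision values equal the
#' primal ones exactly.
#'
#' @param model `predictor_model` of kind `"nystrom_svm"`.
#' @param proj the [fit_projection()] used to build the training embedding.
#' @return object of class `dual_model`: `support_coefficients` (m x L,
#'   centered), `col_means`, `b`, `landmark_ids`, Platt parameters.
#' @export
primal_to_dual <- function(model, proj) {
  if (!inherits(model, "predictor_model") || model$kind != "nystrom_svm")
    stop("primal_to_dual requires a nystrom_svm model")
  stopifnot(inherits(proj, "nystrom_projection"))
  B <- proj$gamma %*% model$W            # m x L
  mu <- colMeans(B)
  Bc <- B - rep(mu, each = nrow(B))
  structure(list(support_coefficients = Bc, col_means = mu, b = model$b,
                 landmark_ids = proj$landmark_ids,
                 label_ids = model$label_ids,
                 platt_params = model$platt_params,
                 constant_prob = model$constant_prob),
            class = "dual_model")
}

#' Dual-path decision values from kernel rows
#'
#' @param dual a [primal_to_dual()] result.
#' @param K_rows [kernel_matrix()] of test-vs-landmark kernel values,
#'   columns in landmark order.
#' @return n x L decision-value matrix, equal to the primal path within
#'   numerical tolerance.
#' @export
dual_decision_values <- function(dual, K_rows) {
  stopifnot(inherits(dual, "dual_model"), inherits(K_rows, "kernel_matrix"))
  if (!identical(K_rows$col_ids, dual$landmark_ids))
    stop("column ids of K_rows do not match landmark order")
  K <- K_rows$values
  K %*% dual$support_coefficients +
    outer(rowSums(K), dual$col_means) +
    rep(dual$b, each = nrow(K))
}

#' Platt calibration of decision values
#'
#' Fits the sigmoid `p(d) = 1 / (1 + exp(A d + B))` to binary outcomes by
#' minimizing the (sample-weighted) regularized cross-entropy with Platt's
#' smoothed targets `(N+ + 1)/(N+ + 2)` and `1/(N- + 2)`, using Newton
#' iterations with backtracking (the numerically stable formulation of Lin,
#' Lin & Weng). For a correctly oriented classifier `A < 0`, so probability
#' is increasing in the decision value.
#'
#' @param decision_values numeric vector of SVM decision values.
#' @param labels 0/1 (or logical) outcomes; both classes must be present.
#' @param weights optional non-negative sample weights.
#' @return named numeric vector `c(A, B)`.
#' @export
fit_platt <- function(decision_values, labels, weights = NULL) {
  d <- as.numeric(decision_values)
  y <- as.numeric(labels)
  stopifnot(length(d) == length(y), all(y %in% c(0, 1)))
  if (is.null(weights)) weights <- rep(1, length(d))
  Np <- sum(weights[y == 1]); Nn <- sum(weights[y == 0])
  if (Np == 0 || Nn == 0)
    stop("fit_platt requires both classes; substitute a prior for ",
         "single-class labels")
  hi <- (Np + 1) / (Np + 2); lo <- 1 / (Nn + 2)
  t <- ifelse(y == 1, hi, lo)
  A <- 0; B <- log((Nn + 1) / (Np + 1))
  obj <- function(A, B) {
    f <- A * d + B
    sum(weights * ifelse(f >= 0, t * f + log1p(exp(-f)),
                         (t - 1) * f + log1p(exp(f))))
  }
  F0 <- obj(A, B)
  for (iter in 1:100) {
    f <- A * d + B
    p <- 1 / (1 + exp(f))        # P(y=1)
    gf <- weights * (t - p)      # dF/df for F = sum w[(t-1)f + log(1+e^f)]
    g <- c(sum(gf * d), sum(gf))
    hw <- weights * p * (1 - p)
    H <- matrix(c(sum(hw * d * d), sum(hw * d), sum(hw * d), sum(hw)), 2) +
      diag(1e-12, 2)
    step <- solve(H, g)
    if (max(abs(g)) < 1e-10) break
    stepsize <- 1
    repeat {
      A1 <- A - stepsize * step[1]; B1 <- B - stepsize * step[2]
      F1 <- obj(A1, B1)
      if (F1 < F0 + 1e-4 * stepsize * sum(-g * step) || stepsize < 1e-10)
        break
      stepsize <- stepsize / 2
    }
    if (stepsize < 1e-10) break
    A <- A1; B <- B1; F0 <- F1
  }
  c(A = A, B = B)
}

platt_probability <- function(d, A, B) 1 / (1 + exp(A * d + B))
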