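# Independent oracles and tiny builders used across the suite.

toy_spectrum <- function(mz, intensity = rep(1, length(mz)),
                         precursor = max(mz) + 50, key = "TOY",
                         id = key, instrument = "qtof", adduct = "[M+H]+") {
  spectrum(mz, intensity, precursor_mz = precursor, structure_key = key,
           compound_id = id, instrument = instrument, adduct = adduct)
}

toy_record <- function(mz, ...) compound_record(toy_spectrum(mz, ...))

random_spectrum <- function(n_peaks, key, id = key, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  toy_spectrum(sort(runif(n_peaks, 50, 450)), runif(n_peaks, 0.05, 1),
               precursor = 500, key = key, id = id)
}

# random PSD matrix via X X' (+ optional jitter rank control)
random_psd <- function(n, rank = n, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * rank), n, rank)
  tcrossprod(X) / rank
}

# brute-force MCC from raw vectors (independent of confusion_counts path)
brute_mcc <- function(pred, truth) {
  pred <- as.logical(pred); truth <- as.logical(truth)
  tp <- sum(pred & truth); tn <- sum(!pred & !truth)
  fp <- sum(pred & !truth); fn <- sum(!pred & truth)
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  if (den == 0) NA_real_ else (tp * tn - fp * fn) / den
}

brute_bm <- function(pred, truth) {
  pred <- as.logical(pred); truth <- as.logical(truth)
  tp <- sum(pred & truth); tn <- sum(!pred & !truth)
  fp <- sum(pred & !truth); fn <- sum(!pred & truth)
  if (tp + fn == 0 || tn + fp == 0) return(NA_real_)
  tp / (tp + fn) + tn / (tn + fp) - 1
}

brute_tanimoto <- function(pred, truth) {
  pred <- as.logical(pred); truth <- as.logical(truth)
  if (sum(pred | truth) == 0) return(1)
  sum(pred & truth) / sum(pred | truth)
}

# Batch QP oracle for the linear SVM: dual coordinate descent on
#   min_w 1/2 ||w||^2 + sum_i C_i max(0, 1 - y_i w.x_i)
# with the bias folded in as an augmented constant feature. Our SGD primal
# minimizes (1/n) sum_i s_i hinge + (1/C) ||w||^2, i.e. C_i = C s_i / (2 n).
svm_dual_cd_oracle <- function(X, y, C = 1, sample_weights = rep(1, nrow(X)),
                               iters = 2000, bias_scale = 1) {
  Xa <- cbind(X, bias_scale)
  n <- nrow(Xa)
  Ci <- C * sample_weights / (2 * n)
  alpha <- numeric(n)
  w <- numeric(ncol(Xa))
  q <- rowSums(Xa^2)
  for (it in seq_len(iters)) {
    for (i in seq_len(n)) {
      g <- y[i] * sum(w * Xa[i, ]) - 1
      a_new <- min(max(alpha[i] - g / q[i], 0), Ci[i])
      d <- a_new - alpha[i]
      if (d != 0) {
        w <- w + d * y[i] * Xa[i, ]
        alpha[i] <- a_new
      }
    }
  }
  list(w = w[-length(w)], b = w[length(w)],
       decision = as.numeric(Xa %*% w))
}

# numerical gradient of the MLP training loss (central differences)
numeric_mlp_grad <- function(par, X, Y, w, l2_output, h = 1e-5) {
  loss <- function(p) fpkit:::mlp_loss(p, X, Y, w, l2_output, eps = 0)
  g <- list(gW = par$W, gb = par$b)
  for (k in seq_along(par$W)) {
    for (idx in seq_along(par$W[[k]])) {
      p1 <- par; p1$W[[k]][idx] <- p1$W[[k]][idx] + h
      p2 <- par; p2$W[[k]][idx] <- p2$W[[k]][idx] - h
      g$gW[[k]][idx] <- (loss(p1) - loss(p2)) / (2 * h)
    }
    for (idx in seq_along(par$b[[k]])) {
      p1 <- par; p1$b[[k]][idx] <- p1$b[[k]][idx] + h
      p2 <- par; p2$b[[k]][idx] <- p2$b[[k]][idx] - h
      g$gb[[k]][idx] <- (loss(p1) - loss(p2)) / (2 * h)
    }
  }
  g
}

# separable two-cluster toy problem in 2D
separable_toy <- function(n = 50, seed = 42, margin = 2) {
  set.seed(seed)
  y <- rep(c(-1, 1), length.out = n)
  X <- matrix(rnorm(2 * n, sd = 0.4), n, 2) + margin * cbind(y, y)
  list(X = X, y = y, Y01 = matrix((y + 1) / 2, ncol = 1))
}
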