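test_that("SGD SVM separates a separable toy set and matches the QP oracle", {
  toy <- separable_toy(n = 50, seed = 42)
  cfg <- train_config(epochs = 200, batch_size = 10, learning_rate = 1e-2,
                      seed = 1, loss = "hinge", svm_C = 4)
  model <- train_nystrom_svm(toy$X, toy$Y01, cfg = cfg,
                             fit_platt_params = FALSE)
  dec <- decision_values(model, toy$X)
  expect_equal(unname(sign(dec[, 1])), toy$y)     # training accuracy 1.0
  oracle <- svm_dual_cd_oracle(toy$X, toy$y, C = 4)
  expect_equal(sign(oracle$decision), toy$y)      # oracle agrees on signs
})

test_that("SVM epochs = 0 returns the zero initialization; seeds reproduce", {
  toy <- separable_toy(n = 20, seed = 7)
  cfg0 <- train_config(epochs = 0, seed = 3, loss = "hinge")
  m0 <- train_nystrom_svm(toy$X, toy$Y01, cfg = cfg0, fit_platt_params = FALSE)
  expect_true(all(m0$W == 0) && all(m0$b == 0))
  cfg <- train_config(epochs = 5, batch_size = 4, seed = 3, loss = "hinge")
  m1 <- train_nystrom_svm(toy$X, toy$Y01, cfg = cfg, fit_platt_params = FALSE)
  m2 <- train_nystrom_svm(toy$X, toy$Y01, cfg = cfg, fit_platt_params = FALSE)
  expect_identical(m1$W, m2$W)
  # single-class label -> constant predictor with prior probability
  Y2 <- cbind(toy$Y01, 1)
  expect_warning(mc <- train_nystrom_svm(toy$X, Y2, cfg = cfg), "single class")
  expect_true(all(mc$W[, 2] == 0))
  expect_equal(mc$constant_prob[2], (20 + 1) / (20 + 2))
  P <- predict_probabilities(mc, toy$X)
  expect_equal(unname(P[, 2]), rep((20 + 1) / (20 + 2), 20))
})

test_that("sample weights influence the SVM fit", {
  set.seed(19)
  X <- matrix(rnorm(80), 40, 2)
  y01 <- as.integer(X[, 1] + 0.5 * rnorm(40) > 0)
  cfg <- train_config(epochs = 50, batch_size = 8, seed = 2, loss = "hinge")
  m_flat <- train_nystrom_svm(X, cbind(y01), cfg = cfg, fit_platt_params = FALSE)
  w <- c(rep(10, 20), rep(0.01, 20))
  m_w <- train_nystrom_svm(X, cbind(y01), weights = w, cfg = cfg,
                           fit_platt_params = FALSE)
  expect_false(identical(m_flat$W, m_w$W))
})

test_that("primal and dual decision values agree within 1e-6", {
  set.seed(23)
  n <- 30
  K <- kernel_matrix(random_psd(n, seed = 23) + 0.3 * diag(n),
                     sprintf("c%02d", 1:n), sprintf("c%02d", 1:n))
  proj <- fit_projection(K)
  X <- nystrom_embed(K, proj)
  Y <- matrix(rbinom(n * 4, 1, 0.4), n, 4)
  cfg <- train_config(epochs = 20, batch_size = 8, seed = 5, loss = "hinge")
  model <- train_nystrom_svm(X, Y, cfg = cfg, fit_platt_params = FALSE)
  dual <- primal_to_dual(model, proj)
  # coefficients are centered per label
  expect_lt(max(abs(colMeans(dual$support_coefficients))), 1e-12)
  # 20 random test inputs: kernel rows vs landmarks
  Z <- matrix(rnorm(20 * n), 20, n) %*% K$values      # rows in span, arbitrary
  K_rows <- kernel_matrix(Z, sprintf("t%02d", 1:20), K$row_ids, check = FALSE)
  prim <- decision_values(model, nystrom_embed(K_rows, proj))
  du <- dual_decision_values(dual, K_rows)
  expect_lt(max(abs(prim - du)), 1e-6)
  # zero weights -> zero coefficients
  m0 <- train_nystrom_svm(X, Y, cfg = train_config(epochs = 0, loss = "hinge"),
                          fit_platt_params = FALSE)
  d0 <- primal_to_dual(m0, proj)
  expect_true(all(d0$support_coefficients == 0))
  # kind mismatch
  dk <- train_deep_kernel(X, Y, cfg = train_config(hidden_sizes = 4,
                                                   epochs = 0, seed = 1))
  expect_error(primal_to_dual(dk, proj), "nystrom_svm")
})

test_that("identity projection: dual coefficients equal centered W", {
  d <- 5
  K <- kernel_matrix(diag(d), letters[1:d], letters[1:d])
  proj <- fit_projection(K)    # gamma = I up to eigenvector sign/order
  set.seed(2)
  Y <- matrix(rbinom(d * 2, 1, 0.5), d, 2)
  model <- train_nystrom_svm(diag(d), Y,
                             cfg = train_config(epochs = 10, batch_size = 2,
                                                seed = 4, loss = "hinge"),
                             fit_platt_params = FALSE)
  dual <- primal_to_dual(model, proj)
  B <- proj$gamma %*% model$W
  expect_equal(dual$support_coefficients,
               B - rep(colMeans(B), each = d), tolerance = 1e-12)
})

test_that("Platt calibration: symmetry, monotonicity, label inversion", {
  d <- c(rep(-1, 50), rep(1, 50))
  y <- c(rep(0, 50), rep(1, 50))
  ab <- fit_platt(d, y)
  expect_lt(abs(ab["B"]), 1e-3)          # symmetric values -> B ~ 0
  expect_lt(ab["A"], 0)                  # correctly oriented: A < 0
  grid <- seq(-3, 3, length.out = 50)
  p <- fpkit:::platt_probability(grid, ab["A"], ab["B"])
  expect_true(all(diff(p) > 0))          # strictly increasing in d
  ab_inv <- fit_platt(d, 1 - y)
  expect_gt(ab_inv["A"], 0)              # inverted labels flip the sign
  expect_error(fit_platt(d, rep(1, 100)), "both classes")
})

test_that("Platt matches an optimizer oracle on noisy decision values", {
  set.seed(31)
  d <- rnorm(200)
  y <- rbinom(200, 1, 1 / (1 + exp(-2.5 * d + 0.4)))
  ab <- fit_platt(d, y)
  Np <- sum(y); Nn <- sum(1 - y)
  t <- ifelse(y == 1, (Np + 1) / (Np + 2), 1 / (Nn + 2))
  nll <- function(par) {
    f <- par[1] * d + par[2]
    sum(ifelse(f >= 0, t * f + log1p(exp(-f)), (t - 1) * f + log1p(exp(f))))
  }
  fit <- stats::optim(c(0, 0), nll, method = "BFGS")
  expect_equal(unname(ab["A"]), fit$par[1], tolerance = 1e-3)
  expect_equal(unname(ab["B"]), fit$par[2], tolerance = 1e-3)
})

test_that("deep kernel head learns a small synthetic problem", {
  set.seed(55)
  n <- 200; d <- 10; L <- 5
  X <- matrix(rnorm(n * d), n, d)
  Wtrue <- matrix(rnorm(d * L, sd = 1.5), d, L)
  Y <- (X %*% Wtrue + matrix(rnorm(n * L, sd = 0.3), n, L) > 0) * 1L
  tr <- 1:150; te <- 151:200
  cfg <- train_config(hidden_sizes = c(32, 32), dropout_rate = 0.2,
                      epochs = 60, batch_size = 25, seed = 9)
  model <- train_deep_kernel(X[tr, ], Y[tr, ], cfg = cfg)
  P <- predict_probabilities(model, X[te, ])
  mccs <- vapply(1:L, function(l)
    mcc(confusion_counts(P[, l] >= 0.5, Y[te, l])), numeric(1))
  expect_gt(mean(mccs, na.rm = TRUE), 0.5)
  # determinism with a fixed seed
  model2 <- train_deep_kernel(X[tr, ], Y[tr, ], cfg = cfg)
  expect_identical(predict_probabilities(model2, X[te, ]), P)
  # training reduces the loss after the first epoch
  w <- rep(1, length(tr))
  par0 <- withr::with_seed(cfg$seed, fpkit:::mlp_init(c(d, 32, 32, L)))
  loss0 <- fpkit:::mlp_loss(par0, X[tr, ], Y[tr, ], w, cfg$l2_output)
  cfg1 <- cfg; cfg1$epochs <- 1L
  m1 <- train_deep_kernel(X[tr, ], Y[tr, ], cfg = cfg1)
  loss1 <- fpkit:::mlp_loss(m1$par, X[tr, ], Y[tr, ], w, cfg$l2_output)
  expect_lt(loss1, loss0)
})

test_that("epochs = 0 gives 0.5 outputs; empty hidden degenerates with warning", {
  X <- matrix(rnorm(20), 10, 2)
  Y <- matrix(rbinom(30, 1, 0.5), 10, 3)
  m0 <- train_deep_kernel(X, Y, cfg = train_config(hidden_sizes = c(8),
                                                   epochs = 0, seed = 1))
  expect_equal(unname(predict_probabilities(m0, X, clamp = c(0, 1))),
               matrix(0.5, 10, 3))
  expect_warning(
    train_deep_kernel(X, Y, cfg = train_config(hidden_sizes = integer(),
                                               epochs = 1, seed = 1)),
    "linear")
})

test_that("MLP gradient matches finite differences; one Adam step reproduces", {
  set.seed(77)
  X <- matrix(rnorm(12), 6, 2)
  Y <- matrix(rbinom(6, 1, 0.5), 6, 1)
  w <- runif(6, 0.5, 2)
  dims <- c(2, 2, 1)
  par <- withr::with_seed(5, fpkit:::mlp_init(dims))
  par$W[[2]][] <- rnorm(2, sd = 0.3)   # non-zero output layer for a real check
  g <- fpkit:::mlp_grad(par, X, Y, w, dropout_rate = 0, l2_output = 1e-3,
                        train = FALSE)
  gn <- numeric_mlp_grad(par, X, Y, w, l2_output = 1e-3)
  for (k in 1:2) {
    expect_equal(g$gW[[k]], gn$gW[[k]], tolerance = 1e-6)
    expect_equal(g$gb[[k]], gn$gb[[k]], tolerance = 1e-6)
  }
  # single batch covering all rows, one epoch, no dropout: the full-batch
  # gradient is permutation-invariant, so the trained parameters equal the
  # initialization minus one hand-computed Adam step (t = 1: m_hat = g,
  # v_hat = g^2, update = lr * g / (|g| + eps))
  cfg <- train_config(hidden_sizes = 2, dropout_rate = 0, l2_output = 0,
                      learning_rate = 1e-3, batch_size = 10, epochs = 1,
                      seed = 5)
  m <- train_deep_kernel(X, Y, w, cfg)
  par0 <- withr::with_seed(5, fpkit:::mlp_init(dims))
  g0 <- fpkit:::mlp_grad(par0, X, Y, w, dropout_rate = 0, l2_output = 0,
                         train = FALSE)
  eps <- 1e-8
  for (k in 1:2) {
    gk <- g0$gW[[k]]
    expect_equal(m$par$W[[k]], par0$W[[k]] - 1e-3 * gk / (abs(gk) + eps),
                 tolerance = 1e-6, ignore_attr = TRUE)
    gbk <- g0$gb[[k]]
    expect_equal(m$par$b[[k]], -1e-3 * gbk / (abs(gbk) + eps),
                 tolerance = 1e-6, ignore_attr = TRUE)
  }
})

test_that("spectrum DNN head trains on binned + formula features", {
  set.seed(91)
  n <- 80
  keys <- sprintf("S%03d", 1:n)
  # two labels tied to two marker masses
  Y <- cbind(rbinom(n, 1, 0.5), rbinom(n, 1, 0.5))
  feats <- t(vapply(1:n, function(i) {
    mz <- c(if (Y[i, 1]) 110.05, if (Y[i, 2]) 230.11, runif(3, 300, 400))
    s <- toy_spectrum(mz, runif(length(mz), 0.5, 1), precursor = 450,
                      key = keys[i])
    as.numeric(bin_spectrum_features(s, bin_width = 1, max_mass = 500))
  }, numeric(1000)))
  cfg <- train_config(hidden_sizes = c(16), dropout_rate = 0.1, epochs = 40,
                      batch_size = 20, seed = 3)
  tr <- 1:60; te <- 61:80
  model <- train_spectrum_dnn(feats[tr, ], Y[tr, ], cfg = cfg)
  P <- predict_probabilities(model, feats[te, ])
  mccs <- vapply(1:2, function(l)
    mcc(confusion_counts(P[, l] >= 0.5, Y[te, l])), numeric(1))
  expect_gt(mean(mccs), 0.2)
  # all-zero spectra give constant predictions
  P0 <- predict_probabilities(model, matrix(0, 4, 1000))
  expect_equal(P0[1, ], P0[3, ])
  expect_error(predict_probabilities(model, feats[te, 1:999]), "dimension")
})

test_that("count_parameters arithmetic and additivity", {
  expect_equal(count_parameters(c(28000, 2500, 8000, 5220)), 131760000)
  expect_equal(count_parameters(c(28000, 5220)), 146160000)
  expect_equal(count_parameters(c(102093, 2500, 8000, 5220)), 316992500)
  expect_equal(count_parameters(c(3, 4), include_bias = TRUE), 16)
  # additive over layer splits
  for (dims in list(c(5, 7, 3), c(10, 2, 8, 4))) {
    mid <- 2
    expect_equal(count_parameters(dims),
                 count_parameters(dims[1:mid]) +
                   count_parameters(dims[mid:length(dims)]))
  }
  expect_error(count_parameters(c(5)), "at least")
  expect_error(count_parameters(c(5, 0)), "positive")
})
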