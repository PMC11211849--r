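test_that("initial features are a sparse identity", {
  X <- init_features(3L)
  expect_equal(as.matrix(X), diag(3))
  v <- stats::rnorm(3)
  expect_equal(as.numeric(X %*% v), v)
  fx <- small_planted(seed = 1)
  u <- suppressMessages(build_gene_universe(fx$collection, fx$labels))
  X <- init_features(u)
  n <- length(u$symbols)
  expect_equal(dim(X), c(n, n))
  expect_equal(Matrix::nnzero(X), n)  # nnz = n, not n^2
})

test_that("residual layer matches the dense evaluation", {
  set.seed(5)
  for (rep in 1:8) {
    n <- sample(10:50, 1); m <- sample(4:15, 1); d <- sample(2:6, 1)
    cc <- random_collection(n, m)
    hg <- hg_from_collection(cc)
    hg$w <- stats::runif(m)
    op <- build_propagation_operator(hg)
    n <- length(hg$universe$symbols)
    X <- matrix(stats::rnorm(n * d), n, d)
    theta <- matrix(stats::rnorm(d * d, sd = 0.3), d, d)
    for (act in c("relu", "elu")) {
      expect_lt(max(abs(residual_layer(X, op, theta, act) -
                        dense_residual_layer(X, dense_operator(hg), theta,
                                             act))), 1e-6)
    }
  }
})

test_that("theta = 0 with ReLU and nonnegative input is an exact identity map", {
  set.seed(6)
  cc <- random_collection(30, 8)
  hg <- hg_from_collection(cc)
  op <- build_propagation_operator(hg)
  n <- length(hg$universe$symbols)
  X <- matrix(abs(stats::rnorm(n * 5)), n, 5)
  out <- residual_layer(X, op, matrix(0, 5, 5), "relu")
  expect_identical(out, X)
})

test_that("zero propagation reduces the layer to sigma(X)", {
  X <- matrix(stats::rnorm(20), 10, 2)
  A0 <- matrix(0, 10, 10)
  theta <- matrix(stats::rnorm(4), 2, 2)
  expect_equal(residual_layer(X, A0, theta, "relu"), pmax(X, 0))
})

test_that("residual layer rejects inconsistent shapes", {
  expect_error(residual_layer(matrix(0, 5, 2), matrix(0, 4, 4),
                              matrix(0, 2, 2)), "shape mismatch")
  expect_error(residual_layer(matrix(0, 4, 2), matrix(0, 4, 4),
                              matrix(0, 3, 3)), "shape mismatch")
})

test_that("eval-mode forward is a valid deterministic probability map", {
  fx <- small_planted(seed = 4)
  u <- suppressMessages(build_gene_universe(fx$collection, fx$labels))
  hg <- weight_hyperedges(build_incidence(fx$collection, u),
                          u$labels$positives)
  op <- build_propagation_operator(hg)
  cfg <- model_config(hidden_dim = 8, epochs = 5, seed = 2)
  set.seed(2)
  params <- hyperprio:::init_params(length(u$symbols), cfg)
  Z1 <- forward_pass(params, op, cfg)
  Z2 <- forward_pass(params, op, cfg)
  expect_identical(Z1, Z2)
  expect_equal(unname(rowSums(Z1)), rep(1, nrow(Z1)), tolerance = 1e-6)
  expect_true(all(Z1 >= 0 & Z1 <= 1))
})

test_that("forward pass is equivariant under gene permutation", {
  set.seed(8)
  cc <- random_collection(25, 10)
  hg <- hg_from_collection(cc)
  n_u <- length(hg$universe$symbols)
  pos <- sample(hg$universe$symbols, 6)
  hg <- weight_hyperedges(hg, pos)
  op <- build_propagation_operator(hg)
  cfg <- model_config(hidden_dim = 4, seed = 3)
  params <- hyperprio:::init_params(n_u, cfg)
  Z <- forward_pass(params, op, cfg)

  perm <- sample(n_u)
  hg_p <- hg
  hg_p$H <- hg$H[perm, ]
  hg_p$universe$symbols <- hg$universe$symbols[perm]
  op_p <- build_propagation_operator(hg_p)
  params_p <- params
  params_p$input_fc <- params$input_fc[perm, ]
  Z_p <- forward_pass(params_p, op_p, cfg)
  expect_equal(Z_p, Z[perm, ], tolerance = 1e-10)
})

test_that("training reduces the loss and is seed-reproducible", {
  fx <- small_planted(seed = 1)
  u <- suppressMessages(build_gene_universe(fx$collection, fx$labels))
  hg <- weight_hyperedges(build_incidence(fx$collection, u),
                          u$labels$positives)
  cfg <- model_config(hidden_dim = 16, epochs = 60, seed = 5)
  m1 <- train_model(hg, u$labels, cfg)
  m2 <- train_model(hg, u$labels, cfg)
  expect_lt(utils::tail(m1$loss_trace, 1), m1$loss_trace[1])
  expect_identical(m1$loss_trace, m2$loss_trace)
  expect_identical(m1$params, m2$params)
})

test_that("compiled and reference training engines agree", {
  fx <- small_planted(seed = 3)
  u <- suppressMessages(build_gene_universe(fx$collection, fx$labels))
  hg <- weight_hyperedges(build_incidence(fx$collection, u),
                          u$labels$positives)
  # dropout active: both engines draw masks from the same seeded RNG stream
  cfg <- model_config(hidden_dim = 12, epochs = 30, seed = 7)
  m_cpp <- train_model(hg, u$labels, cfg, engine = "cpp")
  m_r <- train_model(hg, u$labels, cfg, engine = "r")
  expect_equal(m_cpp$loss_trace, m_r$loss_trace, tolerance = 1e-12)
  expect_equal(m_cpp$params$input_fc, m_r$params$input_fc,
               tolerance = 1e-12)
  expect_equal(m_cpp$params$residual_thetas, m_r$params$residual_thetas,
               tolerance = 1e-12)
})

test_that("the network separates planted positives from negatives", {
  fx <- small_planted(seed = 2)
  u <- suppressMessages(build_gene_universe(fx$collection, fx$labels))
  hg <- weight_hyperedges(build_incidence(fx$collection, u),
                          u$labels$positives)
  cfg <- model_config(hidden_dim = 32, epochs = 150, seed = 1)
  m <- train_model(hg, u$labels, cfg)
  preds <- predict_scores(m, hg)
  s <- stats::setNames(preds$score, preds$gene)
  genes <- c(u$labels$positives, u$labels$negatives)
  y <- as.integer(genes %in% u$labels$positives)
  expect_gt(auroc(s[genes], y), 0.95)  # training-set fit capacity
})

test_that("predict_scores returns a complete, sorted, bounded ranking", {
  fx <- small_planted(seed = 6)
  u <- suppressMessages(build_gene_universe(fx$collection, fx$labels))
  hg <- weight_hyperedges(build_incidence(fx$collection, u),
                          u$labels$positives)
  m <- train_model(hg, u$labels,
                   model_config(hidden_dim = 8, epochs = 20, seed = 1))
  preds <- predict_scores(m, hg)
  expect_equal(nrow(preds), length(u$symbols))
  expect_true(all(preds$score >= 0 & preds$score <= 1))
  expect_false(is.unsorted(rev(preds$score)))
  expect_equal(preds$rank, seq_len(nrow(preds)))
  expect_equal(preds$score[1], max(preds$score))
  expect_setequal(preds$gene, u$symbols)
})

test_that("training rejects degenerate label sets", {
  fx <- small_planted(seed = 1)
  u <- suppressMessages(build_gene_universe(fx$collection, fx$labels))
  hg <- weight_hyperedges(build_incidence(fx$collection, u),
                          u$labels$positives)
  expect_error(
    train_model(hg, labeled_genes("NOTINUNIVERSE", u$labels$negatives[1]),
                model_config(epochs = 1)),
    "outside the hypergraph universe")
})
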