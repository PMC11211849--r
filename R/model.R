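#' Model configuration
#'
#' Hyperparameters of the residual hypergraph convolutional network. The
#' defaults follow the published training protocol where it states them
#' (ADAM, learning rate 0.005, about 300 epochs, three residual layers, two
#' fully connected layers) and standard graph-network practice elsewhere.
#'
#' @param hidden_dim Width of the gene embedding / residual layers.
#' @param n_residual_layers Number of residual convolution layers.
#' @param learning_rate ADAM learning rate.
#' @param epochs Full-batch training epochs.
#' @param activation `"relu"` or `"elu"`.
#' @param dropout Dropout probability applied after the input transform
#'   during training (inverted dropout; inactive at evaluation).
#' @param seed Integer seed controlling weight initialization and dropout.
#' @param class_weighting `"none"` or `"balanced"` (inverse-frequency loss
#'   weights for the positive/negative classes).
#' @param patience If a positive integer, stop early when the training loss
#'   has not improved for that many epochs; default `Inf` (no early stop).
#' @return A `model_config` list.
#' @export
model_config <- function(hidden_dim = 128L, n_residual_layers = 3L,
                         learning_rate = 0.005, epochs = 300L,
                         activation = c("relu", "elu"), dropout = 0.5,
                         seed = 1L, class_weighting = c("none", "balanced"),
                         patience = Inf) {
  activation <- match.arg(activation)
  class_weighting <- match.arg(class_weighting)
  stopifnot(hidden_dim >= 1L, n_residual_layers >= 0L, learning_rate > 0,
            epochs >= 1L, dropout >= 0, dropout < 1, patience >= 1)
  structure(list(hidden_dim = as.integer(hidden_dim),
                 n_residual_layers = as.integer(n_residual_layers),
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 activation = activation, dropout = dropout,
                 seed = as.integer(seed), class_weighting = class_weighting,
                 patience = patience),
            class = "model_config")
}

#' @export
print.model_config <- function(x, ...) {
  cat("model_config: dim", x$hidden_dim, "|", x$n_residual_layers,
      "residual layers |", x$activation, "| lr", x$learning_rate,
      "|", x$epochs, "epochs | dropout", x$dropout,
      "| seed", x$seed, "\n")
  invisible(x)
}

#' Initial gene features: the identity matrix
#'
#' With no external gene features, the initial feature matrix is the n x n
#' identity (stored sparse, nnz = n), so the input linear transform acts as
#' a learned per-gene embedding lookup.
#'
#' @param universe A `gene_universe` (or an integer n).
#' @return Sparse n x n identity matrix.
#' @export
init_features <- function(universe) {
  n <- if (inherits(universe, "gene_universe")) length(universe$symbols)
       else as.integer(universe)
  stopifnot(n >= 1L)
  Matrix::Diagonal(n)
}

activate <- function(x, activation) {
  switch(activation,
    relu = pmax(x, 0),
    elu  = ifelse(x > 0, x, expm1(x)))
}

activate_grad <- function(y, activation) {
  # gradient expressed through the activation output y = sigma(x)
  switch(activation,
    relu = (y > 0) * 1,
    elu  = ifelse(y > 0, 1, y + 1))
}

glorot <- function(nrow, ncol) {
  r <- sqrt(6 / (nrow + ncol))
  matrix(stats::runif(nrow * ncol, -r, r), nrow, ncol)
}

init_params <- function(n_genes, config) {
  d <- config$hidden_dim
  thetas <- replicate(config$n_residual_layers, glorot(d, d),
                      simplify = FALSE)
  list(input_fc = glorot(n_genes, d),
       residual_thetas = thetas,
       output_fc = glorot(d, 2L),
       output_bias = numeric(2L))
}

#' One residual hypergraph convolution layer
#'
#' Computes `sigma(A X Theta + X)`: neighbourhood information propagated
#' through the normalized operator, linearly transformed, plus the identity
#' skip connection. With `Theta = 0`, ReLU and nonnegative input the layer
#' is exactly the identity map, which is the property that protects deep
#' stacks from oversmoothing.
#'
#' @param X n x d feature matrix.
#' @param A A `propagation_operator` (or an n x n matrix).
#' @param theta d x d weight matrix.
#' @param activation `"relu"` or `"elu"`.
#' @return n x d matrix of activations.
#' @export
residual_layer <- function(X, A, theta, activation = "relu") {
  if (inherits(A, "propagation_operator")) A <- A$A
  X <- as.matrix(X)
  if (nrow(A) != nrow(X) || ncol(X) != nrow(theta) ||
      nrow(theta) != ncol(theta)) {
    stop("shape mismatch in residual layer: X is ", nrow(X), "x", ncol(X),
         ", A is ", nrow(A), "x", ncol(A), ", theta is ", nrow(theta), "x",
         ncol(theta))
  }
  P <- as.matrix(A %*% X)
  dimnames(P) <- NULL
  activate(P %*% theta + X, activation)
}

# apply the propagation operator: through the bipartite factor B (A = B B^T,
# two-stage genes -> sets -> genes message passing) when available, else as a
# plain matrix product
propagate <- function(A, X) {
  if (inherits(A, "propagation_operator")) {
    if (!is.null(A$B)) {
      out <- as.matrix(A$B %*% Matrix::crossprod(A$B, X))
      dimnames(out) <- NULL
      return(out)
    }
    A <- A$A
  }
  out <- as.matrix(A %*% X)
  dimnames(out) <- NULL
  out
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1L, max)
  E <- exp(Z)
  E / rowSums(E)
}

check_finite <- function(x, stage) {
  if (!all(is.finite(x))) stop("non-finite values at stage: ", stage)
  x
}

#' Forward pass of the network
#'
#' Pipeline: per-gene embedding `sigma(X0 input_fc)` (with identity input
#' features this is `sigma(input_fc)`), dropout (training mode only), the
#' stack of residual hypergraph convolution layers, then the prediction
#' head `Z = softmax(X Theta_out + b)`. Column 2 of `Z` is the per-gene
#' risk score.
#'
#' @param params Parameter list from training (elements `input_fc`,
#'   `residual_thetas`, `output_fc`, `output_bias`).
#' @param A A `propagation_operator`.
#' @param config A `model_config`.
#' @param training Logical; when `TRUE`, dropout is active (stochastic) and
#'   intermediate activations are returned for backpropagation.
#' @return In evaluation mode, the n x 2 probability matrix `Z`. In training
#'   mode, a list with `Z` and the cached intermediates.
#' @export
forward_pass <- function(params, A, config, training = FALSE) {
  X <- activate(params$input_fc, config$activation)
  check_finite(X, "input transform")
  mask <- NULL
  if (training && config$dropout > 0) {
    keep <- 1 - config$dropout
    mask <- matrix((stats::runif(length(X)) < keep) / keep,
                   nrow(X), ncol(X))
    X <- X * mask
  }
  layer_in <- vector("list", config$n_residual_layers)   # X^(l)
  layer_prop <- vector("list", config$n_residual_layers) # A X^(l)
  for (l in seq_len(config$n_residual_layers)) {
    layer_in[[l]] <- X
    P <- propagate(A, X)
    layer_prop[[l]] <- P
    X <- activate(P %*% params$residual_thetas[[l]] + X, config$activation)
    check_finite(X, paste0("residual layer ", l))
  }
  logits <- sweep(X %*% params$output_fc, 2L, params$output_bias, "+")
  Z <- softmax_rows(check_finite(logits, "output head"))
  if (!training) return(Z)
  list(Z = Z, mask = mask, layer_in = layer_in, layer_prop = layer_prop,
       top = X)
}

cross_entropy <- function(probs, y01, idx, weights) {
  p <- probs[cbind(idx, y01[idx] + 1L)]
  -sum(weights * log(pmax(p, 1e-12))) / sum(weights)
}

adam_step <- function(state, grad, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mhat <- state$m / (1 - beta1^t)
  vhat <- state$v / (1 - beta2^t)
  state$theta <- state$theta - lr * mhat / (sqrt(vhat) + eps)
  state
}

#' Train the residual hypergraph network
#'
#' Full-batch transductive training: every gene is scored each epoch but
#' only labeled genes (training-mask positives and negatives) enter the
#' cross-entropy loss. Optimized with ADAM; gradients are computed by exact
#' backpropagation through the residual stack. Deterministic given
#' `config$seed`.
#'
#' @param hg_weighted A disease-weighted `hypergraph`
#'   (see [weight_hyperedges()]).
#' @param labels A `labeled_genes` whose symbols lie in the hypergraph
#'   universe; these are the genes contributing to the loss.
#' @param config A `model_config`.
#' @param A Optional precomputed `propagation_operator` for `hg_weighted`.
#' @param engine `"cpp"` (compiled training core, the default) or `"r"`
#'   (pure-R reference implementation). Both draw initialization and
#'   dropout from the same seeded RNG stream and agree to numerical
#'   precision; the reference engine exists for verification.
#' @return A `trained_model`: list with `params`, `loss_trace`, `config`
#'   and the label indices used.
#' @export
train_model <- function(hg_weighted, labels, config = model_config(),
                        A = NULL, engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  stopifnot(inherits(hg_weighted, "hypergraph"),
            inherits(labels, "labeled_genes"),
            inherits(config, "model_config"))
  symbols <- hg_weighted$universe$symbols
  pos_idx <- match(labels$positives, symbols)
  neg_idx <- match(labels$negatives, symbols)
  if (anyNA(pos_idx) || anyNA(neg_idx)) {
    stop("labeled genes outside the hypergraph universe; ",
         "build labels with build_gene_universe()")
  }
  if (length(pos_idx) < 1L || length(neg_idx) < 1L) {
    stop("need at least one positive and one negative training gene")
  }
  if (is.null(A)) A <- build_propagation_operator(hg_weighted)
  n <- length(symbols)
  idx <- c(pos_idx, neg_idx)
  y01 <- integer(n)                       # 1 = disease gene
  y01[pos_idx] <- 1L
  wts <- rep(1, length(idx))
  if (config$class_weighting == "balanced") {
    wts <- ifelse(y01[idx] == 1L,
                  length(idx) / (2 * length(pos_idx)),
                  length(idx) / (2 * length(neg_idx)))
  }

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(config$seed)
  params <- init_params(n, config)

  if (engine == "cpp") {
    res <- .train_core(A$B, params$input_fc, params$residual_thetas,
                       params$output_fc, params$output_bias,
                       idx - 1L, y01[idx], wts,
                       config$learning_rate, config$epochs,
                       config$dropout,
                       match(config$activation, c("relu", "elu")) - 1L,
                       config$patience)
    return(structure(list(
      params = list(input_fc = res$input_fc,
                    residual_thetas = res$residual_thetas,
                    output_fc = res$output_fc,
                    output_bias = as.numeric(res$output_bias)),
      loss_trace = res$loss_trace, config = config,
      label_idx = list(positive = pos_idx, negative = neg_idx)),
      class = "trained_model"))
  }

  states <- lapply(flatten_params(params), function(p)
    list(theta = p, m = p * 0, v = p * 0))

  loss_trace <- numeric(config$epochs)
  best <- Inf; since_best <- 0L
  wsum <- sum(wts)
  for (epoch in seq_len(config$epochs)) {
    params <- unflatten_params(lapply(states, `[[`, "theta"), config)
    fw <- forward_pass(params, A, config, training = TRUE)
    loss <- cross_entropy(fw$Z, y01, idx, wts)
    if (!is.finite(loss)) stop("non-finite training loss at epoch ", epoch)
    loss_trace[epoch] <- loss

    # output head gradient: dL/dlogits = (Z - onehot) * w / sum(w), labeled only
    dZ <- matrix(0, n, 2L)
    dZ[idx, ] <- fw$Z[idx, , drop = FALSE]
    dZ[cbind(idx, y01[idx] + 1L)] <- dZ[cbind(idx, y01[idx] + 1L)] - 1
    dZ[idx, ] <- dZ[idx, ] * (wts / wsum)

    grads <- backward_pass(params, A, config, fw, dZ)
    for (k in seq_along(states)) {
      states[[k]] <- adam_step(states[[k]], grads[[k]],
                               config$learning_rate, epoch)
    }

    if (is.finite(config$patience)) {
      if (loss < best - 1e-6) { best <- loss; since_best <- 0L }
      else {
        since_best <- since_best + 1L
        if (since_best >= config$patience) {
          loss_trace <- loss_trace[seq_len(epoch)]
          break
        }
      }
    }
  }
  params <- unflatten_params(lapply(states, `[[`, "theta"), config)
  structure(list(params = params, loss_trace = loss_trace, config = config,
                 label_idx = list(positive = pos_idx, negative = neg_idx)),
            class = "trained_model")
}

flatten_params <- function(params) {
  out <- c(list(input_fc = params$input_fc), params$residual_thetas,
           list(output_fc = params$output_fc,
                output_bias = params$output_bias))
  names(out) <- c("input_fc",
                  if (length(params$residual_thetas))
                    paste0("theta_", seq_along(params$residual_thetas)),
                  "output_fc", "output_bias")
  out
}

unflatten_params <- function(flat, config) {
  L <- config$n_residual_layers
  list(input_fc = flat$input_fc,
       residual_thetas = if (L) unname(flat[paste0("theta_", seq_len(L))])
                         else list(),
       output_fc = flat$output_fc,
       output_bias = flat$output_bias)
}

backward_pass <- function(params, A, config, fw, dZ) {
  L <- config$n_residual_layers
  d_output_fc <- crossprod(fw$top, dZ)
  d_output_bias <- colSums(dZ)
  dX <- tcrossprod(dZ, params$output_fc)          # grad wrt top activations
  d_thetas <- vector("list", L)
  for (l in rev(seq_len(L))) {
    Xout <- if (l == L) fw$top else fw$layer_in[[l + 1L]]
    dY <- dX * activate_grad(Xout, config$activation)
    d_thetas[[l]] <- crossprod(fw$layer_prop[[l]], dY)
    dP <- tcrossprod(dY, params$residual_thetas[[l]])
    dX <- propagate(A, dP) + dY                   # A symmetric
  }
  if (!is.null(fw$mask)) dX <- dX * fw$mask
  X1 <- activate(params$input_fc, config$activation)
  d_input <- dX * activate_grad(X1, config$activation)
  out <- c(list(input_fc = d_input), d_thetas,
           list(output_fc = d_output_fc, output_bias = d_output_bias))
  names(out) <- c("input_fc",
                  if (L) paste0("theta_", seq_len(L)),
                  "output_fc", "output_bias")
  out
}

#' Score and rank all genes with a trained model
#'
#' Evaluation-mode forward pass (no dropout); genes are ordered by
#' descending risk score, ties broken by universe index.
#'
#' @param model A `trained_model` from [train_model()].
#' @param hg_weighted The disease-weighted `hypergraph` used for training
#'   (or any hypergraph over the same universe).
#' @param A Optional precomputed `propagation_operator`.
#' @return A data frame with columns `gene`, `score` (probability of the
#'   disease class) and `rank`, ordered by rank.
#' @export
predict_scores <- function(model, hg_weighted, A = NULL) {
  stopifnot(inherits(model, "trained_model"))
  if (is.null(A)) A <- build_propagation_operator(hg_weighted)
  Z <- forward_pass(model$params, A, model$config, training = FALSE)
  score <- Z[, 2L]
  symbols <- hg_weighted$universe$symbols
  ord <- order(-score, seq_along(score))
  data.frame(gene = symbols[ord], score = score[ord],
             rank = seq_along(ord), stringsAsFactors = FALSE)
}
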