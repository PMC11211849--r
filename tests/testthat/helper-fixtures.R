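# Shared fixtures and independent oracles.

# tiny hand-built collection: universe {A,B,C}, sets {A,B} and {B,C}
tiny_collection <- function() {
  hyperprio:::new_gene_set_collection(list(
    list(name = "S1", description = "d", members = c("A", "B")),
    list(name = "S2", description = "d", members = c("B", "C"))
  ), "tiny")
}

# random hypergraph: n genes, m sets, membership prob p (each set nonempty)
random_collection <- function(n, m, p = 0.2) {
  genes <- sprintf("G%03d", seq_len(n))
  sets <- lapply(seq_len(m), function(b) {
    members <- genes[stats::runif(n) < p]
    if (length(members) == 0L) members <- sample(genes, 1L)
    list(name = sprintf("SET%03d", b), description = "rnd", members = members)
  })
  hyperprio:::new_gene_set_collection(sets, "random")
}

hg_from_collection <- function(collection, labels = NULL) {
  u <- build_gene_universe(collection, labels)
  build_incidence(collection, u)
}

small_planted <- function(seed = 1) {
  generate_fixture(synthetic_config(
    n_genes = 150, n_positives = 25, n_negatives = 50,
    n_disease_sets = 10, n_background_sets = 20,
    set_size_range = c(5, 15), seed = seed))
}

# dense oracle for the normalized propagation operator
dense_operator <- function(hg) {
  H <- as.matrix(hg$H)
  w <- hg$w
  dv <- as.numeric(H %*% w)
  de <- colSums(H)
  Dv <- diag(ifelse(dv > 0, 1 / sqrt(dv), 0), nrow(H))
  De <- diag(ifelse(de > 0, 1 / de, 0), ncol(H))
  Dv %*% H %*% diag(w, length(w)) %*% De %*% t(H) %*% Dv
}

# brute-force residual layer on dense matrices
dense_residual_layer <- function(X, A_dense, theta, activation = "relu") {
  Y <- A_dense %*% X %*% theta + X
  if (activation == "relu") pmax(Y, 0) else ifelse(Y > 0, Y, expm1(Y))
}

# AUROC by exhaustive pair enumeration (ties half credit)
pairwise_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# average precision by direct stepwise accumulation (assumes no tied scores)
stepwise_ap <- function(scores, labels) {
  ord <- order(-scores)
  y <- labels[ord]
  tp <- cumsum(y)
  prec <- tp / seq_along(y)
  sum(prec[y == 1]) / sum(y)
}

# one-sided Fisher p by explicit hypergeometric summation
hypergeom_tail <- function(a, b, c_, d) {
  K <- a + c_       # target size
  nq <- a + b       # query size
  N <- a + b + c_ + d
  ks <- a:min(K, nq)
  sum(choose(K, ks) * choose(N - K, nq - ks)) / choose(N, nq)
}
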