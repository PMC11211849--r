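#' Stratified k-fold split of the labeled genes
#'
#' Shuffles each class with the given seed and deals members round-robin
#' into k folds, so class proportions are preserved per fold up to rounding
#' and the folds partition the labeled genes.
#'
#' @param labels A `labeled_genes`.
#' @param k Number of folds (each class must have at least k members).
#' @param seed Integer seed for the shuffle.
#' @return List of k elements, each a list with `train` and `test`
#'   `labeled_genes`.
#' @export
stratified_kfold <- function(labels, k = 5L, seed = 0L) {
  stopifnot(inherits(labels, "labeled_genes"), k >= 2L)
  if (length(labels$positives) < k || length(labels$negatives) < k) {
    stop("each class needs at least k = ", k, " members")
  }
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  assign_folds <- function(x) {
    x <- sample(x)
    split(x, rep_len(seq_len(k), length(x)))
  }
  pos_folds <- assign_folds(labels$positives)
  neg_folds <- assign_folds(labels$negatives)
  lapply(seq_len(k), function(f) {
    test <- labeled_genes(pos_folds[[f]], neg_folds[[f]])
    train <- labeled_genes(unlist(pos_folds[-f], use.names = FALSE),
                           unlist(neg_folds[-f], use.names = FALSE))
    list(train = train, test = test)
  })
}

#' Area under the ROC curve
#'
#' Mann-Whitney formulation via ranks: the probability that a random
#' positive outscores a random negative, with ties given half credit.
#'
#' @param scores Numeric vector.
#' @param labels Binary vector (1 = positive), same length.
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% c(0L, 1L)))
  n_pos <- sum(labels == 1L); n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    stop("AUROC needs both classes present")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Area under the precision-recall curve (average precision)
#'
#' Average-precision convention: the mean of the precision values at the
#' ranks of the positives when examples are taken in descending score order
#' (no interpolation). Tied scores are averaged over the orderings by
#' treating a tie block as a single PR segment.
#'
#' @param scores Numeric vector.
#' @param labels Binary vector (1 = positive), same length.
#' @return Average precision in \[0, 1\].
#' @export
auprc <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% c(0L, 1L)))
  n_pos <- sum(labels == 1L)
  if (n_pos == 0L) stop("AUPRC needs at least one positive")
  ord <- order(-scores)
  s <- scores[ord]; y <- labels[ord]
  # collapse tie blocks: within a block precision is the block-average
  blocks <- cumsum(!duplicated(s))
  tp_block <- tapply(y, blocks, sum)
  n_block <- tabulate(blocks)
  tp_cum <- cumsum(tp_block)
  n_cum <- cumsum(n_block)
  ap <- 0
  tp_prev <- 0; n_prev <- 0
  for (b in seq_along(tp_block)) {
    tp_b <- tp_block[[b]]
    if (tp_b > 0) {
      # positives inside a tie block are spread evenly across it
      frac <- tp_b / n_block[[b]]
      for (j in seq_len(n_block[[b]])) {
        prec <- (tp_prev + frac * j) / (n_prev + j)
        ap <- ap + frac * prec
      }
    }
    tp_prev <- tp_cum[[b]]; n_prev <- n_cum[[b]]
  }
  unname(ap / n_pos)
}

#' Cross-validate the model with leakage-free per-fold weighting
#'
#' For each fold, hyperedge weights are recomputed from the training-fold
#' positives only (test positives never influence the weights), the network
#' is trained on the training labels, and AUROC / average precision are
#' computed on the held-out test labels. The input hypergraph is never
#' mutated.
#'
#' @param hg An unweighted `hypergraph` (weights all one).
#' @param labels A `labeled_genes` on the hypergraph universe.
#' @param config A `model_config`; `config$seed` is combined with the fold
#'   and `seed` so repeats differ.
#' @param k Number of folds.
#' @param seed Seed for the fold split (and training-seed offset).
#' @return A `cv_result`: data frame with one row per fold (`fold`,
#'   `auroc`, `auprc`, `n_test_pos`, `n_test_neg`), with per-fold scores in
#'   attribute `fold_scores`.
#' @export
cross_validate <- function(hg, labels, config = model_config(), k = 5L,
                           seed = 0L) {
  stopifnot(inherits(hg, "hypergraph"))
  folds <- stratified_kfold(labels, k, seed)
  rows <- vector("list", k)
  fold_scores <- vector("list", k)
  for (f in seq_len(k)) {
    fold <- folds[[f]]
    hg_w <- weight_hyperedges(hg, fold$train$positives)
    A <- build_propagation_operator(hg_w)
    cfg <- config
    cfg$seed <- as.integer((config$seed + 7919 * seed + f) %% .Machine$integer.max)
    model <- train_model(hg_w, fold$train, cfg, A = A)
    preds <- predict_scores(model, hg_w, A = A)
    score_by_gene <- stats::setNames(preds$score, preds$gene)
    test_genes <- c(fold$test$positives, fold$test$negatives)
    y <- rep(c(1L, 0L), c(length(fold$test$positives),
                          length(fold$test$negatives)))
    s <- score_by_gene[test_genes]
    rows[[f]] <- data.frame(fold = f, auroc = auroc(s, y),
                            auprc = auprc(s, y),
                            n_test_pos = sum(y == 1L),
                            n_test_neg = sum(y == 0L))
    fold_scores[[f]] <- data.frame(gene = test_genes, label = y, score = s,
                                   fold = f, row.names = NULL)
  }
  out <- do.call(rbind, rows)
  attr(out, "fold_scores") <- do.call(rbind, fold_scores)
  class(out) <- c("cv_result", class(out))
  out
}

#' Summarize repeated cross-validation
#'
#' @param results A `cv_result` or list of them (e.g. repeats with
#'   different seeds).
#' @return Data frame with mean, sd and normal-theory 95% CI for AUROC and
#'   average precision across all folds.
#' @export
summarize_cv <- function(results) {
  if (inherits(results, "data.frame")) results <- list(results)
  all <- do.call(rbind, lapply(results, as.data.frame))
  summ <- function(x) {
    m <- mean(x); se <- stats::sd(x) / sqrt(length(x))
    c(mean = m, sd = stats::sd(x), ci_lo = m - 1.96 * se,
      ci_hi = m + 1.96 * se)
  }
  out <- rbind(auroc = summ(all$auroc), auprc = summ(all$auprc))
  data.frame(metric = rownames(out), out, row.names = NULL)
}

#' AUPRC against an independent positive set
#'
#' Scores the whole universe against an externally curated positive list:
#' genes in the test list (minus any used in training, which are removed
#' first) are true positives and every other non-training gene is a
#' negative. Prevalence is low by construction, so values are far below
#' within-CV AUPRC.
#'
#' @param scores Named per-gene score vector (names are gene symbols), or
#'   the data frame from [predict_scores()].
#' @param test_positives Character vector: the independent positive list.
#' @param training_labeled Character vector of genes used in training
#'   (positives and negatives); removed from the evaluation pool.
#' @return Average precision over the remaining genes.
#' @export
independent_test_auprc <- function(scores, test_positives,
                                   training_labeled = character()) {
  if (is.data.frame(scores)) {
    scores <- stats::setNames(scores$score, scores$gene)
  }
  test_positives <- unique(toupper(test_positives))
  training_labeled <- unique(toupper(training_labeled))
  pool <- setdiff(names(scores), training_labeled)
  pos <- intersect(test_positives, pool)
  n_removed <- length(intersect(test_positives, training_labeled))
  if (n_removed > 0L) {
    message(n_removed,
            " independent-test gene(s) overlapped training labels; removed")
  }
  if (length(pos) == 0L) {
    stop("no independent-test positives remain after removing training genes")
  }
  y <- as.integer(pool %in% pos)
  auprc(scores[pool], y)
}
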