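test_that("stratified folds partition each class proportionally", {
  labels <- labeled_genes(sprintf("P%02d", 1:10), sprintf("N%02d", 1:10))
  folds <- stratified_kfold(labels, k = 5, seed = 1)
  expect_length(folds, 5L)
  for (f in folds) {
    expect_length(f$test$positives, 2L)
    expect_length(f$test$negatives, 2L)
    expect_length(intersect(f$train$positives, f$test$positives), 0L)
  }
  all_test_pos <- unlist(lapply(folds, function(f) f$test$positives))
  expect_setequal(all_test_pos, labels$positives)
  expect_equal(anyDuplicated(all_test_pos), 0L)
  # seeded determinism
  expect_identical(folds, stratified_kfold(labels, k = 5, seed = 1))
  expect_error(stratified_kfold(labeled_genes("P1", c("N1", "N2")), k = 2),
               "at least k")
})

test_that("uneven classes stratify within one of proportional", {
  labels <- labeled_genes(sprintf("P%02d", 1:13), sprintf("N%02d", 1:29))
  folds <- stratified_kfold(labels, k = 5, seed = 3)
  np <- vapply(folds, function(f) length(f$test$positives), integer(1))
  nn <- vapply(folds, function(f) length(f$test$negatives), integer(1))
  expect_equal(sum(np), 13L); expect_equal(sum(nn), 29L)
  expect_lte(diff(range(np)), 1L)
  expect_lte(diff(range(nn)), 1L)
})

test_that("AUROC matches hand enumeration and pair counting", {
  expect_equal(auroc(c(0.9, 0.8, 0.3, 0.1), c(1, 0, 1, 0)), 0.75)
  expect_equal(auroc(c(5, 4, 3), c(1, 1, 0)), 1)      # perfect separation
  expect_equal(auroc(rep(1, 6), c(1, 0, 1, 0, 0, 1)), 0.5)  # all tied
  set.seed(10)
  for (rep in 1:20) {
    n <- sample(5:100, 1)
    scores <- sample(seq(0, 1, 0.05), n, replace = TRUE)  # forces ties
    y <- stats::rbinom(n, 1, 0.4)
    if (sum(y) == 0 || sum(y) == n) next
    expect_equal(auroc(scores, y), pairwise_auroc(scores, y))
  }
  expect_error(auroc(1:3, c(1, 1, 1)), "both classes")
})

test_that("AUROC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(11)
  scores <- stats::rnorm(200)
  y <- stats::rbinom(200, 1, 0.3)
  expect_equal(auroc(scores, y),
               as.numeric(pROC::auc(pROC::roc(y, scores, quiet = TRUE,
                                              direction = "<"))))
})

test_that("average precision matches hand enumeration and the stepwise oracle", {
  expect_equal(auprc(c(0.9, 0.8, 0.3), c(1, 0, 1)), 5 / 6)
  expect_equal(auprc(c(3, 2, 1), c(1, 1, 0)), 1)      # perfect ranking
  set.seed(12)
  for (rep in 1:20) {
    n <- sample(5:100, 1)
    scores <- stats::runif(n)                          # ties a.s. absent
    y <- stats::rbinom(n, 1, 0.3)
    if (sum(y) == 0) next
    expect_equal(auprc(scores, y), stepwise_ap(scores, y))
  }
  expect_error(auprc(1:3, c(0, 0, 0)), "positive")
})

test_that("average precision of random scores approaches prevalence", {
  set.seed(13)
  pi0 <- 0.15
  vals <- replicate(40, {
    y <- c(rep(1, 30), rep(0, 170))
    auprc(stats::runif(200), y)
  })
  expect_lt(abs(mean(vals) - pi0), 0.05)
  # all-tied scores give exactly the prevalence
  expect_equal(auprc(rep(0.5, 200), c(rep(1, 30), rep(0, 170))), pi0)
})

test_that("per-fold weighting uses train positives only (leakage guard)", {
  # a sentinel hyperedge whose only positive lands in the test fold
  set.seed(20)
  genes <- sprintf("G%03d", 1:40)
  pos <- genes[1:10]; neg <- genes[11:30]
  sentinel_pos <- pos[1]
  cc <- hyperprio:::new_gene_set_collection(c(
    list(list(name = "SENTINEL", description = "",
              members = c(sentinel_pos, genes[31:34]))),
    lapply(1:8, function(i)
      list(name = paste0("S", i), description = "",
           members = sample(genes, 10)))
  ), "t")
  u <- suppressMessages(build_gene_universe(cc, labeled_genes(pos, neg)))
  hg <- build_incidence(cc, u)
  folds <- stratified_kfold(u$labels, k = 5, seed = 0)
  f_test <- which(vapply(folds, function(f)
    sentinel_pos %in% f$test$positives, logical(1)))
  fold <- folds[[f_test]]
  w <- weight_hyperedges(hg, fold$train$positives)$w
  expect_identical(w[[1]], 0)  # sentinel weight is zero in this fold
  # and nonzero when its positive is in training
  f_train <- setdiff(seq_len(5), f_test)[1]
  w2 <- weight_hyperedges(hg, folds[[f_train]]$train$positives)$w
  expect_gt(w2[[1]], 0)
})

test_that("cross-validation recovers planted signal without mutating inputs", {
  fx <- small_planted(seed = 5)
  u <- suppressMessages(build_gene_universe(fx$collection, fx$labels))
  hg <- build_incidence(fx$collection, u)
  w_before <- hg$w
  cv <- cross_validate(hg, u$labels,
                       model_config(hidden_dim = 16, epochs = 120, seed = 1),
                       k = 5, seed = 0)
  expect_identical(hg$w, w_before)
  expect_equal(nrow(cv), 5L)
  expect_true(all(cv$auroc >= 0 & cv$auroc <= 1))
  expect_gt(mean(cv$auroc), 0.8)
  fs <- attr(cv, "fold_scores")
  expect_setequal(fs$gene, c(u$labels$positives, u$labels$negatives))
  summ <- summarize_cv(cv)
  expect_true(all(summ$ci_lo <= summ$mean & summ$mean <= summ$ci_hi))
})

test_that("shuffled labels drive cross-validated AUROC to chance", {
  fx <- small_planted(seed = 14)
  u <- suppressMessages(build_gene_universe(fx$collection, fx$labels))
  hg <- build_incidence(fx$collection, u)
  labeled <- c(u$labels$positives, u$labels$negatives)
  n_pos <- length(u$labels$positives)
  cfg <- model_config(hidden_dim = 16, epochs = 120, seed = 1)
  means <- vapply(1:10, function(s) {
    set.seed(s)
    shuffled <- sample(labeled)
    lab <- labeled_genes(shuffled[seq_len(n_pos)], shuffled[-seq_len(n_pos)])
    mean(cross_validate(hg, lab, cfg, k = 5, seed = s)$auroc)
  }, numeric(1))
  expect_gte(mean(means), 0.4)
  expect_lte(mean(means), 0.6)
})

test_that("independent-test AUPRC removes training genes from the pool", {
  scores <- stats::setNames(seq(1, 0, length.out = 100),
                            sprintf("G%03d", 1:100))
  # test set exactly the top-scored genes -> AP = 1
  expect_equal(independent_test_auprc(scores, names(scores)[1:10]), 1)
  # training genes leave the pool (message reports the overlap)
  expect_message(
    v <- independent_test_auprc(scores, names(scores)[1:10],
                                training_labeled = names(scores)[1:5]),
    "removed")
  expect_equal(v, 1)  # remaining positives still top the reduced pool
  expect_error(independent_test_auprc(scores, names(scores)[1:3],
                                      training_labeled = names(scores)[1:3]),
               "no independent-test positives")
})
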