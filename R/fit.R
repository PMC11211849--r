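#' Fit the hypergraph gene-prioritization model
#'
#' The one-stop fitting interface: builds the gene universe and sparse
#' incidence from the supplied gene-set collections, weights each hyperedge
#' by its fraction of known disease genes, trains the residual hypergraph
#' convolutional network on the labeled genes, and scores every gene in
#' the universe.
#'
#' The model is transductive: the fitted object carries a risk score for
#' every universe gene, labeled or not, and `predict()` retrieves them.
#'
#' @param collections A `gene_set_collection` or list of them (see
#'   [read_gmt()]); hyperedges of the model.
#' @param labels A `labeled_genes`: known disease genes (positives) and
#'   curated negatives. Symbols outside the universe are dropped.
#' @param config A [model_config()].
#' @param min_size,max_size,exclude_patterns Gene-set filter applied before
#'   fitting (see [filter_gene_sets()]).
#' @return A `hyperprio` object: list with `scores` (ranked data frame:
#'   gene, score, rank), `model` (`trained_model`), `hypergraph`
#'   (disease-weighted), `universe`, `labels`, `config` and `call`.
#' @seealso [cross_validate()] for leakage-free performance estimation;
#'   [decile_enrichment()], [fisher_enrichment()] and
#'   [interaction_permutation_test()] for characterizing a ranking.
#' @export
#' @examples
#' fx <- generate_fixture(synthetic_config(n_genes = 120, n_positives = 20,
#'   n_negatives = 40, n_disease_sets = 8, n_background_sets = 12,
#'   set_size_range = c(5, 15), seed = 1))
#' fit <- hyperprio(fx$collection, fx$labels,
#'   config = model_config(hidden_dim = 16, epochs = 30, seed = 1))
#' head(predict(fit))
hyperprio <- function(collections, labels, config = model_config(),
                      min_size = 2L, max_size = Inf,
                      exclude_patterns = character()) {
  cl <- match.call()
  collections <- as_collection_list(collections)
  collections <- lapply(collections, filter_gene_sets, min_size = min_size,
                        max_size = max_size,
                        exclude_patterns = exclude_patterns)
  universe <- build_gene_universe(collections, labels)
  hg <- build_incidence(collections, universe)
  hg_w <- weight_hyperedges(hg, universe$labels$positives)
  A <- build_propagation_operator(hg_w)
  model <- train_model(hg_w, universe$labels, config, A = A)
  scores <- predict_scores(model, hg_w, A = A)
  structure(list(scores = scores, model = model, hypergraph = hg_w,
                 universe = universe, labels = universe$labels,
                 config = config, call = cl),
            class = "hyperprio")
}

#' @export
print.hyperprio <- function(x, ...) {
  cat("Hypergraph gene-prioritization fit\n")
  cat("  genes:", length(x$universe$symbols),
      "| hyperedges:", ncol(x$hypergraph$H), "\n")
  cat("  labeled:", length(x$labels$positives), "positives /",
      length(x$labels$negatives), "negatives\n")
  cat("  final training loss:",
      signif(utils::tail(x$model$loss_trace, 1), 4),
      "after", length(x$model$loss_trace), "epochs\n")
  cat("  top genes:", paste(utils::head(x$scores$gene, 5), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
summary.hyperprio <- function(object, ...) {
  s <- object$scores
  pos <- s$gene %in% object$labels$positives
  neg <- s$gene %in% object$labels$negatives
  lab <- s$score[pos | neg]
  y <- as.integer(s$gene[pos | neg] %in% object$labels$positives)
  out <- list(
    n_genes = nrow(s),
    n_edges = ncol(object$hypergraph$H),
    n_pos = sum(pos), n_neg = sum(neg),
    loss = utils::tail(object$model$loss_trace, 1),
    epochs = length(object$model$loss_trace),
    train_auroc = auroc(lab, y),
    train_auprc = auprc(lab, y),
    score_quartiles = stats::quantile(s$score),
    top = utils::head(s, 10L))
  class(out) <- "summary.hyperprio"
  out
}

#' @export
print.summary.hyperprio <- function(x, ...) {
  cat("Hypergraph gene-prioritization fit:", x$n_genes, "genes,",
      x$n_edges, "hyperedges\n")
  cat("Training labels:", x$n_pos, "positives,", x$n_neg, "negatives\n")
  cat(sprintf("Final loss %.4f after %d epochs\n", x$loss, x$epochs))
  cat(sprintf("Apparent (training) AUROC %.3f, AUPRC %.3f\n",
              x$train_auroc, x$train_auprc))
  cat("Risk-score quartiles:\n")
  print(signif(x$score_quartiles, 3))
  cat("Top-ranked genes:\n")
  print(x$top, row.names = FALSE)
  invisible(x)
}

#' Extract per-gene risk scores
#'
#' @param object A `hyperprio` fit.
#' @param newdata Optional character vector of gene symbols; defaults to
#'   the full ranked universe. Genes outside the universe get `NA`.
#' @param ... Unused.
#' @return If `newdata` is `NULL`, the ranked score data frame; otherwise a
#'   named numeric vector of scores for the requested genes.
#' @export
predict.hyperprio <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$scores)
  newdata <- toupper(newdata)
  idx <- match(newdata, object$scores$gene)
  stats::setNames(object$scores$score[idx], newdata)
}

#' Model coefficients: the learned parameter matrices
#'
#' @param object A `hyperprio` fit.
#' @param ... Unused.
#' @return List with `input_fc` (gene embeddings), `residual_thetas`,
#'   `output_fc` and `output_bias`.
#' @export
coef.hyperprio <- function(object, ...) object$model$params

#' Residuals on the labeled genes
#'
#' Response residuals: observed class (1 = disease gene) minus fitted risk
#' score, for labeled genes only (unlabeled genes have no observed class).
#'
#' @param object A `hyperprio` fit.
#' @param ... Unused.
#' @return Named numeric vector over the labeled genes.
#' @export
residuals.hyperprio <- function(object, ...) {
  s <- stats::setNames(object$scores$score, object$scores$gene)
  genes <- c(object$labels$positives, object$labels$negatives)
  y <- rep(c(1, 0), c(length(object$labels$positives),
                      length(object$labels$negatives)))
  stats::setNames(y - s[genes], genes)
}

#' Diagnostic plots for a fit
#'
#' Left: training loss by epoch. Right: risk-score distributions of the
#' positive, negative and unlabeled genes.
#'
#' @param x A `hyperprio` fit.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.hyperprio <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(x$model$loss_trace, type = "l", xlab = "epoch",
                 ylab = "cross-entropy loss", main = "Training loss", ...)
  s <- stats::setNames(x$scores$score, x$scores$gene)
  groups <- list(
    positive = s[names(s) %in% x$labels$positives],
    negative = s[names(s) %in% x$labels$negatives],
    unlabeled = s[!(names(s) %in% c(x$labels$positives,
                                    x$labels$negatives))])
  graphics::boxplot(groups, ylab = "risk score",
                    main = "Scores by label")
  invisible(x)
}
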