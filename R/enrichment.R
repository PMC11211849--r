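#' One-sided Fisher's exact enrichment of a query list in a target set
#'
#' Builds the 2x2 table over the background (a = query & target, b = query
#' only, c = target only, d = neither) and computes the one-sided
#' ("greater") p-value as the hypergeometric upper tail
#' `P(X >= a)` for `X ~ Hypergeom(|target|, |background| - |target|,
#' |query|)`, plus the sample odds ratio `ad / bc` (`Inf` allowed; `NaN`
#' for the degenerate 0/0 case).
#'
#' @param query,target Character vectors of gene symbols; both are
#'   restricted to the background.
#' @param background Character vector: the gene universe for the test.
#' @return List with `odds_ratio`, `p_value` and `table` (a, b, c, d).
#' @export
fisher_enrichment <- function(query, target, background) {
  background <- unique(toupper(background))
  if (length(background) == 0L) stop("empty background")
  query <- intersect(unique(toupper(query)), background)
  target <- intersect(unique(toupper(target)), background)
  a <- length(intersect(query, target))
  b <- length(query) - a
  c_ <- length(target) - a
  d <- length(background) - a - b - c_
  # P(X >= a), X ~ Hypergeometric(white = |target|, black = rest, drawn = |query|)
  p <- stats::phyper(a - 1L, a + c_, b + d, a + b, lower.tail = FALSE)
  or <- (a * d) / (b * c_)
  list(odds_ratio = or, p_value = p,
       table = c(a = a, b = b, c = c_, d = d))
}

#' Decile enrichment of an annotated gene set along a ranking
#'
#' Splits the ranking into 10 contiguous blocks (first decile = top ranks;
#' when the length is not divisible by 10 the remainder genes are assigned
#' one per decile from the top) and reports, per decile, the fraction of
#' its genes that are annotated and the one-sided hypergeometric p-value
#' for over-representation relative to the whole ranking, with
#' Benjamini-Hochberg adjustment across the 10 deciles.
#'
#' @param ranking Character vector of genes in rank order (best first).
#' @param annotated Character vector: the annotated gene set (e.g. an
#'   external disease-gene catalogue); must intersect the ranking.
#' @return Data frame with `decile`, `n`, `n_annotated`, `fraction`,
#'   `p_value`, `q_value`.
#' @export
decile_enrichment <- function(ranking, annotated) {
  ranking <- toupper(ranking)
  annotated <- unique(toupper(annotated))
  stopifnot(length(ranking) > 0L, !anyDuplicated(ranking))
  n <- length(ranking)
  hits <- ranking %in% annotated
  K <- sum(hits)
  if (K == 0L) stop("annotated set is disjoint from the ranking")
  base_size <- n %/% 10L
  extra <- n %% 10L
  sizes <- rep(base_size, 10L) + c(rep(1L, extra), rep(0L, 10L - extra))
  ends <- cumsum(sizes)
  starts <- ends - sizes + 1L
  k <- vapply(seq_len(10L), function(dd)
    sum(hits[seq.int(starts[dd], ends[dd])]), integer(1))
  p <- stats::phyper(k - 1L, K, n - K, sizes, lower.tail = FALSE)
  data.frame(decile = 1:10, n = sizes, n_annotated = k,
             fraction = k / sizes, p_value = p,
             q_value = stats::p.adjust(p, method = "BH"))
}

#' Top-k predicted genes after exclusions
#'
#' The first `k` genes of a ranking after removing an exclusion list
#' (typically the known disease genes used for training), preserving rank
#' order.
#'
#' @param ranking Character vector in rank order.
#' @param k Number of genes to return.
#' @param exclude Character vector of genes to skip.
#' @return Character vector of length `k`.
#' @export
top_k_predicted <- function(ranking, k, exclude = character()) {
  ranking <- toupper(ranking)
  exclude <- unique(toupper(exclude))
  pool <- ranking[!ranking %in% exclude]
  if (k > length(pool)) {
    stop("requested top ", k, " but only ", length(pool),
         " genes remain after exclusion")
  }
  pool[seq_len(k)]
}

#' Permutation test for interactions between two gene sets
#'
#' Counts network edges with one endpoint in `query` and the other in
#' `reference`, and compares against a null distribution obtained by
#' redrawing `query`-sized gene sets uniformly from the network's nodes
#' excluding `reference`. The empirical p-value uses the add-one estimator
#' `(1 + #\{null >= observed\}) / (1 + n_perm)`, so it is never below
#' `1 / (1 + n_perm)`.
#'
#' @param edges An `edge_list`.
#' @param query Character vector (e.g. newly predicted genes); any overlap
#'   with `reference` is removed first (with a message).
#' @param reference Character vector (e.g. known disease genes).
#' @param n_perm Number of permutations (>= 100).
#' @param seed Integer seed.
#' @return List with `observed`, `p_value`, `null_mean`, `null_sd`,
#'   `null_quantiles` and `n_perm`.
#' @export
interaction_permutation_test <- function(edges, query, reference,
                                         n_perm = 1000L, seed = 0L) {
  stopifnot(inherits(edges, "edge_list"), n_perm >= 100L)
  query <- unique(toupper(query))
  reference <- unique(toupper(reference))
  overlap <- intersect(query, reference)
  if (length(overlap)) {
    message(length(overlap), " query gene(s) also in reference; removed")
    query <- setdiff(query, reference)
  }
  nodes <- unique(c(edges[, 1L], edges[, 2L]))
  candidates <- setdiff(nodes, reference)
  if (length(candidates) < length(query)) {
    stop("network has only ", length(candidates),
         " non-reference nodes; cannot draw sets of size ", length(query))
  }
  in_ref_1 <- edges[, 1L] %in% reference
  in_ref_2 <- edges[, 2L] %in% reference
  count_cross <- function(q) {
    q1 <- edges[, 1L] %in% q
    q2 <- edges[, 2L] %in% q
    sum((q1 & in_ref_2) | (q2 & in_ref_1))
  }
  observed <- count_cross(query)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  null <- vapply(seq_len(n_perm), function(i)
    count_cross(sample(candidates, length(query))), numeric(1))
  list(observed = observed,
       p_value = (1 + sum(null >= observed)) / (1 + n_perm),
       null_mean = mean(null), null_sd = stats::sd(null),
       null_quantiles = stats::quantile(null, c(0.025, 0.5, 0.975)),
       n_perm = as.integer(n_perm))
}

#' Hub genes of a network
#'
#' Genes in the top fraction of the network degree distribution (degree =
#' number of distinct interaction partners).
#'
#' @param edges An `edge_list`.
#' @param top_frac Fraction of nodes to call hubs (default 0.05).
#' @return Character vector of hub gene symbols.
#' @export
hub_genes <- function(edges, top_frac = 0.05) {
  stopifnot(inherits(edges, "edge_list"), top_frac > 0, top_frac <= 1)
  deg <- table(c(edges[, 1L], edges[, 2L]))
  n_hub <- max(1L, floor(length(deg) * top_frac))
  names(sort(deg, decreasing = TRUE))[seq_len(n_hub)]
}
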