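#' Build the sparse gene-by-set incidence structure
#'
#' Constructs the n x m binary incidence matrix H of the hypergraph in which
#' the n universe genes are nodes and the m gene sets (concatenated across
#' collections, in input order) are hyperedges: `H[a, b] = 1` iff gene a
#' belongs to set b. Hyperedge weights are initialized to one.
#'
#' @param collections A `gene_set_collection` or list of them.
#' @param universe A `gene_universe` from [build_gene_universe()]; every set
#'   member must be in it.
#' @return A `hypergraph`: list with `H` (sparse dgCMatrix, n x m), `w`
#'   (length-m weight vector, all ones), `edge_names`, `edge_sizes` and
#'   `universe`.
#' @export
build_incidence <- function(collections, universe) {
  collections <- as_collection_list(collections)
  stopifnot(inherits(universe, "gene_universe"))
  symbols <- universe$symbols
  sets <- unlist(lapply(collections, unclass), recursive = FALSE)
  edge_names <- vapply(sets, `[[`, character(1), "name")
  member_idx <- lapply(sets, function(s) {
    i <- match(s$members, symbols)
    if (anyNA(i)) {
      stop("gene set '", s$name, "' has members outside the universe: ",
           paste(utils::head(s$members[is.na(i)], 5), collapse = ", "),
           " (was the universe built from different collections?)")
    }
    i
  })
  m <- length(sets)
  n <- length(symbols)
  H <- Matrix::sparseMatrix(
    i = unlist(member_idx, use.names = FALSE),
    j = rep.int(seq_len(m), lengths(member_idx)),
    x = 1, dims = c(n, m),
    dimnames = list(symbols, NULL)
  )
  structure(list(H = H, w = rep(1, m), edge_names = edge_names,
                 edge_sizes = lengths(member_idx), universe = universe),
            class = "hypergraph")
}

#' @export
print.hypergraph <- function(x, ...) {
  cat("hypergraph:", nrow(x$H), "genes x", ncol(x$H), "hyperedges,",
      length(x$H@x), "incidences; weights in [",
      signif(min(x$w), 3), ",", signif(max(x$w), 3), "]\n")
  invisible(x)
}

#' Disease-specific hyperedge weighting
#'
#' Sets the weight of each hyperedge to the fraction of its member genes
#' that are known disease genes:
#' `w_i = |members_i intersect positives| / |members_i|`.
#' Hyperedges with no positive member get weight 0 (and are kept); a set of
#' all positives gets weight 1. The input hypergraph is not mutated.
#'
#' In cross-validation this must be called with the training-fold positives
#' only, so no test-set label information leaks into the weights
#' ([cross_validate()] does this per fold).
#'
#' @param hg A `hypergraph`.
#' @param positives Character vector of positive gene symbols (symbols
#'   outside the universe are ignored).
#' @return A new `hypergraph` with updated `w`.
#' @export
weight_hyperedges <- function(hg, positives) {
  stopifnot(inherits(hg, "hypergraph"))
  pos_idx <- match(unique(toupper(positives)), hg$universe$symbols)
  pos_idx <- pos_idx[!is.na(pos_idx)]
  ind <- logical(nrow(hg$H))
  ind[pos_idx] <- TRUE
  # column sums of H restricted to positive rows, over set sizes
  pos_per_edge <- as.numeric(Matrix::crossprod(hg$H, ind))
  hg$w <- pos_per_edge / hg$edge_sizes
  hg
}

#' Node and hyperedge degrees
#'
#' The weighted node degree is `d(v) = sum_e w(e) H(v, e)`; the hyperedge
#' degree is its member count `delta(e) = sum_v H(v, e)`.
#'
#' @param hg A `hypergraph`.
#' @return List with `node` (length-n, named by gene) and `edge` (length-m).
#' @export
compute_degrees <- function(hg) {
  stopifnot(inherits(hg, "hypergraph"))
  node <- as.numeric(hg$H %*% hg$w)
  names(node) <- hg$universe$symbols
  list(node = node, edge = as.numeric(Matrix::colSums(hg$H)))
}

#' Weighted-degree baseline score
#'
#' Ranks genes by their weighted node degree in the disease-weighted
#' hypergraph — the natural propagation-free baseline for the learned model.
#'
#' @param hg A weighted `hypergraph` (see [weight_hyperedges()]).
#' @return Named numeric vector of per-gene scores.
#' @export
weighted_degree_baseline <- function(hg) {
  compute_degrees(hg)$node
}

#' Normalized hypergraph propagation operator
#'
#' Assembles the symmetric n x n operator
#' `A = Dv^{-1/2} H W De^{-1} H^T Dv^{-1/2}`
#' used by the residual convolution layers, with the pseudo-inverse
#' convention `0^{-1/2} := 0` and `0^{-1} := 0`: genes whose weighted degree
#' is zero (no membership in any positively weighted set) get all-zero rows
#' and columns and are flagged in `isolated`.
#'
#' @param hg A `hypergraph` (weighted or unweighted).
#' @return A `propagation_operator`: list with `A` (sparse symmetric
#'   dgCMatrix), its bipartite factor `B` (n x m, with `A = B B^T`; used to
#'   apply the operator as the cheap two-stage genes-to-sets-to-genes
#'   product) and `isolated` (logical length-n).
#' @export
build_propagation_operator <- function(hg) {
  stopifnot(inherits(hg, "hypergraph"))
  deg <- compute_degrees(hg)
  if (all(deg$node == 0)) {
    stop("hypergraph disconnected from labels - all hyperedge weights zero")
  }
  dv_inv_sqrt <- ifelse(deg$node > 0, 1 / sqrt(deg$node), 0)
  de_inv <- ifelse(deg$edge > 0, 1 / deg$edge, 0)
  # B = Dv^{-1/2} H (W De^{-1})^{1/2}; A = B B^T keeps exact symmetry
  col_scale <- sqrt(hg$w * de_inv)
  B <- hg$H
  B@x <- B@x * dv_inv_sqrt[B@i + 1L] *
    col_scale[rep.int(seq_len(ncol(B)), diff(B@p))]
  A <- Matrix::tcrossprod(B)
  A <- methods::as(A, "generalMatrix")
  structure(list(A = A, B = B, isolated = deg$node == 0),
            class = "propagation_operator")
}

#' @export
print.propagation_operator <- function(x, ...) {
  cat("propagation_operator:", nrow(x$A), "x", ncol(x$A),
      "sparse symmetric,", length(x$A@x), "nonzeros,",
      sum(x$isolated), "isolated genes\n")
  invisible(x)
}
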