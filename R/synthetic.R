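#' Configuration for the planted-structure synthetic benchmark
#'
#' The generator emulates the premise that disease genes cluster in a
#' subset of functional gene sets: "disease" sets draw each member from the
#' positive pool with elevated probability `p_pos_in_disease`, while
#' "background" sets draw positives at roughly their prevalence. Defaults
#' give 1000 genes (100 positives, 300 negatives), 40 disease sets and 160
#' background sets of size 10-50.
#'
#' @param n_genes,n_positives,n_negatives Universe and label sizes.
#' @param n_disease_sets,n_background_sets Hyperedge counts per stratum.
#' @param set_size_range Length-2 integer vector: inclusive set-size bounds.
#' @param p_pos_in_disease Probability that a disease-set member is drawn
#'   from the positives.
#' @param p_pos_in_background Same for background sets (default matches the
#'   positive prevalence).
#' @param seed Integer seed.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_genes = 1000L, n_positives = 100L,
                             n_negatives = 300L, n_disease_sets = 40L,
                             n_background_sets = 160L,
                             set_size_range = c(10L, 50L),
                             p_pos_in_disease = 0.6,
                             p_pos_in_background = 0.1,
                             seed = 0L) {
  stopifnot(n_positives + n_negatives <= n_genes,
            p_pos_in_disease >= 0, p_pos_in_disease <= 1,
            p_pos_in_background >= 0, p_pos_in_background <= 1,
            length(set_size_range) == 2L,
            set_size_range[1] >= 2L,
            set_size_range[2] >= set_size_range[1],
            set_size_range[2] <= n_genes)
  structure(list(n_genes = as.integer(n_genes),
                 n_positives = as.integer(n_positives),
                 n_negatives = as.integer(n_negatives),
                 n_disease_sets = as.integer(n_disease_sets),
                 n_background_sets = as.integer(n_background_sets),
                 set_size_range = as.integer(set_size_range),
                 p_pos_in_disease = p_pos_in_disease,
                 p_pos_in_background = p_pos_in_background,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Generate a planted-structure gene-set fixture
#'
#' Produces a gene-set collection and labels with known signal: members of
#' disease sets are drawn from the positive pool with probability
#' `p_pos_in_disease` (else uniformly from the remaining genes), background
#' sets use `p_pos_in_background`. Gene symbols are `G000000`-style, so
#' fixtures can never be mistaken for real gene lists. Deterministic given
#' `cfg$seed`.
#'
#' @param cfg A [synthetic_config()].
#' @param dir Optional directory; when given, writes `sets.gmt`,
#'   `positives.txt`, `negatives.txt` and `manifest.json` there.
#' @return List with `collection` (`gene_set_collection`), `labels`
#'   (`labeled_genes`) and `manifest` (the config plus bookkeeping).
#' @export
generate_fixture <- function(cfg = synthetic_config(), dir = NULL) {
  stopifnot(inherits(cfg, "synthetic_config"))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(cfg$seed)
  genes <- sprintf("G%06d", seq_len(cfg$n_genes) - 1L)
  positives <- genes[seq_len(cfg$n_positives)]
  negatives <- genes[cfg$n_positives + seq_len(cfg$n_negatives)]
  others <- setdiff(genes, positives)

  draw_set <- function(size, p_pos) {
    # draw without replacement, respecting the expected positive fraction
    n_pos <- stats::rbinom(1L, size, p_pos)
    n_pos <- min(n_pos, length(positives))
    c(sample(positives, n_pos), sample(others, size - n_pos))
  }
  sizes <- sample(seq.int(cfg$set_size_range[1], cfg$set_size_range[2]),
                  cfg$n_disease_sets + cfg$n_background_sets, replace = TRUE)
  n_total <- cfg$n_disease_sets + cfg$n_background_sets
  sets <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    disease <- i <= cfg$n_disease_sets
    p <- if (disease) cfg$p_pos_in_disease else cfg$p_pos_in_background
    tag <- if (disease) "DISEASE" else "BACKGROUND"
    sets[[i]] <- list(
      name = sprintf("%s_SET_%03d", tag, i),
      description = sprintf("synthetic %s set", tolower(tag)),
      members = draw_set(sizes[[i]], p))
  }
  collection <- new_gene_set_collection(sets, "synthetic")
  labels <- labeled_genes(positives, negatives)
  manifest <- c(unclass(cfg),
                list(null = cfg$p_pos_in_disease == cfg$p_pos_in_background,
                     n_sets = n_total))
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_gmt(collection, file.path(dir, "sets.gmt"))
    writeLines(positives, file.path(dir, "positives.txt"))
    writeLines(negatives, file.path(dir, "negatives.txt"))
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  list(collection = collection, labels = labels, manifest = manifest)
}

#' Generate a matched null fixture (no planted signal)
#'
#' Identical to [generate_fixture()] except that disease sets draw
#' positives at the same rate as background sets, so rankings should be no
#' better than chance.
#'
#' @param cfg A [synthetic_config()].
#' @param dir Optional output directory.
#' @return As [generate_fixture()]; `manifest$null` is `TRUE`.
#' @export
generate_null_fixture <- function(cfg = synthetic_config(), dir = NULL) {
  cfg$p_pos_in_disease <- cfg$p_pos_in_background
  generate_fixture(cfg, dir)
}

#' Generate a synthetic protein-interaction network
#'
#' Erdos-Renyi-style edges with elevated density inside the positive set:
#' each positive-positive pair is an edge with probability `p_within`,
#' every other pair with `p_between`.
#'
#' @param positives Character vector of genes forming the dense block.
#' @param all_genes Character vector: all network genes.
#' @param p_within,p_between Edge probabilities (`p_within >= p_between`).
#' @param seed Integer seed.
#' @return An `edge_list`.
#' @export
generate_ppi <- function(positives, all_genes, p_within = 0.05,
                         p_between = 0.005, seed = 0L) {
  stopifnot(p_within >= p_between, p_within <= 1, p_between >= 0)
  all_genes <- unique(toupper(all_genes))
  positives <- intersect(unique(toupper(positives)), all_genes)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  n <- length(all_genes)
  pair_i <- rep(seq_len(n - 1L), times = (n - 1L):1L)
  pair_j <- sequence((n - 1L):1L, from = 2:n)
  is_pos <- all_genes %in% positives
  within <- is_pos[pair_i] & is_pos[pair_j]
  p <- ifelse(within, p_within, p_between)
  keep <- stats::runif(length(p)) < p
  edge_list(all_genes[pair_i[keep]], all_genes[pair_j[keep]])
}
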