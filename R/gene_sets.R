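#' Read a gene-set collection from a GMT file
#'
#' Parses the tab-separated GMT interchange format (one gene set per line:
#' set name, description, then one or more member gene symbols). Member
#' symbols are uppercased and de-duplicated; line order is preserved and
#' defines the hyperedge index of the collection.
#'
#' @param path Path to a GMT file (UTF-8).
#' @param source_tag Label recorded on the collection (e.g. `"pathways"`,
#'   `"GO"`); defaults to the file name.
#' @return A `gene_set_collection`: a list with elements `name`,
#'   `description` and `members` per set, plus a `source_tag` attribute.
#' @export
#' @examples
#' tmp <- tempfile(fileext = ".gmt")
#' writeLines("SETA\tdesc\tTP53\tKRAS", tmp)
#' read_gmt(tmp)
read_gmt <- function(path, source_tag = basename(path)) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("GMT file is empty: ", path)
  sets <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L) {
      stop("malformed GMT line ", i, " in ", path,
           ": expected >= 3 tab-separated fields, got ", length(fields))
    }
    members <- unique(toupper(fields[-(1:2)]))
    members <- members[nzchar(members)]
    if (length(members) == 0L) {
      stop("malformed GMT line ", i, " in ", path, ": no member symbols")
    }
    sets[[i]] <- list(name = fields[[1]], description = fields[[2]],
                      members = members)
  }
  nm <- vapply(sets, `[[`, character(1), "name")
  if (anyDuplicated(nm)) {
    stop("duplicate gene-set name(s) in ", path, ": ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  new_gene_set_collection(sets, source_tag)
}

new_gene_set_collection <- function(sets, source_tag = "") {
  structure(sets, source_tag = source_tag, class = "gene_set_collection")
}

#' Write a gene-set collection to a GMT file
#'
#' Inverse of [read_gmt()]: `read_gmt(write_gmt(x, path))` reproduces `x`
#' exactly (members are already uppercase and unique in a valid collection).
#'
#' @param collection A `gene_set_collection`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  lines <- vapply(collection, function(s) {
    paste(c(s$name, s$description, s$members), collapse = "\t")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @export
print.gene_set_collection <- function(x, ...) {
  sizes <- vapply(x, function(s) length(s$members), integer(1))
  cat("gene_set_collection '", attr(x, "source_tag"), "': ", length(x),
      " sets, sizes ", if (length(x)) min(sizes) else 0, "-",
      if (length(x)) max(sizes) else 0, ", ",
      length(unique(unlist(lapply(x, `[[`, "members")))),
      " distinct genes\n", sep = "")
  invisible(x)
}

#' Filter a gene-set collection by size and name patterns
#'
#' Keeps sets whose member count lies in `[min_size, max_size]` and whose
#' name matches none of `exclude_patterns` (case-insensitive substring
#' match). Used to drop sets annotated directly with the disease of interest
#' so that evaluation is not circular, and to drop uninformative singleton
#' or huge sets. Set order is preserved.
#'
#' @param collection A `gene_set_collection`.
#' @param min_size,max_size Inclusive bounds on set size. Defaults 2 and
#'   `Inf`: a singleton hyperedge carries no gene-gene association.
#' @param exclude_patterns Character vector of substrings; any set whose
#'   name contains one (ignoring case) is removed.
#' @return The filtered `gene_set_collection`.
#' @export
filter_gene_sets <- function(collection, min_size = 2L, max_size = Inf,
                             exclude_patterns = character()) {
  stopifnot(inherits(collection, "gene_set_collection"),
            min_size >= 1L, max_size >= min_size)
  keep <- vapply(collection, function(s) {
    n <- length(s$members)
    if (n < min_size || n > max_size) return(FALSE)
    for (p in exclude_patterns) {
      if (grepl(p, s$name, ignore.case = TRUE, fixed = FALSE)) return(FALSE)
    }
    TRUE
  }, logical(1))
  if (!any(keep)) warning("all gene sets removed by filtering")
  new_gene_set_collection(unclass(collection)[keep],
                          attr(collection, "source_tag"))
}

#' Labeled genes: known positives and curated negatives
#'
#' @param positives Character vector of known disease-gene symbols.
#' @param negatives Character vector of negative (neutral) gene symbols.
#' @return A `labeled_genes` object (uppercased, de-duplicated sets).
#' @export
labeled_genes <- function(positives, negatives) {
  positives <- unique(toupper(as.character(positives)))
  negatives <- unique(toupper(as.character(negatives)))
  overlap <- intersect(positives, negatives)
  if (length(overlap)) {
    stop("genes labeled both positive and negative: ",
         paste(utils::head(overlap, 5), collapse = ", "))
  }
  structure(list(positives = positives, negatives = negatives),
            class = "labeled_genes")
}

#' @export
print.labeled_genes <- function(x, ...) {
  cat("labeled_genes:", length(x$positives), "positives,",
      length(x$negatives), "negatives\n")
  invisible(x)
}

#' Build the gene universe from one or more collections
#'
#' The universe is the union of all set members across the collections, in
#' first-occurrence order (collections in input order, sets in collection
#' order, members in set order), so the symbol-to-index map is reproducible.
#' Labels are restricted to the universe; dropped label symbols are counted
#' in a message.
#'
#' @param collections A `gene_set_collection` or list of them.
#' @param labels Optional `labeled_genes`; restricted to the universe.
#' @return A `gene_universe`: list with `symbols` (ordered character) and,
#'   if `labels` was given, the restricted `labels`.
#' @export
build_gene_universe <- function(collections, labels = NULL) {
  collections <- as_collection_list(collections)
  members <- unlist(lapply(collections, function(cc)
    unlist(lapply(cc, `[[`, "members"), use.names = FALSE)),
    use.names = FALSE)
  symbols <- unique(members)
  if (length(symbols) == 0L) stop("empty gene universe: no set members")
  universe <- structure(list(symbols = symbols), class = "gene_universe")
  if (!is.null(labels)) {
    stopifnot(inherits(labels, "labeled_genes"))
    keep_pos <- labels$positives %in% symbols
    keep_neg <- labels$negatives %in% symbols
    dropped <- sum(!keep_pos) + sum(!keep_neg)
    if (dropped > 0L) {
      message(dropped, " labeled gene(s) absent from every gene set; dropped")
    }
    universe$labels <- labeled_genes(labels$positives[keep_pos],
                                     labels$negatives[keep_neg])
  }
  universe
}

#' @export
print.gene_universe <- function(x, ...) {
  cat("gene_universe:", length(x$symbols), "genes\n")
  if (!is.null(x$labels)) print(x$labels)
  invisible(x)
}

as_collection_list <- function(collections) {
  if (inherits(collections, "gene_set_collection")) {
    collections <- list(collections)
  }
  stopifnot(length(collections) >= 1L,
            all(vapply(collections, inherits, logical(1),
                       "gene_set_collection")))
  collections
}

#' Read a plain-text gene list
#'
#' One symbol per line; lines starting with `#` and blank lines are skipped;
#' symbols are uppercased and de-duplicated.
#'
#' @param path File path.
#' @return Character vector of gene symbols (possibly empty, with a warning).
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) stop("gene list file not found: ", path)
  lines <- trimws(readLines(path, encoding = "UTF-8"))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- unique(toupper(lines))
  if (length(out) == 0L) warning("gene list is empty: ", path)
  out
}

#' Read an undirected edge list (two-column TSV of gene symbols)
#'
#' Self-loops are dropped; duplicate edges (in either orientation) collapse
#' to one. Used for the protein-interaction permutation test.
#'
#' @param path Two-column tab-separated file; `#` comment lines skipped.
#' @return An `edge_list`: two-column character matrix with attributes.
#' @export
read_edge_list <- function(path) {
  if (!file.exists(path)) stop("edge list file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 2L)
  if (length(bad)) stop("malformed edge list line ", bad[[1]], " in ", path)
  a <- toupper(vapply(parts, `[[`, character(1), 1L))
  b <- toupper(vapply(parts, `[[`, character(1), 2L))
  edge_list(a, b)
}

#' Construct an edge list from two endpoint vectors
#'
#' @param a,b Equal-length character vectors of gene symbols.
#' @return An `edge_list` object.
#' @export
edge_list <- function(a, b) {
  stopifnot(length(a) == length(b))
  a <- toupper(as.character(a)); b <- toupper(as.character(b))
  keep <- a != b
  a <- a[keep]; b <- b[keep]
  lo <- pmin(a, b); hi <- pmax(a, b)
  key <- paste(lo, hi, sep = "\r")
  dup <- duplicated(key)
  m <- cbind(from = lo[!dup], to = hi[!dup])
  structure(m, class = c("edge_list", class(m)))
}

#' @export
print.edge_list <- function(x, ...) {
  cat("edge_list:", nrow(x), "undirected edges,",
      length(unique(c(x[, 1], x[, 2]))), "nodes\n")
  invisible(x)
}
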