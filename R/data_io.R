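#' Construct a gene network
#'
#' Builds a simple undirected graph from a two-column edge table. Self-loops
#' and duplicate edges are dropped (and counted in a message), so the result
#' always satisfies the simple-graph invariants the downstream Markov-chain
#' and transport machinery relies on.
#'
#' @param edges two-column character matrix or data frame, one edge per row.
#' @param nodes optional character vector of node identifiers; defaults to the
#'   identifiers appearing in `edges`. Isolated nodes may be declared here.
#' @return An object of class `gene_network` with elements `nodes` (character),
#'   `edges` (m x 2 integer index matrix with `edges[, 1] < edges[, 2]`) and
#'   `adj` (per-node integer neighbor list).
#' @export
gene_network <- function(edges, nodes = NULL) {
  edges <- as.matrix(edges)
  if (length(edges) && ncol(edges) != 2)
    stopf("edge table must have exactly two columns")
  storage.mode(edges) <- "character"
  edges <- matrix(trimws(edges), ncol = 2)
  if (is.null(nodes)) nodes <- c_sort(unique(as.vector(edges)))
  nodes <- trimws(as.character(nodes))
  if (anyDuplicated(nodes)) stopf("duplicate node identifiers")
  if (length(edges)) {
    unknown <- setdiff(as.vector(edges), nodes)
    if (length(unknown))
      stopf("edge endpoint(s) not among declared nodes: %s",
            paste(head(unknown, 5), collapse = ", "))
  }

  i <- match(edges[, 1], nodes)
  j <- match(edges[, 2], nodes)
  self <- which(i == j)
  if (length(self)) {
    i <- i[-self]; j <- j[-self]
  }
  lo <- pmin(i, j); hi <- pmax(i, j)
  key <- (lo - 1) * length(nodes) + hi
  dup <- duplicated(key)
  n_dup <- sum(dup)
  if (length(self) || n_dup)
    msgf("gene_network: dropped %d self-loop(s) and %d duplicate edge(s)",
         length(self), n_dup)
  lo <- lo[!dup]; hi <- hi[!dup]
  ord <- c_order(lo, hi)
  em <- cbind(lo[ord], hi[ord])

  adj <- vector("list", length(nodes))
  for (v in seq_along(nodes)) adj[[v]] <- integer(0)
  if (nrow(em)) {
    adj <- lapply(seq_along(nodes), function(v)
      sort(c(em[em[, 1] == v, 2], em[em[, 2] == v, 1])))
  }
  structure(list(nodes = nodes, edges = em, adj = adj),
            class = "gene_network")
}

#' @export
print.gene_network <- function(x, ...) {
  cat(sprintf("gene_network: %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

as_igraph <- function(network) {
  el <- cbind(network$nodes[network$edges[, 1]],
              network$nodes[network$edges[, 2]])
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(network$nodes), name = network$nodes)
  if (nrow(network$edges)) g <- igraph::add_edges(g, t(el))
  g
}

#' Read a two-column edge list
#'
#' Reads an HPRD-style tab- (or whitespace-) delimited edge list, one
#' interaction per line, into a [gene_network()]. Self-loops and duplicate
#' edges are dropped and counted.
#'
#' @param path path to the edge-list file.
#' @param sep field separator; default `""` splits on any whitespace.
#' @return A `gene_network`.
#' @export
read_edge_list <- function(path, sep = "") {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stopf("empty edge list: %s", path)
  parts <- if (nzchar(sep)) strsplit(lines, sep, fixed = TRUE)
           else strsplit(trimws(lines), "[ \t]+")
  bad <- which(vapply(parts, length, 1L) != 2)
  if (length(bad))
    stopf("malformed edge list line %d in %s: %s",
          bad[1], path, lines[bad[1]])
  gene_network(do.call(rbind, parts))
}

#' Restrict a network to the largest connected component of a node subset
#'
#' Takes the subgraph induced by `keep` (intersected with the network's nodes)
#' and returns its largest connected component. Component-size ties are broken
#' in favor of the component containing the lexicographically smallest node,
#' so the result is deterministic.
#'
#' @param network a `gene_network`.
#' @param keep character vector of node identifiers to retain; default all.
#' @return A `gene_network` that is a connected induced subgraph of the input.
#' @export
restrict_to_lcc <- function(network, keep = network$nodes) {
  keep <- intersect(trimws(keep), network$nodes)
  if (!length(keep)) stopf("no declared node is in the keep set")
  idx <- match(keep, network$nodes)
  in_keep <- logical(length(network$nodes))
  in_keep[idx] <- TRUE
  sub_edges <- network$edges[in_keep[network$edges[, 1]] &
                             in_keep[network$edges[, 2]], , drop = FALSE]
  # BFS components over the induced subgraph (isolated kept nodes included)
  comp <- rep(NA_integer_, length(network$nodes))
  nc <- 0L
  adj <- vector("list", length(network$nodes))
  if (nrow(sub_edges)) {
    for (e in seq_len(nrow(sub_edges))) {
      a <- sub_edges[e, 1]; b <- sub_edges[e, 2]
      adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
    }
  }
  for (v in idx) {
    if (!is.na(comp[v])) next
    nc <- nc + 1L
    queue <- v; comp[v] <- nc
    while (length(queue)) {
      u <- queue[[1]]; queue <- queue[-1]
      nb <- adj[[u]]
      new <- nb[is.na(comp[nb])]
      comp[new] <- nc
      queue <- c(queue, new)
    }
  }
  sizes <- tabulate(comp[idx], nbins = nc)
  best <- which(sizes == max(sizes))
  if (length(best) > 1) {
    # tie: component whose smallest member sorts first
    mins <- vapply(best, function(cc)
      min(network$nodes[which(comp == cc)]), "")
    best <- best[c_order(mins)[1]]
  }
  members <- network$nodes[which(comp == best)]
  kept_edges <- sub_edges[comp[sub_edges[, 1]] == best, , drop = FALSE]
  gene_network(cbind(network$nodes[kept_edges[, 1]],
                     network$nodes[kept_edges[, 2]]),
               nodes = c_sort(members))
}

read_id_matrix <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stopf("expected an identifier column plus data: %s", path)
  ids <- trimws(as.character(df[[1]]))
  if (anyDuplicated(ids)) stopf("duplicate row identifiers in %s", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  colnames(m) <- trimws(colnames(df)[-1])
  if (anyDuplicated(colnames(m))) stopf("duplicate column identifiers in %s", path)
  m
}

#' Read an expression / response / descriptor table
#'
#' CSV with a header row and the first column holding row identifiers.
#' `read_expression` additionally checks that all values are nonnegative
#' (the mass-action Markov chain requires nonnegative expression).
#'
#' @param path path to a CSV file.
#' @return A numeric matrix with row and column names; missing cells are `NA`.
#' @export
read_expression <- function(path) {
  m <- read_id_matrix(path)
  if (anyNA(m)) stopf("expression matrix contains missing values: %s", path)
  if (any(m < 0)) stopf("expression values must be nonnegative: %s", path)
  m
}

#' @rdname read_expression
#' @export
read_responses <- function(path) read_id_matrix(path)

#' @rdname read_expression
#' @export
read_descriptors <- function(path) read_id_matrix(path)

#' Write a matrix as CSV with an identifier column
#'
#' Inverse of [read_responses()] and friends; `NA` entries are written as
#' empty cells so a read/write round trip preserves the missingness mask.
#'
#' @param m numeric matrix with dimnames.
#' @param path output path.
#' @param id_name header for the identifier column.
#' @export
write_id_matrix <- function(m, path, id_name = "id") {
  # %.17g guarantees a bit-exact double round trip through the text file
  txt <- matrix(ifelse(is.na(m), "", sprintf("%.17g", m)),
                nrow(m), dimnames = dimnames(m))
  df <- data.frame(rownames(m), txt, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- id_name
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' Each line is `set-name<TAB>description<TAB>member1<TAB>member2...`.
#'
#' @param path path to a GMT file.
#' @return Named list of character vectors (the member genes).
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stopf("empty gene-set file: %s", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, 1L) < 3)
  if (length(bad)) stopf("malformed GMT line %d in %s", bad[1], path)
  sets <- lapply(parts, function(p) unique(trimws(p[-c(1, 2)])))
  names(sets) <- vapply(parts, `[[`, "", 1)
  sets
}

#' Drop cell lines with excessive missing response data
#'
#' Removes rows of a log(IC50) response table whose fraction of missing drugs
#' is strictly greater than `max_missing_frac`.
#'
#' @param responses cell-line x drug numeric matrix, `NA` = unmeasured.
#' @param max_missing_frac maximum tolerated missing fraction (default 0.8).
#' @return The filtered response matrix.
#' @export
filter_cell_lines <- function(responses, max_missing_frac = 0.8) {
  stopifnot(is.matrix(responses), max_missing_frac > 0, max_missing_frac <= 1)
  miss <- rowMeans(is.na(responses))
  keep <- miss <= max_missing_frac
  if (!any(keep)) stopf("all cell lines exceed the missingness threshold")
  if (any(!keep))
    msgf("filter_cell_lines: removed %d of %d cell line(s)",
         sum(!keep), nrow(responses))
  responses[keep, , drop = FALSE]
}

#' Keep drugs measured on more than a fraction of cell lines
#'
#' Retains columns whose observed fraction is strictly greater than
#' `min_coverage_frac`.
#'
#' @inheritParams filter_cell_lines
#' @param min_coverage_frac minimum observed fraction (default 0.5).
#' @export
filter_drugs <- function(responses, min_coverage_frac = 0.5) {
  stopifnot(is.matrix(responses), min_coverage_frac > 0, min_coverage_frac <= 1)
  cover <- colMeans(!is.na(responses))
  keep <- cover > min_coverage_frac
  if (!any(keep)) stopf("no drug passes the coverage threshold")
  if (any(!keep))
    msgf("filter_drugs: removed %d of %d drug(s)",
         sum(!keep), ncol(responses))
  responses[, keep, drop = FALSE]
}
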