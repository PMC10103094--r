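#' Generate a synthetic medical-concept ontology
#'
#' Builds a connected concept graph that stands in for a clinical
#' terminology's parent--child relation structure: a rooted `branching`-ary
#' tree over `n_codes` concept codes, plus a small number of random
#' cross-links (5\% of the tree edge count) emulating lateral
#' "related-to" relations. The first tree level below the root plays the
#' role of class-level concepts.
#'
#' @param n_codes Number of concept codes (nodes); at least 50.
#' @param branching Tree branching factor; at least 2.
#' @param seed Integer seed; the graph is fully determined by it.
#' @param cross_link_frac Fraction of tree edges added as random
#'   cross-links (default 0.05).
#' @return An object of class `concept_graph`: a list with `nodes`
#'   (character codes), `edges` (two-column data frame of undirected
#'   edges), `roots` (class-level codes) and `graph` (the underlying
#'   [igraph::graph] object).
#' @examples
#' g <- generate_ontology(50, branching = 2, seed = 1)
#' length(g$nodes)
#' @export
generate_ontology <- function(n_codes, branching = 3, seed = 1,
                              cross_link_frac = 0.05) {
  if (n_codes < 50) {
    stop("n_codes must be at least 50 to give the embedding a usable ",
         "vocabulary (got ", n_codes, ")")
  }
  if (branching < 2) stop("branching must be at least 2")
  set.seed(seed)

  nodes <- sprintf("C%05d", seq_len(n_codes))
  # complete branching-ary tree: node i (i > 1) hangs off ((i - 2) %/% b) + 1
  child <- 2:n_codes
  parent <- ((child - 2L) %/% branching) + 1L
  tree_edges <- cbind(parent, child)

  n_cross <- round(cross_link_frac * nrow(tree_edges))
  cross <- matrix(integer(0), ncol = 2)
  if (n_cross > 0) {
    existing <- paste(tree_edges[, 1], tree_edges[, 2])
    picked <- character(0)
    out <- matrix(0L, nrow = n_cross, ncol = 2)
    got <- 0L
    while (got < n_cross) {
      a <- sample.int(n_codes, 1L)
      b <- sample.int(n_codes, 1L)
      if (a == b) next
      key <- paste(min(a, b), max(a, b))
      if (key %in% existing || key %in% picked) next
      got <- got + 1L
      out[got, ] <- c(min(a, b), max(a, b))
      picked <- c(picked, key)
    }
    cross <- out
  }

  all_edges <- rbind(tree_edges, cross)
  g <- igraph::graph_from_edgelist(all_edges, directed = FALSE)
  igraph::V(g)$name <- nodes

  structure(
    list(
      nodes = nodes,
      edges = data.frame(from = nodes[all_edges[, 1]],
                         to = nodes[all_edges[, 2]],
                         stringsAsFactors = FALSE),
      n_tree_edges = nrow(tree_edges),
      roots = nodes[2:(1L + min(branching, n_codes - 1L))],
      graph = g
    ),
    class = "concept_graph"
  )
}

#' @export
print.concept_graph <- function(x, ...) {
  cat("<concept_graph> ", length(x$nodes), " codes, ",
      nrow(x$edges), " edges (", nrow(x$edges) - x$n_tree_edges,
      " cross-links)\n", sep = "")
  invisible(x)
}

#' Write / read a concept graph edge list
#'
#' Plain two-column tab-separated edge list; node set is recovered from
#' the edges (the graph is connected by construction).
#'
#' @param graph A `concept_graph`.
#' @param path File path.
#' @export
write_ontology <- function(graph, path) {
  utils::write.table(graph$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_ontology
#' @export
read_ontology <- function(path) {
  ed <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(ed, directed = FALSE)
  nodes <- igraph::V(g)$name
  structure(
    list(nodes = nodes, edges = ed, n_tree_edges = NA_integer_,
         roots = character(0), graph = g),
    class = "concept_graph"
  )
}

# uniform random walks over the graph; returns a list of integer vectors
# (1-based node indices, aligned with graph$nodes)
concept_walks <- function(graph, n_walks, walk_len, seed) {
  set.seed(seed)
  adj <- igraph::as_adj_list(graph$graph, mode = "all")
  adj <- lapply(adj, as.integer)
  n <- length(adj)
  walks <- vector("list", n * n_walks)
  k <- 0L
  for (r in seq_len(n_walks)) {
    starts <- sample.int(n)  # one walk per node, shuffled order
    for (s in starts) {
      w <- integer(walk_len)
      w[1] <- s
      cur <- s
      for (t in 2:walk_len) {
        nb <- adj[[cur]]
        cur <- nb[sample.int(length(nb), 1L)]
        w[t] <- cur
      }
      k <- k + 1L
      walks[[k]] <- w
    }
  }
  walks
}

#' Train concept embeddings on the ontology graph
#'
#' Learns one fixed-length vector per concept code from uniform random
#' walks over the graph, trained with skip-gram and negative sampling
#' (the p = q = 1 special case of node2vec). Training is single-threaded
#' so a fixed seed yields an identical table.
#'
#' @param graph A connected `concept_graph`.
#' @param dim Embedding dimension (default 128, the dimension of the
#'   pretrained clinical-concept embeddings the averaging representation
#'   was designed for).
#' @param walk_len Length of each random walk.
#' @param n_walks Walks started per node.
#' @param window Skip-gram context window half-width.
#' @param seed Integer seed covering both walk generation and SGD.
#' @param negative Negative samples per positive pair.
#' @param epochs Passes over the walk corpus.
#' @param alpha Initial SGD learning rate.
#' @return A numeric matrix with one row per code (rownames are the
#'   concept codes) and `dim` columns; class `embedding_table`.
#' @export
train_embeddings <- function(graph, dim = 128, walk_len = 40, n_walks = 10,
                             window = 5, seed = 1, negative = 5,
                             epochs = 3, alpha = 0.025) {
  if (dim < 2) stop("dim must be at least 2")
  if (!igraph::is_connected(graph$graph)) {
    stop("graph is disconnected: random walks cannot cover the vocabulary")
  }
  walks <- concept_walks(graph, n_walks = n_walks, walk_len = walk_len,
                         seed = seed)
  emb <- sgns_train(walks, vocab_size = length(graph$nodes), dim = dim,
                    window = window, negative = negative, alpha = alpha,
                    epochs = epochs, seed = seed)
  rownames(emb) <- graph$nodes
  class(emb) <- c("embedding_table", class(emb))
  emb
}

#' Write / read an embedding table
#'
#' Headerless whitespace-delimited text: one row per code, `code v1 .. vd`
#' (the word2vec text interchange layout, without the count header line).
#'
#' @param table An `embedding_table` (matrix with code rownames).
#' @param path File path.
#' @export
write_embeddings <- function(table, path) {
  df <- data.frame(code = rownames(table), unclass(table)[, , drop = FALSE])
  utils::write.table(df, path, sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_embeddings
#' @export
read_embeddings <- function(path) {
  df <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  emb <- as.matrix(df[, -1, drop = FALSE])
  rownames(emb) <- df[[1]]
  colnames(emb) <- NULL
  class(emb) <- c("embedding_table", class(emb))
  emb
}
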