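# Prior knowledge graph: weighted graph over variant / gene / pathway
# nodes. Variant nodes carry a mutable positive sampling propensity --
# the hypothesis search's learned state.

#' Construct a prior knowledge graph
#'
#' @param nodes data.frame with columns `id`, `kind`
#'   (`"variant"`, `"gene"` or `"pathway"`) and optionally `matched`
#'   (logical, whether a variant node resolves to a dataset variant).
#' @param edges data.frame with columns `from`, `to`, `weight` (>= 0) and
#'   `source` (provenance tag).
#' @param propensity optional named numeric vector of positive sampling
#'   weights for variant nodes; defaults to uniform 1.
#' @return An object of class `prior_graph`.
#' @export
prior_graph <- function(nodes, edges, propensity = NULL) {
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  check_that(all(c("id", "kind") %in% names(nodes)),
             "`nodes` needs columns id, kind")
  check_that(!anyDuplicated(nodes$id), "node ids must be unique")
  check_that(all(nodes$kind %in% c("variant", "gene", "pathway")),
             "node kind must be variant, gene or pathway")
  if (nrow(edges)) {
    check_that(all(c("from", "to", "weight", "source") %in% names(edges)),
               "`edges` needs columns from, to, weight, source")
    check_that(all(edges$weight >= 0), "edge weights must be >= 0")
    check_that(all(c(edges$from, edges$to) %in% nodes$id),
               "edge endpoints must be declared nodes")
  } else {
    edges <- data.frame(from = character(), to = character(),
                        weight = numeric(), source = character(),
                        stringsAsFactors = FALSE)
  }
  if (!"matched" %in% names(nodes)) nodes$matched <- nodes$kind != "variant"
  vids <- nodes$id[nodes$kind == "variant"]
  if (is.null(propensity)) {
    propensity <- stats::setNames(rep(1, length(vids)), vids)
  } else {
    check_that(setequal(names(propensity), vids),
               "propensity names must be the variant node ids")
    propensity <- propensity[vids]
  }
  check_that(all(propensity > 0), "all propensities must be positive")
  structure(
    list(nodes = nodes, edges = edges, propensity = propensity),
    class = "prior_graph"
  )
}

#' @export
print.prior_graph <- function(x, ...) {
  kinds <- table(x$nodes$kind)
  cat(sprintf(
    "<prior_graph> %d nodes (%s); %d edges\n",
    nrow(x$nodes),
    paste(names(kinds), as.integer(kinds), sep = ": ", collapse = ", "),
    nrow(x$edges)
  ))
  invisible(x)
}

#' Read a prior-graph edge list
#'
#' Expects a TSV with header columns `node_a`, `node_b`, `kind_a`,
#' `kind_b`, `weight`, `source`. Variant nodes that do not resolve to a
#' dataset variant are flagged unmatched, not dropped; propensities start
#' uniform.
#'
#' @param path edge-list TSV.
#' @param dataset optional [genotype_dataset()] used to flag variant nodes.
#' @return A [prior_graph()].
#' @export
read_prior_graph <- function(path, dataset = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE,
                          colClasses = c("character", "character", "character",
                                         "character", "numeric", "character"))
  needed <- c("node_a", "node_b", "kind_a", "kind_b", "weight", "source")
  check_that(all(needed %in% names(df)),
             paste("edge list needs columns:", paste(needed, collapse = ", ")))
  if (nrow(df) && any(df$weight < 0)) {
    stop("negative edge weight in ", path, call. = FALSE)
  }
  nodes <- unique(data.frame(
    id = c(df$node_a, df$node_b),
    kind = c(df$kind_a, df$kind_b),
    stringsAsFactors = FALSE
  ))
  check_that(!anyDuplicated(nodes$id),
             "a node id appears with two different kinds")
  nodes$matched <- nodes$kind != "variant"
  if (!is.null(dataset)) {
    is_var <- nodes$kind == "variant"
    nodes$matched[is_var] <- nodes$id[is_var] %in% dataset$variants$vid
  }
  edges <- data.frame(from = df$node_a, to = df$node_b,
                      weight = df$weight, source = df$source,
                      stringsAsFactors = FALSE)
  prior_graph(nodes, edges)
}

#' Write a prior graph as an edge-list TSV
#'
#' @param graph a [prior_graph()].
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_prior_graph <- function(graph, path) {
  kind_of <- stats::setNames(graph$nodes$kind, graph$nodes$id)
  df <- data.frame(
    node_a = graph$edges$from,
    node_b = graph$edges$to,
    kind_a = unname(kind_of[graph$edges$from]),
    kind_b = unname(kind_of[graph$edges$to]),
    weight = graph$edges$weight,
    source = graph$edges$source,
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# igraph view of the prior graph (undirected, weighted)
graph_igraph <- function(graph) {
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, nrow(graph$nodes),
                            name = graph$nodes$id, kind = graph$nodes$kind)
  if (nrow(graph$edges)) {
    g <- igraph::add_edges(
      g,
      rbind(match(graph$edges$from, graph$nodes$id),
            match(graph$edges$to, graph$nodes$id)),
      weight = graph$edges$weight
    )
  }
  g
}

# For every matched variant node: the matched variant nodes reachable
# within `order` steps (through gene/pathway nodes), excluding itself.
# Returns a named list of character vectors.
variant_neighborhoods <- function(graph, order = 2) {
  vids <- graph$nodes$id[graph$nodes$kind == "variant" & graph$nodes$matched]
  if (!length(vids)) return(list())
  g <- graph_igraph(graph)
  eg <- igraph::ego(g, order = order, nodes = vids)
  out <- lapply(seq_along(vids), function(i) {
    nb <- eg[[i]]$name
    nb[nb %in% vids & nb != vids[i]]
  })
  stats::setNames(out, vids)
}

# variant-to-variant shortest-path distance (in edges) through the graph
variant_distance <- function(graph, vid_a, vid_b) {
  g <- graph_igraph(graph)
  d <- igraph::distances(g, v = vid_a, to = vid_b, weights = NA)
  as.numeric(d)
}
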