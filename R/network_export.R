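# Organism -> compound homology networks and organism -> POP networks,
# with degree-based subsetting and export for Cytoscape-class tools.

homology_network <- function(nodes, edges) {
  deg <- table(c(edges$source, edges$target))
  nodes$degree <- as.integer(deg[nodes$id])
  nodes$degree[is.na(nodes$degree)] <- 0L
  rownames(nodes) <- NULL
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "homology_network")
}

#' @export
print.homology_network <- function(x, ...) {
  cat(sprintf("<homology network> %d nodes, %d edges\n",
              nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Build the organism-to-feature network
#'
#' Directed bipartite network with organisms as sources (diamond nodes)
#' and their features as targets (circle nodes). In `"compound"` mode each
#' cluster with a most-similar-known-compound annotation contributes one
#' edge to that compound weighted by its gene-homology percentage;
#' clusters without a known match all attach to a single `"unknown"` node
#' (typically the largest node of the rendered network). In `"pop"` mode
#' organisms link to their POPs weighted by occurrence count.
#'
#' @param rs A [record_set()].
#' @param mode `"compound"` or `"pop"`.
#' @param policy,n_gram_size Used in `"pop"` mode.
#' @return Object of class `homology_network`: `nodes`
#'   (`id`, `shape`, `degree`) and `edges`
#'   (`source`, `target`, `relation`, `weight`).
#' @export
build_network <- function(rs, mode = c("compound", "pop"), policy = "strict",
                          n_gram_size = 2) {
  mode <- match.arg(mode)
  if (!length(rs$records)) {
    return(homology_network(
      data.frame(id = character(0), shape = character(0),
                 stringsAsFactors = FALSE),
      data.frame(source = character(0), target = character(0),
                 relation = character(0), weight = numeric(0),
                 stringsAsFactors = FALSE)))
  }
  orgs <- unique(vapply(rs$records, `[[`, character(1), "organism"))
  if (mode == "compound") {
    edges <- do.call(rbind, lapply(rs$records, function(r) {
      if (is.null(r$known_match)) {
        data.frame(source = r$organism, target = "unknown",
                   relation = "homolog_of", weight = NA_real_,
                   stringsAsFactors = FALSE)
      } else {
        data.frame(source = r$organism, target = r$known_match$compound_name,
                   relation = "homolog_of",
                   weight = r$known_match$identity_percent,
                   stringsAsFactors = FALSE)
      }
    }))
  } else {
    edges <- do.call(rbind, lapply(rs$records, function(r) {
      ms <- pops_for(r, policy = policy, n_gram_size = n_gram_size)
      if (!length(ms)) return(NULL)
      data.frame(source = r$organism, target = names(ms),
                 relation = "has_pop", weight = as.numeric(ms),
                 stringsAsFactors = FALSE)
    }))
    if (is.null(edges)) {
      edges <- data.frame(source = character(0), target = character(0),
                          relation = character(0), weight = numeric(0),
                          stringsAsFactors = FALSE)
    }
  }
  targets <- setdiff(unique(edges$target), orgs)
  nodes <- data.frame(id = c(orgs, targets),
                      shape = c(rep("diamond", length(orgs)),
                                rep("circle", length(targets))),
                      stringsAsFactors = FALSE)
  homology_network(nodes, edges)
}

#' Subset a network by node degree
#'
#' Keeps nodes whose degree (count of incident edges, direction-blind)
#' meets the threshold; the boundary is inclusive, so a threshold of 5
#' excludes only nodes with fewer than 5 edges. With
#' `keep_neighbors = TRUE` the first neighbors of the retained nodes are
#' also kept (the subset-plus-its-compounds view). Edges survive only when
#' both endpoints do, and degrees are recomputed on the subset, so the
#' operation is idempotent at a fixed threshold when neighbor expansion is
#' off.
#'
#' @param n A `homology_network`.
#' @param min_edges Minimum degree, default 5.
#' @param keep_neighbors Also retain first neighbors of kept nodes.
#' @return A filtered `homology_network`.
#' @export
filter_by_degree <- function(n, min_edges = 5, keep_neighbors = FALSE) {
  stopifnot(min_edges >= 0)
  keep <- n$nodes$id[n$nodes$degree >= min_edges]
  if (keep_neighbors) {
    nb <- c(n$edges$target[n$edges$source %in% keep],
            n$edges$source[n$edges$target %in% keep])
    keep <- union(keep, nb)
  }
  edges <- n$edges[n$edges$source %in% keep & n$edges$target %in% keep, ,
                   drop = FALSE]
  nodes <- n$nodes[n$nodes$id %in% keep, c("id", "shape"), drop = FALSE]
  homology_network(nodes, edges)
}

as_igraph <- function(n) {
  edges <- n$edges
  edges$weight[is.na(edges$weight)] <- 0
  igraph::graph_from_data_frame(edges, directed = TRUE,
                                vertices = n$nodes)
}

#' Export a network for Cytoscape-class tools
#'
#' `"SIF"` writes one `source relation target` line per edge (relations
#' `homolog_of` / `has_pop`); `"GraphML"` carries the shape, degree and
#' weight attributes. Output is deterministic for a fixed input ordering.
#' A sidecar node-attribute TSV (`id`, `shape`, `degree`) can be written
#' with [write_node_attributes()].
#'
#' @param n A `homology_network`.
#' @param path Output file.
#' @param format `"SIF"` or `"GraphML"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(n, path, format = c("SIF", "GraphML")) {
  format <- match.arg(format)
  if (format == "SIF") {
    lines <- sprintf("%s %s %s", n$edges$source, n$edges$relation,
                     n$edges$target)
    writeLines(lines, path)
  } else {
    igraph::write_graph(as_igraph(n), path, format = "graphml")
  }
  invisible(path)
}

#' @rdname write_network
#' @param n A `homology_network`.
#' @export
write_node_attributes <- function(n, path) {
  utils::write.table(n$nodes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read back a GraphML network
#'
#' @param path GraphML file written by [write_network()].
#' @return A `homology_network`.
#' @export
read_network_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  nodes <- data.frame(id = igraph::vertex_attr(g, "name"),
                      shape = igraph::vertex_attr(g, "shape"),
                      stringsAsFactors = FALSE)
  ed <- igraph::as_data_frame(g, what = "edges")
  edges <- data.frame(source = ed$from, target = ed$to,
                      relation = ed$relation, weight = ed$weight,
                      stringsAsFactors = FALSE)
  homology_network(nodes, edges)
}
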