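#' The eight network projection kinds
#'
#' Every reaction dataset is coarse-grained into four simple undirected
#' graphs — a bipartite compound/reaction graph and three unipartite
#' projections — each taken both as the entire graph and as its largest
#' connected component, for eight projections in total.
#'
#' @return data.frame with columns `construction` and `scope` (8 rows).
#' @export
projection_kinds <- function() {
  expand.grid(
    construction = c("bi_full", "uni_compounds", "uni_reactions",
                     "uni_subs_not_connected"),
    scope = c("entire", "largest"),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
}

.constructions <- c("bi_full", "uni_compounds", "uni_reactions",
                    "uni_subs_not_connected")

.pair_edges <- function(a, b = NULL) {
  # unordered distinct pairs: within a (b NULL) or across a x b; self-pairs
  # dropped; each pair canonicalized
  if (is.null(b)) {
    if (length(a) < 2L) return(NULL)
    cb <- utils::combn(a, 2L)
    cbind(pmin(cb[1L, ], cb[2L, ]), pmax(cb[1L, ], cb[2L, ]))
  } else {
    if (!length(a) || !length(b)) return(NULL)
    g <- expand.grid(a = a, b = b, KEEP.OUT.ATTRS = FALSE,
                     stringsAsFactors = FALSE)
    g <- g[g$a != g$b, , drop = FALSE]
    if (!nrow(g)) return(NULL)
    cbind(pmin(g$a, g$b), pmax(g$a, g$b))
  }
}

#' Build one network projection of a reaction dataset
#'
#' Construction rules, applied to the entire dataset:
#' \describe{
#'   \item{`bi_full`}{bipartite graph: a compound node is connected to a
#'     reaction node if it participates in that reaction as substrate or
#'     product.}
#'   \item{`uni_compounds`}{compound nodes; two compounds are connected if
#'     they occur in the same reaction (either side).}
#'   \item{`uni_reactions`}{reaction nodes; two reactions are connected if
#'     they share a compound.}
#'   \item{`uni_subs_not_connected`}{compound nodes; two compounds are
#'     connected only if they occur on opposite sides of the same reaction.}
#' }
#' All graphs are simple: parallel edges are collapsed and no self-loops are
#' created (in particular a compound occurring on both sides of one reaction
#' yields no self-edge, and compound nodes with no surviving edge remain as
#' isolated nodes).
#'
#' @param dataset a [reaction_dataset()].
#' @param construction one of `"bi_full"`, `"uni_compounds"`,
#'   `"uni_reactions"`, `"uni_subs_not_connected"`.
#' @return an object of class `projection_graph` with fields `construction`,
#'   `scope` (`"entire"`), `graph` (an `igraph` object) and `roles` (named
#'   character vector, `"compound"` or `"reaction"` per node).
#' @export
build_projection <- function(dataset, construction = .constructions) {
  stopifnot(inherits(dataset, "reaction_dataset"))
  construction <- match.arg(construction)
  rx <- dataset$reactions
  compounds <- dataset_compounds(dataset)
  rids <- vapply(rx, `[[`, character(1L), "reaction_id")
  edges <- NULL
  if (construction == "bi_full") {
    if (length(intersect(compounds, rids))) {
      stop("bi_full projection requires disjoint compound and reaction ids; ",
           "overlapping: ",
           paste(utils::head(intersect(compounds, rids), 3L), collapse = ", "))
    }
    el <- lapply(rx, function(r) {
      cs <- unique(c(r$substrates, r$products))
      cbind(cs, rep(r$reaction_id, length(cs)))
    })
    edges <- do.call(rbind, el)
    nodes <- c(compounds, rids)
    roles <- c(rep("compound", length(compounds)), rep("reaction", length(rids)))
  } else if (construction == "uni_compounds") {
    el <- lapply(rx, function(r) .pair_edges(unique(c(r$substrates, r$products))))
    edges <- do.call(rbind, el)
    nodes <- compounds
    roles <- rep("compound", length(compounds))
  } else if (construction == "uni_subs_not_connected") {
    el <- lapply(rx, function(r) .pair_edges(r$substrates, r$products))
    edges <- do.call(rbind, el)
    nodes <- compounds
    roles <- rep("compound", length(compounds))
  } else { # uni_reactions
    cpd_of <- lapply(rx, function(r) unique(c(r$substrates, r$products)))
    members <- split(rep(rids, lengths(cpd_of)), unlist(cpd_of, use.names = FALSE))
    el <- lapply(members, function(m) .pair_edges(unique(m)))
    edges <- do.call(rbind, el)
    nodes <- rids
    roles <- rep("reaction", length(rids))
  }
  if (!is.null(edges) && nrow(edges)) {
    edges <- unique(edges)
  } else {
    edges <- matrix(character(), ncol = 2L)
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges[, 1L], to = edges[, 2L], stringsAsFactors = FALSE),
    directed = FALSE, vertices = data.frame(name = nodes, stringsAsFactors = FALSE)
  )
  names(roles) <- nodes
  structure(
    list(construction = construction, scope = "entire", graph = g, roles = roles),
    class = "projection_graph"
  )
}

#' @export
print.projection_graph <- function(x, ...) {
  cat("<projection_graph>", x$construction, "/", x$scope, "\n")
  cat("  nodes:", igraph::vcount(x$graph), " edges:", igraph::ecount(x$graph), "\n")
  invisible(x)
}

#' Largest connected component of a projection
#'
#' Returns the node-induced subgraph on a maximum-cardinality connected
#' component, with the scope flag set to `"largest"`. If the graph is
#' connected, nodes and edges are unchanged. Ties between equally large
#' components are broken deterministically toward the component containing
#' the lexicographically smallest node id.
#'
#' @param projection a `projection_graph`.
#' @return a `projection_graph` with `scope = "largest"`.
#' @export
largest_connected_component <- function(projection) {
  stopifnot(inherits(projection, "projection_graph"))
  g <- projection$graph
  if (igraph::vcount(g) == 0L) stop("empty graph")
  comp <- igraph::components(g)
  big <- which(comp$csize == max(comp$csize))
  if (length(big) > 1L) {
    nm <- igraph::V(g)$name
    firsts <- vapply(big, function(k) min(nm[comp$membership == k]), character(1L))
    big <- big[order(firsts)][1L]
  }
  keep <- igraph::V(g)[comp$membership == big]
  sub <- igraph::induced_subgraph(g, keep)
  structure(
    list(construction = projection$construction, scope = "largest",
         graph = sub, roles = projection$roles[igraph::V(sub)$name]),
    class = "projection_graph"
  )
}

#' Degree sequence of a projection
#'
#' One degree per node. For the bipartite projection the compound-role and
#' reaction-role degrees are pooled into a single sequence, so every
#' projection yields exactly one degree distribution.
#'
#' @param projection a `projection_graph`.
#' @return integer vector of node degrees (length = number of nodes).
#' @export
degree_sequence <- function(projection) {
  stopifnot(inherits(projection, "projection_graph"))
  unname(as.integer(igraph::degree(projection$graph, loops = FALSE)))
}

#' Expand a dataset into all eight projections
#'
#' Builds the four construction rules on the entire dataset and pairs each
#' with its largest connected component.
#'
#' @param dataset a [reaction_dataset()].
#' @return named list with 8 entries (`"<construction>-<scope>"`), each a
#'   list with elements `graph` (a `projection_graph`) and `degrees`.
#' @export
#' @examples
#' ds <- reaction_dataset("toy", "individual", list(
#'   reaction("R1", c("A", "B"), "C"),
#'   reaction("R2", "C", c("D", "E"))
#' ))
#' names(expand_dataset(ds))
expand_dataset <- function(dataset) {
  out <- list()
  for (con in .constructions) {
    entire <- build_projection(dataset, con)
    largest <- largest_connected_component(entire)
    out[[paste0(con, "-entire")]] <- list(graph = entire,
                                          degrees = degree_sequence(entire))
    out[[paste0(con, "-largest")]] <- list(graph = largest,
                                           degrees = degree_sequence(largest))
  }
  out
}

#' Export a projection as a text edge list or JSON bundle
#'
#' @param projection a `projection_graph`.
#' @param path output path.
#' @param format `"edgelist"` (two tab-separated node-id columns; isolated
#'   nodes listed after a trailing `# nodes` comment) or `"json"`
#'   (`{construction, scope, nodes, edges, roles}`).
#' @return `path`, invisibly.
#' @export
export_projection <- function(projection, path, format = c("edgelist", "json")) {
  format <- match.arg(format)
  stopifnot(inherits(projection, "projection_graph"))
  g <- projection$graph
  el <- igraph::as_edgelist(g)
  if (format == "json") {
    jsonlite::write_json(list(
      construction = projection$construction,
      scope = projection$scope,
      nodes = igraph::V(g)$name,
      edges = apply(el, 1L, function(r) list(r[[1L]], r[[2L]])),
      roles = as.list(projection$roles)
    ), path, auto_unbox = TRUE)
    return(invisible(path))
  }
  lines <- apply(el, 1L, paste, collapse = "\t")
  iso <- setdiff(igraph::V(g)$name, unique(as.vector(el)))
  if (length(iso)) lines <- c(lines, "# nodes", iso)
  writeLines(lines, path)
  invisible(path)
}
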