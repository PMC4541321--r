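# Reserved id of the auxiliary ground node; excluded from all reporting.
GROUND_ID <- "__GROUND__"

#' Merge per-pathway graphs into one global graph
#'
#' Nodes and edges are unioned so that each gene and each metabolite appears
#' exactly once; the per-pathway gene membership is kept in the graph
#' attribute `pathway_index`. Node order is deterministic: genes first, then
#' metabolites, each lexicographically by id (C locale), so downstream
#' matrices and weight vectors are reproducible bit-for-bit.
#'
#' @param graphs list of igraphs from [build_pathway_graph()] (or
#'   [build_gene_gene_graph()] for the gene-only variant)
#' @return an igraph with `kind` vertex attribute and `pathway_index` graph
#'   attribute (no ground node yet)
#' @export
merge_graphs <- function(graphs) {
  kinds <- character(0)
  for (g in graphs) {
    k <- stats::setNames(igraph::V(g)$kind, igraph::V(g)$name)
    shared <- intersect(names(kinds), names(k))
    bad <- shared[kinds[shared] != k[shared]]
    if (length(bad))
      stop("node kind conflict across pathways for: ",
           paste(bad, collapse = ", "))
    kinds <- c(kinds, k[setdiff(names(k), names(kinds))])
  }
  edges <- unique(do.call(rbind, lapply(graphs, function(g) {
    igraph::as_edgelist(g, names = TRUE)
  })))
  idx <- list()
  for (g in graphs) {
    gi <- igraph::graph_attr(g, "pathway_index")
    if (is.null(gi)) {
      pid <- igraph::graph_attr(g, "pathway_id")
      if (is.null(pid)) stop("pathway graph lacks a pathway_id attribute")
      gi <- stats::setNames(
        list(sort_c(igraph::V(g)$name[igraph::V(g)$kind == "gene"])), pid)
    }
    for (pid in names(gi))
      idx[[pid]] <- sort_c(union(idx[[pid]], gi[[pid]]))
  }
  names_sorted <- names(kinds)[order(kinds, names(kinds), method = "radix")]
  out <- igraph::make_empty_graph(n = length(names_sorted), directed = TRUE)
  out <- igraph::set_vertex_attr(out, "name", value = names_sorted)
  out <- igraph::set_vertex_attr(out, "kind",
                                 value = unname(kinds[names_sorted]))
  if (!is.null(edges) && nrow(edges)) {
    o <- order(edges[, 1], edges[, 2], method = "radix")
    out <- igraph::add_edges(out, rbind(edges[o, 1], edges[o, 2]))
  }
  igraph::graph_attr(out, "pathway_index") <- idx[sort_c(names(idx))]
  out
}

#' Reverse every edge of the global graph
#'
#' Reversal makes walk mass flow from downstream products toward the
#' upstream genes that generate them, which is what lets the stationary
#' weights promote upstream regulators. Must be applied before the ground
#' node is attached.
#'
#' @param graph the merged global igraph
#' @return the same graph with each edge (u -> v) replaced by (v -> u)
#' @export
reverse_edges <- function(graph) {
  if (GROUND_ID %in% igraph::V(graph)$name)
    stop("edges must be reversed before the ground node is added")
  igraph::reverse_edges(graph)
}

#' Attach the ground node
#'
#' Adds one auxiliary node linked bidirectionally to every existing node.
#' This guarantees that every row of the transition matrix is well defined
#' (no dangling nodes) and that the restart walk converges.
#'
#' @param graph the merged (and typically edge-reversed) global igraph
#' @return the graph with the ground node appended last in node order
#' @export
add_ground_node <- function(graph) {
  if (GROUND_ID %in% igraph::V(graph)$name)
    stop("graph already contains the reserved ground id ", GROUND_ID)
  others <- igraph::V(graph)$name
  graph <- igraph::add_vertices(graph, 1, name = GROUND_ID, kind = "ground")
  if (length(others))
    graph <- igraph::add_edges(graph, c(
      rbind(rep(GROUND_ID, length(others)), others),
      rbind(others, rep(GROUND_ID, length(others)))))
  graph
}

#' Row-normalized transition matrix of the global graph
#'
#' @param graph global igraph with the ground node attached
#' @return a list of class `transition_matrix` with elements `M` (sparse
#'   row-stochastic matrix, `M[i, j] = 1/outdegree(i)` when edge i -> j
#'   exists), `node_ids` and `kinds` aligned to its rows.
#' @export
transition_matrix <- function(graph) {
  if (!GROUND_ID %in% igraph::V(graph)$name)
    stop("transition matrix requires the ground node (add_ground_node)")
  A <- igraph::as_adjacency_matrix(graph, sparse = TRUE)
  A <- methods::as(A, "dMatrix")
  outdeg <- Matrix::rowSums(A)
  if (any(outdeg == 0))
    stop("internal error: node with zero out-degree after grounding")
  M <- Matrix::Diagonal(x = 1 / outdeg) %*% A
  M <- methods::as(M, "CsparseMatrix")
  dimnames(M) <- list(igraph::V(graph)$name, igraph::V(graph)$name)
  structure(list(M = M,
                 node_ids = igraph::V(graph)$name,
                 kinds = igraph::V(graph)$kind),
            class = "transition_matrix")
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat(sprintf("transition_matrix: %d nodes (%s)\n", length(x$node_ids),
              paste(sprintf("%s: %d", names(table(x$kinds)), table(x$kinds)),
                    collapse = ", ")))
  invisible(x)
}

#' Build the full global graph from a reaction table
#'
#' Convenience pipeline: per-pathway construction, merge, edge reversal and
#' grounding in one call.
#'
#' @param records a `reaction_table` covering all pathways
#' @param variant `"gene-metabolite"` for the bipartite graph,
#'   `"gene"` for the metabolite-contracted gene-only graph
#' @param exclude_compounds compound ids to remove first (see
#'   [filter_compounds()]); empty by default — currency metabolites are
#'   kept unless explicitly excluded
#' @return the grounded global igraph
#' @export
build_global_graph <- function(records,
                               variant = c("gene-metabolite", "gene"),
                               exclude_compounds = character(0)) {
  variant <- match.arg(variant)
  records <- filter_compounds(records, exclude_compounds)
  if (variant == "gene-metabolite") {
    per_pw <- lapply(split(seq_len(nrow(records)), records$pathway_id),
                     function(i) build_pathway_graph(records[i, ]))
    g <- merge_graphs(unname(per_pw))
  } else {
    g <- build_gene_gene_graph(records)
    g <- merge_graphs(list(g))  # enforce the deterministic node order
  }
  add_ground_node(reverse_edges(g))
}

#' Pathway membership of the global graph
#'
#' @param graph a global igraph
#' @return named list, pathway id -> character vector of member gene ids
#' @export
pathway_members <- function(graph) {
  idx <- igraph::graph_attr(graph, "pathway_index")
  if (is.null(idx)) stop("graph has no pathway_index attribute")
  idx
}
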