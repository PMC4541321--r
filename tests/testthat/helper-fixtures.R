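# Shared in-code fixtures for the test suite.

# Two-pathway toy reaction table: a linear chain and a reversible step.
toy_reactions <- function() {
  reaction_table(
    pathway_id = c("pwA", "pwA", "pwB"),
    reaction_id = c("r1", "r2", "r3"),
    gene_ids = list("G1", c("G2", "G3"), "G4"),
    substrate_ids = list("C1", "C2", "C3"),
    product_ids = list("C2", "C3", "C4"),
    reversible = c(FALSE, FALSE, TRUE))
}

# Grounded global graph of the toy reaction table.
toy_graph <- function() build_global_graph(toy_reactions())

# Small labeled expression matrix with a clean differential gene.
toy_expr <- function() {
  v <- rbind(
    G1 = c(1, 2, 3, 7, 8, 9),
    G2 = c(5, 6, 4, 6, 5, 4),
    G3 = c(2, 1, 3, 1, 3, 2),
    G4 = c(10, 11, 12, 9, 8, 7))
  colnames(v) <- paste0("s", 1:6)
  labeled_matrix(v, rep(c("A", "B"), each = 3))
}

# Random strongly-label-free cohort for null checks.
random_cohort <- function(n_feat, n_per_class, seed, ids = NULL) {
  set.seed(seed)
  v <- matrix(rnorm(n_feat * 2 * n_per_class), nrow = n_feat)
  rownames(v) <- if (is.null(ids)) paste0("f", seq_len(n_feat)) else ids
  colnames(v) <- paste0("s", seq_len(2 * n_per_class))
  labeled_matrix(v, rep(c("A", "B"), each = n_per_class))
}

# Random grounded transition matrix over n nodes (Erdos-Renyi edges).
random_transition <- function(n, seed, p_edge = 0.05) {
  set.seed(seed)
  g <- igraph::sample_gnp(n, p_edge, directed = TRUE)
  g <- igraph::set_vertex_attr(g, "name",
                               value = sprintf("n%03d", seq_len(n)))
  g <- igraph::set_vertex_attr(g, "kind",
                               value = rep("gene", n))
  transition_matrix(add_ground_node(g))
}

# Random L1-normalized nonnegative start vector.
random_w0 <- function(tm, seed) {
  set.seed(seed)
  w <- stats::runif(length(tm$node_ids))
  w[length(w)] <- 0  # ground last
  stats::setNames(w / sum(w), tm$node_ids)
}

edge_set <- function(g) {
  el <- igraph::as_edgelist(g, names = TRUE)
  sort(paste(el[, 1], el[, 2], sep = "->"))
}
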