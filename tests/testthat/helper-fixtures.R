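# Small shared fixtures, all built in code.

tiny_nodes <- function(n) {
  data.frame(node_id = seq_len(n) - 1L,
             label = sprintf("node%02d", seq_len(n)),
             hemisphere = "midline", region_class = "cortical-frontal",
             epicenter_group = NA_character_, stringsAsFactors = FALSE)
}

# connectome from an explicit upper-triangle weight list; NA = absent
connectome_from_edges <- function(n, edges) {
  W <- matrix(0, n, n)
  P <- matrix(FALSE, n, n)
  for (e in edges) {
    i <- e[[1]] + 1L; j <- e[[2]] + 1L; w <- e[[3]]
    if (!is.na(w)) {
      W[i, j] <- W[j, i] <- w
      P[i, j] <- P[j, i] <- TRUE
    }
  }
  nodes <- tiny_nodes(n)
  dimnames(W) <- dimnames(P) <- list(nodes$label, nodes$label)
  new_connectome(W, P, nodes)
}

# random connected adjacency on <= max_n nodes (for ring BFS properties)
random_adjacency <- function(n, p = 0.2) {
  repeat {
    A <- matrix(runif(n * n) < p, n, n)
    A[lower.tri(A, diag = TRUE)] <- FALSE
    A <- A | t(A)
    g <- igraph::graph_from_adjacency_matrix(A * 1, mode = "undirected")
    if (igraph::is_connected(g)) return(A)
  }
}

# template for a single 2-node epicenter whose incident edges carry the
# whole planted effect (first-ring-only disease model); the default
# n_affected = NA plants on every epicenter-incident edge
single_epicenter_template <- function(seed, n_nodes = 30, density = 0.3,
                                      n_affected = NA) {
  generate_template_network(
    n_nodes = n_nodes, density = density,
    epicenter_spec = list(SN = c(0L, 1L)),
    n_affected_edges = n_affected, n_behavior_edges = 4, seed = seed,
    weak_edge_fraction = 0)
}
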