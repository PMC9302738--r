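# Shared fixtures, built in code.

# community graph / interaction matrix from a 0/1 adjacency with uniform
# strength alpha
cg_from_adj <- function(A) {
  community_graph(igraph::graph_from_adjacency_matrix(A != 0, mode = "undirected"))
}

im_from_adj <- function(A, alpha) {
  build_interactions(cg_from_adj(A), alpha = alpha, sigma = 0)
}

im_pair <- function(alpha) im_from_adj(adjacency_chain(2), alpha)

# fast assembly parameters for small test systems
fast_params <- assembly_params(max_time = 1e5)
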