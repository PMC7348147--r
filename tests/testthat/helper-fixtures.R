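# in-code fixtures and independent oracles shared across test files

# small deterministic count matrix: 2 tissues x 2 groups x 3 replicates
toy_count_matrix <- function(n_genes = 50, seed = 42, n_tissues = 1) {
  cfg <- simulation_config(n_tissues = n_tissues, n_genes = n_genes,
                           n_replicates = 3, deg_fraction = 0.1,
                           lfc_magnitude = 2, nb_dispersion = 0.05,
                           libsize_range = c(5e3, 1e4),
                           network_nodes = min(20, n_genes),
                           network_attach_param = 2,
                           seed = seed)
  simulate_counts(cfg)
}

# undirected path graph A-B-C-... as a signaling_network
path_net <- function(n = 4) {
  labels <- LETTERS[seq_len(n)]
  g <- igraph::make_ring(n, directed = FALSE, circular = FALSE)
  igraph::V(g)$name <- labels
  signaling_network(g, mode = "undirected")
}

ring_net <- function(n = 6) {
  g <- igraph::make_ring(n, directed = FALSE, circular = TRUE)
  igraph::V(g)$name <- paste0("N", seq_len(n))
  signaling_network(g, mode = "undirected")
}

# random connected-ish undirected graph over <= 30 nodes
random_net <- function(n_nodes, p_edge, seed) {
  g <- proxscreen:::with_seed(seed,
    igraph::sample_gnp(n_nodes, p_edge, directed = FALSE))
  igraph::V(g)$name <- sprintf("V%02d", seq_len(n_nodes))
  signaling_network(g, mode = "undirected")
}

# exhaustive BFS shortest-path oracle (hop counts), independent of igraph
bfs_oracle <- function(net, from) {
  g <- net$graph
  nodes <- igraph::V(g)$name
  adj <- lapply(nodes, function(v)
    names(igraph::neighbors(g, v, mode = "all")))
  names(adj) <- nodes
  dist <- stats::setNames(rep(Inf, length(nodes)), nodes)
  dist[from] <- 0
  frontier <- from
  while (length(frontier)) {
    nxt <- character(0)
    for (v in frontier) for (w in adj[[v]]) {
      if (is.infinite(dist[w])) {
        dist[w] <- dist[v] + 1
        nxt <- c(nxt, w)
      }
    }
    frontier <- unique(nxt)
  }
  dist
}

# proximity oracle: mean over D of min over T of BFS distance
proximity_oracle <- function(net, D, Tset, penalty = NULL) {
  if (is.null(penalty)) penalty <- proxscreen:::unreachable_penalty(net)
  mins <- vapply(D, function(d) {
    dd <- bfs_oracle(net, d)[Tset]
    m <- min(dd)
    if (is.infinite(m)) penalty else m
  }, 0)
  mean(mins)
}

# hypergeometric upper-tail by literal subset enumeration (N small)
hyper_enum_oracle <- function(k, K, n, N) {
  marked <- seq_len(K)
  subsets <- utils::combn(N, n)
  overlaps <- colSums(matrix(subsets %in% marked, nrow = n))
  mean(overlaps >= k)
}

# spearman rho on shared genes, independent of package internals
scc_oracle <- function(a, b) {
  shared <- intersect(names(a), names(b))
  stats::cor(a[shared], b[shared], method = "spearman")
}

make_records <- function(seqs, quals) {
  mapply(function(s, q, i) list(id = paste0("r", i), sequence = s, qualities = q),
         seqs, quals, seq_along(seqs), SIMPLIFY = FALSE, USE.NAMES = FALSE)
}
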