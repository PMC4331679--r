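# Independent oracles and small fixture builders used across test files.

# Exhaustive enumeration of all monotone warping paths between two series,
# independent of the DP implementation: recursion over path suffixes with
# no table reuse.
dtw_path_enumeration <- function(s, t) {
  n <- length(s)
  m <- length(t)
  rec <- function(i, j) {
    cost <- abs(s[i] - t[j])
    if (i == n && j == m) return(cost)
    best <- Inf
    if (i < n) best <- min(best, rec(i + 1, j))
    if (j < m) best <- min(best, rec(i, j + 1))
    if (i < n && j < m) best <- min(best, rec(i + 1, j + 1))
    cost + best
  }
  rec(1, 1)
}

# All series of lengths 1..max_len over a finite alphabet.
all_series <- function(alphabet, max_len) {
  out <- list()
  for (l in seq_len(max_len)) {
    g <- do.call(expand.grid, rep(list(alphabet), l))
    for (r in seq_len(nrow(g))) out[[length(out) + 1L]] <- as.numeric(g[r, ])
  }
  out
}

# Random valid network: readout is the last node, random off-diagonal
# edges, none leaving the readout.
random_valid_network <- function(n, p = 0.25) {
  nodes <- sprintf("n%02d", seq_len(n))
  adj <- matrix(runif(n * n) < p, n, n)
  diag(adj) <- FALSE
  adj[n, ] <- FALSE
  idx <- which(adj, arr.ind = TRUE)
  edges <- data.frame(from = nodes[idx[, 1]], to = nodes[idx[, 2]],
                      stringsAsFactors = FALSE)
  signaling_network(nodes, edges, nodes[n])
}

# Small fixed chain network A -> B -> Out used by many tests.
toy_chain_network <- function() {
  signaling_network(c("A", "B", "Out"),
                    data.frame(from = c("A", "B"), to = c("B", "Out")),
                    "Out")
}

# 5-node instance with a planted single-deletion + single-insertion
# rewiring, shared between the GA unit tests.
five_node_instance <- function() {
  nodes <- c("A", "B", "C", "D", "Out")
  net <- signaling_network(
    nodes, data.frame(from = c("A", "B", "C", "A"),
                      to = c("B", "C", "Out", "D")), "Out")
  rmf <- sample_rate_constants(net, seed = 3)
  pl <- plant_rewiring(net, 1, 1, seed = 9)
  ds <- generate_dataset(pl$network, rmf, noise_sigma = 0, seed = 4)
  list(net = net, rmf = rmf, planted = pl, data = ds)
}

edit_keys <- function(d) {
  c(paste(d$deletions$from, d$deletions$to, sep = "->"),
    paste(d$insertions$from, d$insertions$to, sep = "->"))
}
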