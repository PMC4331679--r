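#' Signalling-network topology
#'
#' A `signaling_network` holds an ordered node list, a directed boolean
#' adjacency matrix and the identity of the phenotype read-out node. The
#' read-out species is a pure sink: it accumulates signal but has no
#' outgoing edges, and no node may have a self-loop.
#'
#' @param node_names Character vector of unique node identifiers.
#' @param edges Data frame with character columns `from` and `to`, one row
#'   per directed edge. May have zero rows.
#' @param readout_node Name of the read-out (phenotype) node; must be one
#'   of `node_names`.
#'
#' @return An object of class `signaling_network` with fields `node_names`,
#'   `adjacency` (n x n logical matrix with dimnames) and `readout_node`.
#' @examples
#' net <- signaling_network(c("A", "B", "Out"),
#'                          data.frame(from = "A", to = "B"), "Out")
#' network_edges(net)
#' @export
signaling_network <- function(node_names, edges, readout_node) {
  stopifnot(is.character(node_names), length(node_names) >= 2)
  if (anyDuplicated(node_names))
    stop("node_names must be unique; duplicated: ",
         paste(unique(node_names[duplicated(node_names)]), collapse = ", "))
  if (!readout_node %in% node_names)
    stop("readout_node '", readout_node, "' is not among node_names")
  n <- length(node_names)
  adjacency <- matrix(FALSE, n, n, dimnames = list(node_names, node_names))
  if (nrow(edges) > 0) {
    edges$from <- as.character(edges$from)
    edges$to <- as.character(edges$to)
    bad <- setdiff(c(edges$from, edges$to), node_names)
    if (length(bad) > 0)
      stop("edge endpoints not declared as nodes: ", paste(bad, collapse = ", "))
    key <- paste(edges$from, edges$to, sep = "\r")
    if (anyDuplicated(key))
      stop("duplicate edge(s): ",
           paste(gsub("\r", "->", unique(key[duplicated(key)])), collapse = ", "))
    adjacency[cbind(edges$from, edges$to)] <- TRUE
  }
  out <- structure(list(node_names = node_names, adjacency = adjacency,
                        readout_node = readout_node),
                   class = "signaling_network")
  validate_signaling_network(out)
  out
}

#' @export
print.signaling_network <- function(x, ...) {
  cat("<signaling_network> ", length(x$node_names), " nodes, ",
      sum(x$adjacency), " edges, readout = ", x$readout_node, "\n", sep = "")
  invisible(x)
}

validate_signaling_network <- function(net) {
  adj <- net$adjacency
  if (any(diag(adj)))
    stop("self-loop(s) on: ",
         paste(net$node_names[diag(adj)], collapse = ", "))
  if (any(adj[net$readout_node, ]))
    stop("readout node '", net$readout_node,
         "' must be a pure sink but has outgoing edge(s) to: ",
         paste(net$node_names[adj[net$readout_node, ]], collapse = ", "))
  invisible(net)
}

#' Edge list of a network
#'
#' @param net A [signaling_network()].
#' @return Data frame with columns `from`, `to`, one row per directed edge,
#'   in row-major (by source, then target) order.
#' @export
network_edges <- function(net) {
  idx <- which(t(net$adjacency), arr.ind = FALSE) # row-major scan
  n <- length(net$node_names)
  k <- idx - 1L
  data.frame(from = net$node_names[k %/% n + 1L],
             to = net$node_names[k %% n + 1L],
             stringsAsFactors = FALSE)
}

edge_keys <- function(df) paste(df$from, df$to, sep = "\r")

#' The embedded baseline apoptosis edge table
#'
#' Parses the package's transcription of the baseline 22-node apoptosis
#' system. Each rate constant `rc_k` defines one directed first-order
#' transfer edge: it appears exactly once with a minus sign (draining the
#' source species in the source's own equation) and exactly once with a
#' plus sign (feeding the target), so the source/target pair is recovered
#' by pairing the two occurrences.
#'
#' @return Data frame with columns `rc` (integer 1..32), `from`, `to`.
#' @export
baseline_edge_table <- function() {
  terms <- baseline_equation_terms()
  out <- lapply(sort(unique(terms$rc)), function(k) {
    tk <- terms[terms$rc == k, , drop = FALSE]
    neg <- tk[tk$sign == "-", , drop = FALSE]
    pos <- tk[tk$sign == "+", , drop = FALSE]
    if (nrow(neg) != 1L || nrow(pos) != 1L)
      stop("baseline table integrity: rc_", k,
           " must appear exactly once with each sign")
    if (neg$node != neg$species || pos$species != neg$species)
      stop("baseline table integrity: rc_", k,
           " drain/gain terms disagree on the source species")
    data.frame(rc = k, from = neg$species, to = pos$node,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Signed equation terms of the embedded baseline transcription
#'
#' @return Data frame with columns `node` (equation), `sign` (`"+"`/`"-"`),
#'   `species` (the concentration the term is proportional to) and `rc`
#'   (integer rate-constant index).
#' @export
baseline_equation_terms <- function() {
  path <- system.file("extdata", "baseline_equations.tsv",
                      package = "rewirenet", mustWork = TRUE)
  terms <- utils::read.delim(path, stringsAsFactors = FALSE)
  terms$rc <- as.integer(terms$rc)
  terms
}

#' Build the baseline apoptosis network
#'
#' Constructs the 22-node baseline topology from the embedded transcription:
#' 32 directed edges, one per rate constant, with `"Apop"` as the pure-sink
#' apoptosis read-out. The table is validated at load (22 unique node
#' names, 32 unique ordered pairs, paired +/- occurrences per rate
#' constant); a corrupted transcription raises an error.
#'
#' @return A [signaling_network()] with 22 nodes and 32 edges.
#' @examples
#' n1 <- build_baseline_network()
#' n1
#' @export
build_baseline_network <- function() {
  terms <- baseline_equation_terms()
  node_names <- unique(terms$node)
  if (length(node_names) != 22L)
    stop("baseline table integrity: expected 22 unique node names, got ",
         length(node_names))
  et <- baseline_edge_table()
  if (nrow(et) != 32L || anyDuplicated(edge_keys(et)))
    stop("baseline table integrity: expected 32 unique ordered pairs")
  signaling_network(node_names, et[c("from", "to")], readout_node = "Apop")
}

#' Regenerate rate-equation terms from a topology
#'
#' Applies the first-order transfer rule in reverse: every edge
#' `from -> to` with label `L` contributes the drain term
#' `(node = from, sign = "-", species = from, rc = L)` and the gain term
#' `(node = to, sign = "+", species = from, rc = L)`. Comparing the result
#' with [baseline_equation_terms()] checks that the embedded system and the
#' equation-generation rule agree term by term.
#'
#' @param net A [signaling_network()].
#' @param rc_labels Optional labels per edge, aligned with
#'   [network_edges()] order; defaults to `seq_len(n_edges)`.
#' @return Data frame with columns `node`, `sign`, `species`, `rc`.
#' @export
network_equation_terms <- function(net, rc_labels = NULL) {
  ed <- network_edges(net)
  if (is.null(rc_labels)) rc_labels <- seq_len(nrow(ed))
  stopifnot(length(rc_labels) == nrow(ed))
  rbind(
    data.frame(node = ed$from, sign = "-", species = ed$from, rc = rc_labels,
               stringsAsFactors = FALSE),
    data.frame(node = ed$to, sign = "+", species = ed$from, rc = rc_labels,
               stringsAsFactors = FALSE)
  )
}

## ---- chromosome encoding -------------------------------------------------

#' Bit positions masked in every chromosome
#'
#' Diagonal (self-loop) positions and the read-out node's whole row are
#' structurally forbidden and are held at 0 by every operator that touches
#' chromosomes. Bit `k` (1-based) maps to the ordered pair
#' `(i, j) = ((k-1) %/% n + 1, (k-1) %% n + 1)` — row-major concatenation
#' of the adjacency matrix.
#'
#' @param node_names Node ordering.
#' @param readout_node The read-out node name.
#' @return Sorted integer vector of 1-based masked bit positions.
#' @export
masked_bit_positions <- function(node_names, readout_node) {
  n <- length(node_names)
  r <- match(readout_node, node_names)
  diag_bits <- (seq_len(n) - 1L) * n + seq_len(n)
  readout_bits <- (r - 1L) * n + seq_len(n)
  sort(unique(c(diag_bits, readout_bits)))
}

new_chromosome <- function(bits, node_names, readout_node) {
  structure(list(bits = bits, node_names = node_names,
                 readout_node = readout_node),
            class = "ga_chromosome")
}

#' @export
print.ga_chromosome <- function(x, ...) {
  cat("<ga_chromosome> length ", length(x$bits), " (",
      length(x$node_names), " nodes), ", sum(x$bits), " set bits\n", sep = "")
  invisible(x)
}

apply_bit_mask <- function(bits, node_names, readout_node) {
  bits[masked_bit_positions(node_names, readout_node)] <- FALSE
  bits
}

#' Encode a network as a GA chromosome
#'
#' Concatenates the rows of the adjacency matrix into one binary string of
#' length n^2 (484 for the 22-node baseline): bit `k` is set iff edge
#' `(i, j)` with `i = (k-1) %/% n + 1`, `j = (k-1) %% n + 1` is present.
#'
#' @param net A [signaling_network()].
#' @return A `ga_chromosome`.
#' @export
encode_chromosome <- function(net) {
  bits <- as.vector(t(net$adjacency)) # row-major
  new_chromosome(bits, net$node_names, net$readout_node)
}

#' Decode a GA chromosome back into a network
#'
#' Inverse of [encode_chromosome()]. Bits at structurally forbidden
#' positions (diagonal, read-out row) are cleared with a warning
#' (mask-and-warn policy), so any bitstring of the right length decodes to
#' a valid topology.
#'
#' @param chrom A `ga_chromosome`.
#' @return A [signaling_network()].
#' @export
decode_chromosome <- function(chrom) {
  n <- length(chrom$node_names)
  bits <- chrom$bits
  if (length(bits) != n * n)
    stop("chromosome length ", length(bits), " does not match ",
         n, "^2 = ", n * n, " for its node set")
  masked <- masked_bit_positions(chrom$node_names, chrom$readout_node)
  offending <- sum(bits[masked])
  if (offending > 0) {
    warning("clearing ", offending,
            " set bit(s) at forbidden (diagonal/readout-row) positions")
    bits[masked] <- FALSE
  }
  adjacency <- matrix(bits, n, n, byrow = TRUE,
                      dimnames = list(chrom$node_names, chrom$node_names))
  structure(list(node_names = chrom$node_names, adjacency = adjacency,
                 readout_node = chrom$readout_node),
            class = "signaling_network")
}

## ---- rewiring diffs ------------------------------------------------------

#' Construct a rewiring diff
#'
#' @param insertions,deletions Data frames with columns `from`, `to`
#'   (possibly zero rows). The two sets must be disjoint.
#' @return An object of class `rewiring_diff`.
#' @export
rewiring_diff <- function(insertions = empty_edge_df(),
                          deletions = empty_edge_df()) {
  insertions <- as_edge_df(insertions)
  deletions <- as_edge_df(deletions)
  if (length(intersect(edge_keys(insertions), edge_keys(deletions))) > 0)
    stop("insertions and deletions must be disjoint")
  structure(list(insertions = insertions, deletions = deletions),
            class = "rewiring_diff")
}

empty_edge_df <- function() {
  data.frame(from = character(0), to = character(0), stringsAsFactors = FALSE)
}

as_edge_df <- function(x) {
  stopifnot(is.data.frame(x), all(c("from", "to") %in% names(x)))
  data.frame(from = as.character(x$from), to = as.character(x$to),
             stringsAsFactors = FALSE)
}

#' @export
print.rewiring_diff <- function(x, ...) {
  cat("<rewiring_diff> ", nrow(x$insertions), " insertion(s), ",
      nrow(x$deletions), " deletion(s)\n", sep = "")
  if (nrow(x$insertions))
    cat("  + ", paste(x$insertions$from, x$insertions$to, sep = "->",
                      collapse = ", "), "\n", sep = "")
  if (nrow(x$deletions))
    cat("  - ", paste(x$deletions$from, x$deletions$to, sep = "->",
                      collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Topology difference between two networks
#'
#' @param a,b Two [signaling_network()]s over the same ordered node set.
#' @return A [rewiring_diff()] with `insertions` = edges in `b` not in `a`
#'   and `deletions` = edges in `a` not in `b`, so that
#'   `apply_rewiring(a, diff_networks(a, b))` equals `b`.
#' @export
diff_networks <- function(a, b) {
  if (!identical(a$node_names, b$node_names))
    stop("networks do not share the same ordered node set")
  ea <- network_edges(a); eb <- network_edges(b)
  ka <- edge_keys(ea); kb <- edge_keys(eb)
  rewiring_diff(insertions = eb[!(kb %in% ka), , drop = FALSE],
                deletions = ea[!(ka %in% kb), , drop = FALSE])
}

#' Apply a rewiring diff to a network
#'
#' Deletions must currently exist; insertions must be absent, off-diagonal
#' and must not add outgoing edges to the read-out node. Violations raise
#' an error naming the offending pair. The input network is not modified.
#'
#' @param net A [signaling_network()].
#' @param d A [rewiring_diff()].
#' @return The rewired [signaling_network()].
#' @export
apply_rewiring <- function(net, d) {
  stopifnot(inherits(d, "rewiring_diff"))
  adj <- net$adjacency
  for (i in seq_len(nrow(d$deletions))) {
    from <- d$deletions$from[i]; to <- d$deletions$to[i]
    check_pair_in_net(net, from, to)
    if (!adj[from, to])
      stop("cannot delete absent edge ", from, "->", to)
    adj[from, to] <- FALSE
  }
  for (i in seq_len(nrow(d$insertions))) {
    from <- d$insertions$from[i]; to <- d$insertions$to[i]
    check_pair_in_net(net, from, to)
    if (from == to)
      stop("cannot insert self-loop ", from, "->", to)
    if (from == net$readout_node)
      stop("cannot insert edge leaving the readout node: ", from, "->", to)
    if (adj[from, to])
      stop("cannot insert already-present edge ", from, "->", to)
    adj[from, to] <- TRUE
  }
  out <- net
  out$adjacency <- adj
  validate_signaling_network(out)
  out
}

check_pair_in_net <- function(net, from, to) {
  bad <- setdiff(c(from, to), net$node_names)
  if (length(bad) > 0)
    stop("unknown node(s) in rewiring pair ", from, "->", to, ": ",
         paste(bad, collapse = ", "))
  invisible(NULL)
}
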