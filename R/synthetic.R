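#' Construct an experimental-style dataset
#'
#' Bundles one treatment's measurements in the schema the fitting pipeline
#' consumes: a signalling block (one row per molecule, default 8 time
#' points 0..7) and a phenotype block (default 5 time points 0, 6, 7, 8, 9;
#' an `"apoptosis"` row is mandatory). Because the phenotype grid extends
#' past the signalling grid in index units, phenotype times are mapped
#' linearly onto the simulation horizon (`t * max(signalling) /
#' max(phenotype)`) for comparison with the simulated read-out; the mapped
#' times are stored as `phenotype_sim_times`.
#'
#' @param treatment Treatment label (e.g. "DMSO", "TAR", "DOX", "DT",
#'   "T-D", "D-T" or user-defined).
#' @param signalling Numeric matrix, molecules x signalling time points,
#'   with rownames.
#' @param phenotype Numeric matrix, phenotypes x phenotype time points,
#'   with rownames including `"apoptosis"`.
#' @param signalling_times,phenotype_times Time grids (defaults `0:7` and
#'   `c(0, 6, 7, 8, 9)`).
#' @param readout_node Name of the simulated read-out species the apoptosis
#'   phenotype corresponds to (default "Apop").
#' @param provenance Optional list recording how the dataset was produced
#'   (truth-network hash, seed, noise level, multipliers).
#' @return An object of class `experimental_dataset`.
#' @export
experimental_dataset <- function(treatment, signalling, phenotype,
                                 signalling_times = 0:7,
                                 phenotype_times = c(0, 6, 7, 8, 9),
                                 readout_node = "Apop",
                                 provenance = list()) {
  stopifnot(is.matrix(signalling),
            nrow(signalling) == 0 || !is.null(rownames(signalling)),
            ncol(signalling) == length(signalling_times),
            is.matrix(phenotype),
            nrow(phenotype) == 0 || !is.null(rownames(phenotype)),
            ncol(phenotype) == length(phenotype_times))
  if (!"apoptosis" %in% rownames(phenotype))
    stop("phenotype block must contain an 'apoptosis' row")
  if (any(signalling < 0) || any(phenotype < 0))
    stop("all measurements must be non-negative")
  colnames(signalling) <- paste0("t", signalling_times)
  colnames(phenotype) <- paste0("t", phenotype_times)
  horizon <- max(signalling_times)
  structure(list(
    treatment = treatment,
    signalling = signalling,
    signalling_times = as.numeric(signalling_times),
    phenotype = phenotype,
    phenotype_times = as.numeric(phenotype_times),
    phenotype_sim_times = as.numeric(phenotype_times) * horizon /
      max(phenotype_times),
    readout_node = readout_node,
    provenance = provenance
  ), class = "experimental_dataset")
}

#' @export
print.experimental_dataset <- function(x, ...) {
  cat("<experimental_dataset> treatment ", x$treatment, ": ",
      nrow(x$signalling), " molecules x ", ncol(x$signalling),
      " signalling points; ", nrow(x$phenotype), " phenotype(s) x ",
      ncol(x$phenotype), " points\n", sep = "")
  invisible(x)
}

#' Sample a full rate-constant matrix
#'
#' Draws i.i.d. Uniform(lo, hi) rates for every permissible ordered pair
#' (off-diagonal, not leaving the read-out node) of a network's node set,
#' so that any candidate topology the search may visit has a rate
#' available. Seeded and deterministic; the caller's RNG state is
#' untouched.
#'
#' @param net A [signaling_network()] supplying the node set and read-out.
#' @param lo,hi Positive rate bounds, `0 < lo < hi` (defaults 0.1 and 1.0:
#'   bounded away from 0 so every active edge has a visible effect on the
#'   dynamics).
#' @param seed Integer seed.
#' @return Rate matrix with positive entries on all permissible pairs.
#' @export
sample_rate_constants <- function(net, lo = 0.1, hi = 1.0, seed) {
  if (!(is.numeric(lo) && is.numeric(hi) && lo > 0 && hi > lo))
    stop("invalid bounds: need 0 < lo < hi")
  n <- length(net$node_names)
  rm_ <- withr::with_seed(seed, {
    m <- matrix(stats::runif(n * n, lo, hi), n, n,
                dimnames = list(net$node_names, net$node_names))
    m
  })
  diag(rm_) <- 0
  rm_[net$readout_node, ] <- 0
  validate_rate_matrix(rm_, net$node_names, net$readout_node)
  rm_
}

#' Plant a known rewiring into a network
#'
#' Deletes `n_deletions` uniformly sampled existing edges and inserts
#' `n_insertions` uniformly sampled permissible absent edges (off-diagonal,
#' not leaving the read-out). Used to build ground-truth recovery
#' benchmarks: generate data from the planted network, then check that the
#' search rediscovers exactly these edits.
#'
#' @param net A [signaling_network()].
#' @param n_deletions,n_insertions Edit counts.
#' @param seed Integer seed.
#' @return List with `network` (the rewired [signaling_network()]) and
#'   `diff` (the planted [rewiring_diff()], equal to
#'   `diff_networks(net, network)`).
#' @export
plant_rewiring <- function(net, n_deletions, n_insertions, seed) {
  ed <- network_edges(net)
  if (n_deletions > nrow(ed))
    stop("cannot delete ", n_deletions, " of ", nrow(ed), " edges")
  n <- length(net$node_names)
  adj <- net$adjacency
  permissible <- !adj
  diag(permissible) <- FALSE
  permissible[net$readout_node, ] <- FALSE
  absent <- which(permissible, arr.ind = TRUE)
  if (n_insertions > nrow(absent))
    stop("cannot insert ", n_insertions, " edges: only ", nrow(absent),
         " permissible absent pairs")
  picks <- withr::with_seed(seed, list(
    del = if (n_deletions > 0) sample.int(nrow(ed), n_deletions) else integer(0),
    ins = if (n_insertions > 0) sample.int(nrow(absent), n_insertions) else integer(0)
  ))
  deletions <- ed[picks$del, , drop = FALSE]
  insertions <- data.frame(
    from = net$node_names[absent[picks$ins, "row"]],
    to = net$node_names[absent[picks$ins, "col"]],
    stringsAsFactors = FALSE)
  d <- rewiring_diff(insertions = insertions, deletions = deletions)
  list(network = apply_rewiring(net, d), diff = d)
}

#' Generate a synthetic dataset from a ground-truth network
#'
#' Simulates the truth network from initial concentrations
#' `x0 = multipliers` (all ones = the untreated "DMSO" condition; a
#' treatment is modelled as per-node initial-concentration scaling),
#' samples the signalling block at the signalling time points and the
#' read-out at the phenotype times mapped onto the simulation horizon, and
#' adds seeded Gaussian noise with standard deviation `noise_sigma` times
#' each series' range, truncated at 0.
#'
#' @param truth_net Ground-truth [signaling_network()].
#' @param rm Rate matrix for `truth_net` (and any candidate edges).
#' @param treatment Treatment label stored with the dataset.
#' @param multipliers Non-negative per-node initial-concentration factors
#'   (default all ones).
#' @param noise_sigma Noise level as a fraction of per-series range
#'   (default 0.05; 0 gives the exact simulation).
#' @param seed Integer seed for the noise.
#' @param signalling_times,phenotype_times Measurement grids.
#' @return An [experimental_dataset()] whose provenance records the truth
#'   network hash, seed, noise level and multipliers.
#' @export
generate_dataset <- function(truth_net, rm, treatment = "DMSO",
                             multipliers = NULL, noise_sigma = 0.05, seed,
                             signalling_times = 0:7,
                             phenotype_times = c(0, 6, 7, 8, 9)) {
  n <- length(truth_net$node_names)
  if (is.null(multipliers)) multipliers <- rep(1, n)
  if (any(multipliers < 0)) stop("treatment multipliers must be non-negative")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  horizon <- max(signalling_times)
  pheno_sim <- as.numeric(phenotype_times) * horizon / max(phenotype_times)
  grid <- sort(unique(c(signalling_times, pheno_sim)))
  sim <- simulate_network(truth_net, rm, x0 = multipliers, time_points = grid)
  sig <- t(vapply(truth_net$node_names,
                  function(nd) series_at(sim, nd, at = signalling_times),
                  numeric(length(signalling_times))))
  pheno <- matrix(series_at(sim, truth_net$readout_node, at = pheno_sim),
                  nrow = 1, dimnames = list("apoptosis", NULL))
  if (noise_sigma > 0) {
    noisy <- withr::with_seed(seed, {
      add_range_noise <- function(m) {
        for (i in seq_len(nrow(m))) {
          rng <- max(m[i, ]) - min(m[i, ])
          m[i, ] <- m[i, ] + stats::rnorm(ncol(m), 0, noise_sigma * rng)
        }
        m
      }
      list(sig = add_range_noise(sig), pheno = add_range_noise(pheno))
    })
    sig <- pmax(noisy$sig, 0)
    pheno <- pmax(noisy$pheno, 0)
  }
  experimental_dataset(
    treatment = treatment, signalling = sig, phenotype = pheno,
    signalling_times = signalling_times, phenotype_times = phenotype_times,
    readout_node = truth_net$readout_node,
    provenance = list(
      truth_network_hash = rlang::hash(list(truth_net$node_names,
                                            network_edges(truth_net))),
      seed = seed, noise_sigma = noise_sigma,
      multipliers = as.numeric(multipliers),
      phenotype_time_mapping = "linear index scaling onto max(signalling_times)"
    ))
}
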