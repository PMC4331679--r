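#' Min-max normalise a series to [0, 1]
#'
#' Simulated concentrations are dimensionless while experimental
#' phosphorylation signals carry arbitrary units, so series are rescaled to
#' a common [0, 1] range before alignment. A constant series maps to all
#' zeros.
#'
#' @param s Non-empty finite numeric vector.
#' @return Numeric vector in [0, 1].
#' @export
normalize_series <- function(s) {
  if (length(s) == 0) stop("cannot normalise an empty series")
  if (any(!is.finite(s))) stop("series contains non-finite values")
  rng <- max(s) - min(s)
  if (rng == 0) return(rep(0, length(s)))
  (s - min(s)) / rng
}

#' Dynamic time warping distance
#'
#' Fills the classic DP table `D[i, j] = cost + min(D[i-1, j], D[i, j-1],
#' D[i-1, j-1])` with point cost `|s[i] - t[j]|`, `D[0, 0] = 0` and
#' infinity on the remaining first row/column, and returns `D[n, m]` — the
#' minimal total cost over all monotone warping alignments of the two
#' series. No warping-window constraint is applied.
#'
#' @param s,t Non-empty numeric series (lengths may differ).
#' @return Non-negative scalar; 0 iff the series are DTW-identical.
#' @examples
#' dtw_distance(c(1, 2, 3), c(1, 3)) # 1
#' @export
dtw_distance <- function(s, t) {
  n <- length(s); m <- length(t)
  if (n == 0 || m == 0) stop("cannot compute DTW of an empty series")
  D <- matrix(Inf, n + 1L, m + 1L)
  D[1L, 1L] <- 0
  for (i in seq_len(n)) {
    si <- s[i]
    for (j in seq_len(m)) {
      D[i + 1L, j + 1L] <- abs(si - t[j]) +
        min(D[i, j + 1L], D[i + 1L, j], D[i, j])
    }
  }
  D[n + 1L, m + 1L]
}

#' DTW goodness-of-fit between simulation and dataset
#'
#' Sums the DTW distance between each shared molecule's simulated and
#' experimental signalling series (both sampled at the dataset's
#' signalling time points), plus `pheno_weight` times the DTW distance
#' between the simulated read-out series (sampled at the dataset's
#' phenotype times mapped onto the simulation horizon) and the apoptosis
#' phenotype series. Lower is better; an exact match scores 0. Series are
#' min-max normalised before comparison unless `normalize = FALSE`.
#'
#' @param sim A `time_series_set` sampled at (at least) the dataset's
#'   signalling and mapped phenotype time points.
#' @param data An [experimental_dataset()].
#' @param shared_nodes Molecules to compare; default: all molecules present
#'   in both, excluding the read-out node (which is scored through the
#'   phenotype series).
#' @param pheno_weight Non-negative weight of the phenotype term
#'   (default 1).
#' @param normalize Min-max normalise each series first (default TRUE).
#' @return Non-negative scalar score.
#' @export
fitness_score <- function(sim, data, shared_nodes = NULL, pheno_weight = 1,
                          normalize = TRUE) {
  stopifnot(inherits(sim, "time_series_set"),
            inherits(data, "experimental_dataset"), pheno_weight >= 0)
  if (is.null(shared_nodes)) {
    shared_nodes <- setdiff(intersect(sim$node_names, rownames(data$signalling)),
                            data$readout_node)
  }
  if (length(shared_nodes) == 0 && pheno_weight == 0)
    stop("nothing to compare: empty shared_nodes and zero pheno_weight")
  missing_sim <- setdiff(shared_nodes, sim$node_names)
  missing_dat <- setdiff(shared_nodes, rownames(data$signalling))
  if (length(missing_sim) || length(missing_dat))
    stop("shared_nodes absent from simulation or dataset: ",
         paste(unique(c(missing_sim, missing_dat)), collapse = ", "))
  prep <- if (normalize) normalize_series else identity
  score <- 0
  for (nd in shared_nodes) {
    s_sim <- series_at(sim, nd, at = data$signalling_times)
    score <- score + dtw_distance(prep(s_sim),
                                  prep(data$signalling[nd, ]))
  }
  if (pheno_weight > 0) {
    if (!data$readout_node %in% sim$node_names)
      stop("readout node '", data$readout_node, "' absent from simulation")
    s_ro <- series_at(sim, data$readout_node, at = data$phenotype_sim_times)
    score <- score + pheno_weight *
      dtw_distance(prep(s_ro), prep(data$phenotype["apoptosis", ]))
  }
  score
}
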