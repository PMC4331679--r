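#' Replicate GA runs with derived seeds
#'
#' Runs the genetic algorithm `n_runs` times with seeds
#' `base_seed + 1, ..., base_seed + n_runs`. Replicates share no state, so
#' the result list is identical whether runs execute serially or
#' concurrently; a failing replicate aborts with its seed reported.
#'
#' @param baseline Baseline [signaling_network()].
#' @param rm_full Full rate matrix shared by all replicates (see
#'   [run_ga()]).
#' @param data [experimental_dataset()] to fit.
#' @param cfg [ga_config()]; its `rng_seed` is overridden per replicate.
#' @param n_runs Number of replicates (the reference protocol uses 150;
#'   scaled-down benchmarks use fewer).
#' @param base_seed Integer base seed.
#' @param ... Passed to [run_ga()] (`shared_nodes`, `pheno_weight`, ...).
#' @return List of `ga_result` objects.
#' @export
run_replicates <- function(baseline, rm_full, data, cfg, n_runs, base_seed,
                           ...) {
  stopifnot(n_runs >= 1)
  lapply(seq_len(n_runs), function(i) {
    cfg_i <- cfg
    cfg_i$rng_seed <- as.integer(base_seed + i)
    tryCatch(run_ga(baseline, rm_full, data, cfg_i, ...),
             error = function(e)
               stop("replicate ", i, " (seed ", base_seed + i, ") failed: ",
                    conditionMessage(e)))
  })
}

#' Tally edge edits across replicate runs
#'
#' Diffs each run's final best network against the baseline and counts how
#' often every insertion and deletion occurs. Edits appearing consistently
#' across independent replicates are the conserved rewiring prediction;
#' run-specific edits show up with low counts.
#'
#' @param results Non-empty list of `ga_result`s.
#' @param baseline The reference [signaling_network()].
#' @return A `consensus_rewiring`: list with `n_runs`, and data frames
#'   `insertion_freq` / `deletion_freq` (`from`, `to`, `count`, sorted by
#'   decreasing count).
#' @export
tally_rewirings <- function(results, baseline) {
  if (length(results) == 0) stop("no results to tally")
  ins <- list(); del <- list()
  for (res in results) {
    d <- diff_networks(baseline, res$best_network)
    ins[[length(ins) + 1L]] <- d$insertions
    del[[length(del) + 1L]] <- d$deletions
  }
  count_edges <- function(lst) {
    all <- do.call(rbind, lst)
    if (is.null(all) || nrow(all) == 0)
      return(cbind(empty_edge_df(), count = integer(0)))
    tab <- table(edge_keys(all))
    parts <- strsplit(names(tab), "\r", fixed = TRUE)
    out <- data.frame(from = vapply(parts, `[`, "", 1),
                      to = vapply(parts, `[`, "", 2),
                      count = as.integer(tab), stringsAsFactors = FALSE)
    out[order(-out$count, out$from, out$to), , drop = FALSE]
  }
  structure(list(n_runs = length(results),
                 insertion_freq = count_edges(ins),
                 deletion_freq = count_edges(del)),
            class = "consensus_rewiring")
}

#' @export
print.consensus_rewiring <- function(x, ...) {
  cat("<consensus_rewiring> over ", x$n_runs, " run(s): ",
      nrow(x$insertion_freq), " distinct insertion(s), ",
      nrow(x$deletion_freq), " distinct deletion(s)\n", sep = "")
  show <- function(df, sgn) {
    top <- utils::head(df, 5)
    for (i in seq_len(nrow(top)))
      cat("  ", sgn, " ", top$from[i], "->", top$to[i], "  ",
          top$count[i], "/", x$n_runs, "\n", sep = "")
  }
  show(x$deletion_freq, "-")
  show(x$insertion_freq, "+")
  invisible(x)
}

#' Edits meeting a consensus frequency threshold
#'
#' @param cr A `consensus_rewiring` from [tally_rewirings()].
#' @param threshold_fraction Fraction of runs an edit must reach,
#'   `0 < threshold_fraction <= 1` (default 0.9, matching the >= 90%
#'   frequencies reported for conserved edits in the reference protocol).
#' @return A [rewiring_diff()] of the retained edits.
#' @export
consensus_diff <- function(cr, threshold_fraction = 0.9) {
  stopifnot(threshold_fraction > 0, threshold_fraction <= 1)
  cut <- threshold_fraction * cr$n_runs
  rewiring_diff(
    insertions = cr$insertion_freq[cr$insertion_freq$count >= cut,
                                   c("from", "to"), drop = FALSE],
    deletions = cr$deletion_freq[cr$deletion_freq$count >= cut,
                                 c("from", "to"), drop = FALSE])
}

#' Build the consensus rewired network
#'
#' Applies every edit whose replicate count reaches
#' `threshold_fraction * n_runs` to the baseline. Used staged: fit the
#' control-treatment data from the healthy network to obtain the
#' tumorigenic consensus, then fit the drug-treatment data from that
#' consensus to obtain the drug-sensitive one — the same function serves
#' both stages unchanged.
#'
#' @inheritParams consensus_diff
#' @param baseline The reference [signaling_network()] the tally was made
#'   against.
#' @return The consensus [signaling_network()].
#' @export
build_consensus <- function(cr, baseline, threshold_fraction = 0.9) {
  apply_rewiring(baseline, consensus_diff(cr, threshold_fraction))
}
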