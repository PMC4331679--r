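#' Genetic-algorithm configuration
#'
#' @param max_generations Maximum number of generations (required; the
#'   search also stops early on convergence).
#' @param rng_seed Integer seed making a run fully reproducible (required;
#'   no wall-clock seeding anywhere in the package).
#' @param population_size Number of chromosomes per generation
#'   (default 100).
#' @param n_select Number of best-scoring chromosomes kept for breeding
#'   (default 50).
#' @param mutation_rate Per-bit flip probability applied to every offspring
#'   (default 0.01).
#' @param convergence_patience Generations without a best-score improvement
#'   greater than `epsilon` before stopping (default 10).
#' @param epsilon Minimal improvement counted as progress (default 1e-6).
#' @param init_flip_prob Per-bit flip probability used to scatter the
#'   initial population around the baseline chromosome (default 0.01,
#'   matching the per-offspring mutation load and the few-edit rewiring
#'   scale the method targets).
#' @param init_mode `"baseline"` (baseline-seeded random flips, default) or
#'   `"uniform"` (uniform random bitstrings).
#' @param crossover `"single"` (default) or `"two_point"`.
#' @param generation_mode `"keep_selected"` (default): the `n_select`
#'   survivors pass unchanged into the next generation and mutated
#'   crossover offspring refill the population — selection can retain
#'   progress against the heavy per-offspring mutation load of a long
#'   chromosome. `"replace_all"`: the next generation consists entirely of
#'   `population_size` mutated crossover offspring (no survivors); with
#'   484-bit chromosomes at mutation 0.01 this variant drifts and is kept
#'   for comparison.
#' @return An object of class `ga_config`.
#' @export
ga_config <- function(max_generations, rng_seed,
                      population_size = 100L, n_select = 50L,
                      mutation_rate = 0.01, convergence_patience = 10L,
                      epsilon = 1e-6, init_flip_prob = 0.01,
                      init_mode = c("baseline", "uniform"),
                      crossover = c("single", "two_point"),
                      generation_mode = c("keep_selected", "replace_all")) {
  init_mode <- match.arg(init_mode)
  crossover <- match.arg(crossover)
  generation_mode <- match.arg(generation_mode)
  stopifnot(max_generations >= 1, population_size >= 2,
            n_select >= 1, n_select <= population_size,
            mutation_rate >= 0, mutation_rate <= 1,
            init_flip_prob >= 0, init_flip_prob <= 1,
            convergence_patience >= 1, is.numeric(rng_seed))
  structure(list(max_generations = as.integer(max_generations),
                 rng_seed = as.integer(rng_seed),
                 population_size = as.integer(population_size),
                 n_select = as.integer(n_select),
                 mutation_rate = mutation_rate,
                 convergence_patience = as.integer(convergence_patience),
                 epsilon = epsilon, init_flip_prob = init_flip_prob,
                 init_mode = init_mode, crossover = crossover,
                 generation_mode = generation_mode),
            class = "ga_config")
}

#' Initial GA population
#'
#' Each chromosome starts from the baseline network's encoding with every
#' non-masked bit independently flipped with probability
#' `cfg$init_flip_prob` (or, with `init_mode = "uniform"`, drawn uniformly
#' at random). Masked (diagonal / read-out-row) bits stay 0. Uses the
#' current RNG state; [run_ga()] seeds it from `cfg$rng_seed`.
#'
#' @param baseline A [signaling_network()].
#' @param cfg A [ga_config()].
#' @return List of `cfg$population_size` chromosomes.
#' @export
initialize_population <- function(baseline, cfg) {
  base_chrom <- encode_chromosome(baseline)
  L <- length(base_chrom$bits)
  masked <- masked_bit_positions(base_chrom$node_names,
                                 base_chrom$readout_node)
  lapply(seq_len(cfg$population_size), function(i) {
    bits <- switch(cfg$init_mode,
      baseline = xor(base_chrom$bits, stats::runif(L) < cfg$init_flip_prob),
      uniform = stats::runif(L) < 0.5)
    bits[masked] <- FALSE
    new_chromosome(bits, base_chrom$node_names, base_chrom$readout_node)
  })
}

#' Single-point crossover of two chromosomes
#'
#' Child 1 takes bits `1..point` from the first parent and the remainder
#' from the second; child 2 is the mirror image. Structural masks are
#' re-applied to both children.
#'
#' @param p1,p2 Parent chromosomes of equal length.
#' @param point Cut position, `1 <= point <= length - 1`.
#' @return List of two offspring chromosomes.
#' @export
crossover <- function(p1, p2, point) {
  L <- length(p1$bits)
  stopifnot(length(p2$bits) == L)
  if (point < 1 || point > L - 1)
    stop("crossover point must be in [1, ", L - 1, "]")
  masked <- masked_bit_positions(p1$node_names, p1$readout_node)
  c1 <- c(p1$bits[1:point], p2$bits[(point + 1):L])
  c2 <- c(p2$bits[1:point], p1$bits[(point + 1):L])
  c1[masked] <- FALSE
  c2[masked] <- FALSE
  list(new_chromosome(c1, p1$node_names, p1$readout_node),
       new_chromosome(c2, p1$node_names, p1$readout_node))
}

#' Bit-flip mutation
#'
#' Flips every non-masked bit independently with probability `rate`;
#' masked bits are forced to 0. Uses the current RNG state.
#'
#' @param chrom A chromosome.
#' @param rate Per-bit flip probability in [0, 1] (default 0.01).
#' @return The mutated chromosome.
#' @export
mutate_chromosome <- function(chrom, rate = 0.01) {
  stopifnot(rate >= 0, rate <= 1)
  L <- length(chrom$bits)
  bits <- xor(chrom$bits, stats::runif(L) < rate)
  bits[masked_bit_positions(chrom$node_names, chrom$readout_node)] <- FALSE
  chrom$bits <- bits
  chrom
}

#' Truncation selection with deterministic tie-breaking
#'
#' Returns the `n_select` chromosomes with the lowest fitness. Ties are
#' broken first by smaller Hamming distance to the baseline chromosome,
#' then by lexicographic bit order, so selection is fully deterministic.
#'
#' @param population List of chromosomes.
#' @param scores Numeric fitness vector aligned with `population` (lower
#'   is better).
#' @param n_select How many to keep.
#' @param baseline The baseline [signaling_network()] used for the
#'   Hamming tie-break.
#' @return List of `n_select` chromosomes, best first.
#' @export
select_best <- function(population, scores, n_select, baseline) {
  if (length(population) != length(scores))
    stop("scores and population lengths differ")
  stopifnot(n_select <= length(population))
  base_bits <- encode_chromosome(baseline)$bits
  hamming <- vapply(population, function(ch) sum(xor(ch$bits, base_bits)),
                    numeric(1))
  lexi <- vapply(population, function(ch)
    paste(as.integer(ch$bits), collapse = ""), character(1))
  ord <- order(scores, hamming, lexi)
  population[ord[seq_len(n_select)]]
}

chromosome_key <- function(chrom) {
  paste(as.integer(chrom$bits), collapse = "")
}

#' Run the genetic algorithm
#'
#' Searches topology space for networks minimising the DTW fitness against
#' a dataset. Each generation: evaluate all chromosomes (simulate the
#' decoded topology with the pre-drawn rates, score with
#' [fitness_score()]), keep the `n_select` best, breed offspring by
#' crossover of parent pairs drawn uniformly with replacement from the
#' selected (cut points uniform), and mutate the offspring. Under the
#' default `generation_mode = "keep_selected"` the survivors pass
#' unchanged into the next generation and offspring refill it to
#' `population_size`; under `"replace_all"` the next generation is
#' offspring only. The best network ever evaluated is tracked outside the
#' population and returned. The run stops at `max_generations` or once the
#' best score has not improved by more than `epsilon` for
#' `convergence_patience` generations.
#'
#' Because `rm_full` supplies a fixed rate for every permissible edge,
#' fitness is a deterministic function of the bitstring, and identical
#' seed + config + inputs give bit-identical results. Repeated bitstrings
#' are memoised within a run.
#'
#' @param baseline Baseline [signaling_network()] (initial-population
#'   centre and tie-break reference).
#' @param rm_full Rate matrix with a positive rate for every permissible
#'   (non-masked) ordered pair, e.g. from [sample_rate_constants()],
#'   optionally overwritten with known rates on baseline edges.
#' @param data [experimental_dataset()] to fit.
#' @param cfg [ga_config()].
#' @param shared_nodes,pheno_weight,normalize Passed to [fitness_score()].
#' @param x0 Initial concentrations for the candidate simulations; default:
#'   the dataset's provenance multipliers if recorded, else all ones.
#' @return A `ga_result`: list with `best_network`, `best_chromosome`,
#'   `best_score`, `score_trace` (best-so-far per generation,
#'   non-increasing), `generations_run`, `seed`, `n_evaluations`.
#' @export
run_ga <- function(baseline, rm_full, data, cfg, shared_nodes = NULL,
                   pheno_weight = 1, normalize = TRUE, x0 = NULL) {
  stopifnot(inherits(cfg, "ga_config"))
  validate_rate_matrix(rm_full, baseline$node_names, baseline$readout_node)
  n <- length(baseline$node_names)
  if (is.null(x0)) {
    x0 <- if (!is.null(data$provenance$multipliers))
      data$provenance$multipliers else rep(1, n)
  }
  grid <- sort(unique(c(data$signalling_times, data$phenotype_sim_times)))
  if (is.null(shared_nodes))
    shared_nodes <- setdiff(intersect(baseline$node_names,
                                      rownames(data$signalling)),
                            data$readout_node)
  memo <- new.env(parent = emptyenv())
  n_eval <- 0L
  evaluate <- function(chrom) {
    key <- chromosome_key(chrom)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    sc <- tryCatch({
      net <- decode_chromosome(chrom)
      sim <- simulate_network(net, rm_full, x0 = x0, time_points = grid)
      fitness_score(sim, data, shared_nodes = shared_nodes,
                    pheno_weight = pheno_weight, normalize = normalize)
    }, error = function(e) {
      stop("fitness evaluation failed for chromosome ",
           substr(key, 1, 40), "... : ", conditionMessage(e))
    })
    memo[[key]] <- sc
    n_eval <<- n_eval + 1L
    sc
  }

  state <- withr::with_seed(cfg$rng_seed, {
    pop <- initialize_population(baseline, cfg)
    L <- n * n
    best_score <- Inf
    best_chrom <- NULL
    trace <- numeric(0)
    stalled <- 0L
    gens <- 0L
    for (gen in seq_len(cfg$max_generations)) {
      gens <- gen
      scores <- vapply(pop, evaluate, numeric(1))
      gen_best <- which.min(scores)
      if (scores[gen_best] < best_score - cfg$epsilon) {
        stalled <- 0L
      } else {
        stalled <- stalled + 1L
      }
      if (scores[gen_best] < best_score) {
        best_score <- scores[gen_best]
        best_chrom <- pop[[gen_best]]
      }
      trace <- c(trace, best_score)
      if (stalled >= cfg$convergence_patience || gen == cfg$max_generations)
        break
      selected <- select_best(pop, scores, cfg$n_select, baseline)
      n_offspring <- if (cfg$generation_mode == "keep_selected")
        cfg$population_size - cfg$n_select else cfg$population_size
      offspring <- vector("list", 0L)
      while (length(offspring) < n_offspring) {
        pair <- sample.int(cfg$n_select, 2L, replace = TRUE)
        if (cfg$crossover == "single") {
          pt <- sample.int(L - 1L, 1L)
          kids <- crossover(selected[[pair[1]]], selected[[pair[2]]], pt)
        } else {
          pts <- sort(sample.int(L - 1L, 2L))
          mid <- crossover(selected[[pair[1]]], selected[[pair[2]]], pts[1])
          kids <- crossover(mid[[1]], mid[[2]], pts[2])
        }
        offspring <- c(offspring, kids)
      }
      offspring <- lapply(offspring[seq_len(n_offspring)],
                          mutate_chromosome, rate = cfg$mutation_rate)
      pop <- if (cfg$generation_mode == "keep_selected")
        c(selected, offspring) else offspring
    }
    list(best_chrom = best_chrom, best_score = best_score,
         trace = trace, gens = gens)
  })
  best_chrom <- state$best_chrom
  best_score <- state$best_score
  trace <- state$trace
  gens <- state$gens
  structure(list(best_network = decode_chromosome(best_chrom),
                 best_chromosome = best_chrom,
                 best_score = best_score,
                 score_trace = trace,
                 generations_run = gens,
                 seed = cfg$rng_seed,
                 n_evaluations = n_eval),
            class = "ga_result")
}

#' @export
print.ga_result <- function(x, ...) {
  cat("<ga_result> best score ", format(x$best_score, digits = 6), " after ",
      x$generations_run, " generation(s), ", x$n_evaluations,
      " unique evaluations (seed ", x$seed, ")\n", sep = "")
  invisible(x)
}
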