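test_that("config validation catches inconsistent settings", {
  expect_error(ga_config(max_generations = 10, rng_seed = 1, n_select = 200))
  expect_error(ga_config(max_generations = 10, rng_seed = 1,
                         mutation_rate = 1.5))
  expect_error(ga_config(max_generations = 0, rng_seed = 1))
})

test_that("initial population is baseline-centred and seeded-deterministic", {
  n1 <- build_baseline_network()
  cfg0 <- ga_config(max_generations = 5, rng_seed = 1, init_flip_prob = 0,
                    population_size = 10, n_select = 5)
  pop0 <- withr::with_seed(1, initialize_population(n1, cfg0))
  base_bits <- encode_chromosome(n1)$bits
  expect_length(pop0, 10)
  for (ch in pop0) expect_identical(ch$bits, base_bits)

  cfg <- ga_config(max_generations = 5, rng_seed = 1, population_size = 100)
  p1 <- withr::with_seed(9, initialize_population(n1, cfg))
  p2 <- withr::with_seed(9, initialize_population(n1, cfg))
  expect_identical(p1, p2)
  expect_length(p1, 100)
  masked <- masked_bit_positions(n1$node_names, "Apop")
  for (ch in p1[1:10]) expect_false(any(ch$bits[masked]))
})

test_that("single-point crossover splices and re-masks as defined", {
  net <- toy_chain_network() # 3 nodes, free bits at positions 2, 3, 4, 6
  mk <- function(on) {
    ch <- encode_chromosome(net)
    ch$bits[] <- FALSE
    ch$bits[on] <- TRUE
    ch
  }
  p1 <- mk(c(2, 3)); p2 <- mk(c(4, 6))
  kids <- crossover(p1, p2, 3)
  expect_identical(which(kids[[1]]$bits), c(2L, 3L, 4L, 6L))
  expect_identical(which(kids[[2]]$bits), integer(0))
  # identical parents reproduce themselves for any cut point
  for (pt in c(1, 5, 8)) {
    kk <- crossover(p1, p1, pt)
    expect_identical(kk[[1]]$bits, p1$bits)
    expect_identical(kk[[2]]$bits, p1$bits)
  }
  # exchange property: at every position the children's bits are a
  # permutation of the parents' bits
  withr::with_seed(2, {
    net8 <- random_valid_network(8)
    c1 <- encode_chromosome(net8)
    c2 <- encode_chromosome(random_valid_network(8))
    c2$node_names <- c1$node_names; c2$readout_node <- c1$readout_node
    c2$bits[masked_bit_positions(c1$node_names, c1$readout_node)] <- FALSE
    kk <- crossover(c1, c2, 30)
    expect_identical(kk[[1]]$bits + kk[[2]]$bits, c1$bits + c2$bits)
  })
  expect_error(crossover(p1, p2, 0), "point")
  expect_error(crossover(p1, p2, 9), "point")
})

test_that("mutation respects rate extremes, masks and its expected load", {
  n1 <- build_baseline_network()
  ch <- encode_chromosome(n1)
  masked <- masked_bit_positions(n1$node_names, "Apop")
  free <- setdiff(seq_along(ch$bits), masked)
  expect_identical(withr::with_seed(1, mutate_chromosome(ch, 0)), ch)
  full <- withr::with_seed(1, mutate_chromosome(ch, 1))
  expect_identical(full$bits[free], !ch$bits[free])
  expect_false(any(full$bits[masked]))
  # empirical per-bit flip ratio over 2e4 draws (acceptance scales to 1e5)
  flips <- withr::with_seed(3, {
    tot <- 0
    for (k in 1:20000)
      tot <- tot + sum(xor(mutate_chromosome(ch, 0.01)$bits[free],
                           ch$bits[free]))
    tot
  })
  rate_hat <- flips / (20000 * length(free))
  expect_equal(rate_hat, 0.01, tolerance = 0.03)
})

test_that("selection truncates deterministically with the stated tie rules", {
  net <- toy_chain_network()
  base <- encode_chromosome(net)
  mk <- function(on) { ch <- base; ch$bits[] <- FALSE; ch$bits[on] <- TRUE; ch }
  # baseline encodes edges A->B, B->Out as bits {2, 6}
  pop <- list(mk(c(2, 3)),      # Hamming 2, lexicographically largest
              mk(c(2, 3, 4)),   # Hamming 3
              mk(c(4, 6)),      # Hamming 2
              mk(c(2, 4)))      # Hamming 2
  # equal scores: Hamming to baseline, then lexicographic bit order
  expect_identical(select_best(pop, rep(1, 4), 4, net), pop[c(3, 4, 1, 2)])
  # score dominates the tie-breaks
  sel <- select_best(pop, c(9, 1, 1, 1), 2, net)
  expect_identical(sel, pop[c(3, 4)])
  # equal score and equal Hamming distance: lexicographic order decides
  lex <- select_best(list(mk(3), mk(4)), c(0, 0), 1, net)
  expect_identical(which(lex[[1]]$bits), 4L)
  expect_error(select_best(pop, c(1, 2), 2, net), "lengths differ")
})

test_that("GA finds the known global optimum on noiseless self data", {
  net <- toy_chain_network()
  rmf <- sample_rate_constants(net, seed = 21)
  ds <- generate_dataset(net, rmf, noise_sigma = 0, seed = 1)
  cfg <- ga_config(max_generations = 10, rng_seed = 5, population_size = 30,
                   n_select = 15)
  res <- run_ga(net, rmf, ds, cfg)
  expect_identical(res$best_score, 0)
  expect_identical(res$best_network$adjacency, net$adjacency)
  expect_true(all(diff(res$score_trace) <= 0))
  masked <- masked_bit_positions(net$node_names, "Out")
  expect_false(any(res$best_chromosome$bits[masked]))
  # bit-identical reproducibility from the seed
  res2 <- run_ga(net, rmf, ds, cfg)
  expect_identical(res, res2)
})

test_that("GA matches exhaustive neighbourhood search on a 5-node planted instance", {
  inst <- five_node_instance()
  grid <- sort(unique(c(inst$data$signalling_times,
                        inst$data$phenotype_sim_times)))
  # brute-force oracle: all topologies within Hamming distance 2 of baseline
  ch0 <- encode_chromosome(inst$net)
  free <- setdiff(seq_len(25), masked_bit_positions(inst$net$node_names, "Out"))
  cands <- list(ch0$bits)
  for (b in free) { x <- ch0$bits; x[b] <- !x[b]; cands[[length(cands) + 1]] <- x }
  cb <- utils::combn(free, 2)
  for (k in seq_len(ncol(cb))) {
    x <- ch0$bits; x[cb[, k]] <- !x[cb[, k]]
    cands[[length(cands) + 1]] <- x
  }
  brute <- vapply(cands, function(bits) {
    ch <- ch0; ch$bits <- bits
    fitness_score(simulate_network(decode_chromosome(ch), inst$rmf,
                                   time_points = grid), inst$data)
  }, numeric(1))
  expect_equal(min(brute), 0) # the planted truth is in the neighbourhood
  truth_bits <- encode_chromosome(inst$planted$network)$bits
  expect_identical(cands[[which.min(brute)]], truth_bits)

  hits <- 0
  for (s in 1:20) {
    cfg <- ga_config(max_generations = 30, rng_seed = s,
                     convergence_patience = 30)
    res <- run_ga(inst$net, inst$rmf, inst$data, cfg)
    hits <- hits + (abs(res$best_score - min(brute)) < 1e-9)
  }
  expect_gte(hits, 18)
})
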