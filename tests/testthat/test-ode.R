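test_that("rate operator reproduces the transfer rule exactly", {
  net <- signaling_network(c("A", "B"), data.frame(from = "A", to = "B"), "B")
  rm2 <- rate_matrix(c("A", "B"), data.frame(from = "A", to = "B", rate = 2),
                     "B")
  M <- build_rate_operator(net, rm2)
  expect_equal(unname(M), matrix(c(-2, 2, 0, 0), 2, 2))
})

test_that("baseline AKT equation matches the transcribed terms", {
  n1 <- build_baseline_network()
  rmf <- sample_rate_constants(n1, seed = 2)
  M <- build_rate_operator(n1, rmf)
  akt <- match("AKT", n1$node_names)
  # dAKT/dt = -rates(AKT, p53) * AKT + rates(HER2, AKT) * HER2
  expected <- numeric(22)
  expected[akt] <- -rmf["AKT", "p53"]
  expected[match("HER2", n1$node_names)] <- rmf["HER2", "AKT"]
  expect_equal(unname(M[akt, ]), expected)
})

test_that("operator columns sum to zero for random networks", {
  withr::with_seed(5, {
    for (k in 1:30) {
      net <- random_valid_network(sample(3:22, 1))
      rmf <- sample_rate_constants(net, seed = k)
      M <- build_rate_operator(net, rmf)
      expect_lt(max(abs(colSums(M))), 1e-12)
      expect_true(all(M[row(M) != col(M)] >= 0))
    }
  })
})

test_that("an active edge without a rate is a configuration error", {
  net <- toy_chain_network()
  rm0 <- rate_matrix(net$node_names,
                     data.frame(from = "A", to = "B", rate = 1), "Out")
  expect_error(build_rate_operator(net, rm0), "B->Out")
})

test_that("simulation handles degenerate and closed-form cases", {
  net <- toy_chain_network()
  # all rates zero: edgeless network stays at x0
  empty <- signaling_network(net$node_names,
                             data.frame(from = character(0),
                                        to = character(0)), "Out")
  rm0 <- matrix(0, 3, 3, dimnames = list(net$node_names, net$node_names))
  sim0 <- simulate_network(empty, rm0, x0 = c(2, 1, 0.5), time_points = 0:4)
  expect_equal(sim0$values, matrix(rep(c(2, 1, 0.5), each = 5), 5, 3,
                                   dimnames = list(NULL, net$node_names)))
  # one-step decay A -> B at rate 1: A(1) = exp(-1)
  two <- signaling_network(c("A", "B"), data.frame(from = "A", to = "B"), "B")
  rm1 <- rate_matrix(c("A", "B"), data.frame(from = "A", to = "B", rate = 1),
                     "B")
  sim1 <- simulate_network(two, rm1, x0 = c(1, 0), time_points = c(0, 1))
  expect_equal(unname(sim1$values[2, "A"]), exp(-1), tolerance = 1e-7)
  expect_equal(unname(sim1$values[2, "B"]), 1 - exp(-1), tolerance = 1e-7)
  expect_error(simulate_network(two, rm1, x0 = c(1, 0), time_points = 1:3),
               "start at 0")
})

test_that("simulation conserves mass and matches the matrix exponential", {
  n1 <- build_baseline_network()
  rmf <- sample_rate_constants(n1, seed = 8)
  sim <- simulate_network(n1, rmf)
  expect_lt(max(abs(rowSums(sim$values) - 22)) / 22, 1e-6)
  M <- build_rate_operator(n1, rmf)
  for (tt in c(1, 4, 7)) {
    ref <- reference_solution(M, rep(1, 22), tt)
    expect_lt(max(abs(sim$values[sim$time_points == tt, ] - ref)), 1e-6)
  }
  # cross-validation on random instances (more in the acceptance suite)
  withr::with_seed(31, {
    for (k in 1:20) {
      net <- random_valid_network(sample(3:22, 1))
      rmk <- sample_rate_constants(net, seed = 1000 + k)
      tps <- c(0, sort(runif(3, 0.5, 7)))
      simk <- simulate_network(net, rmk, time_points = tps)
      Mk <- build_rate_operator(net, rmk)
      for (i in seq_along(tps)) {
        expect_lt(max(abs(simk$values[i, ] -
                            reference_solution(Mk, rep(1, length(net$node_names)),
                                               tps[i]))), 1e-6)
      }
    }
  })
})

test_that("the readout series is non-decreasing and values stay non-negative", {
  n1 <- build_baseline_network()
  rmf <- sample_rate_constants(n1, seed = 13)
  sim <- simulate_network(n1, rmf, time_points = seq(0, 7, by = 0.5))
  apop <- series_at(sim, "Apop")
  expect_true(all(diff(apop) >= -1e-9))
  expect_true(all(sim$values >= 0))
})

test_that("reference_solution handles identity cases", {
  M <- matrix(0, 3, 3)
  expect_equal(reference_solution(M, c(1, 2, 3), 5), c(1, 2, 3))
  M2 <- matrix(rnorm(9), 3, 3)
  expect_equal(reference_solution(M2, c(1, 2, 3), 0), c(1, 2, 3))
})
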