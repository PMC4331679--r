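test_that("baseline apoptosis network has the transcribed structure", {
  n1 <- build_baseline_network()
  expect_length(n1$node_names, 22)
  expect_identical(n1$readout_node, "Apop")
  ed <- network_edges(n1)
  expect_identical(nrow(ed), 32L)
  expect_true(n1$adjacency["AKT", "p53"])       # rc_18
  expect_true(n1$adjacency["Casp3", "Apop"])    # rc_1, sole readout inflow
  expect_true(n1$adjacency["SMAC", "XIAP"])     # rc_21
  expect_false(any(n1$adjacency["Apop", ]))
  expect_false(any(diag(n1$adjacency)))
  # every rate constant 1..32 defines exactly one edge
  et <- baseline_edge_table()
  expect_identical(et$rc, 1:32)
  expect_false(anyDuplicated(paste(et$from, et$to)) > 0)
})

test_that("constructor rejects malformed networks", {
  expect_error(signaling_network(c("A", "A", "Out"),
                                 data.frame(from = "A", to = "Out"), "Out"),
               "unique")
  expect_error(signaling_network(c("A", "B"),
                                 data.frame(from = "A", to = "B"), "Z"),
               "readout")
  expect_error(signaling_network(c("A", "B"),
                                 data.frame(from = "A", to = "A"), "B"),
               "self-loop")
  expect_error(signaling_network(c("A", "B"),
                                 data.frame(from = "B", to = "A"), "B"),
               "pure sink")
  expect_error(signaling_network(c("A", "B"),
                                 data.frame(from = c("A", "A"),
                                            to = c("B", "B")), "B"),
               "duplicate")
})

test_that("chromosome encoding is row-major with the stated length", {
  n1 <- build_baseline_network()
  ch <- encode_chromosome(n1)
  expect_length(ch$bits, 484)
  expect_identical(sum(ch$bits), 32L)
  # bit position arithmetic: AKT -> p53
  i <- match("AKT", n1$node_names); j <- match("p53", n1$node_names)
  expect_true(ch$bits[(i - 1) * 22 + j])
  # edgeless network encodes to all zeros
  empty <- signaling_network(n1$node_names, data.frame(from = character(0),
                                                       to = character(0)),
                             "Apop")
  expect_identical(sum(encode_chromosome(empty)$bits), 0L)
})

test_that("encode/decode round-trips on random valid networks", {
  withr::with_seed(101, {
    for (k in 1:1000) {
      n <- sample(3:22, 1)
      net <- random_valid_network(n)
      back <- decode_chromosome(encode_chromosome(net))
      expect_identical(back$adjacency, net$adjacency)
      expect_identical(back$readout_node, net$readout_node)
    }
  })
})

test_that("decode masks forbidden bits with a warning and checks length", {
  net <- toy_chain_network()
  ch <- encode_chromosome(net)
  ch$bits[1] <- TRUE # diagonal (A, A)
  expect_warning(dec <- decode_chromosome(ch), "forbidden")
  expect_identical(dec$adjacency, net$adjacency)
  ch2 <- encode_chromosome(net)
  ch2$bits <- ch2$bits[-1]
  expect_error(decode_chromosome(ch2), "length")
})

test_that("diff and apply are mutually inverse", {
  n1 <- build_baseline_network()
  d0 <- diff_networks(n1, n1)
  expect_identical(nrow(d0$insertions) + nrow(d0$deletions), 0L)
  expect_identical(apply_rewiring(n1, d0)$adjacency, n1$adjacency)

  one_del <- rewiring_diff(deletions = data.frame(from = "SMAC", to = "XIAP"))
  n1b <- apply_rewiring(n1, one_del)
  d <- diff_networks(n1, n1b)
  expect_identical(d$deletions, data.frame(from = "SMAC", to = "XIAP",
                                           stringsAsFactors = FALSE))
  expect_identical(nrow(d$insertions), 0L)
  # swapping the arguments swaps the roles
  dr <- diff_networks(n1b, n1)
  expect_identical(dr$insertions, d$deletions)
  expect_identical(dr$deletions, d$insertions)

  withr::with_seed(77, {
    for (k in 1:50) {
      a <- random_valid_network(8)
      b <- random_valid_network(8)
      expect_identical(apply_rewiring(a, diff_networks(a, b))$adjacency,
                       b$adjacency)
    }
  })
})

test_that("apply_rewiring enforces its preconditions by name", {
  n1 <- build_baseline_network()
  expect_error(apply_rewiring(n1, rewiring_diff(
    deletions = data.frame(from = "XIAP", to = "SMAC"))),
    "absent edge XIAP->SMAC")
  expect_error(apply_rewiring(n1, rewiring_diff(
    insertions = data.frame(from = "SMAC", to = "XIAP"))),
    "already-present")
  expect_error(apply_rewiring(n1, rewiring_diff(
    insertions = data.frame(from = "Apop", to = "Casp3"))),
    "readout")
  expect_error(diff_networks(n1, toy_chain_network()), "node set")
  expect_error(rewiring_diff(insertions = data.frame(from = "A", to = "B"),
                             deletions = data.frame(from = "A", to = "B")),
               "disjoint")
})
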