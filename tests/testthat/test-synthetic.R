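test_that("generation is deterministic under a seed", {
  a <- random_network(4, edge_probability = 0.5, seed = 7)
  b <- random_network(4, edge_probability = 0.5, seed = 7)
  expect_identical(a$interactions, b$interactions)
  expect_identical(tidy(random_parameters(a, seed = 3)),
                   tidy(random_parameters(b, seed = 3)))
  c_ <- random_network(4, edge_probability = 0.5, seed = 8)
  expect_false(identical(a$interactions, c_$interactions))
  # a fully connected pair is reproducible edge for edge
  full <- random_network(2, edge_probability = 1, seed = 7)
  expect_equal(nrow(full$interactions), 2)
})

test_that("every generated entity is regulated", {
  lonely <- random_network(1, edge_probability = 0, seed = 1)
  expect_equal(nrow(lonely$interactions), 1)
  expect_equal(lonely$interactions$source, lonely$interactions$target)
  expect_equal(attr(lonely, "added_self_inputs"), "v1")
  for (seed in 1:10) {
    net <- random_network(5, edge_probability = 0.2, seed = seed)
    expect_true(all(net$entities$name %in% net$interactions$target))
  }
})

test_that("edge counts follow the binomial expectation", {
  p <- 0.17
  n <- 9
  counts <- vapply(1:300, function(seed) {
    net <- random_network(n, edge_probability = p, seed = seed,
                          ensure_regulated = FALSE)
    nrow(net$interactions)
  }, numeric(1))
  npairs <- n * (n - 1)
  mu <- p * npairs
  sdev <- sqrt(npairs * p * (1 - p)) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - mu), 3 * sdev + 1e-9)
})

test_that("snoussi-only sampling always passes the validator", {
  for (seed in 1:50) {
    net <- random_network(4, edge_probability = 0.5, seed = seed)
    ps <- random_parameters(net, snoussi_only = TRUE, seed = seed + 1000L)
    expect_true(validate_parameters(net, ps, snoussi = TRUE)$ok)
  }
})

test_that("the no-positive-circuit generator delivers what it promises", {
  for (seed in 1:10) {
    net <- random_network_no_positive_circuit(4, edge_probability = 0.4,
                                              seed = seed)
    circ <- network_circuits(net)
    expect_true(all(circ$sign == "-"))
    expect_true(all(net$entities$name %in% net$interactions$target))
  }
})

test_that("generated models exercise the whole pipeline", {
  for (seed in 1:20) {
    m <- random_boolean_model(4, seed)
    g <- state_graph(m)
    expect_equal(nrow(g$states), 16)
    at <- attractors(g)
    expect_gte(nrow(at$attractors), 1)
    # attractor basins cover every state
    covered <- Reduce(`|`, lapply(at$attractors$states,
                                  function(s) reachable_to_states(g, s)))
    expect_true(all(covered))
    bc <- state_betweenness(g)
    expect_true(all(bc$betweenness >= 0))
    f <- random_formula(m$network, depth = 3L)
    expect_type(ctl_holds(g, f), "logical")
  }
})
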