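test_that("targets and successors follow the K table", {
  m <- two_node_model()
  expect_equal(target_level(m, c(0, 0), "a"), 1L)  # inhibitor absent
  expect_equal(target_level(m, c(1, 1), "a"), 0L)  # inhibitor present
  expect_equal(state_label(successors(m, c(0, 0))), "10")
  expect_equal(state_label(successors(m, c(1, 0))), "11")
})

test_that("the 2-node loop yields the canonical 4-state cycle", {
  g <- state_graph(two_node_model())
  expect_equal(nrow(g$states), 4)
  expect_equal(nrow(g$edges), 4)
  expect_setequal(paste(tidy(g)$from, tidy(g)$to),
                  c("00 10", "10 11", "11 01", "01 00"))
  expect_equal(nrow(fixed_points(g)), 0)
  at <- attractors(g)
  expect_equal(nrow(at$attractors), 1)
  expect_equal(at$attractors$kind, "cyclic")
  expect_equal(at$attractors$size, 4)
})

test_that("a constant Boolean entity decays to its sole fixed point", {
  net <- brn("s")
  m <- brn_model(net, parameter_set(net, data.frame(entity = "s",
                                                    resources = "", K = 0L)))
  g <- state_graph(m)
  expect_equal(nrow(g$states), 2)
  expect_equal(tidy(g), tibble::tibble(from = "1", to = "0"))
  expect_equal(fixed_points(m)$state, "0")
  at <- attractors(g)
  expect_equal(at$attractors$kind, "fixed_point")
  expect_equal(tidy(at)$example_state, "0")

  m1 <- brn_model(net, parameter_set(net, data.frame(entity = "s",
                                                     resources = "", K = 1L)))
  expect_equal(fixed_points(m1)$state, "1")
})

test_that("every transition is a unitary asynchronous step", {
  for (seed in 1:15) {
    m <- random_boolean_model(4, seed)
    g <- state_graph(m)
    expect_equal(nrow(g$states), state_count(m$network))
    d <- abs(g$states[g$edges$from, , drop = FALSE] -
               g$states[g$edges$to, , drop = FALSE])
    expect_true(all(rowSums(d) == 1))
    expect_true(all(d %in% c(0L, 1L)))
    # fixed points are exactly the successor-free states
    fp <- fixed_points(g)$state
    scan <- g$labels[vapply(seq_len(nrow(g$states)), function(i) {
      nrow(successors(m, g$states[i, ])) == 0L
    }, logical(1))]
    expect_equal(fp, scan)
  }
})

test_that("multilevel entities move one level at a time toward K", {
  net <- brn(tibble::tibble(name = c("x", "y"), max_level = c(2L, 1L)),
             data.frame(source = "y", target = "x", sign = "+",
                        threshold = 1L))
  grid <- parameter_grid(net)
  grid$K <- ifelse(grid$entity == "x" & grid$resources == "y", 2L, 0L)
  m <- brn_model(net, parameter_set(net, grid))
  expect_equal(nrow(state_graph(m)$states), 6)
  # from (0, 1): x is called to 2 but steps to 1 first
  succ <- successors(m, c(x = 0, y = 1))
  expect_true("11" %in% state_label(succ))
  expect_false("21" %in% state_label(succ))
})

test_that("the state-space cap refuses oversized graphs", {
  net <- random_network(8, edge_probability = 0.3, seed = 1)
  m <- brn_model(net, random_parameters(net, seed = 2))
  expect_error(state_graph(m, cap = 100), "cap")
})

test_that("reachability follows directed paths", {
  g <- state_graph(two_node_model())
  expect_true(is_reachable(g, "00", "01"))
  expect_true(is_reachable(g, "01", "01"))
  net <- brn("s")
  m <- brn_model(net, parameter_set(net, data.frame(entity = "s",
                                                    resources = "", K = 0L)))
  g1 <- state_graph(m)
  expect_true(is_reachable(g1, "1", "0"))
  expect_false(is_reachable(g1, "0", "1"))
  expect_error(is_reachable(g, "7", "00"), "unknown state")
})
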