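test_that("betweenness matches hand-computed values on small digraphs", {
  # chain 1 -> 3 -> 2: the middle node carries the single shortest path
  chain <- digraph_as_state_graph(3, c(1, 3), c(3, 2))
  bc <- state_betweenness(chain)
  expect_equal(bc$betweenness[bc$id == 3], 1)
  expect_equal(bc$state[1], "s03")
  # diamond 1 -> {3, 4} -> 2: each middle node carries half
  diamond <- digraph_as_state_graph(4, c(1, 1, 3, 4), c(3, 4, 2, 2))
  bcd <- state_betweenness(diamond)
  expect_equal(bcd$betweenness[bcd$id == 3], 0.5)
  expect_equal(bcd$betweenness[bcd$id == 4], 0.5)
  # an isolated sink is never traversed
  expect_equal(bcd$betweenness[bcd$id == 2], 0)
})

test_that("ranking is total and lexicographic under ties", {
  cmap <- tibble::tibble(id = 1:3, state = c("b", "a", "c"),
                         betweenness = c(0, 0, 0))
  expect_equal(rank_states(cmap)$state, c("a", "b", "c"))
  expect_equal(rank_states(cmap)$rank, 1:3)
})

test_that("the maximal-centrality cycle is found and edge-valid", {
  g <- state_graph(two_node_model())
  tr <- max_centrality_cycle(g)
  expect_equal(tr$kind, "cycle")
  expect_equal(tr$states$state, c("00", "10", "11", "01"))
  # consecutive trajectory states (and the wrap-around) are transitions
  ids <- c(tr$states$id, tr$states$id[1])
  ekey <- paste(g$edges$from, g$edges$to)
  expect_true(all(paste(ids[-length(ids)], ids[-1]) %in% ekey))

  net <- brn("s")
  m <- brn_model(net, parameter_set(net, data.frame(entity = "s",
                                                    resources = "", K = 0L)))
  expect_error(max_centrality_cycle(state_graph(m)), "acyclic")
})

test_that("cycle scoring prefers high-betweenness members", {
  # two disjoint 2-cycles, one passing through a high-betweenness bridge
  g <- digraph_as_state_graph(6, c(1, 2, 3, 4, 5, 3, 6),
                              c(2, 1, 4, 3, 3, 6, 5))
  cm <- state_betweenness(g)
  tr <- max_centrality_cycle(g, centrality = cm)
  expect_true(all(tr$states$id %in% c(3, 4, 5, 6)))
})

test_that("bifurcation states separate distinct fates", {
  # fork: 1 -> 2 (fixed), 1 -> 3 (fixed)
  fork <- digraph_as_state_graph(3, c(1, 1), c(2, 3))
  bf <- bifurcation_states(fork)
  expect_equal(bf$id, 1L)
  # a single-attractor graph has none
  g <- state_graph(two_node_model())
  expect_equal(nrow(bifurcation_states(g)), 0)
})

test_that("max-centrality paths follow the higher-scoring branch", {
  # diamond with unequal betweenness forced via an extra feeder through 3
  g <- digraph_as_state_graph(5, c(1, 1, 3, 4, 5), c(3, 4, 2, 2, 3))
  cm <- state_betweenness(g)
  expect_gt(cm$betweenness[cm$id == 3], cm$betweenness[cm$id == 4])
  tr <- max_centrality_path(g, "s01", "s02", centrality = cm)
  expect_equal(tr$states$id, c(1, 3, 2))
  # chain: unique path returned as-is
  chain <- digraph_as_state_graph(3, c(1, 3), c(3, 2))
  expect_equal(max_centrality_path(chain, "s01", "s02")$states$id, c(1, 3, 2))
  expect_error(max_centrality_path(chain, "s02", "s01"), "not reachable")
})

test_that("trajectory classification flags deadlock-committed states", {
  model <- hif1_model()
  g <- state_graph(model)
  fx <- hif1_fixtures()
  at <- label_attractors(g, recovery_formula =
    "VEGF = 0 & OGT = 0 & GLUT1 = 0 & HIF-1 = 0 & AKT = 1 & P53 = 0")
  expect_equal(sort(at$attractors$label), c("deadlock", "recovery"))
  tr <- max_centrality_path(g, fx$trajectory_source, fx$deadlock, atts = at)
  expect_equal(tr$states$state[nrow(tr$states)], fx$deadlock)
  expect_equal(tr$states$classification[nrow(tr$states)], "toward_deadlock")
  expect_true("bifurcation" %in% tr$states$classification)
  ekey <- paste(g$edges$from, g$edges$to)
  ids <- tr$states$id
  expect_true(all(paste(ids[-length(ids)], ids[-1]) %in% ekey))
})
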