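test_that("unconstrained enumeration recovers the full table space", {
  net <- two_node_net()
  cat_all <- enumerate_parameters(net, "true")
  expect_length(cat_all$parameter_sets, 16)
  expect_equal(cat_all$labels, paste0("M", 1:16))
  expect_false(cat_all$partial)
})

test_that("CTL-filtered enumeration matches a hand brute force", {
  net <- two_node_net()
  specs <- c("AG(EF(a = 0 & b = 0))", "EF(AG(a = 1 & b = 1))",
             "A[ a = 0 U b = 1 ] | AG(a = 0)")
  for (sp in specs) {
    got <- enumerate_parameters(net, sp)
    f <- parse_ctl(sp, net)
    want <- 0L
    for (ka0 in 0:1) for (ka1 in 0:1) for (kb0 in 0:1) for (kb1 in 0:1) {
      ng <- naive_two_node_graph(c(ka0, ka1), c(kb0, kb1))
      sg <- digraph_as_state_graph(4, ng$from, ng$to)
      sg$states <- ng$states
      sg$model <- list(network = net)
      if (all(oracle_sat(sg, f))) want <- want + 1L
    }
    expect_equal(length(got$parameter_sets), want, label = sp)
  }
})

test_that("constraint propagation never changes the catalog", {
  # spec with a stability pattern: pruning must equal naive enumeration
  net <- two_node_net()
  sp <- "(a = 1 & b = 1) -> EF(AG(a = 1 & b = 1))"
  with_p <- enumerate_parameters(net, sp, propagate = TRUE)
  without <- enumerate_parameters(net, sp, propagate = FALSE)
  expect_gt(length(with_p$parameter_sets), 0)
  expect_lt(with_p$n_examined, without$n_examined)
  expect_equal(lapply(with_p$parameter_sets, function(p) p$table),
               lapply(without$parameter_sets, function(p) p$table))

  for (seed in 1:5) {
    rn <- random_network(2, edge_probability = 0.8, seed = seed)
    pat <- paste(rn$entities$name, "=", c(1, 0), collapse = " & ")
    spec <- paste0("EF(AG(", pat, "))")
    a <- enumerate_parameters(rn, spec, propagate = TRUE)
    b <- enumerate_parameters(rn, spec, propagate = FALSE)
    expect_equal(lapply(a$parameter_sets, function(p) p$table),
                 lapply(b$parameter_sets, function(p) p$table))
  }
})

test_that("tightening options never enlarges the catalog", {
  net <- two_node_net()
  base <- enumerate_parameters(net, "AG(EF(a = 0 & b = 0))")
  tight <- enumerate_parameters(net, "AG(EF(a = 0 & b = 0))", snoussi = TRUE)
  expect_lte(length(tight$parameter_sets), length(base$parameter_sets))
  key <- function(p) paste(p$table$K, collapse = "")
  expect_true(all(vapply(tight$parameter_sets, key, character(1)) %in%
                    vapply(base$parameter_sets, key, character(1))))
})

test_that("catalog members re-verify and export as a rectangular table", {
  net <- two_node_net()
  cat_ <- enumerate_parameters(net, "AG(EF(a = 0 & b = 0))")
  f <- parse_ctl("AG(EF(a = 0 & b = 0))", net)
  for (ps in cat_$parameter_sets) {
    expect_true(ctl_holds(state_graph(brn_model(net, ps)), f))
  }
  tab <- parameter_table(cat_)
  expect_equal(nrow(tab), 4)
  expect_equal(ncol(tab), 2 + length(cat_$parameter_sets))
  expect_error(parameter_table(enumerate_parameters(net, "false")),
               "empty catalog")
})

test_that("anchors restrict the frame and conflicts yield empty catalogs", {
  net <- two_node_net()
  # anchoring (0,0) steady forces K_a({b}) = 0 and K_b({}) = 0
  anc <- enumerate_parameters(net, "true", anchor_steady = "00")
  expect_length(anc$parameter_sets, 4)
  for (ps in anc$parameter_sets) {
    g <- state_graph(brn_model(net, ps))
    expect_true("00" %in% fixed_points(g)$state)
  }
  confl <- enumerate_parameters(net, "true", anchor_steady = "00",
                                fixed_entries = data.frame(
                                  entity = "b", resources = "", K = 1L))
  expect_length(confl$parameter_sets, 0)
  expect_match(confl$note, "conflicting")
})

test_that("select_model applies its criteria in deterministic order", {
  net <- two_node_net()
  cat_ <- enumerate_parameters(net, "true")
  m <- select_model(cat_, unique_deadlock_at = "11")
  expect_equal(fixed_points(m)$state, "11")
  expect_error(select_model(cat_, unique_deadlock_at = "11",
                            require_cycle_through = c("00", "10", "11", "01")),
               "no catalog member")
  cyc <- select_model(cat_, require_cycle_through = c("00", "10", "11", "01"))
  expect_equal(nrow(fixed_points(cyc)), 0)
  # a spec pinning all four transitions of the cycle has a singleton catalog
  cycle_spec <- paste("((a=0&b=0) -> AX(a=1&b=0))",
                      "((a=1&b=0) -> AX(a=1&b=1))",
                      "((a=1&b=1) -> AX(a=0&b=1))",
                      "((a=0&b=1) -> AX(a=0&b=0))", sep = " & ")
  single <- enumerate_parameters(net, cycle_spec)
  expect_length(single$parameter_sets, 1)
  expect_s3_class(
    select_model(single, require_cycle_through = c("00", "10", "11", "01")),
    "brn_model")
})

test_that("the packaged parameter set is a member of its own catalog", {
  model <- hif1_model()
  forms <- hif1_ctl(model$network)
  own <- enumerate_parameters(model$network, forms,
                              fixed_entries = model$parameters$table,
                              propagate = FALSE)
  expect_length(own$parameter_sets, 1)
  expect_equal(own$parameter_sets[[1]]$table, model$parameters$table)
  expect_equal(param_value(own$parameter_sets[[1]], "HIF-1", "ERK"), 1L)
})
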