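test_that("network construction validates its inputs", {
  net <- two_node_net()
  expect_s3_class(net, "brn")
  expect_equal(regulators(net, "a")$source, "b")
  expect_equal(regulators(net, "b")$source, "a")

  expect_error(brn(c("a", "a")), "duplicate entity name")
  expect_error(brn("a", data.frame(source = "a", target = "zz", sign = "+",
                                   threshold = 1L)),
               "unknown interaction endpoint")
  expect_error(brn(c("a", "b"),
                   data.frame(source = "a", target = "b", sign = "+",
                              threshold = 2L)),
               "threshold out of range")
  expect_error(brn(c("a", "b"),
                   data.frame(source = c("a", "a"), target = c("b", "b"),
                              sign = c("+", "-"), threshold = 1L)),
               "one interaction per ordered")
  expect_error(brn(c("a", "b"),
                   data.frame(source = "a", target = "b", sign = "x",
                              threshold = 1L)),
               "sign")
})

test_that("state counts follow the product of level ranges", {
  expect_equal(state_count(two_node_net()), 4)
  expect_equal(state_count(brn("a")), 2)
  ml <- brn(tibble::tibble(name = c("x", "y"), max_level = c(2L, 1L)))
  expect_equal(state_count(ml), 6)
  expect_equal(state_count(hif1_network()), 512)
})

test_that("resources follow the activator-present / inhibitor-absent rule", {
  net <- two_node_net()
  # b inhibits a: absent inhibitor is a resource
  expect_equal(resources(net, c(a = 1, b = 0), "a"), "b")
  expect_equal(resources(net, c(a = 1, b = 1), "a"), character())
  # a activates b: activator at threshold is a resource
  expect_equal(resources(net, c(a = 1, b = 1), "b"), "a")
  expect_equal(resources(net, c(a = 0, b = 1), "b"), character())
  expect_error(resources(net, c(a = 1, b = 0), "zz"), "unknown entity")
  expect_error(resources(net, c(2, 0), "a"), "out of range")
})

test_that("in the deadlock state p53's sole resource is the absent AKT signal", {
  net <- hif1_network()
  dl <- parse_state(hif1_fixtures()$deadlock, net)
  expect_equal(resources(net, dl, "p53"), "AKT")
})

test_that("resources are monotone for Boolean networks", {
  for (seed in 1:20) {
    net <- random_network(4, edge_probability = 0.6, seed = seed)
    st <- parse_state(sample(c("0000", "0101", "1110", "1111"), 1), net)
    for (v in net$entities$name) {
      res <- resources(net, st, v)
      expect_true(all(res %in% regulators(net, v)$source))
      for (u in regulators(net, v)$source) {
        if (u == v) next
        st2 <- st
        st2[[u]] <- 1L
        res2 <- resources(net, st2, v)
        sgn <- regulators(net, v)$sign[regulators(net, v)$source == u]
        if (sgn == "+" && u %in% res) expect_true(u %in% res2)
        if (sgn == "-" && !(u %in% res)) expect_false(u %in% res2)
      }
    }
  }
})

test_that("entity-name spellings are normalized against a network", {
  net <- hif1_network()
  expect_equal(normalize_entity(c("GLUT1", "P53", "BCAT", "CMYC", "HIF1"), net),
               c("GLUT-1", "p53", "β-catenin", "C-MYC", "HIF-1"))
  expect_equal(normalize_entity("p53", net), "p53")
})
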