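test_that("the parser accepts the observation dialect", {
  net <- hif1_network()
  f <- parse_ctl("VEGF = 1 & AKT = 0", net)
  expect_equal(f$op, "and")
  expect_equal(f$args[[1]]$entity, "VEGF")
  expect_equal(f$args[[2]]$entity, "AKT")

  g <- parse_ctl("EF(AG(HIF-1 = 1))", net)
  expect_equal(g$op, "EF")
  expect_equal(g$args[[1]]$op, "AG")
  expect_equal(g$args[[1]]$args[[1]]$entity, "HIF-1")

  # mixed spellings normalize; implication is right-associative;
  # & binds tighter than |, which binds tighter than ->
  h <- parse_ctl("GLUT1 = 1 | P53 = 0 & BCAT = 1 -> CMYC = 1 -> OGT = 0", net)
  expect_equal(h$op, "implies")
  expect_equal(h$args[[2]]$op, "implies")
  expect_equal(h$args[[1]]$op, "or")
  expect_equal(h$args[[1]]$args[[2]]$op, "and")

  u <- parse_ctl("E[ VEGF = 1 U AKT = 0 ]", net)
  expect_equal(u$op, "EU")
})

test_that("the parser rejects malformed or out-of-range formulas", {
  net <- two_node_net()
  expect_error(parse_ctl("EG(a = 2)", net), "out of range")
  expect_error(parse_ctl("a = 1 &", net), "syntax error")
  expect_error(parse_ctl("zz = 1", net), "unknown entity")
  expect_error(parse_ctl("a == 1", net), "syntax error")
})

test_that("semantics match hand-checked sets on the 4-state cycle", {
  g <- state_graph(two_node_model())
  expect_equal(sum(ctl_satisfy(g, "EF(a = 1 & b = 1)")$satisfied), 4)
  expect_equal(sum(ctl_satisfy(g, "EF(false)")$satisfied), 0)
  expect_true(ctl_holds(g, "true", "all_states"))
  expect_true(ctl_holds(g, "AG(EF(a = 0 & b = 0))", "all_states"))
  expect_false(ctl_holds(g, "AG(a = 1)", "some_state"))
  expect_true(ctl_holds(g, "EX(a = 1 & b = 0)", "at", at = "00"))
})

test_that("deadlocks behave as self-loops for temporal operators", {
  net <- brn("s")
  m <- brn_model(net, parameter_set(net, data.frame(entity = "s",
                                                    resources = "", K = 1L)))
  g <- state_graph(m)  # 0 -> 1, 1 is a fixed point
  expect_true(ctl_holds(g, "AG(s = 1)", "at", at = "1"))
  expect_true(ctl_holds(g, "EF(AG(s = 1))", "all_states"))
  expect_true(ctl_holds(g, "EX(s = 1)", "at", at = "1"))
})

test_that("CTL algebraic identities hold on random models", {
  for (seed in 1:10) {
    m <- random_boolean_model(3, seed)
    g <- state_graph(m)
    phi <- random_formula(m$network, depth = 3L)
    psi <- random_formula(m$network, depth = 2L)
    s_phi <- ctl_satisfy(g, phi)$satisfied
    neg <- structure(list(op = "not", args = list(phi)),
                     class = "ctl_formula")
    expect_equal(ctl_satisfy(g, neg)$satisfied, !s_phi)
    disj <- structure(list(op = "or", args = list(phi, psi)),
                      class = "ctl_formula")
    expect_equal(ctl_satisfy(g, disj)$satisfied,
                 s_phi | ctl_satisfy(g, psi)$satisfied)
    ef <- structure(list(op = "EF", args = list(phi)), class = "ctl_formula")
    eg <- structure(list(op = "EG", args = list(phi)), class = "ctl_formula")
    expect_true(all(ctl_satisfy(g, ef)$satisfied | !s_phi))   # phi subset EF phi
    expect_true(all(s_phi | !ctl_satisfy(g, eg)$satisfied))   # EG phi subset phi
    # AG/EF and AF/EG duality
    ag <- structure(list(op = "AG", args = list(phi)), class = "ctl_formula")
    ef_n <- structure(list(op = "EF", args = list(neg)), class = "ctl_formula")
    expect_equal(ctl_satisfy(g, ag)$satisfied,
                 !ctl_satisfy(g, ef_n)$satisfied)
  }
})

test_that("adding transitions never shrinks an EF set", {
  m <- two_node_model()
  g <- state_graph(m)
  f <- parse_ctl("EF(a = 1 & b = 0)", m$network)
  base <- ctl_satisfy(g, f)$satisfied
  g2 <- g
  g2$edges <- dplyr::bind_rows(g2$edges, tibble::tibble(from = 2L, to = 1L))
  g2$deadlocks <- setdiff(g2$deadlocks, 2L)
  expect_true(all(base <= ctl_satisfy(g2, f)$satisfied))
})

test_that("formula files round through text form", {
  net <- hif1_network()
  forms <- hif1_ctl(net)
  expect_length(forms, 3)
  reparsed <- lapply(forms, function(f) parse_ctl(format(f), net))
  g <- state_graph(hif1_model())
  for (i in seq_along(forms)) {
    expect_equal(ctl_satisfy(g, reparsed[[i]])$satisfied,
                 ctl_satisfy(g, forms[[i]])$satisfied)
  }
})
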