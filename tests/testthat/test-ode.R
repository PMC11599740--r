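unreg_system <- function(beta = 1, gamma = 0.5, x0 = 0) {
  net <- brn("s")
  m <- brn_model(net, parameter_set(net, data.frame(entity = "s",
                                                    resources = "", K = 1L)))
  brn_to_ode(m, ode_kinetics(net, beta = beta, gamma = gamma, x0 = x0))
}

test_that("an unregulated species follows its closed form", {
  sys <- unreg_system()
  expect_equal(sys$f(0), 1)  # constant production
  tr <- attr(simulate_ode(sys, 2, n_points = 3, rtol = 1e-10, atol = 1e-12),
             "matrix")
  expect_equal(unname(tr[3, 2]), 2 * (1 - exp(-0.5 * 2)), tolerance = 1e-6)
  eq <- ode_equilibrium(sys, tol = 1e-10)
  expect_equal(as.numeric(eq), 2, tolerance = 1e-8)
})

test_that("Hill activation is half-maximal at its threshold", {
  net <- brn(c("u", "v"), data.frame(source = "u", target = "v", sign = "+",
                                     threshold = 1L))
  grid <- parameter_grid(net)
  grid$K <- ifelse(grid$entity == "v" & grid$resources == "u", 1L, 0L)
  grid$K[grid$entity == "u"] <- 0L
  m <- brn_model(net, parameter_set(net, grid))
  sys <- brn_to_ode(m, ode_kinetics(net, theta = 0.5, h = 4))
  f <- sys$f(c(u = 0.5, v = 0))
  expect_equal(f[2], 0.5)
  # and the regulation function stays within [0, 1]
  for (x in c(0, 0.1, 0.5, 2, 10)) {
    expect_true(all(sys$f(c(u = x, v = 0)) >= 0))
    expect_true(all(sys$f(c(u = x, v = 0)) <= 1))
  }
})

test_that("sign-product regulation ignores the K table", {
  net <- two_node_net()
  sys <- brn_to_ode(two_node_model(), ode_kinetics(net), regulation = "product")
  # a's sole regulator b is inhibitory: f_a = 1 - H(b)
  f_low <- sys$f(c(a = 0, b = 0))
  f_high <- sys$f(c(a = 0, b = 2))
  expect_gt(f_low[1], 0.9)
  expect_lt(f_high[1], 0.1)
  expect_error(brn_to_ode(net, ode_kinetics(net), regulation = "table"),
               "brn_model")
})

test_that("trajectories stay non-negative and bounded by beta/gamma", {
  for (seed in 1:5) {
    m <- random_boolean_model(3, seed)
    kin <- random_kinetics(m$network, seed = seed)
    sys <- brn_to_ode(m, kin)
    tr <- attr(simulate_ode(sys, 30), "matrix")
    expect_true(all(tr[, -1] >= 0))
    cap <- sys$beta / sys$gamma
    for (j in seq_along(sys$species)) {
      expect_true(all(tr[, j + 1] <= max(cap[j], sys$x0[j]) + 1e-6))
    }
  }
})

test_that("symmetric mutual activation keeps its symmetry at equilibrium", {
  net <- brn(c("x", "y"), data.frame(source = c("x", "y"),
                                     target = c("y", "x"),
                                     sign = "+", threshold = 1L))
  grid <- parameter_grid(net)
  grid$K <- as.integer(grid$resources != "")
  m <- brn_model(net, parameter_set(net, grid))
  sys <- brn_to_ode(m, ode_kinetics(net, beta = 1, gamma = 1, x0 = 0.9))
  eq <- ode_equilibrium(sys, tol = 1e-10)
  expect_equal(unname(eq["x"]), unname(eq["y"]), tolerance = 1e-8)
})

test_that("equilibrium sensitivities of beta/gamma are exactly +/- 1", {
  sys <- unreg_system()
  expect_equal(ode_sensitivity(sys, "s", "beta:s"), 1, tolerance = 1e-6)
  expect_equal(ode_sensitivity(sys, "s", "gamma:s"), -1, tolerance = 1e-6)
  expect_error(ode_sensitivity(sys, "s", "beta:zz"), "unknown species")
  expect_error(ode_sensitivity(sys, "zz", "beta:s"), "unknown output")
})

test_that("the packaged scenarios behave as documented", {
  model <- hif1_model()
  net <- model$network
  # demo_b: VEGF clears faster than ERK over the 20-unit window
  sys_b <- brn_to_ode(model, hif1_kinetics("demo_b", net))
  tr <- attr(simulate_ode(sys_b, 20), "matrix")
  fin <- stats::setNames(tr[nrow(tr), -1], sys_b$species)
  expect_lt(fin[["VEGF"]], fin[["ERK"]])
  expect_gt(max(tr[, "VEGF"]), tr[1, "VEGF"])  # transient rise
  # demo_c: GLUT-1 responds positively to ERK production
  sys_c <- brn_to_ode(model, hif1_kinetics("demo_c", net))
  expect_gt(ode_sensitivity(sys_c, "GLUT-1", "beta:ERK"), 0)
  # demo_d: the equilibrium contract holds
  sys_d <- brn_to_ode(model, hif1_kinetics("demo_d", net))
  eq <- ode_equilibrium(sys_d, tol = 1e-8)
  expect_lte(attr(eq, "residual"), 1e-8)
})

test_that("the recovery scenario equilibrium mirrors the homeostatic pattern", {
  model <- hif1_model()
  sys <- brn_to_ode(model, hif1_kinetics("recovery", model$network))
  eq <- ode_equilibrium(sys, tol = 1e-8)
  patt <- paste(as.integer(eq > 0.5), collapse = "")
  expect_equal(patt, hif1_fixtures()$recovery)
})

test_that("kinetics files validate their contents", {
  net <- two_node_net()
  expect_error(ode_kinetics(net, gamma = 0), "out of range")
  expect_error(ode_kinetics(net, beta = c(zz = 1)), "unknown species")
  kin <- hif1_kinetics("pathogenic")
  expect_equal(nrow(kin$species), 9)
  expect_equal(nrow(kin$edges), 14)
  expect_true(all(kin$edges$theta == 0.5))
})
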