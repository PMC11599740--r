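#' The packaged HIF-1 case study
#'
#' A nine-entity Boolean regulatory network of hypoxia-driven cancer
#' signalling — HIF-1, ERK, VEGF, p53, β-catenin, AKT, GLUT-1, C-MYC, OGT,
#' in that fixed state-vector order — with fourteen signed interactions:
#' HIF-1 activates VEGF and GLUT-1; ERK activates HIF-1 and GLUT-1; p53
#' inhibits HIF-1 and VEGF; VEGF activates ERK and AKT; AKT inhibits p53 and
#' β-catenin; β-catenin activates C-MYC; C-MYC activates VEGF; GLUT-1
#' activates OGT; OGT activates C-MYC. The published interaction figure does
#' not print its edge list; this reconstruction follows the textual
#' description of the pathways and the three positive feedback loops
#' (VEGF/ERK via HIF-1; VEGF/AKT/p53; C-MYC/VEGF/ERK/GLUT-1/OGT) and the
#' C-MYC/VEGF/AKT/β-catenin negative circuit, constrained to exactly
#' fourteen edges. An alternative reading (HIF-1 activates ERK directly,
#' dropping the p53 inhibition of HIF-1) ships as `variant = "alt"`.
#'
#' @param variant `"canonical"` (default) or `"alt"`.
#' @return `hif1_network()`: a `brn`; `hif1_model()`: a `brn_model`
#'   carrying the packaged selected parameter set.
#' @export
hif1_network <- function(variant = c("canonical", "alt")) {
  variant <- match.arg(variant)
  if (variant == "alt") {
    return(read_model(qd_file("hif1_alt.json")))
  }
  hif1_model()$network
}

#' @rdname hif1_network
#' @export
hif1_model <- function() {
  read_model(qd_file("hif1.json"))
}

qd_file <- function(name) {
  path <- system.file("extdata", name, package = "qualdyn")
  if (!nzchar(path)) {
    # during development (load_all) fall back to the source tree
    path <- file.path("inst", "extdata", name)
  }
  if (!file.exists(path)) stop("packaged file not found: ", name,
                               call. = FALSE)
  path
}

#' Printed qualitative states of the case study
#'
#' The fixture states of the published analysis: the pathogenic deadlock
#' `(1,1,1,1,1,0,1,1,1)`, the recovery state `(0,0,0,0,0,1,0,0,0)`, the
#' twelve-state maximal-centrality cycle (p53, β-catenin and AKT constant at
#' 1), the seven bifurcation / critical-trajectory states, and the source
#' state of the highest-centrality trajectory.
#'
#' @return a list with elements `entity_order`, `deadlock`, `recovery`,
#'   `cycle12`, `bifurcations`, `trajectory_source` (states as digit strings
#'   in entity order).
#' @export
hif1_fixtures <- function() {
  jsonlite::fromJSON(qd_file("fixtures.json"))
}

#' The case-study observation formulas
#'
#' The three temporal-logic observations used to identify the logical
#' parameters: permanence of the pathogenic pattern, permanence of the
#' homeostatic pattern, and reachability of the fully engaged intermediate
#' configuration.
#'
#' @param net a `brn` to parse against (default: the packaged network), or
#'   NULL to return the raw strings.
#' @return a list of `ctl_formula`, or a character vector if `net` is NULL.
#' @export
hif1_ctl <- function(net = hif1_network()) {
  read_ctl(qd_file("table1.ctl"), net = net)
}

#' Packaged kinetics scenarios for the ODE stage
#'
#' `"pathogenic"` and `"recovery"` start near the two logical stable
#' patterns and are calibrated so the continuous equilibria, thresholded at
#' each species' Hill threshold, reproduce them. `"demo_a"` perturbs the
#' three guardians (p53, β-catenin, AKT); `"demo_b"` is a VEGF/ERK/HIF-1
#' pulse with slow ERK degradation; `"demo_c"` hyperactivates ERK and
#' GLUT-1; `"demo_d"` is the corresponding inhibition scenario.
#'
#' @param scenario one of `"pathogenic"`, `"recovery"`, `"demo_a"` ...
#'   `"demo_d"`.
#' @param net the network the kinetics are for (default: packaged).
#' @return an `ode_kinetics`.
#' @export
hif1_kinetics <- function(scenario = c("pathogenic", "recovery", "demo_a",
                                       "demo_b", "demo_c", "demo_d"),
                          net = hif1_network()) {
  scenario <- match.arg(scenario)
  read_kinetics(qd_file(paste0(scenario, ".yaml")), net)
}

#' Reproduce the case-study analysis end to end
#'
#' Runs the full pipeline on the packaged model and checks every headline
#' claim: state-space size (512), the two stable states (pathogenic
#' deadlock and recovery), satisfaction of the three observation formulas,
#' validity and constancy structure of the printed twelve-state cycle,
#' reachability of both fates from each printed bifurcation state, and the
#' highest-centrality trajectory's destination. Failed claims are recorded
#' in the report, not raised. With an output directory, also writes
#' `report.json`, `report.txt`, the state graph (`state_graph.graphml`) and
#' the centrality ranking (`centrality.csv`); the JSON report is
#' byte-identical across runs.
#'
#' @param out_dir optional output directory (created if missing).
#' @return a tibble with columns `claim`, `expected`, `observed`, `pass`.
#' @export
reproduce_hif1 <- function(out_dir = NULL) {
  model <- hif1_model()
  net <- model$network
  fx <- hif1_fixtures()
  graph <- state_graph(model)
  claims <- list()
  add <- function(claim, expected, observed) {
    claims[[length(claims) + 1L]] <<- tibble::tibble(
      claim = claim, expected = as.character(expected),
      observed = as.character(observed),
      pass = identical(as.character(expected), as.character(observed)))
  }

  add("entities", 9L, nrow(net$entities))
  add("interactions", 14L, nrow(net$interactions))
  add("states_total", 512L, nrow(graph$states))

  fp <- fixed_points(graph)$state
  add("pathogenic_deadlock_is_fixed_point", TRUE, fx$deadlock %in% fp)
  add("recovery_is_fixed_point", TRUE, fx$recovery %in% fp)
  add("stable_states", paste(sort(c(fx$deadlock, fx$recovery)), collapse = ","),
      paste(sort(fp), collapse = ","))

  forms <- hif1_ctl(net)
  for (i in seq_along(forms)) {
    add(paste0("ctl_formula_", i, "_holds"), TRUE, ctl_holds(graph, forms[[i]]))
  }

  # printed cycle: closed walk; p53 / b-catenin / AKT constant at 1; the six
  # other entities each change at least once
  cyc <- parse_state(fx$cycle12, net)
  closed <- rbind(cyc, cyc[1, ])
  idx <- state_index(graph$engine, closed)
  ekey <- paste(graph$edges$from, graph$edges$to, sep = "\r")
  steps_ok <- all(paste(idx[-length(idx)], idx[-1], sep = "\r") %in% ekey)
  add("cycle12_closed_walk", TRUE, steps_ok)
  const <- c("p53", "β-catenin", "AKT")
  add("cycle12_guardians_constant_at_1", TRUE,
      all(cyc[, const] == 1L))
  others <- setdiff(colnames(cyc), const)
  add("cycle12_other_entities_oscillate", TRUE,
      all(apply(cyc[, others], 2L, function(x) length(unique(x)) > 1L)))

  atts <- label_attractors(graph, recovery_formula = ctl_conjunction(list(
    "VEGF = 0 & OGT = 0 & GLUT1 = 0 & HIF-1 = 0 & AKT = 1 & P53 = 0"),
    net = net))
  lab <- atts$attractors$label
  rec_states <- unlist(atts$attractors$states[lab == "recovery"])
  dead_states <- unlist(atts$attractors$states[lab == "deadlock"])
  for (b in fx$bifurcations) {
    add(paste0("bifurcation_", b, "_reaches_both"), TRUE,
        is_reachable(graph, b, graph$labels[dead_states]) &&
          is_reachable(graph, b, graph$labels[rec_states]))
  }
  add("trajectory_source_reaches_deadlock", TRUE,
      is_reachable(graph, fx$trajectory_source, fx$deadlock))

  report <- dplyr::bind_rows(claims)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    writeLines(jsonlite::toJSON(report, pretty = 2),
               file.path(out_dir, "report.json"))
    writeLines(c(sprintf("HIF-1 case-study reproduction: %d/%d claims pass",
                         sum(report$pass), nrow(report)),
                 sprintf("  [%s] %-40s expected=%s observed=%s",
                         ifelse(report$pass, "ok", "FAIL"), report$claim,
                         report$expected, report$observed)),
               file.path(out_dir, "report.txt"))
    cmap <- state_betweenness(graph)
    write_centrality(cmap, file.path(out_dir, "centrality.csv"))
    export_state_graph(graph, file.path(out_dir, "state_graph.graphml"),
                       format = "graphml", centrality = cmap)
  }
  report
}
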