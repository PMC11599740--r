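# Shared fixtures: the two-entity activation/inhibition loop whose
# asynchronous dynamics form the canonical 4-state homeostasis cycle
# (0,0) -> (1,0) -> (1,1) -> (0,1) -> (0,0).

two_node_net <- function() {
  brn(c("a", "b"),
      data.frame(source = c("a", "b"), target = c("b", "a"),
                 sign = c("+", "-"), threshold = 1L))
}

two_node_model <- function() {
  net <- two_node_net()
  brn_model(net, parameter_set(net, data.frame(
    entity = c("a", "a", "b", "b"),
    resources = c("", "b", "", "a"),
    K = c(0L, 1L, 0L, 1L))))
}

# a synthetic `state_graph` over an arbitrary digraph, for graph-metric
# tests that do not need real model dynamics
digraph_as_state_graph <- function(n, from, to) {
  labels <- sprintf("s%02d", seq_len(n))
  states <- matrix(seq_len(n), ncol = 1, dimnames = list(NULL, "v1"))
  net <- brn(tibble::tibble(name = "v1", max_level = max(1L, n - 1L)))
  structure(list(model = list(network = net), states = states,
                 labels = labels,
                 edges = tibble::tibble(from = as.integer(from),
                                        to = as.integer(to)),
                 deadlocks = setdiff(seq_len(n), unique(from)),
                 engine = NULL),
            class = "state_graph")
}

# reflexive-transitive predecessors of `targets` in a state graph
reachable_to_states <- function(graph, targets) {
  n <- nrow(graph$states)
  seen <- logical(n)
  seen[targets] <- TRUE
  repeat {
    add <- unique(graph$edges$from[seen[graph$edges$to] &
                                     !seen[graph$edges$from]])
    if (!length(add)) break
    seen[add] <- TRUE
  }
  seen
}

random_boolean_model <- function(n, seed, edge_probability = 0.5) {
  net <- random_network(n, edge_probability = edge_probability, seed = seed)
  brn_model(net, random_parameters(net, seed = seed + 1L))
}
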