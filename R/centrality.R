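#' Betweenness centrality of qualitative states
#'
#' For each state e, the sum over ordered state pairs (s, t), all three
#' distinct, of the fraction of shortest directed paths from s to t passing
#' through e (pairs with no path contribute 0). Directed, unweighted,
#' unnormalized, endpoints excluded — the classic Freeman betweenness on the
#' state transition digraph, computed with igraph. States that are likely to
#' be traversed en route between many pairs of qualitative states rank high;
#' such states flag influential configurations of the biological system.
#'
#' @param graph a `state_graph`.
#' @return a tibble with columns `id` (state row index), `state` (digit
#'   string), `betweenness` and `rank` (dense: descending betweenness,
#'   lexicographic tie-break), ordered by rank.
#' @export
state_betweenness <- function(graph) {
  stopifnot(inherits(graph, "state_graph"))
  g <- graph_igraph(graph)
  bc <- igraph::betweenness(g, directed = TRUE, normalized = FALSE)
  out <- tibble::tibble(id = seq_len(nrow(graph$states)),
                        state = graph$labels,
                        betweenness = as.numeric(bc))
  rank_states(out)
}

#' Rank states by betweenness
#'
#' Total order: descending betweenness, then lexicographic state label, so
#' the ranking is stable across runs.
#'
#' @param cmap a tibble with columns `state` and `betweenness` (as returned
#'   by [state_betweenness()]).
#' @return the same tibble ordered by rank, with a `rank` column added or
#'   rewritten.
#' @export
rank_states <- function(cmap) {
  stopifnot(all(c("state", "betweenness") %in% names(cmap)))
  o <- order(-cmap$betweenness, cmap$state)
  out <- cmap[o, ]
  out$rank <- seq_len(nrow(out))
  out
}

# ---- trajectories -----------------------------------------------------------

new_trajectory <- function(graph, idx, kind, centrality, classification) {
  tr <- tibble::tibble(step = seq_along(idx),
                       id = idx,
                       state = graph$labels[idx],
                       betweenness = centrality$betweenness[
                         match(idx, centrality$id)],
                       classification = classification)
  structure(list(kind = kind, states = tr,
                 mean_betweenness = mean(tr$betweenness)),
            class = "brn_trajectory")
}

#' @export
print.brn_trajectory <- function(x, ...) {
  cat(sprintf("<brn_trajectory> %s of %d state(s), mean betweenness %.3f\n",
              x$kind, nrow(x$states), x$mean_betweenness))
  print(x$states)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.brn_trajectory <- function(x, ...) x$states

#' @exportS3Method generics::glance
glance.brn_trajectory <- function(x, ...) {
  tibble::tibble(kind = x$kind, length = nrow(x$states),
                 mean_betweenness = x$mean_betweenness)
}

#' Label attractors as pathogenic deadlocks or recovery regions
#'
#' An attractor is labelled `"recovery"` when all of its states satisfy
#' `recovery_formula` (typically the homeostatic labels of the observation
#' set); with no formula given, cyclic attractors — sustained oscillation,
#' the generic signature of homeostasis — are labelled recovery. Fixed-point
#' attractors not labelled recovery are `"deadlock"`; anything else is
#' `"cyclic"`.
#'
#' @param graph a `state_graph`.
#' @param atts a `brn_attractors` (computed if NULL).
#' @param recovery_formula a `ctl_formula` or string, or NULL.
#' @return the `brn_attractors` with a `label` column added to
#'   `$attractors`.
#' @export
label_attractors <- function(graph, atts = NULL, recovery_formula = NULL) {
  if (is.null(atts)) atts <- attractors(graph)
  a <- atts$attractors
  if (!is.null(recovery_formula)) {
    if (is.character(recovery_formula)) {
      recovery_formula <- parse_ctl(recovery_formula, graph$model$network)
    }
    sat <- ctl_eval(ctl_env(graph), recovery_formula)
    rec <- vapply(a$states, function(s) all(sat[s]), logical(1))
  } else {
    rec <- a$kind == "cyclic"
  }
  a$label <- ifelse(rec, "recovery",
                    ifelse(a$kind == "fixed_point", "deadlock", "cyclic"))
  atts$attractors <- a
  atts
}

# per-state logical matrix: state x attractor reachability
attractor_reach <- function(graph, atts) {
  vapply(atts$attractors$states,
         function(s) reachable_to(graph, s),
         logical(nrow(graph$states)))
}

classify_reach <- function(reach_row, labels) {
  dead <- any(reach_row & labels == "deadlock")
  rec <- any(reach_row & labels == "recovery")
  if (dead && rec) "bifurcation"
  else if (dead) "toward_deadlock"
  else if (rec) "toward_recovery"
  else "toward_cyclic"
}

#' Bifurcation states of a state graph
#'
#' Non-attractor states with at least two successors whose reachable
#' attractor sets differ: the points where the system's fate is decided.
#'
#' @param graph a `state_graph`.
#' @param atts a `brn_attractors` (computed if NULL).
#' @return a tibble with columns `id`, `state` (lexicographic order) and
#'   `n_successors`.
#' @export
bifurcation_states <- function(graph, atts = NULL) {
  stopifnot(inherits(graph, "state_graph"))
  if (is.null(atts)) atts <- attractors(graph)
  if (nrow(atts$attractors) < 2L) {
    return(tibble::tibble(id = integer(), state = character(),
                          n_successors = integer()))
  }
  reach <- attractor_reach(graph, atts)
  adj <- split(graph$edges$to, factor(graph$edges$from,
                                      levels = seq_len(nrow(graph$states))))
  candidates <- which(is.na(atts$membership))
  hit <- vapply(candidates, function(s) {
    succ <- adj[[s]]
    if (length(succ) < 2L) return(FALSE)
    profiles <- unique(apply(reach[succ, , drop = FALSE], 1L, paste,
                             collapse = ""))
    length(profiles) > 1L
  }, logical(1))
  idx <- candidates[hit]
  idx <- idx[order(graph$labels[idx])]
  tibble::tibble(id = idx, state = graph$labels[idx],
                 n_successors = lengths(adj[idx]))
}

# ---- cycle extraction -------------------------------------------------------

# Bounded simple-cycle enumeration: for each anchor vertex (ascending), DFS
# over vertices >= anchor within the same nontrivial SCC; every return to the
# anchor yields a cycle. Stops after `max_cycles` cycles or `max_steps`
# expansions.
enumerate_simple_cycles <- function(n, from, to, max_cycles = 1e5,
                                    max_steps = NULL) {
  if (is.null(max_steps)) max_steps <- 50 * max_cycles
  comp <- scc_membership(from, to, n)
  keep <- comp[from] == comp[to]
  adj <- split(to[keep], factor(from[keep], levels = seq_len(n)))
  cycles <- list()
  steps <- 0L
  capped <- FALSE
  for (anchor in seq_len(n)) {
    if (capped) break
    if (!length(adj[[anchor]])) next
    path <- anchor
    onpath <- logical(n); onpath[anchor] <- TRUE
    ptr <- 1L
    kids <- list(adj[[anchor]][adj[[anchor]] >= anchor])
    while (length(path)) {
      steps <- steps + 1L
      if (length(cycles) >= max_cycles || steps > max_steps) {
        capped <- TRUE
        break
      }
      d <- length(path)
      ks <- kids[[d]]
      if (ptr[d] <= length(ks)) {
        w <- ks[ptr[d]]
        ptr[d] <- ptr[d] + 1L
        if (w == anchor) {
          cycles[[length(cycles) + 1L]] <- path
        } else if (!onpath[w] && w > anchor) {
          path <- c(path, w)
          onpath[w] <- TRUE
          ptr <- c(ptr, 1L)
          kids[[d + 1L]] <- adj[[w]][adj[[w]] >= anchor]
        }
      } else {
        onpath[path[d]] <- FALSE
        path <- path[-d]
        ptr <- ptr[-d]
        kids[d] <- NULL
      }
    }
  }
  list(cycles = cycles, capped = capped)
}

#' Cycle with the highest betweenness centrality
#'
#' Enumerates simple cycles of the state graph (within non-trivial strongly
#' connected components, up to `search_cap` cycles) and returns the one
#' maximizing the chosen score of its states' betweenness (default: the
#' mean). Ties prefer the longer cycle, then the lexicographically smallest
#' starting state. The search cap makes the enumeration explicitly bounded;
#' when it is hit the best cycle among those enumerated is returned with a
#' warning.
#'
#' @param graph a `state_graph`.
#' @param centrality a [state_betweenness()] tibble (computed if NULL).
#' @param search_cap maximum number of simple cycles examined.
#' @param score `"mean"`, `"min"` or `"sum"` of member betweenness.
#' @param atts optional `brn_attractors` used to classify the cycle states.
#' @return a `brn_trajectory` of kind `"cycle"` (the closing step back to
#'   the first state is implicit).
#' @export
max_centrality_cycle <- function(graph, centrality = NULL, search_cap = 1e5,
                                 score = c("mean", "min", "sum"),
                                 atts = NULL) {
  stopifnot(inherits(graph, "state_graph"))
  score <- match.arg(score)
  if (is.null(centrality)) centrality <- state_betweenness(graph)
  res <- enumerate_simple_cycles(nrow(graph$states), graph$edges$from,
                                 graph$edges$to, max_cycles = search_cap)
  if (!length(res$cycles)) {
    if (res$capped) stop("cycle search cap exhausted before any cycle found",
                         call. = FALSE)
    stop("the state graph is acyclic: no cycle to extract", call. = FALSE)
  }
  if (res$capped) {
    warning("cycle search cap reached; best cycle among ",
            length(res$cycles), " enumerated", call. = FALSE)
  }
  bc <- numeric(nrow(graph$states))
  bc[centrality$id] <- centrality$betweenness
  sc <- vapply(res$cycles, function(cy) {
    switch(score, mean = mean(bc[cy]), min = min(bc[cy]), sum = sum(bc[cy]))
  }, numeric(1))
  len <- lengths(res$cycles)
  first <- vapply(res$cycles, function(cy) min(graph$labels[cy]), character(1))
  best <- order(-sc, -len, first)[1]
  cy <- res$cycles[[best]]
  # canonical rotation: start at the lexicographically smallest state
  r <- order(graph$labels[cy])[1]
  cy <- c(cy[r:length(cy)], cy[seq_len(r - 1L)])
  cls <- trajectory_classification(graph, cy, atts)
  new_trajectory(graph, cy, "cycle", centrality, cls)
}

trajectory_classification <- function(graph, idx, atts) {
  if (is.null(atts)) atts <- label_attractors(graph)
  if (!("label" %in% names(atts$attractors))) {
    atts <- label_attractors(graph, atts)
  }
  reach <- attractor_reach(graph, atts)
  vapply(idx, function(s) classify_reach(reach[s, ], atts$attractors$label),
         character(1))
}

#' Highest-centrality shortest path between states
#'
#' Among all shortest directed paths from `src` to (the nearest state of)
#' `dst`, returns the one maximizing the mean betweenness of its
#' intermediate states, computed by dynamic programming over the BFS layer
#' DAG (ties broken toward the lexicographically smallest state). Each state
#' on the path is classified by which labelled attractors remain reachable
#' from it (`toward_deadlock`, `toward_recovery`, `bifurcation`).
#'
#' @param graph a `state_graph`.
#' @param src source state (digit string or level vector).
#' @param dst destination state or set of states.
#' @param centrality a [state_betweenness()] tibble (computed if NULL).
#' @param atts optional `brn_attractors` for the classification.
#' @return a `brn_trajectory` of kind `"path"`.
#' @export
max_centrality_path <- function(graph, src, dst, centrality = NULL,
                                atts = NULL) {
  stopifnot(inherits(graph, "state_graph"))
  if (is.null(centrality)) centrality <- state_betweenness(graph)
  s <- resolve_state_idx(graph, src)
  d <- resolve_state_idx(graph, dst)
  Z <- nrow(graph$states)
  adj <- split(graph$edges$to, factor(graph$edges$from, levels = seq_len(Z)))
  dist <- rep(NA_integer_, Z)
  dist[s] <- 0L
  frontier <- s
  goal <- NA_integer_
  while (length(frontier) && is.na(goal)) {
    hitd <- intersect(frontier, d)
    if (length(hitd)) {
      goal <- hitd
      break
    }
    nxt <- unique(unlist(adj[frontier], use.names = FALSE))
    nxt <- nxt[is.na(dist[nxt])]
    dist[nxt] <- dist[frontier[1]] + 1L
    frontier <- nxt
  }
  if (length(goal) == 0L || all(is.na(goal))) {
    stop("destination not reachable from source", call. = FALSE)
  }
  bc <- numeric(Z)
  bc[centrality$id] <- centrality$betweenness
  # DP over the shortest-path DAG: best cumulative intermediate betweenness
  L <- dist[goal[1]]
  best <- rep(-Inf, Z)
  pred <- rep(NA_integer_, Z)
  best[s] <- 0
  if (L > 0L) {
    for (layer in 1:L) {
      cur <- which(dist == layer - 1L & is.finite(best))
      for (u in cur) {
        for (w in adj[[u]]) {
          if (is.na(dist[w]) || dist[w] != layer) next
          gain <- best[u] + if (layer == L) 0 else bc[w]
          better <- gain > best[w] ||
            (gain == best[w] && !is.na(pred[w]) &&
               graph$labels[u] < graph$labels[pred[w]])
          if (is.na(pred[w]) && is.infinite(best[w])) better <- TRUE
          if (better) {
            best[w] <- gain
            pred[w] <- u
          }
        }
      }
    }
  }
  ends <- goal[is.finite(best[goal])]
  end <- ends[order(-best[ends], graph$labels[ends])][1]
  path <- end
  while (path[1] != s) path <- c(pred[path[1]], path)
  cls <- trajectory_classification(graph, path, atts)
  new_trajectory(graph, path, "path", centrality, cls)
}
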