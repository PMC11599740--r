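# Independent oracles used to cross-check the implementation.

# ---- brute-force CTL semantics ---------------------------------------------
# Explicit path/lasso search over an adjacency list (deadlocks get a
# self-loop), structurally unlike the package's fixpoint labelling.

oracle_adj <- function(graph) {
  n <- nrow(graph$states)
  adj <- split(graph$edges$to, factor(graph$edges$from, levels = seq_len(n)))
  for (d in graph$deadlocks) adj[[d]] <- c(adj[[d]], d)
  adj
}

# can `s` reach any state in `targets` using only states in `allowed`?
oracle_reach <- function(adj, s, targets, allowed = NULL) {
  n <- length(adj)
  ok <- rep(TRUE, n)
  if (!is.null(allowed)) ok <- allowed
  seen <- rep(FALSE, n)
  stack <- s
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (seen[v]) next
    seen[v] <- TRUE
    if (v %in% targets) return(TRUE)
    nxt <- adj[[v]]
    if (!is.null(allowed)) nxt <- nxt[ok[nxt]]
    stack <- c(stack, nxt[!seen[nxt]])
  }
  FALSE
}

# does an infinite path staying inside `inside` start at s?  (lasso search:
# reach, within `inside`, some state lying on a cycle of `inside`)
oracle_lasso <- function(adj, s, inside) {
  if (!inside[s]) return(FALSE)
  n <- length(adj)
  on_cycle <- vapply(seq_len(n), function(v) {
    inside[v] && any(vapply(adj[[v]][inside[adj[[v]]]], function(w) {
      w == v || oracle_reach(adj, w, v, allowed = inside)
    }, logical(1)))
  }, logical(1))
  any(on_cycle) && oracle_reach(adj, s, which(on_cycle), allowed = inside)
}

oracle_sat <- function(graph, f) {
  adj <- oracle_adj(graph)
  n <- length(adj)
  S <- graph$states
  ev <- function(f) {
    switch(f$op,
      atom = S[, f$entity] == f$level,
      true = rep(TRUE, n),
      false = rep(FALSE, n),
      not = !ev(f$args[[1]]),
      and = ev(f$args[[1]]) & ev(f$args[[2]]),
      or = ev(f$args[[1]]) | ev(f$args[[2]]),
      implies = !ev(f$args[[1]]) | ev(f$args[[2]]),
      EX = {
        x <- ev(f$args[[1]])
        vapply(seq_len(n), function(v) any(x[adj[[v]]]), logical(1))
      },
      AX = {
        x <- ev(f$args[[1]])
        vapply(seq_len(n), function(v) all(x[adj[[v]]]), logical(1))
      },
      EF = {
        x <- ev(f$args[[1]])
        vapply(seq_len(n), function(v) oracle_reach(adj, v, which(x)),
               logical(1))
      },
      EG = {
        x <- ev(f$args[[1]])
        vapply(seq_len(n), function(v) oracle_lasso(adj, v, x), logical(1))
      },
      AF = {  # no path avoids phi forever
        x <- ev(f$args[[1]])
        !vapply(seq_len(n), function(v) oracle_lasso(adj, v, !x), logical(1))
      },
      AG = {  # no reachable state violates phi
        x <- ev(f$args[[1]])
        !vapply(seq_len(n), function(v) oracle_reach(adj, v, which(!x)),
                logical(1))
      },
      EU = {  # p-states path into a q-state
        p <- ev(f$args[[1]])
        q <- ev(f$args[[2]])
        vapply(seq_len(n), function(v) {
          if (q[v]) return(TRUE)
          p[v] && oracle_reach_through(adj, v, p, q)
        }, logical(1))
      },
      AU = {  # semantics: on every path, q eventually, p until then
        p <- ev(f$args[[1]])
        q <- ev(f$args[[2]])
        bad_mid <- !p & !q
        e_bad <- vapply(seq_len(n), function(v) {
          if (bad_mid[v]) return(TRUE)
          !q[v] && oracle_reach_through(adj, v, !q, bad_mid)
        }, logical(1))
        eg_nq <- vapply(seq_len(n), function(v) oracle_lasso(adj, v, !q),
                        logical(1))
        !(e_bad | eg_nq)
      },
      stop("oracle: unknown op ", f$op))
  }
  ev(f)
}

# path v -> ... -> (state in final), all intermediates (incl. v) in `mid`
oracle_reach_through <- function(adj, v, mid, final) {
  n <- length(adj)
  seen <- rep(FALSE, n)
  stack <- v
  while (length(stack)) {
    u <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (seen[u]) next
    seen[u] <- TRUE
    if (!mid[u] && u != v) next
    if (u != v && final[u]) return(TRUE)
    for (w in adj[[u]]) {
      if (final[w]) return(TRUE)
      if (mid[w] && !seen[w]) stack <- c(stack, w)
    }
  }
  FALSE
}

# random CTL ASTs of bounded depth over a network's entities
random_formula <- function(net, depth = 4L) {
  ops1 <- c("not", "EX", "EF", "EG", "AX", "AF", "AG")
  ops2 <- c("and", "or", "implies", "EU", "AU")
  gen <- function(d) {
    if (d == 0L || runif(1) < 0.3) {
      i <- sample.int(nrow(net$entities), 1L)
      return(list(op = "atom", entity = net$entities$name[i],
                  level = sample.int(net$entities$max_level[i] + 1L, 1L) - 1L,
                  args = list()))
    }
    if (runif(1) < 0.55) {
      list(op = sample(ops1, 1L), args = list(gen(d - 1L)))
    } else {
      list(op = sample(ops2, 1L), args = list(gen(d - 1L), gen(d - 1L)))
    }
  }
  structure(gen(depth), class = "ctl_formula")
}

# ---- brute-force betweenness ------------------------------------------------
# Enumerates every shortest path of every ordered pair by depth-limited DFS
# and counts pass-throughs.

oracle_betweenness <- function(n, from, to) {
  adj <- split(to, factor(from, levels = seq_len(n)))
  dist_from <- function(s) {
    d <- rep(Inf, n); d[s] <- 0
    frontier <- s
    while (length(frontier)) {
      nxt <- unique(unlist(adj[frontier], use.names = FALSE))
      nxt <- nxt[is.infinite(d[nxt])]
      d[nxt] <- d[frontier[1]] + 1
      frontier <- nxt
    }
    d
  }
  bc <- numeric(n)
  for (s in seq_len(n)) {
    d <- dist_from(s)
    for (t in seq_len(n)) {
      if (t == s || is.infinite(d[t])) next
      # enumerate all shortest s->t paths
      paths <- list()
      walk <- function(v, acc) {
        if (v == t) {
          paths[[length(paths) + 1L]] <<- acc
          return(invisible())
        }
        for (w in adj[[v]]) {
          if (d[w] == d[v] + 1 && d[w] <= d[t]) walk(w, c(acc, w))
        }
      }
      walk(s, s)
      np <- length(paths)
      if (np == 0L) next
      inner <- unlist(lapply(paths, function(p) p[-c(1, length(p))]))
      if (length(inner)) {
        tab <- table(inner)
        bc[as.integer(names(tab))] <- bc[as.integer(names(tab))] + tab / np
      }
    }
  }
  bc
}

# ---- naive 2-entity Boolean dynamics ---------------------------------------
# Hand-rolled asynchronous update for the 2-node loop family, used to
# brute-force parameter enumeration independently of the engine.
# K tables are given as k_a = c(K_a(), K_a(b)), k_b = c(K_b(), K_b(a));
# the edge signs are a ->(+) b, b -|(-) a.

naive_two_node_graph <- function(k_a, k_b) {
  states <- expand.grid(b = 0:1, a = 0:1)[, c("a", "b")]
  states <- as.matrix(states[order(states$a, states$b), ])
  edges <- list()
  for (i in 1:4) {
    a <- states[i, 1]; b <- states[i, 2]
    ka <- if (b < 1) k_a[2] else k_a[1]   # b inhibitor: resource iff b == 0
    kb <- if (a >= 1) k_b[2] else k_b[1]  # a activator: resource iff a == 1
    if (ka != a) edges[[length(edges) + 1L]] <- c(i, which(
      states[, 1] == a + sign(ka - a) & states[, 2] == b))
    if (kb != b) edges[[length(edges) + 1L]] <- c(i, which(
      states[, 1] == a & states[, 2] == b + sign(kb - b)))
  }
  em <- if (length(edges)) do.call(rbind, edges) else
    matrix(integer(), ncol = 2)
  list(states = states, from = em[, 1], to = em[, 2])
}
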