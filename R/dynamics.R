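#' Couple a network with a logical parameter set
#'
#' A model instance (network + complete K table) is the object whose
#' asynchronous dynamics are analysed.
#'
#' @param network a `brn`.
#' @param parameters a `brn_params` complete for `network`.
#' @return an object of class `brn_model`.
#' @export
brn_model <- function(network, parameters) {
  stopifnot(inherits(network, "brn"), inherits(parameters, "brn_params"))
  if (!setequal(unique(parameters$table$entity), network$entities$name)) {
    stop("parameter set does not cover the network's entities", call. = FALSE)
  }
  structure(list(network = network, parameters = parameters),
            class = "brn_model")
}

#' @export
print.brn_model <- function(x, ...) {
  cat(format(x$network), "with", nrow(x$parameters$table),
      "logical parameters\n")
  invisible(x)
}

# ---- internal engine --------------------------------------------------------
# Precomputes, for a model, the full lexicographic state enumeration, the
# per-entity resource-subset mask of every state, and the mixed-radix weights
# used to index neighbouring states arithmetically.
brn_engine <- function(model, cap = 1e6) {
  net <- model$network
  n <- nrow(net$entities)
  base <- net$entities$max_level + 1L
  Z <- prod(as.numeric(base))
  if (Z > cap) {
    stop("state space has ", format(Z, big.mark = ","),
         " states, exceeding the cap of ", format(cap, big.mark = ","),
         "; raise `cap` explicitly if this is intended", call. = FALSE)
  }
  Z <- as.integer(Z)
  # weights: first entity most significant => lexicographic digit-string order
  w <- rev(cumprod(rev(c(base[-1L], 1L))))
  S <- matrix(0L, nrow = Z, ncol = n, dimnames = list(NULL, net$entities$name))
  idx0 <- 0:(Z - 1L)
  for (j in seq_len(n)) S[, j] <- as.integer((idx0 %/% w[j]) %% base[j])

  regs <- lapply(net$entities$name, function(v) regulators(net, v))
  names(regs) <- net$entities$name
  rimask <- matrix(0L, nrow = Z, ncol = n)
  for (j in seq_len(n)) {
    rg <- regs[[j]]
    if (nrow(rg) == 0L) next
    m <- integer(Z)
    for (i in seq_len(nrow(rg))) {
      lev <- S[, rg$source[i]]
      res <- if (rg$sign[i] == "+") lev >= rg$threshold[i] else lev < rg$threshold[i]
      m <- m + as.integer(res) * 2L^(i - 1L)
    }
    rimask[, j] <- m
  }
  list(model = model, n = n, base = base, weights = as.integer(w), Z = Z,
       S = S, rimask = rimask, regs = regs)
}

engine_targets <- function(eng, kmap = NULL) {
  if (is.null(kmap)) kmap <- eng$model$parameters$kmap
  Tm <- eng$S
  for (j in seq_len(eng$n)) {
    Tm[, j] <- kmap[[j]][eng$rimask[, j] + 1L]
  }
  Tm
}

engine_edges <- function(eng, Tm = NULL) {
  if (is.null(Tm)) Tm <- engine_targets(eng)
  delta <- sign(Tm - eng$S)
  mv <- which(delta != 0L, arr.ind = TRUE)
  from <- mv[, 1L]
  to <- from + delta[mv] * eng$weights[mv[, 2L]]
  o <- order(from, to)
  list(from = from[o], to = to[o])
}

# ---- qualitative state helpers ---------------------------------------------

#' Serialize / parse qualitative states as digit strings
#'
#' States are written as undelimited digit strings in entity order, e.g.
#' `"111110111"` (a dot separator is used if any entity has more than nine
#' levels).
#'
#' @param state an integer state vector, or a matrix of states (one per row).
#' @param net a `brn`.
#' @param x a digit string (or vector of them).
#' @return `state_label()`: character; `parse_state()`: a named integer
#'   vector (or matrix) in entity order.
#' @export
state_label <- function(state) {
  if (is.matrix(state)) {
    sep <- if (max(state) > 9L) "." else ""
    return(apply(state, 1L, paste, collapse = sep))
  }
  paste(state, collapse = if (max(state) > 9L) "." else "")
}

#' @rdname state_label
#' @export
parse_state <- function(x, net) {
  one <- function(s) {
    lev <- if (grepl(".", s, fixed = TRUE)) {
      as.integer(strsplit(s, ".", fixed = TRUE)[[1]])
    } else {
      as.integer(strsplit(gsub("[(), ]", "", s), "")[[1]])
    }
    check_state(net, lev)
  }
  if (length(x) == 1L) return(one(x))
  t(vapply(x, one, integer(nrow(net$entities))))
}

state_index <- function(eng, state) {
  if (!is.matrix(state)) state <- matrix(state, nrow = 1L)
  as.integer(state %*% eng$weights + 1L)
}

#' Target level of an entity in a state
#'
#' The logical parameter K of the entity evaluated at its current resource
#' set: the level the entity is attracted toward.
#'
#' @param model a `brn_model`.
#' @param state an integer state vector.
#' @param entity an entity name.
#' @return an integer level.
#' @export
target_level <- function(model, state, entity) {
  stopifnot(inherits(model, "brn_model"))
  state <- check_state(model$network, state)
  res <- resources(model$network, state, entity)
  regs <- regulators(model$network, entity)$source
  model$parameters$kmap[[entity]][subset_mask(regs, paste(res, collapse = ",")) + 1L]
}

#' Asynchronous unitary successors of a state
#'
#' For each entity whose target level differs from its current level, the
#' state with that entity moved one unit toward the target (all other
#' coordinates unchanged). An empty result means the state is a fixed point
#' (deadlock).
#'
#' @param model a `brn_model`.
#' @param state an integer state vector.
#' @return a matrix of successor states (possibly 0 rows), one per row, in
#'   entity order.
#' @export
successors <- function(model, state) {
  stopifnot(inherits(model, "brn_model"))
  state <- check_state(model$network, state)
  nm <- model$network$entities$name
  out <- list()
  for (v in nm) {
    k <- target_level(model, state, v)
    if (k != state[[v]]) {
      s2 <- state
      s2[[v]] <- state[[v]] + sign(k - state[[v]])
      out[[length(out) + 1L]] <- s2
    }
  }
  if (!length(out)) {
    return(matrix(integer(), ncol = length(nm), dimnames = list(NULL, nm)))
  }
  do.call(rbind, out)
}

# ---- state graph ------------------------------------------------------------

#' Build the asynchronous state transition graph
#'
#' Exhaustively enumerates all qualitative states (lexicographic in entity
#' order) and all asynchronous unitary transitions: each transition changes
#' exactly one coordinate by exactly one unit, toward that entity's target
#' level.
#'
#' @param model a `brn_model`.
#' @param cap refuse to enumerate more than this many states (default 1e6).
#' @return an object of class `state_graph` with fields `states` (integer
#'   matrix, one state per row), `labels` (digit strings), `edges` (tibble
#'   `from`/`to` of state row indices) and `model`.
#' @export
state_graph <- function(model, cap = 1e6) {
  stopifnot(inherits(model, "brn_model"))
  eng <- brn_engine(model, cap = cap)
  ed <- engine_edges(eng)
  out_deg <- tabulate(ed$from, nbins = eng$Z)
  structure(list(model = model, states = eng$S,
                 labels = state_label(eng$S),
                 edges = tibble::tibble(from = ed$from, to = ed$to),
                 deadlocks = which(out_deg == 0L),
                 engine = eng),
            class = "state_graph")
}

#' @export
print.state_graph <- function(x, ...) {
  cat(sprintf("<state_graph> %d states, %d transitions, %d deadlock(s)\n",
              nrow(x$states), nrow(x$edges), length(x$deadlocks)))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.state_graph <- function(x, ...) {
  tibble::tibble(from = x$labels[x$edges$from], to = x$labels[x$edges$to])
}

#' @exportS3Method generics::glance
glance.state_graph <- function(x, ...) {
  tibble::tibble(n_states = nrow(x$states), n_transitions = nrow(x$edges),
                 n_deadlocks = length(x$deadlocks))
}

graph_igraph <- function(graph) {
  igraph::graph_from_data_frame(
    data.frame(from = graph$edges$from, to = graph$edges$to),
    directed = TRUE,
    vertices = data.frame(name = seq_len(nrow(graph$states))))
}

#' Fixed points (deadlock states) of a model
#'
#' States with no outgoing transition, in lexicographic order.
#'
#' @param model a `brn_model` (or a built `state_graph`).
#' @param cap passed to [state_graph()] when `model` is a `brn_model`.
#' @return a tibble with columns `state` (digit string) and one column per
#'   entity.
#' @export
fixed_points <- function(model, cap = 1e6) {
  graph <- if (inherits(model, "state_graph")) model else state_graph(model, cap)
  idx <- graph$deadlocks
  out <- tibble::as_tibble(as.data.frame(graph$states[idx, , drop = FALSE]))
  dplyr::bind_cols(tibble::tibble(state = graph$labels[idx]), out)
}

#' Attractors (terminal strongly connected components)
#'
#' An attractor is a set of states no transition leaves: a terminal SCC of
#' the state graph. A singleton attractor with no outgoing transition is a
#' fixed point; every other attractor is cyclic and models sustained
#' oscillation.
#'
#' @param graph a `state_graph`.
#' @return an object of class `brn_attractors`: a list with `membership`
#'   (per-state attractor id, NA for transient states) and `attractors`, a
#'   tibble with columns id, kind (`"fixed_point"`/`"cyclic"`), size and
#'   `states` (list column of state row indices).
#' @export
attractors <- function(graph) {
  stopifnot(inherits(graph, "state_graph"))
  Z <- nrow(graph$states)
  comp <- scc_membership(graph$edges$from, graph$edges$to, Z)
  # terminal components: no edge leaves the component
  leaves <- comp[graph$edges$from] != comp[graph$edges$to]
  nonterminal <- unique(comp[graph$edges$from][leaves])
  term_ids <- setdiff(unique(comp), nonterminal)
  membership <- rep(NA_integer_, Z)
  atts <- list()
  # deterministic order: by smallest state index in the component
  firsts <- vapply(term_ids, function(id) min(which(comp == id)), integer(1))
  term_ids <- term_ids[order(firsts)]
  for (i in seq_along(term_ids)) {
    st <- which(comp == term_ids[i])
    membership[st] <- i
    kind <- if (length(st) == 1L && st[1] %in% graph$deadlocks) "fixed_point"
            else "cyclic"
    atts[[i]] <- tibble::tibble(id = i, kind = kind, size = length(st),
                                states = list(st))
  }
  structure(list(membership = membership,
                 attractors = dplyr::bind_rows(atts),
                 graph_labels = graph$labels),
            class = "brn_attractors")
}

# Tarjan SCC, iterative (avoids deep recursion on large graphs)
scc_membership <- function(from, to, n) {
  adj <- split(to, factor(from, levels = seq_len(n)))
  index <- rep(NA_integer_, n); low <- integer(n)
  onstack <- logical(n); stk <- integer(0)
  comp <- integer(n); ncomp <- 0L; counter <- 0L
  for (root in seq_len(n)) {
    if (!is.na(index[root])) next
    # iterative DFS with explicit frames: node + child pointer
    frames_node <- root; frames_ptr <- 1L
    counter <- counter + 1L
    index[root] <- counter; low[root] <- counter
    stk <- c(stk, root); onstack[root] <- TRUE
    while (length(frames_node)) {
      d <- length(frames_node)
      v <- frames_node[d]
      kids <- adj[[v]]
      if (frames_ptr[d] <= length(kids)) {
        w <- kids[frames_ptr[d]]
        frames_ptr[d] <- frames_ptr[d] + 1L
        if (is.na(index[w])) {
          counter <- counter + 1L
          index[w] <- counter; low[w] <- counter
          stk <- c(stk, w); onstack[w] <- TRUE
          frames_node <- c(frames_node, w); frames_ptr <- c(frames_ptr, 1L)
        } else if (onstack[w]) {
          low[v] <- min(low[v], index[w])
        }
      } else {
        frames_node <- frames_node[-d]; frames_ptr <- frames_ptr[-d]
        if (d > 1L) {
          p <- frames_node[d - 1L]
          low[p] <- min(low[p], low[v])
        }
        if (low[v] == index[v]) {
          ncomp <- ncomp + 1L
          repeat {
            w <- stk[length(stk)]; stk <- stk[-length(stk)]
            onstack[w] <- FALSE; comp[w] <- ncomp
            if (w == v) break
          }
        }
      }
    }
  }
  comp
}

#' @export
print.brn_attractors <- function(x, ...) {
  cat(sprintf("<brn_attractors> %d attractor(s)\n", nrow(x$attractors)))
  print(tidy(x))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.brn_attractors <- function(x, ...) {
  tibble::tibble(id = x$attractors$id, kind = x$attractors$kind,
                 size = x$attractors$size,
                 example_state = vapply(x$attractors$states,
                                        function(s) x$graph_labels[min(s)],
                                        character(1)))
}

# logical vector over states: which states can reach any of `targets`
reachable_to <- function(graph, targets) {
  Z <- nrow(graph$states)
  radj <- split(graph$edges$from, factor(graph$edges$to, levels = seq_len(Z)))
  seen <- logical(Z)
  seen[targets] <- TRUE
  frontier <- targets
  while (length(frontier)) {
    pre <- unique(unlist(radj[frontier], use.names = FALSE))
    frontier <- pre[!seen[pre]]
    seen[frontier] <- TRUE
  }
  seen
}

resolve_state_idx <- function(graph, state) {
  if (is.character(state)) {
    i <- match(state, graph$labels)
    if (anyNA(i)) stop("unknown state: ", paste(state[is.na(i)], collapse = ", "),
                       call. = FALSE)
    return(i)
  }
  if (is.matrix(state)) return(state_index(graph$engine, state))
  state_index(graph$engine, check_state(graph$model$network, state))
}

#' Is a state (or state set) reachable from another?
#'
#' @param graph a `state_graph`.
#' @param src source state (digit string, integer vector, or row index).
#' @param dst destination state or set of states (digit strings, state
#'   matrix, or indices).
#' @return `TRUE` iff a directed path from `src` reaches some state in `dst`
#'   (a state reaches itself).
#' @export
is_reachable <- function(graph, src, dst) {
  stopifnot(inherits(graph, "state_graph"))
  s <- resolve_state_idx(graph, src)
  d <- resolve_state_idx(graph, dst)
  reachable_to(graph, d)[s]
}
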