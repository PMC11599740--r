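#' Enumerate logical parameter sets compatible with a CTL specification
#'
#' Searches the space of complete K tables of `net` and keeps those whose
#' asynchronous state graph satisfies the CTL specification. The raw space
#' is the product over entities of `(max_level+1)^(2^|regulators|)` tables,
#' so the search supports three pruning mechanisms, all of which fix
#' individual K entries before enumeration:
#'
#' * `propagate = TRUE` (default): entries forced by the specification
#'   itself. For every stability pattern in the specification — a subformula
#'   of shape `p -> EF(AG(q))` with `q` a conjunction of atoms — any entity
#'   constrained by `q` whose regulators are all constrained by `q` has a
#'   resource set that is constant across the `q`-region; its K there must
#'   equal its `q`-level, otherwise `AG(q)` is unsatisfiable and so is the
#'   implication (the antecedent's region is always non-empty).
#' * `anchor_steady`: states required to be fixed points; every entity's K
#'   at its resource set in such a state is fixed to the state's level.
#' * `anchor_walk`: a sequence of states whose consecutive transitions are
#'   required to exist; each transition fixes the stepping entity's K at the
#'   source state.
#'
#' Anchors are search-frame restrictions, not consequences of the CTL
#' specification; every surviving candidate is still verified in full with
#' [ctl_holds()].
#'
#' @param net a `brn`.
#' @param spec a `ctl_formula`, a string, or a list of either (combined as a
#'   conjunction).
#' @param snoussi,observability structural filters applied to candidates
#'   (see [validate_parameters()]); both default off.
#' @param holds_mode passed to [ctl_holds()] (default `"all_states"`).
#' @param max_models stop after this many accepted models (flagging the
#'   catalog as partial).
#' @param search_cap stop after examining this many candidates (flagging the
#'   catalog as partial).
#' @param fixed_entries optional data frame (entity, resources, K) of
#'   entries fixed by the caller.
#' @param anchor_steady optional state matrix / list of states / character
#'   vector of digit strings.
#' @param anchor_walk optional ordered state matrix or digit strings; append
#'   the first state again to require a closed walk.
#' @param propagate derive forced entries from the specification (default
#'   TRUE).
#' @param progress print a note every 1000 candidates.
#' @return an object of class `brn_catalog`: fields `network`,
#'   `parameter_sets` (list of [parameter_set()] objects, deterministic
#'   lexicographic order over the flattened K vector), `labels`
#'   (`M1`...`Mn`), `n_examined`, `partial`.
#' @export
enumerate_parameters <- function(net, spec,
                                 snoussi = FALSE, observability = FALSE,
                                 holds_mode = "all_states",
                                 max_models = 10000L, search_cap = 1e6,
                                 fixed_entries = NULL,
                                 anchor_steady = NULL, anchor_walk = NULL,
                                 propagate = TRUE, progress = FALSE) {
  stopifnot(inherits(net, "brn"), max_models >= 1L)
  spec <- as_ctl_spec(spec, net)
  eng <- brn_engine(list(network = net), cap = 1e6)

  forced <- list()  # named list: "entity\rmask" -> K
  add_forced <- function(entity, mask, k, origin) {
    key <- paste(entity, mask, sep = "\r")
    if (!is.null(forced[[key]]) && forced[[key]] != k) {
      attr(forced, "conflict") <<- sprintf(
        "conflicting forced entries for K_%s(%s): %d vs %d (%s)",
        entity, mask_label(regulators(net, entity)$source, mask),
        forced[[key]], k, origin)
    }
    forced[[key]] <<- as.integer(k)
  }

  if (!is.null(fixed_entries)) {
    fe <- tibble::as_tibble(fixed_entries)
    for (i in seq_len(nrow(fe))) {
      v <- normalize_entity(fe$entity[i], net)
      lab <- canon_resource_label(net, v, fe$resources[i])
      add_forced(v, subset_mask(regulators(net, v)$source, lab), fe$K[i],
                 "fixed_entries")
    }
  }
  if (propagate) {
    for (pat in ctl_stability_patterns(spec)) {
      for (v in names(pat)) {
        rg <- regulators(net, v)
        if (nrow(rg) > 0L && !all(rg$source %in% names(pat))) next
        msk <- 0L
        if (nrow(rg) > 0L) {
          lev <- pat[rg$source]
          res <- ifelse(rg$sign == "+", lev >= rg$threshold, lev < rg$threshold)
          msk <- sum(as.integer(res) * 2L^(seq_len(nrow(rg)) - 1L))
        }
        add_forced(v, msk, pat[[v]], "propagation")
      }
    }
  }
  for (s in as_state_list(anchor_steady, net)) {
    for (j in seq_len(eng$n)) {
      v <- net$entities$name[j]
      add_forced(v, eng$rimask[state_index(eng, s), j], s[j], "anchor_steady")
    }
  }
  walk <- as_state_list(anchor_walk, net)
  if (length(walk) >= 2L) {
    for (i in seq_len(length(walk) - 1L)) {
      s <- walk[[i]]; s2 <- walk[[i + 1L]]
      d <- which(s != s2)
      if (length(d) != 1L || abs(s[d] - s2[d]) != 1L) {
        stop("anchor_walk steps must change exactly one entity by one unit ",
             "(step ", i, ")", call. = FALSE)
      }
      v <- net$entities$name[d]
      # the stepping entity's target must lie strictly on the far side
      k <- s2[d]  # Boolean-adequate; for multilevel any K beyond also works,
                  # but the unitary transition itself only requires K != s[d]
                  # on that side; we pin the minimal consistent choice
      add_forced(v, eng$rimask[state_index(eng, s), d], k, "anchor_walk")
    }
  }

  empty_catalog <- function(msg, examined = 0L) {
    structure(list(network = net, parameter_sets = list(), labels = character(),
                   n_examined = examined, partial = FALSE, note = msg),
              class = "brn_catalog")
  }
  if (!is.null(attr(forced, "conflict"))) {
    return(empty_catalog(attr(forced, "conflict")))
  }

  # per-entity slot layout: forced vs free masks, in canonical (size, lex) order
  ml <- net$entities$max_level
  slots <- list()   # per free slot: list(entity_idx, mask, n_choices)
  template <- lapply(seq_len(eng$n), function(j) {
    regs <- eng$regs[[j]]$source
    nm <- 2L^length(regs)
    kv <- rep(NA_integer_, nm)
    labs <- subset_labels(regs)
    for (lab in labs) {
      m <- subset_mask(regs, lab)
      key <- paste(net$entities$name[j], m, sep = "\r")
      if (!is.null(forced[[key]])) kv[m + 1L] <- forced[[key]]
    }
    for (lab in labs) {
      m <- subset_mask(regs, lab)
      if (is.na(kv[m + 1L])) {
        slots[[length(slots) + 1L]] <<- list(j = j, mask = m,
                                             nch = ml[j] + 1L)
      }
    }
    kv
  })
  nslot <- length(slots)
  nch <- vapply(slots, function(s) s$nch, integer(1))
  n_comb <- prod(as.numeric(nch))

  env_tpl <- list(Z = eng$Z, deadlocks = NULL, S = eng$S,
                  names = net$entities$name)
  accepted <- list()
  partial <- FALSE
  examined <- 0L
  ix <- rep(0L, max(nslot, 1L))  # mixed-radix counter, first slot most significant
  repeat {
    if (examined >= search_cap) { partial <- TRUE; break }
    examined <- examined + 1L
    kmap <- template
    if (nslot > 0L) {
      for (t in seq_len(nslot)) {
        kmap[[slots[[t]]$j]][slots[[t]]$mask + 1L] <- ix[t]
      }
    }
    ok <- TRUE
    if (snoussi || observability) {
      names(kmap) <- net$entities$name
      ps0 <- structure(list(table = NULL, kmap = kmap), class = "brn_params")
      rep0 <- validate_parameters(net, ps0, snoussi = snoussi,
                                  observability = observability)
      ok <- rep0$ok
    }
    if (ok) {
      Tm <- eng$S
      for (j in seq_len(eng$n)) Tm[, j] <- kmap[[j]][eng$rimask[, j] + 1L]
      ed <- engine_edges(eng, Tm)
      env <- env_tpl
      env$from <- ed$from; env$to <- ed$to
      env$deadlocks <- which(tabulate(ed$from, nbins = eng$Z) == 0L)
      sat <- ctl_eval(env, spec)
      hold <- switch(holds_mode, all_states = all(sat), some_state = any(sat),
                     stop("unsupported holds_mode for enumeration"))
      if (hold) {
        accepted[[length(accepted) + 1L]] <- kmap
        if (length(accepted) >= max_models) {
          partial <- examined < n_comb
          break
        }
      }
    }
    if (progress && examined %% 1000L == 0L) {
      message("examined ", examined, " / ", format(n_comb, big.mark = ","),
              " candidates, ", length(accepted), " accepted")
    }
    # advance counter (last slot fastest => lexicographic over flattened K)
    if (nslot == 0L) break
    t <- nslot
    repeat {
      ix[t] <- ix[t] + 1L
      if (ix[t] < nch[t]) break
      ix[t] <- 0L
      t <- t - 1L
      if (t == 0L) break
    }
    if (t == 0L) break
  }

  sets <- lapply(accepted, function(kmap) {
    grid <- parameter_grid(net)
    grid$K <- vapply(seq_len(nrow(grid)), function(i) {
      j <- match(grid$entity[i], net$entities$name)
      kmap[[j]][subset_mask(eng$regs[[j]]$source, grid$resources[i]) + 1L]
    }, integer(1))
    parameter_set(net, grid)
  })
  structure(list(network = net, parameter_sets = sets,
                 labels = if (length(sets)) paste0("M", seq_along(sets))
                          else character(),
                 n_examined = examined, partial = partial, note = NULL),
            class = "brn_catalog")
}

as_ctl_spec <- function(spec, net) {
  if (is.character(spec) && length(spec) == 1L) return(parse_ctl(spec, net))
  if (inherits(spec, "ctl_formula")) return(spec)
  if (is.list(spec) || is.character(spec)) {
    return(ctl_conjunction(as.list(spec), net))
  }
  stop("`spec` must be a CTL formula, string, or list of them", call. = FALSE)
}

as_state_list <- function(x, net) {
  if (is.null(x)) return(list())
  if (is.character(x)) x <- parse_state(x, net)
  if (is.matrix(x)) return(lapply(seq_len(nrow(x)), function(i)
    check_state(net, x[i, ])))
  if (is.list(x)) return(lapply(x, check_state, net = net))
  list(check_state(net, x))
}

# Stability patterns: named level vectors from conjuncts of shape
# p -> EF(AG(q)) or EF(AG(q)), with q a pure conjunction of atoms and p (when
# present) a satisfiable conjunction of atoms, so the q-region must be
# reachable-stable in every accepted model. Only top-level conjuncts are
# considered: under negation or disjunction the forcing would be unsound.
ctl_stability_patterns <- function(f) {
  out <- list()
  conjunct <- function(node) {
    if (node$op == "and") {
      conjunct(node$args[[1]])
      conjunct(node$args[[2]])
      return(invisible())
    }
    target <- NULL
    if (node$op == "implies") {
      ante <- atom_conjunction(node$args[[1]])
      if (!is.null(ante)) target <- node$args[[2]]
    } else {
      target <- node
    }
    if (!is.null(target) && target$op == "EF" &&
        target$args[[1]]$op == "AG") {
      pat <- atom_conjunction(target$args[[1]]$args[[1]])
      if (!is.null(pat)) out[[length(out) + 1L]] <<- pat
    }
    invisible()
  }
  conjunct(f)
  out
}

atom_conjunction <- function(f) {
  acc <- c()
  ok <- TRUE
  walk <- function(node) {
    if (!ok) return()
    if (node$op == "and") { walk(node$args[[1]]); walk(node$args[[2]]) }
    else if (node$op == "atom") {
      lv <- node$level; names(lv) <- node$entity
      acc <<- c(acc, lv)
    } else ok <<- FALSE
  }
  walk(f)
  if (!ok || !length(acc) || anyDuplicated(names(acc))) return(NULL)
  acc
}

#' @export
print.brn_catalog <- function(x, ...) {
  cat(sprintf("<brn_catalog> %d model(s) (%s examined%s)\n",
              length(x$parameter_sets), format(x$n_examined, big.mark = ","),
              if (x$partial) ", PARTIAL" else ""))
  if (!is.null(x$note)) cat("note:", x$note, "\n")
  invisible(x)
}

#' @exportS3Method generics::glance
glance.brn_catalog <- function(x, ...) {
  tibble::tibble(n_models = length(x$parameter_sets),
                 n_examined = x$n_examined, partial = x$partial)
}

#' @exportS3Method generics::tidy
tidy.brn_catalog <- function(x, ...) parameter_table(x)

#' Rectangular K table of a model catalog
#'
#' One row per logical parameter (entity order, then subset size, then
#' lexicographic), one column per catalog member.
#'
#' @param catalog a `brn_catalog`.
#' @return a tibble: entity, resources, then M1...Mn columns.
#' @export
parameter_table <- function(catalog) {
  stopifnot(inherits(catalog, "brn_catalog"))
  if (!length(catalog$parameter_sets)) {
    stop("empty catalog", call. = FALSE)
  }
  out <- parameter_grid(catalog$network)
  for (i in seq_along(catalog$parameter_sets)) {
    out[[catalog$labels[i]]] <- catalog$parameter_sets[[i]]$table$K
  }
  out
}

#' Select a catalog member by dynamic criteria
#'
#' Filters the catalog (in deterministic catalog order) to members whose
#' state graph meets every given criterion, then returns the first match; if
#' `prefer_fewest_snoussi` is set, the match with the fewest Snoussi
#' monotonicity violations (ties broken by catalog order) is returned
#' instead, favouring the most sign-consistent table.
#'
#' @param catalog a `brn_catalog`.
#' @param unique_deadlock_at a state (digit string or vector): the member's
#'   fixed points must equal exactly this state. Or NULL.
#' @param fixed_points_exactly a set of states (digit strings / matrix): the
#'   member's fixed points must equal exactly this set. Or NULL.
#' @param require_cycle_through an ordered set of states (digit strings or
#'   matrix) that must form a closed walk in the member's state graph.
#' @param prefer_fewest_snoussi among qualifying members, prefer the one
#'   with fewest Snoussi violations (default FALSE: first match wins).
#' @return a `brn_model`.
#' @export
select_model <- function(catalog, unique_deadlock_at = NULL,
                         fixed_points_exactly = NULL,
                         require_cycle_through = NULL,
                         prefer_fewest_snoussi = FALSE) {
  stopifnot(inherits(catalog, "brn_catalog"))
  if (!length(catalog$parameter_sets)) stop("empty catalog", call. = FALSE)
  net <- catalog$network
  if (!is.null(unique_deadlock_at)) {
    if (!is.null(fixed_points_exactly)) {
      stop("give either `unique_deadlock_at` or `fixed_points_exactly`",
           call. = FALSE)
    }
    fixed_points_exactly <- unique_deadlock_at
  }
  want_fp <- if (!is.null(fixed_points_exactly)) {
    sort(vapply(as_state_list(fixed_points_exactly, net), state_label,
                character(1)))
  }
  fails <- character()
  hits <- integer()
  for (i in seq_along(catalog$parameter_sets)) {
    model <- brn_model(net, catalog$parameter_sets[[i]])
    graph <- state_graph(model)
    ok <- TRUE
    if (!is.null(want_fp)) {
      got <- sort(graph$labels[graph$deadlocks])
      if (!identical(got, want_fp)) {
        ok <- FALSE
        fails <- c(fails, sprintf("%s: fixed points {%s} != {%s}",
                                  catalog$labels[i],
                                  paste(got, collapse = ","),
                                  paste(want_fp, collapse = ",")))
      }
    }
    if (ok && !is.null(require_cycle_through)) {
      cyc <- as_state_list(require_cycle_through, net)
      cyc <- c(cyc, cyc[1])
      idx <- vapply(cyc, function(s) state_index(graph$engine, s), integer(1))
      ekey <- paste(graph$edges$from, graph$edges$to, sep = "\r")
      steps <- paste(idx[-length(idx)], idx[-1], sep = "\r")
      missing <- !(steps %in% ekey)
      if (any(missing)) {
        ok <- FALSE
        fails <- c(fails, sprintf("%s: cycle step %d missing",
                                  catalog$labels[i], which(missing)[1]))
      }
    }
    if (ok) {
      if (!prefer_fewest_snoussi) return(model)
      hits <- c(hits, i)
    }
  }
  if (length(hits)) {
    nv <- vapply(hits, function(i) {
      nrow(validate_parameters(net, catalog$parameter_sets[[i]],
                               snoussi = TRUE)$violations)
    }, integer(1))
    best <- hits[which.min(nv)]
    return(brn_model(net, catalog$parameter_sets[[best]]))
  }
  stop("no catalog member meets the criteria:\n  ",
       paste(head(fails, 20), collapse = "\n  "), call. = FALSE)
}
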