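#' Parse a CTL formula
#'
#' Accepts the dialect used for logical-model observations: atoms
#' `NAME = n`, boolean constants `true`/`⊤` and `false`/`⊥`, connectives
#' `!` (negation), `&` (conjunction), `|` (disjunction), `->` or `⇒`
#' (implication, right-associative), the temporal operators `EX EF EG AX AF
#' AG`, until forms `E[p U q]` / `A[p U q]`, and parentheses. `&` binds
#' tighter than `|`, which binds tighter than implication. Entity names are
#' normalized (e.g. `GLUT1`/`GLUT-1`, `P53`/`p53`, `BCAT`/`β-catenin`,
#' `CMYC`/`C-MYC`) and checked against the network, and atom levels must lie
#' within `[0, max_level]`.
#'
#' @param text a single formula string.
#' @param net a `brn` the formula's atoms are resolved against.
#' @return an object of class `ctl_formula` (an abstract syntax tree).
#' @examples
#' net <- brn(c("a", "b"))
#' parse_ctl("EF(AG(a = 1 & b = 0))", net)
#' @export
parse_ctl <- function(text, net) {
  stopifnot(is.character(text), length(text) == 1L, inherits(net, "brn"))
  toks <- ctl_tokenize(text)
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$pos <- 1L
  ast <- ctl_parse_implication(st, net)
  if (st$pos <= nrow(st$toks)) {
    ctl_error(st, "unexpected trailing input")
  }
  structure(ast, class = "ctl_formula")
}

ctl_tokenize <- function(text) {
  pats <- c(
    space = "\\s+",
    name  = "[A-Za-zβ][A-Za-z0-9_β]*(?:-[A-Za-z0-9β]+)*",
    int   = "[0-9]+",
    op    = "->|⇒|⊤|⊥|¬|∧|∨|[()\\[\\]=&|!]"
  )
  pos <- 1L
  out <- list()
  n <- nchar(text)
  while (pos <= n) {
    rest <- substr(text, pos, n)
    matched <- FALSE
    for (ty in names(pats)) {
      m <- regexpr(paste0("^(?:", pats[[ty]], ")"), rest, perl = TRUE)
      if (m == 1L) {
        len <- attr(m, "match.length")
        if (ty != "space") {
          out[[length(out) + 1L]] <- data.frame(
            type = ty, value = substr(rest, 1L, len), pos = pos)
        }
        pos <- pos + len
        matched <- TRUE
        break
      }
    }
    if (!matched) {
      stop(sprintf("CTL syntax error at position %d: unexpected character %s",
                   pos, dQuote(substr(text, pos, pos))), call. = FALSE)
    }
  }
  if (!length(out)) stop("empty CTL formula", call. = FALSE)
  do.call(rbind, out)
}

ctl_peek <- function(st) {
  if (st$pos > nrow(st$toks)) return(NULL)
  st$toks[st$pos, ]
}

ctl_take <- function(st) {
  t <- ctl_peek(st)
  st$pos <- st$pos + 1L
  t
}

ctl_expect <- function(st, value) {
  t <- ctl_take(st)
  if (is.null(t) || t$value != value) {
    ctl_error(st, paste0("expected ", dQuote(value)))
  }
  t
}

ctl_error <- function(st, msg) {
  t <- ctl_peek(st)
  where <- if (is.null(t)) "end of input" else
    sprintf("position %d (near %s)", t$pos, dQuote(t$value))
  stop("CTL syntax error at ", where, ": ", msg, call. = FALSE)
}

ctl_parse_implication <- function(st, net) {
  lhs <- ctl_parse_or(st, net)
  t <- ctl_peek(st)
  if (!is.null(t) && t$value %in% c("->", "⇒")) {
    ctl_take(st)
    rhs <- ctl_parse_implication(st, net)  # right-associative
    return(list(op = "implies", args = list(lhs, rhs)))
  }
  lhs
}

ctl_parse_or <- function(st, net) {
  lhs <- ctl_parse_and(st, net)
  repeat {
    t <- ctl_peek(st)
    if (is.null(t) || !(t$value %in% c("|", "∨"))) return(lhs)
    ctl_take(st)
    lhs <- list(op = "or", args = list(lhs, ctl_parse_and(st, net)))
  }
}

ctl_parse_and <- function(st, net) {
  lhs <- ctl_parse_unary(st, net)
  repeat {
    t <- ctl_peek(st)
    if (is.null(t) || !(t$value %in% c("&", "∧"))) return(lhs)
    ctl_take(st)
    lhs <- list(op = "and", args = list(lhs, ctl_parse_unary(st, net)))
  }
}

ctl_parse_unary <- function(st, net) {
  t <- ctl_peek(st)
  if (is.null(t)) ctl_error(st, "formula expected")
  if (t$value %in% c("!", "¬")) {
    ctl_take(st)
    return(list(op = "not", args = list(ctl_parse_unary(st, net))))
  }
  if (t$type == "name" && t$value %in% c("EX", "EF", "EG", "AX", "AF", "AG")) {
    ctl_take(st)
    return(list(op = t$value, args = list(ctl_parse_unary(st, net))))
  }
  if (t$type == "name" && t$value %in% c("E", "A")) {
    nxt <- if (st$pos + 1L <= nrow(st$toks)) st$toks[st$pos + 1L, ] else NULL
    if (!is.null(nxt) && nxt$value == "[") {
      q <- ctl_take(st)$value
      ctl_expect(st, "[")
      p <- ctl_parse_implication(st, net)
      u <- ctl_take(st)
      if (is.null(u) || u$value != "U") ctl_error(st, "expected \"U\"")
      r <- ctl_parse_implication(st, net)
      ctl_expect(st, "]")
      return(list(op = paste0(q, "U"), args = list(p, r)))
    }
  }
  ctl_parse_atom(st, net)
}

ctl_parse_atom <- function(st, net) {
  t <- ctl_peek(st)
  if (is.null(t)) ctl_error(st, "atom expected")
  if (t$value == "(") {
    ctl_take(st)
    inner <- ctl_parse_implication(st, net)
    ctl_expect(st, ")")
    return(inner)
  }
  if (t$value %in% c("⊤") || identical(toupper(t$value), "TRUE")) {
    ctl_take(st)
    return(list(op = "true", args = list()))
  }
  if (t$value %in% c("⊥") || identical(toupper(t$value), "FALSE")) {
    ctl_take(st)
    return(list(op = "false", args = list()))
  }
  if (t$type == "name") {
    nm <- normalize_entity(ctl_take(st)$value, net)
    i <- match(nm, net$entities$name)
    if (is.na(i)) {
      stop("CTL formula names unknown entity ", dQuote(nm), call. = FALSE)
    }
    ctl_expect(st, "=")
    lv <- ctl_take(st)
    if (is.null(lv) || lv$type != "int") ctl_error(st, "expected a level")
    level <- as.integer(lv$value)
    if (level > net$entities$max_level[i]) {
      stop("atom level out of range: ", nm, " = ", level, " but max_level is ",
           net$entities$max_level[i], call. = FALSE)
    }
    return(list(op = "atom", entity = nm, level = level, args = list()))
  }
  ctl_error(st, "atom expected")
}

#' @export
format.ctl_formula <- function(x, ...) ctl_deparse(x)

#' @export
print.ctl_formula <- function(x, ...) {
  cat("<ctl_formula>", ctl_deparse(x), "\n")
  invisible(x)
}

ctl_deparse <- function(f) {
  switch(f$op,
    atom = paste0(f$entity, " = ", f$level),
    true = "true", false = "false",
    not = paste0("!", ctl_deparse_p(f$args[[1]])),
    and = paste0(ctl_deparse_p(f$args[[1]]), " & ", ctl_deparse_p(f$args[[2]])),
    or = paste0(ctl_deparse_p(f$args[[1]]), " | ", ctl_deparse_p(f$args[[2]])),
    implies = paste0(ctl_deparse_p(f$args[[1]]), " -> ",
                     ctl_deparse_p(f$args[[2]])),
    EU = paste0("E[", ctl_deparse(f$args[[1]]), " U ",
                ctl_deparse(f$args[[2]]), "]"),
    AU = paste0("A[", ctl_deparse(f$args[[1]]), " U ",
                ctl_deparse(f$args[[2]]), "]"),
    paste0(f$op, " ", ctl_deparse_p(f$args[[1]])))
}

ctl_deparse_p <- function(f) {
  if (f$op %in% c("atom", "true", "false", "not")) ctl_deparse(f)
  else paste0("(", ctl_deparse(f), ")")
}

# ---- semantics --------------------------------------------------------------

# CTL requires a total transition relation; deadlock states are given an
# implicit self-loop, so AG of a deadlock's own labels holds there.
ctl_env <- function(graph) {
  Z <- nrow(graph$states)
  list(Z = Z, from = graph$edges$from, to = graph$edges$to,
       deadlocks = graph$deadlocks, S = graph$states,
       names = graph$model$network$entities$name)
}

ctl_ex <- function(env, X) {
  out <- logical(env$Z)
  out[env$from[X[env$to]]] <- TRUE
  out[env$deadlocks] <- out[env$deadlocks] | X[env$deadlocks]
  out
}

ctl_eval <- function(env, f) {
  op <- f$op
  if (op == "atom") return(env$S[, f$entity] == f$level)
  if (op == "true") return(rep(TRUE, env$Z))
  if (op == "false") return(rep(FALSE, env$Z))
  if (op == "not") return(!ctl_eval(env, f$args[[1]]))
  if (op == "and") return(ctl_eval(env, f$args[[1]]) & ctl_eval(env, f$args[[2]]))
  if (op == "or") return(ctl_eval(env, f$args[[1]]) | ctl_eval(env, f$args[[2]]))
  if (op == "implies") {
    return(!ctl_eval(env, f$args[[1]]) | ctl_eval(env, f$args[[2]]))
  }
  if (op == "EX") return(ctl_ex(env, ctl_eval(env, f$args[[1]])))
  if (op == "AX") return(!ctl_ex(env, !ctl_eval(env, f$args[[1]])))
  if (op == "EF") {  # least fixpoint of  phi | EX X
    phi <- ctl_eval(env, f$args[[1]])
    X <- phi
    repeat {
      X2 <- X | ctl_ex(env, X)
      if (identical(X2, X)) return(X)
      X <- X2
    }
  }
  if (op == "EG") {  # greatest fixpoint of  phi & EX X
    phi <- ctl_eval(env, f$args[[1]])
    X <- phi
    repeat {
      X2 <- X & ctl_ex(env, X)
      if (identical(X2, X)) return(X)
      X <- X2
    }
  }
  if (op == "AF") {  # dual: AF phi = !EG !phi
    neg <- list(op = "not", args = list(f$args[[1]]))
    return(!ctl_eval(env, list(op = "EG", args = list(neg))))
  }
  if (op == "AG") {  # dual: AG phi = !EF !phi
    neg <- list(op = "not", args = list(f$args[[1]]))
    return(!ctl_eval(env, list(op = "EF", args = list(neg))))
  }
  if (op == "EU") {  # least fixpoint of  q | (p & EX X)
    p <- ctl_eval(env, f$args[[1]])
    q <- ctl_eval(env, f$args[[2]])
    X <- q
    repeat {
      X2 <- q | (p & ctl_ex(env, X))
      if (identical(X2, X)) return(X)
      X <- X2
    }
  }
  if (op == "AU") {  # A[p U q] = !(E[!q U (!p & !q)] | EG !q)
    p <- ctl_eval(env, f$args[[1]])
    q <- ctl_eval(env, f$args[[2]])
    X <- !q
    repeat {
      X2 <- !q & ctl_ex(env, X)
      if (identical(X2, X)) break
      X <- X2
    }
    eg_nq <- X
    Y <- (!p & !q)
    repeat {
      Y2 <- (!p & !q) | (!q & ctl_ex(env, Y))
      if (identical(Y2, Y)) break
      Y <- Y2
    }
    return(!(Y | eg_nq))
  }
  stop("unknown CTL operator: ", op, call. = FALSE)
}

#' States satisfying a CTL formula
#'
#' Standard CTL semantics over the state graph by fixpoint labelling; fixed
#' points are treated as having a self-loop so the transition relation is
#' total.
#'
#' @param graph a `state_graph`.
#' @param formula a `ctl_formula` (or a string, parsed against the graph's
#'   network).
#' @return a tibble with columns `state` (digit string) and `satisfied`
#'   (logical), one row per state of the graph.
#' @export
ctl_satisfy <- function(graph, formula) {
  stopifnot(inherits(graph, "state_graph"))
  if (is.character(formula)) formula <- parse_ctl(formula, graph$model$network)
  sat <- ctl_eval(ctl_env(graph), formula)
  tibble::tibble(state = graph$labels, satisfied = sat)
}

#' Does a CTL formula hold on a state graph?
#'
#' @param graph a `state_graph`.
#' @param formula a `ctl_formula` or string.
#' @param mode `"all_states"` (the default: the formula must hold in every
#'   state, the convention for parameter identification with
#'   implication-shaped observations), `"some_state"`, or `"at"` (hold at
#'   every state of `at`).
#' @param at states (digit strings / matrix / vector) for `mode = "at"`.
#' @return `TRUE` or `FALSE`.
#' @export
ctl_holds <- function(graph, formula,
                      mode = c("all_states", "some_state", "at"), at = NULL) {
  mode <- match.arg(mode)
  if (is.character(formula)) formula <- parse_ctl(formula, graph$model$network)
  sat <- ctl_eval(ctl_env(graph), formula)
  switch(mode,
         all_states = all(sat),
         some_state = any(sat),
         at = all(sat[resolve_state_idx(graph, at)]))
}

#' Combine several formulas into one conjunction
#'
#' @param formulas a list of `ctl_formula` objects (or strings).
#' @param net a `brn`, required when strings are supplied.
#' @return a `ctl_formula`.
#' @export
ctl_conjunction <- function(formulas, net = NULL) {
  formulas <- lapply(formulas, function(f) {
    if (is.character(f)) parse_ctl(f, net) else f
  })
  out <- formulas[[1]]
  for (f in formulas[-1]) out <- list(op = "and", args = list(out, f))
  structure(out, class = "ctl_formula")
}

#' Read CTL formulas from a text file
#'
#' One formula per line; blank lines and `#` comments are ignored.
#'
#' @param path file path.
#' @param net optional `brn`; when given, each line is parsed and a list of
#'   `ctl_formula` objects is returned, otherwise the raw strings.
#' @return a character vector or a list of `ctl_formula`.
#' @export
read_ctl <- function(path, net = NULL) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (is.null(net)) return(lines)
  lapply(lines, parse_ctl, net = net)
}
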