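#' Random regulatory networks
#'
#' Samples a signed, thresholded directed graph: each ordered entity pair
#' (including self-pairs) receives an edge with probability
#' `edge_probability`, inhibitory with probability `inhibition_probability`,
#' with a threshold uniform in `[1, max_level]` of the source. When
#' `ensure_regulated` is set (the default, matching the regime of curated
#' signalling models where every entity is regulated), entities left without
#' a predecessor get a self-input of random sign, flagged in
#' `attr(net, "added_self_inputs")`. Identical `seed` gives identical
#' output; sampling is integer-based.
#'
#' @param n_entities number of entities (>= 1), named `v1`, `v2`, ...
#' @param edge_probability per ordered pair, in \[0, 1\].
#' @param inhibition_probability probability an edge is inhibitory.
#' @param max_level maximal level of every entity (1 = Boolean).
#' @param seed integer seed (NULL leaves the RNG state alone).
#' @param ensure_regulated guarantee every entity has a predecessor.
#' @param allow_self allow self-edges during sampling (default FALSE; the
#'   predecessor guarantee may still add them).
#' @return a `brn`.
#' @export
random_network <- function(n_entities, edge_probability = 0.3,
                           inhibition_probability = 0.5, max_level = 1L,
                           seed = NULL, ensure_regulated = TRUE,
                           allow_self = FALSE) {
  stopifnot(n_entities >= 1, edge_probability >= 0, edge_probability <= 1,
            inhibition_probability >= 0, inhibition_probability <= 1,
            max_level >= 1)
  with_seed(seed, {
    nm <- paste0("v", seq_len(n_entities))
    pairs <- expand.grid(source = nm, target = nm, stringsAsFactors = FALSE)
    if (!allow_self) pairs <- pairs[pairs$source != pairs$target, ]
    pairs <- pairs[order(pairs$source, pairs$target), ]
    keep <- runif(nrow(pairs)) < edge_probability
    ia <- pairs[keep, , drop = FALSE]
    n_e <- nrow(ia)
    ia$sign <- ifelse(runif(n_e) < inhibition_probability, "-", "+")
    ia$threshold <- if (max_level == 1L) rep(1L, n_e) else
      sample.int(max_level, n_e, replace = TRUE)
    added <- character()
    if (ensure_regulated) {
      for (v in nm) {
        if (!v %in% ia$target) {
          ia <- rbind(ia, data.frame(
            source = v, target = v,
            sign = if (runif(1) < inhibition_probability) "-" else "+",
            threshold = 1L))
          added <- c(added, v)
        }
      }
    }
    net <- brn(tibble::tibble(name = nm, max_level = as.integer(max_level)),
               ia)
    attr(net, "added_self_inputs") <- added
    net
  })
}

#' Random complete parameter tables
#'
#' Uniform sampling of a complete K table. With `snoussi_only`, the table is
#' sampled by monotone completion — entries are drawn in order of resource
#' subset size, each uniform between the maximum K of its immediate subsets
#' and `max_level` — so the result always passes the Snoussi validator.
#'
#' @param net a `brn`.
#' @param snoussi_only sample only Snoussi-monotone tables.
#' @param seed integer seed (NULL leaves the RNG state alone).
#' @return a `brn_params`.
#' @export
random_parameters <- function(net, snoussi_only = FALSE, seed = NULL) {
  stopifnot(inherits(net, "brn"))
  with_seed(seed, {
    grid <- parameter_grid(net)
    ml <- net$entities$max_level[match(grid$entity, net$entities$name)]
    if (!snoussi_only) {
      grid$K <- vapply(ml, function(m) sample.int(m + 1L, 1L) - 1L, integer(1))
    } else {
      grid$K <- NA_integer_
      for (v in net$entities$name) {
        regs <- regulators(net, v)$source
        m_v <- net$entities$max_level[match(v, net$entities$name)]
        rows <- which(grid$entity == v)
        kv <- integer(2^length(regs))
        masks_by_size <- order(vapply(0:(2^length(regs) - 1L), bitcount,
                                      integer(1)))
        for (m in (masks_by_size - 1L)) {
          lower <- 0L
          if (m > 0L) {
            subs <- Filter(function(s) bitwAnd(s, m) == s && s != m,
                           0:(m - 1L))
            if (length(subs)) lower <- max(kv[subs + 1L])
          }
          kv[m + 1L] <- lower + sample.int(m_v - lower + 1L, 1L) - 1L
        }
        for (i in rows) {
          grid$K[i] <- kv[subset_mask(regs, grid$resources[i]) + 1L]
        }
      }
    }
    parameter_set(net, grid)
  })
}

bitcount <- function(m) {
  n <- 0L
  while (m > 0L) {
    n <- n + bitwAnd(m, 1L)
    m <- bitwShiftR(m, 1L)
  }
  n
}

#' Random networks without positive circuits
#'
#' Rejection sampling on circuit signs: networks are drawn with
#' [random_network()] (with any needed self-inputs forced inhibitory) until
#' one has no positive circuit — no simple directed cycle with an even
#' number of inhibitions. Such networks admit at most one fixed point under
#' Snoussi-monotone parameters (the discrete positive-circuit requirement
#' for multistationarity), which the property tests exercise.
#'
#' @inheritParams random_network
#' @param max_tries rejection-sampling cap.
#' @return a `brn` with no positive circuit.
#' @export
random_network_no_positive_circuit <- function(n_entities,
                                               edge_probability = 0.3,
                                               inhibition_probability = 0.5,
                                               max_level = 1L, seed = NULL,
                                               max_tries = 500L) {
  with_seed(seed, {
    for (i in seq_len(max_tries)) {
      net <- random_network(n_entities, edge_probability,
                            inhibition_probability, max_level,
                            seed = NULL, ensure_regulated = FALSE)
      # force any self-loop inhibitory, then regulate leftovers negatively
      ia <- net$interactions
      ia$sign[ia$source == ia$target] <- "-"
      for (v in net$entities$name) {
        if (!v %in% ia$target) {
          ia <- rbind(ia, tibble::tibble(source = v, target = v, sign = "-",
                                         threshold = 1L))
        }
      }
      net <- brn(net$entities, ia)
      if (!has_positive_circuit(net)) return(net)
    }
    stop("no positive-circuit-free network found in ", max_tries, " tries",
         call. = FALSE)
  })
}

#' Circuits of the interaction graph
#'
#' Enumerates simple directed cycles of the (entity-level) interaction graph
#' and their signs (product of edge signs: positive iff the number of
#' inhibitions is even).
#'
#' @param net a `brn`.
#' @param max_cycles enumeration cap.
#' @return a tibble with columns `nodes` (list of entity-name vectors,
#'   cyclic order) and `sign` (`"+"`/`"-"`).
#' @export
network_circuits <- function(net, max_cycles = 1e4) {
  stopifnot(inherits(net, "brn"))
  nm <- net$entities$name
  from <- match(net$interactions$source, nm)
  to <- match(net$interactions$target, nm)
  res <- enumerate_simple_cycles(length(nm), from, to, max_cycles = max_cycles)
  if (res$capped) warning("circuit enumeration cap reached", call. = FALSE)
  ekey <- paste(from, to, sep = "\r")
  sgn <- ifelse(net$interactions$sign == "-", -1L, 1L)
  rows <- lapply(res$cycles, function(cy) {
    closed <- c(cy, cy[1])
    prod_sign <- prod(sgn[match(paste(closed[-length(closed)], closed[-1],
                                      sep = "\r"), ekey)])
    tibble::tibble(nodes = list(nm[cy]),
                   sign = if (prod_sign > 0) "+" else "-")
  })
  if (!length(rows)) {
    return(tibble::tibble(nodes = list(), sign = character()))
  }
  dplyr::bind_rows(rows)
}

has_positive_circuit <- function(net) {
  circ <- network_circuits(net)
  any(circ$sign == "+")
}

#' Random kinetics for the ODE translation
#'
#' Production and degradation rates log-uniform in `[0.2, 2]`, initial
#' concentrations uniform in `[0, 1]`, thresholds 0.5 and Hill coefficient
#' 4 (mid-steep).
#'
#' @param net a `brn`.
#' @param seed integer seed (NULL leaves the RNG state alone).
#' @return an `ode_kinetics`.
#' @export
random_kinetics <- function(net, seed = NULL) {
  with_seed(seed, {
    nm <- net$entities$name
    lu <- function(n) exp(runif(n, log(0.2), log(2)))
    ode_kinetics(net,
                 beta = stats::setNames(lu(length(nm)), nm),
                 gamma = stats::setNames(lu(length(nm)), nm),
                 x0 = stats::setNames(runif(length(nm)), nm),
                 theta = 0.5, h = 4)
  })
}

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
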