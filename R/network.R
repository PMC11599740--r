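#' Build a biological regulatory network
#'
#' A regulatory network is a signed, thresholded directed graph over named
#' entities (genes/proteins). Each entity has a maximal discrete expression
#' level `max_level` (1 for a Boolean entity); each interaction carries an
#' activation (`"+"`) or inhibition (`"-"`) sign and an integer threshold.
#' The row order of `entities` is significant: it defines the coordinate
#' order of every qualitative state vector downstream.
#'
#' @param entities a data frame with columns `name` (unique identifiers) and
#'   `max_level` (integers >= 1). A character vector of names is accepted and
#'   taken as Boolean entities.
#' @param interactions a data frame with columns `source`, `target`, `sign`
#'   (`"+"` or `"-"`) and `threshold` (integer >= 1, at most the source's
#'   `max_level`). At most one interaction per ordered (source, target) pair.
#' @return an object of class `brn`.
#' @examples
#' net <- brn(c("a", "b"),
#'            data.frame(source = c("a", "b"), target = c("b", "a"),
#'                       sign = c("+", "-"), threshold = 1L))
#' state_count(net)
#' @export
brn <- function(entities, interactions = NULL) {
  if (is.character(entities)) {
    entities <- tibble::tibble(name = entities, max_level = 1L)
  }
  entities <- tibble::as_tibble(entities)
  if (!all(c("name", "max_level") %in% names(entities))) {
    if (identical(names(entities), "name")) entities$max_level <- 1L
    else stop("`entities` needs columns `name` and `max_level`", call. = FALSE)
  }
  entities$name <- as.character(entities$name)
  entities$max_level <- as.integer(entities$max_level)
  if (anyNA(entities$name) || any(!nzchar(entities$name))) {
    stop("entity names must be non-empty", call. = FALSE)
  }
  if (anyDuplicated(entities$name)) {
    stop("duplicate entity name: ",
         paste(unique(entities$name[duplicated(entities$name)]), collapse = ", "),
         call. = FALSE)
  }
  if (any(entities$max_level < 1L)) {
    stop("`max_level` must be >= 1 for every entity", call. = FALSE)
  }

  if (is.null(interactions)) {
    interactions <- tibble::tibble(source = character(), target = character(),
                                   sign = character(), threshold = integer())
  }
  interactions <- tibble::as_tibble(interactions)
  need <- c("source", "target", "sign", "threshold")
  if (!all(need %in% names(interactions))) {
    stop("`interactions` needs columns source, target, sign, threshold",
         call. = FALSE)
  }
  interactions <- interactions[need]
  interactions$source <- as.character(interactions$source)
  interactions$target <- as.character(interactions$target)
  interactions$sign <- as.character(interactions$sign)
  interactions$threshold <- as.integer(interactions$threshold)

  unknown <- setdiff(c(interactions$source, interactions$target), entities$name)
  if (length(unknown)) {
    stop("unknown interaction endpoint: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (!all(interactions$sign %in% c("+", "-"))) {
    stop("interaction sign must be \"+\" or \"-\"", call. = FALSE)
  }
  pair <- paste(interactions$source, interactions$target, sep = "\r")
  if (anyDuplicated(pair)) {
    stop("at most one interaction per ordered (source, target) pair",
         call. = FALSE)
  }
  src_max <- entities$max_level[match(interactions$source, entities$name)]
  bad <- interactions$threshold < 1L | interactions$threshold > src_max
  if (any(bad)) {
    stop("threshold out of range (must satisfy 1 <= threshold <= max_level of ",
         "the source) for edge(s): ",
         paste(interactions$source[bad], "->", interactions$target[bad],
               collapse = ", "),
         call. = FALSE)
  }

  structure(list(entities = entities, interactions = interactions),
            class = "brn")
}

#' @export
print.brn <- function(x, ...) {
  cat(sprintf("<brn> %d entities, %d interactions, %s states\n",
              nrow(x$entities), nrow(x$interactions),
              format(state_count(x), big.mark = ",")))
  cat("entity order:", paste(x$entities$name, collapse = ", "), "\n")
  invisible(x)
}

#' @export
format.brn <- function(x, ...) {
  sprintf("<brn: %d entities, %d interactions>",
          nrow(x$entities), nrow(x$interactions))
}

#' Entity and interaction tables of a network
#'
#' @param net a `brn` object.
#' @return a tibble (`entities`: name, max_level; `interactions`: source,
#'   target, sign, threshold).
#' @export
brn_entities <- function(net) {
  stopifnot(inherits(net, "brn"))
  net$entities
}

#' @rdname brn_entities
#' @export
brn_interactions <- function(net) {
  stopifnot(inherits(net, "brn"))
  net$interactions
}

#' @exportS3Method generics::tidy
tidy.brn <- function(x, ...) x$interactions

#' @exportS3Method generics::glance
glance.brn <- function(x, ...) {
  tibble::tibble(n_entities = nrow(x$entities),
                 n_interactions = nrow(x$interactions),
                 n_states = state_count(x))
}

entity_index <- function(net, entity) {
  i <- match(entity, net$entities$name)
  if (anyNA(i)) {
    stop("unknown entity: ", paste(entity[is.na(i)], collapse = ", "),
         call. = FALSE)
  }
  i
}

#' Regulators (predecessors) of an entity
#'
#' Returns the interactions pointing into `entity`, ordered by the network's
#' entity order of their sources. The empty tibble means the entity is
#' unregulated.
#'
#' @param net a `brn`.
#' @param entity an entity name.
#' @return a tibble with columns source, sign, threshold.
#' @export
regulators <- function(net, entity) {
  entity_index(net, entity)
  ia <- net$interactions[net$interactions$target == entity, , drop = FALSE]
  ia <- ia[order(match(ia$source, net$entities$name)), c("source", "sign", "threshold")]
  tibble::as_tibble(ia)
}

#' Number of qualitative states of a network
#'
#' The product over entities of `max_level + 1`.
#'
#' @param net a `brn`.
#' @return an integer (double if very large).
#' @export
state_count <- function(net) {
  stopifnot(inherits(net, "brn"))
  prod(as.numeric(net$entities$max_level) + 1)
}

check_state <- function(net, state) {
  nm <- net$entities$name
  if (!is.null(names(state))) {
    if (!setequal(names(state), nm)) {
      stop("state names do not match the network's entities", call. = FALSE)
    }
    state <- state[nm]
  }
  state <- as.integer(state)
  if (length(state) != nrow(net$entities)) {
    stop("state must have one level per entity (", nrow(net$entities), ")",
         call. = FALSE)
  }
  if (anyNA(state) || any(state < 0L) || any(state > net$entities$max_level)) {
    stop("state levels out of range", call. = FALSE)
  }
  names(state) <- nm
  state
}

#' Resources of an entity in a qualitative state
#'
#' A regulator counts as a resource when it is "acting" on the target: an
#' activator at or above its threshold, or an inhibitor strictly below its
#' threshold (the absence of an inhibitor is itself a resource).
#'
#' @param net a `brn`.
#' @param state an integer state vector in entity order (optionally named).
#' @param target the entity whose resources are requested.
#' @return a character vector of regulator names (subset of the regulators
#'   of `target`), in entity order.
#' @export
resources <- function(net, state, target) {
  state <- check_state(net, state)
  reg <- regulators(net, target)
  if (nrow(reg) == 0L) return(character())
  lev <- state[reg$source]
  act <- reg$sign == "+"
  is_res <- (act & lev >= reg$threshold) | (!act & lev < reg$threshold)
  reg$source[is_res]
}

#' Canonical entity-name normalization
#'
#' The case-study literature mixes spellings (GLUT1 vs GLUT-1, P53 vs p53,
#' BCAT vs β-catenin, CMYC vs C-MYC, HIF1 vs HIF-1). This map is applied
#' when parsing CTL text so formulas written in either spelling resolve to
#' the same entity.
#'
#' @param name a character vector of entity names.
#' @param net optionally, a `brn`: names are only rewritten when the rewrite
#'   matches one of its entities.
#' @return normalized names.
#' @export
normalize_entity <- function(name, net = NULL) {
  map <- c("GLUT1" = "GLUT-1", "P53" = "p53", "BCAT" = "β-catenin",
           "CMYC" = "C-MYC", "HIF1" = "HIF-1", "BCATENIN" = "β-catenin")
  out <- name
  hit <- match(name, names(map))
  out[!is.na(hit)] <- map[hit[!is.na(hit)]]
  if (!is.null(net)) {
    keep <- out %in% net$entities$name | !(name %in% net$entities$name)
    out[!keep] <- name[!keep]
  }
  out
}
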