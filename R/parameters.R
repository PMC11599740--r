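#' All (entity, resource-subset) rows a complete parameter table must cover
#'
#' For each entity, one row per subset of its regulators (an unregulated
#' entity has the single empty-set row). Rows are ordered by entity order,
#' then subset size, then lexicographically.
#'
#' @param net a `brn`.
#' @return a tibble with columns `entity` and `resources` (comma-separated
#'   regulator names, `""` for the empty set).
#' @export
parameter_grid <- function(net) {
  stopifnot(inherits(net, "brn"))
  rows <- lapply(net$entities$name, function(v) {
    regs <- regulators(net, v)$source
    subs <- subset_labels(regs)
    tibble::tibble(entity = v, resources = subs)
  })
  dplyr::bind_rows(rows)
}

# all subsets of `regs` as comma-joined labels, ordered size then lexicographic
subset_labels <- function(regs) {
  k <- length(regs)
  if (k == 0L) return("")
  masks <- 0:(2^k - 1)
  labs <- vapply(masks, function(m) {
    paste(regs[bitwAnd(m, 2^(seq_len(k) - 1)) > 0], collapse = ",")
  }, character(1))
  sizes <- vapply(masks, function(m) sum(bitwAnd(m, 2^(seq_len(k) - 1)) > 0),
                  numeric(1))
  labs[order(sizes, labs)]
}

canon_resource_label <- function(net, entity, resources) {
  regs <- regulators(net, entity)$source
  if (length(resources) == 1L && (is.na(resources) || resources == "")) {
    return("")
  }
  parts <- unlist(strsplit(resources, ",", fixed = TRUE))
  parts <- trimws(parts)
  parts <- parts[nzchar(parts)]
  parts <- normalize_entity(parts, net)
  bad <- setdiff(parts, regs)
  if (length(bad)) {
    stop("resource subset for ", entity, " names non-regulator(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(parts)) stop("duplicated resource in subset", call. = FALSE)
  paste(regs[regs %in% parts], collapse = ",")
}

#' Build a logical parameter set (the K table)
#'
#' The K table maps each (entity, resource subset) pair to the target level
#' the entity is attracted toward when exactly that subset of its regulators
#' is acting. The table must be complete: one entry for every subset of every
#' entity's regulators, each K within `[0, max_level]`.
#'
#' @param net a `brn`.
#' @param table a data frame with columns `entity`, `resources`
#'   (comma-separated regulator names; `""` or `NA` for the empty set) and
#'   `K` (integer target levels).
#' @return an object of class `brn_params`.
#' @export
parameter_set <- function(net, table) {
  stopifnot(inherits(net, "brn"))
  table <- tibble::as_tibble(table)
  if (!all(c("entity", "resources", "K") %in% names(table))) {
    stop("`table` needs columns entity, resources, K", call. = FALSE)
  }
  table$entity <- normalize_entity(as.character(table$entity), net)
  entity_index(net, unique(table$entity))
  table$resources <- ifelse(is.na(table$resources), "",
                            as.character(table$resources))
  table$resources <- vapply(seq_len(nrow(table)), function(i) {
    canon_resource_label(net, table$entity[i], table$resources[i])
  }, character(1))
  table$K <- as.integer(table$K)

  grid <- parameter_grid(net)
  key <- paste(table$entity, table$resources, sep = "\r")
  gkey <- paste(grid$entity, grid$resources, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (entity, resources) entry in parameter table", call. = FALSE)
  }
  missing <- setdiff(gkey, key)
  if (length(missing)) {
    stop("incomplete parameter table: missing ", length(missing),
         " entries (first: ", sub("\r", " / {", missing[1]), "})", call. = FALSE)
  }
  extra <- setdiff(key, gkey)
  if (length(extra)) {
    stop("parameter table has entries for unknown subsets", call. = FALSE)
  }
  ml <- net$entities$max_level[match(table$entity, net$entities$name)]
  if (anyNA(table$K) || any(table$K < 0L) || any(table$K > ml)) {
    stop("K values out of range [0, max_level]", call. = FALSE)
  }

  # canonical row order
  table <- table[match(gkey, key), ]
  # fast lookup form: per entity an integer vector indexed by subset bitmask+1
  kmap <- lapply(net$entities$name, function(v) {
    regs <- regulators(net, v)$source
    rows <- table[table$entity == v, ]
    kv <- integer(2^length(regs))
    for (i in seq_len(nrow(rows))) {
      kv[subset_mask(regs, rows$resources[i]) + 1L] <- rows$K[i]
    }
    kv
  })
  names(kmap) <- net$entities$name

  structure(list(table = table, kmap = kmap), class = "brn_params")
}

subset_mask <- function(regs, label) {
  if (label == "") return(0L)
  parts <- unlist(strsplit(label, ",", fixed = TRUE))
  sum(2L^(match(parts, regs) - 1L))
}

#' @export
print.brn_params <- function(x, ...) {
  cat(sprintf("<brn_params> %d logical parameters over %d entities\n",
              nrow(x$table), length(x$kmap)))
  print(x$table, n = 12)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.brn_params <- function(x, ...) x$table

#' Look up a single logical parameter K
#'
#' @param params a `brn_params`.
#' @param entity an entity name.
#' @param resources a character vector of resource names (or a single
#'   comma-separated string).
#' @return the integer target level.
#' @export
param_value <- function(params, entity, resources = character()) {
  stopifnot(inherits(params, "brn_params"))
  lab <- paste(resources, collapse = ",")
  row <- params$table$entity == entity &
    vapply(params$table$resources, function(r) {
      setequal(strsplit(r, ",")[[1]], strsplit(lab, ",")[[1]])
    }, logical(1))
  if (!any(row)) stop("no such parameter entry", call. = FALSE)
  params$table$K[row][1]
}

#' Validate a parameter set against structural constraints
#'
#' Always checks completeness and level ranges (these raise on failure, since
#' an incomplete table is not a `brn_params`). Optionally reports violations
#' of the Snoussi condition (K non-decreasing under resource-subset
#' inclusion, which makes declared edge signs globally effective) and of
#' observability (every interaction changes at least one K value).
#'
#' @param net a `brn`.
#' @param params a `brn_params` for `net`.
#' @param snoussi,observability logical flags; both default off.
#' @return an object of class `brn_validation` with fields `ok` and
#'   `violations` (a tibble: rule, entity, detail).
#' @export
validate_parameters <- function(net, params, snoussi = FALSE,
                                observability = FALSE) {
  stopifnot(inherits(net, "brn"), inherits(params, "brn_params"))
  viol <- list()

  if (snoussi) {
    for (v in net$entities$name) {
      regs <- regulators(net, v)$source
      kv <- params$kmap[[v]]
      nmask <- length(kv) - 1L
      if (nmask < 1L) next
      for (m in 0:nmask) {
        for (j in seq_along(regs)) {
          b <- 2L^(j - 1L)
          if (bitwAnd(m, b) == 0L) {
            if (kv[m + 1L] > kv[bitwOr(m, b) + 1L]) {
              viol[[length(viol) + 1L]] <- tibble::tibble(
                rule = "snoussi", entity = v,
                detail = sprintf("K(%s)=%d > K(%s)=%d",
                                 mask_label(regs, m), kv[m + 1L],
                                 mask_label(regs, bitwOr(m, b)),
                                 kv[bitwOr(m, b) + 1L]))
            }
          }
        }
      }
    }
  }

  if (observability) {
    for (i in seq_len(nrow(net$interactions))) {
      u <- net$interactions$source[i]
      v <- net$interactions$target[i]
      regs <- regulators(net, v)$source
      kv <- params$kmap[[v]]
      b <- 2L^(match(u, regs) - 1L)
      masks <- 0:(length(kv) - 1L)
      lo <- masks[bitwAnd(masks, b) == 0L]
      if (all(kv[lo + 1L] == kv[bitwOr(lo, b) + 1L])) {
        viol[[length(viol) + 1L]] <- tibble::tibble(
          rule = "observability", entity = v,
          detail = sprintf("edge %s -> %s never changes K", u, v))
      }
    }
  }

  violations <- if (length(viol)) dplyr::bind_rows(viol) else
    tibble::tibble(rule = character(), entity = character(),
                   detail = character())
  structure(list(ok = nrow(violations) == 0L, violations = violations),
            class = "brn_validation")
}

mask_label <- function(regs, m) {
  if (m == 0L) return("{}")
  paste0("{", paste(regs[bitwAnd(m, 2L^(seq_along(regs) - 1L)) > 0],
                    collapse = ","), "}")
}

#' @export
print.brn_validation <- function(x, ...) {
  cat(sprintf("<brn_validation> ok = %s (%d violation(s))\n",
              x$ok, nrow(x$violations)))
  if (nrow(x$violations)) print(x$violations)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.brn_validation <- function(x, ...) x$violations
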