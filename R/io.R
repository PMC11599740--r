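#' Read / write model files
#'
#' The on-disk model format is JSON with keys `entity_order` (required; it
#' defines the coordinate order of every state vector), `entities` (name,
#' max_level), `interactions` (source, target, sign `"+"`/`"-"`, threshold)
#' and, optionally, `parameters` (entity -> list of `{resources: [names],
#' K}`). `write_model(read_model(p))` re-serializes `p` canonically and
#' byte-identically.
#'
#' @param path file path.
#' @return `read_model()`: a `brn_model` when the file carries parameters,
#'   otherwise a `brn`. `write_model()`: the path, invisibly.
#' @export
read_model <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(doc$entity_order)) {
    stop("model file has no `entity_order` key: ", path, call. = FALSE)
  }
  order <- unlist(doc$entity_order)
  ents <- dplyr::bind_rows(lapply(doc$entities, function(e) {
    tibble::tibble(name = e$name,
                   max_level = if (is.null(e$max_level)) 1L else
                     as.integer(e$max_level))
  }))
  if (!setequal(ents$name, order) || nrow(ents) != length(order)) {
    stop("`entity_order` is inconsistent with `entities` in ", path,
         call. = FALSE)
  }
  ents <- ents[match(order, ents$name), ]
  ia <- dplyr::bind_rows(lapply(doc$interactions, function(e) {
    if (!e$sign %in% c("+", "-")) {
      stop("unknown interaction sign ", dQuote(e$sign), " in ", path,
           call. = FALSE)
    }
    tibble::tibble(source = e$source, target = e$target, sign = e$sign,
                   threshold = if (is.null(e$threshold)) 1L else
                     as.integer(e$threshold))
  }))
  net <- brn(ents, ia)
  if (is.null(doc$parameters)) return(net)
  rows <- lapply(names(doc$parameters), function(v) {
    dplyr::bind_rows(lapply(doc$parameters[[v]], function(p) {
      tibble::tibble(entity = v,
                     resources = paste(unlist(p$resources), collapse = ","),
                     K = as.integer(p$K))
    }))
  })
  brn_model(net, parameter_set(net, dplyr::bind_rows(rows)))
}

#' @rdname read_model
#' @param x a `brn` or `brn_model`.
#' @export
write_model <- function(x, path) {
  net <- if (inherits(x, "brn_model")) x$network else x
  stopifnot(inherits(net, "brn"))
  doc <- list(
    entity_order = net$entities$name,
    entities = lapply(seq_len(nrow(net$entities)), function(i) {
      list(name = net$entities$name[i],
           max_level = net$entities$max_level[i])
    }),
    interactions = lapply(seq_len(nrow(net$interactions)), function(i) {
      as.list(net$interactions[i, ])
    })
  )
  if (inherits(x, "brn_model")) {
    tab <- x$parameters$table
    doc$parameters <- lapply(stats::setNames(net$entities$name,
                                             net$entities$name), function(v) {
      rows <- tab[tab$entity == v, ]
      lapply(seq_len(nrow(rows)), function(i) {
        res <- rows$resources[i]
        list(resources = if (nzchar(res)) strsplit(res, ",")[[1]] else
               character(),
             K = rows$K[i])
      })
    })
  }
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = 2)
  writeLines(json, path, useBytes = FALSE)
  invisible(path)
}

#' Export a state graph for external viewers
#'
#' Nodes are labelled with digit-string states in entity order; when a
#' centrality table is supplied each node carries a `betweenness`
#' attribute. The CSV format is a two-column from/to edge list of state
#' labels. Node and edge order are deterministic.
#'
#' @param graph a `state_graph`.
#' @param path output file.
#' @param format `"graphml"`, `"dot"` or `"csv"`.
#' @param centrality optional [state_betweenness()] tibble.
#' @return the path, invisibly.
#' @export
export_state_graph <- function(graph, path,
                               format = c("graphml", "dot", "csv"),
                               centrality = NULL) {
  stopifnot(inherits(graph, "state_graph"))
  format <- match.arg(format)
  if (format == "csv") {
    utils::write.csv(tidy(graph), path, row.names = FALSE, quote = FALSE)
    return(invisible(path))
  }
  vattr <- data.frame(name = graph$labels)
  if (!is.null(centrality)) {
    vattr$betweenness <- centrality$betweenness[match(seq_len(nrow(vattr)),
                                                      centrality$id)]
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = graph$labels[graph$edges$from],
               to = graph$labels[graph$edges$to]),
    directed = TRUE, vertices = vattr)
  igraph::write_graph(g, path, format = format)
  invisible(path)
}

#' Write a centrality ranking as CSV
#'
#' Columns: state, betweenness, rank.
#'
#' @param centrality a [state_betweenness()] tibble.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_centrality <- function(centrality, path) {
  utils::write.csv(centrality[, c("state", "betweenness", "rank")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
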