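#' Export a network in Graphviz DOT format
#'
#' One `digraph` with a node statement per variable and one edge statement
#' per directed edge; the edge label is the strength rounded to two
#' decimals and the pen width grows proportionally with the strength, so
#' stronger dependencies are drawn bolder.
#'
#' @param model a `bn_model` or `markov_neighborhood`.
#' @param path optional output path; when `NULL` the DOT text is returned.
#' @param name graph name.
#' @return the DOT text, invisibly when written to `path`.
#' @export
export_dot <- function(model, path = NULL, name = "bn") {
  if (inherits(model, "markov_neighborhood")) {
    nodes <- c(model$center, model$members)
    edges <- model$induced_edges
  } else {
    nodes <- model$nodes
    edges <- model$edges
  }
  quote_id <- function(x) paste0("\"", gsub("\"", "\\\\\"", x), "\"")
  lines <- c(sprintf("digraph %s {", name),
             paste0("  ", quote_id(nodes), ";"))
  if (!is.null(edges) && nrow(edges)) {
    s <- edges$strength %||% rep(NA_real_, nrow(edges))
    penw <- ifelse(is.na(s), 1, pmax(0.5, pmin(8, 1 + 0.35 * pmax(s, 0))))
    lab <- ifelse(is.na(s), "", sprintf(" [label=\"%.2f\", penwidth=%.2f]",
                                        s, penw))
    lines <- c(lines, sprintf("  %s -> %s%s;", quote_id(edges$from),
                              quote_id(edges$to), lab))
  }
  lines <- c(lines, "}")
  txt <- paste(lines, collapse = "\n")
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Parse the node and edge statements of a DOT digraph
#'
#' Minimal reader used for round-trip checks of [export_dot()] output.
#'
#' @param txt DOT text or a file path.
#' @return list with `nodes` and `edges` (data.frame `from`, `to`,
#'   `label`).
#' @export
parse_dot <- function(txt) {
  if (length(txt) == 1L && file.exists(txt)) txt <- readLines(txt)
  txt <- unlist(strsplit(paste(txt, collapse = "\n"), "\n"))
  body <- grep("^\\s*(digraph|\\})", txt, value = TRUE, invert = TRUE)
  em <- regmatches(body,
    regexec("^\\s*\"([^\"]+)\"\\s*->\\s*\"([^\"]+)\"\\s*(\\[label=\"([^\"]*)\")?", body))
  is_edge <- lengths(em) > 0
  edges <- do.call(rbind, lapply(em[is_edge], function(m)
    data.frame(from = m[2], to = m[3],
               label = if (nchar(m[5])) as.numeric(m[5]) else NA_real_,
               stringsAsFactors = FALSE)))
  nm <- regmatches(body[!is_edge],
                   regexec("^\\s*\"([^\"]+)\"\\s*;", body[!is_edge]))
  nodes <- vapply(nm[lengths(nm) > 0], `[`, character(1), 2)
  list(nodes = nodes,
       edges = edges %||% data.frame(from = character(0), to = character(0),
                                     label = numeric(0)))
}

#' Read a model serialized by [write_bn_json()]
#' @param path JSON path.
#' @return a `bn_model` (without score traces).
#' @export
read_bn_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  edges <- if (length(j$edges)) as.data.frame(j$edges)
           else data.frame(from = character(0), to = character(0),
                           strength = numeric(0))
  parents <- setNames(lapply(j$nodes, function(v)
    edges$from[edges$to == v]), j$nodes)
  structure(list(nodes = j$nodes, parents = parents, edges = edges,
                 log_score = j$log_score, traces = NULL,
                 config = do.call(score_config, as.list(j$config))),
            class = "bn_model")
}

#' Serialize a learned model as JSON
#' @param model a `bn_model`.
#' @param path output path.
#' @export
write_bn_json <- function(model, path) {
  jsonlite::write_json(
    list(nodes = model$nodes,
         edges = model$edges,
         log_score = model$log_score,
         strength_log_base = 10,
         config = unclass(model$config)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
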