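#' Treatment-guideline decision graphs
#'
#' A guideline is a directed acyclic graph whose nodes (decision points,
#' therapies, terminals) carry predicates over named clinical facts (PSA,
#' T category, Gleason sum, life expectancy, ...). Given a patient's fact
#' set, [evaluate_guideline()] highlights the therapeutic path the facts
#' satisfy — the programmatic counterpart of a flowchart lighting up the
#' applicable steps as the clinician enters data.
#'
#' Predicates use a deliberately small language — comparisons (`<`, `<=`,
#' `>`, `>=`, `==`, `!=`), set membership (`%in%` with `c(...)`), and
#' `&&`/`||`/`!` — evaluated under Kleene three-valued logic: a fact the
#' caller has not supplied makes a comparison *unknown*, and an unknown
#' predicate never highlights a node (it is recorded as unmet instead).
#' This mirrors incremental data entry in clinic: partial facts give a
#' partial, never a wrong, highlighting. No arbitrary code can run.
#'
#' Guideline *content* is data, not code: graphs are authored in YAML (see
#' the packaged `guideline_prostate.yaml`, a deliberately simplified
#' risk-tier-to-therapy flow making no claim of fidelity to any published
#' guideline) and validated at load time.
#'
#' @name guideline_engine
NULL

NODE_KINDS <- c("decision", "therapy", "terminal")

ALLOWED_CALLS <- c("<", "<=", ">", ">=", "==", "!=", "%in%",
                   "&", "&&", "|", "||", "!", "(", "c")

# Collect fact names referenced by a predicate expression; error on any
# construct outside the whitelist.
predicate_vars <- function(expr) {
  if (is.atomic(expr)) return(character(0))
  if (is.name(expr)) return(as.character(expr))
  if (is.call(expr)) {
    fn <- as.character(expr[[1]])
    if (!fn %in% ALLOWED_CALLS) {
      stop_data("predicate uses disallowed function '%s'", fn)
    }
    return(unique(unlist(lapply(as.list(expr)[-1], predicate_vars))))
  }
  stop_data("unsupported construct in predicate")
}

parse_predicate <- function(text, declared_facts, where) {
  if (is.logical(text) && length(text) == 1L) {
    return(list(expr = text, vars = character(0)))
  }
  if (!is.character(text) || length(text) != 1L) {
    stop_data("%s: predicate must be a string or boolean", where)
  }
  if (tolower(text) %in% c("true", "yes")) {
    return(list(expr = TRUE, vars = character(0)))
  }
  expr <- tryCatch(str2lang(text),
                   error = function(e) stop_data("%s: unparseable predicate '%s'",
                                                 where, text))
  vars <- predicate_vars(expr)
  unknown <- setdiff(vars, declared_facts)
  if (length(unknown)) {
    stop_data("%s: predicate references undeclared fact(s): %s",
              where, paste(unknown, collapse = ", "))
  }
  list(expr = expr, vars = vars)
}

# Three-valued %in%: an unknown left operand yields unknown, not FALSE.
in3 <- function(x, table) if (is.na(x)) NA else x %in% table

eval_predicate <- function(pred, facts) {
  if (is.logical(pred$expr)) return(pred$expr)
  env <- new.env(parent = baseenv())
  assign("%in%", in3, envir = env)
  for (v in pred$vars) {
    assign(v, if (is.null(facts[[v]])) NA else facts[[v]], envir = env)
  }
  out <- eval(pred$expr, env)
  if (!is.logical(out) || length(out) != 1L) {
    stop_data("predicate did not evaluate to a single logical")
  }
  out
}

#' Load and validate a guideline graph
#'
#' Reads a YAML guideline definition: a `facts` block declaring the fact
#' vocabulary, a `nodes` list (`id`, `label`, `kind`, optional `predicate`,
#' default always-true), an `edges` list (`from`, `to`, optional
#' `predicate`) and the `entry` node id. Load-time validation rejects
#' duplicate or dangling ids, cycles (the offending cycle is named),
#' multiple designated entries and predicates over undeclared facts.
#'
#' @param file Path to a YAML guideline file.
#' @return A validated `guideline_graph`.
#' @export
load_guideline <- function(file) {
  if (!file.exists(file)) stop_data("guideline file not found: %s", file)
  doc <- yaml::read_yaml(file)
  for (fld in c("entry", "nodes")) {
    if (is.null(doc[[fld]])) stop_data("guideline %s: missing '%s'", file, fld)
  }
  declared_facts <- names(doc$facts)
  ids <- vapply(doc$nodes, function(n) as.character(n$id), character(1))
  if (anyDuplicated(ids)) {
    stop_data("guideline %s: duplicate node id(s): %s", file,
              paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  nodes <- lapply(doc$nodes, function(n) {
    kind <- match.arg(as.character(n$kind), NODE_KINDS)
    pred <- parse_predicate(if (is.null(n$predicate)) TRUE else n$predicate,
                            declared_facts, sprintf("node '%s'", n$id))
    list(id = as.character(n$id),
         label = if (is.null(n$label)) as.character(n$id)
                 else as.character(n$label),
         kind = kind, predicate = pred)
  })
  names(nodes) <- ids
  edges <- lapply(doc$edges, function(e) {
    for (endp in c("from", "to")) {
      if (!as.character(e[[endp]]) %in% ids) {
        stop_data("guideline %s: edge references missing node '%s'", file,
                  e[[endp]])
      }
    }
    pred <- if (is.null(e$predicate)) list(expr = TRUE, vars = character(0))
            else parse_predicate(e$predicate, declared_facts,
                                 sprintf("edge %s->%s", e$from, e$to))
    list(from = as.character(e$from), to = as.character(e$to),
         predicate = pred)
  })
  entry <- as.character(doc$entry)
  if (length(entry) != 1L || !entry %in% ids) {
    stop_data("guideline %s: entry must name exactly one existing node", file)
  }
  graph <- structure(list(nodes = nodes, edges = edges, entry = entry,
                          facts = declared_facts),
                     class = "guideline_graph")
  cyc <- find_cycle(graph)
  if (!is.null(cyc)) {
    stop_data("guideline %s contains a cycle: %s", file,
              paste(cyc, collapse = " -> "))
  }
  graph
}

# DFS cycle detection; returns the node ids on a cycle, or NULL.
find_cycle <- function(graph) {
  adj <- split(vapply(graph$edges, `[[`, character(1), "to"),
               vapply(graph$edges, `[[`, character(1), "from"))
  state <- new.env()
  visit <- function(id, path) {
    st <- state[[id]]
    if (identical(st, "active")) return(path[seq(match(id, path), length(path))])
    if (identical(st, "done")) return(NULL)
    state[[id]] <- "active"
    for (child in adj[[id]]) {
      cyc <- visit(child, c(path, child))
      if (!is.null(cyc)) return(cyc)
    }
    state[[id]] <- "done"
    NULL
  }
  for (id in names(graph$nodes)) {
    cyc <- visit(id, id)
    if (!is.null(cyc)) return(cyc)
  }
  NULL
}

#' @export
print.guideline_graph <- function(x, ...) {
  kinds <- table(vapply(x$nodes, `[[`, character(1), "kind"))
  cat(sprintf("<guideline_graph> %d nodes (%s), %d edges, entry '%s'\n",
              length(x$nodes),
              paste(sprintf("%d %s", kinds, names(kinds)), collapse = ", "),
              length(x$edges), x$entry))
  invisible(x)
}

#' Evaluate a guideline graph against a patient's facts
#'
#' Traverses from the entry node. A node is *highlighted* when it is
#' reachable through edges and nodes whose predicates all evaluate true
#' under the supplied facts; a predicate over a missing fact evaluates
#' *unknown*, which stops highlighting at that node but records it in
#' `unmet`. Missing facts are allowed — partial facts yield partial
#' highlighting.
#'
#' @param graph A [load_guideline()] result.
#' @param facts Named list of fact values, e.g.
#'   `list(psa = 82.35, t_category = "T2c", gleason_sum = 7)`.
#' @return An `evaluation_trace`: `highlighted` (node ids on the satisfied
#'   path, in traversal order), `visited` (all ids whose predicates were
#'   evaluated) and `unmet` (visited but not highlighted).
#' @export
evaluate_guideline <- function(graph, facts = list()) {
  stopifnot(inherits(graph, "guideline_graph"))
  status <- new.env()
  node_status <- function(id) {
    if (is.null(status[[id]])) {
      status[[id]] <- eval_predicate(graph$nodes[[id]]$predicate, facts)
    }
    status[[id]]
  }
  highlighted <- character(0)
  visited <- character(0)
  frontier <- graph$entry
  visited <- graph$entry
  if (isTRUE(node_status(graph$entry))) highlighted <- graph$entry
  while (length(frontier)) {
    nxt <- character(0)
    for (id in frontier) {
      if (!id %in% highlighted) next
      for (e in graph$edges) {
        if (e$from != id) next
        child <- e$to
        edge_ok <- eval_predicate(e$predicate, facts)
        child_ok <- node_status(child)
        if (!child %in% visited) visited <- c(visited, child)
        if (isTRUE(edge_ok) && isTRUE(child_ok) &&
            !child %in% highlighted) {
          highlighted <- c(highlighted, child)
          nxt <- c(nxt, child)
        }
      }
    }
    frontier <- unique(nxt)
  }
  structure(list(highlighted = highlighted,
                 visited = visited,
                 unmet = setdiff(visited, highlighted)),
            class = "evaluation_trace")
}

#' @export
print.evaluation_trace <- function(x, ...) {
  cat("<evaluation_trace>\n")
  cat("  highlighted:", if (length(x$highlighted))
    paste(x$highlighted, collapse = " -> ") else "(none)", "\n")
  if (length(x$unmet)) cat("  unmet:", paste(x$unmet, collapse = ", "), "\n")
  invisible(x)
}

#' Render an evaluation trace
#'
#' `"text"` lists the highlighted path in traversal order with node labels;
#' `"dot"` emits a Graphviz document in which highlighted nodes are filled
#' (so the satisfied therapeutic path stands out from the rest of the
#' flowchart).
#'
#' @param graph The graph the trace came from.
#' @param trace An [evaluate_guideline()] result over `graph`.
#' @param format `"text"` or `"dot"`.
#' @return A character vector of output lines.
#' @export
render_trace <- function(graph, trace, format = c("text", "dot")) {
  format <- match.arg(format)
  if (!all(trace$visited %in% names(graph$nodes))) {
    stop_data("trace references nodes absent from this graph")
  }
  if (format == "text") {
    lines <- vapply(trace$highlighted, function(id) {
      n <- graph$nodes[[id]]
      sprintf("%s [%s] %s", id, n$kind, n$label)
    }, character(1))
    return(unname(lines))
  }
  esc <- function(s) gsub('"', '\\\\"', s)
  out <- c("digraph guideline {", "  rankdir=TB;")
  for (id in names(graph$nodes)) {
    n <- graph$nodes[[id]]
    style <- if (id %in% trace$highlighted) {
      ' style=filled fillcolor="pink"'
    } else ""
    out <- c(out, sprintf('  "%s" [label="%s" shape=%s%s];', esc(id),
                          esc(n$label),
                          if (n$kind == "decision") "diamond" else "box",
                          style))
  }
  for (e in graph$edges) {
    out <- c(out, sprintf('  "%s" -> "%s";', esc(e$from), esc(e$to)))
  }
  c(out, "}")
}
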