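# Ternary regulatory network data model: nodes, signed (optionally
# conditional) edges, system states, and the YAML document format.

.CATEGORIES <- c("immune_cell", "signaling_molecule", "pathogen", "other")

#' Construct a ternary regulatory network
#'
#' A ternary network is a set of named nodes, each taking states -1
#' (suppressed), 0 (normal) or +1 (increased), connected by signed regulatory
#' edges. An edge may carry a condition: it only counts as a regulator when
#' the condition node occupies one of the listed states. Clamped nodes are
#' held at an externally imposed value (environmental inputs such as a
#' pathogen load) and never update.
#'
#' @param nodes a data frame with columns `name` (unique, nonempty strings),
#'   and optionally `display` (pretty label), `category` (one of
#'   `"immune_cell"`, `"signaling_molecule"`, `"pathogen"`, `"other"`) and
#'   `clamped` (logical, default `FALSE`).
#' @param edges a list of edges, each a list with elements `from`, `to`,
#'   `sign` (+1 stimulation, -1 inhibition) and optionally `condition`, itself
#'   a list with `node` and `states` (a nonempty subset of -1, 0, +1).
#' @return an object of class `ternaryNetwork`.
#' @examples
#' toy <- ternaryNetwork(
#'   nodes = data.frame(name = c("X", "Y")),
#'   edges = list(list(from = "X", to = "Y", sign = +1))
#' )
#' @seealso [loadNetwork()], [saveNetwork()], [regulatorsOf()]
#' @export
ternaryNetwork <- function(nodes, edges = list()) {
  if (is.character(nodes)) nodes <- data.frame(name = nodes)
  if (!is.data.frame(nodes) || is.null(nodes$name)) {
    inputError("'nodes' must be a data frame with a 'name' column")
  }
  nodes$name <- as.character(nodes$name)
  if (is.null(nodes$display)) nodes$display <- nodes$name
  nodes$display <- ifelse(is.na(nodes$display), nodes$name,
                          as.character(nodes$display))
  if (is.null(nodes$category)) nodes$category <- "other"
  nodes$category <- as.character(nodes$category)
  if (is.null(nodes$clamped)) nodes$clamped <- FALSE
  nodes$clamped <- as.logical(nodes$clamped)
  nodes <- nodes[, c("name", "display", "category", "clamped")]

  edges <- lapply(edges, .canonicalEdge)
  model <- structure(list(nodes = nodes, edges = edges),
                     class = "ternaryNetwork")
  validateNetwork(model)
  model
}

.canonicalEdge <- function(e) {
  if (is.null(e$from) || is.null(e$to) || is.null(e$sign)) {
    inputError("edge must have 'from', 'to' and 'sign' fields")
  }
  sgn <- e$sign
  if (is.character(sgn)) sgn <- switch(sgn, "+" = 1L, "-" = -1L, NA_integer_)
  sgn <- suppressWarnings(as.integer(sgn))
  cond <- e$condition
  if (!is.null(cond)) {
    cond <- list(node = as.character(cond$node),
                 states = sort(unique(as.integer(cond$states))))
  }
  list(from = as.character(e$from), to = as.character(e$to),
       sign = sgn, condition = cond)
}

#' Validate a ternary network
#'
#' Checks all model invariants: at least one node, unique nonempty node
#' names, legal categories, edge endpoints and condition nodes declared in
#' the model, edge signs in \{-1, +1\}, and condition states a nonempty
#' subset of \{-1, 0, +1\}. Signals an input error naming the offending
#' element; a malformed document never yields a partially built model.
#'
#' @param model a `ternaryNetwork`.
#' @return `TRUE`, invisibly.
#' @export
validateNetwork <- function(model) {
  nodes <- model$nodes
  if (nrow(nodes) < 1L) inputError("a network needs at least one node")
  if (any(!nzchar(nodes$name)) || anyNA(nodes$name)) {
    inputError("node names must be nonempty")
  }
  dup <- nodes$name[duplicated(nodes$name)]
  if (length(dup)) inputError("duplicate node name: '%s'", dup[[1L]])
  bad <- setdiff(nodes$category, .CATEGORIES)
  if (length(bad)) {
    inputError("unknown node category '%s' (must be one of %s)",
               bad[[1L]], paste(.CATEGORIES, collapse = ", "))
  }
  for (e in model$edges) {
    lbl <- sprintf("edge %s -> %s", e$from, e$to)
    for (nm in c(e$from, e$to)) {
      if (!nm %in% nodes$name) {
        inputError("%s refers to undeclared node '%s'", lbl, nm)
      }
    }
    if (is.na(e$sign) || !e$sign %in% c(-1L, 1L)) {
      inputError("%s has invalid sign (must be '+'/'-' or +1/-1)", lbl)
    }
    if (!is.null(e$condition)) {
      if (!e$condition$node %in% nodes$name) {
        inputError("%s condition refers to undeclared node '%s'",
                   lbl, e$condition$node)
      }
      if (length(e$condition$states) == 0L) {
        inputError("%s condition has an empty state set", lbl)
      }
      .checkTernary(e$condition$states, sprintf("%s condition states", lbl))
    }
  }
  invisible(TRUE)
}

#' @export
print.ternaryNetwork <- function(x, ...) {
  ncond <- sum(vapply(x$edges, function(e) !is.null(e$condition), logical(1)))
  cat(sprintf("Ternary regulatory network: %d nodes, %d edges (%d conditional)\n",
              nrow(x$nodes), length(x$edges), ncond))
  nclamp <- sum(x$nodes$clamped)
  if (nclamp > 0L) {
    cat(sprintf("Clamped nodes: %s\n",
                paste(x$nodes$name[x$nodes$clamped], collapse = ", ")))
  }
  invisible(x)
}

#' Node names of a network
#'
#' @param model a `ternaryNetwork`.
#' @return character vector of node names, in model order.
#' @export
nodeNames <- function(model) model$nodes$name

#' Compare two networks for semantic equality
#'
#' Edge order is semantically irrelevant; two models are equal when they have
#' the same nodes (names, display labels, categories, clamp flags, order) and
#' the same edge multiset (signs and conditions included).
#'
#' @param a,b `ternaryNetwork` objects.
#' @return logical.
#' @export
networksEqual <- function(a, b) {
  if (!identical(a$nodes, b$nodes)) return(FALSE)
  key <- function(e) {
    cond <- if (is.null(e$condition)) "" else {
      sprintf("|%s:%s", e$condition$node,
              paste(e$condition$states, collapse = ","))
    }
    sprintf("%s>%s*%d%s", e$from, e$to, e$sign, cond)
  }
  ka <- sort(vapply(a$edges, key, character(1)))
  kb <- sort(vapply(b$edges, key, character(1)))
  identical(ka, kb)
}

#' Read a ternary network from a YAML document
#'
#' The document has a `nodes` list (`name`, optional `display`, `category`,
#' `clamped`) and an `edges` list (`from`, `to`, `sign` as `"+"`/`"-"`,
#' optional `condition: {node, states}`). Parse failures report the YAML
#' line; validation failures name the offending node or edge.
#'
#' @param file path to a YAML network document, or a single string containing
#'   YAML text.
#' @return a validated `ternaryNetwork`.
#' @export
loadNetwork <- function(file) {
  if (length(file) != 1L || !is.character(file)) {
    inputError("'file' must be a single path or YAML string")
  }
  isPath <- !grepl("\n", file)
  if (isPath && !file.exists(file)) {
    inputError("network file '%s' does not exist", file)
  }
  doc <- tryCatch(
    if (isPath) yaml::read_yaml(file) else yaml::yaml.load(file),
    error = function(e) {
      inputError("network document is not valid YAML: %s",
                 conditionMessage(e))
    }
  )
  if (!is.list(doc)) inputError("network document is not a YAML mapping")
  if (is.null(doc$nodes)) inputError("network document has no 'nodes' section")
  nodes <- do.call(rbind, lapply(doc$nodes, function(n) {
    if (is.null(n$name)) inputError("a node entry is missing 'name'")
    data.frame(name = n$name,
               display = if (is.null(n$display)) n$name else n$display,
               category = if (is.null(n$category)) "other" else n$category,
               clamped = isTRUE(n$clamped))
  }))
  edges <- if (is.null(doc$edges)) list() else doc$edges
  ternaryNetwork(nodes, edges)
}

#' Write a ternary network to a YAML document
#'
#' Round-trips with [loadNetwork()]: reloading the saved document yields a
#' model equal to the original under [networksEqual()].
#'
#' @param model a `ternaryNetwork`.
#' @param file path to write to, or `NULL` to return the YAML text.
#' @return the YAML text, invisibly if written to a file.
#' @export
saveNetwork <- function(model, file = NULL) {
  validateNetwork(model)
  nodes <- lapply(seq_len(nrow(model$nodes)), function(i) {
    n <- model$nodes[i, ]
    out <- list(name = n$name)
    if (!identical(n$display, n$name)) out$display <- n$display
    out$category <- n$category
    if (n$clamped) out$clamped <- TRUE
    out
  })
  edges <- lapply(model$edges, function(e) {
    out <- list(from = e$from, to = e$to,
                sign = if (e$sign > 0L) "+" else "-")
    if (!is.null(e$condition)) {
      out$condition <- list(node = e$condition$node,
                            states = as.list(e$condition$states))
    }
    out
  })
  txt <- yaml::as.yaml(list(nodes = nodes, edges = edges))
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}

#' Construct a system state
#'
#' A system state assigns one of -1, 0, +1 to every node of the model.
#'
#' @param model a `ternaryNetwork`.
#' @param values a named vector covering exactly the model's node set, or a
#'   single value to assign to all nodes.
#' @return a named integer vector over the model's nodes, in model order.
#' @examples
#' toy <- ternaryNetwork(c("X", "Y"),
#'                       list(list(from = "X", to = "Y", sign = 1)))
#' systemState(toy, c(X = 1, Y = 0))
#' systemState(toy, 0)   # the all-normal state
#' @export
systemState <- function(model, values) {
  nms <- nodeNames(model)
  if (length(values) == 1L && is.null(names(values))) {
    values <- stats::setNames(rep(as.integer(values), length(nms)), nms)
  }
  if (is.null(names(values)) || !setequal(names(values), nms)) {
    inputError("state must assign a value to exactly the model's %d nodes",
               length(nms))
  }
  v <- as.integer(values[nms])
  .checkTernary(v, "state")
  stats::setNames(v, nms)
}

.checkState <- function(model, state) {
  nms <- nodeNames(model)
  if (is.null(names(state)) || !setequal(names(state), nms)) {
    inputError("state names do not match the model's node set")
  }
  .checkTernary(state, "state")
  invisible(TRUE)
}

# Per-node incoming-edge index used by the engine; computed once per model.
# For node i: integer vectors of source positions and signs plus condition
# node positions (0 = unconditional) and condition state sets.
.regulatorIndex <- function(model) {
  nms <- nodeNames(model)
  idx <- lapply(nms, function(nm) {
    list(src = integer(0), sign = integer(0),
         cnode = integer(0), cstates = list())
  })
  names(idx) <- nms
  for (e in model$edges) {
    t <- e$to
    idx[[t]]$src <- c(idx[[t]]$src, match(e$from, nms))
    idx[[t]]$sign <- c(idx[[t]]$sign, e$sign)
    if (is.null(e$condition)) {
      idx[[t]]$cnode <- c(idx[[t]]$cnode, 0L)
      idx[[t]]$cstates <- c(idx[[t]]$cstates, list(NULL))
    } else {
      idx[[t]]$cnode <- c(idx[[t]]$cnode, match(e$condition$node, nms))
      idx[[t]]$cstates <- c(idx[[t]]$cstates, list(e$condition$states))
    }
  }
  idx
}

#' States of a node's condition-satisfied regulators
#'
#' Returns the current states of all activating and inhibiting regulators of
#' `node` whose condition (if any) is satisfied by `state`; edges with
#' unsatisfied conditions are excluded entirely.
#'
#' @param model a `ternaryNetwork`.
#' @param node a node name.
#' @param state a system state (see [systemState()]).
#' @return a list with integer vectors `activators` and `inhibitors` holding
#'   the regulator states.
#' @export
regulatorsOf <- function(model, node, state) {
  nms <- nodeNames(model)
  if (!node %in% nms) inputError("unknown node '%s'", node)
  .checkState(model, state)
  state <- state[nms]
  ri <- .regulatorIndex(model)[[node]]
  keep <- vapply(seq_along(ri$src), function(j) {
    ri$cnode[j] == 0L || state[[ri$cnode[j]]] %in% ri$cstates[[j]]
  }, logical(1))
  vals <- state[ri$src[keep]]
  sgns <- ri$sign[keep]
  list(activators = unname(vals[sgns > 0L]),
       inhibitors = unname(vals[sgns < 0L]))
}
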