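# Balanced ternary update rule, asynchronous dynamics and exact steady-state
# enumeration (vectorized exhaustive scan + backtracking constraint search).

#' Next value of a node under the balanced ternary update rule
#'
#' Let A be the sign of the summed states of all condition-satisfied
#' activators of the node, and I the sign of the summed states of all
#' condition-satisfied inhibitors. The node's next value is:
#' \itemize{
#'   \item the current value, if the node is clamped;
#'   \item 0, if no regulator's condition is satisfied (deviations decay to
#'     the normal level without input);
#'   \item A, if only activators are present;
#'   \item -I, if only inhibitors are present;
#'   \item with both present: the current value when A = I and A != 0 (a
#'     simultaneous equal push from both sides leaves the node unchanged),
#'     otherwise sign(A - I).
#' }
#'
#' @param model a `ternaryNetwork`.
#' @param node a node name.
#' @param state a system state (see [systemState()]).
#' @return the target value in \{-1, 0, +1\}.
#' @export
targetValue <- function(model, node, state) {
  nms <- nodeNames(model)
  if (!node %in% nms) inputError("unknown node '%s'", node)
  .checkState(model, state)
  unname(targetVector(model, state)[node])
}

#' Target values of all nodes at once
#'
#' @inheritParams targetValue
#' @return named integer vector of targets, one per node.
#' @export
targetVector <- function(model, state) {
  .checkState(model, state)
  nms <- nodeNames(model)
  state <- state[nms]
  M <- matrix(state, nrow = 1L, dimnames = list(NULL, nms))
  stats::setNames(drop(.targetMatrix(model, M)), nms)
}

# Vectorized targets for a matrix of states (rows = states, cols = nodes in
# model order). The workhorse behind isSteady, successors, the transition
# graph and brute-force enumeration.
.targetMatrix <- function(model, M) {
  nms <- nodeNames(model)
  n <- length(nms)
  S <- nrow(M)
  ri <- .regulatorIndex(model)
  clamped <- model$nodes$clamped
  T <- matrix(0L, nrow = S, ncol = n)
  for (i in seq_len(n)) {
    if (clamped[i]) {
      T[, i] <- M[, i]
      next
    }
    r <- ri[[i]]
    k <- length(r$src)
    if (k == 0L) next
    actSum <- inhSum <- numeric(S)
    nAct <- nInh <- numeric(S)
    for (j in seq_len(k)) {
      sat <- if (r$cnode[j] == 0L) rep(TRUE, S) else
        M[, r$cnode[j]] %in% r$cstates[[j]]
      if (r$sign[j] > 0L) {
        actSum <- actSum + M[, r$src[j]] * sat
        nAct <- nAct + sat
      } else {
        inhSum <- inhSum + M[, r$src[j]] * sat
        nInh <- nInh + sat
      }
    }
    A <- .sgn(actSum)
    I <- .sgn(inhSum)
    tgt <- integer(S)
    onlyAct <- nAct > 0 & nInh == 0
    onlyInh <- nInh > 0 & nAct == 0
    both <- nAct > 0 & nInh > 0
    tgt[onlyAct] <- A[onlyAct]
    tgt[onlyInh] <- -I[onlyInh]
    retain <- both & A == I & A != 0L
    push <- both & !retain
    tgt[retain] <- M[retain, i]
    tgt[push] <- .sgn(A[push] - I[push])
    T[, i] <- tgt
  }
  T
}

#' Is a state a steady state?
#'
#' A steady state is one in which every node's target value equals its
#' current value: the system does not evolve in time.
#'
#' @inheritParams targetValue
#' @return logical.
#' @export
isSteady <- function(model, state) {
  all(targetVector(model, state) == state[nodeNames(model)])
}

#' Asynchronous successors of a state
#'
#' Under asynchronous updating only one node changes per step. Each node
#' whose target differs from its current value yields one successor. With
#' `stepwise = TRUE` (the default) the node moves a single level toward its
#' target (-1 <-> 0 <-> +1, never a two-level jump); with `stepwise = FALSE`
#' it jumps directly to the target. Both conventions have identical fixed
#' points.
#'
#' @inheritParams targetValue
#' @param stepwise move one level per step (default) or jump to the target.
#' @return a list of successor states; empty if and only if `state` is
#'   steady.
#' @export
stateSuccessors <- function(model, state, stepwise = TRUE) {
  nms <- nodeNames(model)
  .checkState(model, state)
  state <- state[nms]
  tgt <- targetVector(model, state)
  moving <- which(tgt != state)
  lapply(moving, function(i) {
    s2 <- state
    s2[i] <- if (stepwise) state[i] + .sgn(tgt[i] - state[i]) else tgt[i]
    s2
  })
}

.allStates <- function(nfree) {
  if (nfree == 0L) return(matrix(integer(0), nrow = 1L, ncol = 0L))
  S <- 3L^nfree
  idx <- 0:(S - 1L)
  M <- matrix(0L, nrow = S, ncol = nfree)
  for (k in seq_len(nfree)) {
    M[, k] <- as.integer((idx %/% 3L^(k - 1L)) %% 3L) - 1L
  }
  M
}

# Row index (1-based) of a full state matrix row within .allStates ordering,
# looking only at the free columns.
.stateIndex <- function(M, freeCols) {
  idx <- rep(1, nrow(M))
  for (k in seq_along(freeCols)) {
    idx <- idx + (M[, freeCols[k]] + 1) * 3^(k - 1)
  }
  as.integer(idx)
}

.resolveClamps <- function(model, clamps) {
  nms <- nodeNames(model)
  cl <- stats::setNames(rep(0L, length(nms)), nms)
  clampedNames <- nms[model$nodes$clamped]
  if (!is.null(clamps)) {
    if (is.null(names(clamps))) inputError("'clamps' must be a named vector")
    unknown <- setdiff(names(clamps), nms)
    if (length(unknown)) inputError("unknown clamped node '%s'", unknown[[1L]])
    notClamped <- setdiff(names(clamps), clampedNames)
    if (length(notClamped)) {
      inputError("node '%s' is not declared clamped in the model",
                 notClamped[[1L]])
    }
    .checkTernary(as.integer(clamps), "clamp")
    cl[names(clamps)] <- as.integer(clamps)
  }
  cl
}

#' Full asynchronous state-transition graph
#'
#' Builds the directed graph over all assignments of the free (unclamped)
#' nodes, with clamped nodes fixed at `clamps` (default 0). Arcs are the
#' asynchronous one-node moves of [stateSuccessors()]; steady states are
#' exactly the sink vertices.
#'
#' @inheritParams stateSuccessors
#' @param clamps named vector of values for clamped nodes (default: all 0).
#' @param cap maximum number of vertices (default `3^12`); beyond this, use
#'   [enumerateSteadyStates()] instead.
#' @return an object of class `ternaryTransitionGraph`: a list with `states`
#'   (vertex matrix, one row per state), `edges` (data frame `from`, `to`,
#'   `node`, row indices into `states`), and `sinks` (row indices of steady
#'   states).
#' @export
transitionGraph <- function(model, clamps = NULL, cap = 3^12,
                            stepwise = TRUE) {
  nms <- nodeNames(model)
  cl <- .resolveClamps(model, clamps)
  free <- which(!model$nodes$clamped)
  if (3^length(free) > cap) {
    inputError(paste("state space has 3^%d vertices, above the cap of %g;",
                     "use enumerateSteadyStates() for steady states"),
               length(free), cap)
  }
  Mf <- .allStates(length(free))
  S <- nrow(Mf)
  M <- matrix(rep(cl, each = S), nrow = S, dimnames = list(NULL, nms))
  M[, free] <- Mf
  T <- .targetMatrix(model, M)
  from <- to <- integer(0)
  via <- character(0)
  for (k in seq_along(free)) {
    j <- free[k]
    mv <- which(T[, j] != M[, j])
    if (!length(mv)) next
    M2 <- M[mv, , drop = FALSE]
    M2[, j] <- if (stepwise) M2[, j] + .sgn(T[mv, j] - M2[, j]) else T[mv, j]
    from <- c(from, mv)
    to <- c(to, .stateIndex(M2, free))
    via <- c(via, rep(nms[j], length(mv)))
  }
  sinks <- setdiff(seq_len(S), unique(from))
  structure(list(states = M,
                 edges = data.frame(from = from, to = to, node = via),
                 sinks = sinks, freeNodes = nms[free]),
            class = "ternaryTransitionGraph")
}

#' @export
print.ternaryTransitionGraph <- function(x, ...) {
  cat(sprintf("Asynchronous transition graph: %d states, %d arcs, %d sink(s)\n",
              nrow(x$states), nrow(x$edges), length(x$sinks)))
  invisible(x)
}

#' Export a transition graph as DOT or edge-list CSV
#'
#' @param graph a `ternaryTransitionGraph`.
#' @param file output path.
#' @param format `"dot"` for Graphviz, `"csv"` for an edge list.
#' @return the file path, invisibly.
#' @export
exportTransitionGraph <- function(graph, file, format = c("dot", "csv")) {
  format <- match.arg(format)
  lab <- apply(graph$states, 1L, paste, collapse = ",")
  if (format == "csv") {
    utils::write.csv(data.frame(from = lab[graph$edges$from],
                                to = lab[graph$edges$to],
                                node = graph$edges$node),
                     file, row.names = FALSE)
  } else {
    lines <- c("digraph transitions {",
               sprintf('  "%s" -> "%s" [label="%s"];',
                       lab[graph$edges$from], lab[graph$edges$to],
                       graph$edges$node),
               "}")
    writeLines(lines, file)
  }
  invisible(file)
}

#' Enumerate all steady states of a ternary network
#'
#' Finds the complete set of fixed points of the update rule with clamped
#' nodes held at `clamps`. The default `"constraint_search"` method is a
#' backtracking search over node assignments with constraint propagation:
#' whenever all regulators (and condition nodes) of a node are assigned, the
#' node's fixed-point constraint either forces its value or prunes the
#' branch, so only genuine feedback nodes are ever branched on. This scales
#' to networks far beyond exhaustive reach. `"brute_force"` scans all
#' 3^(free nodes) assignments and serves as the independent oracle on small
#' models.
#'
#' @inheritParams transitionGraph
#' @param method `"constraint_search"` (exact, scalable) or `"brute_force"`
#'   (exact, exhaustive; small models only).
#' @return an object of class `steadyStateSet`: a list with `states` (matrix
#'   with one row per steady state, columns = nodes, rows in lexicographic
#'   order) and `method`.
#' @examples
#' mi <- ternaryNetwork(c("X", "Y"), list(
#'   list(from = "X", to = "Y", sign = -1),
#'   list(from = "Y", to = "X", sign = -1)
#' ))
#' enumerateSteadyStates(mi)   # (0,0), (+1,-1), (-1,+1)
#' @export
enumerateSteadyStates <- function(model, clamps = NULL,
                                  method = c("constraint_search",
                                             "brute_force")) {
  method <- match.arg(method)
  cl <- .resolveClamps(model, clamps)
  states <- if (method == "brute_force") {
    .enumerateBrute(model, cl)
  } else {
    .enumerateConstraint(model, cl)
  }
  colnames(states) <- nodeNames(model)
  if (nrow(states) > 1L) {
    ord <- do.call(order, as.data.frame(states))
    states <- states[ord, , drop = FALSE]
  }
  structure(list(states = states, method = method, clamps = cl),
            class = "steadyStateSet")
}

#' @export
print.steadyStateSet <- function(x, ...) {
  cat(sprintf("%d steady state(s) (method: %s)\n", nrow(x$states), x$method))
  print(x$states)
  invisible(x)
}

.enumerateBrute <- function(model, cl) {
  nms <- nodeNames(model)
  free <- which(!model$nodes$clamped)
  if (3^length(free) > 3^14) {
    inputError("model too large for brute-force enumeration (3^%d states)",
               length(free))
  }
  Mf <- .allStates(length(free))
  S <- nrow(Mf)
  M <- matrix(rep(cl, each = S), nrow = S)
  M[, free] <- Mf
  T <- .targetMatrix(model, M)
  steady <- rowSums(T != M) == 0L
  M[steady, , drop = FALSE]
}

.enumerateConstraint <- function(model, cl) {
  nms <- nodeNames(model)
  n <- length(nms)
  ri <- .regulatorIndex(model)
  clamped <- model$nodes$clamped
  deps <- lapply(ri, function(r) unique(c(r$src, r$cnode[r$cnode > 0L])))

  # target of node i given values v (all deps of i assigned);
  # returns NA for the retention case (constraint vacuously satisfied)
  nodeTarget <- function(i, v) {
    r <- ri[[i]]
    k <- length(r$src)
    if (k == 0L) return(0L)
    actSum <- inhSum <- 0L
    nAct <- nInh <- 0L
    for (j in seq_len(k)) {
      if (r$cnode[j] != 0L && !(v[r$cnode[j]] %in% r$cstates[[j]])) next
      if (r$sign[j] > 0L) {
        actSum <- actSum + v[r$src[j]]
        nAct <- nAct + 1L
      } else {
        inhSum <- inhSum + v[r$src[j]]
        nInh <- nInh + 1L
      }
    }
    if (nAct == 0L && nInh == 0L) return(0L)
    A <- .sgn(actSum)
    I <- .sgn(inhSum)
    if (nInh == 0L) return(A)
    if (nAct == 0L) return(-I)
    if (A == I && A != 0L) return(NA_integer_)
    .sgn(A - I)
  }

  solutions <- list()
  recurse <- function(vals) {
    # propagate: any unclamped node with all deps assigned is forced/checked
    repeat {
      progress <- FALSE
      for (i in seq_len(n)) {
        if (clamped[i]) next
        d <- deps[[i]]
        if (length(d) && anyNA(vals[d])) next
        tg <- nodeTarget(i, vals)
        if (is.na(tg)) next   # retention: any value is a fixed point here
        if (!is.na(vals[i])) {
          if (vals[i] != tg) return(invisible(NULL))
        } else {
          vals[i] <- tg
          progress <- TRUE
        }
      }
      if (!progress) break
    }
    un <- which(is.na(vals))
    if (!length(un)) {
      if (all(targetVector(model,
                           stats::setNames(vals, nms)) == vals)) {
        solutions[[length(solutions) + 1L]] <<- vals
      }
      return(invisible(NULL))
    }
    # branch on the unassigned node with the most assigned dependencies
    score <- vapply(un, function(i) {
      d <- deps[[i]]
      if (!length(d)) 1 else mean(!is.na(vals[d]))
    }, numeric(1))
    pick <- un[which.max(score)]
    for (v in .TERNARY) {
      v2 <- vals
      v2[pick] <- v
      recurse(v2)
    }
    invisible(NULL)
  }

  init <- rep(NA_integer_, n)
  init[clamped] <- cl[clamped]
  recurse(init)
  if (!length(solutions)) {
    return(matrix(integer(0), nrow = 0L, ncol = n))
  }
  M <- do.call(rbind, solutions)
  M[!duplicated(M), , drop = FALSE]
}

#' Write or read a single system state as CSV
#'
#' The CSV has columns `node` and `value`.
#'
#' @param state a system state.
#' @param file path.
#' @return `writeState` returns the path invisibly; `readState` returns a
#'   named integer vector.
#' @export
writeState <- function(state, file) {
  utils::write.csv(data.frame(node = names(state), value = as.integer(state)),
                   file, row.names = FALSE)
  invisible(file)
}

#' @rdname writeState
#' @export
readState <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  stats::setNames(as.integer(df$value), df$node)
}
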