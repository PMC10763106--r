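# Metric multidimensional scaling by stress majorization (SMACOF), with the
# stress reported in Kruskal's normalized form
# sqrt( sum (d - delta)^2 / sum delta^2 ).

.stress1 <- function(delta, d) {
  num <- sum((d - delta)^2) / 2   # symmetric matrices: halve double count
  den <- sum(delta^2) / 2
  if (den == 0) return(0)
  sqrt(num / den)
}

.pairwiseDist <- function(X) as.matrix(stats::dist(X))

# One SMACOF run from a given configuration; raw stress is non-increasing
# across Guttman transforms.
.smacofRun <- function(delta, X, maxIter, tol) {
  n <- nrow(delta)
  for (it in seq_len(maxIter)) {
    d <- .pairwiseDist(X)
    ratio <- matrix(0, n, n)
    pos <- d > 0
    ratio[pos] <- delta[pos] / d[pos]
    B <- -ratio
    diag(B) <- 0
    diag(B) <- -rowSums(B)
    Xnew <- B %*% X / n
    if (max(abs(Xnew - X)) < tol) {
      X <- Xnew
      break
    }
    X <- Xnew
  }
  X
}

#' Embed a dissimilarity matrix in the plane by stress-minimizing MDS
#'
#' Minimizes metric stress by majorization (the Guttman transform) from
#' several seeded random starts and returns the best configuration. The
#' reported stress is Kruskal's criterion normalized by the sum of squares
#' of the dissimilarities: `sqrt(sum((d - delta)^2) / sum(delta^2))`, where
#' `delta` are the input dissimilarities and `d` the embedded Euclidean
#' distances. The returned configuration is gauge-fixed: centroid at the
#' origin, first principal axis along x, and sign chosen so the first point
#' has nonnegative x (and the second nonnegative y when free), making plots
#' reproducible.
#'
#' @param delta a symmetric, zero-diagonal, nonnegative dissimilarity matrix
#'   (n >= 2), optionally with dimnames used as point labels.
#' @param seed integer seed for the random starts.
#' @param restarts number of seeded random starts (default 8); the best
#'   final stress wins, ties broken by first found.
#' @param maxIter majorization iterations per start.
#' @param tol convergence tolerance on the configuration change.
#' @return an object of class `mdsEmbedding`: list with `coordinates`
#'   (n x 2 matrix), `stress` (normalized Kruskal stress) and `labels`.
#' @examples
#' delta <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3)
#' fit <- embedMDS(delta, seed = 1)
#' fit$stress   # ~0: any 3-point metric embeds exactly in the plane
#' @export
embedMDS <- function(delta, seed = 1L, restarts = 8L, maxIter = 2000L,
                     tol = 1e-12) {
  if (!is.matrix(delta)) delta <- as.matrix(delta)
  n <- nrow(delta)
  if (n < 2L || ncol(delta) != n) {
    inputError("'delta' must be a square matrix with n >= 2")
  }
  if (max(abs(delta - t(delta))) > 1e-10 || any(abs(diag(delta)) > 1e-12)) {
    inputError("'delta' must be symmetric with a zero diagonal")
  }
  if (any(delta < 0)) inputError("dissimilarities must be nonnegative")
  labels <- rownames(delta)
  if (is.null(labels)) labels <- paste0("P", seq_len(n))

  if (all(delta == 0)) {
    coords <- matrix(0, n, 2L, dimnames = list(labels, c("x", "y")))
    return(structure(list(coordinates = coords, stress = 0,
                          labels = labels), class = "mdsEmbedding"))
  }

  scale0 <- max(delta)
  best <- NULL
  bestStress <- Inf
  set.seed(as.integer(seed))
  for (rs in seq_len(restarts)) {
    X0 <- matrix(stats::rnorm(n * 2L, sd = scale0), n, 2L)
    X <- .smacofRun(delta, X0, maxIter, tol)
    s <- .stress1(delta, .pairwiseDist(X))
    if (s < bestStress - 1e-15) {
      bestStress <- s
      best <- X
    }
  }

  # gauge fixing: center, rotate principal axis onto x, fix signs
  X <- scale(best, center = TRUE, scale = FALSE)
  sv <- svd(X)
  X <- sv$u %*% diag(sv$d, 2L)
  if (X[1L, 1L] < 0) X[, 1L] <- -X[, 1L]
  ypos <- which(abs(X[, 2L]) > 1e-9)
  if (length(ypos) && X[ypos[1L], 2L] < 0) X[, 2L] <- -X[, 2L]
  dimnames(X) <- list(labels, c("x", "y"))

  structure(list(coordinates = X,
                 stress = .stress1(delta, .pairwiseDist(X)),
                 labels = labels),
            class = "mdsEmbedding")
}

#' @export
print.mdsEmbedding <- function(x, ...) {
  cat(sprintf("2-D stress-minimizing MDS embedding (%d points), stress = %.3g\n",
              nrow(x$coordinates), x$stress))
  print(round(x$coordinates, 4))
  invisible(x)
}

#' Write embedding coordinates as CSV
#'
#' @param embedding an `mdsEmbedding`.
#' @param file path.
#' @return the path, invisibly.
#' @export
writeEmbedding <- function(embedding, file) {
  utils::write.csv(data.frame(label = embedding$labels,
                              x = embedding$coordinates[, 1L],
                              y = embedding$coordinates[, 2L]),
                   file, row.names = FALSE)
  invisible(file)
}

#' Plot a 2-D embedding of model states and cohort profile
#'
#' Base-graphics scatter of the embedded points with labels, mirroring the
#' usual presentation of state-vs-profile projections.
#'
#' @param x an `mdsEmbedding`.
#' @param ... passed to [graphics::plot()].
#' @return the embedding, invisibly.
#' @export
plot.mdsEmbedding <- function(x, ...) {
  co <- x$coordinates
  pad <- 0.15 * max(diff(range(co[, 1])), diff(range(co[, 2])), 1e-9)
  graphics::plot(co, pch = 19,
                 xlim = range(co[, 1]) + c(-pad, pad),
                 ylim = range(co[, 2]) + c(-pad, pad),
                 xlab = "dimension 1", ylab = "dimension 2", ...)
  graphics::text(co, labels = x$labels, pos = 3)
  invisible(x)
}
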