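# Cohort-to-steady-state concordance: Welch t-tests per marker, direction-
# aware p-values, Brown's dependent-p combination, dissimilarity assembly.

.P_EPS <- 1e-15

#' Welch (heteroscedastic) two-sample t-test
#'
#' Thin wrapper around [stats::t.test()] with Satterthwaite degrees of
#' freedom, returning the two-tailed p-value. The degenerate case where both
#' samples have zero variance is handled by convention: equal means give
#' `p_two = 1` (t = 0); unequal means give `p_two = 0` (t = +/-Inf).
#'
#' @param a,b numeric samples (each of length >= 2).
#' @return a list with `t`, `df` and `p_two`.
#' @export
welchT <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) {
    inputError("each sample needs at least 2 observations")
  }
  if (anyNA(a) || anyNA(b) || any(!is.finite(c(a, b)))) {
    inputError("samples must be finite and free of missing values")
  }
  va <- stats::var(a)
  vb <- stats::var(b)
  if (va == 0 && vb == 0) {
    if (mean(a) == mean(b)) {
      return(list(t = 0, df = length(a) + length(b) - 2, p_two = 1))
    }
    return(list(t = sign(mean(a) - mean(b)) * Inf,
                df = length(a) + length(b) - 2, p_two = 0))
  }
  ht <- stats::t.test(a, b, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p_two = ht$p.value)
}

#' Direction-aware p-value against a predicted ternary level
#'
#' Maps a Welch t statistic (case minus control) onto a concordance p-value
#' for a model-predicted marker level, so that SMALL values always mean
#' "consistent with the prediction":
#' \itemize{
#'   \item predicted +1: upper-tail one-sided p (small when cases exceed
#'     controls);
#'   \item predicted -1: lower-tail one-sided p;
#'   \item predicted 0: `1 - p_two` (small when the groups coincide).
#' }
#' The result is clipped to `[1e-15, 1]` so logarithms stay finite.
#'
#' @param t Welch t statistic (case vs control).
#' @param df Welch-Satterthwaite degrees of freedom.
#' @param predicted the state's predicted level, in \{-1, 0, +1\}.
#' @return a probability in `[1e-15, 1]`.
#' @export
directionalP <- function(t, df, predicted) {
  .checkTernary(predicted, "predicted level")
  if (df <= 0) inputError("df must be positive")
  p <- if (predicted == 1L) {
    stats::pt(t, df, lower.tail = FALSE)
  } else if (predicted == -1L) {
    stats::pt(t, df, lower.tail = TRUE)
  } else {
    1 - 2 * stats::pt(-abs(t), df)
  }
  min(max(p, .P_EPS), 1)
}

#' Group-centered marker correlation matrix
#'
#' Pearson correlations between the log2 marker columns after centering each
#' marker within its group, so that inter-cytokine dependence - not the
#' case/control effect - is what is estimated. This is the correlation input
#' to [brownCombine()].
#'
#' @param cohort a cohort table (see [readCohort()] / [generateCohort()]):
#'   data frame with `subject_id`, `group`, `sex` and one numeric column per
#'   marker.
#' @param markers character vector of marker column names (default: all 12
#'   panel markers present in the table).
#' @return a symmetric correlation matrix with unit diagonal. Zero-variance
#'   markers get zero correlations, with a warning.
#' @export
markerCorrelations <- function(cohort, markers = panelMarkers()) {
  .checkCohort(cohort, markers, minPerGroup = 1L)
  if (nrow(cohort) < 3L) inputError("need at least 3 subjects")
  X <- as.matrix(cohort[, markers, drop = FALSE])
  for (g in unique(cohort$group)) {
    idx <- cohort$group == g
    X[idx, ] <- scale(X[idx, , drop = FALSE], center = TRUE, scale = FALSE)
  }
  sds <- apply(X, 2L, stats::sd)
  r <- suppressWarnings(stats::cor(X))
  if (any(sds == 0)) {
    warning("zero-variance marker(s): ",
            paste(markers[sds == 0], collapse = ", "),
            "; their correlations are set to 0")
    r[sds == 0, ] <- 0
    r[, sds == 0] <- 0
  }
  diag(r) <- 1
  r
}

# Covariance of -2 ln p_i and -2 ln p_j as a function of the correlation of
# the underlying statistics.
.brownCov <- function(r, method = c("kost-mcdermott", "brown-table")) {
  method <- match.arg(method)
  if (method == "kost-mcdermott") {
    # cubic polynomial approximation, valid over r in [-1, 1]
    3.263 * r + 0.710 * r^2 + 0.027 * r^3
  } else {
    # two-branch quadratic fit to the original tabulated values
    ifelse(r >= 0, r * (3.25 + 0.75 * r), r * (3.27 + 0.71 * r))
  }
}

#' Combine dependent p-values by Brown's method
#'
#' Fisher's statistic X = -2 sum(ln p) is referred to a rescaled chi-square
#' whose scale c and effective degrees of freedom f absorb the dependence
#' between tests: E = 2k, Var = 4k + 2 sum_\{i<j\} cov_ij, c = Var / (2E),
#' f = 2 E^2 / Var, and P = Pr(chi^2_f > X / c). The pairwise covariances
#' cov(-2 ln p_i, -2 ln p_j) are approximated from the marker correlations
#' by the Kost-McDermott cubic (default) or the original tabulated
#' approximation. With an identity correlation matrix the method reduces
#' exactly to Fisher's; with perfectly duplicated tests (r = 1) it collapses
#' to the single-test p-value.
#'
#' @param p vector of k probabilities in (0, 1]; values are clipped below at
#'   `1e-15`.
#' @param r k x k correlation matrix (default: identity, i.e. Fisher).
#' @param method covariance approximation: `"kost-mcdermott"` or
#'   `"brown-table"`.
#' @return a list with `X` (Fisher statistic), `c` (scale), `f` (effective
#'   df) and `P` (the aggregate tail probability in (0, 1]).
#' @examples
#' brownCombine(c(0.05, 0.05))                    # Fisher: ~0.01748
#' brownCombine(c(0.05, 0.05), matrix(1, 2, 2))   # collapse: 0.05
#' @export
brownCombine <- function(p, r = NULL, method = c("kost-mcdermott",
                                                 "brown-table")) {
  method <- match.arg(method)
  k <- length(p)
  if (k < 1L) inputError("need at least one p-value")
  if (any(p <= 0 | p > 1)) inputError("p-values must lie in (0, 1]")
  p <- pmin(pmax(p, .P_EPS), 1)
  if (is.null(r)) r <- diag(k)
  if (!is.matrix(r) || nrow(r) != k || ncol(r) != k) {
    inputError("'r' must be a %d x %d correlation matrix", k, k)
  }
  if (max(abs(r - t(r))) > 1e-8 || any(abs(diag(r) - 1) > 1e-8)) {
    inputError("'r' must be symmetric with unit diagonal")
  }
  X <- -2 * sum(log(p))
  E <- 2 * k
  covSum <- if (k > 1L) {
    rij <- r[upper.tri(r)]
    sum(.brownCov(rij, method))
  } else 0
  Var <- 4 * k + 2 * covSum
  if (Var <= 0) {
    warning("non-positive Brown variance; falling back to independence")
    Var <- 4 * k
  }
  cc <- Var / (2 * E)
  f <- 2 * E^2 / Var
  P <- stats::pchisq(X / cc, df = f, lower.tail = FALSE)
  list(X = X, c = cc, f = f, P = max(P, .P_EPS))
}

#' The 12 assay panel markers
#'
#' Column names (ASCII) of the plasma cytokine panel used throughout the
#' package.
#'
#' @return character vector of 12 marker names.
#' @export
panelMarkers <- function() {
  c("IL1b", "IL2", "IL4", "IL6", "IL8", "IL10",
    "IL12p70", "IL13", "IL17", "IL23", "IFNg", "TNFa")
}

.checkCohort <- function(cohort, markers = panelMarkers(),
                         minPerGroup = 2L) {
  need <- c("subject_id", "group", "sex")
  miss <- setdiff(need, names(cohort))
  if (length(miss)) {
    inputError("cohort table is missing column '%s'", miss[[1L]])
  }
  missM <- setdiff(markers, names(cohort))
  if (length(missM)) {
    inputError("cohort table is missing marker column '%s'", missM[[1L]])
  }
  for (m in markers) {
    if (!is.numeric(cohort[[m]]) || any(!is.finite(cohort[[m]]))) {
      inputError("marker column '%s' must be finite numeric", m)
    }
  }
  tab <- table(cohort$group)
  if (any(tab < minPerGroup)) {
    inputError("group '%s' has fewer than %d subjects",
               names(tab)[which.min(tab)], minPerGroup)
  }
  invisible(TRUE)
}

# Normalized L1 distance between two predicted ternary profiles over the
# mapped markers: mean |v - w| / 2, in [0, 1]. This places the model states
# jointly in one embedding; the construction is isolated here.
.statePairDissimilarity <- function(v, w) mean(abs(v - w)) / 2

#' Compare a cytokine cohort with the model's steady states
#'
#' For one sex stratum: each of the 12 panel markers is tested case vs
#' control with a Welch t-test; the t statistic is turned into a
#' direction-aware p-value against each reference state's predicted ternary
#' level at the mapped node; the 12 dependent p-values are combined with
#' Brown's method using the cohort's group-centered marker correlations.
#' The aggregate P serves as the dissimilarity between the case-group
#' profile and that state (0 = complete overlap). Model-model
#' dissimilarities are the normalized L1 distance between predicted
#' profiles, so states and cohort can be embedded jointly.
#'
#' @param cohort a cohort table (both sexes allowed; the stratum is
#'   selected here).
#' @param references reference states as from [loadMucosalFixture()].
#' @param panelMap named character vector marker -> node name.
#' @param sex which stratum to analyze (`"F"` or `"M"`).
#' @param cohortLabel label for the case-group point (default `"cohort"`).
#' @param includeControls also place the control group as a point, compared
#'   against all-normal predictions (default `FALSE`; by default controls
#'   are only the t-test reference).
#' @param method Brown covariance approximation, see [brownCombine()].
#' @return an object of class `stateComparison`: list with `markerTests`
#'   (long data frame: state, marker, predicted, t, df, p_two,
#'   p_directional), `aggregate` (data frame: state, X, c, f, P, rank),
#'   `dissimilarity` (symmetric matrix over states + cohort),
#'   `correlations`, `sex`, `nearest` (label of the minimum-P state).
#' @export
compareToStates <- function(cohort, references, panelMap,
                            sex = c("F", "M"), cohortLabel = "cohort",
                            includeControls = FALSE,
                            method = c("kost-mcdermott", "brown-table")) {
  sex <- match.arg(sex)
  method <- match.arg(method)
  markers <- names(panelMap)
  .checkCohort(cohort, markers, minPerGroup = 1L)
  sub <- cohort[cohort$sex == sex, , drop = FALSE]
  if (!all(c("case", "control") %in% sub$group)) {
    inputError("stratum '%s' needs both 'case' and 'control' subjects", sex)
  }
  tab <- table(sub$group)
  if (any(tab[c("case", "control")] < 2L)) {
    inputError("stratum '%s' needs >= 2 subjects per group", sex)
  }

  r <- markerCorrelations(sub, markers)
  caseRows <- sub$group == "case"

  # Welch tests are state-independent; direction mapping is per state
  base <- lapply(markers, function(m) {
    welchT(sub[[m]][caseRows], sub[[m]][!caseRows])
  })
  names(base) <- markers

  labels <- vapply(references, `[[`, character(1), "label")
  tests <- list()
  agg <- list()
  for (ref in references) {
    pred <- vapply(markers, function(m) ref$state[[panelMap[[m]]]],
                   integer(1))
    pdir <- vapply(markers, function(m) {
      directionalP(base[[m]]$t, base[[m]]$df, pred[[m]])
    }, numeric(1))
    br <- brownCombine(pdir, r, method = method)
    tests[[ref$label]] <- data.frame(
      state = ref$label, marker = markers, predicted = pred,
      t = vapply(base, `[[`, numeric(1), "t"),
      df = vapply(base, `[[`, numeric(1), "df"),
      p_two = vapply(base, `[[`, numeric(1), "p_two"),
      p_directional = pdir, row.names = NULL)
    agg[[ref$label]] <- data.frame(state = ref$label, X = br$X, c = br$c,
                                   f = br$f, P = br$P)
  }
  markerTests <- do.call(rbind, c(tests, list(make.row.names = FALSE)))
  aggregate <- do.call(rbind, c(agg, list(make.row.names = FALSE)))
  aggregate$rank <- rank(aggregate$P, ties.method = "first")

  pointLabels <- c(labels, cohortLabel)
  n <- length(pointLabels)
  D <- matrix(0, n, n, dimnames = list(pointLabels, pointLabels))
  for (i in seq_along(references)) {
    for (j in seq_along(references)) {
      if (i == j) next
      vi <- vapply(markers, function(m)
        references[[i]]$state[[panelMap[[m]]]], integer(1))
      vj <- vapply(markers, function(m)
        references[[j]]$state[[panelMap[[m]]]], integer(1))
      D[i, j] <- .statePairDissimilarity(vi, vj)
    }
    D[i, n] <- D[n, i] <- aggregate$P[aggregate$state == labels[i]]
  }

  if (includeControls) {
    zero <- rep(0L, length(markers))
    ctrlTests <- lapply(markers, function(m) {
      welchT(sub[[m]][!caseRows], sub[[m]][caseRows])
    })
    pdir <- vapply(seq_along(markers), function(i) {
      directionalP(ctrlTests[[i]]$t, ctrlTests[[i]]$df, 0L)
    }, numeric(1))
    brc <- brownCombine(pdir, r, method = method)
    D <- rbind(cbind(D, 0), 0)
    lbl <- paste0(cohortLabel, "_controls")
    rownames(D)[n + 1L] <- colnames(D)[n + 1L] <- lbl
    for (i in seq_along(references)) {
      vi <- vapply(markers, function(m)
        references[[i]]$state[[panelMap[[m]]]], integer(1))
      D[i, n + 1L] <- D[n + 1L, i] <- .statePairDissimilarity(vi, zero)
    }
    D[n, n + 1L] <- D[n + 1L, n] <- brc$P
  }

  structure(list(markerTests = markerTests, aggregate = aggregate,
                 dissimilarity = D, correlations = r, sex = sex,
                 nearest = aggregate$state[which.min(aggregate$P)]),
            class = "stateComparison")
}

#' @export
print.stateComparison <- function(x, ...) {
  cat(sprintf("Cohort vs model steady states (stratum %s)\n", x$sex))
  print(x$aggregate, row.names = FALSE)
  cat(sprintf("Nearest state (smallest aggregate P): %s\n", x$nearest))
  invisible(x)
}

#' Read / write a cytokine cohort CSV
#'
#' The CSV dialect has columns `subject_id`, `group` (`case`/`control`),
#' `sex` (`F`/`M`) and one numeric column per marker (log2 scale).
#'
#' @param file path.
#' @param cohort a cohort data frame.
#' @return `readCohort` returns the validated data frame; `writeCohort`
#'   returns the path invisibly.
#' @export
readCohort <- function(file) {
  if (!file.exists(file)) inputError("cohort file '%s' does not exist", file)
  df <- utils::read.csv(file, stringsAsFactors = FALSE,
                        colClasses = c(subject_id = "character",
                                       group = "character",
                                       sex = "character"))
  .checkCohort(df, intersect(panelMarkers(), names(df)), minPerGroup = 1L)
  df
}

#' @rdname readCohort
#' @export
writeCohort <- function(cohort, file) {
  utils::write.csv(cohort, file, row.names = FALSE)
  invisible(file)
}
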