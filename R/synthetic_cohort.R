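# Seeded synthetic cytokine cohorts with the statistical structure the
# comparison stage assumes: multivariate log2-normal markers with
# exchangeable correlation and optional state-aligned group shifts.

#' Configuration for a synthetic cytokine cohort
#'
#' Defaults mirror the study strata: 29 cases / 36 controls for the female
#' stratum and 25 / 28 for the male stratum. Markers are modeled on the
#' log2 scale as multivariate normal with a common baseline mean and SD and
#' exchangeable correlation `rho`. When `effectState` names a reference
#' state, the case-group mean of each mapped marker is shifted by
#' `effectSize * baselineSd` in the direction of that state's predicted
#' ternary level (predicted 0 means no shift); `"null"` injects no shift.
#'
#' @param sex `"F"` or `"M"`; sets the default sample sizes.
#' @param nCase,nControl group sizes (>= 2); defaults depend on `sex`.
#' @param baselineMean,baselineSd per-marker baseline on the log2 scale
#'   (synthetic defaults: 4.0 and 1.0 log2 units).
#' @param effectState `"null"` or a reference state label (`"SS0"`,
#'   `"SS1"`, `"SS2"`).
#' @param effectSize case-group shift in SD units (default 0.8).
#' @param rho exchangeable inter-marker correlation in `[0, 1)` (default
#'   0.3), or a full 12 x 12 correlation matrix for stress-testing.
#' @param seed integer seed; generation is deterministic given the config.
#' @return a list of class `cohortConfig`.
#' @export
cohortConfig <- function(sex = c("F", "M"), nCase = NULL, nControl = NULL,
                         baselineMean = 4.0, baselineSd = 1.0,
                         effectState = "null", effectSize = 0.8,
                         rho = 0.3, seed = 1L) {
  sex <- match.arg(sex)
  if (is.null(nCase)) nCase <- if (sex == "F") 29L else 25L
  if (is.null(nControl)) nControl <- if (sex == "F") 36L else 28L
  if (nCase < 2L || nControl < 2L) inputError("group sizes must be >= 2")
  if (baselineSd <= 0) inputError("baselineSd must be positive")
  if (!effectState %in% c("null", "SS0", "SS1", "SS2")) {
    inputError("effectState must be 'null' or one of SS0/SS1/SS2")
  }
  if (is.matrix(rho)) {
    k <- length(panelMarkers())
    if (!identical(dim(rho), c(k, k))) {
      inputError("a correlation matrix 'rho' must be %d x %d", k, k)
    }
  } else if (rho < 0 || rho >= 1) {
    inputError("exchangeable rho must lie in [0, 1)")
  }
  structure(list(sex = sex, nCase = as.integer(nCase),
                 nControl = as.integer(nControl),
                 baselineMean = baselineMean, baselineSd = baselineSd,
                 effectState = effectState, effectSize = effectSize,
                 rho = rho, seed = as.integer(seed)),
            class = "cohortConfig")
}

#' Generate a synthetic cytokine cohort
#'
#' Draws subjects from a multivariate normal on the log2 scale with the
#' configured exchangeable correlation, shifting the case-group mean per
#' marker by `effectSize * baselineSd * predicted` where `predicted` is the
#' effect state's ternary level at the mapped node. Deterministic given the
#' config's seed.
#'
#' @param config a [cohortConfig()].
#' @param fixture fixture list as from [loadMucosalFixture()]; used for the
#'   reference states and panel map.
#' @return a cohort data frame (`subject_id`, `group`, `sex`, 12 marker
#'   columns).
#' @export
generateCohort <- function(config, fixture = loadMucosalFixture()) {
  stopifnot(inherits(config, "cohortConfig"))
  markers <- panelMarkers()
  k <- length(markers)
  Sigma <- if (is.matrix(config$rho)) {
    config$baselineSd^2 * config$rho
  } else {
    config$baselineSd^2 *
      ((1 - config$rho) * diag(k) + config$rho * matrix(1, k, k))
  }
  shift <- rep(0, k)
  if (config$effectState != "null") {
    ref <- fixture$references[[config$effectState]]
    pred <- vapply(markers, function(m)
      ref$state[[fixture$panelMap[[m]]]], integer(1))
    shift <- config$effectSize * config$baselineSd * pred
  }
  n <- config$nCase + config$nControl
  set.seed(config$seed)
  X <- MASS::mvrnorm(n, mu = rep(config$baselineMean, k), Sigma = Sigma)
  group <- c(rep("case", config$nCase), rep("control", config$nControl))
  X[group == "case", ] <- sweep(X[group == "case", , drop = FALSE], 2L,
                                shift, "+")
  out <- data.frame(
    subject_id = sprintf("%s%03d", tolower(config$sex), seq_len(n)),
    group = group, sex = config$sex)
  out[markers] <- as.data.frame(X)
  out
}

#' Per-marker standardized mean differences
#'
#' Cohen's-d-style estimates (case minus control over pooled SD), used for
#' generator self-validation: injected effect directions and sizes must be
#' recovered within sampling error.
#'
#' @param cohort a cohort data frame.
#' @param markers marker columns (default: the 12 panel markers).
#' @return named numeric vector of standardized differences.
#' @export
estimateEffects <- function(cohort, markers = panelMarkers()) {
  .checkCohort(cohort, markers)
  caseRows <- cohort$group == "case"
  vapply(markers, function(m) {
    a <- cohort[[m]][caseRows]
    b <- cohort[[m]][!caseRows]
    sp <- sqrt(((length(a) - 1) * stats::var(a) +
                  (length(b) - 1) * stats::var(b)) /
                 (length(a) + length(b) - 2))
    (mean(a) - mean(b)) / sp
  }, numeric(1))
}
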