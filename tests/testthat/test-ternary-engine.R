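# Independent oracle for the update rule of a single target node: takes the
# multisets of (condition-satisfied) activator and inhibitor states plus the
# current value, written directly from the rule's case analysis.
ruleOracle <- function(act, inh, current, clamped = FALSE) {
  if (clamped) return(as.integer(current))
  if (length(act) == 0L && length(inh) == 0L) return(0L)
  A <- as.integer(sign(sum(act)))
  I <- as.integer(sign(sum(inh)))
  if (length(inh) == 0L) return(A)
  if (length(act) == 0L) return(-I)
  if (A == I && A != 0L) return(as.integer(current))
  as.integer(sign(A - I))
}

# star network: regulators R1..Rk feeding one target node T
starNet <- function(signs, clampedTarget = FALSE) {
  k <- length(signs)
  regs <- if (k == 0L) character(0) else paste0("R", seq_len(k))
  nodes <- data.frame(name = c(regs, "T"),
                      clamped = c(rep(TRUE, k), clampedTarget))
  edges <- lapply(seq_len(k), function(i)
    list(from = regs[i], to = "T", sign = signs[i]))
  ternaryNetwork(nodes, edges)
}

test_that("targetValue matches the truth-table oracle for all configurations up to 3 regulators", {
  for (k in 0:3) {
    signCombos <- if (k == 0L) list(integer(0)) else
      asplit(as.matrix(expand.grid(rep(list(c(-1L, 1L)), k))), 1L)
    for (signs in signCombos) {
      net <- starNet(as.integer(signs))
      valueCombos <- as.matrix(expand.grid(rep(list(c(-1L, 0L, 1L)), k + 1L)))
      for (row in seq_len(nrow(valueCombos))) {
        v <- as.integer(valueCombos[row, ])
        st <- systemState(net, stats::setNames(v, nodeNames(net)))
        act <- v[seq_len(k)][signs > 0L]
        inh <- v[seq_len(k)][signs < 0L]
        expect_identical(targetValue(net, "T", st),
                         ruleOracle(act, inh, v[k + 1L]))
      }
    }
  }
})

test_that("hand-picked rule cases: activation, conflict retention, decay, inhibition", {
  net <- starNet(c(1L))
  expect_identical(targetValue(net, "T", systemState(net, c(R1 = 1, T = 0))), 1L)

  both <- starNet(c(1L, -1L))
  # activators and inhibitors both increased: value remains unchanged
  expect_identical(
    targetValue(both, "T", systemState(both, c(R1 = 1, R2 = 1, T = -1))), -1L)
  # symmetric retention for a simultaneous decrease
  expect_identical(
    targetValue(both, "T", systemState(both, c(R1 = -1, R2 = -1, T = 1))), 1L)

  iso <- ternaryNetwork("T")
  expect_identical(targetValue(iso, "T", c(T = 1L)), 0L)

  inhOnly <- starNet(c(-1L))
  expect_identical(targetValue(inhOnly, "T", systemState(inhOnly, c(R1 = 1, T = 0))), -1L)
  expect_identical(targetValue(inhOnly, "T", systemState(inhOnly, c(R1 = -1, T = 0))), 1L)

  clamped <- starNet(c(1L), clampedTarget = TRUE)
  expect_identical(targetValue(clamped, "T",
                               systemState(clamped, c(R1 = 1, T = -1))), -1L)
})

test_that("a fixed +1 unconditional activator can never lower the target", {
  # sweep all signed regulator configurations up to 3 regulators
  for (k in 1:3) {
    for (signs in asplit(as.matrix(expand.grid(rep(list(c(-1L, 1L)), k))), 1L)) {
      base <- starNet(as.integer(signs))
      plus <- starNet(c(as.integer(signs), 1L))
      valueCombos <- as.matrix(expand.grid(rep(list(c(-1L, 0L, 1L)), k + 1L)))
      for (row in seq_len(nrow(valueCombos))) {
        v <- as.integer(valueCombos[row, ])
        stBase <- systemState(base, stats::setNames(v, nodeNames(base)))
        vPlus <- stats::setNames(c(v[seq_len(k)], 1L, v[k + 1L]),
                                 nodeNames(plus))
        expect_gte(targetValue(plus, "T", systemState(plus, vPlus)),
                   targetValue(base, "T", stBase))
      }
    }
  }
})

test_that("isSteady identifies fixed points of mutual inhibition", {
  mi <- mutualInhibitionNet()
  expect_true(isSteady(mi, systemState(mi, c(X = 0, Y = 0))))
  expect_true(isSteady(mi, systemState(mi, c(X = 1, Y = -1))))
  expect_false(isSteady(mi, systemState(mi, c(X = 1, Y = 1))))
})

test_that("successors implement one-step asynchronous moves", {
  mi <- mutualInhibitionNet()
  expect_length(stateSuccessors(mi, systemState(mi, c(X = 1, Y = -1))), 0L)

  # single node two levels from target moves one step only
  net <- starNet(1L)
  st <- systemState(net, c(R1 = 1, T = -1))
  succ <- stateSuccessors(net, st)
  expect_length(succ, 1L)
  expect_identical(unname(succ[[1L]]["T"]), 0L)
  # jump-to-target convention reaches the target directly
  jump <- stateSuccessors(net, st, stepwise = FALSE)
  expect_identical(unname(jump[[1L]]["T"]), 1L)

  # two off-target nodes give exactly two successors, one move each
  st2 <- systemState(mi, c(X = 1, Y = 1))
  succ2 <- stateSuccessors(mi, st2)
  expect_length(succ2, 2L)
  for (s in succ2) expect_equal(sum(s != st2), 1L)
})

test_that("every successor differs from its parent in exactly one node by one level", {
  set.seed(21)
  for (rep in 1:20) {
    net <- randomNet(sample(3:7, 1L))
    nms <- nodeNames(net)
    st <- systemState(net, stats::setNames(
      sample(c(-1L, 0L, 1L), length(nms), replace = TRUE), nms))
    for (s in stateSuccessors(net, st)) {
      d <- abs(s - st)
      expect_equal(sum(d != 0L), 1L)
      expect_equal(max(d), 1L)
    }
  }
})

test_that("transition graph of an isolated node decays to the zero sink", {
  iso <- ternaryNetwork("X")
  tg <- transitionGraph(iso)
  expect_equal(nrow(tg$states), 3L)
  expect_equal(nrow(tg$edges), 2L)   # -1 -> 0 and +1 -> 0
  expect_equal(tg$states[tg$sinks, , drop = TRUE], c(X = 0L))
})

test_that("transition graph sinks equal enumerated steady states", {
  mi <- mutualInhibitionNet()
  tg <- transitionGraph(mi)
  sinkKeys <- statesAsKeys(tg$states[tg$sinks, , drop = FALSE])
  expect_setequal(sinkKeys, c("0,0", "1,-1", "-1,1"))
  set.seed(31)
  for (rep in 1:10) {
    net <- randomNet(sample(3:6, 1L))
    tg <- transitionGraph(net)
    ss <- enumerateSteadyStates(net)
    expect_identical(statesAsKeys(tg$states[tg$sinks, , drop = FALSE]),
                     statesAsKeys(ss$states))
  }
  expect_error(transitionGraph(randomNet(8), cap = 3^5), "cap")
})

test_that("steady-state enumeration handles canonical motifs", {
  expect_equal(nrow(enumerateSteadyStates(selfActivatorNet())$states), 3L)
  mi <- enumerateSteadyStates(mutualInhibitionNet())
  expect_equal(statesAsKeys(mi$states), sort(c("0,0", "1,-1", "-1,1")))
  # clamped node held at its clamp in every steady state
  net <- ternaryNetwork(data.frame(name = c("E", "X"),
                                   clamped = c(TRUE, FALSE)),
                        list(list(from = "E", to = "X", sign = 1)))
  ss <- enumerateSteadyStates(net, clamps = c(E = 1L))
  expect_true(all(ss$states[, "E"] == 1L))
  expect_equal(statesAsKeys(ss$states), "1,1")
})

test_that("constraint search equals exhaustive scan on seeded random networks", {
  set.seed(41)
  for (rep in 1:40) {
    net <- randomNet(sample(3:7, 1L),
                     density = stats::runif(1, 0.2, 0.5))
    cs <- enumerateSteadyStates(net, method = "constraint_search")
    bf <- enumerateSteadyStates(net, method = "brute_force")
    expect_identical(statesAsKeys(cs$states), statesAsKeys(bf$states))
  }
})

test_that("the engine is deterministic", {
  set.seed(51)
  net <- randomNet(6)
  a <- enumerateSteadyStates(net)
  b <- enumerateSteadyStates(net)
  expect_identical(a$states, b$states)
})

test_that("transition graphs export as DOT and CSV, states as CSV", {
  mi <- mutualInhibitionNet()
  tg <- transitionGraph(mi)
  dot <- withr::local_tempfile(fileext = ".dot")
  exportTransitionGraph(tg, dot, "dot")
  expect_match(readLines(dot)[1], "digraph")
  csv <- withr::local_tempfile(fileext = ".csv")
  exportTransitionGraph(tg, csv, "csv")
  expect_equal(nrow(utils::read.csv(csv)), nrow(tg$edges))

  st <- systemState(mi, c(X = 1, Y = -1))
  f <- withr::local_tempfile(fileext = ".csv")
  writeState(st, f)
  expect_identical(readState(f), st)
})
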