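# Shared network builders and generators for the engine tests.

mutualInhibitionNet <- function() {
  ternaryNetwork(c("X", "Y"), list(
    list(from = "X", to = "Y", sign = -1),
    list(from = "Y", to = "X", sign = -1)
  ))
}

selfActivatorNet <- function() {
  ternaryNetwork("X", list(list(from = "X", to = "X", sign = +1)))
}

# Random signed network, optionally with conditional edges; plain-R RNG so
# generation is reproducible under set.seed.
randomNet <- function(n, density = 0.35, pCond = 0.15) {
  nms <- paste0("N", seq_len(n))
  edges <- list()
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (stats::runif(1) >= density) next
      e <- list(from = nms[i], to = nms[j],
                sign = sample(c(-1L, 1L), 1L))
      if (stats::runif(1) < pCond) {
        e$condition <- list(node = sample(nms, 1L),
                            states = sort(sample(c(-1L, 0L, 1L),
                                                 sample(1:2, 1L))))
      }
      edges[[length(edges) + 1L]] <- e
    }
  }
  ternaryNetwork(nms, edges)
}

statesAsKeys <- function(m) {
  if (nrow(m) == 0L) return(character(0))
  sort(unname(apply(m, 1L, paste, collapse = ",")))
}
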