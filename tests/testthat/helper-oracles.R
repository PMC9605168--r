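# Independent oracles used across test files.

# Flood-fill connected components on a hexagonal periodic mask, written
# without igraph: repeated frontier expansion from each unvisited cell.
flood_fill_components <- function(mask, config) {
  labels <- integer(config$n)
  nextlab <- 0L
  for (start in which(mask)) {
    if (labels[start] > 0L) next
    nextlab <- nextlab + 1L
    frontier <- start
    labels[start] <- nextlab
    while (length(frontier)) {
      nb <- unique(as.vector(config$nbr[frontier, , drop = FALSE]))
      nb <- nb[mask[nb] & labels[nb] == 0L]
      labels[nb] <- nextlab
      frontier <- nb
    }
  }
  list(n = nextlab, sizes = if (nextlab) sort(tabulate(labels[labels > 0L]),
                                              decreasing = TRUE)
                            else integer(0))
}

# Direct single-pass evaluation of the three window reactions on scalars,
# written as explicit sequential bookkeeping (independent of the vectorized
# pmin implementation).
window_oracle <- function(n11, n13, c14, c15) {
  destroyed <- min(c14, n11)
  n11 <- n11 - destroyed
  made13 <- min(c15, n11)
  n11 <- n11 - made13
  n13 <- n13 + made13
  paired <- min(n13, n11)
  n13 <- n13 - paired
  n11 <- n11 + paired
  c(n11 = n11, n13 = n13, released = destroyed)
}

# Small standard-ish run used by several tests (kept tiny for speed).
tiny_run <- function(steps = 120, seed = 11, width = 20, height = 20, ...) {
  run_protocell(run_config(width = width, height = height, steps = steps,
                           seed = seed, record_every = 20, ...))
}
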