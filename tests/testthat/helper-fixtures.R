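# Shared test utilities: brute-force oracles and small builders.

# O(n^2) reference for neighbour queries.
brute_pairs <- function(x, y, radius) {
  n <- length(x)
  out <- list()
  for (i in seq_len(n)) {
    d <- sqrt((x - x[i])^2 + (y - y[i])^2)
    j <- which(d <= radius & seq_len(n) != i)
    if (length(j)) out[[length(out) + 1L]] <-
        data.frame(i = i, j = j, dist = d[j])
  }
  if (!length(out)) return(data.frame(i = integer(), j = integer(),
                                      dist = numeric()))
  do.call(rbind, out)
}

# O(n^2) reference for local confluence.
brute_confluence <- function(x, y, surface, radius) {
  n <- length(x)
  conf <- numeric(n)
  for (i in seq_len(n)) {
    d <- sqrt((x - x[i])^2 + (y - y[i])^2)
    conf[i] <- sum(surface[d <= radius & seq_len(n) != i]) / (pi * radius^2)
  }
  pmin(conf, 1)
}

# A small plate carrying `n` staggered cells of the standard type.
test_plate <- function(n = 20, width = 500, height = 500, serum = 10,
                       seed = 1, params = nih3t3_like_params()) {
  set.seed(seed)
  plate <- new_plate(width, height, serum_level = serum)
  plate$cells <- seed_cells(n, params, width, height, init = "staggered")
  plate
}

# Minimal cell type: a single cycle edge, no movement, no death.
single_edge_params <- function(from = "G1", to = "G1c", base_prob = 0.3,
                               factors = list()) {
  nih3t3_like_params(
    transition_edges = list(transition_edge(from, to, base_prob,
                                            factors = factors)),
    phase_motility = c(G1 = 0, G1c = 0, S = 0, G2 = 0, M = 0, G0 = 0,
                       APO = 0, DAMAGED = 0, DEAD = 0))
}

# Cached scenario runs shared by the acceptance suite (each computed once).
.run_cache <- new.env(parent = emptyenv())
cached_run <- function(key, fn) {
  if (is.null(.run_cache[[key]])) .run_cache[[key]] <- fn()
  .run_cache[[key]]
}
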