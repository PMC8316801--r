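# Small graph fixtures built in code.

# straight path of n nodes, unit lengths
path_graph <- function(n, mu0 = 1) {
  pixel_graph(
    data.frame(id = seq_len(n), x = (seq_len(n) - 0.5) / n, y = 0.5),
    data.frame(from = seq_len(n - 1), to = seq.int(2, n), length = 1,
               mu0 = mu0))
}

# 4-connectivity star: centre pixel + 4 axis neighbours
star_graph <- function() {
  f <- pixel_field(matrix(c(0, 1, 0,
                            1, 1, 1,
                            0, 1, 0), 3, 3, byrow = TRUE))
  build_pixel_graph(f, 0.5, connectivity = 4)
}

# ring of n nodes, unit lengths
ring_graph <- function(n = 8, mu0 = NULL) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  mu <- mu0 %||% (1 + 0.01 * seq_len(n))   # generic position: no exact ties
  pixel_graph(
    data.frame(id = seq_len(n), x = 0.5 + 0.3 * cos(th),
               y = 0.5 + 0.3 * sin(th)),
    data.frame(from = seq_len(n), to = c(seq.int(2, n), 1L),
               length = 1, mu0 = mu))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# an extracted network made of chosen pixel-graph edges with unit weights
network_from_pixel_edges_for_test <- function(g, idx) {
  img2net:::network_from_pixel_edges(g, idx, weights = rep(1, length(idx)))
}

# brute-force 8-neighbour edge enumeration (Chebyshev distance 1)
oracle_pixel_edges <- function(mask) {
  rc <- which(mask, arr.ind = TRUE)
  W <- ncol(mask)
  ids <- (rc[, 1] - 1L) * W + rc[, 2]
  out <- NULL
  for (a in seq_len(nrow(rc))) for (b in seq_len(nrow(rc))) {
    if (ids[a] >= ids[b]) next
    dr <- abs(rc[a, 1] - rc[b, 1]); dc <- abs(rc[a, 2] - rc[b, 2])
    if (max(dr, dc) == 1)
      out <- rbind(out, data.frame(from = ids[a], to = ids[b],
                                   length = sqrt(dr^2 + dc^2)))
  }
  if (is.null(out)) data.frame(from = integer(), to = integer(),
                               length = numeric())
  else out[order(out$from, out$to), ]
}
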