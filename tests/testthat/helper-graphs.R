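# small named graphs used across tests
cycle_graph <- function(n) {
  molgraph(cbind(as.character(seq_len(n)), as.character(c(seq_len(n)[-1], 1L))))
}

path_graph <- function(n) {
  molgraph(cbind(as.character(seq_len(n - 1L)), as.character(seq_len(n)[-1L])))
}

star_graph <- function(k) {
  molgraph(cbind("c", paste0("l", seq_len(k))))
}

# random simple graph on n labelled vertices, keeping isolated vertices
random_graph <- function(n, prob = 0.4) {
  g <- igraph::sample_gnp(n, prob)
  igraph::V(g)$name <- as.character(seq_len(n))
  g
}

# labelled graph from an edge-subset bitmask over the n*(n-1)/2 vertex pairs
graph_from_mask <- function(n, mask) {
  pairs <- t(utils::combn(n, 2L))
  sel <- bitwAnd(mask, bitwShiftL(1L, seq_len(nrow(pairs)) - 1L)) != 0L
  molgraph(
    cbind(as.character(pairs[sel, 1L]), as.character(pairs[sel, 2L])),
    vertices = as.character(seq_len(n))
  )
}

# Independent edge-loop oracle: recomputes weights and index values directly
# from the adjacency structure, never touching the package's partition path.
naive_weights <- function(g, weighting) {
  d <- igraph::degree(g)
  if (weighting == "degree") {
    return(d)
  }
  vapply(
    igraph::V(g),
    function(v) sum(d[as.integer(igraph::neighbors(g, v))]),
    numeric(1L)
  )
}

naive_index <- function(g, index, weighting = "neighborhood") {
  w <- naive_weights(g, weighting)
  ends <- igraph::as_edgelist(g, names = FALSE)
  if (nrow(ends) == 0L) return(0)
  x <- w[ends[, 1L]]
  y <- w[ends[, 2L]]
  contrib <- switch(index,
    AL = abs(x - y),
    IRL = abs(log(x) - log(y)),
    IRRT = abs(x - y) / 2,
    IRF = (x - y)^2,
    IRA = (x^-0.5 - y^-0.5)^2,
    IRDIF = abs(x / y - y / x),
    IRLF = abs(x - y) / sqrt(x * y),
    LA = 2 * abs(x - y) / (x + y),
    IRDI = log(1 + abs(x - y)),
    IRGA = log((x + y) / (2 * sqrt(x * y))),
    IRB = (sqrt(x) - sqrt(y))^2,
    stop("bad index")
  )
  sum(contrib)
}
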