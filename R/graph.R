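#' Construct a validated molecular graph
#'
#' Builds a simple undirected labelled graph from an edge list. Molecular
#' graphs here are bare skeletons: atoms are opaque vertex labels, bonds are
#' unordered vertex pairs. Self-loops are rejected; duplicate edges are
#' collapsed with a warning. Isolated vertices are allowed (they are rejected
#' later only by index formulas that take logs, ratios or roots of a zero
#' weight).
#'
#' @param edges two-column matrix or data.frame of vertex labels, one edge
#'   per row. May have zero rows.
#' @param vertices optional character vector of vertex labels; must contain
#'   every edge endpoint. Use it to carry isolated vertices.
#' @return an [igraph::igraph] object with a `name` vertex attribute.
#' @export
#' @examples
#' g <- molgraph(cbind(c("a", "b", "c"), c("b", "c", "d")))
#' igraph::vcount(g)
molgraph <- function(edges, vertices = NULL) {
  edges <- as.matrix(edges)
  if (length(edges) == 0L) {
    edges <- matrix(character(), ncol = 2L)
  }
  if (ncol(edges) != 2L) {
    stop("`edges` must have exactly two columns", call. = FALSE)
  }
  storage.mode(edges) <- "character"
  if (anyNA(edges)) stop("edge endpoints must not be NA", call. = FALSE)
  loops <- edges[, 1L] == edges[, 2L]
  if (any(loops)) {
    stop(
      "self-loop not allowed: ",
      paste(unique(edges[loops, 1L]), collapse = ", "),
      call. = FALSE
    )
  }
  key <- paste(pmin(edges[, 1L], edges[, 2L]), pmax(edges[, 1L], edges[, 2L]))
  if (anyDuplicated(key)) {
    warning(
      sum(duplicated(key)), " duplicate edge(s) collapsed",
      call. = FALSE
    )
    edges <- edges[!duplicated(key), , drop = FALSE]
  }
  verts <- unique(as.vector(t(edges)))
  if (!is.null(vertices)) {
    vertices <- as.character(vertices)
    missing_ep <- setdiff(verts, vertices)
    if (length(missing_ep)) {
      stop(
        "edge endpoints not in `vertices`: ",
        paste(missing_ep, collapse = ", "),
        call. = FALSE
      )
    }
    verts <- vertices
  }
  igraph::graph_from_data_frame(
    as.data.frame(edges, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = verts, stringsAsFactors = FALSE)
  )
}

stopifnot_molgraph <- function(g) {
  if (!igraph::is_igraph(g)) stop("expected an igraph object", call. = FALSE)
  if (igraph::is_directed(g)) stop("graph must be undirected", call. = FALSE)
  if (igraph::any_loop(g) || igraph::any_multiple(g)) {
    stop("graph must be simple (no loops, no parallel edges)", call. = FALSE)
  }
  if (is.null(igraph::V(g)$name)) {
    igraph::V(g)$name <- as.character(seq_len(igraph::vcount(g)) - 1L)
  }
  g
}

#' Vertex weightings: degree and neighborhood degree sum
#'
#' `degree_weights()` assigns each vertex its degree d(u). `neighborhood_weights()`
#' assigns each vertex the sum of its neighbours' degrees, the neighborhood
#' degree sum delta(u). Summed over all vertices the neighborhood weights
#' equal the first Zagreb index, i.e. `sum(delta) == sum(d^2)`.
#'
#' @param g a molecular graph (see [molgraph()]).
#' @return named integer vector over all vertices, with attribute
#'   `weighting` set to `"degree"` or `"neighborhood"`.
#' @export
degree_weights <- function(g) {
  g <- stopifnot_molgraph(g)
  w <- igraph::degree(g)
  storage.mode(w) <- "integer"
  attr(w, "weighting") <- "degree"
  w
}

#' @rdname degree_weights
#' @export
neighborhood_weights <- function(g) {
  g <- stopifnot_molgraph(g)
  d <- igraph::degree(g)
  adj <- igraph::as_adj_list(g)
  w <- vapply(adj, function(nb) sum(d[as.integer(nb)]), numeric(1L))
  names(w) <- igraph::V(g)$name
  storage.mode(w) <- "integer"
  attr(w, "weighting") <- "neighborhood"
  w
}

#' @rdname degree_weights
#' @param weighting which weighting to compute.
#' @export
vertex_weights <- function(g, weighting = c("neighborhood", "degree")) {
  weighting <- match.arg(weighting)
  switch(weighting,
    degree = degree_weights(g),
    neighborhood = neighborhood_weights(g)
  )
}

#' Edge partition of a graph under a vertex weighting
#'
#' Groups the edges of `g` by the unordered pair of endpoint weights. The
#' pair is stored ordered as `(w_hi, w_lo)` with `w_hi >= w_lo`, so (9,8)
#' and (8,9) fall in the same class. The partition is a sufficient statistic
#' for every edge-additive index: frequencies always sum to the number of
#' edges. Rows are sorted by `(w_hi, w_lo)` descending, which also fixes the
#' summation order used by [evaluate_index()].
#'
#' @param g a molecular graph.
#' @param weighting `"neighborhood"` (default) or `"degree"`; ignored when
#'   `weights` is supplied.
#' @param weights optional precomputed vertex weighting (a named vector as
#'   returned by [vertex_weights()]) covering every vertex of `g`.
#' @return data.frame of class `edge_partition` with columns `w_hi`, `w_lo`,
#'   `freq`, and attribute `weighting`.
#' @export
#' @examples
#' p4 <- molgraph(cbind(c("1", "2", "3"), c("2", "3", "4")))
#' edge_partition(p4)  # {(3,2): 2, (3,3): 1}
edge_partition <- function(g, weighting = c("neighborhood", "degree"),
                           weights = NULL) {
  g <- stopifnot_molgraph(g)
  if (is.null(weights)) {
    weights <- vertex_weights(g, match.arg(weighting))
  } else {
    if (is.null(names(weights)) ||
        !all(igraph::V(g)$name %in% names(weights))) {
      stop("`weights` must be named and cover every vertex of `g`",
        call. = FALSE
      )
    }
  }
  ends <- igraph::as_edgelist(g, names = TRUE)
  wu <- unname(weights[ends[, 1L]])
  wv <- unname(weights[ends[, 2L]])
  part <- data.frame(w_hi = pmax(wu, wv), w_lo = pmin(wu, wv))
  if (nrow(part) == 0L) {
    agg <- data.frame(w_hi = integer(), w_lo = integer(), freq = integer())
  } else {
    agg <- stats::aggregate(
      list(freq = rep.int(1L, nrow(part))),
      by = part[c("w_hi", "w_lo")],
      FUN = sum
    )
  }
  as_edge_partition(agg, weighting = attr(weights, "weighting"))
}

#' Coerce and validate an edge partition
#'
#' @param x data.frame with columns `w_hi`, `w_lo`, `freq`.
#' @param weighting optional label recording which weighting produced the
#'   partition.
#' @return the validated, canonically sorted `edge_partition`.
#' @export
as_edge_partition <- function(x, weighting = NULL) {
  x <- as.data.frame(x)
  need <- c("w_hi", "w_lo", "freq")
  if (!all(need %in% names(x))) {
    stop("an edge partition needs columns w_hi, w_lo, freq", call. = FALSE)
  }
  x <- x[need]
  if (any(x$w_hi < x$w_lo)) {
    hi <- pmax(x$w_hi, x$w_lo)
    x$w_lo <- pmin(x$w_hi, x$w_lo)
    x$w_hi <- hi
  }
  if (any(x$freq < 0)) stop("frequencies must be non-negative", call. = FALSE)
  if (any(x$w_lo < 0)) stop("weights must be non-negative", call. = FALSE)
  x <- x[x$freq > 0 | nrow(x) == 0L, , drop = FALSE]
  x <- x[order(-x$w_hi, -x$w_lo), , drop = FALSE]
  rownames(x) <- NULL
  class(x) <- c("edge_partition", "data.frame")
  attr(x, "weighting") <- weighting
  x
}

#' Read a molecular graph from a file
#'
#' Two interchange formats are supported. The edge-list dialect is one
#' whitespace-separated vertex pair per line, with blank lines and `#`
#' comments ignored; labels are arbitrary tokens (0-based integers by
#' convention). GraphML is read through igraph and must carry vertex names
#' in the standard `name` attribute (plain ids are synthesised otherwise).
#'
#' @param path file to read.
#' @param format `"edgelist"` or `"graphml"`.
#' @return a molecular graph.
#' @export
read_molgraph <- function(path, format = c("edgelist", "graphml")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    g <- igraph::as_undirected(g, mode = "collapse")
    return(stopifnot_molgraph(g))
  }
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  keep <- grepl("\\S", lines)
  toks <- strsplit(trimws(lines[keep]), "\\s+")
  bad <- which(lengths(toks) != 2L)
  if (length(bad)) {
    stop(
      "malformed edge list line ", which(keep)[bad[1L]], " in ", path,
      ": expected two whitespace-separated labels",
      call. = FALSE
    )
  }
  edges <- do.call(rbind, toks)
  if (is.null(edges)) edges <- matrix(character(), ncol = 2L)
  molgraph(edges)
}

#' Write a molecular graph to a file
#'
#' Round-trips with [read_molgraph()]: labels and the edge set are preserved
#' exactly.
#'
#' @param g a molecular graph.
#' @param path output file.
#' @param format `"edgelist"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
write_molgraph <- function(g, path, format = c("edgelist", "graphml")) {
  g <- stopifnot_molgraph(g)
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(g, path, format = "graphml")
  } else {
    ends <- igraph::as_edgelist(g, names = TRUE)
    writeLines(
      c(
        "# edge list: one edge per line, whitespace-separated labels",
        if (nrow(ends)) paste(ends[, 1L], ends[, 2L])
      ),
      path
    )
  }
  invisible(path)
}
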