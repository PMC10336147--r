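# Registry of the eleven edge-additive irregularity forms. Each per-edge
# contribution is a symmetric function of the two endpoint weights that
# vanishes when they are equal; LA and IRRT carry the leading factors 2 and
# 1/2 as prefactors. `strict` marks forms whose contribution is undefined at
# weight zero (logs, ratios, inverse roots) and which must reject zero
# weights; the spec'd strict set also includes IRB.
index_registry <- function() {
  list(
    AL    = list(f = function(x, y) abs(x - y),                 pre = 1,   strict = FALSE),
    IRL   = list(f = function(x, y) abs(log(x) - log(y)),       pre = 1,   strict = TRUE),
    IRRT  = list(f = function(x, y) abs(x - y),                 pre = 0.5, strict = FALSE),
    IRF   = list(f = function(x, y) (x - y)^2,                  pre = 1,   strict = FALSE),
    IRA   = list(f = function(x, y) (1 / sqrt(x) - 1 / sqrt(y))^2, pre = 1, strict = TRUE),
    IRDIF = list(f = function(x, y) abs(x / y - y / x),         pre = 1,   strict = TRUE),
    IRLF  = list(f = function(x, y) abs(x - y) / sqrt(x * y),   pre = 1,   strict = TRUE),
    LA    = list(f = function(x, y) abs(x - y) / (x + y),       pre = 2,   strict = FALSE),
    IRDI  = list(f = function(x, y) log(1 + abs(x - y)),        pre = 1,   strict = FALSE),
    IRGA  = list(f = function(x, y) log((x + y) / (2 * sqrt(x * y))), pre = 1, strict = TRUE),
    IRB   = list(f = function(x, y) (sqrt(x) - sqrt(y))^2,      pre = 1,   strict = TRUE)
  )
}

#' Names of the supported irregularity indices
#'
#' Returns the canonical evaluation order. Under the neighborhood weighting
#' these are conventionally written with an `N_` prefix (N_AL, N_IRL, ...).
#'
#' @return character vector of index names.
#' @export
irregularity_indices <- function() {
  names(index_registry())
}

#' Evaluate one irregularity index on an edge partition
#'
#' Computes `prefactor * sum(freq * contribution(w_hi, w_lo))` over the
#' partition classes, summing in the canonical class order (sorted by
#' `(w_hi, w_lo)` descending) so results are bit-reproducible. Weights are
#' exact integers and contributions are evaluated in full double precision;
#' no rounded intermediates enter the sum.
#'
#' @param partition an `edge_partition` (from [edge_partition()] or
#'   [as_edge_partition()]), or a graph, in which case its partition under
#'   `weighting` is computed first.
#' @param index index name, one of [irregularity_indices()].
#' @param weighting used only when `partition` is a graph.
#' @return the index value (non-negative scalar).
#' @export
#' @examples
#' c5 <- molgraph(cbind(as.character(1:5), as.character(c(2:5, 1))))
#' evaluate_index(c5, "AL")  # 0: regular graph
evaluate_index <- function(partition, index,
                           weighting = c("neighborhood", "degree")) {
  reg <- index_registry()
  if (!is.character(index) || length(index) != 1L || !index %in% names(reg)) {
    stop(
      "unknown index; choose one of: ",
      paste(names(reg), collapse = ", "),
      call. = FALSE
    )
  }
  if (igraph::is_igraph(partition)) {
    partition <- edge_partition(partition, match.arg(weighting))
  }
  partition <- as_edge_partition(
    partition,
    weighting = attr(partition, "weighting")
  )
  def <- reg[[index]]
  if (def$strict && nrow(partition) && any(partition$w_lo <= 0)) {
    stop(
      "index ", index, " is undefined for zero endpoint weights ",
      "(log/ratio/root of 0); remove isolated-vertex weights first",
      call. = FALSE
    )
  }
  if (nrow(partition) == 0L) {
    return(0)
  }
  def$pre * sum(partition$freq * def$f(partition$w_hi, partition$w_lo))
}

#' Evaluate all eleven indices
#'
#' Batch evaluation in the canonical order. A domain error in one index
#' (e.g. a zero weight hitting a logarithmic form) does not abort the rest:
#' the failing index gets `NA` and its error message is kept in the `error`
#' column.
#'
#' @param x a molecular graph or an `edge_partition`.
#' @param weighting `"neighborhood"` or `"degree"` (used when `x` is a graph;
#'   recorded in the output either way).
#' @param indices subset of [irregularity_indices()] to evaluate.
#' @return data.frame with columns `index`, `weighting`, `value`, `error`.
#' @export
evaluate_all <- function(x, weighting = c("neighborhood", "degree"),
                         indices = irregularity_indices()) {
  weighting <- match.arg(weighting)
  indices <- match.arg(indices, irregularity_indices(), several.ok = TRUE)
  if (igraph::is_igraph(x)) {
    part <- edge_partition(x, weighting)
  } else {
    part <- as_edge_partition(x, weighting = attr(x, "weighting"))
    if (!is.null(attr(part, "weighting"))) weighting <- attr(part, "weighting")
  }
  res <- lapply(indices, function(idx) {
    tryCatch(
      list(value = evaluate_index(part, idx), error = NA_character_),
      error = function(e) list(value = NA_real_, error = conditionMessage(e))
    )
  })
  data.frame(
    index = indices,
    weighting = weighting,
    value = vapply(res, `[[`, numeric(1L), "value"),
    error = vapply(res, `[[`, character(1L), "error"),
    stringsAsFactors = FALSE
  )
}
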