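test_that("per-edge contributions are symmetric, non-negative, zero on ties", {
  reg <- nanoirr:::index_registry()
  set.seed(3)
  xs <- sample(1:30, 40, replace = TRUE)
  ys <- sample(1:30, 40, replace = TRUE)
  for (nm in names(reg)) {
    f <- reg[[nm]]$f
    expect_equal(f(xs, xs), rep(0, length(xs)), info = nm)
    expect_equal(f(xs, ys), f(ys, xs), info = nm)
    expect_true(all(f(xs, ys) >= 0), info = nm) # IRGA >= 0 by AM-GM
  }
})

test_that("evaluate_index matches hand-worked small cases", {
  p4 <- edge_partition(path_graph(4)) # {(3,2):2, (3,3):1}
  expect_equal(evaluate_index(p4, "AL"), 2) # 2*|3-2|
  expect_equal(evaluate_index(p4, "IRRT"), 1)
  expect_equal(evaluate_index(p4, "IRF"), 2)
  expect_equal(evaluate_index(p4, "IRDI"), 2 * log(2))

  # every index vanishes on a regular graph's single-class partition
  for (idx in irregularity_indices()) {
    expect_equal(evaluate_index(cycle_graph(5), idx), 0, info = idx)
  }
  expect_error(evaluate_index(p4, "NOPE"), "unknown index")
})

test_that("all indices vanish on regular graphs under both weightings", {
  set.seed(5)
  regulars <- list(
    cycle_graph(7),
    molgraph(t(utils::combn(as.character(1:5), 2))), # K5
    local({
      g <- igraph::sample_k_regular(12, 3)
      igraph::V(g)$name <- as.character(1:12)
      g
    })
  )
  for (g in regulars) {
    for (wt in c("degree", "neighborhood")) {
      vals <- evaluate_all(g, wt)
      expect_true(all(vals$value == 0))
      expect_true(all(is.na(vals$error)))
    }
  }
})

test_that("IRRT is exactly half of AL on arbitrary partitions", {
  set.seed(9)
  for (rep in 1:50) {
    g <- random_graph(sample(3:12, 1L))
    for (wt in c("degree", "neighborhood")) {
      part <- edge_partition(g, wt)
      expect_identical(
        evaluate_index(part, "IRRT"),
        evaluate_index(part, "AL") / 2
      )
    }
  }
})

test_that("index values are invariant under vertex relabelling", {
  set.seed(13)
  g <- hac5c7_graph(3, 2)
  perm <- sample(igraph::vcount(g))
  h <- igraph::permute(g, perm)
  igraph::V(h)$name <- paste0("v", seq_len(igraph::vcount(h)))
  for (wt in c("degree", "neighborhood")) {
    expect_equal(
      evaluate_all(g, wt)$value,
      evaluate_all(h, wt)$value,
      tolerance = 1e-14
    )
  }
})

test_that("doubling every class frequency doubles every index", {
  part <- edge_partition(hac5c6c7_graph(2, 2))
  doubled <- as_edge_partition(transform(part, freq = 2 * freq))
  for (idx in irregularity_indices()) {
    expect_equal(
      evaluate_index(doubled, idx),
      2 * evaluate_index(part, idx),
      tolerance = 1e-14
    )
  }
})

test_that("graph evaluation equals partition evaluation and the naive oracle", {
  # exhaustive over all labelled graphs on 4 vertices, then seeded random
  # graphs on 5-7 vertices
  run_case <- function(g) {
    for (wt in c("degree", "neighborhood")) {
      part <- edge_partition(g, wt)
      for (idx in irregularity_indices()) {
        engine <- evaluate_index(part, idx)
        expect_equal(engine, evaluate_index(g, idx, wt), tolerance = 0)
        expect_equal(engine, naive_index(g, idx, wt), tolerance = 1e-12)
      }
    }
  }
  for (mask in 0:63) run_case(graph_from_mask(4L, mask))
  set.seed(21)
  for (rep in 1:60) run_case(random_graph(sample(5:7, 1L), stats::runif(1, 0.2, 0.9)))
})

test_that("zero weights are rejected by log/ratio/root indices only", {
  part <- as_edge_partition(data.frame(w_hi = c(3, 2), w_lo = c(0, 2), freq = c(1, 4)))
  strict <- c("IRL", "IRA", "IRDIF", "IRLF", "IRGA", "IRB")
  for (idx in strict) {
    expect_error(evaluate_index(part, idx), idx)
  }
  expect_equal(evaluate_index(part, "AL"), 3)
  expect_equal(evaluate_index(part, "IRF"), 9)

  vals <- evaluate_all(part)
  expect_true(all(is.na(vals$value[vals$index %in% strict])))
  expect_true(all(!is.na(vals$value[!vals$index %in% strict])))
  expect_true(all(grepl("undefined", vals$error[vals$index %in% strict])))
})

test_that("evaluate_all keeps the canonical index order", {
  expect_identical(
    evaluate_all(path_graph(4))$index,
    c(
      "AL", "IRL", "IRRT", "IRF", "IRA", "IRDIF",
      "IRLF", "LA", "IRDI", "IRGA", "IRB"
    )
  )
})
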