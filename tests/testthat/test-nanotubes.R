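test_that("HAC5C7 realizes its neighborhood edge partition exactly", {
  for (p in 2:5) {
    for (q in 2:4) {
      g <- hac5c7_graph(p, q)
      deg <- igraph::degree(g)
      expect_equal(igraph::vcount(g), 8 * p * q)
      expect_equal(igraph::ecount(g), 12 * p * q - p)
      expect_true(all(deg %in% c(2L, 3L)))
      expect_equal(sum(deg == 2L), 2 * p)
      expect_true(igraph::is_connected(g))
      part <- edge_partition(g, "neighborhood")
      want <- nanotube_partition("HAC5C7", p, q)
      expect_equal(part$w_hi, want$w_hi)
      expect_equal(part$w_lo, want$w_lo)
      expect_equal(part$freq, as.numeric(want$freq))
    }
  }
})

test_that("HAC5C6C7 realizes the graphical repair of its partition", {
  for (p in 2:5) {
    for (q in 2:4) {
      g <- hac5c6c7_graph(p, q)
      deg <- igraph::degree(g)
      expect_equal(igraph::vcount(g), 8 * p * q + 6 * p)
      expect_equal(igraph::ecount(g), 12 * p * q + 7 * p)
      expect_true(all(deg %in% c(2L, 3L)))
      expect_true(igraph::is_connected(g))
      part <- edge_partition(g, "neighborhood")
      want <- nanotube_partition("HAC5C6C7", p, q, realized = TRUE)
      expect_equal(part[c("w_hi", "w_lo")], want[c("w_hi", "w_lo")],
        ignore_attr = TRUE
      )
      expect_equal(part$freq, as.numeric(want$freq))
    }
  }
})

test_that("neighborhood indices on generated tubes are independent of q", {
  for (family in c("HAC5C7", "HAC5C6C7")) {
    vals <- sapply(
      2:4,
      function(q) evaluate_all(nanotube_graph(family, 3, q))$value
    )
    expect_equal(vals[, 1], vals[, 2], tolerance = 1e-12)
    expect_equal(vals[, 1], vals[, 3], tolerance = 1e-12)
  }
})

test_that("generated HAC5C7 index values equal closed-form coefficient * p", {
  cf <- closed_form_table("HAC5C7")
  for (p in 2:6) {
    vals <- evaluate_all(hac5c7_graph(p, 2))
    expect_equal(vals$value, cf$p_coefficient * p, tolerance = 1e-9)
  }
})

test_that("rotating the circumferential origin gives an isomorphic tube", {
  relabel <- function(g, p, shift) {
    nm <- igraph::V(g)$name
    parts <- do.call(rbind, strsplit(nm, ".", fixed = TRUE))
    col <- suppressWarnings(as.integer(parts[, 2L]))
    bulk <- !is.na(col) # gadget labels carry the column in field 3
    if (any(!bulk)) {
      col[!bulk] <- as.integer(parts[!bulk, 3L])
      parts[!bulk, 3L] <- (col[!bulk] + shift) %% p
    }
    parts[bulk, 2L] <- (col[bulk] + shift) %% p
    igraph::V(g)$name <- apply(parts, 1L, paste, collapse = ".")
    g
  }
  for (family in c("HAC5C7", "HAC5C6C7")) {
    g <- nanotube_graph(family, 4, 2)
    h <- relabel(g, 4, 1L)
    expect_true(igraph::isomorphic(g, h))
    expect_setequal(igraph::V(g)$name, igraph::V(h)$name)
    expect_equal(
      edge_partition(g)$freq,
      edge_partition(h)$freq
    )
  }
})

test_that("parameters below 2 are rejected", {
  expect_error(hac5c7_graph(1, 3), "p, q > 1")
  expect_error(hac5c6c7_graph(3, 1), "p, q > 1")
  expect_error(hac5c7_graph(2.5, 2), "integers")
  expect_error(nanotube_graph("no_such_family", 2, 2), "unknown nanotube family")
})

test_that("validate_nanotube passes the realizable contract and audits the published one", {
  rep57 <- validate_nanotube(hac5c7_graph(3, 2), "HAC5C7", 3, 2)
  expect_true(all(rep57$pass[!rep57$published]))
  # published vertex count 8pq+p is incompatible with the partition: flagged
  expect_false(rep57$pass[rep57$check == "published_vertex_count"])
  expect_true(rep57$pass[rep57$check == "published_partition"])

  rep567 <- validate_nanotube(hac5c6c7_graph(3, 2), "HAC5C6C7", 3, 2)
  expect_true(all(rep567$pass[!rep567$published]))
  # the published table's (8,7) class is not graphical: flagged
  expect_false(rep567$pass[rep567$check == "published_partition"])

  # a damaged graph fails the edge-count and partition checks
  g <- hac5c7_graph(3, 2)
  g2 <- igraph::delete_edges(g, 1)
  bad <- validate_nanotube(g2, "HAC5C7", 3, 2)
  expect_false(bad$pass[bad$check == "edge_count"])
  expect_false(bad$pass[bad$check == "neighborhood_partition"])

  # a completely wrong graph fails the vertex count
  worse <- validate_nanotube(cycle_graph(5), "HAC5C7", 3, 2)
  expect_false(worse$pass[worse$check == "vertex_count"])
})
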