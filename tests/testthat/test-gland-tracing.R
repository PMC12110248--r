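# Layered graph construction, shortest-path extraction, phases and labels.

test_that("the layered graph has full bipartite structure plus virtual nodes", {
  set.seed(5)
  sizes <- c(2, 3, 3, 2)
  layers <- lapply(seq_along(sizes), function(l)
    data.frame(layer = l, x = sort(runif(sizes[l], 0, 300)),
               y = c(120, 190, 210, 250)[l], index = seq_len(sizes[l]),
               height = 1, prominence = 0.5, width = 10))
  g <- build_layered_graph(layers)
  expect_equal(igraph::ecount(g), 6 + 9 + 6 + 2 + 2)
  w <- igraph::E(g)$weight
  expect_true(all(w >= 0))
  virt <- igraph::incident(g, "SRC")
  expect_true(all(igraph::E(g)$weight[as.integer(virt)] == 0))
  # single chain: 3 inter-layer edges plus one source and one sink edge
  chain <- peaks_from_columns(matrix(100, 4, 1))
  g2 <- build_layered_graph(chain)
  expect_equal(igraph::ecount(g2), 5)
  expect_error(build_layered_graph(peaks_from_columns(
    matrix(c(100, NA, NA, NA), 4, 1))), "fewer than 2")
})

test_that("the shortest path of aligned peaks is the vertical column", {
  chain <- peaks_from_columns(matrix(100, 4, 1), rows = c(120, 190, 210, 250))
  sp <- shortest_gland_path(build_layered_graph(chain))
  expect_equal(sp$length, 70 + 20 + 40)
  # a zig-zag competitor loses to a straight column
  xc <- matrix(c(100, 100, 100, 100,
                 200, 230, 200, 230), 4, 2)
  g <- build_layered_graph(peaks_from_columns(xc))
  sp2 <- shortest_gland_path(g)
  xs <- igraph::V(g)$x[match(sp2$ids, igraph::V(g)$name)]
  expect_true(all(xs == 100))
})

test_that("Dijkstra matches exhaustive path enumeration on random graphs", {
  set.seed(17)
  n_checked <- 0
  for (i in 1:30) {
    pl <- random_peak_layers()
    nonempty <- sum(vapply(pl, nrow, integer(1)) > 0)
    if (nonempty < 2) next
    g <- build_layered_graph(pl)
    sp <- shortest_gland_path(g)
    ref <- bf_min_path(lapply(pl, function(p) p[, c("x", "y")]))
    if (is.null(sp)) {
      expect_identical(ref, Inf)
    } else {
      expect_equal(sp$length, ref, tolerance = 1e-9)
      n_checked <- n_checked + 1
    }
  }
  expect_gt(n_checked, 5)
})

test_that("phase structure separates long, medium and short glands", {
  # three aligned full columns, all spans below the threshold
  full3 <- peaks_from_columns(matrix(rep(c(100, 180, 260), each = 4), 4, 3))
  glands <- trace_glands(full3)
  expect_length(glands, 3)
  expect_true(all(vapply(glands, `[[`, character(1), "label") == "L"))
  # two full columns plus one bottom-2-only column at pair distance 40
  xc <- matrix(c(100, 100, 100, 100,
                 180, 180, 180, 180,
                 NA,  NA,  260, 260), 4, 3)
  pl <- peaks_from_columns(xc)
  glands2 <- trace_glands(pl)
  labs <- vapply(glands2, `[[`, character(1), "label")
  expect_equal(sort(labs), c("L", "L", "S"))
  # the S pair spans its two bottom rows, 28 px apart (< 60)
  s <- glands2[[which(labs == "S")]]
  expect_equal(s$path_length, 28)
  # a bottom pair 75 px apart is not a gland (strictly-shorter-than-60 rule)
  far <- peaks_from_columns(matrix(c(NA, NA, 260, 260), 4, 1),
                            rows = c(120, 169, 183, 258))
  expect_length(trace_glands(far), 0)
})

test_that("an empty middle layer disconnects full-length paths", {
  xc <- matrix(c(100, NA, 100, 100), 4, 1)
  pl <- peaks_from_columns(xc)
  glands <- trace_glands(pl)
  # only the bottom pair survives, as a short gland
  expect_length(glands, 1)
  expect_equal(glands[[1]]$label, "S")
})

test_that("extraction is node-disjoint, ordered, and oracle-equivalent", {
  set.seed(23)
  for (i in 1:12) {
    pl <- random_peak_layers(max_nodes = 4)
    glands <- trace_glands(pl)
    # node-disjointness
    keys <- unlist(lapply(glands, function(g)
      paste(g$nodes$layer, g$nodes$x, sep = ":")))
    expect_equal(anyDuplicated(keys), 0)
    # extraction order monotone within each phase
    ord <- order(vapply(glands, `[[`, integer(1), "order"))
    gg <- glands[ord]
    ph <- vapply(gg, `[[`, numeric(1), "phase")
    len <- vapply(gg, `[[`, numeric(1), "path_length")
    for (p in unique(ph))
      expect_true(all(diff(len[ph == p]) >= -1e-9))
    # multiset of (n_layers, length) matches the enumeration oracle
    ref <- bf_trace(pl)
    got <- sort(vapply(glands, function(g)
      round(g$path_length, 6) + 1000 * g$n_layers, numeric(1)))
    want <- sort(vapply(ref, function(g)
      round(g$length, 6) + 1000 * g$n_layers, numeric(1)))
    expect_equal(got, want, tolerance = 1e-6)
  }
})

test_that("labels discretize gland length by layer count", {
  expect_equal(classify_gland(4), "L")
  expect_equal(classify_gland(3), "M")
  expect_equal(classify_gland(2), "S")
  expect_error(classify_gland(1), "between")
  expect_error(classify_gland(5), "between")
})
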