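test_that("X-maze graph satisfies its structural invariants", {
  g <- test_graph()
  expect_equal(g$total_length, 230)
  deg <- igraph::degree(g$graph)
  expect_equal(sum(deg == 1), 4)
  expect_equal(sum(deg == 3), 2)
  expect_true(igraph::is_connected(g$graph))
  # layout intervals disjoint with 15-cm buffers between blocks
  lay <- g$layout
  expect_true(all(lay$lin_start[-1] - utils::head(lay$lin_end, -1) == 15))
  expect_equal(lay$buffer_before, c(0, 15, 15, 15, 15))
  # anchor: N sample reward at 0-10, S sample reward at 65-75
  expect_equal(segment_of(c(5, 70), g)$segment,
               c("sample_reward", "sample_reward"))
  expect_equal(segment_of(c(5, 70), g)$side, c("N", "S"))
  expect_error(build_xmaze_graph(arm_length = -1), "positive")
})

test_that("track distances match the maze geometry", {
  g <- test_graph()
  # the two sample ports are 100 cm apart; sample-to-choice ports 130 cm
  expect_equal(track_distance(0, 65, g), 100)
  expect_equal(track_distance(0, 225, g), 130)
  expect_equal(track_distance(0, 290, g), 130)
  expect_equal(track_distance(65, 225, g), 130)
  expect_equal(track_distance(42, 42, g), 0)
  expect_error(track_distance(55, 0, g), "off-track")  # buffer position
})

test_that("track distance agrees with a 1-cm brute-force graph oracle", {
  g <- test_graph()
  # oracle: breadth of shortest paths on a 1-cm discretization of the graph,
  # built independently from node coordinates and edge lengths
  grid <- mecnonlocal:::chance_grid(g)
  nod <- lapply(seq_len(nrow(g$edges)), function(i)
    seq(g$layout$lin_start[i] + 0.5, g$layout$lin_end[i] - 0.5, 1))
  ids <- unlist(nod)
  # adjacency: consecutive cm within an edge + junction links between edges
  n <- length(ids)
  adj <- matrix(FALSE, n, n)
  off <- 0
  for (i in seq_along(nod)) {
    m <- length(nod[[i]])
    for (k in seq_len(m - 1)) adj[off + k, off + k + 1] <- TRUE
    off <- off + m
  }
  # connect edge endpoints sharing a node (distance 1 cm between end cells)
  ends <- do.call(rbind, lapply(seq_along(nod), function(i) {
    m <- length(nod[[i]])
    first <- sum(lengths(nod[seq_len(i - 1)])) + 1
    data.frame(idx = c(first, first + m - 1),
               node = c(g$edges$from[i], g$edges$to[i]))
  }))
  for (nd in unique(ends$node)) {
    at <- ends$idx[ends$node == nd]
    if (length(at) > 1)
      for (a in at) for (b in at) if (a != b) adj[a, b] <- TRUE
  }
  adj <- adj | t(adj)
  gg <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  D <- igraph::distances(gg)
  set.seed(5)
  pick <- sample(n, 50)
  for (k in seq_len(25)) {
    a <- pick[k]; b <- pick[51 - k]
    expect_equal(track_distance(ids[a], ids[b], g), D[a, b],
                 tolerance = 1e-6)
  }
})

test_that("linearization round-trips and respects the snap radius", {
  g <- test_graph()
  expect_equal(linearize(g$nodes$x[1], g$nodes$y[1], g), 0)  # N sample port
  set.seed(2)
  p <- runif(200, 0, 290)
  p <- p[!is.na(mecnonlocal:::linear_to_edge(p, g)$edge)][1:100]
  xy <- embed_linear(p, g)
  expect_equal(linearize(xy[, 1], xy[, 2], g), p, tolerance = 1e-9)
  # a faraway point is off-track
  expect_true(is.na(linearize(500, 500, g)))
  # center-arm midpoint lands inside the center segment
  mid <- linearize(15, 0, g)
  expect_equal(segment_of(mid, g)$segment, "center")
})

test_that("segments tile the track with the half-open boundary convention", {
  g <- test_graph()
  expect_equal(segment_of(0, g)$segment, "sample_reward")
  expect_equal(segment_of(9.99, g)$segment, "sample_reward")
  expect_equal(segment_of(10, g)$segment, "sample_arm")
  tb <- track_bins(g)
  totals <- table(tb$segment) * g$bin_size
  expect_equal(unname(totals[segment_levels()]),
               c(20, 80, 30, 80, 20), ignore_attr = TRUE)
  expect_equal(nrow(tb), 115)
})

test_that("chance levels sum to one over the five segments at any position", {
  g <- test_graph()
  set.seed(3)
  for (pos in c(0, 40, 70, 145, 260)) {
    tot <- sum(vapply(segment_levels(), function(s)
      chance_level(pos, s, g), 0))
    expect_equal(tot, 1, tolerance = 1e-12)
  }
  expect_error(chance_level(0, "sample_reward", g, local_radius = 400),
               "denominator|maze")
})

test_that("graph JSON serialization round-trips", {
  g <- test_graph()
  tf <- tempfile(fileext = ".json")
  track_to_json(g, tf)
  g2 <- track_from_json(tf)
  expect_equal(g2$layout, g$layout)
  expect_equal(g2$total_length, g$total_length)
})
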