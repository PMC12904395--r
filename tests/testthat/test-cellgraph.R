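test_that("edge threshold is the pooled median major axis length", {
  cells <- point_cells(cbind(1:3, 0, 0))
  cells$major_axis_length_um <- c(10, 20, 30)
  expect_equal(compute_edge_threshold(cells), 20)
  cells4 <- point_cells(cbind(1:4, 0, 0))
  cells4$major_axis_length_um <- c(10, 20, 30, 40)
  expect_equal(compute_edge_threshold(cells4), 25)
  # brute-force sort-and-pick oracle on a log-normal sample
  set.seed(8)
  lens <- rlnorm(1001, log(12), 0.4)
  cells_big <- point_cells(cbind(seq_along(lens), 0, 0))
  cells_big$major_axis_length_um <- lens
  expect_equal(compute_edge_threshold(cells_big), sort(lens)[501])
  expect_error(compute_edge_threshold(point_cells(matrix(0, 0, 3))), "empty graph")
})

test_that("unit-disk edges follow the closed-disk rule", {
  cells <- point_cells(cbind(c(0, 5, 10), 0, 0))
  g <- build_cell_graph(cells, 6)
  expect_equal(nrow(g$edges), 2L)
  g0 <- build_cell_graph(cells, 4)
  expect_equal(nrow(g0$edges), 0L)
  # boundary-inclusive: distance exactly equal to the threshold is an edge
  g5 <- build_cell_graph(cells, 5)
  expect_equal(nrow(g5$edges), 2L)
  expect_error(build_cell_graph(rbind(cells, cells[1, ]), 5), "duplicate")
})

test_that("grid-bucketed neighbour search equals brute force exactly", {
  set.seed(12)
  pts <- cbind(runif(500, 0, 100), runif(500, 0, 100), runif(500, 0, 20))
  cells <- point_cells(pts)
  r <- 8
  fast <- build_cell_graph(cells, r, grid_cutoff = 100)   # forces grid path
  slow <- build_cell_graph(cells, r, grid_cutoff = 1e6)   # forces brute force
  canon <- function(e) {
    e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
    e[order(e[, 1], e[, 2]), , drop = FALSE]
  }
  expect_equal(unname(canon(fast$edges)), unname(canon(slow$edges)))
})

test_that("closed-form graph features are exact", {
  k2 <- graph_features(build_cell_graph(point_cells(cbind(c(0, 1), 0, 0)), 2))
  expect_equal(k2$estrada_index, exp(1) + exp(-1), tolerance = 1e-10)
  k3 <- graph_features(build_cell_graph(
    point_cells(cbind(c(0, 1, 0.5), c(0, 0, 0.8), 0)), 2))
  expect_equal(k3$estrada_index, exp(2) + 2 * exp(-1), tolerance = 1e-10)
  expect_equal(k3$local_communication_efficiency, 1)
  expect_equal(k3$average_connections, 2)
  p3 <- build_cell_graph(point_cells(cbind(c(0, 5, 10), 0, 0)), 6)
  f <- graph_features(p3)
  expect_equal(f$average_connections, 4 / 3)
  expect_equal(f$local_communication_efficiency, 0)
  expect_equal(graph_features(p3, efficiency = "global")$local_communication_efficiency,
               5 / 6)
  edgeless <- graph_features(build_cell_graph(
    point_cells(cbind(seq(0, 60, 10), 0, 0)), 4))
  expect_equal(edgeless$estrada_index, 7)
  expect_equal(edgeless$isolated_count, 7L)
  expect_equal(edgeless$average_connections, 0)
  expect_equal(edgeless$local_communication_efficiency, 0)
})

test_that("the empty graph yields zero features with an explicit flag", {
  g <- build_cell_graph(point_cells(matrix(0, 0, 3)), 5)
  f <- graph_features(g)
  expect_true(f$empty)
  expect_equal(f$estrada_index, 0)
  expect_equal(f$average_connections, 0)
})

test_that("estrada index agrees with the dense matrix-exponential oracle", {
  skip_if_not_installed("Matrix")
  set.seed(33)
  for (n in c(10, 60, 150)) {
    pts <- cbind(runif(n, 0, 50), runif(n, 0, 50), runif(n, 0, 10))
    g <- build_cell_graph(point_cells(pts), 8)
    f <- graph_features(g)
    A <- igraph::as_adjacency_matrix(as_igraph(g), sparse = FALSE)
    oracle <- sum(diag(as.matrix(Matrix::expm(A))))
    expect_equal(f$estrada_index, oracle, tolerance = 1e-8)
  }
})

test_that("graph features are monotone in the threshold", {
  set.seed(7)
  pts <- cbind(runif(80, 0, 60), runif(80, 0, 60), runif(80, 0, 15))
  cells <- point_cells(pts)
  thresholds <- c(4, 7, 10, 14)
  feats <- lapply(thresholds, function(r) {
    g <- build_cell_graph(cells, r)
    list(f = graph_features(g), e = nrow(g$edges))
  })
  edges <- vapply(feats, function(x) x$e, numeric(1))
  estrada <- vapply(feats, function(x) x$f$estrada_index, numeric(1))
  avg <- vapply(feats, function(x) x$f$average_connections, numeric(1))
  iso <- vapply(feats, function(x) x$f$isolated_count, numeric(1))
  expect_true(all(diff(edges) >= 0))
  expect_true(all(diff(estrada) >= 0))
  expect_true(all(diff(avg) >= 0))
  expect_true(all(diff(iso) <= 0))
})

test_that("features are invariant to relabeling and coordinate scaling", {
  set.seed(19)
  pts <- cbind(runif(50, 0, 40), runif(50, 0, 40), runif(50, 0, 10))
  cells <- point_cells(pts)
  f1 <- graph_features(build_cell_graph(cells, 9))
  perm <- sample(nrow(cells))
  shuffled <- cells[perm, ]
  shuffled$cell_id <- seq_len(nrow(cells))
  f2 <- graph_features(build_cell_graph(shuffled, 9))
  expect_equal(f1[, 1:4], f2[, 1:4])
  # scaling all coordinates and the threshold leaves the graph identical
  scaled <- cells
  scaled[, c("x_um", "y_um", "z_um")] <- scaled[, c("x_um", "y_um", "z_um")] * 3.7
  f3 <- graph_features(build_cell_graph(scaled, 9 * 3.7))
  expect_equal(f1[, 1:4], f3[, 1:4])
})

test_that("local efficiency matches a brute-force neighbour-subgraph oracle", {
  # independent oracle: adjacency matrix, neighbour-induced submatrix,
  # BFS distances by repeated boolean matrix products
  bfs_dist <- function(A) {
    n <- nrow(A)
    D <- matrix(Inf, n, n); diag(D) <- 0
    reach <- diag(TRUE, n)
    Ab <- A > 0
    for (k in seq_len(n)) {
      reach_new <- reach | (reach %*% Ab > 0)
      newly <- reach_new & !reach & is.infinite(D)
      D[newly] <- k
      if (all(reach_new == reach)) break
      reach <- reach_new
    }
    D
  }
  set.seed(41)
  pts <- cbind(runif(60, 0, 50), runif(60, 0, 50), runif(60, 0, 10))
  g <- build_cell_graph(point_cells(pts), 10)
  f <- graph_features(g)
  A <- igraph::as_adjacency_matrix(as_igraph(g), sparse = FALSE)
  oracle <- mean(vapply(seq_len(nrow(A)), function(v) {
    nb <- which(A[v, ] > 0)
    if (length(nb) < 2) return(0)
    D <- bfs_dist(A[nb, nb, drop = FALSE])
    inv <- 1 / D[upper.tri(D)]
    mean(ifelse(is.finite(inv), inv, 0))
  }, numeric(1)))
  expect_equal(f$local_communication_efficiency, oracle, tolerance = 1e-10)
})

test_that("graph export writes GraphML and an edge list", {
  g <- build_cell_graph(point_cells(cbind(c(0, 5, 10), 0, 0)), 6)
  dir <- withr::local_tempdir()
  paths <- write_cell_graph(g, file.path(dir, "g.graphml"),
                            file.path(dir, "edges.csv"))
  expect_true(all(file.exists(paths)))
  el <- read.csv(file.path(dir, "edges.csv"))
  expect_equal(nrow(el), 2L)
})
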