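#' Image-specific unit-disk edge threshold
#'
#' The edge radius of an image's cell graph is the median major axis
#' length over all detected macrophages of that image, both markers
#' pooled (even counts: mean of the two central values).
#'
#' @param cells tibble with a `major_axis_length_um` column (both markers).
#' @return Threshold in um.
#' @export
compute_edge_threshold <- function(cells) {
  lens <- cells$major_axis_length_um
  lens <- lens[is.finite(lens)]
  if (!length(lens)) {
    stopf("no cells with a defined major axis length: emit an empty graph with an undefined threshold instead")
  }
  stats::median(lens)
}

#' Build the geometric unit-disk cell graph of one image
#'
#' One node per cell (CD68+ and CD163+ pooled); an undirected edge joins
#' two cells iff the Euclidean distance between their centroids is at
#' most `threshold_um` (closed disk: equality is an edge). For more than
#' `grid_cutoff` cells, neighbour search uses spatial grid buckets of
#' side `threshold_um`; the resulting edge set is identical to the
#' brute-force all-pairs construction.
#'
#' @param cells tibble from [measure_cells()] (needs `cell_id`, `marker`,
#'   `x_um`, `y_um`, `z_um`); the combined `marker:cell_id` node ids must
#'   be unique.
#' @param threshold_um edge radius in um (> 0).
#' @param grid_cutoff cell count above which grid bucketing is used.
#' @return Object of class `cell_graph`: `nodes` tibble, integer `edges`
#'   matrix (node indices, i < j), `threshold_used`.
#' @export
build_cell_graph <- function(cells, threshold_um, grid_cutoff = 400L) {
  if (!is.numeric(threshold_um) || length(threshold_um) != 1 || threshold_um <= 0) {
    stopf("threshold_um must be a single positive number")
  }
  nodes <- tibble::tibble(
    uid = if (nrow(cells)) paste0(cells$marker, ":", cells$cell_id) else character(0),
    marker = cells$marker,
    x_um = cells$x_um, y_um = cells$y_um, z_um = cells$z_um)
  if (anyDuplicated(nodes$uid)) {
    stopf("duplicate cell ids: %s",
          paste(unique(nodes$uid[duplicated(nodes$uid)]), collapse = ", "))
  }
  if (nrow(nodes) && any(!is.finite(c(nodes$x_um, nodes$y_um, nodes$z_um)))) {
    stopf("non-finite centroid coordinates")
  }
  n <- nrow(nodes)
  pts <- cbind(nodes$x_um, nodes$y_um, nodes$z_um)
  edges <- if (n < 2) {
    matrix(integer(0), ncol = 2)
  } else if (n <= grid_cutoff) {
    d <- as.matrix(stats::dist(pts))
    which(upper.tri(d) & d <= threshold_um, arr.ind = TRUE)
  } else {
    grid_disk_edges(pts, threshold_um)
  }
  colnames(edges) <- c("i", "j")
  structure(list(nodes = nodes, edges = edges, threshold_used = threshold_um),
            class = "cell_graph")
}

# grid-bucketed closed-disk neighbour search; equals brute force exactly
grid_disk_edges <- function(pts, r) {
  key <- apply(floor(sweep(pts, 2, r, "/")), 1, paste, collapse = ",")
  buckets <- split(seq_len(nrow(pts)), key)
  cell_of <- floor(sweep(pts, 2, r, "/"))
  res_i <- integer(0); res_j <- integer(0)
  neigh <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  for (i in seq_len(nrow(pts))) {
    cand <- integer(0)
    for (o in seq_len(nrow(neigh))) {
      k <- paste(cell_of[i, ] + neigh[o, ], collapse = ",")
      b <- buckets[[k]]
      if (!is.null(b)) cand <- c(cand, b)
    }
    cand <- cand[cand > i]
    if (!length(cand)) next
    dd <- sqrt(colSums((t(pts[cand, , drop = FALSE]) - pts[i, ])^2))
    hit <- cand[dd <= r]
    res_i <- c(res_i, rep.int(i, length(hit))); res_j <- c(res_j, hit)
  }
  cbind(res_i, res_j)
}

#' @export
print.cell_graph <- function(x, ...) {
  cat(sprintf("<cell_graph> %d node(s), %d edge(s), threshold %.3g um\n",
              nrow(x$nodes), nrow(x$edges), x$threshold_used))
  invisible(x)
}

#' Convert a cell graph to igraph
#' @param g a [build_cell_graph()] result.
#' @return An undirected igraph object with `uid` and `marker` attributes.
#' @export
as_igraph <- function(g) {
  stopifnot(inherits(g, "cell_graph"))
  ig <- igraph::make_empty_graph(n = nrow(g$nodes), directed = FALSE)
  if (nrow(g$edges)) ig <- igraph::add_edges(ig, t(g$edges))
  igraph::set_vertex_attr(igraph::set_vertex_attr(ig, "uid", value = g$nodes$uid),
                          "marker", value = g$nodes$marker)
}

#' Spatial-distribution features of a cell graph
#'
#' Computes the four distribution features of the pathomic profile:
#' mean degree `2|E|/n`, isolated-cell count, Estrada index
#' `sum_i exp(lambda_i)` over the adjacency eigenvalues (3D packing /
#' compactness), and communication efficiency. The default efficiency is
#' local: the average over nodes of the mean inverse shortest-path length
#' within each node's neighbour-induced subgraph (0 for nodes with fewer
#' than 2 neighbours); `efficiency = "global"` instead returns the mean
#' inverse shortest-path length over all ordered node pairs of the whole
#' graph. `estrada_scope = "largest_component"` restricts the Estrada
#' index to the largest connected component.
#'
#' @param g a [build_cell_graph()] result.
#' @param efficiency `"local"` (default) or `"global"`.
#' @param estrada_scope `"full"` (default) or `"largest_component"`.
#' @return Tibble with `average_connections`, `isolated_count`,
#'   `local_communication_efficiency`, `estrada_index`, `n_nodes`,
#'   `n_edges` and an `empty` flag (empty graph: features 0 by definition).
#' @export
graph_features <- function(g, efficiency = c("local", "global"),
                           estrada_scope = c("full", "largest_component")) {
  stopifnot(inherits(g, "cell_graph"))
  efficiency <- match.arg(efficiency)
  estrada_scope <- match.arg(estrada_scope)
  n <- nrow(g$nodes)
  if (n == 0) {
    return(tibble::tibble(average_connections = 0, isolated_count = 0L,
                          local_communication_efficiency = 0,
                          estrada_index = 0, n_nodes = 0L, n_edges = 0L,
                          empty = TRUE))
  }
  ig <- as_igraph(g)
  deg <- igraph::degree(ig)
  eg <- ig
  if (estrada_scope == "largest_component") {
    comp <- igraph::components(ig)
    eg <- igraph::induced_subgraph(ig, which(comp$membership == which.max(comp$csize)))
  }
  tibble::tibble(
    average_connections = 2 * nrow(g$edges) / n,
    isolated_count = sum(deg == 0L),
    local_communication_efficiency =
      if (efficiency == "local") local_efficiency_mean(ig) else igraph::global_efficiency(ig),
    estrada_index = estrada_index(eg),
    n_nodes = n, n_edges = nrow(g$edges), empty = FALSE)
}

# Estrada index of an igraph object via the symmetric adjacency spectrum
estrada_index <- function(ig) {
  n <- igraph::vcount(ig)
  if (n == 0) return(0)
  A <- igraph::as_adjacency_matrix(ig, sparse = FALSE)
  sum(exp(eigen(A, symmetric = TRUE, only.values = TRUE)$values))
}

# Latora-Marchiori local efficiency, averaged over all nodes
# (nodes with < 2 neighbours contribute 0)
local_efficiency_mean <- function(ig) {
  n <- igraph::vcount(ig)
  if (n == 0) return(0)
  effs <- vapply(seq_len(n), function(v) {
    nb <- as.integer(igraph::neighbors(ig, v))
    k <- length(nb)
    if (k < 2) return(0)
    sub <- igraph::induced_subgraph(ig, nb)
    D <- igraph::distances(sub)
    inv <- 1 / D[upper.tri(D)]
    inv[!is.finite(inv)] <- 0
    mean(inv)  # ordered-pair mean equals the unordered mean by symmetry
  }, numeric(1))
  mean(effs)
}

#' Export a cell graph as GraphML and/or edge-list CSV
#'
#' @param g a [build_cell_graph()] result.
#' @param graphml_path,edges_path output paths (either may be `NULL`).
#' @return Invisibly, the written paths.
#' @export
write_cell_graph <- function(g, graphml_path = NULL, edges_path = NULL) {
  stopifnot(inherits(g, "cell_graph"))
  written <- character(0)
  if (!is.null(graphml_path)) {
    igraph::write_graph(as_igraph(g), graphml_path, format = "graphml")
    written <- c(written, graphml_path)
  }
  if (!is.null(edges_path)) {
    el <- data.frame(from = g$nodes$uid[g$edges[, 1]],
                     to = g$nodes$uid[g$edges[, 2]])
    utils::write.csv(el, edges_path, row.names = FALSE)
    written <- c(written, edges_path)
  }
  invisible(written)
}
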