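#' Manhattan street lattice
#'
#' Builds the synthetic street network: a square lattice of nodes every
#' `block` metres over `[0, extent]^2`, with horizontal and vertical
#' segments between adjacent nodes. Network operations (service areas,
#' walking distances) run on the corresponding igraph with edge weights
#' equal to segment length.
#'
#' @param extent Side length of the square region, metres.
#' @param block Block size (node spacing), metres (default 200).
#' @return A `street_lattice`: `nodes` (data.frame id, x, y), `segments`
#'   (data.frame x0, y0, x1, y1, length), `graph` (igraph), `block`,
#'   `extent`.
#' @export
street_lattice <- function(extent, block = 200) {
  if (extent <= 0 || block <= 0) stop("extent and block must be positive")
  if (extent %% block != 0) stop("extent must be a multiple of block size")
  k <- as.integer(extent / block)  # k+1 nodes per side
  xs <- seq(0, extent, by = block)
  nodes <- expand.grid(x = xs, y = xs)
  nodes$id <- seq_len(nrow(nodes))
  node_at <- function(ix, iy) iy * (k + 1L) + ix + 1L  # 0-based grid index
  ix <- rep(0:k, times = k + 1L)
  iy <- rep(0:k, each = k + 1L)
  # horizontal edges
  h_from <- node_at(ix[ix < k], iy[ix < k])
  h_to <- h_from + 1L
  # vertical edges
  v_from <- node_at(ix[iy < k], iy[iy < k])
  v_to <- v_from + (k + 1L)
  from <- c(h_from, v_from); to <- c(h_to, v_to)
  segments <- data.frame(
    x0 = nodes$x[from], y0 = nodes$y[from],
    x1 = nodes$x[to], y1 = nodes$y[to])
  segments$length <- abs(segments$x1 - segments$x0) +
    abs(segments$y1 - segments$y0)
  g <- igraph::graph_from_edgelist(cbind(from, to), directed = FALSE)
  igraph::E(g)$weight <- segments$length
  structure(list(nodes = nodes[, c("id", "x", "y")], segments = segments,
                 edge_from = from, edge_to = to, graph = g,
                 block = block, extent = extent),
            class = "street_lattice")
}

#' Snap a point to the nearest lattice node
#'
#' @param streets A `street_lattice`.
#' @param x,y Point coordinates, metres.
#' @return List with `id`, `x`, `y`, and `offset` (euclidean snap distance).
#' @export
snap_to_node <- function(streets, x, y) {
  d2 <- (streets$nodes$x - x)^2 + (streets$nodes$y - y)^2
  i <- which.min(d2)
  list(id = streets$nodes$id[i], x = streets$nodes$x[i],
       y = streets$nodes$y[i], offset = sqrt(d2[i]))
}

#' Shortest-path network distances from a point
#'
#' Distances along the lattice from the node nearest `(x, y)` to every
#' lattice node.
#'
#' @param streets A `street_lattice`.
#' @param x,y Source point, metres.
#' @return Numeric vector of network distances per node (node order as in
#'   `streets$nodes`), with attribute `source_node`.
#' @export
lattice_node_distances <- function(streets, x, y) {
  src <- snap_to_node(streets, x, y)
  d <- as.numeric(igraph::distances(streets$graph, v = src$id,
                                    weights = igraph::E(streets$graph)$weight))
  attr(d, "source_node") <- src
  d
}
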