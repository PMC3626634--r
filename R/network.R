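# Weighted functional graphs and topology measures.
#
# The functional graph has electrodes as nodes and coherences as edge
# weights. Edge strength w maps to a functional distance d = -ln(w):
# perfect synchrony (w = 1) is distance 0, incoherence (w = 0) infinitely
# far. Shortest functional paths define the characteristic path length
# (mean shortest distance; driven by weak links, infinite for disconnected
# graphs) and the global efficiency (mean inverse shortest distance; driven
# by strong links, finite for disconnected graphs). Segregation is
# quantified by the geometric-mean (Onnela-form) weighted clustering
# coefficient with the raw coherence weights, which are already in [0, 1].

#' Build the weighted functional graph
#'
#' @param m A `band_coherence` object or a symmetric weight matrix with
#'   entries in `[0, 1]` (the diagonal is ignored).
#' @return An object of class `functional_graph`: `nodes` (names),
#'   `weights` (symmetric, zero diagonal), `distances` (`-log(weights)`,
#'   `Inf` where the weight is 0).
#' @export
build_graph <- function(m) {
  W <- if (inherits(m, "band_coherence")) m$values else as.matrix(m)
  if (nrow(W) != ncol(W)) stop("weight matrix must be square")
  if (any(!is.finite(W)) || any(W < 0) || any(W > 1))
    stop("edge weights must be finite and lie in [0, 1]")
  if (max(abs(W - t(W))) > 1e-12) stop("weight matrix must be symmetric")
  W <- (W + t(W)) / 2
  diag(W) <- 0
  D <- -log(W)              # w = 0 -> Inf, w = 1 -> 0
  diag(D) <- 0
  nodes <- rownames(W)
  if (is.null(nodes)) nodes <- sprintf("n%02d", seq_len(nrow(W)))
  dimnames(W) <- dimnames(D) <- list(nodes, nodes)
  structure(list(nodes = nodes, weights = W, distances = D),
            class = "functional_graph")
}

#' @export
print.functional_graph <- function(x, ...) {
  cat(sprintf("functional graph: %d nodes, %d positive-weight edges\n",
              length(x$nodes), sum(x$weights[upper.tri(x$weights)] > 0)))
  invisible(x)
}

# Shortest functional distances between all node pairs (Dijkstra on the
# -log weights; edges with infinite distance are absent).
shortest_distances <- function(D) {
  n <- nrow(D)
  ut <- which(upper.tri(D) & is.finite(D), arr.ind = TRUE)
  if (nrow(ut) == 0) {
    out <- matrix(Inf, n, n); diag(out) <- 0
    return(out)
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = ut[, 1], to = ut[, 2], weight = D[ut]),
    directed = FALSE,
    vertices = data.frame(name = as.character(seq_len(n))))
  sp <- igraph::distances(g, algorithm = "dijkstra")
  ord <- match(as.character(seq_len(n)), rownames(sp))
  sp[ord, ord]
}

#' Characteristic path length
#'
#' Mean shortest functional-path distance over all unordered node pairs;
#' `Inf` if any pair is unreachable.
#'
#' @param g A `functional_graph`.
#' @return Scalar (functional-distance units), possibly `Inf`.
#' @export
characteristic_path_length <- function(g) {
  stopifnot(inherits(g, "functional_graph"))
  sp <- shortest_distances(g$distances)
  mean(sp[upper.tri(sp)])
}

EFFICIENCY_EPS <- 1e-12

efficiency_from_distances <- function(D) {
  sp <- shortest_distances(D)
  v <- sp[upper.tri(sp)]
  if (length(v) == 0) return(0)
  inv <- ifelse(is.infinite(v), 0, 1 / pmax(v, EFFICIENCY_EPS))
  mean(inv)
}

#' Global efficiency
#'
#' Mean inverse shortest functional-path distance over all unordered node
#' pairs. Unreachable pairs contribute 0, so the measure stays finite for
#' disconnected graphs; a zero-distance pair (weight exactly 1) contributes
#' the capped value `1/1e-12`.
#'
#' @param g A `functional_graph`.
#' @return Scalar (inverse-distance units), `>= 0`.
#' @export
global_efficiency <- function(g) {
  stopifnot(inherits(g, "functional_graph"))
  efficiency_from_distances(g$distances)
}

#' Weighted clustering coefficient
#'
#' Network average of the per-node geometric-mean weighted clustering
#' `C_i = sum_{j,h} (w_ij w_ih w_jh)^(1/3) / (k_i (k_i - 1))` with the raw
#' coherence weights (bounded by 1, so no normalization is applied) and
#' `k_i` the number of positive-weight neighbors. Nodes with fewer than two
#' neighbors have `C_i = 0` by convention.
#'
#' @param g A `functional_graph`.
#' @param per_node If `TRUE`, return the per-node vector instead of the
#'   network mean.
#' @return Scalar in `[0, 1]`, or a named vector when `per_node = TRUE`.
#' @export
clustering_coefficient <- function(g, per_node = FALSE) {
  stopifnot(inherits(g, "functional_graph"))
  W <- g$weights
  W3 <- W^(1 / 3)
  num <- diag(W3 %*% W3 %*% W3)
  k <- rowSums(W > 0)
  ci <- ifelse(k >= 2, num / (k * (k - 1)), 0)
  names(ci) <- g$nodes
  if (per_node) ci else mean(ci)
}

#' All three topology measures
#'
#' @param g A `functional_graph`.
#' @return One-row data frame: `path_length`, `clustering`, `efficiency`.
#' @export
graph_metrics <- function(g) {
  data.frame(
    path_length = characteristic_path_length(g),
    clustering = clustering_coefficient(g),
    efficiency = global_efficiency(g)
  )
}
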