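# Network resilience to node removal, and hub concentration.
#
# Attacks and failures are simulated by deleting nodes together with their
# edges and recomputing the global efficiency of the damaged graph relative
# to baseline. "Highly connected" is ranked by node strength (sum of
# incident weights): on a fully weighted graph every node has the same
# binary degree, so strength is the meaningful hub ranking.

#' Node strength (weighted degree)
#'
#' @param g A `functional_graph`.
#' @return Named numeric vector of per-node strengths.
#' @export
node_strength <- function(g) {
  stopifnot(inherits(g, "functional_graph"))
  stats::setNames(rowSums(g$weights), g$nodes)
}

subgraph_efficiency <- function(g, keep) {
  if (length(keep) < 2) return(0)
  efficiency_from_distances(g$distances[keep, keep, drop = FALSE])
}

#' Targeted attack
#'
#' Nodes are ranked once by strength on the intact graph (ties broken by
#' node order); for each `k = 0..k_max` the top-`k` nodes are removed
#' simultaneously and the global efficiency of the remaining subgraph is
#' reported relative to baseline. With `sequential = TRUE` the ranking is
#' recomputed after each single removal instead.
#'
#' @param g A `functional_graph`.
#' @param k_max Maximum number of nodes removed (default 5; must be below
#'   the node count).
#' @param sequential Re-rank after every removal (default `FALSE`).
#' @return A data frame of class `resilience_profile` with columns `mode`,
#'   `k`, `relative_efficiency`; the removal order is in
#'   `attr(, "removal_order")`.
#' @export
targeted_attack <- function(g, k_max = 5, sequential = FALSE) {
  stopifnot(inherits(g, "functional_graph"), k_max >= 0,
            k_max < length(g$nodes))
  e0 <- global_efficiency(g)
  if (e0 <= 0) stop("baseline global efficiency is zero: resilience undefined")
  n <- length(g$nodes)
  if (sequential) {
    removed <- integer(0)
    order_names <- character(0)
    rel <- numeric(k_max)
    for (k in seq_len(k_max)) {
      keep <- setdiff(seq_len(n), removed)
      s <- rowSums(g$weights[keep, keep, drop = FALSE])
      pick <- keep[order(-s, seq_along(s))[1]]
      removed <- c(removed, pick)
      order_names <- c(order_names, g$nodes[pick])
      rel[k] <- subgraph_efficiency(g, setdiff(seq_len(n), removed)) / e0
    }
    out <- data.frame(mode = "targeted", k = 0:k_max,
                      relative_efficiency = c(1, rel))
    attr(out, "removal_order") <- order_names
  } else {
    s <- node_strength(g)
    ord <- order(-s, seq_along(s))
    rel <- vapply(0:k_max, function(k) {
      if (k == 0) return(1)
      keep <- setdiff(seq_len(n), ord[seq_len(k)])
      subgraph_efficiency(g, keep) / e0
    }, numeric(1))
    out <- data.frame(mode = "targeted", k = 0:k_max,
                      relative_efficiency = rel)
    attr(out, "removal_order") <- g$nodes[ord[seq_len(max(k_max, 1))]]
  }
  class(out) <- c("resilience_profile", class(out))
  out
}

#' Random failure
#'
#' For each `k = 0..k_max`, removes `k` uniformly drawn nodes (without
#' replacement within a draw) and reports the mean and SD over `replicates`
#' draws of the damaged-over-baseline global efficiency ratio. Seeded and
#' reproducible.
#'
#' @param g A `functional_graph`.
#' @param k_max Maximum number of nodes removed (default 5).
#' @param replicates Number of random draws per `k` (default 1000).
#' @param seed Optional integer seed (the caller's RNG state is restored).
#' @return A data frame of class `resilience_profile` with columns `mode`,
#'   `k`, `relative_efficiency` (mean), `sd`, `replicates`.
#' @export
random_failure <- function(g, k_max = 5, replicates = 1000, seed = NULL) {
  stopifnot(inherits(g, "functional_graph"), replicates >= 1,
            k_max >= 0, k_max < length(g$nodes))
  e0 <- global_efficiency(g)
  if (e0 <= 0) stop("baseline global efficiency is zero: resilience undefined")
  n <- length(g$nodes)
  run <- function() {
    res <- lapply(0:k_max, function(k) {
      if (k == 0)
        return(data.frame(mode = "random", k = 0, relative_efficiency = 1,
                          sd = 0, replicates = as.integer(replicates)))
      r <- vapply(seq_len(replicates), function(i) {
        keep <- setdiff(seq_len(n), sample.int(n, k))
        subgraph_efficiency(g, keep) / e0
      }, numeric(1))
      data.frame(mode = "random", k = k, relative_efficiency = mean(r),
                 sd = stats::sd(r), replicates = as.integer(replicates))
    })
    do.call(rbind, res)
  }
  out <- if (is.null(seed)) run() else with_seed(seed, run())
  out$sd[is.na(out$sd)] <- 0
  class(out) <- c("resilience_profile", class(out))
  out
}

#' Hub concentration profile
#'
#' Node strengths are sorted in decreasing order (ties broken by node
#' order); the strength at each requested rank is divided by the total
#' strength of all nodes.
#'
#' @param g A `functional_graph`.
#' @param ranks Integer ranks to report (default the top 3 hubs).
#' @return Data frame with `rank`, `node`, `normalized_degree`.
#' @export
hub_normalized_degree <- function(g, ranks = 1:3) {
  stopifnot(inherits(g, "functional_graph"), all(ranks >= 1),
            all(ranks <= length(g$nodes)))
  s <- node_strength(g)
  ord <- order(-s, seq_along(s))
  total <- sum(s)
  data.frame(rank = ranks, node = g$nodes[ord[ranks]],
             normalized_degree = s[ord[ranks]] / total,
             row.names = NULL)
}
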