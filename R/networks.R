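#' Directed source network
#'
#' A small directed graph describing which source couples into which.  Edges
#' are ordered pairs `(source, target)` of 1-based node indices with no
#' self-loops.
#'
#' @param n_nodes number of nodes.
#' @param edges integer matrix with columns `source`, `target`.
#' @return An object of class `directed_network`.
#' @export
directed_network <- function(n_nodes, edges) {
  edges <- matrix(as.integer(edges), ncol = 2,
                  dimnames = list(NULL, c("source", "target")))
  stopifnot(n_nodes >= 1,
            all(edges >= 1L), all(edges <= n_nodes),
            all(edges[, 1] != edges[, 2]),
            nrow(edges) <= n_nodes * (n_nodes - 1))
  if (anyDuplicated(paste(edges[, 1], edges[, 2]))) {
    stop("duplicate edges in network")
  }
  structure(list(n_nodes = as.integer(n_nodes), edges = edges),
            class = "directed_network")
}

#' Adjacency matrix of a directed network
#'
#' Returns the binary adjacency in the flow convention used throughout the
#' package: `adj[i, j] = 1` means an edge from node `j` to node `i`.
#'
#' @param network a `directed_network`.
#' @return Integer `n_nodes` x `n_nodes` matrix with zero diagonal.
#' @export
network_adjacency <- function(network) {
  adj <- matrix(0L, network$n_nodes, network$n_nodes)
  if (nrow(network$edges) > 0) {
    adj[cbind(network$edges[, "target"], network$edges[, "source"])] <- 1L
  }
  adj
}

random_digraph <- function(n_nodes, n_edges) {
  slots <- which(diag(n_nodes) == 0)         # off-diagonal linear indices
  pick <- sample(slots, n_edges)
  target <- ((pick - 1L) %% n_nodes) + 1L    # row index = target
  source <- ((pick - 1L) %/% n_nodes) + 1L   # column index = source
  directed_network(n_nodes, cbind(source, target))
}

#' Generate a source network with low or high mean local efficiency
#'
#' Draws directed graphs with exactly `n_edges` edges uniformly at random and
#' keeps the first whose mean local efficiency falls on the requested side of
#' the median of a random-graph null with the same size parameters
#' (`low`: strictly below the null median; `high`: strictly above).  When the
#' null distribution is degenerate (every graph with these parameters has the
#' same efficiency, e.g. 2 nodes / 2 edges) any draw qualifies for either
#' class.  The realized efficiency and class band are stored as attributes.
#'
#' @param n_nodes,n_edges graph size; `n_edges <= n_nodes * (n_nodes - 1)`.
#' @param target_class `"low"` or `"high"`.
#' @param seed integer seed fixing all randomness.
#' @param n_null number of null draws used to locate the class boundary.
#' @param max_attempts rejection-sampling budget; exceeded only when the
#'   requested band is unreachable, which signals an inconsistent config.
#' @return A `directed_network` with attributes `mean_local_efficiency`,
#'   `class_band` (the realized `[lower, upper]` efficiency band of the
#'   class) and `null_median`.
#' @export
generate_source_network <- function(n_nodes, n_edges,
                                    target_class = c("low", "high"),
                                    seed,
                                    n_null = 200L,
                                    max_attempts = 5000L) {
  target_class <- match.arg(target_class)
  stopifnot(n_edges >= 0, n_edges <= n_nodes * (n_nodes - 1))
  withr::with_seed(seed, {
    null_eff <- vapply(seq_len(n_null), function(i) {
      mean(cpp_local_efficiency(network_adjacency(random_digraph(n_nodes, n_edges))))
    }, numeric(1))
    med <- stats::median(null_eff)
    degenerate <- max(null_eff) == min(null_eff)
    # when the median coincides with an extreme of the null (heavy ties,
    # e.g. mass at zero efficiency), the open half-line is empty; accept
    # the boundary value there so the classes stay ordered but reachable
    low_ok <- function(e) e < med || (med == min(null_eff) && e == med)
    high_ok <- function(e) e > med || (med == max(null_eff) && e == med)
    for (attempt in seq_len(max_attempts)) {
      net <- random_digraph(n_nodes, n_edges)
      eff <- mean(cpp_local_efficiency(network_adjacency(net)))
      ok <- degenerate ||
        (target_class == "low" && low_ok(eff)) ||
        (target_class == "high" && high_ok(eff))
      if (ok) {
        attr(net, "mean_local_efficiency") <- eff
        attr(net, "class_band") <- if (degenerate) c(eff, eff) else {
          if (target_class == "low") c(min(null_eff), med) else c(med, max(null_eff))
        }
        attr(net, "null_median") <- med
        attr(net, "target_class") <- target_class
        return(net)
      }
    }
    stop("could not reach the '", target_class, "' efficiency band in ",
         max_attempts, " attempts; config is inconsistent")
  })
}
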