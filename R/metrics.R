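#' Nodal clustering coefficient of a binary network
#'
#' The clustering coefficient of a region is the ratio of existing
#' connections to all possible connections among that region's neighbors:
#' `C_i = 2 t_i / (k_i (k_i - 1))`, where `t_i` counts edges among the
#' neighbors of `i`. Regions with fewer than two neighbors get `C_i = 0`.
#'
#' @param net A `cc_binary_network` (or 0/1 adjacency matrix).
#' @return Named numeric vector of clustering coefficients.
#' @export
clustering_coefficient <- function(net) {
  a <- as_adjacency(net)
  k <- rowSums(a)
  tri <- diag(a %*% a %*% a) / 2 # closed triangles through each node
  c_i <- ifelse(k < 2, 0, 2 * tri / (k * (k - 1)))
  setNames(as.numeric(c_i), rownames(a))
}

#' Unnormalized shortest-path betweenness centrality
#'
#' Number of shortest paths between other region pairs passing through each
#' region: `B_i = sum over unordered pairs (s, t) of sigma_st(i)/sigma_st`.
#' Pairs in different components contribute zero.
#'
#' @inheritParams clustering_coefficient
#' @return Named numeric vector of betweenness values.
#' @export
betweenness_centrality <- function(net) {
  a <- as_adjacency(net)
  g <- igraph::graph_from_adjacency_matrix(a, mode = "undirected")
  b <- igraph::betweenness(g, directed = FALSE, normalized = FALSE)
  setNames(as.numeric(b), rownames(a))
}

#' Detect network modules by greedy modularity maximization
#'
#' Partitions the network into non-overlapping modules by greedy
#' agglomerative maximization of the Newman modularity
#' `Q = sum_s (e_ss - a_s^2)`, where `e_ss` is the fraction of edges inside
#' module `s` and `a_s` the fraction of edge ends attached to it. The
#' algorithm is deterministic; `seed` is accepted for interface stability.
#'
#' @inheritParams clustering_coefficient
#' @param seed Ignored by the deterministic greedy algorithm; kept so all
#'   stochastic-looking stages share one calling convention.
#' @return Object of class `cc_partition`: list with `membership` (named
#'   integer vector), `modularity` (Q of the returned partition) and
#'   `n_modules`.
#' @export
detect_modules <- function(net, seed = NULL) {
  a <- as_adjacency(net)
  if (nrow(a) < 2) {
    abort("Module detection needs at least 2 regions.", class = "cc_graph_error")
  }
  g <- igraph::graph_from_adjacency_matrix(a, mode = "undirected")
  cl <- igraph::cluster_fast_greedy(g)
  memb <- igraph::membership(cl)
  structure(
    list(membership = setNames(as.integer(memb), rownames(a)),
         modularity = as.numeric(igraph::modularity(g, memb)),
         n_modules = length(unique(as.integer(memb)))),
    class = "cc_partition"
  )
}

#' @export
print.cc_partition <- function(x, ...) {
  cat(sprintf("<cc_partition> %d modules, Q = %.4f\n", x$n_modules,
              x$modularity))
  invisible(x)
}

#' Modularity Q of a given partition
#'
#' @inheritParams clustering_coefficient
#' @param membership Integer module labels, one per region.
#' @return Newman modularity of the partition.
#' @export
modularity_q <- function(net, membership) {
  a <- as_adjacency(net)
  g <- igraph::graph_from_adjacency_matrix(a, mode = "undirected")
  as.numeric(igraph::modularity(g, membership))
}

#' Participation coefficient of each region under a module partition
#'
#' `P_i = 1 - sum_s (k_is / k_i)^2`, where `k_is` counts edges from region
#' `i` into module `s`. Zero for isolated regions; zero when all neighbors
#' share the region's own module; bounded above by `1 - 1/M` for `M` modules.
#'
#' @inheritParams clustering_coefficient
#' @param partition A `cc_partition` or named/plain integer membership vector
#'   covering all regions.
#' @return Named numeric vector of participation coefficients.
#' @export
participation_coefficient <- function(net, partition) {
  a <- as_adjacency(net)
  memb <- if (inherits(partition, "cc_partition")) partition$membership
          else partition
  if (length(memb) != nrow(a)) {
    abort("Partition must cover all regions.", class = "cc_graph_error")
  }
  k <- rowSums(a)
  mods <- sort(unique(as.integer(memb)))
  # k_is: edges from i into each module
  kis <- vapply(mods, function(s) rowSums(a[, memb == s, drop = FALSE]),
                numeric(nrow(a)))
  p <- 1 - rowSums((kis / pmax(k, 1))^2)
  p[k == 0] <- 0
  setNames(as.numeric(p), rownames(a))
}

#' Per-region nodal metric table for one binary network
#'
#' Computes degree, clustering coefficient, betweenness centrality, module
#' membership and participation coefficient for every region.
#'
#' @inheritParams clustering_coefficient
#' @param partition Optional precomputed `cc_partition`; detected with
#'   [detect_modules()] when absent.
#' @return Tibble with columns `region`, `degree`, `clustering`,
#'   `betweenness`, `module`, `participation`.
#' @export
node_metrics <- function(net, partition = NULL) {
  a <- as_adjacency(net)
  partition <- partition %||% detect_modules(net)
  tibble(
    region = rownames(a),
    degree = as.numeric(rowSums(a)),
    clustering = unname(clustering_coefficient(a)),
    betweenness = unname(betweenness_centrality(a)),
    module = unname(partition$membership[rownames(a)]),
    participation = unname(participation_coefficient(a, partition))
  )
}

#' Group-averaged nodal metrics with a group-level module partition
#'
#' Per-subject degree, clustering and betweenness are averaged across
#' subjects (so averaged degrees are generally non-integer); the module
#' partition and participation coefficients are computed once on the
#' group-mean network, obtained by binarizing the mean adjacency matrix to
#' its minimum connection density.
#'
#' @param nets Named list of `cc_binary_network` objects sharing region labels.
#' @return List with `metrics` (tibble as [node_metrics()]), `partition`
#'   (`cc_partition` of the group-mean network) and `mean_network`.
#' @export
group_mean_metrics <- function(nets) {
  if (length(nets) == 0) abort("`nets` is empty.", class = "cc_config_error")
  labs <- nets[[1]]$region_labels
  per <- map(nets, function(nw) {
    a <- as_adjacency(nw)
    cbind(degree = rowSums(a),
          clustering = unname(clustering_coefficient(a)),
          betweenness = unname(betweenness_centrality(a)))
  })
  avg <- Reduce(`+`, per) / length(per)
  mean_adj <- Reduce(`+`, map(nets, as_adjacency)) / length(nets)
  mean_net <- binarize_min_density(mean_adj)
  part <- detect_modules(mean_net)
  metrics <- tibble(
    region = labs,
    degree = unname(avg[, "degree"]),
    clustering = unname(avg[, "clustering"]),
    betweenness = unname(avg[, "betweenness"]),
    module = unname(part$membership[labs]),
    participation = unname(participation_coefficient(mean_net, part))
  )
  list(metrics = metrics, partition = part, mean_network = mean_net)
}

as_adjacency <- function(net) {
  a <- if (inherits(net, "cc_binary_network")) net$adjacency else net
  if (!is.matrix(a) || nrow(a) != ncol(a)) {
    abort("Expected a square adjacency matrix or cc_binary_network.",
          class = "cc_graph_error")
  }
  if (!all(a %in% c(0, 1))) {
    abort("Adjacency must be binary.", class = "cc_graph_error")
  }
  diag(a) <- 0
  if (is.null(rownames(a))) {
    rownames(a) <- colnames(a) <- paste0("R", seq_len(nrow(a)))
  }
  storage.mode(a) <- "double"
  a
}
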