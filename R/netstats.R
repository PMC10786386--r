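#' Node centrality on the clinical interaction network
#'
#' Degree centrality of node i is its number of edges, the i-th row sum of
#' the adjacency matrix. Closeness centrality is (n - 1) divided by the sum
#' of shortest-path distances from i to all other nodes; on disconnected
#' graphs the Wasserman-Faust scaling is applied (within-component closeness
#' multiplied by the fraction of other nodes reachable), which keeps values
#' finite and comparable after node removal; an isolated node has closeness
#' 0 by convention. Betweenness centrality of i sums, over unordered pairs
#' {j, k} not containing i, the fraction of shortest j-k paths passing
#' through i (counted exactly, Brandes-style), normalized by
#' (n - 1)(n - 2) / 2 so values lie in [0, 1]; with fewer than three nodes
#' all betweenness values are 0.
#'
#' @param net An undirected igraph network.
#' @return [degree_centrality()], [closeness_centrality()] and
#'   [betweenness_centrality()] return named numeric vectors;
#'   [node_centrality()] returns a data frame with columns `node`, `degree`,
#'   `closeness`, `betweenness`.
#' @examples
#' g <- igraph::make_graph(~ a - b, b - c) # path a-b-c
#' closeness_centrality(g)                 # b = 1, endpoints = 2/3
#' betweenness_centrality(g)               # b = 1, endpoints = 0
#' @export
degree_centrality <- function(net) {
  igraph::degree(net)
}

#' @rdname degree_centrality
#' @export
closeness_centrality <- function(net) {
  n <- igraph::vcount(net)
  if (n == 0) return(setNames(numeric(0), character(0)))
  if (n == 1) return(setNames(0, igraph::V(net)$name))
  d <- igraph::distances(net)
  vapply(seq_len(n), function(i) {
    di <- d[i, -i]
    reach <- is.finite(di)
    r <- sum(reach)
    if (r == 0) return(0)
    (r / (n - 1)) * (r / sum(di[reach]))
  }, numeric(1)) -> cl
  setNames(cl, rownames(d))
}

#' @rdname degree_centrality
#' @export
betweenness_centrality <- function(net) {
  n <- igraph::vcount(net)
  if (n < 3) {
    return(setNames(rep(0, n), igraph::V(net)$name))
  }
  igraph::betweenness(net, directed = FALSE, normalized = TRUE)
}

#' @rdname degree_centrality
#' @export
node_centrality <- function(net) {
  data.frame(
    node = igraph::V(net)$name,
    degree = unname(degree_centrality(net)),
    closeness = unname(closeness_centrality(net)),
    betweenness = unname(betweenness_centrality(net)),
    stringsAsFactors = FALSE
  )
}

#' Global efficiency
#'
#' The mean inverse shortest-path length over all ordered node pairs,
#' `g = 1/(n(n-1)) * sum_{i != j} 1/d_ij`, with unreachable pairs
#' contributing 0. Equals 1 on a complete graph and 0 on an edgeless one; a
#' proxy for how efficiently information propagates on the network.
#'
#' @param net An undirected igraph network with at least two nodes.
#' @return A scalar in [0, 1].
#' @export
global_efficiency <- function(net) {
  n <- igraph::vcount(net)
  if (n < 2) stop("global efficiency is undefined for fewer than 2 nodes")
  d <- igraph::distances(net)
  inv <- 1 / d
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

#' Greedy modularity communities
#'
#' Agglomerative (Clauset-Newman-Moore style) modularity maximization:
#' starting from singleton communities, repeatedly merge the pair of
#' connected communities with the largest modularity gain until no merge
#' increases modularity. The algorithm is deterministic: when two merges tie
#' on the gain, the lexicographically smallest community pair is merged
#' (communities are labelled by their alphabetically smallest member).
#' Disconnected components are never merged.
#'
#' @param net An undirected igraph network.
#' @return An object of class `community_partition`: a list with
#'   `membership` (named integer vector), `modularity` and `n_communities`.
#' @export
detect_communities <- function(net) {
  nodes <- igraph::V(net)$name
  n <- length(nodes)
  m <- igraph::ecount(net)
  if (n == 0 || m == 0) {
    membership <- setNames(seq_len(n), nodes)
    return(structure(list(membership = membership, modularity = 0,
                          n_communities = n),
                     class = "community_partition"))
  }
  A <- as.matrix(igraph::as_adjacency_matrix(net))
  deg <- rowSums(A)
  # community state: E[c1,c2] edge counts, a[c] degree sums, label = smallest member
  comm <- as.list(seq_len(n))
  E <- A                 # E[i,j] = edges between singleton communities
  a <- deg
  intra <- rep(0, n)
  active <- rep(TRUE, n)
  label <- nodes
  tol <- 1e-12
  repeat {
    best <- NULL
    best_dq <- -Inf
    act <- which(active)
    if (length(act) < 2) break
    for (ii in seq_along(act)) {
      for (jj in seq_len(ii - 1L)) {
        c1 <- act[jj]; c2 <- act[ii]
        if (E[c1, c2] == 0) next
        dq <- E[c1, c2] / m - 2 * (a[c1] / (2 * m)) * (a[c2] / (2 * m))
        pair <- sort(c(label[c1], label[c2]))
        take <- dq > best_dq + tol ||
          (!is.null(best) && abs(dq - best_dq) <= tol &&
           (pair[1] < best$pair[1] ||
            (pair[1] == best$pair[1] && pair[2] < best$pair[2])))
        if (is.null(best) || take) {
          best <- list(c1 = c1, c2 = c2, pair = pair)
          best_dq <- max(best_dq, dq)
        }
      }
    }
    if (is.null(best) || best_dq <= tol) break
    c1 <- best$c1; c2 <- best$c2
    comm[[c1]] <- c(comm[[c1]], comm[[c2]])
    intra[c1] <- intra[c1] + intra[c2] + E[c1, c2]
    a[c1] <- a[c1] + a[c2]
    E[c1, ] <- E[c1, ] + E[c2, ]
    E[, c1] <- E[, c1] + E[, c2]
    E[c1, c1] <- 0
    active[c2] <- FALSE
    label[c1] <- min(label[c1], label[c2])
  }
  act <- which(active)
  membership <- integer(n)
  # order communities by label for stable ids
  act <- act[order(label[act])]
  for (k in seq_along(act)) membership[comm[[act[k]]]] <- k
  membership <- setNames(membership, nodes)
  q <- sum(vapply(act, function(c1) {
    intra[c1] / m - (a[c1] / (2 * m))^2
  }, numeric(1)))
  structure(list(membership = membership, modularity = q,
                 n_communities = length(act)),
            class = "community_partition")
}

#' @export
print.community_partition <- function(x, ...) {
  cat("Community partition:", x$n_communities, "communities, modularity",
      sprintf("%.4f", x$modularity), "\n")
  for (k in seq_len(x$n_communities)) {
    cat(sprintf("  [%d] %s\n", k,
                paste(names(x$membership)[x$membership == k], collapse = ", ")))
  }
  invisible(x)
}
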