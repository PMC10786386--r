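# --- internal state helpers -------------------------------------------------

# Dense-matrix view of an igraph network for the swap machinery.
net_state <- function(net, forbidden = NULL) {
  nodes <- igraph::V(net)$name
  if (is.null(nodes)) nodes <- as.character(seq_len(igraph::vcount(net)))
  adj <- as.matrix(igraph::as_adjacency_matrix(net))
  storage.mode(adj) <- "integer"
  dimnames(adj) <- list(nodes, nodes)
  edges <- igraph::as_edgelist(net, names = FALSE)
  storage.mode(edges) <- "integer"
  if (is.null(forbidden)) forbidden <- derive_forbidden(net)
  stopifnot(identical(dim(forbidden), dim(adj)))
  list(adj = adj, edges = edges, forbidden = forbidden, nodes = nodes)
}

# Forbidden-edge matrix from the vertex attributes that
# build_interaction_network() stores; all-FALSE when attributes are absent.
derive_forbidden <- function(net) {
  n <- igraph::vcount(net)
  nodes <- igraph::V(net)$name
  attrs <- igraph::vertex_attr_names(net)
  needed <- c("category", "team", "role", "psychiatry_restricted")
  if (!all(needed %in% attrs)) {
    return(matrix(FALSE, n, n, dimnames = list(nodes, nodes)))
  }
  cat_df <- validate_catalog(data.frame(
    name = nodes,
    category = igraph::V(net)$category,
    team = igraph::V(net)$team,
    role = igraph::V(net)$role,
    psychiatry_restricted = igraph::V(net)$psychiatry_restricted,
    stringsAsFactors = FALSE
  ))
  forbidden_matrix(nodes, cat_df)
}

state_to_graph <- function(state, template) {
  g <- igraph::graph_from_adjacency_matrix(state$adj, mode = "undirected")
  for (at in igraph::vertex_attr_names(template)) {
    if (at == "name") next
    g <- igraph::set_vertex_attr(g, at, value = igraph::vertex_attr(template, at))
  }
  g
}

r_connected <- function(adj) {
  n <- nrow(adj)
  seen <- logical(n)
  stack <- 1L
  seen[1L] <- TRUE
  while (length(stack) > 0) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    nb <- which(adj[v, ] == 1L & !seen)
    seen[nb] <- TRUE
    stack <- c(stack, nb)
  }
  all(seen)
}

# Pure-R reference for the constrained connected double-edge swap; consumes
# 4 uniform draws per attempt in the same order as the compiled path.
r_shuffle <- function(adj, edges, forbidden, attempts) {
  m <- nrow(edges)
  succ <- 0L
  for (t in seq_len(attempts)) {
    u4 <- runif(4)
    e1 <- min(floor(u4[1] * m) + 1L, m)
    e2 <- min(floor(u4[2] * m) + 1L, m)
    f1 <- u4[3] < 0.5
    f2 <- u4[4] < 0.5
    if (e1 == e2) next
    i <- edges[e1, if (f1) 2L else 1L]; j <- edges[e1, if (f1) 1L else 2L]
    v <- edges[e2, if (f2) 2L else 1L]; u <- edges[e2, if (f2) 1L else 2L]
    if (i == v || j == u) next
    if (adj[i, v] == 1L || adj[j, u] == 1L) next
    if (forbidden[i, v] || forbidden[j, u]) next
    adj[i, j] <- adj[j, i] <- 0L
    adj[v, u] <- adj[u, v] <- 0L
    adj[i, v] <- adj[v, i] <- 1L
    adj[j, u] <- adj[u, j] <- 1L
    if (r_connected(adj)) {
      edges[e1, ] <- c(i, v)
      edges[e2, ] <- c(j, u)
      succ <- succ + 1L
    } else {
      adj[i, v] <- adj[v, i] <- 0L
      adj[j, u] <- adj[u, j] <- 0L
      adj[i, j] <- adj[j, i] <- 1L
      adj[v, u] <- adj[u, v] <- 1L
    }
  }
  list(adjacency = adj, edges = edges, n_success = succ)
}

# --- exported operations ----------------------------------------------------

#' Constrained connected double-edge swap
#'
#' One randomization move of the degree-preserving null model: two connected
#' node pairs (i, j) and (v, u) are drawn uniformly at random and the edges
#' are rewired to (i, v) and (j, u). The swap is applied only if both
#' proposed edges are absent from the network, neither is forbidden under
#' the operational policy, no self-loop or duplicate edge arises, and the
#' network remains connected; otherwise the network is returned unchanged
#' with `success = FALSE`. Failed attempts are normal and are counted as
#' attempts by [shuffle_network()]. Randomness comes from R's global RNG
#' (use `set.seed()` for reproducibility).
#'
#' @param net A connected undirected igraph network.
#' @param forbidden Optional logical matrix of forbidden node pairs; by
#'   default derived from the network's catalog vertex attributes (all
#'   allowed when the attributes are absent).
#' @return A list with elements `net` (the possibly rewired network) and
#'   `success` (logical).
#' @export
attempt_constrained_swap <- function(net, forbidden = NULL) {
  state <- net_state(net, forbidden)
  res <- r_shuffle(state$adj, state$edges, state$forbidden, 1L)
  out_state <- list(adj = res$adjacency)
  list(net = state_to_graph(out_state, net), success = res$n_success > 0)
}

#' Randomly shuffle a network by constrained double-edge swaps
#'
#' Applies [attempt_constrained_swap()] moves sequentially for a fixed
#' number of attempts (successful or not), preserving every node's degree,
#' connectivity, and the forbidden-edge policy. The default engine is
#' compiled; `compiled = FALSE` runs a pure-R reference that consumes the
#' identical RNG stream and produces bit-identical results.
#'
#' @inheritParams attempt_constrained_swap
#' @param attempts Number of swap attempts (default 20000).
#' @param compiled Use the compiled swap loop (default `TRUE`).
#' @return A list with elements `net` (the shuffled network) and
#'   `n_success` (number of successful swaps).
#' @export
shuffle_network <- function(net, attempts = 20000, forbidden = NULL,
                            compiled = TRUE) {
  stopifnot(igraph::is_connected(net))
  state <- net_state(net, forbidden)
  if (attempts == 0) {
    return(list(net = net, n_success = 0L))
  }
  res <- if (compiled) {
    cpp_shuffle(state$adj, state$edges, state$forbidden, as.integer(attempts))
  } else {
    r_shuffle(state$adj, state$edges, state$forbidden, as.integer(attempts))
  }
  dimnames(res$adjacency) <- dimnames(state$adj)
  list(net = state_to_graph(list(adj = res$adjacency), net),
       n_success = as.integer(res$n_success))
}

#' Ensemble of shuffled networks
#'
#' Generates `n_shuffles` independent shuffles of the network, each from
#' `attempts` constrained connected double-edge swap attempts. One master
#' seed generates a per-shuffle child seed via `sample.int()`, so the
#' ensemble is reproducible bit for bit and individual members can be
#' regenerated independently. Normalized betweenness centrality of every
#' node is recorded per shuffle.
#'
#' @inheritParams shuffle_network
#' @param n_shuffles Number of shuffled networks (default 1000).
#' @param seed Master RNG seed for the ensemble.
#' @param keep_networks Also return the shuffled igraph objects.
#' @return An object of class `shuffle_ensemble`: a list with `betweenness`
#'   (nodes x shuffles matrix), `n_success` (per-shuffle successful swap
#'   counts), `seeds`, `attempts`, `observed` (betweenness of the input
#'   network) and optionally `networks`.
#' @export
shuffle_ensemble <- function(net, n_shuffles = 1000, attempts = 20000,
                             seed = 1, forbidden = NULL,
                             keep_networks = FALSE, compiled = TRUE) {
  stopifnot(igraph::is_connected(net))
  set.seed(seed)
  child_seeds <- sample.int(2147483646L, n_shuffles)
  nodes <- igraph::V(net)$name
  bet <- matrix(NA_real_, length(nodes), n_shuffles,
                dimnames = list(nodes, NULL))
  n_success <- integer(n_shuffles)
  networks <- if (keep_networks) vector("list", n_shuffles) else NULL
  state <- net_state(net, forbidden)
  for (k in seq_len(n_shuffles)) {
    set.seed(child_seeds[k])
    res <- if (compiled) {
      cpp_shuffle(state$adj, state$edges, state$forbidden,
                  as.integer(attempts))
    } else {
      r_shuffle(state$adj, state$edges, state$forbidden, as.integer(attempts))
    }
    dimnames(res$adjacency) <- dimnames(state$adj)
    g <- igraph::graph_from_adjacency_matrix(res$adjacency,
                                             mode = "undirected")
    bet[, k] <- betweenness_centrality(g)[nodes]
    n_success[k] <- res$n_success
    if (keep_networks) networks[[k]] <- state_to_graph(list(adj = res$adjacency), net)
  }
  structure(list(betweenness = bet, n_success = n_success,
                 seeds = child_seeds, attempts = attempts,
                 observed = betweenness_centrality(net)[nodes],
                 networks = networks),
            class = "shuffle_ensemble")
}

#' @export
print.shuffle_ensemble <- function(x, ...) {
  cat("Shuffle ensemble:", ncol(x$betweenness), "networks,",
      x$attempts, "attempts each\n")
  cat(sprintf("  successful swaps per shuffle: mean %.0f (range %d-%d)\n",
              mean(x$n_success), min(x$n_success), max(x$n_success)))
  invisible(x)
}

#' Percentile significance of a node's betweenness
#'
#' Locates the observed betweenness centrality of a node within the null
#' distribution of that same node's betweenness over a shuffled ensemble.
#' The percentile uses midpoint (average-rank) handling of exact ties to
#' avoid flag flips from floating-point equality; the node is flagged when
#' the percentile exceeds 95.
#'
#' @param net The observed network the ensemble was generated from.
#' @param node A node name present in `net`.
#' @param ensemble A [shuffle_ensemble()].
#' @return An object of class `percentile_test`: a list with `node`,
#'   `observed`, `percentile` and `flagged`.
#' @export
betweenness_percentile_test <- function(net, node, ensemble) {
  stopifnot(inherits(ensemble, "shuffle_ensemble"))
  if (!node %in% rownames(ensemble$betweenness)) {
    stop("node not in ensemble: ", node)
  }
  observed <- betweenness_centrality(net)[[node]]
  null_dist <- ensemble$betweenness[node, ]
  pct <- 100 * (sum(null_dist < observed) + 0.5 * sum(null_dist == observed)) /
    length(null_dist)
  structure(list(node = node, observed = observed, percentile = pct,
                 flagged = pct > 95),
            class = "percentile_test")
}

#' @export
print.percentile_test <- function(x, ...) {
  cat(sprintf("Betweenness of %s: %.4f at percentile %.1f of the null (%s)\n",
              x$node, x$observed, x$percentile,
              if (x$flagged) "flagged, > 95th" else "not flagged"))
  invisible(x)
}

#' Impact of removing a node
#'
#' Recomputes global efficiency and per-doctor closeness centrality after
#' deleting one node. The efficiency change is reported as a percentage of
#' the pre-removal value; closeness uses the Wasserman-Faust convention so
#' values stay finite if the removal disconnects the network.
#'
#' @param net An undirected igraph network with at least 3 nodes.
#' @param node Name of the node to remove.
#' @return An object of class `removal_impact`: a list with `node`,
#'   `g_before`, `g_after`, `delta_g_pct` and `doctor_closeness` (a data
#'   frame with closeness before/after and the change, for every node with
#'   role `doctor`).
#' @export
node_removal_impact <- function(net, node) {
  stopifnot(node %in% igraph::V(net)$name, igraph::vcount(net) >= 3)
  g_before <- global_efficiency(net)
  cl_before <- closeness_centrality(net)
  reduced <- igraph::delete_vertices(net, node)
  g_after <- global_efficiency(reduced)
  cl_after <- closeness_centrality(reduced)
  doctors <- character(0)
  if ("role" %in% igraph::vertex_attr_names(net)) {
    doctors <- igraph::V(net)$name[igraph::V(net)$role == "doctor"]
    doctors <- setdiff(doctors, node)
  }
  doctor_closeness <- data.frame(
    node = doctors,
    before = unname(cl_before[doctors]),
    after = unname(cl_after[doctors]),
    delta = unname(cl_after[doctors] - cl_before[doctors]),
    stringsAsFactors = FALSE
  )
  structure(list(node = node, g_before = g_before, g_after = g_after,
                 delta_g_pct = 100 * (g_after - g_before) / g_before,
                 doctor_closeness = doctor_closeness),
            class = "removal_impact")
}

#' @export
print.removal_impact <- function(x, ...) {
  cat(sprintf("Removal of %s: global efficiency %.4f -> %.4f (%+.2f%%)\n",
              x$node, x$g_before, x$g_after, x$delta_g_pct))
  if (nrow(x$doctor_closeness) > 0) {
    cat("  closeness change for doctors:\n")
    print(x$doctor_closeness, row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' Default candidate edges for restoration
#'
#' All absent doctor-doctor pairs with one endpoint in the Emergency
#' Medical team and the other in the Emergency Psychiatry team, evaluated
#' on the network after removal of `removed`. Doctor-doctor edges are never
#' forbidden under the policy.
#'
#' @param net The original network (with catalog vertex attributes).
#' @param removed Name of the node whose removal is being mitigated.
#' @return A two-column character matrix of candidate edges.
#' @export
default_restoration_candidates <- function(net, removed) {
  stopifnot(all(c("role", "team") %in% igraph::vertex_attr_names(net)))
  v <- igraph::V(net)
  em <- v$name[v$role == "doctor" & v$team == "emergency_medical"]
  ep <- v$name[v$role == "doctor" & v$team == "emergency_psychiatry"]
  em <- setdiff(em, removed)
  ep <- setdiff(ep, removed)
  pairs <- expand.grid(from = em, to = ep, stringsAsFactors = FALSE)
  reduced <- igraph::delete_vertices(net, removed)
  keep <- !apply(pairs, 1, function(p) {
    igraph::are_adjacent(reduced, p[1], p[2])
  })
  as.matrix(pairs[keep, , drop = FALSE])
}

edge_label <- function(a, b) paste(sort(c(a, b)), collapse = "|")

#' Greedy edge restoration after node removal
#'
#' Removes a compromised node, then adds candidate edges one at a time,
#' each time choosing the edge that maximizes the increase in global
#' efficiency, until all candidates are added. When several candidates tie
#' on the gain the greedy rule no longer determines a unique sequence, so
#' all greedy-optimal orderings are enumerated (equivalently: every
#' permutation of the remaining candidates that is step-wise optimal) and
#' the tied candidates are reported as tie groups. The canonical sequence
#' breaks ties alphabetically.
#'
#' @param net An undirected igraph network.
#' @param removed Node to remove before restoring.
#' @param candidates Two-column matrix of candidate edges, absent from the
#'   post-removal network and not forbidden; defaults to
#'   [default_restoration_candidates()].
#' @param max_sequences Cap on explicitly enumerated optimal sequences.
#' @return An object of class `restoration_trace`: list with `removed`,
#'   `candidates` (labels), `sequence` (canonical order of addition),
#'   `g_trace` (efficiency after removal and after each addition),
#'   `g_before_removal`, `sequences` (all optimal orderings, up to the
#'   cap), `n_optimal_sequences` and `tie_groups`.
#' @export
greedy_edge_restoration <- function(net, removed, candidates = NULL,
                                    max_sequences = 1000) {
  if (is.null(candidates)) {
    candidates <- default_restoration_candidates(net, removed)
  }
  candidates <- as.matrix(candidates)
  stopifnot(ncol(candidates) == 2)
  g_before_removal <- global_efficiency(net)
  reduced <- igraph::delete_vertices(net, removed)
  forb <- derive_forbidden(reduced)
  nodes <- igraph::V(reduced)$name
  nc <- nrow(candidates)
  labels <- apply(candidates, 1, function(p) edge_label(p[1], p[2]))
  if (anyDuplicated(labels)) stop("duplicate candidate edges")
  idx <- cbind(match(candidates[, 1], nodes), match(candidates[, 2], nodes))
  if (anyNA(idx)) stop("candidate endpoint not in the post-removal network")
  base_adj <- as.matrix(igraph::as_adjacency_matrix(reduced))
  for (k in seq_len(nc)) {
    if (base_adj[idx[k, 1], idx[k, 2]] == 1) {
      stop("candidate edge already present: ", labels[k])
    }
    if (forb[idx[k, 1], idx[k, 2]]) {
      stop("candidate edge is forbidden: ", labels[k])
    }
  }
  n <- nrow(base_adj)

  g_memo <- new.env(parent = emptyenv())
  g_of <- function(mask) {
    key <- as.character(mask)
    if (!is.null(g_memo[[key]])) return(g_memo[[key]])
    adj <- base_adj
    for (k in seq_len(nc)) {
      if (bitwAnd(mask, bitwShiftL(1L, k - 1L)) != 0L) {
        adj[idx[k, 1], idx[k, 2]] <- adj[idx[k, 2], idx[k, 1]] <- 1
      }
    }
    g <- global_efficiency(igraph::graph_from_adjacency_matrix(
      adj, mode = "undirected"))
    g_memo[[key]] <- g
    g
  }

  tol <- 1e-12
  argmax_of <- function(mask) {
    remaining <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(nc) - 1L)) == 0L)
    if (length(remaining) == 0) return(integer(0))
    gains <- vapply(remaining, function(k) {
      g_of(bitwOr(mask, bitwShiftL(1L, k - 1L))) - g_of(mask)
    }, numeric(1))
    remaining[gains >= max(gains) - tol]
  }

  # canonical (alphabetical tie-break) sequence and trace
  mask <- 0L
  sequence <- character(0)
  g_trace <- g_of(0L)
  tie_groups <- list()
  for (step in seq_len(nc)) {
    am <- argmax_of(mask)
    if (length(am) > 1) tie_groups[[length(tie_groups) + 1]] <- labels[am]
    pick <- am[order(labels[am])][1]
    sequence <- c(sequence, labels[pick])
    mask <- bitwOr(mask, bitwShiftL(1L, pick - 1L))
    g_trace <- c(g_trace, g_of(mask))
  }

  # enumerate all greedy-optimal orderings (DFS over the argmax DAG)
  sequences <- list()
  n_optimal <- 0
  dfs <- function(mask, prefix) {
    if (length(prefix) == nc) {
      n_optimal <<- n_optimal + 1
      if (length(sequences) < max_sequences) {
        sequences[[length(sequences) + 1]] <<- labels[prefix]
      }
      return(invisible())
    }
    for (k in argmax_of(mask)) {
      dfs(bitwOr(mask, bitwShiftL(1L, k - 1L)), c(prefix, k))
    }
  }
  dfs(0L, integer(0))

  structure(list(removed = removed, candidates = labels,
                 sequence = sequence, g_trace = g_trace,
                 g_before_removal = g_before_removal,
                 sequences = sequences, n_optimal_sequences = n_optimal,
                 tie_groups = tie_groups),
            class = "restoration_trace")
}

#' @export
print.restoration_trace <- function(x, ...) {
  cat("Greedy edge restoration after removing", x$removed, "\n")
  cat(sprintf("  efficiency before removal %.4f, after removal %.4f\n",
              x$g_before_removal, x$g_trace[1]))
  for (i in seq_along(x$sequence)) {
    cat(sprintf("  + %-35s g = %.4f\n", x$sequence[i], x$g_trace[i + 1]))
  }
  if (length(x$tie_groups) > 0) {
    cat("  tie groups:",
        paste(vapply(x$tie_groups, paste, "", collapse = " ~ "),
              collapse = "; "), "\n")
    cat("  optimal sequences:", x$n_optimal_sequences, "\n")
  }
  invisible(x)
}
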