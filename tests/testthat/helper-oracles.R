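# Brute-force oracles, independent of the package implementation: BFS
# distances, explicit enumeration of all shortest paths for betweenness,
# and exhaustive set-partition search for modularity.

bf_adj <- function(g) {
  a <- as.matrix(igraph::as_adjacency_matrix(g))
  storage.mode(a) <- "integer"
  a
}

bf_distances <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  for (s in seq_len(n)) {
    frontier <- s
    dist <- 0
    while (length(frontier) > 0) {
      dist <- dist + 1
      nxt <- integer(0)
      for (v in frontier) {
        for (w in which(adj[v, ] == 1L)) {
          if (d[s, w] > dist) {
            d[s, w] <- dist
            nxt <- c(nxt, w)
          }
        }
      }
      frontier <- unique(nxt)
    }
  }
  d
}

# all shortest paths from j to k as a list of vertex index sequences
bf_shortest_paths <- function(adj, d, j, k) {
  if (!is.finite(d[j, k])) return(list())
  if (j == k) return(list(j))
  out <- list()
  for (w in which(adj[j, ] == 1L)) {
    if (d[w, k] == d[j, k] - 1) {
      for (tail in bf_shortest_paths(adj, d, w, k)) {
        out[[length(out) + 1]] <- c(j, tail)
      }
    }
  }
  out
}

bf_betweenness <- function(g) {
  adj <- bf_adj(g)
  n <- nrow(adj)
  if (n < 3) return(setNames(rep(0, n), igraph::V(g)$name))
  d <- bf_distances(adj)
  b <- numeric(n)
  for (j in seq_len(n - 1)) {
    for (k in (j + 1):n) {
      paths <- bf_shortest_paths(adj, d, j, k)
      sigma <- length(paths)
      if (sigma == 0) next
      interior <- unlist(lapply(paths, function(p) p[-c(1, length(p))]))
      if (length(interior) == 0) next
      counts <- table(interior)
      idx <- as.integer(names(counts))
      b[idx] <- b[idx] + as.numeric(counts) / sigma
    }
  }
  setNames(b / ((n - 1) * (n - 2) / 2), igraph::V(g)$name)
}

bf_closeness <- function(g) {
  adj <- bf_adj(g)
  n <- nrow(adj)
  d <- bf_distances(adj)
  setNames(vapply(seq_len(n), function(i) {
    di <- d[i, -i]
    r <- sum(is.finite(di))
    if (r == 0) return(0)
    (r / (n - 1)) * (r / sum(di[is.finite(di)]))
  }, numeric(1)), igraph::V(g)$name)
}

bf_efficiency <- function(g) {
  adj <- bf_adj(g)
  n <- nrow(adj)
  d <- bf_distances(adj)
  inv <- 1 / d
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

# all set partitions of 1..n via restricted growth strings
all_partitions <- function(n) {
  out <- list()
  grow <- function(rgs, maxv) {
    if (length(rgs) == n) {
      out[[length(out) + 1]] <<- rgs
      return(invisible())
    }
    for (v in seq_len(maxv + 1)) {
      grow(c(rgs, v), max(maxv, v))
    }
  }
  grow(1L, 1L)
  out
}

bf_best_modularity <- function(g) {
  n <- igraph::vcount(g)
  best_q <- -Inf
  best <- NULL
  for (p in all_partitions(n)) {
    q <- igraph::modularity(g, p)
    if (q > best_q) {
      best_q <- q
      best <- p
    }
  }
  list(membership = best, modularity = best_q)
}

# brute-force naive Bayes posterior by explicit products
bf_nb_posterior <- function(x_train, y_train, x_new, alpha = 1) {
  n1 <- sum(y_train == 1)
  n0 <- sum(y_train == 0)
  p1 <- (colSums(x_train[y_train == 1, , drop = FALSE]) + alpha) / (n1 + 2 * alpha)
  p0 <- (colSums(x_train[y_train == 0, , drop = FALSE]) + alpha) / (n0 + 2 * alpha)
  prior1 <- n1 / length(y_train)
  prior0 <- n0 / length(y_train)
  t(apply(x_new, 1, function(row) {
    l1 <- prior1 * prod(p1^row * (1 - p1)^(1 - row))
    l0 <- prior0 * prod(p0^row * (1 - p0)^(1 - row))
    c(`0` = l0 / (l0 + l1), `1` = l1 / (l0 + l1))
  }))
}
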