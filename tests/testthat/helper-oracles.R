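# Independent brute-force oracles used across the suite.

# --- optimal 1-D classification by exhaustive search -------------------------
# all contiguous partitions of the sorted values into k classes; returns the
# minimal total within-class sum of squared deviations and the class sizes
brute_partition <- function(values, k) {
  x <- sort(values)
  n <- length(x)
  sse <- function(v) sum((v - mean(v))^2)
  best <- list(loss = Inf, sizes = NULL)
  # compositions of n into k positive parts
  rec <- function(start, parts_left, sizes, loss) {
    if (loss >= best$loss) return()
    if (parts_left == 1) {
      l <- loss + sse(x[start:n])
      if (l < best$loss) best <<- list(loss = l, sizes = c(sizes, n - start + 1))
      return()
    }
    for (end in start:(n - parts_left + 1)) {
      rec(end + 1, parts_left - 1, c(sizes, end - start + 1),
          loss + sse(x[start:end]))
    }
  }
  rec(1, k, integer(0), 0)
  best
}

# --- betweenness by explicit shortest-path enumeration -----------------------
# adj: logical adjacency matrix of a directed graph (no self loops)
brute_betweenness <- function(adj) {
  n <- nrow(adj)
  dist <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    d <- rep(Inf, n); d[s] <- 0; q <- s
    while (length(q)) {
      v <- q[1]; q <- q[-1]
      for (w in which(adj[v, ])) {
        if (!is.finite(d[w])) { d[w] <- d[v] + 1; q <- c(q, w) }
      }
    }
    dist[s, ] <- d
  }
  bet <- numeric(n)
  for (s in seq_len(n)) for (t in seq_len(n)) {
    if (s == t || !is.finite(dist[s, t]) || dist[s, t] < 2) next
    # enumerate every shortest s->t path along the BFS DAG
    paths <- list()
    rec <- function(v, acc) {
      if (v == t) { paths[[length(paths) + 1]] <<- acc; return() }
      for (w in which(adj[v, ])) {
        if (is.finite(dist[w, t]) && dist[w, t] == dist[s, t] - dist[s, v] - 1) {
          rec(w, c(acc, w))
        }
      }
    }
    rec(s, integer(0))
    for (p in paths) {
      interior <- p[-length(p)]
      bet[interior] <- bet[interior] + 1 / length(paths)
    }
  }
  bet
}

random_digraph <- function(n, p = 0.35) {
  adj <- matrix(runif(n * n) < p, n, n)
  diag(adj) <- FALSE
  adj
}

graph_from_adj <- function(adj, weights = NULL) {
  idx <- which(adj, arr.ind = TRUE)
  nm <- paste0("a", seq_len(nrow(adj)))
  w <- if (is.null(weights)) rep(1, nrow(idx)) else weights
  igraph::graph_from_data_frame(
    data.frame(from = nm[idx[, 1]], to = nm[idx[, 2]], weight = w),
    directed = TRUE, vertices = nm)
}

# --- random small Bayesian networks ------------------------------------------
random_bbn <- function(n_nodes = 5, max_states = 3, p_edge = 0.4) {
  nms <- paste0("N", seq_len(n_nodes))
  nodes <- list()
  for (i in seq_len(n_nodes)) {
    k <- sample(2:max_states, 1)
    states <- paste0("s", seq_len(k))
    parents <- if (i > 1) nms[seq_len(i - 1)][runif(i - 1) < p_edge] else character(0)
    cards <- vapply(parents, function(p) length(nodes[[p]]$states), integer(1))
    nrows <- prod(c(1, cards))
    cpt <- t(vapply(seq_len(nrows), function(r) {
      w <- runif(k) + 0.05
      w / sum(w)
    }, numeric(k)))
    nodes[[nms[i]]] <- bbn_node(nms[i], states, parents, cpt)
  }
  bbn(nodes)
}

# two-node net used in several engine tests
two_node_net <- function() {
  bbn(list(
    bbn_node("A", c("s", "n"), character(0), matrix(c(0.5, 0.5), 1)),
    bbn_node("B", c("y", "n"), "A", rbind(c(0.8, 0.2), c(0.2, 0.8)))
  ))
}

# calibrated networks are expensive enough to share across test files
.cal_cache <- new.env(parent = emptyenv())
get_calibrated <- function(sector) {
  if (is.null(.cal_cache[[sector]])) {
    .cal_cache[[sector]] <- calibrate_si_network(sector)
  }
  .cal_cache[[sector]]
}
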