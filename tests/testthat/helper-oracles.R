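## Independent oracles used across the suite.  These deliberately avoid the
## code paths of the package (and of igraph's centrality algorithms): BFS
## with explicit path counting on an adjacency matrix, direct hypergeometric
## PMF summation, and a literal Benjamini-Hochberg step-up.

random_test_graph <- function(n, p, seed) {
  withr::with_seed(seed, {
    A <- matrix(0L, n, n)
    up <- upper.tri(A)
    A[up] <- as.integer(runif(sum(up)) < p)
    A <- A + t(A)
    dimnames(A) <- list(sprintf("v%02d", 1:n), sprintf("v%02d", 1:n))
    A
  })
}

adjacency_to_igraph <- function(A) {
  igraph::graph_from_adjacency_matrix(A, mode = "undirected")
}

## level-synchronous BFS from one source, counting shortest paths
bfs_source <- function(A, s) {
  n <- nrow(A)
  dist <- rep(Inf, n)
  sig <- rep(0, n)
  dist[s] <- 0
  sig[s] <- 1
  frontier <- s
  d <- 0
  repeat {
    contrib <- as.vector(crossprod(A[frontier, , drop = FALSE],
                                   sig[frontier]))
    new <- which(is.infinite(dist) & contrib > 0)
    if (length(new) == 0L) break
    d <- d + 1
    dist[new] <- d
    sig[new] <- contrib[new]
    frontier <- new
  }
  list(dist = dist, sig = sig)
}

## exhaustive all-pairs centralities: a node v lies on a shortest s-t path
## iff d(s,v) + d(v,t) = d(s,t); the path fraction is sig(s,v)*sig(v,t)/sig(s,t)
oracle_centralities <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  S <- matrix(0, n, n)
  for (s in seq_len(n)) {
    r <- bfs_source(A, s)
    D[s, ] <- r$dist
    S[s, ] <- r$sig
  }
  B <- numeric(n)
  for (v in seq_len(n)) {
    on_path <- (outer(D[, v], D[v, ], "+") == D) & is.finite(D)
    frac <- outer(S[, v], S[v, ]) / ifelse(S > 0, S, 1)
    w <- frac * on_path
    w[v, ] <- 0
    w[, v] <- 0
    diag(w) <- 0
    B[v] <- sum(w) / 2
  }
  Bn <- if (n < 3) rep(0, n) else 2 * B / ((n - 1) * (n - 2))
  Cl <- vapply(seq_len(n), function(i) {
    di <- D[i, -i]
    di <- di[is.finite(di)]
    if (length(di) == 0L) 0 else 1 / mean(di)
  }, numeric(1))
  list(degree = rowSums(A), betweenness = Bn, closeness = Cl,
       node = rownames(A))
}

## direct PMF of Hypergeometric(N, K, n) via binomial coefficients
hyper_pmf <- function(k, K, n, N) {
  choose(K, k) * choose(N - K, n - k) / choose(N, n)
}

oracle_upper_tail <- function(k, K, n, N) {
  ks <- k:min(K, n)
  sum(hyper_pmf(ks, K, n, N))
}

## literal step-up: adjusted_(i) = min_{j >= i} m * p_(j) / j, capped at 1
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj_sorted <- pmin(1, rev(cummin(rev(m * p[ord] / seq_len(m)))))
  out <- numeric(m)
  out[ord] <- adj_sorted
  out
}

## 5-node path graph used in the worked screening example
path5 <- function() igraph::make_graph(~ a - b - c - d - e)
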