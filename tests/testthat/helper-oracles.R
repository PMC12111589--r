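# Independent oracles used by the tests. These deliberately re-derive every
# quantity with plain loops / exhaustive enumeration, never through the
# package's own code paths.

# Loop-based gray relational analysis straight from the two printed
# equations, with mean pre-treatment.
bruteGra <- function(peaks, effects, xi = 0.1) {
  comps <- lapply(seq_len(nrow(peaks)), function(i) {
    v <- peaks[i, ]
    v / mean(v)
  })
  inds <- lapply(seq_len(ncol(effects)), function(j) {
    v <- effects[, j]
    v / mean(v)
  })
  grades <- matrix(NA_real_, length(inds), length(comps))
  for (j in seq_along(inds)) {
    x0 <- inds[[j]]
    dmin <- Inf
    dmax <- -Inf
    for (i in seq_along(comps)) {
      for (k in seq_along(x0)) {
        d <- abs(x0[k] - comps[[i]][k])
        if (d < dmin) dmin <- d
        if (d > dmax) dmax <- d
      }
    }
    for (i in seq_along(comps)) {
      acc <- 0
      for (k in seq_along(x0))
        acc <- acc + (dmin + xi * dmax) / (abs(x0[k] - comps[[i]][k]) + xi * dmax)
      grades[j, i] <- acc / length(x0)
    }
  }
  rownames(grades) <- colnames(effects)
  colnames(grades) <- rownames(peaks)
  list(grades = grades, relevancy = colMeans(grades))
}

# Exhaustive simple-path enumeration for degree / betweenness / closeness on
# small graphs (adjacency matrix input).
bruteTopology <- function(adj) {
  n <- nrow(adj)
  allPaths <- function(s, t) {
    res <- list()
    dfs <- function(path) {
      v <- path[length(path)]
      if (v == t) {
        res[[length(res) + 1]] <<- path
        return(invisible())
      }
      for (w in which(adj[v, ] == 1)) if (!(w %in% path)) dfs(c(path, w))
    }
    dfs(s)
    res
  }
  deg <- rowSums(adj)
  btw <- numeric(n)
  dist <- matrix(Inf, n, n)
  diag(dist) <- 0
  for (s in seq_len(n)) for (t in seq_len(n)) if (s < t) {
    ps <- allPaths(s, t)
    if (length(ps)) {
      lens <- vapply(ps, length, integer(1)) - 1L
      dmin <- min(lens)
      dist[s, t] <- dist[t, s] <- dmin
      sps <- ps[lens == dmin]
      for (v in setdiff(seq_len(n), c(s, t))) {
        cnt <- sum(vapply(sps, function(p) v %in% p, logical(1)))
        btw[v] <- btw[v] + cnt / length(sps)
      }
    }
  }
  clo <- vapply(seq_len(n), function(v) {
    dv <- dist[v, -v]
    dv <- dv[is.finite(dv)]
    if (length(dv)) length(dv) / sum(dv) else 0
  }, numeric(1))
  list(degree = deg, betweenness = btw, closeness = clo)
}

# Random simple undirected graph as an edge data.frame + node ids.
randomGraph <- function(n, p = 0.4) {
  ids <- paste0("n", seq_len(n))
  adj <- matrix(0L, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    if (runif(1) < p) adj[i, j] <- adj[j, i] <- 1L
  idx <- which(upper.tri(adj) & adj == 1, arr.ind = TRUE)
  edges <- data.frame(from = ids[idx[, 1]], to = ids[idx[, 2]],
                      stringsAsFactors = FALSE)
  list(adj = adj, edges = edges, ids = ids)
}

# Hypergeometric upper tail P(X >= k) by complete enumeration of all draws
# of size q from N with m marked items.
enumHyperP <- function(N, m, q, k) {
  combos <- utils::combn(N, q)
  hits <- colSums(combos <= m)  # items 1..m are the pathway members
  mean(hits >= k)
}

# Two well-separated Gaussian classes for discriminant-model fixtures.
separatedClasses <- function(n = 20, p = 25, shift = 4) {
  y <- rep(c("A", "B"), each = n / 2)
  X <- matrix(rnorm(n * p), n, p)
  X[y == "B", 1:5] <- X[y == "B", 1:5] + shift
  colnames(X) <- paste0("f", seq_len(p))
  list(X = X, y = y)
}
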