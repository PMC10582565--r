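# Independent oracles, deliberately implemented without igraph's
# algorithms: shortest-path structure comes from walk counting on
# adjacency-matrix powers, path sets from explicit recursive enumeration.

# distances and shortest-path counts from matrix powers:
# (A^k)[j, k] counts walks of length k, and the first k with a nonzero
# entry gives both the distance and the number of shortest paths.
oracle_path_structure <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  S <- diag(1, n)
  P <- diag(1, n)
  if (n > 1) {
    for (k in seq_len(n - 1)) {
      P <- P %*% A
      new <- is.infinite(D) & P > 0
      D[new] <- k
      S[new] <- P[new]
    }
  }
  list(D = D, S = S)
}

# brute-force fractional betweenness: for every ordered triple (j, i, k),
# a shortest j-k path passes through i iff d(j,i) + d(i,k) = d(j,k), and
# the fraction of such paths is sigma(j,i) * sigma(i,k) / sigma(j,k).
oracle_betweenness <- function(A, normalized = FALSE) {
  n <- nrow(A)
  cb <- numeric(n)
  if (n >= 3) {
    ps <- oracle_path_structure(A)
    D <- ps$D
    S <- ps$S
    for (i in seq_len(n)) {
      on_path <- outer(D[, i], D[i, ], "+") == D & is.finite(D)
      on_path[i, ] <- FALSE
      on_path[, i] <- FALSE
      diag(on_path) <- FALSE
      frac <- outer(S[, i], S[i, ], "*") / S
      cb[i] <- sum(frac[on_path]) / 2
    }
    if (normalized) cb <- cb / ((n - 1) * (n - 2) / 2)
  }
  cb
}

# all shortest paths between two nodes by recursive descent on the
# distance matrix (returns list of index vectors)
oracle_all_shortest_paths <- function(A, from, to) {
  ps <- oracle_path_structure(A)
  D <- ps$D
  if (is.infinite(D[from, to])) return(list())
  descend <- function(cur) {
    if (cur == to) return(list(cur))
    nxt <- which(A[cur, ] > 0 & D[cur, to] == D[, to] + 1)
    out <- list()
    for (v in nxt) {
      for (tail in descend(v)) out[[length(out) + 1L]] <- c(cur, tail)
    }
    out
  }
  descend(from)
}

# implied sign over all shortest paths, by explicit enumeration
oracle_implied_sign <- function(A, signs, from, to) {
  if (A[from, to] > 0) return(signs[from, to])
  paths <- oracle_all_shortest_paths(A, from, to)
  if (!length(paths)) return(NA_integer_)
  vals <- vapply(paths, function(p) {
    prod(signs[cbind(p[-length(p)], p[-1])])
  }, numeric(1))
  u <- unique(vals)
  if (length(u) == 1) as.integer(u) else NA_integer_
}

# exhaustive search oracle: best satisfied fraction over every connected
# spanning edge subset x sign assignment (observed edges pinned)
oracle_best_fraction <- function(tracts, observed) {
  nodes <- sort(unique(c(tracts$region_a, tracts$region_b)))
  n <- length(nodes)
  ia <- match(tracts$region_a, nodes)
  ib <- match(tracts$region_b, nodes)
  m <- nrow(tracts)
  oa <- match(observed$region_a, nodes)
  ob <- match(observed$region_b, nodes)
  obs_sign <- observed$direction

  # pinned signs for tract edges directly observed
  pin <- rep(NA_integer_, m)
  for (e in seq_len(m)) {
    hit <- (oa == ia[e] & ob == ib[e]) | (oa == ib[e] & ob == ia[e])
    if (any(hit)) pin[e] <- obs_sign[which(hit)[1]]
  }

  connected <- function(mask) {
    # union-find over nodes
    parent <- seq_len(n)
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    for (e in which(mask)) {
      ra <- find(ia[e]); rb <- find(ib[e])
      if (ra != rb) parent[ra] <- rb
    }
    length(unique(vapply(seq_len(n), find, integer(1)))) == 1
  }

  best <- -Inf
  for (code in seq_len(2^m) - 1L) {
    mask <- as.logical(bitwAnd(code, bitwShiftL(1L, seq_len(m) - 1L)))
    if (!connected(mask)) next
    free <- which(mask & is.na(pin))
    for (scode in seq_len(2^length(free)) - 1L) {
      sgn <- pin
      if (length(free)) {
        bits <- as.logical(bitwAnd(scode, bitwShiftL(1L, seq_along(free) - 1L)))
        sgn[free] <- ifelse(bits, 1L, -1L)
      }
      A <- matrix(0L, n, n)
      Sg <- matrix(NA_integer_, n, n)
      for (e in which(mask)) {
        A[ia[e], ib[e]] <- A[ib[e], ia[e]] <- 1L
        Sg[ia[e], ib[e]] <- Sg[ib[e], ia[e]] <- sgn[e]
      }
      ok <- vapply(seq_along(oa), function(i) {
        s <- oracle_implied_sign(A, Sg, oa[i], ob[i])
        !is.na(s) && s == obs_sign[i]
      }, logical(1))
      best <- max(best, mean(ok))
    }
  }
  best
}

# all labelled connected graphs on n nodes, as adjacency matrices
oracle_connected_graphs <- function(n) {
  pairs <- t(utils::combn(n, 2))
  m <- nrow(pairs)
  out <- list()
  for (code in seq_len(2^m) - 1L) {
    bits <- as.integer(intToBits(code))[seq_len(m)]
    A <- matrix(0L, n, n)
    A[pairs] <- bits
    A <- A + t(A)
    R <- diag(1, n) + A
    Rk <- R
    for (i in seq_len(max(0, n - 2))) Rk <- Rk %*% R
    if (all(Rk > 0)) out[[length(out) + 1L]] <- A
  }
  out
}
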