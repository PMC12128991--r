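# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Rand index between two labelings of the same items
rand_index <- function(a, b) {
  n <- length(a)
  if (n < 2) return(1)
  agree <- 0L; total <- 0L
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    same_a <- a[i] == a[j]
    same_b <- b[i] == b[j]
    agree <- agree + as.integer(same_a == same_b)
    total <- total + 1L
  }
  agree / total
}

# brute-force clone grouping: pairwise rule evaluated literally, components
# taken by igraph (an implementation independent of the package's BFS)
oracle_group <- function(m, rel_tol = 0.5) {
  n <- nrow(m)
  if (n == 0) return(integer(0))
  A <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    p1 <- m[i, ] > 0; p2 <- m[j, ] > 0
    if (!identical(p1, p2) || !any(p1)) next
    sh <- which(p1)
    ok <- all(abs(m[i, sh] - m[j, sh]) / pmax(m[i, sh], m[j, sh]) <= rel_tol)
    A[i, j] <- ok
  }
  g <- igraph::graph_from_adjacency_matrix(A, mode = "max")
  igraph::components(g)$membership
}

# brute-force extent bounds: scan every pair of positive segments
oracle_extent <- function(positive, geometry) {
  pos <- which(as.numeric(positive) > 0)
  lo <- 0; hi <- 0
  for (i in pos) for (j in pos) {
    lo <- max(lo, geometry$start_mm[j] - geometry$end_mm[i])
    hi <- max(hi, geometry$end_mm[j] - geometry$start_mm[i])
  }
  if (length(pos) == 1)
    hi <- geometry$end_mm[pos] - geometry$start_mm[pos]
  c(lo, hi)
}

# Clopper-Pearson 95% binomial interval
cp_interval <- function(x, n) {
  lo <- if (x == 0) 0 else qbeta(0.025, x, n - x + 1)
  hi <- if (x == n) 1 else qbeta(0.975, x + 1, n - x)
  c(lo, hi)
}

# Spearman rank correlation from first principles (average ranks for ties)
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}
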