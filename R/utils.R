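# Internal helpers shared across modules.

# Canonical string key for an allele multiset; missing cells map to "".
.cellKey <- function(cell) paste(cell, collapse = "/")

# Dirichlet draw (rows = independent draws).
.rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  x <- matrix(stats::rgamma(n * k, shape = alpha), n, k, byrow = TRUE)
  sw <- rowSums(x)
  # guard against all-zero rows for tiny alphas
  bad <- sw == 0
  if (any(bad)) {
    x[bad, ] <- t(vapply(which(bad), function(i) {
      v <- numeric(k); v[sample.int(k, 1L)] <- 1; v
    }, numeric(k)))
    sw[bad] <- 1
  }
  x / sw
}

# Deterministic per-task child seeds from a master seed: fixed counter scheme
# so adding tasks never reshuffles earlier ones. Keeps results < 2^31.
spawnSeeds <- function(master, n, stream = 0L) {
  master <- as.double(master)
  idx <- seq_len(n) - 1
  as.integer((master * 48271 + stream * 1299721 + idx * 2654435761) %% 2147483587) + 1L
}

# All permutations of 1..n (n small), as a list of integer vectors.
.permutations <- function(n) {
  if (n == 1L) return(list(1L))
  smaller <- .permutations(n - 1L)
  out <- vector("list", n * length(smaller))
  j <- 0L
  for (p in smaller) {
    for (pos in 0:(n - 1L)) {
      j <- j + 1L
      out[[j]] <- c(p[seq_len(pos)], n, if (pos < n - 1L) p[(pos + 1L):(n - 1L)])
    }
  }
  out
}

# Optimal column permutation minimising sum_i sum_k (A[,perm[k]] - B[,k])^2,
# i.e. assign columns of A (reference) to columns of B. Returns integer
# vector perm with perm[k] = reference column matched to column k of B.
.alignPermutation <- function(ref, Q) {
  K <- ncol(ref)
  # cost[j, k]: squared distance between ref column j and Q column k
  cost <- matrix(0, K, K)
  for (j in seq_len(K)) for (k in seq_len(K)) {
    cost[j, k] <- sum((ref[, j] - Q[, k])^2)
  }
  hungarian_solve(cost)
}
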