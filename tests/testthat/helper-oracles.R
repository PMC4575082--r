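# Independent brute-force oracles, deliberately written as direct
# transcriptions of definitions (explicit loops, no shared code with the
# package internals).

# DP from an explicit pattern histogram.
oracle_dp <- function(patternCounts) {
  n <- sum(patternCounts)
  acc <- 0
  for (cnt in patternCounts) acc <- acc + (cnt / n)^2
  1 - acc
}

# Log-likelihood by explicit triple loop over individuals, loci, copies.
oracle_loglik <- function(tab, Q, P, eps = 1e-300) {
  total <- 0
  loci <- lociNames(tab)
  for (i in seq_len(nInd(tab))) {
    for (l in seq_along(loci)) {
      cell <- genotypeCalls(tab, loci[l])[[i]]
      for (allele in cell) {
        s <- 0
        for (k in seq_len(ncol(Q)))
          s <- s + Q[i, k] * P[[l]][k, as.character(allele)]
        total <- total + log(max(s, eps))
      }
    }
  }
  total
}

# All permutations of 1..n.
oracle_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in oracle_perms(n - 1)) {
    for (pos in 0:(n - 1)) {
      out[[length(out) + 1]] <-
        as.integer(c(p[seq_len(pos)], n, if (pos < n - 1) p[(pos + 1):(n - 1)]))
    }
  }
  out
}

# Exhaustive-search alignment: permutation perm (perm[k] = reference column
# for run column k) minimising the squared distance.
oracle_align <- function(ref, Q) {
  K <- ncol(ref)
  best <- NULL
  bestCost <- Inf
  for (perm in oracle_perms(K)) {
    aligned <- Q
    aligned[, perm] <- Q
    cost <- sum((ref - aligned)^2)
    if (cost < bestCost) {
      bestCost <- cost
      best <- perm
    }
  }
  list(perm = best, cost = bestCost)
}

# Weir-Cockerham-style variance components by direct sums of squares for one
# locus: cells is a list of integer allele vectors (one per individual,
# empty = missing), grp a parallel group vector. Returns list(g, i, w)
# summed over alleles, or NULL when a group has < 2 scored individuals.
oracle_fst_components <- function(cells, grp) {
  scored <- lengths(cells) > 0
  cells <- unname(cells[scored])
  grp <- as.character(grp[scored])
  if (length(unique(grp)) < 2) return(NULL)
  if (any(table(grp) < 2)) return(NULL)
  alleles <- sort(unique(unlist(cells)))
  groups <- unique(grp)
  r <- length(groups)
  M <- length(cells)
  ncop <- lengths(cells)
  N <- sum(ncop)
  sg <- si <- sw <- 0
  for (A in alleles) {
    y <- lapply(cells, function(cl) as.numeric(cl == A))
    ybar_i <- vapply(y, mean, numeric(1))
    ssw <- ssi <- ssg <- 0
    grand <- sum(unlist(y)) / N
    for (j in groups) {
      sel <- grp == j
      nj <- sum(ncop[sel])
      ybar_j <- sum(unlist(y[sel])) / nj
      ssg <- ssg + nj * (ybar_j - grand)^2
      for (ii in which(sel)) {
        ssi <- ssi + ncop[ii] * (ybar_i[ii] - ybar_j)^2
        ssw <- ssw + sum((y[[ii]] - ybar_i[ii])^2)
      }
    }
    dfw <- N - M; dfi <- M - r; dfg <- r - 1
    Sj <- vapply(groups, function(j) {
      sel <- grp == j
      sum(ncop[sel]^2) / sum(ncop[sel])
    }, numeric(1))
    k1 <- (N - sum(Sj)) / dfi
    k2 <- (sum(Sj) - sum(ncop^2) / N) / dfg
    k3 <- (N - sum(vapply(groups, function(j) sum(ncop[grp == j]), numeric(1))^2 / N)) / dfg
    msw <- if (dfw > 0) ssw / dfw else 0
    msi <- ssi / dfi
    msg <- ssg / dfg
    vw <- msw
    vi <- (msi - msw) / k1
    vg <- (msg - msw - k2 * vi) / k3
    sg <- sg + vg; si <- si + vi; sw <- sw + vw
  }
  list(g = sg, i = si, w = sw)
}

# F_ST realized in a simulation's true population frequencies, in the
# variance-components (theta) convention the estimator targets: per locus
# and allele, the among-population variance of allele frequencies (sample
# variance across populations, divisor r-1) over that variance plus the
# mean within-population indicator variance; ratio of sums across loci and
# alleles.
oracle_realized_fst <- function(popFreqs) {
  num <- den <- 0
  for (pf in popFreqs) {
    r <- nrow(pf)
    for (a in seq_len(ncol(pf))) {
      v <- sum((pf[, a] - mean(pf[, a]))^2) / (r - 1)
      h <- mean(pf[, a] * (1 - pf[, a]))
      num <- num + v
      den <- den + v + h
    }
  }
  num / den
}
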