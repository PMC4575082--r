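make_run <- function(Q, lnL = -100) {
  new("AdmixtureRun", Q = Q, P = list(), lnLTrace = c(lnL, lnL),
      lnProbData = lnL, seed = 1L, config = list())
}

make_ensemble <- function(K, meanL, sdL, nruns = 2L) {
  Q <- matrix(1 / K, 2, K)
  new("AdmixtureEnsemble", K = as.integer(K),
      runs = replicate(nruns, make_run(Q), simplify = FALSE),
      alignment = replicate(nruns, seq_len(K), simplify = FALSE),
      meanQ = Q, meanL = meanL, sdL = sdL)
}

test_that("alignment is the identity for identical runs and undoes label
           switching", {
  Q <- rdirichlet_h(6, c(1, 1))
  ens <- alignRuns(list(make_run(Q), make_run(Q)))
  expect_identical(ens@alignment[[2]], 1:2)
  expect_equal(ens@meanQ, Q)

  ens2 <- alignRuns(list(make_run(Q), make_run(Q[, 2:1])))
  expect_identical(ens2@alignment[[2]], c(2L, 1L))
  expect_equal(ens2@meanQ, Q)
})

test_that("exact assignment equals brute-force permutation search
           (property)", {
  for (seed in 1:100) {
    set.seed(seed)
    K <- sample(2:5, 1)
    ref <- rdirichlet_h(8, rep(0.7, K))
    applied <- sample(K)
    noisy <- ref + matrix(runif(8 * K, 0, 0.05), 8, K)
    noisy <- noisy / rowSums(noisy)
    Qb <- noisy
    Qb[, applied] <- noisy   # scramble columns by a known permutation
    got <- structscan:::.alignPermutation(ref, Qb)
    oracle <- oracle_align(ref, Qb)
    aligned <- Qb; aligned[, got] <- Qb
    expect_equal(sum((ref - aligned)^2), oracle$cost)
  }
})

test_that("the Evanno table implements the second-difference formula", {
  ens <- list(make_ensemble(1, -120, 1), make_ensemble(2, -100, 1),
              make_ensemble(3, -95, 1), make_ensemble(4, -94, 1))
  ev <- evannoTable(ens)
  expect_equal(ev$K, c(2, 3))
  expect_equal(ev$deltaK, c(15, 4))
  expect_equal(bestK(ev), list(K = 2, deltaK = 15))

  # invariant to shifting all meanL by a constant
  ens2 <- list(make_ensemble(1, -120 + 55, 1), make_ensemble(2, -100 + 55, 1),
               make_ensemble(3, -95 + 55, 1), make_ensemble(4, -94 + 55, 1))
  expect_equal(evannoTable(ens2)$deltaK, ev$deltaK)
})

test_that("flat evidence gives zero delta-K and zero sd flags an undefined
           row", {
  flat <- lapply(1:4, function(K) make_ensemble(K, -50, 0.5))
  expect_equal(evannoTable(flat)$deltaK, c(0, 0))

  degenerate <- list(make_ensemble(1, -120, 1), make_ensemble(2, -100, 0),
                     make_ensemble(3, -95, 1))
  expect_warning(ev <- evannoTable(degenerate), "sdL = 0")
  expect_true(is.na(ev$deltaK[ev$K == 2]))
  expect_error(bestK(ev[is.na(ev$deltaK), , drop = FALSE]), "no defined")
})

test_that("single defined row is returned as best K", {
  ev <- data.frame(K = 3, meanL = -10, sdL = 1, Lp = 1, absLpp = 2,
                   deltaK = 2)
  expect_equal(bestK(ev)$K, 3)
})

test_that("membership summaries compute Qm and the strong fraction", {
  Q <- matrix(c(1, 0, 1, 0), 2, byrow = TRUE)
  ms <- membershipSummaries(Q)
  expect_equal(ms$Qm, 1)
  expect_equal(ms$propStrong, 1)

  Qh <- matrix(0.5, 2, 2)
  ms2 <- membershipSummaries(Qh, 0.8)
  expect_equal(ms2$Qm, 0.5)
  expect_equal(ms2$propStrong, 0)

  Qm <- rbind(c(0.9, 0.1), c(0.6, 0.4))
  rownames(Qm) <- c("a", "b")
  ms3 <- membershipSummaries(Qm, 0.8)
  expect_equal(ms3$Qm, 0.75)
  expect_equal(ms3$propStrong, 0.5)
  expect_identical(ms3$strongIDs, "a")

  # invariant under column permutation
  ms4 <- membershipSummaries(Qm[, 2:1], 0.8)
  expect_equal(ms4$Qm, ms3$Qm)
  expect_equal(ms4$propStrong, ms3$propStrong)
})

test_that("runEnsembles spawns distinct seeds and aligns runs", {
  sim <- simulateCollection(simConfig(KTrue = 2, nPerPop = 10, nLoci = 5,
                                      seed = 13))
  ens <- runEnsembles(sim$table, kValues = 2, runsPerK = 3, seed = 1,
                      burnIn = 200, iterations = 400)[["2"]]
  seeds <- vapply(ens@runs, slot, integer(1), "seed")
  expect_equal(length(unique(seeds)), 3L)
  expect_equal(unname(rowSums(ens@meanQ)), rep(1, 20), tolerance = 1e-9)
})
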