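test_that("K = 1 forces full membership in the single cluster", {
  gt <- random_table(3)
  r <- runAdmixture(gt, modelConfig(K = 1, burnIn = 50, iterations = 100))
  expect_true(all(membershipMatrix(r) == 1))
})

test_that("with no data the posterior mean of q recovers the prior (1/K)", {
  n <- 12
  calls <- matrix(vector("list", n * 3), n, 3)
  calls[] <- list(integer(0))
  gt <- GenotypeTable(calls, ids = paste0("i", 1:n))
  K <- 3
  iters <- 4000
  r <- runAdmixture(gt, modelConfig(K = K, alpha = 0.5, updateAlpha = FALSE,
                                    burnIn = 100, iterations = iters,
                                    seed = 42))
  # q rows are fresh Dirichlet(0.5) draws each sweep; the grand mean of one
  # column has MC standard error sqrt(Var Beta(0.5, (K-1)*0.5) / (n*iters))
  se <- sqrt((1 / K) * (1 - 1 / K) / (0.5 * K + 1) / (n * iters))
  expect_lt(max(abs(colMeans(membershipMatrix(r)) - 1 / K)), 3 * se)
})

test_that("log-likelihood handles the closed-form cases", {
  gt <- make_table(list(a = list(L = c(100L, 100L))))
  Q <- matrix(1, 1, 1)
  P1 <- list(L = matrix(1, 1, 1, dimnames = list(NULL, "100")))
  expect_equal(logLikelihood(gt, Q, P1), 0)
  Phalf <- list(L = matrix(c(0.5, 0.5), 1, 2,
                           dimnames = list(NULL, c("100", "104"))))
  expect_equal(logLikelihood(gt, Q, Phalf), 2 * log(0.5))
})

test_that("log-likelihood matches a brute-force re-implementation (property)", {
  for (seed in 1:100) {
    set.seed(seed)
    gt <- random_table(seed, n = 5, m = 3)
    K <- sample(2:4, 1)
    Q <- rdirichlet_h(nInd(gt), rep(1, K))
    P <- lapply(lociNames(gt), function(l) {
      alleles <- sort(unique(unlist(genotypeCalls(gt, l))))
      if (length(alleles) == 0) alleles <- 100L
      m <- rdirichlet_h(K, rep(1, length(alleles)))
      colnames(m) <- as.character(alleles)
      m
    })
    expect_equal(logLikelihood(gt, Q, P), oracle_loglik(gt, Q, P))
  }
})

test_that("runs are bitwise reproducible under a fixed seed", {
  sim <- simulateCollection(simConfig(KTrue = 2, nPerPop = 8, nLoci = 4,
                                      seed = 5))
  cfg <- modelConfig(K = 2, burnIn = 200, iterations = 300, seed = 77)
  r1 <- runAdmixture(sim$table, cfg)
  r2 <- runAdmixture(sim$table, cfg)
  expect_identical(membershipMatrix(r1), membershipMatrix(r2))
  expect_identical(r1@lnLTrace, r2@lnLTrace)
})

test_that("two fully differentiated populations are assigned almost
           perfectly", {
  # 2 populations fixed for different alleles at 5 loci
  n <- 20
  calls <- matrix(vector("list", n * 5), n, 5)
  for (i in seq_len(n)) for (l in 1:5)
    calls[[i, l]] <- rep(if (i <= n / 2) 100L else 120L, 2)
  gt <- GenotypeTable(calls, ids = paste0("i", 1:n))
  r <- runAdmixture(gt, modelConfig(K = 2, burnIn = 2000, iterations = 5000,
                                    seed = 9))
  truth <- list(trueQ = matrix(rep(c(1, 0, 0, 1), each = n / 2), n, 2),
                popAssign = rep(1:2, each = n / 2))
  rownames(truth$trueQ) <- paste0("i", 1:n)
  expect_gte(assignmentAccuracy(membershipMatrix(r), truth), 0.99)
})

test_that("different seeds agree up to label permutation on structured
           data", {
  sim <- simulateCollection(simConfig(KTrue = 2, nPerPop = 20, F = 0.2,
                                      nLoci = 8, seed = 21))
  r1 <- runAdmixture(sim$table, modelConfig(K = 2, burnIn = 1000,
                                            iterations = 2000, seed = 1))
  r2 <- runAdmixture(sim$table, modelConfig(K = 2, burnIn = 1000,
                                            iterations = 2000, seed = 2))
  st <- stabilityIndex(membershipMatrix(r1), membershipMatrix(r2))
  expect_gt(st$D, 0.95)
})

test_that("popflag mode pins flagged individuals and trains the rest", {
  sim <- simulateCollection(simConfig(KTrue = 2, nPerPop = 15, F = 0.2,
                                      nLoci = 8, seed = 31))
  gt <- sim$table
  lab <- paste0("P", sim$truth$popAssign)
  flag <- rep(c(TRUE, FALSE), length.out = nInd(gt))
  popInfo(gt) <- data.frame(label = ifelse(flag, lab, NA), flag = flag)
  r <- runAdmixture(gt, modelConfig(K = 2, burnIn = 500, iterations = 1000,
                                    seed = 4, mode = "popflag"))
  Q <- membershipMatrix(r)
  expect_true(all(apply(Q[flag, ], 1, max) == 1))
  acc <- mean(colnames(Q)[max.col(Q[!flag, ])] == lab[!flag])
  expect_gte(acc, 0.9)
})

test_that("configuration and mode errors are caught", {
  gt <- random_table(1)
  expect_error(modelConfig(K = 0), "K")
  expect_error(runAdmixture(gt, modelConfig(K = 2, mode = "popflag")),
               "flagged")
  empty <- GenotypeTable(matrix(vector("list", 0), 0, 1,
                                dimnames = list(NULL, "L")),
                         ids = character(0), ploidy = integer(0))
  expect_error(runAdmixture(empty, modelConfig(K = 2)), "empty")
})
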