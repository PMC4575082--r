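test_that("complete differentiation gives F_ST = 1 and a null duplicate
           gives F_ST <= 0", {
  gt <- fixed_two_pop_table(nPerPop = 4, m = 3)
  grouping <- setNames(rep(c("A", "B"), each = 4), indIDs(gt))
  res <- pairwiseFst(gt, grouping, nPermutations = 99, seed = 2)
  expect_equal(unname(res$pairwise["A", "B"]), 1)
  expect_lte(res$pValues["A", "B"], 0.05)

  # one sample duplicated as two groups (identical allele-copy samples):
  # among-group sums of squares vanish, so the estimate cannot be positive
  sim <- simulateCollection(simConfig(KTrue = 1, nPerPop = 8, nLoci = 5,
                                      seed = 3))
  calls <- rbind(sim$table@calls, sim$table@calls)
  ids <- c(paste0("a", 1:8), paste0("b", 1:8))
  dupTab <- GenotypeTable(calls, ids = ids,
                          markers = markerInfo(sim$table))
  dup <- setNames(rep(c("X", "Y"), each = 8), ids)
  res2 <- pairwiseFst(dupTab, dup, nPermutations = 199, seed = 5)
  expect_lte(unname(res2$pairwise["X", "Y"]), 1e-12)
  expect_gt(res2$pValues["X", "Y"], 0.5)
})

test_that("variance components match the direct sums-of-squares oracle
           (property)", {
  for (seed in 1:100) {
    set.seed(seed)
    gt <- random_table(seed, n = 10, m = 1, triploid = TRUE)
    grp <- sample(c("A", "B", "C"), 10, replace = TRUE)
    cells <- genotypeCalls(gt, "loc01")
    oracle <- oracle_fst_components(cells, grp)
    data <- structscan:::.fstData(gt, "loc01")
    grouping <- setNames(grp, indIDs(gt))
    comp <- structscan:::.componentsByLocus(data, grouping)
    if (is.null(oracle)) {
      expect_true(anyNA(comp))
    } else {
      expect_equal(comp["g", 1], oracle$g, tolerance = 1e-10)
      expect_equal(comp["i", 1], oracle$i, tolerance = 1e-10)
      expect_equal(comp["w", 1], oracle$w, tolerance = 1e-10)
    }
  }
})

test_that("per-locus ranking handles monomorphic and fixed loci", {
  n <- 8
  calls <- matrix(vector("list", n * 2), n, 2)
  for (i in seq_len(n)) {
    calls[[i, 1]] <- c(100L, 100L)                       # monomorphic
    calls[[i, 2]] <- rep(if (i <= 4) 100L else 120L, 2L) # fixed per group
  }
  gt <- GenotypeTable(calls, ids = paste0("i", 1:n))
  grouping <- setNames(rep(c("A", "B"), each = 4), indIDs(gt))
  ranks <- perLocusFstRanking(gt, grouping)
  expect_equal(unname(ranks[1]), 0)
  expect_equal(unname(ranks[2]), 1)
})

test_that("multi-group per-locus F_ST equals the oracle on a random
           three-group toy", {
  set.seed(88)
  gt <- random_table(77, n = 12, m = 3, triploid = TRUE, missing = FALSE)
  grp <- rep(c("A", "B", "C"), each = 4)
  grouping <- setNames(grp, indIDs(gt))
  ranks <- perLocusFstRanking(gt, grouping)
  for (l in seq_len(3)) {
    oracle <- oracle_fst_components(genotypeCalls(gt, lociNames(gt)[l]), grp)
    expect_equal(unname(ranks[l]),
                 oracle$g / (oracle$g + oracle$i + oracle$w),
                 tolerance = 1e-10)
  }
})

test_that("loci are combined as ratio of averages, not average of ratios", {
  # locus 1 strongly differentiated but few alleles; locus 2 undifferentiated
  n <- 8
  calls <- matrix(vector("list", n * 2), n, 2)
  set.seed(42)
  for (i in seq_len(n)) {
    calls[[i, 1]] <- rep(if (i <= 4) 100L else 120L, 2L)
    calls[[i, 2]] <- sort(sample(c(100L, 104L, 108L, 112L), 2, replace = TRUE))
  }
  gt <- GenotypeTable(calls, ids = paste0("i", 1:n))
  grouping <- setNames(rep(c("A", "B"), each = 4), indIDs(gt))
  res <- pairwiseFst(gt, grouping, nPermutations = 0)
  avgOfRatios <- mean(res$perLocus)
  data <- structscan:::.fstData(gt, lociNames(gt))
  comp <- structscan:::.componentsByLocus(data, grouping)
  ratioOfAvgs <- sum(comp["g", ]) / sum(comp)
  expect_equal(unname(res$pairwise["A", "B"]), ratioOfAvgs)
  expect_false(isTRUE(all.equal(res$pairwise["A", "B"], avgOfRatios)))
})

test_that("degenerate groupings are rejected or dropped with a warning", {
  gt <- fixed_two_pop_table(4, 2)
  tiny <- setNames(c("A", rep("B", 7)), indIDs(gt))
  expect_error(pairwiseFst(gt, tiny, nPermutations = 0), "two individuals")

  # a locus missing entirely in one group is dropped, not fatal
  gt2 <- gt
  calls <- gt2@calls
  for (i in 1:4) calls[[i, 1]] <- integer(0)
  gt3 <- GenotypeTable(calls, ids = indIDs(gt))
  grouping <- setNames(rep(c("A", "B"), each = 4), indIDs(gt))
  expect_warning(res <- pairwiseFst(gt3, grouping, nPermutations = 0),
                 "dropped")
  expect_equal(unname(res$pairwise["A", "B"]), 1)  # from the surviving loci
})
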