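test_that("wide dialect parses calls and missing codes", {
  tf <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,ploidy,popflag,poplabel,locA_1,locA_2",
               "g1,2,0,,100,104",
               "g2,2,0,,-9,-9"), tf)
  gt <- readGenotypeTable(tf, "wide")
  expect_equal(nInd(gt), 2L)
  expect_equal(genotypeCalls(gt, "locA")[["g1"]], c(100L, 104L))
  expect_identical(genotypeCalls(gt, "locA")[["g2"]], integer(0))
})

test_that("malformed rows, unknown codes and duplicate ids are rejected", {
  tf <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,ploidy,popflag,poplabel,locA_1,locA_2",
               "g1,2,0,,100"), tf)
  expect_error(readGenotypeTable(tf, "wide"), "row 1")
  writeLines(c("id,ploidy,popflag,poplabel,locA_1,locA_2",
               "g1,2,0,,100,??"), tf)
  expect_error(readGenotypeTable(tf, "wide"), "\\?\\?")
  writeLines(c("id,ploidy,popflag,poplabel,locA_1,locA_2",
               "g1,2,0,,100,104",
               "g1,2,0,,100,104"), tf)
  expect_error(readGenotypeTable(tf, "wide"), "duplicate")
})

test_that("a cell cannot hold more alleles than the individual's ploidy", {
  tf <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,ploidy,popflag,poplabel,locA_1,locA_2,locA_3",
               "g1,2,0,,100,104,108"), tf)
  expect_error(readGenotypeTable(tf, "wide"), "ploidy")
})

test_that("triploid individuals occupy three allele rows in structure format", {
  gt <- make_table(list(t1 = list(locA = c(100L, 104L, 108L))), ploidy = 3L)
  tf <- withr::local_tempfile(fileext = ".txt")
  writeGenotypeTable(gt, tf, "structure")
  lines <- readLines(tf)
  expect_length(lines, 4L)  # header + one row per allele copy
  expect_equal(vapply(strsplit(lines[-1], "\t"), `[[`, character(1), 4L),
               c("100", "104", "108"))
})

test_that("empty table writes a header-only file", {
  gt <- GenotypeTable(matrix(vector("list", 0), 0, 2,
                             dimnames = list(NULL, c("a", "b"))),
                      ids = character(0), ploidy = integer(0))
  tf <- withr::local_tempfile(fileext = ".csv")
  writeGenotypeTable(gt, tf, "wide")
  expect_length(readLines(tf), 1L)
})

test_that("write-then-read is the identity for both dialects (property)", {
  for (seed in 1:12) {
    gt <- random_table(seed)
    for (dialect in c("wide", "structure")) {
      tf <- withr::local_tempfile()
      writeGenotypeTable(gt, tf, dialect)
      back <- readGenotypeTable(tf, dialect)
      expect_identical(back@calls, gt@calls)
      expect_identical(ploidy(back), ploidy(gt))
      expect_identical(indIDs(back), indIDs(gt))
    }
  }
})

test_that("writing is byte-stable for a fixed table and dialect", {
  gt <- random_table(99)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  writeGenotypeTable(gt, f1, "wide")
  writeGenotypeTable(gt, f2, "wide")
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("spreadsheet-export layout reads with configurable columns", {
  tf <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("Genotype,Ploidy,CH01d09,CH-Vf1",
               "acc1,2,120/124,130/130",
               "acc2,3,120/122/126,132/134",
               "acc3,2,,130/136"), tf)
  gt <- readGenotypeTable(tf, "s1", idColumn = "Genotype",
                          ploidyColumn = "Ploidy")
  expect_equal(nInd(gt), 3L)
  expect_equal(nLoci(gt), 2L)
  expect_equal(ploidy(gt), c(2L, 3L, 2L))
  expect_equal(genotypeCalls(gt, "CH01d09")[["acc2"]], c(120L, 122L, 126L))
  # acc2 shows only two copies at CH-Vf1: dosage-ambiguous, kept as observed
  expect_equal(genotypeCalls(gt, "CH-Vf1")[["acc2"]], c(132L, 134L))
  expect_identical(genotypeCalls(gt, "CH01d09")[["acc3"]], integer(0))
  # s1 round-trip through the package writer
  tf2 <- withr::local_tempfile(fileext = ".csv")
  writeGenotypeTable(gt, tf2, "s1")
  back <- readGenotypeTable(tf2, "s1", idColumn = "Genotype",
                            ploidyColumn = "Ploidy")
  expect_identical(back@calls, gt@calls)
})

test_that("popflag labels survive a wide round-trip", {
  gt <- random_table(5)
  popInfo(gt) <- data.frame(label = c("A", NA, "B", NA, NA, "A"),
                            flag = c(TRUE, FALSE, TRUE, FALSE, FALSE, TRUE))
  tf <- withr::local_tempfile()
  writeGenotypeTable(gt, tf, "wide")
  back <- readGenotypeTable(tf, "wide")
  expect_identical(popFlags(back), popFlags(gt))
  expect_identical(popLabels(back)[popFlags(back)],
                   popLabels(gt)[popFlags(gt)])
})

test_that("run and stability reports serialize to stable CSV", {
  sim <- simulateCollection(simConfig(KTrue = 2, nPerPop = 6, nLoci = 3,
                                      seed = 9))
  r <- runAdmixture(sim$table, modelConfig(K = 2, burnIn = 100,
                                           iterations = 200, seed = 2))
  d <- withr::local_tempdir()
  writeRunResult(r, d)
  expect_setequal(list.files(d), c("Q.csv", "lnL_trace.csv", "config.txt"))
  Q <- utils::read.csv(file.path(d, "Q.csv"), check.names = FALSE)
  expect_equal(nrow(Q), nInd(sim$table))

  f <- withr::local_tempfile(fileext = ".csv")
  rep <- writeStabilityReport(membershipMatrix(r), membershipMatrix(r), f)
  expect_equal(rep$value[rep$id == "summary_D"], 1)
  expect_true(file.exists(f))
})
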