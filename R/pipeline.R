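#' Pipeline configuration
#'
#' Bundles the settings of the marker-number and criterion-validation
#' experiments. Defaults follow the package's analysis conventions: a K
#' sweep starting at 1 (so the delta-K statistic is defined at K = 2), 10
#' replicate runs per K, the 0.8 strong-assignment threshold, and 1000
#' permutations for F_ST tests. Sweep counts default to the scaled-down
#' values of [modelConfig()].
#'
#' @param kValues K sweep (default 1:10).
#' @param runsPerK replicate runs per K.
#' @param burnIn,iterations Gibbs sweep counts per run.
#' @param strongQ strong-assignment threshold (default 0.8).
#' @param permutations permutations for F_ST significance.
#' @param seed master seed; per-run seeds are spawned by a fixed counter
#'   scheme so adding runs never reshuffles earlier ones.
#' @param fixedK optional: skip model selection and analyse at this K.
#' @param nested run nested subgroup analyses (one level).
#' @param alpha,lambda sampler priors (see [modelConfig()]).
#' @param updateAlpha default \code{FALSE} here, unlike [modelConfig()]:
#'   experiments compare analyses across marker sets, and holding the
#'   admixture prior fixed ensures the differences measured (stability D,
#'   reassignments) are attributable to the loci used rather than to the
#'   per-analysis drift of an inferred alpha.
#' @return a list of class \code{"pipelineConfig"}.
#' @export
pipelineConfig <- function(kValues = 1:10, runsPerK = 10L, burnIn = 2000L,
                           iterations = 5000L, strongQ = 0.8,
                           permutations = 1000L, seed = 1L, fixedK = NULL,
                           nested = FALSE, alpha = 0.5, lambda = 1.0,
                           updateAlpha = FALSE) {
  if (strongQ <= 0 || strongQ > 1) stop("strongQ must be in (0, 1]")
  structure(list(kValues = as.integer(kValues),
                 runsPerK = as.integer(runsPerK),
                 burnIn = as.integer(burnIn),
                 iterations = as.integer(iterations),
                 strongQ = strongQ, permutations = as.integer(permutations),
                 seed = as.integer(seed), fixedK = fixedK, nested = nested,
                 alpha = alpha, lambda = lambda, updateAlpha = updateAlpha),
            class = "pipelineConfig")
}

#' Form overlapping subgroups for nested structure analysis
#'
#' For each cluster c of a parent partition, the subgroup holds all
#' individuals except those with a membership value to another cluster of
#' at least \code{strongQ}. Weakly assigned individuals therefore appear in
#' several subgroups, which keeps subgroup composition fixed across marker
#' sets so that changes in the nested structure depend only on the loci
#' used.
#'
#' @param Q parent membership matrix (rows named by individual id).
#' @param strongQ strong-assignment threshold (default 0.8).
#' @return named list of id vectors, one per cluster; subgroups smaller
#'   than 2 are flagged with a warning.
#' @export
formSubgroups <- function(Q, strongQ = 0.8) {
  ids <- rownames(Q)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(Q)))
  K <- ncol(Q)
  out <- vector("list", K)
  names(out) <- paste0("G", seq_len(K))
  for (c in seq_len(K)) {
    strongElsewhere <- apply(Q[, -c, drop = FALSE] >= strongQ, 1L, any)
    out[[c]] <- ids[!strongElsewhere]
    if (length(out[[c]]) < 2L)
      warning("degenerate subgroup for cluster ", c,
              " (fewer than 2 individuals)")
  }
  out
}

#' Final structure inference with prior-population flags
#'
#' Re-runs the admixture analysis with the population information obtained
#' from a previous (sub)grouping: genotypes strongly assigned to a group
#' are flagged with that label (PopFlag = 1) and act as training members,
#' while the remaining genotypes are inferred freely and may stay admixed.
#'
#' @param table a [GenotypeTable-class].
#' @param assignments named character vector id -> group label for the
#'   strongly assigned genotypes (others omitted or NA).
#' @param config a [pipelineConfig()]; the run uses
#'   \code{K = } number of distinct labels unless \code{config$fixedK} is
#'   set.
#' @return an [AdmixtureEnsemble-class] in popflag mode.
#' @export
finalStructureWithPriors <- function(table, assignments,
                                     config = pipelineConfig()) {
  assignments <- assignments[!is.na(assignments)]
  if (length(assignments) == 0L)
    stop("popflag mode refused: no strongly assigned genotypes")
  lab <- rep(NA_character_, nInd(table))
  names(lab) <- indIDs(table)
  lab[names(assignments)] <- assignments
  popInfo(table) <- data.frame(label = lab, flag = !is.na(lab))
  K <- if (!is.null(config$fixedK)) config$fixedK
       else length(unique(assignments))
  seeds <- spawnSeeds(config$seed, config$runsPerK, stream = 7919L)
  runs <- lapply(seeds, function(s)
    runAdmixture(table, modelConfig(K = K, burnIn = config$burnIn,
                                    iterations = config$iterations,
                                    alpha = config$alpha,
                                    lambda = config$lambda,
                                    updateAlpha = config$updateAlpha,
                                    seed = s, mode = "popflag")))
  alignRuns(runs)
}

# Model selection for one marker subset: ensembles over the K sweep plus the
# Evanno table and chosen K. With config$fixedK the sweep collapses to one K.
.analyseSubset <- function(table, config, seed) {
  if (!is.null(config$fixedK)) {
    ens <- runEnsembles(table, kValues = config$fixedK,
                        runsPerK = config$runsPerK, seed = seed,
                        burnIn = config$burnIn,
                        iterations = config$iterations,
                        alpha = config$alpha, lambda = config$lambda,
                        updateAlpha = config$updateAlpha)
    return(list(ensembles = ens, evanno = NULL,
                bestK = config$fixedK, deltaK = NA_real_))
  }
  ens <- runEnsembles(table, kValues = config$kValues,
                      runsPerK = config$runsPerK, seed = seed,
                      burnIn = config$burnIn, iterations = config$iterations,
                      alpha = config$alpha, lambda = config$lambda,
                      updateAlpha = config$updateAlpha)
  ev <- evannoTable(ens)
  bk <- bestK(ev)
  list(ensembles = ens, evanno = ev, bestK = bk$K, deltaK = bk$deltaK)
}

# Strong-genotype grouping from a membership matrix: id -> "G<k>".
.strongGrouping <- function(Q, strongQ) {
  ms <- membershipSummaries(Q, strongQ)
  ids <- rownames(Q)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(Q)))
  strong <- ids %in% ms$strongIDs
  stats::setNames(paste0("G", ms$assignment[strong]), ids[strong])
}

# Pairwise F_ST over strongly assigned genotypes; NULL when the grouping is
# too degenerate (fewer than two groups of two).
.strongFst <- function(table, Q, config) {
  grouping <- .strongGrouping(Q, config$strongQ)
  if (length(grouping) == 0L) return(NULL)
  sizes <- base::table(grouping)
  if (length(sizes) < 2L || any(sizes < 2L)) return(NULL)
  pairwiseFst(table, grouping, nPermutations = config$permutations,
              seed = config$seed)
}

#' Incremental marker-number experiment
#'
#' Adds loci one at a time along \code{orderedLoci} and, for every prefix
#' length t = 2..T, runs the replicate K sweep, selects the best-supported
#' K by delta-K, summarises memberships (Qm, strongly assigned fraction),
#' computes the similarity D with the analysis at t-1 (at the smaller
#' count's chosen K for both analyses), optionally forms nested subgroups,
#' and estimates pairwise F_ST over the strongly assigned genotypes.
#' Deterministic under the master seed; a failure at one t is recorded,
#' not fatal.
#'
#' @param table a [GenotypeTable-class].
#' @param orderedLoci inclusion order (length >= 2), e.g. from
#'   [orderMarkers()].
#' @param config a [pipelineConfig()].
#' @param outputDir optional directory: per-t Evanno tables and mean-Q
#'   matrices plus a summary table are written as CSV.
#' @return list of per-t records (class \code{"incrementalExperiment"});
#'   each record holds \code{t}, \code{loci}, \code{bestK}, \code{deltaK},
#'   \code{Qm}, \code{propStrong}, \code{D_prev}, \code{fst},
#'   \code{subgroups}, \code{error}. A \code{summary} data.frame is
#'   attached as an attribute.
#' @export
incrementalMarkerExperiment <- function(table, orderedLoci,
                                        config = pipelineConfig(),
                                        outputDir = NULL) {
  T <- length(orderedLoci)
  if (T < 2L) stop("need at least two ordered loci")
  unknown <- setdiff(orderedLoci, lociNames(table))
  if (length(unknown)) stop("unknown locus: ", unknown[1L])
  if (!is.null(outputDir) && !dir.exists(outputDir))
    dir.create(outputDir, recursive = TRUE)
  tSeeds <- spawnSeeds(config$seed, T, stream = 104729L)
  records <- vector("list", T - 1L)
  prev <- NULL
  for (t in 2:T) {
    loci_t <- orderedLoci[seq_len(t)]
    rec <- list(t = t, loci = loci_t, bestK = NA_integer_,
                deltaK = NA_real_, Qm = NA_real_, propStrong = NA_real_,
                D_prev = NA_real_, fst = NULL, subgroups = NULL,
                error = NULL)
    res <- tryCatch({
      sub <- table[, loci_t]
      an <- .analyseSubset(sub, config, tSeeds[t])
      Q <- membershipMatrix(an$ensembles[[as.character(an$bestK)]])
      ms <- membershipSummaries(Q, config$strongQ)
      rec$bestK <- an$bestK
      rec$deltaK <- an$deltaK
      rec$Qm <- ms$Qm
      rec$propStrong <- ms$propStrong
      if (!is.null(prev)) {
        # D at the smaller count's chosen K, for both analyses
        Kd <- as.character(prev$bestK)
        if (!is.null(prev$ensembles[[Kd]]) && !is.null(an$ensembles[[Kd]])) {
          rec$D_prev <- stabilityIndex(
            membershipMatrix(prev$ensembles[[Kd]]),
            membershipMatrix(an$ensembles[[Kd]]))$D
        }
      }
      if (an$bestK >= 2L) {
        rec$subgroups <- formSubgroups(Q, config$strongQ)
        rec$fst <- .strongFst(sub, Q, config)
      }
      if (!is.null(outputDir)) {
        if (!is.null(an$evanno))
          utils::write.csv(an$evanno,
                           file.path(outputDir, sprintf("evanno_t%02d.csv", t)),
                           row.names = FALSE)
        utils::write.csv(data.frame(id = rownames(Q), Q,
                                    check.names = FALSE),
                         file.path(outputDir, sprintf("meanQ_t%02d.csv", t)),
                         row.names = FALSE)
      }
      an
    }, error = function(e) {
      rec$error <<- conditionMessage(e)
      NULL
    })
    records[[t - 1L]] <- rec
    if (!is.null(res)) prev <- res
  }
  summary <- data.frame(
    t = vapply(records, `[[`, numeric(1), "t"),
    bestK = vapply(records, function(r) as.numeric(r$bestK), numeric(1)),
    deltaK = vapply(records, `[[`, numeric(1), "deltaK"),
    Qm = vapply(records, `[[`, numeric(1), "Qm"),
    propStrong = vapply(records, `[[`, numeric(1), "propStrong"),
    D_prev = vapply(records, `[[`, numeric(1), "D_prev"),
    meanFst = vapply(records, function(r) {
      if (is.null(r$fst)) NA_real_
      else mean(r$fst$pairwise[upper.tri(r$fst$pairwise)])
    }, numeric(1))
  )
  if (!is.null(outputDir))
    utils::write.csv(summary, file.path(outputDir, "summary.csv"),
                     row.names = FALSE)
  attr(records, "summary") <- summary
  class(records) <- "incrementalExperiment"
  records
}

#' Criterion-validation experiment
#'
#' Crosses two sorting criteria (per-locus DP, per-locus multi-group F_ST
#' from a reference full-marker analysis) with two choosing scenarios
#' ("most"/"least" discriminant, both under the linkage-group round-robin
#' constraint) at the requested marker-set sizes. Each cell selects its
#' marker set, runs the replicate K sweep, and compares the resulting
#' memberships with the full-set reference analysis (similarity D at the
#' reference K, reassignment fractions) plus pairwise F_ST over strong
#' genotypes.
#'
#' @param table a [GenotypeTable-class].
#' @param config a [pipelineConfig()].
#' @param sizes marker-set sizes to test (default \code{c(6, 12)}).
#' @param reference optional precomputed reference analysis (the result of
#'   a previous call's \code{reference} element) to avoid re-running the
#'   full-set sweep.
#' @return list with \code{records} (one per criterion x scenario x size;
#'   each holds the chosen loci, bestK, deltaK, Qm, propStrong, D_vs_full,
#'   reassignment fractions and the pairwise F_ST result), \code{summary}
#'   data.frame, and \code{reference}.
#' @export
criterionValidationExperiment <- function(table, config = pipelineConfig(),
                                          sizes = c(6L, 12L),
                                          reference = NULL) {
  if (any(sizes > nLoci(table))) stop("size exceeds the number of loci")
  if (is.null(reference)) {
    an <- .analyseSubset(table, config,
                         spawnSeeds(config$seed, 1L, stream = 65537L))
    refQ <- membershipMatrix(an$ensembles[[as.character(an$bestK)]])
    grouping <- .strongGrouping(refQ, config$strongQ)
    reference <- list(analysis = an, Q = refQ, grouping = grouping)
  }
  refK <- reference$analysis$bestK
  dp <- stats::setNames(markerStatsTable(table)$DP, lociNames(table))
  fstCrit <- perLocusFstRanking(table, reference$grouping)
  fstCrit[is.na(fstCrit)] <- 0
  lg <- markerInfo(table)
  grid <- expand.grid(criterion = c("DP", "FST"),
                      scenario = c("most", "least"),
                      size = sizes, stringsAsFactors = FALSE)
  cellSeeds <- spawnSeeds(config$seed, nrow(grid), stream = 131071L)
  records <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    crit <- if (grid$criterion[g] == "DP") dp else fstCrit
    loci <- chooseMarkerSet(crit, lg, grid$scenario[g], grid$size[g])
    sub <- table[, loci]
    an <- .analyseSubset(sub, config, cellSeeds[g])
    Q <- membershipMatrix(an$ensembles[[as.character(an$bestK)]])
    ms <- membershipSummaries(Q, config$strongQ)
    Kd <- as.character(refK)
    D <- fracAll <- fracStrong <- NA_real_
    if (!is.null(an$ensembles[[Kd]])) {
      Qk <- membershipMatrix(an$ensembles[[Kd]])
      D <- stabilityIndex(reference$Q, Qk)$D
      rr <- reassignmentReport(reference$Q, Qk, config$strongQ)
      fracAll <- rr$fracChangedAll
      fracStrong <- rr$fracChangedStrong
    }
    records[[g]] <- list(criterion = grid$criterion[g],
                         scenario = grid$scenario[g], size = grid$size[g],
                         loci = loci, bestK = an$bestK, deltaK = an$deltaK,
                         Qm = ms$Qm, propStrong = ms$propStrong,
                         D_vs_full = D, fracChangedAll = fracAll,
                         fracChangedStrong = fracStrong,
                         fst = if (an$bestK >= 2L) .strongFst(sub, Q, config))
  }
  summary <- data.frame(
    criterion = grid$criterion, scenario = grid$scenario, size = grid$size,
    bestK = vapply(records, function(r) as.numeric(r$bestK), numeric(1)),
    deltaK = vapply(records, `[[`, numeric(1), "deltaK"),
    Qm = vapply(records, `[[`, numeric(1), "Qm"),
    propStrong = vapply(records, `[[`, numeric(1), "propStrong"),
    D_vs_full = vapply(records, `[[`, numeric(1), "D_vs_full"),
    fracChangedAll = vapply(records, `[[`, numeric(1), "fracChangedAll"),
    fracChangedStrong = vapply(records, `[[`, numeric(1), "fracChangedStrong")
  )
  list(records = records, summary = summary, reference = reference)
}
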