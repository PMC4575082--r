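#' Align replicate runs and average memberships
#'
#' Cluster labels are arbitrary in each run (label switching). Taking the
#' first run as reference, every other run's columns are permuted by the
#' permutation minimising \eqn{\sum_i \sum_k (q_{ik} - q^{ref}_{ik})^2},
#' found exactly by optimal assignment on the K x K column-distance matrix
#' (Hungarian algorithm); the aligned matrices are then averaged.
#'
#' @param runs list of [AdmixtureRun-class] objects with equal n and K.
#' @return an [AdmixtureEnsemble-class].
#' @export
alignRuns <- function(runs) {
  if (length(runs) < 1L) stop("need at least one run")
  Qs <- lapply(runs, membershipMatrix)
  n <- nrow(Qs[[1L]]); K <- ncol(Qs[[1L]])
  if (!all(vapply(Qs, function(q) nrow(q) == n && ncol(q) == K, logical(1))))
    stop("all runs must share the same n and K")
  ref <- Qs[[1L]]
  alignment <- vector("list", length(runs))
  alignment[[1L]] <- seq_len(K)
  acc <- ref
  if (length(runs) > 1L) for (r in 2:length(runs)) {
    perm <- .alignPermutation(ref, Qs[[r]])
    alignment[[r]] <- perm
    aligned <- Qs[[r]]
    aligned[, perm] <- Qs[[r]]
    acc <- acc + aligned
  }
  meanQ <- acc / length(runs)
  dimnames(meanQ) <- dimnames(ref)
  L <- vapply(runs, slot, numeric(1), "lnProbData")
  new("AdmixtureEnsemble", K = as.integer(K), runs = runs,
      alignment = alignment, meanQ = meanQ,
      meanL = mean(L), sdL = if (length(L) > 1L) stats::sd(L) else 0)
}

#' Replicate-run ensembles over a sweep of K
#'
#' Runs the sampler \code{runsPerK} times for each K in \code{kValues}
#' (seeds spawned deterministically from \code{seed}) and aligns each
#' ensemble.
#'
#' @param table a [GenotypeTable-class].
#' @param kValues integer vector of K values (default 1:10, so the Evanno
#'   statistic is defined at K = 2).
#' @param runsPerK replicate runs per K (default 10).
#' @param seed master seed.
#' @param ... further arguments to [modelConfig()] (burnIn, iterations,
#'   mode, ...).
#' @return named list of [AdmixtureEnsemble-class], one per K.
#' @export
runEnsembles <- function(table, kValues = 1:10, runsPerK = 10L, seed = 1L,
                         ...) {
  out <- vector("list", length(kValues))
  names(out) <- as.character(kValues)
  for (j in seq_along(kValues)) {
    K <- kValues[j]
    seeds <- spawnSeeds(seed, runsPerK, stream = K)
    runs <- lapply(seeds, function(s)
      runAdmixture(table, modelConfig(K = K, seed = s, ...)))
    out[[j]] <- alignRuns(runs)
  }
  out
}

#' Evanno delta-K table
#'
#' From the per-K mean and sd of the model-evidence estimates L(K) over
#' replicate runs, computes the successive differences
#' \eqn{L'(K) = \bar L(K) - \bar L(K-1)}, the absolute second differences
#' \eqn{|L''(K)| = |\bar L(K+1) - 2\bar L(K) + \bar L(K-1)|}, and
#' \eqn{\Delta K = |L''(K)| / sd(L(K))}. Rows exist only for interior K;
#' an interior K with \code{sdL = 0} yields an \code{NA} delta-K (reported,
#' not fatal).
#'
#' @param ensembles list of [AdmixtureEnsemble-class] over consecutive K
#'   values (at least 3), each with at least 2 runs.
#' @return data.frame with columns \code{K}, \code{meanL}, \code{sdL},
#'   \code{Lp}, \code{absLpp}, \code{deltaK} (one row per interior K).
#' @export
evannoTable <- function(ensembles) {
  Ks <- vapply(ensembles, slot, integer(1), "K")
  o <- order(Ks)
  Ks <- Ks[o]; ensembles <- ensembles[o]
  if (length(Ks) < 3L) stop("need at least three consecutive K values")
  if (!all(diff(Ks) == 1L)) stop("K values must be consecutive")
  if (any(vapply(ensembles, function(e) length(e@runs), integer(1)) < 2L))
    stop("need at least two runs per K for the Evanno statistic")
  meanL <- vapply(ensembles, slot, numeric(1), "meanL")
  sdL <- vapply(ensembles, slot, numeric(1), "sdL")
  interior <- 2:(length(Ks) - 1L)
  Lp <- meanL[interior] - meanL[interior - 1L]
  absLpp <- abs(meanL[interior + 1L] - 2 * meanL[interior] + meanL[interior - 1L])
  deltaK <- ifelse(sdL[interior] > 0, absLpp / sdL[interior], NA_real_)
  if (anyNA(deltaK))
    warning("delta-K undefined (sdL = 0) at K = ",
            paste(Ks[interior][is.na(deltaK)], collapse = ", "))
  data.frame(K = Ks[interior], meanL = meanL[interior], sdL = sdL[interior],
             Lp = Lp, absLpp = absLpp, deltaK = deltaK)
}

#' Best-supported K by the delta-K criterion
#'
#' Returns the K with the highest defined delta-K (the height being an
#' indicator of the strength of the structure signal); ties break toward
#' smaller K.
#'
#' @param evanno data.frame from [evannoTable()].
#' @return list with elements \code{K} and \code{deltaK}.
#' @export
bestK <- function(evanno) {
  ok <- which(!is.na(evanno$deltaK))
  if (length(ok) == 0L) stop("no defined delta-K rows")
  best <- ok[which.max(evanno$deltaK[ok])]
  list(K = evanno$K[best], deltaK = evanno$deltaK[best])
}

#' Membership summaries: mean assignment and strongly assigned fraction
#'
#' \code{Qm} is the mean over individuals of the largest membership
#' coefficient; \code{propStrong} is the fraction of individuals whose
#' largest membership reaches \code{threshold} (default convention 0.8),
#' and \code{strongIDs} names them.
#'
#' @param Q membership matrix (rows sum to 1), e.g. \code{meanQ} of an
#'   ensemble.
#' @param threshold strong-assignment threshold in (0, 1].
#' @return list with \code{Qm}, \code{propStrong}, \code{strongIDs},
#'   \code{assignment} (argmax cluster per individual).
#' @export
membershipSummaries <- function(Q, threshold = 0.8) {
  if (is.null(dim(Q)) || nrow(Q) == 0L) stop("empty membership matrix")
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  qmax <- apply(Q, 1L, max)
  strong <- qmax >= threshold
  ids <- rownames(Q)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(Q)))
  list(Qm = mean(qmax), propStrong = mean(strong), strongIDs = ids[strong],
       assignment = max.col(Q, ties.method = "first"))
}
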