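#' Simulation settings for synthetic SSR collections
#'
#' Parameters of the F-model generator used throughout the package's tests
#' and simulation studies. Population allele frequencies are correlated
#' Dirichlet perturbations of ancestral frequencies with drift parameter F,
#' matching the correlated-frequency worldview of Structure-type models, so
#' the configured F directly tunes the realized differentiation: F around
#' 0.10 emulates a major division of the germplasm, 0.06 a moderate one and
#' 0.03 a weak (but significant) sub-structure.
#'
#' @param KTrue number of source populations.
#' @param nPerPop individuals drawn per population.
#' @param F drift parameter in (0, 1); scalar or one value per population.
#' @param nLoci number of SSR loci.
#' @param allelesPerLocus distinct alleles per locus (>= 2).
#' @param ancestralConcentration Dirichlet concentration for ancestral
#'   frequencies.
#' @param admixtureFraction fraction of individuals whose ancestry q is drawn
#'   from Dirichlet(admixtureAlpha) instead of being a pure indicator.
#' @param admixtureAlpha Dirichlet parameter for admixed ancestries.
#' @param cloneFraction clonal duplicates emitted, as a fraction of founder
#'   count; clones copy the founder's genotype (and triploidy) under a new
#'   id.
#' @param triploidFraction probability a founder is triploid.
#' @param missingRate per-cell missingness probability.
#' @param nLinkageGroups linkage groups to spread loci over, round-robin
#'   (default: one group per locus, emulating a panel that covers all
#'   linkage groups).
#' @param alleleSizeStart,alleleSizeStep emitted allele labels are plausible
#'   fragment sizes \code{start + step * (0:(A-1))}.
#' @param seed RNG seed.
#' @return a validated list of class \code{"simConfig"}.
#' @export
simConfig <- function(KTrue = 3L, nPerPop = 50L, F = 0.15, nLoci = 12L,
                      allelesPerLocus = 10L, ancestralConcentration = 1.0,
                      admixtureFraction = 0, admixtureAlpha = 0.3,
                      cloneFraction = 0, triploidFraction = 0,
                      missingRate = 0, nLinkageGroups = nLoci,
                      alleleSizeStart = 100L, alleleSizeStep = 2L,
                      seed = 1L) {
  if (KTrue < 1L) stop("KTrue must be >= 1")
  if (nPerPop < 1L) stop("nPerPop must be >= 1")
  if (allelesPerLocus < 2L) stop("allelesPerLocus must be >= 2")
  rates <- c(admixtureFraction, cloneFraction, triploidFraction, missingRate)
  if (any(rates < 0 | rates > 1)) stop("rates must be in [0, 1]")
  if (any(F <= 0 | F >= 1)) stop("F must be in (0, 1)")
  if (length(F) == 1L) F <- rep(F, KTrue)
  if (length(F) != KTrue) stop("F must be scalar or length KTrue")
  structure(list(KTrue = as.integer(KTrue), nPerPop = as.integer(nPerPop),
                 F = F, nLoci = as.integer(nLoci),
                 allelesPerLocus = as.integer(allelesPerLocus),
                 ancestralConcentration = ancestralConcentration,
                 admixtureFraction = admixtureFraction,
                 admixtureAlpha = admixtureAlpha,
                 cloneFraction = cloneFraction,
                 triploidFraction = triploidFraction,
                 missingRate = missingRate,
                 nLinkageGroups = as.integer(nLinkageGroups),
                 alleleSizeStart = as.integer(alleleSizeStart),
                 alleleSizeStep = as.integer(alleleSizeStep),
                 seed = as.integer(seed)),
            class = "simConfig")
}

#' Simulate an SSR germplasm collection with known truth
#'
#' F-model generator: per locus, ancestral allele frequencies are drawn from
#' a symmetric Dirichlet; population k's frequencies from
#' Dirichlet(p_anc * (1 - F_k) / F_k). Non-admixed individuals have an
#' indicator ancestry vector; admixed ones draw q from a symmetric
#' Dirichlet. Each allele copy picks a source population from q, then an
#' allele from that population's frequencies. Clonal duplicates repeat a
#' founder's complete genotype under a new id; triploids carry three copies;
#' per-cell missingness erases emitted calls (the truth keeps the complete
#' genotype). Deterministic under the configured seed.
#'
#' @param config a [simConfig()].
#' @return list with \code{table} (a [GenotypeTable-class]) and \code{truth}
#'   (list: \code{trueQ}, \code{popFreqs}, \code{ancestralFreqs},
#'   \code{popAssign}, \code{cloneMap}, \code{completeCalls},
#'   \code{founderIDs}).
#' @examples
#' sim <- simulateCollection(simConfig(KTrue = 2, nPerPop = 5, nLoci = 3,
#'                                     seed = 7))
#' sim$table
#' @export
simulateCollection <- function(config) {
  stopifnot(inherits(config, "simConfig"))
  set.seed(config$seed)
  K <- config$KTrue
  A <- config$allelesPerLocus
  L <- config$nLoci
  sizes <- config$alleleSizeStart + config$alleleSizeStep * (seq_len(A) - 1L)

  anc <- .rdirichlet(L, rep(config$ancestralConcentration, A))  # L x A
  popFreqs <- vector("list", L)
  for (l in seq_len(L)) {
    pf <- matrix(0, K, A)
    for (k in seq_len(K)) {
      fk <- config$F[k]
      pf[k, ] <- .rdirichlet(1L, anc[l, ] * (1 - fk) / fk)
    }
    colnames(pf) <- as.character(sizes)
    popFreqs[[l]] <- pf
  }

  nF <- K * config$nPerPop
  popAssign <- rep(seq_len(K), each = config$nPerPop)
  admixed <- stats::runif(nF) < config$admixtureFraction
  trueQ <- matrix(0, nF, K)
  trueQ[cbind(seq_len(nF), popAssign)] <- 1
  if (any(admixed))
    trueQ[admixed, ] <- .rdirichlet(sum(admixed), rep(config$admixtureAlpha, K))
  pl <- ifelse(stats::runif(nF) < config$triploidFraction, 3L, 2L)

  complete <- matrix(vector("list", nF * L), nF, L)
  for (i in seq_len(nF)) {
    src <- sample.int(K, pl[i] * L, replace = TRUE, prob = trueQ[i, ])
    src <- matrix(src, pl[i], L)
    for (l in seq_len(L)) {
      a <- vapply(src[, l], function(k)
        sample.int(A, 1L, prob = popFreqs[[l]][k, ]), integer(1))
      complete[[i, l]] <- sort(sizes[a])
    }
  }

  nC <- round(config$cloneFraction * nF)
  founderIDs <- sprintf("ind%03d", seq_len(nF))
  cloneOf <- if (nC > 0L) sample.int(nF, nC, replace = TRUE) else integer(0)
  ids <- c(founderIDs, sprintf("clone%03d", seq_len(nC)))
  allRows <- c(seq_len(nF), cloneOf)
  calls <- complete[allRows, , drop = FALSE]
  plAll <- pl[allRows]
  trueQAll <- trueQ[allRows, , drop = FALSE]
  popAll <- popAssign[allRows]

  if (config$missingRate > 0) {
    drop <- stats::runif(length(calls)) < config$missingRate
    calls[drop] <- list(integer(0))
  }

  lg <- paste0("LG", rep_len(seq_len(config$nLinkageGroups), L))
  markers <- data.frame(name = sprintf("ssr%02d", seq_len(L)),
                        linkage_group = lg, stringsAsFactors = FALSE)
  dimnames(calls) <- list(ids, markers$name)
  tab <- GenotypeTable(calls, ids = ids, ploidy = plAll, markers = markers)
  rownames(trueQAll) <- ids
  names(popFreqs) <- markers$name
  truth <- list(trueQ = trueQAll,
                popFreqs = popFreqs,
                ancestralFreqs = anc,
                popAssign = stats::setNames(popAll, ids),
                cloneMap = stats::setNames(founderIDs[cloneOf],
                                           ids[nF + seq_len(nC)]),
                completeCalls = complete,
                founderIDs = founderIDs)
  list(table = tab, truth = truth)
}

#' Assignment accuracy of an inferred membership matrix against truth
#'
#' Aligns the inferred clusters to the true populations by optimal
#' assignment (padding if K differs) and returns the fraction of
#' individuals whose modal inferred cluster matches their true source
#' population.
#'
#' @param Q inferred membership matrix.
#' @param truth the truth component of [simulateCollection()].
#' @return accuracy in [0, 1].
#' @export
assignmentAccuracy <- function(Q, truth) {
  trueQ <- truth$trueQ
  st <- stabilityIndex(trueQ, Q)
  perm <- st$alignmentPermutation
  K <- max(ncol(Q), ncol(trueQ))
  Qp <- cbind(Q, matrix(0, nrow(Q), K - ncol(Q)))
  aligned <- Qp
  aligned[, perm] <- Qp
  mean(max.col(aligned, ties.method = "first") == truth$popAssign)
}
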