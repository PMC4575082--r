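#' Admixture model configuration
#'
#' Settings for one Structure-type Gibbs-sampler run. Defaults use the
#' scaled-down sweep counts suitable for testing and simulation studies
#' (2e3 burn-in, 5e3 recorded); the full-scale settings used for real
#' germplasm analyses (7.5e4 burn-in, 2e5 recorded) can be requested
#' explicitly.
#'
#' @param K number of clusters (>= 1).
#' @param burnIn discarded sweeps.
#' @param iterations recorded sweeps.
#' @param alpha admixture Dirichlet parameter (initial value if
#'   \code{updateAlpha}).
#' @param lambda allele-frequency Dirichlet parameter.
#' @param seed RNG seed for the run.
#' @param mode \code{"unsupervised"} or \code{"popflag"} (flagged individuals
#'   act as pure training members of their labelled population).
#' @param updateAlpha if \code{TRUE} (the default, mirroring Structure's
#'   inferred-alpha behaviour), alpha is given a Metropolis update with a
#'   uniform prior on \code{(0, alphaMax)}; inferring alpha sharpens the
#'   evidence curve markedly when individuals are nearly unadmixed.
#' @param alphaPropSD,alphaMax Metropolis proposal sd and prior upper bound.
#' @return a validated list of class \code{"modelConfig"}.
#' @export
modelConfig <- function(K, burnIn = 2000L, iterations = 5000L, alpha = 0.5,
                        lambda = 1.0, seed = 1L,
                        mode = c("unsupervised", "popflag"),
                        updateAlpha = TRUE, alphaPropSD = 0.05,
                        alphaMax = 10) {
  mode <- match.arg(mode)
  if (K < 1L) stop("K must be >= 1")
  if (burnIn < 1L || iterations < 1L) stop("burnIn and iterations must be > 0")
  if (alpha <= 0 || lambda <= 0) stop("alpha and lambda must be > 0")
  structure(list(K = as.integer(K), burnIn = as.integer(burnIn),
                 iterations = as.integer(iterations), alpha = alpha,
                 lambda = lambda, seed = as.integer(seed), mode = mode,
                 updateAlpha = updateAlpha, alphaPropSD = alphaPropSD,
                 alphaMax = alphaMax),
            class = "modelConfig")
}

# Flatten observed allele copies to index vectors for the C++ sampler.
# Allele levels per locus are the sorted distinct sizes present in the table.
.copyData <- function(table) {
  n <- nInd(table)
  m <- nLoci(table)
  levels <- vector("list", m)
  ci <- cl <- ca <- vector("list", m)
  for (l in seq_len(m)) {
    cells <- table@calls[, l]
    lens <- lengths(cells)
    levels[[l]] <- sort(unique(unlist(cells)))
    if (length(levels[[l]]) == 0L) levels[[l]] <- integer(1)  # placeholder
    ci[[l]] <- rep(seq_len(n) - 1L, lens)
    cl[[l]] <- rep(l - 1L, sum(lens))
    ca[[l]] <- match(unlist(cells), levels[[l]]) - 1L
  }
  list(copy_ind = as.integer(unlist(ci)),
       copy_loc = as.integer(unlist(cl)),
       copy_allele = as.integer(unlist(ca)),
       n_alleles = vapply(levels, length, integer(1)),
       levels = levels)
}

#' Run the admixture Gibbs sampler
#'
#' Bayesian admixture inference for multi-allelic SSR genotypes of mixed
#' ploidy. Each observed allele copy carries a latent cluster assignment z;
#' the sampler iterates z | p,q (categorical, proportional to
#' \eqn{q_{ik} p_k(allele)}), p | z (Dirichlet(lambda + counts) per cluster
#' and locus), q | z (Dirichlet(alpha + per-individual counts)). Missing
#' copies are skipped, so dosage-ambiguous cells contribute only their
#' observed copies (unobserved copies are treated as missing at random).
#' The model evidence L(K) is estimated as mean(lnL) - var(lnL)/2 over the
#' recorded trace. Identical seed and input give identical results.
#'
#' In popflag mode, individuals with \code{popFlag = TRUE} are pinned to
#' their labelled population: their copies always originate from that
#' cluster and their membership row is the indicator vector, so they act as
#' training data for the unflagged individuals.
#'
#' @param table a [GenotypeTable-class] with at least one individual.
#' @param config a [modelConfig()].
#' @return an [AdmixtureRun-class].
#' @export
runAdmixture <- function(table, config) {
  stopifnot(inherits(config, "modelConfig"))
  n <- nInd(table)
  if (n == 0L) stop("empty table")
  flag <- rep(-1L, n)
  if (config$mode == "popflag") {
    flagged <- popFlags(table)
    if (!any(flagged)) stop("popflag mode requires at least one flagged individual")
    labs <- sort(unique(popLabels(table)[flagged]))
    if (length(labs) > config$K)
      stop("more flagged population labels (", length(labs),
           ") than clusters K = ", config$K)
    flag[flagged] <- match(popLabels(table)[flagged], labs) - 1L
  } else {
    labs <- NULL
  }
  cd <- .copyData(table)
  fit <- gibbs_admixture(cd$copy_ind, cd$copy_loc, cd$copy_allele,
                         n, nLoci(table), cd$n_alleles, config$K, flag,
                         config$alpha, config$lambda, config$burnIn,
                         config$iterations, config$updateAlpha,
                         config$alphaPropSD, config$alphaMax, config$seed)
  Q <- fit$Q
  rownames(Q) <- indIDs(table)
  if (!is.null(labs) && length(labs)) {
    colnames(Q) <- c(labs, rep(NA_character_,
                               config$K - length(labs)))[seq_len(config$K)]
  }
  P <- fit$P
  names(P) <- lociNames(table)
  for (l in seq_along(P)) colnames(P[[l]]) <- as.character(cd$levels[[l]])
  trace <- as.numeric(fit$lnL)
  v <- if (length(trace) > 1L) stats::var(trace) else 0
  new("AdmixtureRun", Q = Q, P = P, lnLTrace = trace,
      lnProbData = mean(trace) - v / 2, seed = config$seed,
      config = unclass(config))
}

#' Admixture log-likelihood of a (Q, P) state
#'
#' Sum over all observed allele copies of \eqn{\log \sum_k q_{ik}
#' p_k(allele)}; always \eqn{\le 0}. Probabilities below \code{eps} are
#' floored (and the flooring is reported via a warning), so alleles with
#' zero probability under every cluster cannot produce \code{-Inf}.
#'
#' @param table a [GenotypeTable-class].
#' @param Q membership matrix (individuals x K).
#' @param P list of per-locus K x n_alleles frequency matrices with allele
#'   labels as column names (as in [AdmixtureRun-class]).
#' @param eps probability floor.
#' @return scalar log-likelihood.
#' @export
logLikelihood <- function(table, Q, P, eps = 1e-300) {
  if (nrow(Q) != nInd(table)) stop("Q rows must match individuals")
  if (length(P) != nLoci(table)) stop("P must have one matrix per locus")
  cd <- .copyData(table)
  # remap copy allele indices to each P matrix's column order
  Pm <- vector("list", length(P))
  for (l in seq_along(P)) {
    lev <- as.character(cd$levels[[l]])
    if (!all(lev %in% colnames(P[[l]]))) {
      # allele absent from P: append zero columns (floored by eps downstream)
      miss <- setdiff(lev, colnames(P[[l]]))
      add <- matrix(0, nrow(P[[l]]), length(miss), dimnames = list(NULL, miss))
      P[[l]] <- cbind(P[[l]], add)
      warning("allele(s) absent from P at locus ", l,
              "; probability floored at eps")
    }
    Pm[[l]] <- P[[l]][, lev, drop = FALSE]
  }
  admixture_loglik(cd$copy_ind, cd$copy_loc, cd$copy_allele, Q, Pm, eps)
}
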