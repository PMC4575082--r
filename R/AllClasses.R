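#' @import methods
NULL

#' SSR genotype collection
#'
#' Container for a germplasm collection genotyped at multi-allelic codominant
#' SSR loci. Each cell holds the unordered multiset of allele sizes (bp)
#' observed for one individual at one locus; a cell may hold fewer copies than
#' the individual's ploidy (dosage-ambiguous or partially missing call) or be
#' empty (missing). Individuals are diploid or triploid. Optional per-individual
#' population flags mark prior population information for supervised admixture
#' runs.
#'
#' @slot ids character vector of unique accession identifiers, in input order.
#' @slot ploidy integer vector (2 or 3), parallel to \code{ids}.
#' @slot popLabel character vector of population labels (\code{NA} when unset).
#' @slot popFlag logical vector; \code{TRUE} marks the label as prior
#'   information (the PopFlag convention).
#' @slot markerInfo data.frame with columns \code{name} (unique locus
#'   identifier) and \code{linkage_group} (non-empty chromosome/linkage-group
#'   label); optional \code{size_min}, \code{size_max}.
#' @slot calls a list-mode matrix (individuals x loci); each element is a
#'   sorted integer vector of allele sizes, length between 0 and the
#'   individual's ploidy.
#'
#' @seealso [GenotypeTable()] for the constructor,
#'   [readGenotypeTable()] for file input.
#' @export
setClass("GenotypeTable",
  representation(
    ids = "character",
    ploidy = "integer",
    popLabel = "character",
    popFlag = "logical",
    markerInfo = "data.frame",
    calls = "matrix"
  )
)

setValidity("GenotypeTable", function(object) {
  msg <- character()
  n <- length(object@ids)
  m <- nrow(object@markerInfo)
  if (anyDuplicated(object@ids)) {
    msg <- c(msg, sprintf("duplicate individual id: %s",
                          object@ids[duplicated(object@ids)][1L]))
  }
  if (length(object@ploidy) != n || !all(object@ploidy %in% c(2L, 3L)))
    msg <- c(msg, "ploidy must be 2 or 3 for every individual")
  if (length(object@popLabel) != n || length(object@popFlag) != n)
    msg <- c(msg, "popLabel/popFlag must be parallel to ids")
  if (any(object@popFlag & is.na(object@popLabel)))
    msg <- c(msg, "popFlag set without a population label")
  if (!all(c("name", "linkage_group") %in% names(object@markerInfo)))
    msg <- c(msg, "markerInfo needs columns 'name' and 'linkage_group'")
  else {
    if (anyDuplicated(object@markerInfo$name))
      msg <- c(msg, "duplicate marker name")
    lg <- as.character(object@markerInfo$linkage_group)
    if (any(is.na(lg) | !nzchar(lg)))
      msg <- c(msg, "linkage_group must be non-empty for every marker")
  }
  if (!is.list(object@calls) || !identical(dim(object@calls), c(n, m))) {
    msg <- c(msg, "calls must be an individuals x loci list-matrix")
  } else if (n > 0L && m > 0L) {
    len <- matrix(lengths(object@calls), n, m)
    if (any(len > object@ploidy))
      msg <- c(msg, "a cell holds more allele copies than the individual's ploidy")
    ok <- vapply(object@calls, function(a) {
      is.numeric(a) && !anyNA(a) && all(a > 0) && all(a == floor(a))
    }, logical(1))
    if (!all(ok))
      msg <- c(msg, "allele labels must be positive integers")
  }
  if (length(msg)) msg else TRUE
})

#' One Structure-type admixture run
#'
#' Posterior summaries of a single Gibbs-sampler run: the posterior-mean
#' membership matrix Q (individuals x clusters), posterior-mean cluster allele
#' frequencies per locus, the recorded log-likelihood trace, and the
#' mean-minus-half-variance model-evidence estimate ln Pr(X|K).
#'
#' @slot Q numeric matrix, rows sum to 1.
#' @slot P list (one element per locus) of K x n_alleles frequency matrices
#'   with allele labels as column names.
#' @slot lnLTrace numeric vector, one entry per recorded sweep.
#' @slot lnProbData scalar model-evidence estimate L(K).
#' @slot seed integer seed the run was launched with.
#' @slot config list echo of the model configuration.
#' @export
setClass("AdmixtureRun",
  representation(
    Q = "matrix",
    P = "list",
    lnLTrace = "numeric",
    lnProbData = "numeric",
    seed = "integer",
    config = "list"
  )
)

setValidity("AdmixtureRun", function(object) {
  msg <- character()
  if (nrow(object@Q) > 0) {
    rs <- rowSums(object@Q)
    if (max(abs(rs - 1)) > 1e-9)
      msg <- c(msg, "rows of Q must sum to 1 (tolerance 1e-9)")
  }
  if (!is.finite(object@lnProbData))
    msg <- c(msg, "lnProbData must be finite")
  if (length(msg)) msg else TRUE
})

#' Aligned multi-run ensemble for one K
#'
#' Replicate admixture runs at a common K, label-aligned to the first run by
#' exact optimal assignment, with the averaged membership matrix and the
#' mean/sd of the per-run model-evidence estimates (the ingredients of the
#' Evanno delta-K statistic).
#'
#' @slot K integer number of clusters.
#' @slot runs list of [AdmixtureRun-class] objects.
#' @slot alignment list of integer column permutations (one per run;
#'   \code{alignment[[r]][k]} is the reference column that run r's column k
#'   maps to).
#' @slot meanQ averaged aligned membership matrix.
#' @slot meanL,sdL mean and standard deviation of \code{lnProbData} across runs.
#' @export
setClass("AdmixtureEnsemble",
  representation(
    K = "integer",
    runs = "list",
    alignment = "list",
    meanQ = "matrix",
    meanL = "numeric",
    sdL = "numeric"
  )
)

setValidity("AdmixtureEnsemble", function(object) {
  msg <- character()
  if (length(object@runs) < 1L) msg <- c(msg, "at least one run required")
  if (nrow(object@meanQ) > 0) {
    rs <- rowSums(object@meanQ)
    if (max(abs(rs - 1)) > 1e-8)
      msg <- c(msg, "rows of meanQ must sum to 1")
  }
  if (object@sdL < 0) msg <- c(msg, "sdL must be >= 0")
  if (length(msg)) msg else TRUE
})
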