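#' Construct a GenotypeTable
#'
#' @param calls list-matrix (individuals x loci) of integer allele-size
#'   vectors, or a list of per-individual lists; cells may be empty
#'   (missing call). Cells are sorted on construction so a cell is an
#'   unordered multiset.
#' @param ids character vector of accession identifiers (default from
#'   rownames).
#' @param ploidy integer vector, 2 or 3 per individual (default 2).
#' @param markers data.frame with columns \code{name} and
#'   \code{linkage_group}; default gives each locus its own linkage group
#'   named after itself.
#' @param popLabel,popFlag optional prior-population information per
#'   individual.
#' @return a validated [GenotypeTable-class].
#' @examples
#' gt <- GenotypeTable(
#'   calls = list(ind1 = list(locA = c(100L, 104L)),
#'                ind2 = list(locA = integer(0))),
#'   ploidy = c(2L, 2L)
#' )
#' nInd(gt)
#' @export
GenotypeTable <- function(calls, ids = NULL, ploidy = NULL, markers = NULL,
                          popLabel = NULL, popFlag = NULL) {
  if (is.list(calls) && !is.matrix(calls)) {
    # list of individuals, each a named list of loci
    loci <- unique(unlist(lapply(calls, names)))
    if (is.null(ids)) ids <- names(calls)
    mat <- matrix(vector("list", length(calls) * length(loci)),
                  length(calls), length(loci),
                  dimnames = list(ids, loci))
    for (i in seq_along(calls)) for (l in loci) {
      cell <- calls[[i]][[l]]
      mat[[i, l]] <- if (is.null(cell)) integer(0) else as.integer(cell)
    }
    calls <- mat
  }
  n <- nrow(calls)
  m <- ncol(calls)
  if (is.null(ids)) ids <- rownames(calls)
  if (is.null(ids)) ids <- paste0("ind", seq_len(n))
  if (is.null(ploidy)) ploidy <- rep(2L, n)
  if (length(ploidy) == 1L) ploidy <- rep(as.integer(ploidy), n)
  if (is.null(markers)) {
    loci <- colnames(calls)
    if (is.null(loci)) loci <- paste0("loc", seq_len(m))
    markers <- data.frame(name = loci, linkage_group = loci,
                          stringsAsFactors = FALSE)
  }
  if (is.null(popLabel)) popLabel <- rep(NA_character_, n)
  if (is.null(popFlag)) popFlag <- rep(FALSE, n)
  calls[] <- lapply(calls, function(a) sort(as.integer(a)))
  dimnames(calls) <- list(ids, markers$name)
  new("GenotypeTable",
      ids = as.character(ids), ploidy = as.integer(ploidy),
      popLabel = as.character(popLabel), popFlag = as.logical(popFlag),
      markerInfo = markers, calls = calls)
}

#' @rdname GenotypeTable
#' @param x,object a \code{GenotypeTable}.
#' @export
setGeneric("nInd", function(x) standardGeneric("nInd"))

#' @rdname GenotypeTable
#' @export
setGeneric("nLoci", function(x) standardGeneric("nLoci"))

#' @rdname GenotypeTable
#' @export
setGeneric("indIDs", function(x) standardGeneric("indIDs"))

#' @rdname GenotypeTable
#' @export
setGeneric("lociNames", function(x) standardGeneric("lociNames"))

#' @rdname GenotypeTable
#' @export
setGeneric("ploidy", function(x) standardGeneric("ploidy"))

#' @rdname GenotypeTable
#' @export
setGeneric("markerInfo", function(x) standardGeneric("markerInfo"))

#' @rdname GenotypeTable
#' @export
setGeneric("genotypeCalls", function(x, ...) standardGeneric("genotypeCalls"))

#' @rdname GenotypeTable
#' @export
setGeneric("popLabels", function(x) standardGeneric("popLabels"))

#' @rdname GenotypeTable
#' @export
setGeneric("popFlags", function(x) standardGeneric("popFlags"))

#' @rdname GenotypeTable
#' @param value replacement value.
#' @export
setGeneric("popInfo<-", function(x, value) standardGeneric("popInfo<-"))

setMethod("nInd", "GenotypeTable", function(x) length(x@ids))
setMethod("nLoci", "GenotypeTable", function(x) nrow(x@markerInfo))
setMethod("indIDs", "GenotypeTable", function(x) x@ids)
setMethod("lociNames", "GenotypeTable", function(x) x@markerInfo$name)
setMethod("ploidy", "GenotypeTable", function(x) x@ploidy)
setMethod("markerInfo", "GenotypeTable", function(x) x@markerInfo)
setMethod("popLabels", "GenotypeTable", function(x) x@popLabel)
setMethod("popFlags", "GenotypeTable", function(x) x@popFlag)

#' @rdname GenotypeTable
#' @param locus optional locus name; if given, returns the list of cells for
#'   that locus, else the full list-matrix.
#' @export
setMethod("genotypeCalls", "GenotypeTable", function(x, locus = NULL) {
  if (is.null(locus)) return(x@calls)
  if (!locus %in% x@markerInfo$name)
    stop("unknown locus: ", locus)
  x@calls[, locus]
})

#' @rdname GenotypeTable
#' @export
setMethod("popInfo<-", "GenotypeTable", function(x, value) {
  stopifnot(is.data.frame(value), all(c("label", "flag") %in% names(value)))
  x@popLabel <- as.character(value$label)
  x@popFlag <- as.logical(value$flag)
  validObject(x)
  x
})

#' @rdname GenotypeTable
#' @param i,j individual / locus indices (numeric, logical or names).
#' @param drop ignored.
#' @param ... unused.
#' @export
setMethod("[", "GenotypeTable", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nInd(x))
  if (missing(j)) j <- seq_len(nLoci(x))
  if (is.character(i)) i <- match(i, x@ids)
  if (is.character(j)) j <- match(j, x@markerInfo$name)
  if (anyNA(i) || anyNA(j)) stop("unknown individual or locus name in subset")
  new("GenotypeTable",
      ids = x@ids[i], ploidy = x@ploidy[i],
      popLabel = x@popLabel[i], popFlag = x@popFlag[i],
      markerInfo = x@markerInfo[j, , drop = FALSE],
      calls = x@calls[i, j, drop = FALSE])
})

setMethod("show", "GenotypeTable", function(object) {
  miss <- if (length(object@calls)) {
    mean(lengths(object@calls) == 0)
  } else NA_real_
  cat("GenotypeTable with", nInd(object), "individuals x",
      nLoci(object), "SSR loci\n")
  cat("  ploidy:", paste(names(table(object@ploidy)),
                         table(object@ploidy), sep = "n=", collapse = ", "),
      "\n")
  cat("  linkage groups:",
      length(unique(object@markerInfo$linkage_group)), "\n")
  if (!is.na(miss)) cat(sprintf("  missing cells: %.1f%%\n", 100 * miss))
  if (any(object@popFlag))
    cat("  flagged individuals (PopFlag=1):", sum(object@popFlag), "\n")
  invisible(NULL)
})

setMethod("show", "AdmixtureRun", function(object) {
  cat("AdmixtureRun: n =", nrow(object@Q), ", K =", ncol(object@Q),
      ", recorded sweeps =", length(object@lnLTrace), "\n")
  cat(sprintf("  ln Pr(X|K) = %.2f  (seed %d)\n",
              object@lnProbData, object@seed))
  invisible(NULL)
})

setMethod("show", "AdmixtureEnsemble", function(object) {
  cat("AdmixtureEnsemble: K =", object@K, "over", length(object@runs),
      "aligned runs\n")
  cat(sprintf("  mean L(K) = %.2f, sd = %.3f\n", object@meanL, object@sdL))
  invisible(NULL)
})

#' Accessors for admixture results
#'
#' \code{membershipMatrix} returns the posterior-mean membership matrix Q of a
#' run, or the aligned, run-averaged matrix of an ensemble.
#' \code{logEvidence} returns the model-evidence estimate(s) L(K).
#'
#' @param x an [AdmixtureRun-class] or [AdmixtureEnsemble-class].
#' @export
setGeneric("membershipMatrix", function(x) standardGeneric("membershipMatrix"))

#' @rdname membershipMatrix
#' @export
setGeneric("logEvidence", function(x) standardGeneric("logEvidence"))

setMethod("membershipMatrix", "AdmixtureRun", function(x) x@Q)
setMethod("membershipMatrix", "AdmixtureEnsemble", function(x) x@meanQ)
setMethod("logEvidence", "AdmixtureRun", function(x) x@lnProbData)
setMethod("logEvidence", "AdmixtureEnsemble",
          function(x) vapply(x@runs, slot, numeric(1), "lnProbData"))
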