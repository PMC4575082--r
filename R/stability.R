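#' Cross-analysis assignment stability
#'
#' Compares the membership matrices of the same genotypes from two structure
#' analyses (e.g. different marker sets). Columns of \code{Qb} are first
#' aligned to \code{Qa} by exact optimal assignment (as in [alignRuns()]).
#' The per-genotype stability is the root-mean-square membership discrepancy
#' \deqn{D_i = \sqrt{\sum_k (q_{ik} - q'_{ik})^2 / K}}
#' and the average similarity between analyses is \eqn{D = 1 - \frac1n \sum_i
#' D_i}, a value in [0, 1] (1 = identical assignments). The printed form of
#' the index is also available without the square root
#' (\code{convention = "squared"}); both keep D in [0, 1].
#'
#' If the two analyses used different K, the narrower matrix is padded with
#' zero columns before alignment and the result is flagged
#' (\code{padded = TRUE}); the main use compares analyses at a common K.
#'
#' @param Qa,Qb membership matrices over the same individuals (rows sum
#'   to 1).
#' @param convention \code{"rms"} (default) or \code{"squared"}.
#' @return list with \code{perGenotype} (named D_i vector), \code{D},
#'   \code{alignmentPermutation}, \code{n}, \code{padded}.
#' @examples
#' Qa <- matrix(c(1, 0, 0, 1), 2, byrow = TRUE)
#' stabilityIndex(Qa, Qa)$D            # 1: identical analyses
#' stabilityIndex(Qa, Qa[, 2:1])$D     # 1: label switching is aligned away
#' @export
stabilityIndex <- function(Qa, Qb, convention = c("rms", "squared")) {
  convention <- match.arg(convention)
  if (nrow(Qa) != nrow(Qb)) stop("different individual sets")
  if (!is.null(rownames(Qa)) && !is.null(rownames(Qb)) &&
      !identical(rownames(Qa), rownames(Qb)))
    stop("different individual sets (row names disagree)")
  padded <- FALSE
  if (ncol(Qa) != ncol(Qb)) {
    padded <- TRUE
    K <- max(ncol(Qa), ncol(Qb))
    pad <- function(Q) cbind(Q, matrix(0, nrow(Q), K - ncol(Q)))
    Qa <- pad(Qa); Qb <- pad(Qb)
  }
  K <- ncol(Qa)
  # The aligned permutation minimises the summed per-genotype discrepancy
  # itself. Under the squared convention that is an assignment problem; under
  # the RMS convention the square root couples columns, so the optimum is
  # found by enumeration for the K range in practical use, with the
  # assignment solution as fallback for very large K.
  diFor <- function(perm) {
    aligned <- Qb
    aligned[, perm] <- Qb
    d2 <- rowSums((Qa - aligned)^2) / K
    if (convention == "rms") sqrt(d2) else d2
  }
  if (convention == "rms" && K <= 7L) {
    perms <- .permutations(K)
    sums <- vapply(perms, function(p) sum(diFor(p)), numeric(1))
    perm <- perms[[which.min(sums)]]
  } else {
    perm <- .alignPermutation(Qa, Qb)
  }
  Di <- diFor(perm)
  names(Di) <- rownames(Qa)
  list(perGenotype = Di, D = 1 - mean(Di), alignmentPermutation = perm,
       n = nrow(Qa), padded = padded)
}

#' Reassignment report between two analyses
#'
#' After aligning \code{Qb} to \code{Qa}, reports the fraction of genotypes
#' whose modal cluster differs between the two analyses, over all genotypes
#' and restricted to the genotypes strongly assigned in \code{Qa}
#' (\eqn{\max_k q_{ik} \ge} \code{strongQ}). If no genotype is strong, the
#' strong fraction is 0 and \code{emptyStrong} is \code{TRUE}.
#'
#' @param Qa,Qb membership matrices over the same individuals.
#' @param strongQ strong-assignment threshold (default 0.8).
#' @return list with \code{fracChangedAll}, \code{fracChangedStrong},
#'   \code{emptyStrong}, \code{changedIDs}.
#' @export
reassignmentReport <- function(Qa, Qb, strongQ = 0.8) {
  st <- stabilityIndex(Qa, Qb)
  perm <- st$alignmentPermutation
  if (ncol(Qa) != ncol(Qb)) stop("reassignment report requires a common K")
  Qb_aligned <- Qb
  Qb_aligned[, perm] <- Qb
  a <- max.col(Qa, ties.method = "first")
  b <- max.col(Qb_aligned, ties.method = "first")
  changed <- a != b
  strong <- apply(Qa, 1L, max) >= strongQ
  ids <- rownames(Qa)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(Qa)))
  list(fracChangedAll = mean(changed),
       fracChangedStrong = if (any(strong)) mean(changed[strong]) else 0,
       emptyStrong = !any(strong),
       changedIDs = ids[changed])
}
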