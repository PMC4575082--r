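#' Banding-pattern spectrum of one locus
#'
#' The "banding pattern" of an individual at an SSR locus is the unordered
#' multiset of allele sizes it displays; dosage-ambiguous cells count as their
#' observed multiset. The spectrum tabulates pattern frequencies over all
#' scored (non-missing) individuals, the unit entering the discrimination
#' power formula.
#'
#' @param table a [GenotypeTable-class].
#' @param locus locus name.
#' @return list with \code{locus}, \code{patterns} (named integer vector;
#'   names are \code{/}-joined sorted allele multisets), \code{n_scored}.
#' @export
bandingPatterns <- function(table, locus) {
  cells <- genotypeCalls(table, locus)
  keys <- vapply(cells, .cellKey, character(1))
  keys <- keys[nzchar(keys)]
  counts <- base::table(keys)
  list(locus = locus,
       patterns = stats::setNames(as.integer(counts), names(counts)),
       n_scored = length(keys))
}

#' Discrimination power of a banding-pattern spectrum
#'
#' DP = 1 - sum_i p_i^2, where p_i is the frequency of the i-th banding
#' pattern among scored individuals: the probability that two individuals
#' drawn at random show different patterns at the locus. Bounded above by
#' 1 - 1/n_scored.
#'
#' @param spectrum result of [bandingPatterns()].
#' @return DP in \code{[0, 1 - 1/n_scored]}.
#' @examples
#' gt <- GenotypeTable(list(
#'   a = list(L = c(100L, 104L)), b = list(L = c(100L, 104L)),
#'   c = list(L = c(100L, 108L)), d = list(L = c(104L, 108L))))
#' discriminationPower(bandingPatterns(gt, "L"))  # 1 - (0.5^2+0.25^2+0.25^2)
#' @export
discriminationPower <- function(spectrum) {
  if (spectrum$n_scored == 0L)
    stop("discrimination power undefined: no scored individuals at locus ",
         spectrum$locus)
  p <- spectrum$patterns / spectrum$n_scored
  1 - sum(p^2)
}

#' Per-locus fingerprinting statistics
#'
#' Computes, for one locus: the number of distinct alleles, the effective
#' number of alleles (reciprocal of the sum of squared allele frequencies,
#' counted over allele copies), the number of distinct banding patterns, and
#' the discrimination power. Missing cells are excluded from \code{n_scored}.
#'
#' @param table a [GenotypeTable-class].
#' @param locus locus name.
#' @return one-row data.frame with columns \code{locus}, \code{DP},
#'   \code{n_alleles}, \code{effective_alleles}, \code{n_patterns},
#'   \code{n_scored}.
#' @export
markerStats <- function(table, locus) {
  spec <- bandingPatterns(table, locus)
  if (spec$n_scored == 0L)
    stop("all cells missing at locus ", locus)
  copies <- unlist(genotypeCalls(table, locus))
  af <- base::table(copies) / length(copies)
  data.frame(locus = locus,
             DP = discriminationPower(spec),
             n_alleles = length(af),
             effective_alleles = 1 / sum(af^2),
             n_patterns = length(spec$patterns),
             n_scored = spec$n_scored,
             stringsAsFactors = FALSE)
}

#' Fingerprinting statistics for every locus
#'
#' @param table a [GenotypeTable-class].
#' @return data.frame with one row per locus (see [markerStats()]).
#' @export
markerStatsTable <- function(table) {
  do.call(rbind, lapply(lociNames(table), function(l) markerStats(table, l)))
}

#' Cumulative discrimination along an ordered marker list
#'
#' Element t is the number of distinct multilocus profiles over the first t
#' loci, profiles compared as tuples of per-locus allele multisets (missing
#' cells compare equal only to missing). Non-decreasing; the last element is
#' at most the number of individuals.
#'
#' @param table a [GenotypeTable-class].
#' @param orderedLoci character vector of locus names, in inclusion order.
#' @return integer vector, one element per prefix length.
#' @export
cumulativeDiscrimination <- function(table, orderedLoci) {
  if (length(orderedLoci) == 0L) stop("orderedLoci must be non-empty")
  unknown <- setdiff(orderedLoci, lociNames(table))
  if (length(unknown)) stop("unknown locus name: ", unknown[1L])
  profile <- rep("", nInd(table))
  out <- integer(length(orderedLoci))
  for (t in seq_along(orderedLoci)) {
    keys <- vapply(genotypeCalls(table, orderedLoci[t]), .cellKey, character(1))
    profile <- paste(profile, keys, sep = "|")
    out[t] <- length(unique(profile))
  }
  out
}

#' Linkage-group-aware marker ordering
#'
#' Orders loci by a criterion (e.g. DP or per-locus F_ST) under the
#' round-robin linkage-group constraint: within a round no linkage group is
#' repeated, and a new round starts only once every group that still has
#' unused markers has been represented in the current round. Within
#' eligibility the highest criterion value goes first; ties break by locus
#' name, ascending.
#'
#' @param criterionValues named numeric vector, one value per locus.
#' @param linkageGroups named character vector mapping locus to linkage
#'   group, or a data.frame with columns \code{name}, \code{linkage_group}.
#' @return character vector: all loci, each exactly once, in inclusion order.
#' @export
orderMarkers <- function(criterionValues, linkageGroups) {
  if (is.data.frame(linkageGroups)) {
    linkageGroups <- stats::setNames(as.character(linkageGroups$linkage_group),
                                     linkageGroups$name)
  }
  loci <- names(criterionValues)
  if (is.null(loci) || !all(loci %in% names(linkageGroups)))
    stop("every locus needs a criterion value and a linkage group")
  lg <- linkageGroups[loci]
  # stable pre-sort: criterion descending, name ascending for ties
  ord <- order(-criterionValues, loci)
  remaining <- loci[ord]
  out <- character(0)
  usedThisRound <- character(0)
  while (length(remaining)) {
    eligible <- remaining[!(lg[remaining] %in% usedThisRound)]
    if (length(eligible) == 0L) {            # round complete
      usedThisRound <- character(0)
      eligible <- remaining
    }
    pick <- eligible[1L]
    out <- c(out, pick)
    usedThisRound <- c(usedThisRound, lg[[pick]])
    remaining <- setdiff(remaining, pick)
  }
  out
}

#' Choose a marker set under a sorting criterion and choosing scenario
#'
#' Applies [orderMarkers()] with the criterion as-is for the "most
#' discriminant" scenario or negated for the "least discriminant" one (the
#' linkage-group round-robin constraint applies in both), then returns the
#' first \code{size} loci.
#'
#' @param criterionValues named numeric vector (e.g. per-locus DP or F_ST).
#' @param linkageGroups as in [orderMarkers()].
#' @param scenario \code{"most"} or \code{"least"}.
#' @param size number of loci to select.
#' @return character vector of \code{size} locus names.
#' @export
chooseMarkerSet <- function(criterionValues, linkageGroups,
                            scenario = c("most", "least"), size) {
  scenario <- match.arg(scenario)
  if (size < 1L || size > length(criterionValues))
    stop("size out of range: ", size)
  vals <- if (scenario == "least") -criterionValues else criterionValues
  orderMarkers(vals, linkageGroups)[seq_len(size)]
}
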