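# Ploidy-aware Weir-Cockerham-style F_ST.
#
# For each locus and each allele, an indicator variable over allele copies is
# decomposed by unbalanced nested ANOVA into among-group (sig2_g),
# among-individual-within-group (sig2_i) and within-individual (sig2_w)
# variance components; each individual contributes its own observed copies
# (ploidy-aware; dosage-ambiguous cells contribute only the copies seen).
# F_ST is the ratio of summed components, summed over alleles and loci
# (ratio of averages, never average of ratios).

# Per-locus precomputation: copy-count matrix (scored individuals x alleles)
# and copies per individual.
.locusCounts <- function(table, locus) {
  cells <- genotypeCalls(table, locus)
  lens <- lengths(cells)
  scored <- which(lens > 0L)
  alleles <- sort(unique(unlist(cells)))
  S <- matrix(0L, length(scored), length(alleles),
              dimnames = list(indIDs(table)[scored], as.character(alleles)))
  for (r in seq_along(scored)) {
    tb <- base::table(cells[[scored[r]]])
    S[r, names(tb)] <- as.integer(tb)
  }
  list(S = S, ncop = lens[scored], scored = indIDs(table)[scored])
}

# Precompute per-locus copy counts once so repeated groupings (permutation
# tests) avoid re-walking the genotype cells.
.fstData <- function(table, loci) {
  stats::setNames(lapply(loci, function(l) .locusCounts(table, l)), loci)
}

# Positions of each locus's scored individuals within an id vector, computed
# once so permutation loops avoid repeated string matching.
.fstIndex <- function(data, ids) {
  lapply(data, function(lc) match(lc$scored, ids))
}

# Components per locus given integer group codes (1..r) parallel to ids.
# Returns a 3 x n_loci matrix (NA columns for loci unusable under the
# grouping: a group with < 2 scored individuals there).
.componentsByCodes <- function(data, index, codes, r) {
  loci <- names(data)
  out <- matrix(NA_real_, 3L, length(loci),
                dimnames = list(c("g", "i", "w"), loci))
  for (j in seq_along(loci)) {
    lc <- data[[j]]
    pos <- index[[j]]
    keep <- which(!is.na(pos))
    if (length(keep) == 0L) next
    out[, j] <- wc_components(lc$S[keep, , drop = FALSE], lc$ncop[keep],
                              codes[pos[keep]], r)
  }
  out
}

# Components per locus for a named grouping (id -> group label).
.componentsByLocus <- function(data, grouping) {
  ids <- names(grouping)
  lev <- sort(unique(grouping))
  codes <- match(grouping, lev)
  .componentsByCodes(data, .fstIndex(data, ids), codes, length(lev))
}

.ratioOfSums <- function(comp) {
  ok <- !is.na(comp["g", ])
  if (!any(ok)) return(NA_real_)
  num <- sum(comp["g", ok])
  den <- sum(comp[, ok])
  if (den == 0) return(NA_real_)
  num / den
}

#' Pairwise F_ST between groups with permutation tests
#'
#' For every pair of groups, estimates F_ST as the ratio of summed
#' ploidy-aware variance components over loci (among-group over total) and
#' tests it by permuting individuals between the pair's groups:
#' \eqn{p = (1 + \#\{F^{perm} \ge F^{obs}\}) / (1 + n_{perm})}. Loci with a
#' group having fewer than two scored individuals are dropped for that pair
#' (with a warning). Negative estimates are reported as computed unless
#' \code{clampNegative}.
#'
#' @param table a [GenotypeTable-class].
#' @param grouping named character vector: individual id -> group label.
#'   Individuals absent from it are ignored (e.g. only strongly assigned
#'   genotypes).
#' @param loci loci to use (default all).
#' @param nPermutations permutations per pair (default 1000).
#' @param seed RNG seed for the permutations.
#' @param clampNegative clamp negative estimates at 0.
#' @return list with \code{groups}, \code{pairwise} (symmetric F_ST matrix,
#'   diagonal 0), \code{pValues}, \code{perLocus} (multi-group per-locus
#'   F_ST over all groups), \code{overall} (multi-group multi-locus F_ST),
#'   \code{nPermutations}.
#' @export
pairwiseFst <- function(table, grouping, loci = lociNames(table),
                        nPermutations = 1000L, seed = 1L,
                        clampNegative = FALSE) {
  grouping <- grouping[!is.na(grouping)]
  groups <- sort(unique(grouping))
  sizes <- base::table(grouping)
  if (length(groups) < 2L || any(sizes < 2L))
    stop("need at least two groups with at least two individuals each")
  data <- .fstData(table, loci)
  comp <- .componentsByLocus(data, grouping)
  if (anyNA(comp["g", ]))
    warning("dropped ", sum(is.na(comp["g", ])),
            " locus/loci unusable under this grouping")
  tot <- colSums(comp)
  perLocus <- ifelse(!is.na(tot) & tot != 0, comp["g", ] / tot,
                     ifelse(is.na(tot), NA_real_, 0))
  overall <- .ratioOfSums(comp)
  G <- length(groups)
  fst <- matrix(0, G, G, dimnames = list(groups, groups))
  pv <- matrix(NA_real_, G, G, dimnames = list(groups, groups))
  set.seed(seed)
  for (a in seq_len(G - 1L)) for (b in (a + 1L):G) {
    ids <- names(grouping)[grouping %in% groups[c(a, b)]]
    gr <- grouping[ids]
    codes <- ifelse(gr == groups[a], 1L, 2L)
    index <- .fstIndex(data, ids)
    obs <- .ratioOfSums(.componentsByCodes(data, index, codes, 2L))
    fst[a, b] <- fst[b, a] <- if (clampNegative) max(0, obs) else obs
    if (nPermutations > 0L && !is.na(obs)) {
      hits <- 0L
      for (p in seq_len(nPermutations)) {
        f <- .ratioOfSums(.componentsByCodes(data, index, sample(codes), 2L))
        if (!is.na(f) && f >= obs) hits <- hits + 1L
      }
      pv[a, b] <- pv[b, a] <- (1 + hits) / (1 + nPermutations)
    }
  }
  list(groups = groups, pairwise = fst, pValues = pv, perLocus = perLocus,
       overall = overall, nPermutations = as.integer(nPermutations))
}

#' Per-locus F_ST for marker ranking
#'
#' Multi-group per-locus F_ST values (among all inferred populations
#' simultaneously), usable as criterion values for [orderMarkers()] /
#' [chooseMarkerSet()]. A monomorphic locus scores 0. The
#' \code{"pairwise-mean"} method averages the per-locus estimate over all
#' group pairs instead.
#'
#' @param table a [GenotypeTable-class].
#' @param grouping named vector id -> group label.
#' @param loci loci to rank (default all).
#' @param method \code{"multigroup"} (default) or \code{"pairwise-mean"}.
#' @return named numeric vector, one value per locus (NA for dropped loci).
#' @export
perLocusFstRanking <- function(table, grouping, loci = lociNames(table),
                               method = c("multigroup", "pairwise-mean")) {
  method <- match.arg(method)
  grouping <- grouping[!is.na(grouping)]
  data <- .fstData(table, loci)
  if (method == "multigroup") {
    comp <- .componentsByLocus(data, grouping)
    tot <- colSums(comp)
    out <- ifelse(!is.na(tot) & tot != 0, comp["g", ] / tot,
                  ifelse(is.na(tot), NA_real_, 0))
    return(stats::setNames(as.numeric(out), loci))
  }
  groups <- sort(unique(grouping))
  acc <- matrix(0, length(loci), 2L)  # sum of estimates, count
  for (a in seq_len(length(groups) - 1L))
    for (b in (a + 1L):length(groups)) {
      ids <- names(grouping)[grouping %in% groups[c(a, b)]]
      comp <- .componentsByLocus(data, grouping[ids])
      tot <- colSums(comp)
      est <- comp["g", ] / tot
      ok <- !is.na(est)
      acc[ok, 1L] <- acc[ok, 1L] + est[ok]
      acc[ok, 2L] <- acc[ok, 2L] + 1
    }
  stats::setNames(ifelse(acc[, 2L] > 0, acc[, 1L] / acc[, 2L], NA_real_),
                  loci)
}
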