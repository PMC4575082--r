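#' Reference fingerprinting statistics for a 25-SSR pear panel
#'
#' Published summary statistics of a 25-locus microsatellite panel used to
#' fingerprint a European pear (\emph{Pyrus communis}) germplasm collection
#' of 244 accessions spanning 15 linkage groups: per-locus discrimination
#' power (DP), allele counts, effective allele numbers, banding-pattern
#' counts, the linkage-group-aware inclusion order, and the cumulative
#' number of genotypes discriminated. Useful as realistic criterion input
#' for [orderMarkers()] and [chooseMarkerSet()] and as a reference for the
#' ordering algorithm.
#'
#' @return data.frame with columns \code{inclusion_order}, \code{locus},
#'   \code{linkage_group}, \code{DP}, \code{n_alleles},
#'   \code{effective_alleles}, \code{n_patterns},
#'   \code{cumulative_genotypes}.
#' @examples
#' panel <- pearPanelStats()
#' head(orderMarkers(setNames(panel$DP, panel$locus),
#'                   setNames(panel$linkage_group, panel$locus)))
#' @export
pearPanelStats <- function() {
  path <- system.file("extdata", "pear25_panel.csv", package = "structscan",
                      mustWork = TRUE)
  df <- utils::read.csv(path, colClasses = c(
    inclusion_order = "integer", locus = "character",
    linkage_group = "character", DP = "numeric", n_alleles = "integer",
    effective_alleles = "numeric", n_patterns = "integer",
    cumulative_genotypes = "integer"))
  df
}
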