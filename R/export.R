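#' Serialize one admixture run to a directory
#'
#' Writes the run's membership matrix (\code{Q.csv}, individuals x
#' clusters), its log-likelihood trace (\code{lnL_trace.csv}) and an echo of
#' the configuration (\code{config.txt}, \code{key: value} lines) into
#' \code{dir}. Output is byte-stable for a fixed run.
#'
#' @param run an [AdmixtureRun-class].
#' @param dir output directory (created if needed).
#' @return invisibly, \code{dir}.
#' @export
writeRunResult <- function(run, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  Q <- membershipMatrix(run)
  utils::write.csv(data.frame(id = rownames(Q), Q, check.names = FALSE),
                   file.path(dir, "Q.csv"), row.names = FALSE)
  utils::write.csv(data.frame(sweep = seq_along(run@lnLTrace),
                              lnL = run@lnLTrace),
                   file.path(dir, "lnL_trace.csv"), row.names = FALSE)
  cfg <- c(run@config, list(ln_prob_data = run@lnProbData))
  writeLines(paste0(names(cfg), ": ",
                    vapply(cfg, function(v) paste(format(v), collapse = " "),
                           character(1))),
             file.path(dir, "config.txt"))
  invisible(dir)
}

#' Write a stability report as CSV
#'
#' Per-genotype D_i values followed by a summary row carrying the
#' similarity index D and the reassignment fractions between the two
#' analyses.
#'
#' @param Qa,Qb membership matrices over the same individuals.
#' @param path output file.
#' @param strongQ strong-assignment threshold for the reassignment
#'   fractions.
#' @param convention see [stabilityIndex()].
#' @return invisibly, the report data.frame.
#' @export
writeStabilityReport <- function(Qa, Qb, path, strongQ = 0.8,
                                 convention = c("rms", "squared")) {
  st <- stabilityIndex(Qa, Qb, convention = match.arg(convention))
  rr <- reassignmentReport(Qa, Qb, strongQ)
  df <- data.frame(id = c(names(st$perGenotype), "summary_D",
                          "summary_frac_changed_all",
                          "summary_frac_changed_strong"),
                   value = c(unname(st$perGenotype), st$D,
                             rr$fracChangedAll, rr$fracChangedStrong))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
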