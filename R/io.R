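#' Read an SSR genotype table
#'
#' Reads a genotype collection from one of three plain-text dialects:
#' \describe{
#'   \item{\code{"wide"}}{one row per individual; header
#'     \code{id,ploidy,popflag,poplabel,<locus>_1,...,<locus>_p} with p the
#'     table-wide maximum ploidy. Diploids leave the third allele column at
#'     the missing code. Comma-separated.}
#'   \item{\code{"structure"}}{Structure-style tab-separated layout: one row
#'     per allele copy (an individual of ploidy p occupies p consecutive
#'     rows), columns \code{id popflag poplabel <locus...>}. Ploidy is the
#'     number of rows an id occupies.}
#'   \item{\code{"s1"}}{spreadsheet-export layout used for unique-genotype
#'     supplements: a CSV whose header row carries locus names, one row per
#'     genotype, alleles within a cell joined by \code{/}. Column mapping is
#'     configurable via \code{idColumn}/\code{ploidyColumn}.}
#' }
#' The missing code is \code{-9} on disk (Structure convention) and an empty
#' allele multiset in memory. Dosage-ambiguous cells (fewer copies listed
#' than ploidy) are kept as their observed copies.
#'
#' @param path file to read.
#' @param dialect one of \code{"wide"}, \code{"structure"}, \code{"s1"}.
#' @param linkageGroups optional named vector mapping locus name to linkage
#'   group (otherwise each locus gets its own group).
#' @param idColumn,ploidyColumn for dialect \code{"s1"}: name of the
#'   identifier column (default first column) and of an optional ploidy
#'   column; all other columns are treated as loci.
#' @param missingCode missing-allele code on disk (default \code{"-9"}).
#' @return a validated [GenotypeTable-class].
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' writeLines(c("id,ploidy,popflag,poplabel,locA_1,locA_2",
#'              "g1,2,0,,100,104", "g2,2,0,,-9,-9"), tf)
#' gt <- readGenotypeTable(tf, "wide")
#' genotypeCalls(gt, "locA")
#' @export
readGenotypeTable <- function(path, dialect = c("wide", "structure", "s1"),
                              linkageGroups = NULL, idColumn = NULL,
                              ploidyColumn = NULL, missingCode = "-9") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  gt <- switch(dialect,
    wide = .readWide(path, missingCode),
    structure = .readStructure(path, missingCode),
    s1 = .readS1(path, idColumn, ploidyColumn, missingCode)
  )
  if (!is.null(linkageGroups)) {
    mi <- gt@markerInfo
    hit <- mi$name %in% names(linkageGroups)
    mi$linkage_group[hit] <- as.character(linkageGroups[mi$name[hit]])
    gt@markerInfo <- mi
  }
  validObject(gt)
  gt
}

.parseAllele <- function(x, missingCode, where) {
  x <- trimws(x)
  out <- suppressWarnings(as.integer(x))
  miss <- x == missingCode | x == "" | is.na(x)
  if (any(is.na(out) & !miss))
    stop("unknown allele or missing code '", x[is.na(out) & !miss][1L],
         "' at ", where)
  out[miss] <- NA_integer_
  out
}

.readWide <- function(path, missingCode) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  header <- strsplit(lines[1L], ",", fixed = TRUE)[[1L]]
  fixed <- c("id", "ploidy", "popflag", "poplabel")
  if (!identical(tolower(header[1:4]), fixed))
    stop("wide dialect requires header id,ploidy,popflag,poplabel,...")
  alleleCols <- header[-(1:4)]
  loci <- unique(sub("_[0-9]+$", "", alleleCols))
  perLocus <- lapply(loci, function(l) which(sub("_[0-9]+$", "", alleleCols) == l))
  body <- lines[-1L]
  n <- length(body)
  ids <- character(n); pl <- integer(n)
  flag <- logical(n); lab <- character(n)
  calls <- matrix(vector("list", n * length(loci)), n, length(loci))
  for (i in seq_len(n)) {
    f <- strsplit(body[i], ",", fixed = TRUE)[[1L]]
    if (length(f) != length(header))
      stop("malformed row width at data row ", i, " of ", basename(path),
           " (", length(f), " fields, expected ", length(header), ")")
    ids[i] <- f[1L]
    pl[i] <- as.integer(f[2L])
    flag[i] <- f[3L] %in% c("1", "TRUE", "true")
    lab[i] <- if (nzchar(f[4L])) f[4L] else NA_character_
    av <- f[-(1:4)]
    for (l in seq_along(loci)) {
      a <- .parseAllele(av[perLocus[[l]]], missingCode,
                        paste0("row ", i, ", locus ", loci[l]))
      calls[[i, l]] <- sort(a[!is.na(a)])
    }
  }
  GenotypeTable(calls,
                ids = ids, ploidy = pl,
                markers = data.frame(name = loci, linkage_group = loci,
                                     stringsAsFactors = FALSE),
                popLabel = lab, popFlag = flag)
}

.readStructure <- function(path, missingCode) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  if (!identical(tolower(header[1:3]), c("id", "popflag", "poplabel")))
    stop("structure dialect requires header id\tpopflag\tpoplabel\t<loci>")
  loci <- header[-(1:3)]
  body <- lines[-1L]
  fields <- strsplit(body, "\t", fixed = TRUE)
  widths <- lengths(fields)
  if (any(widths != length(header)))
    stop("malformed row width at data row ", which(widths != length(header))[1L],
         " of ", basename(path))
  rowIds <- vapply(fields, `[[`, character(1), 1L)
  ids <- unique(rowIds)
  if (any(diff(match(rowIds, ids)) < 0))
    stop("rows of one individual must be contiguous in structure dialect")
  n <- length(ids)
  calls <- matrix(vector("list", n * length(loci)), n, length(loci))
  pl <- integer(n); flag <- logical(n); lab <- character(n)
  for (i in seq_len(n)) {
    rows <- fields[rowIds == ids[i]]
    pl[i] <- length(rows)
    flag[i] <- rows[[1L]][2L] %in% c("1", "TRUE", "true")
    lab[i] <- if (nzchar(rows[[1L]][3L])) rows[[1L]][3L] else NA_character_
    for (l in seq_along(loci)) {
      a <- vapply(rows, `[[`, character(1), l + 3L)
      a <- .parseAllele(a, missingCode, paste0("individual ", ids[i],
                                               ", locus ", loci[l]))
      calls[[i, l]] <- sort(a[!is.na(a)])
    }
  }
  GenotypeTable(calls, ids = ids, ploidy = pl,
                markers = data.frame(name = loci, linkage_group = loci,
                                     stringsAsFactors = FALSE),
                popLabel = lab, popFlag = flag)
}

.readS1 <- function(path, idColumn, ploidyColumn, missingCode) {
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  if (is.null(idColumn)) idColumn <- names(df)[1L]
  if (!idColumn %in% names(df)) stop("id column '", idColumn, "' not found")
  lociCols <- setdiff(names(df), c(idColumn, ploidyColumn))
  n <- nrow(df)
  calls <- matrix(vector("list", n * length(lociCols)), n, length(lociCols))
  maxCopies <- integer(n)
  for (i in seq_len(n)) for (l in seq_along(lociCols)) {
    cell <- df[[lociCols[l]]][i]
    parts <- if (is.na(cell) || !nzchar(trimws(cell))) character(0)
             else strsplit(cell, "/", fixed = TRUE)[[1L]]
    a <- .parseAllele(parts, missingCode,
                      paste0("row ", i, ", locus ", lociCols[l]))
    calls[[i, l]] <- sort(a[!is.na(a)])
    maxCopies[i] <- max(maxCopies[i], length(calls[[i, l]]))
  }
  pl <- if (!is.null(ploidyColumn)) as.integer(df[[ploidyColumn]])
        else pmax(2L, maxCopies)
  GenotypeTable(calls, ids = df[[idColumn]], ploidy = pl,
                markers = data.frame(name = lociCols,
                                     linkage_group = lociCols,
                                     stringsAsFactors = FALSE))
}

#' Write an SSR genotype table
#'
#' Inverse of [readGenotypeTable()]; output is byte-stable for a fixed table
#' and dialect, and \code{read(write(x))} returns a table identical to
#' \code{x} (for \code{"wide"} and \code{"structure"}; the \code{"s1"} export
#' does not carry popflag information).
#'
#' @param table a [GenotypeTable-class].
#' @param path output file.
#' @param dialect see [readGenotypeTable()].
#' @param missingCode missing-allele code (default \code{"-9"}).
#' @return invisibly, \code{path}.
#' @export
writeGenotypeTable <- function(table, path,
                               dialect = c("wide", "structure", "s1"),
                               missingCode = "-9") {
  dialect <- match.arg(dialect)
  validObject(table)
  loci <- lociNames(table)
  n <- nInd(table)
  lab <- ifelse(is.na(table@popLabel), "", table@popLabel)
  lines <- switch(dialect,
    wide = {
      p <- if (n) max(table@ploidy) else 2L
      hdr <- paste(c("id", "ploidy", "popflag", "poplabel",
                     unlist(lapply(loci, function(l) paste0(l, "_", seq_len(p))))),
                   collapse = ",")
      rows <- vapply(seq_len(n), function(i) {
        cells <- unlist(lapply(seq_along(loci), function(l) {
          a <- as.character(table@calls[[i, l]])
          c(a, rep(missingCode, p - length(a)))
        }))
        paste(c(table@ids[i], table@ploidy[i],
                as.integer(table@popFlag[i]), lab[i], cells), collapse = ",")
      }, character(1))
      c(hdr, rows)
    },
    structure = {
      hdr <- paste(c("id", "popflag", "poplabel", loci), collapse = "\t")
      rows <- unlist(lapply(seq_len(n), function(i) {
        p <- table@ploidy[i]
        vapply(seq_len(p), function(copy) {
          cells <- vapply(seq_along(loci), function(l) {
            a <- table@calls[[i, l]]
            if (copy <= length(a)) as.character(a[copy]) else missingCode
          }, character(1))
          paste(c(table@ids[i], as.integer(table@popFlag[i]), lab[i], cells),
                collapse = "\t")
        }, character(1))
      }))
      c(hdr, rows)
    },
    s1 = {
      hdr <- paste(c("Genotype", "Ploidy", loci), collapse = ",")
      rows <- vapply(seq_len(n), function(i) {
        cells <- vapply(seq_along(loci), function(l) {
          paste(table@calls[[i, l]], collapse = "/")
        }, character(1))
        paste(c(table@ids[i], table@ploidy[i], cells), collapse = ",")
      }, character(1))
      c(hdr, rows)
    }
  )
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}
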