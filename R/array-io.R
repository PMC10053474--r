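# Photometric table IO and the join into a screen dataset.

#' Read a photometric intensity table
#'
#' Two dialects are supported:
#'
#' * `"tsv"`: plain tab-separated with header; required columns `spot_id`,
#'   `channel`, `intensity`; optional `background`, `flag`, `row`, `col`.
#' * `"gpr"`: a GenePix-results-style table. An optional ATF preamble
#'   (`ATF <version>` line, header-count line, quoted `"key=value"`
#'   records) is skipped; the column table must carry `Row`, `Column`, an
#'   `ID` or `Name` column, and per-wavelength foreground medians
#'   (`F635 Median`, `F532 Median`, ...; background `B... Median` columns
#'   are read when present). Each wavelength becomes one channel labelled
#'   by the wavelength, and `spot_id` is taken from `ID`/`Name`.
#'
#' Malformed rows fail loudly with their (1-based, data) row numbers:
#' negative intensities and duplicate (spot, channel) records are errors.
#'
#' @param path File path.
#' @param dialect `"tsv"` or `"gpr"`.
#' @return `data.frame` with columns `spot_id`, `channel`, `intensity`
#'   and, when available, `background`, `row`, `col`.
#' @export
readPhotometricTable <- function(path, dialect = c("tsv", "gpr")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- if (dialect == "tsv") .readPlainTsv(path) else .readGprLike(path)
  .validateIntensityTable(tab)
}

.readPlainTsv <- function(path) {
  tab <- as.data.frame(data.table::fread(path, sep = "\t", header = TRUE))
  need <- c("spot_id", "channel", "intensity")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("photometric table lacks required column(s): ",
         paste(miss, collapse = ", "))
  tab$spot_id <- as.character(tab$spot_id)
  tab$channel <- as.character(tab$channel)
  tab
}

.readGprLike <- function(path) {
  lines <- readLines(path, warn = FALSE)
  skip <- 0L
  if (length(lines) && grepl("^ATF", lines[1L])) {
    nhead <- suppressWarnings(as.integer(strsplit(trimws(lines[2L]), "\\s+")[[1L]][1L]))
    if (is.na(nhead)) stop("malformed ATF preamble: bad header-count line")
    skip <- 2L + nhead
  }
  tab <- as.data.frame(data.table::fread(path, sep = "\t", header = TRUE,
                                         skip = skip, quote = "\""))
  idcol <- intersect(c("ID", "Name"), names(tab))[1L]
  if (is.na(idcol) || !all(c("Row", "Column") %in% names(tab)))
    stop("gpr-like table needs Row, Column and an ID or Name column")
  fcols <- grep("^F[0-9]+ Median$", names(tab), value = TRUE)
  if (!length(fcols))
    stop("gpr-like table has no 'F<wavelength> Median' columns")
  long <- do.call(rbind, lapply(fcols, function(fc) {
    wl <- sub("^F([0-9]+) Median$", "\\1", fc)
    bc <- paste0("B", wl, " Median")
    data.frame(spot_id = as.character(tab[[idcol]]),
               row = tab$Row, col = tab$Column,
               channel = wl, intensity = as.numeric(tab[[fc]]),
               background = if (bc %in% names(tab)) as.numeric(tab[[bc]])
                            else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(long) <- NULL
  long
}

.validateIntensityTable <- function(tab) {
  bad <- which(!is.finite(tab$intensity) | tab$intensity < 0)
  if (length(bad))
    stop("negative or non-finite intensity at data row(s): ",
         paste(utils::head(bad, 10L), collapse = ", "))
  key <- paste(tab$spot_id, tab$channel, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- which(duplicated(key))
    stop("duplicate (spot, channel) record(s) at data row(s): ",
         paste(utils::head(dup, 10L), collapse = ", "))
  }
  tab
}

#' Write an intensity table
#'
#' Writes the plain TSV dialect that [readPhotometricTable()] reads back
#' (round-trip identical on the `spot_id`/`channel`/`intensity` fields).
#'
#' @param table `data.frame` with at least `spot_id`, `channel`,
#'   `intensity`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
writeIntensityTable <- function(table, path) {
  need <- c("spot_id", "channel", "intensity")
  miss <- setdiff(need, names(table))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  keep <- intersect(c("spot_id", "row", "col", "channel", "intensity",
                      "background"), names(table))
  data.table::fwrite(table[, keep], path, sep = "\t", eol = "\n", quote = FALSE)
  invisible(path)
}

#' Join intensities with an array manifest into a screen dataset
#'
#' Joins a photometric table with the array design, maps raw channel
#' labels to RNA channels, and records unmatched spots. Intensity records
#' whose spot id is absent from the manifest are tolerated up to
#' `tolerance` (a fraction of all records; default 0, i.e. any unmatched
#' record is an error). Manifest spots without intensity records are kept
#' in `missingSpots()`.
#'
#' @param design An [ArrayDesign-class] (or manifest path).
#' @param intensities Intensity `data.frame` from [readPhotometricTable()]
#'   or [simulateScreen()].
#' @param channelMap Named character vector mapping raw channel labels to
#'   RNA channels (e.g. `c("635" = "A12", "532" = "U12")`); `NULL` uses
#'   the labels as-is.
#' @param tolerance Maximum tolerated fraction of unmatched intensity
#'   records.
#' @param backgroundSubtract Subtract the `background` column from the
#'   foreground intensity (clamped at 0) before analysis. Off by default.
#' @return A [ScreenDataset-class].
#' @export
buildScreenDataset <- function(design, intensities, channelMap = NULL,
                               tolerance = 0, backgroundSubtract = FALSE) {
  if (is.character(design)) design <- readManifest(design)
  stopifnot(is(design, "ArrayDesign"))
  intensities <- .validateIntensityTable(as.data.frame(intensities))
  if (backgroundSubtract) {
    if (!"background" %in% names(intensities))
      stop("backgroundSubtract requires a background column")
    intensities$intensity <- pmax(intensities$intensity -
                                  intensities$background, 0)
  }
  raw <- unique(intensities$channel)
  if (is.null(channelMap)) channelMap <- stats::setNames(raw, raw)
  unknown <- setdiff(raw, names(channelMap))
  if (length(unknown))
    stop("channel(s) without RNA mapping: ", paste(unknown, collapse = ", "))

  sp <- design@spots
  unmatched <- setdiff(unique(intensities$spot_id), sp$spot_id)
  frac <- sum(intensities$spot_id %in% unmatched) / nrow(intensities)
  if (frac > tolerance)
    stop(sprintf("%.1f%% of intensity records have spot ids absent from the manifest (tolerance %.1f%%); e.g. %s",
                 100 * frac, 100 * tolerance,
                 paste(utils::head(unmatched, 5L), collapse = ", ")))
  keep <- intensities$spot_id %in% sp$spot_id
  it <- intensities[keep, c("spot_id", "channel", "intensity")]
  joined <- merge(sp, it, by = "spot_id", sort = FALSE)
  joined$rna <- unname(channelMap[joined$channel])
  joined <- joined[order(joined$spot_id, joined$rna),
                   c("spot_id", "row", "col", "peptide", "library_id",
                     "copy", "channel", "rna", "intensity")]
  rownames(joined) <- NULL
  new("ScreenDataset",
      signals = joined,
      channelMap = channelMap,
      missingSpots = setdiff(sp$spot_id, it$spot_id),
      design = design)
}

#' Aggregate spot signals per peptide
#'
#' @param dataset A [ScreenDataset-class].
#' @param aggregate Aggregation statistic over replicate spots
#'   (default median).
#' @return `data.frame` with one row per (peptide, RNA channel):
#'   `peptide`, `library_id`, `rna`, `intensity`, `nSpots`.
#' @export
aggregateSignals <- function(dataset, aggregate = stats::median) {
  stopifnot(is(dataset, "ScreenDataset"))
  dt <- data.table::as.data.table(dataset@signals)
  intensity <- NULL  # NSE note for R CMD check
  out <- dt[, list(intensity = aggregate(intensity), nSpots = .N),
            by = c("peptide", "library_id", "rna")]
  data.table::setorderv(out, c("library_id", "rna", "peptide"))
  as.data.frame(out)
}

#' Per-channel summary statistics
#'
#' Mean and sample standard deviation (n-1 denominator) of the
#' fluorescence intensities per (library/protocode, RNA channel), at spot
#' or per-peptide level.
#'
#' @param dataset A [ScreenDataset-class].
#' @param level `"spot"` (every replicate spot contributes) or
#'   `"peptide"` (aggregated intensities).
#' @param aggregate Peptide-level aggregation statistic (default median).
#' @return `data.frame`: `library_id`, `rna`, `n`, `mean`, `sd`.
#' @export
channelSummary <- function(dataset, level = c("spot", "peptide"),
                           aggregate = stats::median) {
  stopifnot(is(dataset, "ScreenDataset"))
  level <- match.arg(level)
  df <- if (level == "spot") dataset@signals
        else aggregateSignals(dataset, aggregate)
  dt <- data.table::as.data.table(df)
  intensity <- NULL
  out <- dt[, list(n = .N, mean = mean(intensity), sd = stats::sd(intensity)),
            by = c("library_id", "rna")]
  data.table::setorderv(out, c("library_id", "rna"))
  as.data.frame(out)
}
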