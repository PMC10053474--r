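# Per-peptide sum properties: charge, molecular weight, hydrophobicity,
# helix propensity.

#' Load a residue property scale
#'
#' Scales are tab-separated `residue  value` tables with `# key: value`
#' comment headers declaring `name`, `units` and the terminal adjustments
#' `nterm` / `cterm` (added once per peptide; zero for side-chain-only
#' scales on acetylated, linker-attached array peptides).
#'
#' @param path Scale file path.
#' @return A [PropertyScale-class].
#' @export
loadPropertyScale <- function(path) {
  if (!file.exists(path)) stop("no such scale file: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    m <- regmatches(h, regexec("^#\\s*(\\w+)\\s*:\\s*(.*?)\\s*$", h))[[1L]]
    if (length(m) == 3L) meta[[m[2L]]] <- m[3L]
  }
  tab <- utils::read.delim(text = paste(lines[!grepl("^#", lines)],
                                        collapse = "\n"),
                           stringsAsFactors = FALSE)
  if (!all(c("residue", "value") %in% names(tab)))
    stop("scale file needs 'residue' and 'value' columns: ", path)
  new("PropertyScale",
      name = meta$name %||% sub("\\.tsv$", "", basename(path)),
      units = meta$units %||% "",
      values = stats::setNames(as.numeric(tab$value), tab$residue),
      nTerm = as.numeric(meta$nterm %||% 0),
      cTerm = as.numeric(meta$cterm %||% 0))
}

#' Bundled default property scales
#'
#' Four scales matching the screen's property analyses: side-chain formal
#' `charge` near pH 7.4 (e; termini contribute 0 because array peptides
#' are N-acetylated and C-linker-attached), `molecular_weight` (average
#' residue masses in Da plus the acetyl adjustment), Kyte-Doolittle
#' `hydrophobicity`, and Pace-Scholtz `helix_propensity` (kcal/mol). All
#' scales are plain text under `inst/extdata/scales/` and can be edited or
#' replaced via [loadPropertyScale()].
#'
#' @return Named list of [PropertyScale-class] objects.
#' @examples
#' names(defaultScales())
#' @export
defaultScales <- function() {
  dir <- system.file("extdata", "scales", package = "protopep", mustWork = TRUE)
  files <- list.files(dir, pattern = "\\.tsv$", full.names = TRUE)
  scales <- lapply(files, loadPropertyScale)
  stats::setNames(scales, vapply(scales, function(s) s@name, character(1L)))
}

#' Sum a residue property over peptide sequences
#'
#' `sumProperty(x)` is the sum of the scale value of every residue plus
#' the scale's terminal adjustments; with zero terminal adjustments it is
#' additive under concatenation and invariant to residue order.
#'
#' @param sequences Character vector of peptide sequences.
#' @param scale A [PropertyScale-class].
#' @return Numeric vector of summed property values (units: the scale's).
#' @examples
#' charge <- defaultScales()$charge
#' sumProperty("KKKKKK", charge)   # +6
#' sumProperty("DDD", charge)      # -3
#' @export
sumProperty <- function(sequences, scale) {
  stopifnot(is(scale, "PropertyScale"))
  if (!length(sequences) || any(!nzchar(sequences)))
    stop("sequences must be non-empty")
  res <- strsplit(sequences, "")
  used <- unique(unlist(res))
  miss <- setdiff(used, names(scale@values))
  if (length(miss))
    stop(sprintf("residue(s) missing from scale '%s': %s",
                 scale@name, paste(miss, collapse = ", ")))
  vapply(res, function(r) sum(scale@values[r]), numeric(1L)) +
    scale@nTerm + scale@cTerm
}

#' Per-peptide property table
#'
#' One row per (peptide, RNA channel) with all property sums and the
#' aggregated fluorescence intensity: the input for property-vs-intensity
#' scatter analyses.
#'
#' @param dataset A [ScreenDataset-class].
#' @param scales Named list of [PropertyScale-class] objects
#'   (default [defaultScales()]).
#' @param aggregate Spot aggregation statistic (default median).
#' @return `data.frame`: `peptide`, `library_id`, `rna`, `intensity`,
#'   `nSpots`, then one column per scale.
#' @export
propertyTable <- function(dataset, scales = defaultScales(),
                          aggregate = stats::median) {
  agg <- aggregateSignals(dataset, aggregate)
  peps <- unique(agg$peptide)
  props <- lapply(scales, function(s)
    stats::setNames(sumProperty(peps, s), peps))
  for (nm in names(props)) agg[[nm]] <- unname(props[[nm]][agg$peptide])
  agg
}
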