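# Single-position substitution scans of a seed peptide.

#' Generate a single-position substitution scan
#'
#' All variants of `seed` with exactly one position replaced by one of the
#' substitute residues, ordered position-major then by substitute order
#' (for a polyproline 7-mer with substitutes A, G, R the first variant is
#' APPPPPP and the last PPPPPPR). A substitute equal to the seed residue
#' at a position reproduces the seed and is excluded from the variants;
#' the unmodified seed is included once as a reference row with
#' `position = 0`.
#'
#' @param seed Seed peptide sequence.
#' @param substitutes Character vector of substitute residues, in display
#'   order.
#' @return A [SubstitutionScan-class].
#' @examples
#' scan <- generateScan("PPPPPPP", c("A", "G", "R"))
#' nrow(scanVariants(scan))   # 22 = 21 variants + the seed reference
#' @export
generateScan <- function(seed, substitutes) {
  stopifnot(length(seed) == 1L, nzchar(seed))
  substitutes <- as.character(substitutes)
  if (!length(substitutes)) stop("substitutes must be non-empty")
  if (any(nchar(substitutes) != 1L)) stop("substitutes must be single residues")
  if (anyDuplicated(substitutes)) stop("duplicate substitutes")
  res <- strsplit(seed, "")[[1L]]
  rows <- list(data.frame(position = 0L, residue = NA_character_,
                          sequence = seed, stringsAsFactors = FALSE))
  for (p in seq_along(res)) {
    for (s in substitutes) {
      if (s == res[p]) next
      v <- res; v[p] <- s
      rows[[length(rows) + 1L]] <- data.frame(
        position = p, residue = s, sequence = paste(v, collapse = ""),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 1L)
    stop("empty scan: every substitute equals the seed residue at every position")
  new("SubstitutionScan", seed = seed, substitutes = substitutes,
      variants = do.call(rbind, rows))
}

#' Intensity matrix of a substitution scan
#'
#' Looks up every scan variant in a screen dataset and arranges the
#' aggregated intensities as a position x substitute matrix (rows =
#' positions 1..L from the N-terminus, columns = substitutes in the order
#' given). Cells whose variant carries the seed residue (no distinct
#' variant exists) or whose variant is missing from the dataset are `NA`;
#' missing variants additionally raise a warning and are listed.
#'
#' @param scan A [SubstitutionScan-class].
#' @param dataset A [ScreenDataset-class] whose manifest contains the
#'   variants.
#' @param channel RNA channel to read.
#' @param aggregate Aggregation statistic over replicate spots
#'   (default median, matching [aggregateSignals()]).
#' @return A list with elements `matrix` (position x substitute), `best`
#'   (`data.frame` row: `position`, `residue`, `sequence`, `intensity`;
#'   ties broken position-major, then substitute order), `seedIntensity`
#'   (reference intensity of the unmodified seed, `NA` when absent) and
#'   `missing` (variant sequences without signals).
#' @export
scanMatrix <- function(scan, dataset, channel, aggregate = stats::median) {
  stopifnot(is(scan, "SubstitutionScan"), is(dataset, "ScreenDataset"))
  sig <- dataset@signals
  if (!channel %in% sig$rna)
    stop(sprintf("channel '%s' absent from the dataset", channel))
  sig <- sig[sig$rna == channel, , drop = FALSE]
  dt <- data.table::as.data.table(sig)
  intensity <- NULL
  agg <- dt[, list(intensity = aggregate(intensity)), by = "peptide"]
  lookup <- stats::setNames(agg$intensity, agg$peptide)

  v <- scan@variants[scan@variants$position > 0L, , drop = FALSE]
  L <- nchar(scan@seed)
  m <- matrix(NA_real_, nrow = L, ncol = length(scan@substitutes),
              dimnames = list(position = as.character(seq_len(L)),
                              residue = scan@substitutes))
  v$intensity <- unname(lookup[v$sequence])
  for (i in seq_len(nrow(v)))
    m[v$position[i], v$residue[i]] <- v$intensity[i]
  missing <- v$sequence[is.na(v$intensity)]
  if (length(missing))
    warning(sprintf("%d scan variant(s) missing from the dataset: %s",
                    length(missing),
                    paste(utils::head(missing, 5L), collapse = ", ")))
  present <- v[!is.na(v$intensity), , drop = FALSE]
  best <- if (nrow(present)) {
    present <- present[order(present$position,
                             match(present$residue, scan@substitutes)), ]
    present[which.max(present$intensity),
            c("position", "residue", "sequence", "intensity")]
  } else {
    data.frame(position = NA_integer_, residue = NA_character_,
               sequence = NA_character_, intensity = NA_real_)
  }
  rownames(best) <- NULL
  list(matrix = m, best = best,
       seedIntensity = unname(lookup[scan@seed]) %||% NA_real_,
       missing = missing)
}
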