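# Combinatorial peptide library enumeration and array layout.

#' Enumerate a fully combinatorial peptide library
#'
#' Generates all `|alphabet|^length` peptides over an amino-acid alphabet,
#' in deterministic lexicographic order (alphabet order as given).
#'
#' @param alphabet Character vector of distinct one-letter residue symbols.
#' @param length Peptide length in residues (>= 1).
#' @param libraryId Library identifier (conventionally the protocode name).
#' @param copies Default replicate spot count per peptide (used by
#'   [layoutArray()]).
#' @param cap Refuse enumerations larger than this many peptides.
#' @return A [PeptideLibrary-class].
#' @examples
#' lib <- enumerateLibrary(c("G", "P", "A", "R"), 7)  # 4^7 = 16384 peptides
#' length(peptides(lib))
#' @export
enumerateLibrary <- function(alphabet, length, libraryId = "library",
                             copies = 1L, cap = 1e7) {
  alphabet <- as.character(alphabet)
  if (!length(alphabet)) stop("alphabet must be non-empty")
  if (anyDuplicated(alphabet))
    stop("duplicate alphabet symbols: ",
         paste(unique(alphabet[duplicated(alphabet)]), collapse = ", "))
  if (any(nchar(alphabet) != 1L)) stop("alphabet symbols must be single letters")
  length <- as.integer(length)
  if (is.na(length) || length < 1L) stop("length must be a positive integer")
  n <- base::length(alphabet)^as.numeric(length)
  if (n > cap)
    stop(sprintf("enumeration of %.0f peptides exceeds the cap (%.0f)", n, cap))
  # expand.grid varies the first factor fastest; feed positions in reverse
  # so the leftmost residue varies slowest (true lexicographic order).
  grid <- do.call(expand.grid,
                  c(rep(list(alphabet), length), stringsAsFactors = FALSE))
  peps <- do.call(paste0, rev(grid))
  new("PeptideLibrary", libraryId = libraryId, alphabet = alphabet,
      width = length, peptides = peps, copies = as.integer(copies))
}

#' Seeded random subset of a peptide library
#'
#' Uniform subsample without replacement, preserving the library's peptide
#' order among retained sequences. Stands in for a synthesized library that
#' is smaller than the full combinatorial enumeration.
#'
#' @param library A [PeptideLibrary-class].
#' @param n Number of peptides to keep (`0 <= n <= |peptides|`).
#' @param seed RNG seed.
#' @return A [PeptideLibrary-class] with `n` peptides.
#' @export
subsetLibrary <- function(library, n, seed = 1L) {
  stopifnot(is(library, "PeptideLibrary"))
  n <- as.integer(n)
  total <- length(library@peptides)
  if (is.na(n) || n < 0L) stop("n must be a non-negative integer")
  if (n > total)
    stop(sprintf("n (%d) exceeds the library size (%d)", n, total))
  if (n == total) return(library)
  keep <- sort(withSeed(seed, sample.int(total, n)))
  initialize(library, peptides = library@peptides[keep])
}

#' Combine peptide libraries into a randomized array layout
#'
#' Places every peptide of every library on a grid, `copies` times each,
#' at seeded pseudo-random positions (random allocation avoids local
#' incubation artifacts). Identical inputs and seed give an identical
#' layout.
#'
#' @param libraries A [PeptideLibrary-class] or list thereof.
#' @param copies Integer vector of replicate counts, recycled over
#'   libraries; `NULL` uses each library's own `copies` slot.
#' @param seed Layout seed.
#' @param nrow,ncol Grid dimensions; `NULL` picks the smallest near-square
#'   grid holding all spots.
#' @param pitch Spot pitch in micrometers (metadata).
#' @param acetylN,linkerBetaAla Chemistry metadata flags: N-terminal
#'   acetylation and C-terminal beta-alanine linker.
#' @return An [ArrayDesign-class].
#' @examples
#' lib <- enumerateLibrary(c("G", "P"), 3, "toy")
#' design <- layoutArray(lib, copies = 2, seed = 7)
#' nrow(spots(design))   # 16
#' @export
layoutArray <- function(libraries, copies = NULL, seed = 1L,
                        nrow = NULL, ncol = NULL, pitch = 60,
                        acetylN = TRUE, linkerBetaAla = TRUE) {
  if (is(libraries, "PeptideLibrary")) libraries <- list(libraries)
  stopifnot(all(vapply(libraries, is, logical(1L), "PeptideLibrary")))
  ids <- vapply(libraries, libraryId, character(1L))
  if (anyDuplicated(ids)) stop("duplicate library ids")
  names(libraries) <- ids
  if (is.null(copies)) copies <- vapply(libraries, function(l) l@copies, integer(1L))
  copies <- rep_len(as.integer(copies), length(libraries))
  if (any(copies < 1L)) stop("copies must be >= 1")

  entries <- do.call(rbind, lapply(seq_along(libraries), function(i) {
    lib <- libraries[[i]]
    data.frame(
      peptide = rep(lib@peptides, each = copies[i]),
      library_id = lib@libraryId,
      copy = rep.int(seq_len(copies[i]), length(lib@peptides)),
      stringsAsFactors = FALSE)
  }))
  n <- base::nrow(entries)
  if (is.null(ncol) && is.null(nrow)) {
    ncol <- ceiling(sqrt(n)); nrow <- ceiling(n / ncol)
  } else if (is.null(ncol)) ncol <- ceiling(n / nrow)
  else if (is.null(nrow)) nrow <- ceiling(n / ncol)
  nrow <- as.integer(nrow); ncol <- as.integer(ncol)
  if (as.numeric(nrow) * ncol < n)
    stop(sprintf("grid %d x %d too small for %d spots", nrow, ncol, n))

  cells <- withSeed(seed, sample.int(nrow * ncol, n))
  spots <- data.frame(
    spot_id = sprintf("S%06d", seq_len(n)),
    row = (cells - 1L) %/% ncol + 1L,
    col = (cells - 1L) %% ncol + 1L,
    entries,
    stringsAsFactors = FALSE)

  new("ArrayDesign", spots = spots, libraries = libraries,
      seed = as.integer(seed), dim = c(nrow, ncol), pitch = pitch,
      acetylN = acetylN, linkerBetaAla = linkerBetaAla)
}

#' Write / read an array design manifest
#'
#' The manifest is a tab-separated file with columns
#' `spot_id  row  col  peptide  library_id  copy`. Writing the same design
#' twice produces byte-identical files. `readManifest()` rebuilds an
#' [ArrayDesign-class] from a manifest (library alphabets are recovered
#' from the observed residues).
#'
#' @param design An [ArrayDesign-class].
#' @param path File path.
#' @return `writeManifest()`: the path, invisibly. `readManifest()`: an
#'   [ArrayDesign-class].
#' @export
writeManifest <- function(design, path) {
  stopifnot(is(design, "ArrayDesign"))
  sp <- design@spots[, c("spot_id", "row", "col", "peptide", "library_id", "copy")]
  data.table::fwrite(sp, path, sep = "\t", eol = "\n", quote = FALSE)
  invisible(path)
}

#' @rdname writeManifest
#' @export
readManifest <- function(path) {
  sp <- as.data.frame(data.table::fread(path, sep = "\t", header = TRUE,
                                        colClasses = list(character = "spot_id")))
  need <- c("spot_id", "row", "col", "peptide", "library_id", "copy")
  miss <- setdiff(need, names(sp))
  if (length(miss))
    stop("manifest lacks column(s): ", paste(miss, collapse = ", "))
  sp <- sp[, need]
  libs <- lapply(split(sp, sp$library_id), function(d) {
    peps <- unique(d$peptide)
    new("PeptideLibrary",
        libraryId = d$library_id[1L],
        alphabet = sort(unique(strsplit(paste(peps, collapse = ""), "")[[1L]])),
        width = as.integer(nchar(peps[1L])),
        peptides = peps,
        copies = as.integer(max(d$copy)))
  })
  new("ArrayDesign", spots = sp, libraries = libs, seed = NA_integer_,
      dim = c(max(sp$row), max(sp$col)), pitch = NA_real_,
      acetylN = NA, linkerBetaAla = NA)
}

#' Export unique library peptides as FASTA
#'
#' @param library A [PeptideLibrary-class].
#' @param path Output FASTA path.
#' @return The path, invisibly.
#' @export
exportFasta <- function(library, path) {
  stopifnot(is(library, "PeptideLibrary"))
  aas <- Biostrings::AAStringSet(library@peptides)
  names(aas) <- sprintf("%s_%06d", library@libraryId, seq_along(aas))
  Biostrings::writeXStringSet(aas, path)
  invisible(path)
}
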