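# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single non-missing number")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Watson-Crick transition of single RNA bases: A<->G, U<->C.
.TRANSITION <- c(A = "G", G = "A", U = "C", C = "U")

# Complementary base (for reverse complements of codons).
.COMPLEMENT <- c(A = "U", U = "A", G = "C", C = "G")

.checkCodons <- function(codons) {
  ok <- grepl("^[ACGU]{3}$", codons)
  if (!all(ok))
    stop("malformed codon(s): ", paste(codons[!ok], collapse = ", "))
  invisible(codons)
}

# Apply the A<->G / U<->C transition at the given codon positions.
mutateCodon <- function(codon, positions) {
  .checkCodons(codon)
  vapply(codon, function(cd) {
    b <- strsplit(cd, "", fixed = TRUE)[[1L]]
    b[positions] <- .TRANSITION[b[positions]]
    paste(b, collapse = "")
  }, character(1L), USE.NAMES = FALSE)
}

# Reverse complement of RNA codons.
revcompCodon <- function(codon) {
  .checkCodons(codon)
  vapply(codon, function(cd) {
    b <- strsplit(cd, "", fixed = TRUE)[[1L]]
    paste(rev(.COMPLEMENT[b]), collapse = "")
  }, character(1L), USE.NAMES = FALSE)
}

# One-letter canonical amino acids.
.AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
           "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Placeholder members of the protocodes (X1, X1*, X2, ...): amino acids that
# disappeared before or during fusion, leaving stop codons behind.
.isPlaceholder <- function(aa) grepl("^X[0-9]+\\*?$", aa)

.validAaSymbol <- function(aa) aa %in% .AA20 | .isPlaceholder(aa)

#' Standard genetic code table
#'
#' The 64-codon standard genetic code as a named character vector mapping
#' RNA codons to one-letter amino-acid symbols, with `"*"` for the three
#' stop codons (UAA, UAG, UGA). Derived from [Biostrings::GENETIC_CODE].
#'
#' @return Named character vector of length 64 (names are RNA codons).
#' @examples
#' sgc <- sgcTable()
#' sgc[["UUU"]]              # "F"
#' names(sgc)[sgc == "*"]    # the stop codons
#' @export
sgcTable <- function() {
  gc <- Biostrings::GENETIC_CODE
  stats::setNames(as.character(gc), chartr("T", "U", names(gc)))
}

# Codons the SGC assigns to the late-entering amino acids Met and Trp.
# Fusion of the protocodes can reach these codons (e.g. AUG from AUA, UGG
# from CGG); the SGC assigns them to amino acids that joined the code after
# the fusion, so validation annotates rather than fails them.
.LATE_ENTRY <- c(AUG = "M", UGG = "W")

`%||%` <- function(a, b) if (is.null(a)) b else a
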