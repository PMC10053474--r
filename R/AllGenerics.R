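# Generics and accessors.

#' @rdname accessors
#' @export
setGeneric("peptides", function(x) standardGeneric("peptides"))

#' @rdname accessors
#' @export
setGeneric("libraryId", function(x) standardGeneric("libraryId"))

#' @rdname accessors
#' @export
setGeneric("peptideAlphabet", function(x) standardGeneric("peptideAlphabet"))

#' @rdname accessors
#' @export
setGeneric("spots", function(x) standardGeneric("spots"))

#' @rdname accessors
#' @export
setGeneric("signals", function(x) standardGeneric("signals"))

#' @rdname accessors
#' @export
setGeneric("channelMap", function(x) standardGeneric("channelMap"))

#' @rdname accessors
#' @export
setGeneric("missingSpots", function(x) standardGeneric("missingSpots"))

#' @rdname accessors
#' @export
setGeneric("assignments", function(x) standardGeneric("assignments"))

#' @rdname accessors
#' @export
setGeneric("complementPairs", function(x) standardGeneric("complementPairs"))

#' @rdname accessors
#' @export
setGeneric("isDominant", function(x) standardGeneric("isDominant"))

#' @rdname accessors
#' @export
setGeneric("fragmentScores", function(x) standardGeneric("fragmentScores"))

#' @rdname accessors
#' @export
setGeneric("gatedFragments", function(x) standardGeneric("gatedFragments"))

#' @rdname accessors
#' @export
setGeneric("signatureColumns", function(x) standardGeneric("signatureColumns"))

#' @rdname accessors
#' @export
setGeneric("scanVariants", function(x) standardGeneric("scanVariants"))

#' @rdname accessors
#' @export
setGeneric("channelBaselines", function(x) standardGeneric("channelBaselines"))

#' @rdname accessors
#' @export
setGeneric("plantedEffects", function(x) standardGeneric("plantedEffects"))

#' Accessors for protopep S4 classes
#'
#' Small read-only accessors: `peptides()` and `peptideAlphabet()` for
#' [PeptideLibrary-class], `spots()` for [ArrayDesign-class], `signals()`,
#' `channelMap()` and `missingSpots()` for [ScreenDataset-class],
#' `assignments()`, `complementPairs()` and `isDominant()` for
#' [Protocode-class], `fragmentScores()` / `gatedFragments()` for
#' [FragmentScores-class], `signatureColumns()` for
#' [SignatureTable-class], `scanVariants()` for [SubstitutionScan-class],
#' `channelBaselines()` / `plantedEffects()` for [SimConfig-class].
#'
#' @param x An object of the matching class.
#' @return The slot contents (data.frames, vectors or lists; never a
#'   reference into the object).
#' @name accessors
NULL

#' @rdname accessors
setMethod("peptides", "PeptideLibrary", function(x) x@peptides)
#' @rdname accessors
setMethod("libraryId", "PeptideLibrary", function(x) x@libraryId)
#' @rdname accessors
setMethod("peptideAlphabet", "PeptideLibrary", function(x) x@alphabet)
#' @rdname accessors
setMethod("spots", "ArrayDesign", function(x) x@spots)
#' @rdname accessors
setMethod("signals", "ScreenDataset", function(x) x@signals)
#' @rdname accessors
setMethod("channelMap", "ScreenDataset", function(x) x@channelMap)
#' @rdname accessors
setMethod("missingSpots", "ScreenDataset", function(x) x@missingSpots)
#' @rdname accessors
setMethod("assignments", "Protocode", function(x) x@assignments)
#' @rdname accessors
setMethod("complementPairs", "Protocode", function(x) x@complementPairs)
#' @rdname accessors
setMethod("isDominant", "Protocode", function(x) x@dominant)
#' @rdname accessors
setMethod("fragmentScores", "FragmentScores", function(x) x@scores)
#' @rdname accessors
setMethod("gatedFragments", "FragmentScores", function(x) x@gated)
#' @rdname accessors
setMethod("signatureColumns", "SignatureTable", function(x) x@columns)
#' @rdname accessors
setMethod("scanVariants", "SubstitutionScan", function(x) x@variants)
#' @rdname accessors
setMethod("channelBaselines", "SimConfig", function(x) x@baselines)
#' @rdname accessors
setMethod("plantedEffects", "SimConfig", function(x) x@effects)

# -- show methods -----------------------------------------------------------

setMethod("show", "Protocode", function(object) {
  cat(sprintf("Protocode '%s' (%s) over {%s}\n", object@name,
              if (object@dominant) "dominant" else "recessive",
              paste(object@baseAlphabet, collapse = ",")))
  for (aa in names(object@assignments)) {
    del <- if (aa %in% object@deleted) " [deleted]" else ""
    cat(sprintf("  %-4s %s%s\n", aa,
                paste(object@assignments[[aa]], collapse = ", "), del))
  }
})

setMethod("show", "FusionResult", function(object) {
  cat(sprintf("FusionResult: %d amino acids across %d protocodes\n",
              nrow(object@table), length(unique(object@table$protocode))))
  if (nrow(object@conflicts))
    cat(sprintf("  %d unresolved re-assignment(s)\n", nrow(object@conflicts)))
})

setMethod("show", "SgcValidation", function(object) {
  s <- object@summary
  cat(sprintf("SgcValidation: %d/%d amino acids consistent with the SGC\n",
              sum(s$passed), nrow(s)))
  if (any(!s$passed)) {
    bad <- s[!s$passed, ]
    cat("  mismatches:", paste(sprintf("%s/%s", bad$protocode, bad$aa),
                               collapse = ", "), "\n")
  }
})

setMethod("show", "PeptideLibrary", function(object) {
  cat(sprintf("PeptideLibrary '%s': %d peptides, %d-mers over {%s}, %d cop%s\n",
              object@libraryId, length(object@peptides), object@width,
              paste(object@alphabet, collapse = ","), object@copies,
              if (object@copies == 1L) "y" else "ies"))
})

setMethod("show", "ArrayDesign", function(object) {
  cat(sprintf("ArrayDesign: %d spots on a %d x %d grid (seed %d)\n",
              nrow(object@spots), object@dim[1L], object@dim[2L], object@seed))
  for (lib in object@libraries) show(lib)
})

setMethod("show", "ScreenDataset", function(object) {
  cat(sprintf("ScreenDataset: %d signals, %d peptides, channels: %s\n",
              nrow(object@signals), length(unique(object@signals$peptide)),
              paste(sort(unique(object@signals$rna)), collapse = ", ")))
  if (length(object@missingSpots))
    cat(sprintf("  %d manifest spot(s) without intensities\n",
                length(object@missingSpots)))
})

setMethod("show", "FragmentScores", function(object) {
  cat(sprintf("FragmentScores: %d scored, %d gated (library %s, channel %s, %s level)\n",
              nrow(object@scores), nrow(object@gated),
              object@libraryId, object@channel, object@level))
  print(utils::head(object@scores, 5L), row.names = FALSE)
})

setMethod("show", "SignatureTable", function(object) {
  cat(sprintf("SignatureTable: columns %s (top %d)\n",
              paste(names(object@columns), collapse = ", "), object@topN))
})

setMethod("show", "SubstitutionScan", function(object) {
  cat(sprintf("SubstitutionScan of %s with {%s}: %d variants\n",
              object@seed, paste(object@substitutes, collapse = ","),
              sum(object@variants$position > 0L)))
})

setMethod("show", "SimConfig", function(object) {
  cat(sprintf("SimConfig: %d spots, channels %s, sigma=%.3g, seed=%d\n",
              nrow(object@design@spots),
              paste(names(object@baselines), collapse = ", "),
              object@sigma, object@seed))
  if (nrow(object@effects)) {
    cat("  planted effects:\n")
    print(object@effects, row.names = FALSE)
  }
})

setMethod("show", "PropertyScale", function(object) {
  cat(sprintf("PropertyScale '%s' [%s]: %d residues, nTerm=%g, cTerm=%g\n",
              object@name, object@units, length(object@values),
              object@nTerm, object@cTerm))
})
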