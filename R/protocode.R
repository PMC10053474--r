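# Protocode configuration loading.

#' Path to the bundled protocode configuration
#'
#' The default configuration transcribes the codon assignments of the four
#' protocodes (dominant/recessive AU and GC), the placeholder members
#' X1, X1*, X2 with their deleted flags, and the codon-level complement
#' pairs. The package never invents assignments: [loadProtocodes()] reads
#' this file (or a user-supplied one in the same format).
#'
#' @return File path of the YAML configuration.
#' @export
protocodeConfigFile <- function() {
  system.file("extdata", "protocodes.yaml", package = "protopep",
              mustWork = TRUE)
}

#' Load protocode codon assignments
#'
#' Parses a protocode configuration (see [protocodeConfigFile()] for the
#' format) into validated [Protocode-class] objects. Loading fails loudly
#' on any invariant violation: a codon using a base outside the protocode's
#' two-base alphabet, a codon assigned to two amino acids within one
#' protocode, an unknown amino-acid symbol, or a complement pair whose
#' codons are not reverse complements.
#'
#' @param config Path to a YAML configuration, or a pre-parsed list in the
#'   same structure. Default: the bundled configuration.
#' @return Named list of [Protocode-class] objects.
#' @examples
#' pcs <- loadProtocodes()
#' names(pcs)
#' assignments(pcs[["AU-dominant"]])$F   # "UUU"
#' @export
loadProtocodes <- function(config = protocodeConfigFile()) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  if (!is.list(cfg) || is.null(names(cfg)))
    stop("protocode configuration must be a named list of protocodes")
  out <- lapply(names(cfg), function(nm) {
    pc <- cfg[[nm]]
    dominance <- match.arg(pc$dominance, c("dominant", "recessive"))
    members <- lapply(pc$members, function(x) as.character(unlist(x)))
    cp <- pc$complement_pairs %||% list()
    cpdf <- if (length(cp)) {
      do.call(rbind, lapply(cp, function(q) {
        if (length(q) != 4L)
          stop("complement pairs must be (aa, codon, aa, codon) quadruples")
        data.frame(aa1 = q[[1L]], codon1 = q[[2L]], aa2 = q[[3L]],
                   codon2 = q[[4L]], stringsAsFactors = FALSE)
      }))
    } else data.frame(aa1 = character(), codon1 = character(),
                      aa2 = character(), codon2 = character())
    new("Protocode",
        name = nm,
        baseAlphabet = as.character(unlist(pc$bases)),
        assignments = members,
        deleted = as.character(unlist(pc$deleted %||% character())),
        complementPairs = cpdf,
        dominant = dominance == "dominant")
  })
  stats::setNames(out, names(cfg))
}
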