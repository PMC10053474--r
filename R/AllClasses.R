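# S4 classes for the protocode / peptide-array data model.

#' Protocode: a two-base codon assignment
#'
#' A protocode assigns amino acids (and placeholder members such as X1) to
#' 3-mer codons over a two-base alphabet, either (A,U) or (G,C). Dominant
#' protocodes keep their assignments through combinatorial fusion with the
#' standard genetic code; recessive protocodes are re-assigned.
#'
#' @slot name One of `"AU-dominant"`, `"AU-recessive"`, `"GC-dominant"`,
#'   `"GC-recessive"` (other names are allowed for experimentation).
#' @slot baseAlphabet Ordered pair of complementary RNA bases.
#' @slot assignments Named list: amino-acid symbol -> character vector of
#'   codons over `baseAlphabet`.
#' @slot deleted Character vector of placeholder members flagged as deleted
#'   (their disappearance creates stop codons after fusion).
#' @slot complementPairs `data.frame` with columns `aa1, codon1, aa2, codon2`;
#'   each row records two within-protocode assignments whose codons are
#'   reverse complements.
#' @slot dominant Logical scalar.
#' @export
setClass("Protocode",
  representation(
    name = "character",
    baseAlphabet = "character",
    assignments = "list",
    deleted = "character",
    complementPairs = "data.frame",
    dominant = "logical"
  )
)

setValidity("Protocode", function(object) {
  msg <- character()
  if (length(object@baseAlphabet) != 2L ||
      !all(object@baseAlphabet %in% names(.COMPLEMENT)) ||
      .COMPLEMENT[[object@baseAlphabet[1L]]] != object@baseAlphabet[2L])
    msg <- c(msg, "baseAlphabet must be an ordered pair of complementary RNA bases")
  aas <- names(object@assignments)
  if (is.null(aas) || any(!nzchar(aas)))
    msg <- c(msg, "assignments must be a named list")
  bad <- aas[!.validAaSymbol(aas)]
  if (length(bad))
    msg <- c(msg, paste0("unknown amino-acid symbol(s): ", paste(bad, collapse = ", ")))
  codons <- unlist(object@assignments, use.names = FALSE)
  if (length(codons)) {
    if (!all(grepl("^[ACGU]{3}$", codons)))
      msg <- c(msg, "malformed codon(s) in assignments")
    else {
      letters <- unique(strsplit(paste(codons, collapse = ""), "")[[1L]])
      off <- setdiff(letters, object@baseAlphabet)
      if (length(off))
        msg <- c(msg, paste0("codon base(s) outside the protocode alphabet: ",
                             paste(off, collapse = ", ")))
      if (anyDuplicated(codons))
        msg <- c(msg, paste0("codon assigned to two amino acids: ",
                             paste(unique(codons[duplicated(codons)]), collapse = ", ")))
    }
  }
  if (length(setdiff(object@deleted, aas)))
    msg <- c(msg, "deleted members must be listed in assignments")
  cp <- object@complementPairs
  if (nrow(cp)) {
    need <- c("aa1", "codon1", "aa2", "codon2")
    if (!all(need %in% names(cp)))
      msg <- c(msg, "complementPairs needs columns aa1, codon1, aa2, codon2")
    else {
      for (i in seq_len(nrow(cp))) {
        c1 <- cp$codon1[i]; c2 <- cp$codon2[i]
        if (!c1 %in% (object@assignments[[cp$aa1[i]]] %||% character()) ||
            !c2 %in% (object@assignments[[cp$aa2[i]]] %||% character()))
          msg <- c(msg, sprintf("complement pair %d refers to an unassigned codon", i))
        else if (revcompCodon(c1) != c2)
          msg <- c(msg, sprintf("complement pair %d: %s / %s are not reverse complements",
                                i, c1, c2))
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' Result of combinatorial protocode fusion
#'
#' @slot table `data.frame` with one row per (protocode, amino acid):
#'   columns `protocode`, `aa`, `dominant`, `deleted`, and list-columns
#'   `original` (protocode codons), `fused` (codon set after fusion) and
#'   `rules` (per fused codon, the mutation rule that produced it:
#'   `"original"`, `"third-position"`, `"first-position"`,
#'   `"first-and-third"`).
#' @slot conflicts `data.frame` of re-assignment failures (`protocode`,
#'   `aa`, `codon`, `reason`); empty when the take-what's-left resolution
#'   succeeded for every recessive codon.
#' @export
setClass("FusionResult",
  representation(table = "data.frame", conflicts = "data.frame")
)

#' Validation of a fusion result against the standard genetic code
#'
#' @slot codons Per fused codon: `protocode`, `aa`, `codon`, `sgc` (the
#'   SGC's assignment), `status` (`"match"`, `"stop_emergent"`,
#'   `"late_entry"`, `"reassigned"`, `"mismatch"`).
#' @slot summary Per amino acid: `protocode`, `aa`, `passed`, `nMismatch`.
#' @export
setClass("SgcValidation",
  representation(codons = "data.frame", summary = "data.frame")
)

#' Fully combinatorial peptide library
#'
#' @slot libraryId Library identifier (conventionally the protocode name).
#' @slot alphabet Ordered character vector of one-letter residue symbols.
#' @slot width Peptide length in residues.
#' @slot peptides Unique peptide sequences (N- to C-terminal).
#' @slot copies Default replicate spot count per peptide for array layout.
#' @export
setClass("PeptideLibrary",
  representation(
    libraryId = "character",
    alphabet = "character",
    width = "integer",
    peptides = "character",
    copies = "integer"
  )
)

setValidity("PeptideLibrary", function(object) {
  msg <- character()
  if (anyDuplicated(object@alphabet))
    msg <- c(msg, "duplicate alphabet symbols")
  if (length(object@peptides)) {
    if (!all(nchar(object@peptides) == object@width))
      msg <- c(msg, "all peptides must have exactly `width` residues")
    if (anyDuplicated(object@peptides))
      msg <- c(msg, "duplicate peptide sequences")
    used <- unique(strsplit(paste(object@peptides, collapse = ""), "")[[1L]])
    if (length(setdiff(used, object@alphabet)))
      msg <- c(msg, "peptides use residues outside the alphabet")
    if (length(object@peptides) > length(object@alphabet)^as.numeric(object@width))
      msg <- c(msg, "more peptides than |alphabet|^width")
  }
  if (object@copies < 1L) msg <- c(msg, "copies must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Randomized, replicated array design
#'
#' @slot spots `data.frame` with columns `spot_id`, `row`, `col`,
#'   `peptide`, `library_id`, `copy`.
#' @slot libraries Named list of [PeptideLibrary-class] objects.
#' @slot seed Layout seed.
#' @slot dim Grid dimensions `c(nrow, ncol)`.
#' @slot pitch Spot pitch in micrometers (metadata only).
#' @slot acetylN,linkerBetaAla Synthesis chemistry flags (metadata only):
#'   N-terminal acetylation and C-terminal beta-alanine linker.
#' @export
setClass("ArrayDesign",
  representation(
    spots = "data.frame",
    libraries = "list",
    seed = "integer",
    dim = "integer",
    pitch = "numeric",
    acetylN = "logical",
    linkerBetaAla = "logical"
  )
)

setValidity("ArrayDesign", function(object) {
  msg <- character()
  sp <- object@spots
  need <- c("spot_id", "row", "col", "peptide", "library_id", "copy")
  if (!all(need %in% names(sp)))
    return(paste("spots must have columns", paste(need, collapse = ", ")))
  if (anyDuplicated(sp$spot_id)) msg <- c(msg, "duplicate spot ids")
  if (anyDuplicated(sp[, c("row", "col")])) msg <- c(msg, "duplicate spot coordinates")
  if (any(sp$row < 1L) || any(sp$row > object@dim[1L]) ||
      any(sp$col < 1L) || any(sp$col > object@dim[2L]))
    msg <- c(msg, "spot coordinates outside the grid")
  for (lid in unique(sp$library_id)) {
    lib <- object@libraries[[lid]]
    if (is.null(lib)) { msg <- c(msg, paste0("undeclared library: ", lid)); next }
    pep <- sp$peptide[sp$library_id == lid]
    if (length(setdiff(unique(pep), lib@peptides)))
      msg <- c(msg, paste0("spots carry peptides not in library ", lid))
    tab <- table(pep)
    if (length(unique(tab)) != 1L)
      msg <- c(msg, paste0("unequal replicate counts within library ", lid))
  }
  if (length(msg)) msg else TRUE
})

#' Joined screen dataset
#'
#' Join of spot-level intensities with the array manifest: one row per
#' (spot, RNA channel) carrying the peptide, its library/protocode and the
#' fluorescence intensity in arbitrary units.
#'
#' @slot signals `data.frame` with columns `spot_id`, `row`, `col`,
#'   `peptide`, `library_id`, `copy`, `channel` (raw label), `rna`
#'   (mapped RNA channel), `intensity`.
#' @slot channelMap Named character vector, raw channel label -> RNA channel.
#' @slot missingSpots Manifest spot ids with no intensity record.
#' @slot design The originating [ArrayDesign-class].
#' @export
setClass("ScreenDataset",
  representation(
    signals = "data.frame",
    channelMap = "character",
    missingSpots = "character",
    design = "ArrayDesign"
  )
)

#' Fragment interaction scores
#'
#' Interaction scores R = mean(I)/sd(I) over the signal set I of every
#' contiguous peptide fragment, plus the fragments excluded by the
#' support / positive-sd gate (reported, never scored as infinite).
#'
#' @slot scores `data.frame`: `fragment`, `length`, `support`, `mean`,
#'   `sd`, `R`, ordered by descending R (ties: longer fragment first, then
#'   lexicographic).
#' @slot gated `data.frame`: fragments failing the gate, with `reason`.
#' @slot channel RNA channel scored.
#' @slot libraryId Library scored.
#' @slot level `"spot"` or `"peptide"`.
#' @export
setClass("FragmentScores",
  representation(
    scores = "data.frame",
    gated = "data.frame",
    channel = "character",
    libraryId = "character",
    level = "character"
  )
)

#' Signature table of ranked fragment columns
#'
#' Column n holds all scored fragments of lengths kMin..n ranked by
#' descending interaction score, cut at the top N; consecutive columns
#' reveal the displacement of short signatures by longer ones.
#'
#' @slot columns Named list of `data.frame`s (`rank`, `fragment`, `length`,
#'   `R`), names like `"3mer"`, `"3-4mer"`, ...
#' @slot topN Top cut per column.
#' @slot kMin Minimum fragment length ranked.
#' @export
setClass("SignatureTable",
  representation(columns = "list", topN = "integer", kMin = "integer")
)

#' Single-position substitution scan
#'
#' @slot seed Seed peptide sequence.
#' @slot substitutes Substitute residues, in display order.
#' @slot variants `data.frame`: `position`, `residue`, `sequence`,
#'   position-major then residue order; the unmodified seed is included as
#'   a reference row with `position = 0`.
#' @export
setClass("SubstitutionScan",
  representation(seed = "character", substitutes = "character",
                 variants = "data.frame")
)

setValidity("SubstitutionScan", function(object) {
  v <- object@variants[object@variants$position > 0L, , drop = FALSE]
  if (!nrow(v)) return("empty scan: substitutes equal the seed at every position")
  seedRes <- strsplit(object@seed, "")[[1L]]
  ok <- vapply(seq_len(nrow(v)), function(i) {
    s <- strsplit(v$sequence[i], "")[[1L]]
    p <- v$position[i]
    sum(s != seedRes) == 1L && s[p] == v$residue[i] && seedRes[p] != v$residue[i]
  }, logical(1L))
  if (!all(ok)) return("variants must differ from the seed at exactly their position")
  TRUE
})

#' Generative model for synthetic screens
#'
#' Spot intensity model: for spot s with peptide p in channel c,
#' `I = baseline_c * libraryEffect(p, c) * prod(effect^matches) *
#' exp(coef * property(p)) * exp(N(0, sigma^2))`.
#'
#' @slot design [ArrayDesign-class] to simulate on.
#' @slot baselines Named numeric, RNA channel -> baseline intensity (> 0).
#' @slot effects `data.frame` of planted motif effects: `motif`, `channel`,
#'   `effect` (> 0 multiplier), `mode` (`"occurrence"` or `"presence"`),
#'   `saturation` (max counted occurrences, NA = none), `position`
#'   (anchor position, NA = anywhere).
#' @slot libraryEffects `data.frame`: `library_id`, `channel`, `effect`.
#' @slot propertyEffect Empty list, or `list(scale = PropertyScale,
#'   coef = numeric)` adding `coef * sumProperty(p)` to log-intensity.
#' @slot sigma Lognormal spot-noise sigma (log scale, >= 0).
#' @slot seed Default simulation seed.
#' @export
setClass("SimConfig",
  representation(
    design = "ArrayDesign",
    baselines = "numeric",
    effects = "data.frame",
    libraryEffects = "data.frame",
    propertyEffect = "list",
    sigma = "numeric",
    seed = "integer"
  )
)

setValidity("SimConfig", function(object) {
  msg <- character()
  if (!length(object@baselines) || is.null(names(object@baselines)))
    msg <- c(msg, "baselines must be a named numeric vector")
  if (any(object@baselines <= 0)) msg <- c(msg, "baselines must be > 0")
  if (object@sigma < 0) msg <- c(msg, "sigma must be >= 0")
  ef <- object@effects
  if (nrow(ef)) {
    if (any(ef$effect <= 0)) msg <- c(msg, "effect multipliers must be > 0")
    if (!all(ef$channel %in% names(object@baselines)))
      msg <- c(msg, "effect channels must have baselines")
    if (!all(ef$mode %in% c("occurrence", "presence")))
      msg <- c(msg, "effect mode must be 'occurrence' or 'presence'")
    alpha <- unique(unlist(lapply(object@design@libraries, function(l) l@alphabet)))
    bad <- vapply(ef$motif, function(m)
      length(setdiff(strsplit(m, "")[[1L]], alpha)) > 0, logical(1L))
    if (any(bad))
      msg <- c(msg, paste0("motif uses residues outside the design alphabet: ",
                           paste(ef$motif[bad], collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' Residue property scale
#'
#' @slot name Scale name (e.g. `"charge"`).
#' @slot units Units of the summed property (e, Da, kcal/mol, ...).
#' @slot values Named numeric, residue -> value.
#' @slot nTerm,cTerm Terminal adjustments added once per peptide
#'   (acetylated N-terminus, linker-attached C-terminus).
#' @export
setClass("PropertyScale",
  representation(name = "character", units = "character",
                 values = "numeric", nTerm = "numeric", cTerm = "numeric")
)

setValidity("PropertyScale", function(object) {
  if (is.null(names(object@values)) || !all(nzchar(names(object@values))))
    return("values must be a named numeric vector (residue -> value)")
  TRUE
})
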