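# Synthetic screen generator: multiplicative planted effects with
# lognormal spot noise.

#' Construct a synthetic-screen configuration
#'
#' The generative model for spot s carrying peptide p in channel c is
#' multiplicative (log-additive):
#' `I(s) = baseline_c * libEffect(library(p), c) *
#'   prod_e effect_e^n_e(p) * exp(coef * property(p)) * exp(N(0, sigma^2))`
#' where `n_e(p)` is the number of (overlapping) occurrences of motif e in
#' p, capped at `saturation` and reduced to an indicator for
#' `mode = "presence"`; position-anchored effects fire when the motif
#' occurs at exactly the anchor position.
#'
#' @param design An [ArrayDesign-class].
#' @param baselines Named numeric: RNA channel -> baseline intensity
#'   (arbitrary fluorescence units, > 0).
#' @param effects `data.frame` of planted motif effects with columns
#'   `motif`, `channel`, `effect` (> 0), and optionally `mode`
#'   (`"occurrence"` default, or `"presence"`), `saturation` (max counted
#'   occurrences; `NA` = uncapped) and `position` (anchor; `NA` =
#'   anywhere).
#' @param libraryEffects `data.frame` with `library_id`, `channel`,
#'   `effect`: per-library multipliers (e.g. a dominant-protocode boost).
#' @param propertyEffect `NULL`, or `list(scale = PropertyScale, coef =
#'   numeric)`: adds `coef * sumProperty(p, scale)` to the log intensity.
#' @param sigma Lognormal spot-noise standard deviation on the log scale.
#' @param seed Default simulation seed (overridable in
#'   [simulateScreen()]).
#' @return A [SimConfig-class].
#' @export
simConfig <- function(design, baselines, effects = NULL,
                      libraryEffects = NULL, propertyEffect = NULL,
                      sigma = 0.3, seed = 1L) {
  stopifnot(is(design, "ArrayDesign"))
  ef <- if (is.null(effects) || !NROW(effects))
    data.frame(motif = character(), channel = character(), effect = numeric(),
               mode = character(), saturation = numeric(), position = numeric())
  else {
    ef <- as.data.frame(effects)
    if (!all(c("motif", "channel", "effect") %in% names(ef)))
      stop("effects needs columns motif, channel, effect")
    if (is.null(ef$mode)) ef$mode <- "occurrence"
    if (is.null(ef$saturation)) ef$saturation <- NA_real_
    if (is.null(ef$position)) ef$position <- NA_real_
    ef[, c("motif", "channel", "effect", "mode", "saturation", "position")]
  }
  le <- if (is.null(libraryEffects) || !NROW(libraryEffects))
    data.frame(library_id = character(), channel = character(),
               effect = numeric())
  else as.data.frame(libraryEffects)[, c("library_id", "channel", "effect")]
  new("SimConfig", design = design,
      baselines = baselines, effects = ef, libraryEffects = le,
      propertyEffect = propertyEffect %||% list(),
      sigma = sigma, seed = as.integer(seed))
}

# Deterministic per-peptide multiplier (baseline x library x motif x
# property terms) for one channel; no noise.
.channelMultiplier <- function(config, channel, peptides, libraryIds) {
  base <- config@baselines[[channel]]
  mult <- rep(base, length(peptides))
  le <- config@libraryEffects
  le <- le[le$channel == channel, , drop = FALSE]
  for (i in seq_len(nrow(le)))
    mult[libraryIds == le$library_id[i]] <- mult[libraryIds == le$library_id[i]] *
      le$effect[i]
  ef <- config@effects
  ef <- ef[ef$channel == channel, , drop = FALSE]
  if (nrow(ef)) {
    aas <- Biostrings::AAStringSet(peptides)
    for (i in seq_len(nrow(ef))) {
      if (is.na(ef$position[i])) {
        n <- Biostrings::vcountPattern(ef$motif[i], aas)
      } else {
        p <- as.integer(ef$position[i])
        n <- as.integer(substr(peptides, p, p + nchar(ef$motif[i]) - 1L) ==
                        ef$motif[i])
      }
      if (!is.na(ef$saturation[i])) n <- pmin(n, ef$saturation[i])
      if (ef$mode[i] == "presence") n <- as.integer(n > 0L)
      mult <- mult * ef$effect[i]^n
    }
  }
  pe <- config@propertyEffect
  if (length(pe))
    mult <- mult * exp(pe$coef * sumProperty(peptides, pe$scale))
  mult
}

#' Simulate a synthetic screen
#'
#' Draws one intensity per (spot, channel) under the configuration's
#' generative model (see [simConfig()]). With `sigma = 0` the output is
#' the exact closed-form intensity. The result is readable by
#' [buildScreenDataset()] directly or through a
#' [writeIntensityTable()] / [readPhotometricTable()] round trip, and is
#' deterministic given the seed.
#'
#' @param config A [SimConfig-class].
#' @param seed Simulation seed; defaults to the config's.
#' @return `data.frame` with columns `spot_id`, `row`, `col`, `channel`,
#'   `intensity` (channels ordered as in the config's baselines).
#' @examples
#' lib <- enumerateLibrary(c("G", "P"), 3, "toy")
#' cfg <- simConfig(layoutArray(lib, copies = 2, seed = 1),
#'                  baselines = c(C12 = 100), sigma = 0)
#' all(simulateScreen(cfg)$intensity == 100)
#' @export
simulateScreen <- function(config, seed = NULL) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  seed <- as.integer(seed %||% config@seed)
  sp <- config@design@spots
  peps <- unique(sp$peptide)
  lid <- sp$library_id[match(peps, sp$peptide)]
  channels <- names(config@baselines)
  noise <- withSeed(seed, {
    matrix(stats::rnorm(nrow(sp) * length(channels), 0, 1),
           nrow = nrow(sp), ncol = length(channels))
  })
  out <- lapply(seq_along(channels), function(ci) {
    mult <- .channelMultiplier(config, channels[ci], peps, lid)
    spotMult <- mult[match(sp$peptide, peps)]
    data.frame(spot_id = sp$spot_id, row = sp$row, col = sp$col,
               channel = channels[ci],
               intensity = spotMult * exp(config@sigma * noise[, ci]),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Simulation config for a substitution-scan mini-array
#'
#' The substitution scan is its own small chip: only the seed peptide and
#' its single-position variants are synthesized. This helper lays the
#' scan's peptides out as a replicated mini-array and reuses a template
#' configuration's channel baselines, planted effects, library effects,
#' property effect and noise, so the scan is screened under the same
#' generative model as the full library.
#'
#' @param scan A [SubstitutionScan-class].
#' @param template A [SimConfig-class] supplying the generative model.
#' @param copies Replicate spots per variant.
#' @param seed Layout seed (also the returned config's default seed).
#' @param libraryId Library id for the scan peptides; defaults to the
#'   template's first library with a matching alphabet, else `"scan"`.
#' @return A [SimConfig-class] over the scan mini-array.
#' @export
scanScreenConfig <- function(scan, template, copies = 2L, seed = 1L,
                             libraryId = NULL) {
  stopifnot(is(scan, "SubstitutionScan"), is(template, "SimConfig"))
  seqs <- unique(scan@variants$sequence)
  alpha <- sort(unique(strsplit(paste(seqs, collapse = ""), "")[[1L]]))
  if (is.null(libraryId)) {
    hit <- Filter(function(l) all(alpha %in% l@alphabet),
                  template@design@libraries)
    libraryId <- if (length(hit)) hit[[1L]]@libraryId else "scan"
  }
  lib <- new("PeptideLibrary", libraryId = libraryId, alphabet = alpha,
             width = nchar(scan@seed), peptides = seqs,
             copies = as.integer(copies))
  design <- layoutArray(lib, seed = seed)
  simConfig(design, baselines = template@baselines,
            effects = template@effects,
            libraryEffects = template@libraryEffects,
            propertyEffect = if (length(template@propertyEffect))
              template@propertyEffect else NULL,
            sigma = template@sigma, seed = seed)
}

#' Ready-made configurations emulating the two screens
#'
#' Order-of-magnitude emulations of the AU and GC screens (they are not
#' fits to any measured data):
#'
#' * `"AU"`: the 6-mer AU libraries - the full dominant enumeration
#'   (5 residues, K/F/N/I/Y) plus the recessive one (6 residues,
#'   E/L/D/V/Q/H), subsampled together to `auSize` peptides (default
#'   23,403, the synthesized library size) - laid out at 3 copies.
#'   Channels `A12` and `U12` with baselines 1500 and 60 (ratio 25: the
#'   adenine channel dominates the uracil channel by well over an order
#'   of magnitude), a dominant-library boost in `A12`, and planted
#'   per-occurrence F and Y effects in `A12` (aromatic side chains drive
#'   adenine binding).
#' * `"GC"`: the full 7-mer GC libraries (dominant G/P/A/R and recessive
#'   S/T/C/R, 16,384 peptides each) at 2 copies. Channels `C12` and
#'   `G12` with baselines 3000 and 1000 (ratio 3), a dominant-library
#'   boost in `C12`, a planted per-occurrence proline effect (x2 per P,
#'   saturating at 5 occurrences: polyproline runs exhaust their binding
#'   potential at the 5-mer level) and, when `positionBonus = TRUE`, an
#'   alanine-at-position-4 bonus (x3) in `C12` so that a polyproline
#'   substitution scan recovers PPPAPPP as the strongest binder.
#'
#' @param which `"AU"` or `"GC"`.
#' @param seed Seed used for the layout, the AU subsample and as the
#'   config's default simulation seed.
#' @param copies Replicate spots per peptide (default 3 for AU, 2 for GC).
#' @param auSize Synthesized AU library size (subsampled from the 62,281
#'   full combinatorial enumeration).
#' @param positionBonus Include the GC preset's alanine-at-position-4
#'   bonus effect.
#' @param sigma Lognormal noise sigma.
#' @return A [SimConfig-class].
#' @export
presetPaperlike <- function(which = c("AU", "GC"), seed = 1L,
                            copies = NULL, auSize = 23403L,
                            positionBonus = TRUE, sigma = 0.3) {
  which <- match.arg(which)
  if (which == "AU") {
    copies <- as.integer(copies %||% 3L)
    dom <- enumerateLibrary(c("K", "F", "N", "I", "Y"), 6L,
                            "AU-dominant", copies = copies)
    rec <- enumerateLibrary(c("E", "L", "D", "V", "Q", "H"), 6L,
                            "AU-recessive", copies = copies)
    # Subsample the pooled enumeration down to the synthesized size,
    # keeping the dominant/recessive split induced by the draw.
    nDom <- length(dom@peptides)
    total <- nDom + length(rec@peptides)
    keep <- sort(withSeed(seed, sample.int(total, min(auSize, total))))
    dom <- initialize(dom, peptides = dom@peptides[keep[keep <= nDom]])
    rec <- initialize(rec, peptides = rec@peptides[keep[keep > nDom] - nDom])
    design <- layoutArray(list(dom, rec), seed = seed)
    effects <- data.frame(
      motif = c("F", "Y"), channel = "A12", effect = c(1.25, 1.2),
      mode = "occurrence", saturation = NA_real_, position = NA_real_)
    libEff <- data.frame(library_id = "AU-dominant", channel = "A12",
                         effect = 1.3)
    simConfig(design, baselines = c(A12 = 1500, U12 = 60),
              effects = effects, libraryEffects = libEff,
              sigma = sigma, seed = seed)
  } else {
    copies <- as.integer(copies %||% 2L)
    dom <- enumerateLibrary(c("G", "P", "A", "R"), 7L,
                            "GC-dominant", copies = copies)
    rec <- enumerateLibrary(c("S", "T", "C", "R"), 7L,
                            "GC-recessive", copies = copies)
    design <- layoutArray(list(dom, rec), seed = seed)
    effects <- data.frame(
      motif = "P", channel = "C12", effect = 2, mode = "occurrence",
      saturation = 5, position = NA_real_)
    if (positionBonus)
      effects <- rbind(effects, data.frame(
        motif = "A", channel = "C12", effect = 3, mode = "presence",
        saturation = NA_real_, position = 4))
    libEff <- data.frame(library_id = c("GC-dominant", "GC-dominant"),
                         channel = c("C12", "G12"), effect = c(2.5, 1.2))
    simConfig(design, baselines = c(C12 = 3000, G12 = 1000),
              effects = effects, libraryEffects = libEff,
              sigma = sigma, seed = seed)
  }
}
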