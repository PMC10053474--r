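# Independent oracles and small fixture builders, kept deliberately naive.

# Brute-force fragment scorer: nested loops over peptides and substring
# windows, collecting signal sets in an environment. Independent of the
# package's data.table path.
bruteForceFragmentScores <- function(signalTable, kMin = 3L, kMax = NULL,
                                     minSupport = 3L) {
  peps <- unique(signalTable$peptide)
  L <- nchar(peps[1L])
  if (is.null(kMax)) kMax <- L
  sets <- new.env(parent = emptyenv())
  for (p in peps) {
    sig <- signalTable$intensity[signalTable$peptide == p]
    frags <- character()
    for (k in kMin:kMax)
      for (s in 1:(L - k + 1L))
        frags <- c(frags, substr(p, s, s + k - 1L))
    for (f in unique(frags))
      assign(f, c(if (exists(f, sets)) get(f, sets) else numeric(), sig),
             envir = sets)
  }
  frags <- ls(sets)
  out <- data.frame(fragment = frags,
                    support = NA_real_, mean = NA_real_, sd = NA_real_,
                    R = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_along(frags)) {
    x <- get(frags[i], sets)
    out$support[i] <- length(x)
    out$mean[i] <- mean(x)
    out$sd[i] <- sd(x)
    out$R[i] <- if (length(x) >= minSupport && isTRUE(sd(x) > 0))
      mean(x) / sd(x) else NA_real_
  }
  out
}

# Minimal screen dataset straight from explicit spot records.
toyDataset <- function(spotTable, width = NULL) {
  libs <- lapply(split(spotTable, spotTable$library_id), function(d) {
    peps <- unique(d$peptide)
    new("PeptideLibrary", libraryId = d$library_id[1L],
        alphabet = sort(unique(strsplit(paste(peps, collapse = ""), "")[[1L]])),
        width = as.integer(nchar(peps[1L])), peptides = peps,
        copies = as.integer(max(table(d$peptide[d$rna == d$rna[1L]]))))
  })
  n <- nrow(spotTable)
  ids <- unique(spotTable[, c("spot_id", "peptide", "library_id")])
  design <- new("ArrayDesign",
                spots = data.frame(spot_id = ids$spot_id,
                                   row = seq_len(nrow(ids)), col = 1L,
                                   peptide = ids$peptide,
                                   library_id = ids$library_id,
                                   copy = as.integer(ave(seq_len(nrow(ids)),
                                                         ids$peptide,
                                                         FUN = seq_along)),
                                   stringsAsFactors = FALSE),
                libraries = libs, seed = 0L,
                dim = c(nrow(ids), 1L), pitch = 60,
                acetylN = TRUE, linkerBetaAla = TRUE)
  sig <- merge(design@spots, spotTable[, c("spot_id", "rna", "intensity")],
               by = "spot_id")
  sig$channel <- sig$rna
  sig <- sig[order(sig$spot_id, sig$rna),
             c("spot_id", "row", "col", "peptide", "library_id", "copy",
               "channel", "rna", "intensity")]
  rownames(sig) <- NULL
  rnas <- unique(spotTable$rna)
  new("ScreenDataset", signals = sig,
      channelMap = setNames(rnas, rnas),
      missingSpots = character(), design = design)
}

# Small simulated dataset: full combinatorial library, planted effects.
simulatedDataset <- function(alphabet, width, copies = 2L, seed = 1L,
                             baselines = c(C12 = 100), effects = NULL,
                             libraryId = "lib", sigma = 0.3,
                             propertyEffect = NULL) {
  lib <- enumerateLibrary(alphabet, width, libraryId, copies = copies)
  design <- layoutArray(lib, seed = seed)
  cfg <- simConfig(design, baselines = baselines, effects = effects,
                   propertyEffect = propertyEffect, sigma = sigma,
                   seed = seed)
  buildScreenDataset(design, simulateScreen(cfg, seed = seed))
}

# Sample skewness g1.
skewness1 <- function(x) mean((x - mean(x))^3) / sd(x)^3
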