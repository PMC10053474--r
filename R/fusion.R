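# Combinatorial fusion of protocodes onto the standard genetic code.

#' Apply the combinatorial fusion rules to a protocode set
#'
#' Fusion merges the AU- and GC-protocodes into the 4-base code via
#' Watson-Crick transition mutations (A<->G, U<->C):
#'
#' * **Dominant** protocodes keep their original codon assignments and gain
#'   the third-position transition mutant of every original codon.
#' * **Recessive** protocodes lose their originals (the dominant competitor
#'   keeps them) and take what's left: for every original codon, the
#'   first-position and the first-and-third-position transition images,
#'   provided the target codon is free, i.e. not claimed by any dominant
#'   fused set and not already assigned to another recessive amino acid.
#'   Because transitions commute with complementation, taking both images
#'   preserves the original within-protocode complement pairing (the
#'   first-and-third images of complementary originals remain reverse
#'   complements); this is checked and any violation reported.
#'
#' A recessive codon for which neither transition image is free is recorded
#' in the `conflicts` slot (reported per amino acid, never silently
#' dropped). A dominant amino acid with an empty codon set is an error.
#'
#' @param protocodes Named list of [Protocode-class] objects (typically
#'   [loadProtocodes()] output). Dominant and recessive protocodes of both
#'   base families may be fused together; the free-codon constraint is
#'   evaluated over the whole set.
#' @return A [FusionResult-class].
#' @examples
#' fr <- applyFusion(loadProtocodes())
#' tab <- fusionTable(fr)
#' tab$fused[tab$aa == "F" & tab$protocode == "AU-dominant"]  # UUU, UUC
#' @export
applyFusion <- function(protocodes) {
  if (!length(protocodes)) stop("empty protocode set")
  lapply(protocodes, validObject)

  dom <- Filter(isDominant, protocodes)
  rec <- Filter(function(p) !isDominant(p), protocodes)

  rows <- list()
  addRow <- function(pc, aa, original, fused, rules) {
    rows[[length(rows) + 1L]] <<- data.frame(
      protocode = pc@name, aa = aa, dominant = pc@dominant,
      deleted = aa %in% pc@deleted,
      original = I(list(original)), fused = I(list(fused)),
      rules = I(list(rules)), stringsAsFactors = FALSE)
  }

  # Dominant: originals plus their third-position transition mutants.
  occupied <- character()
  for (pc in dom) {
    for (aa in names(pc@assignments)) {
      orig <- pc@assignments[[aa]]
      if (!length(orig))
        stop(sprintf("dominant amino acid %s in %s has an empty codon set",
                     aa, pc@name))
      mut <- mutateCodon(orig, 3L)
      fused <- c(orig, setdiff(mut, orig))
      rules <- c(rep("original", length(orig)),
                 rep("third-position", length(setdiff(mut, orig))))
      addRow(pc, aa, orig, fused, rules)
      occupied <- c(occupied, fused)
    }
  }
  if (anyDuplicated(occupied))
    stop("dominant fused sets collide: ",
         paste(unique(occupied[duplicated(occupied)]), collapse = ", "))

  # Recessive: take what's left via first-position / first-and-third
  # transitions into free codons.
  conflicts <- list()
  taken <- occupied
  for (pc in rec) {
    for (aa in names(pc@assignments)) {
      orig <- pc@assignments[[aa]]
      fused <- character(); rules <- character()
      for (cd in orig) {
        for (rule in c("first-position", "first-and-third")) {
          target <- if (rule == "first-position") mutateCodon(cd, 1L)
                    else mutateCodon(cd, c(1L, 3L))
          if (target %in% taken) {
            conflicts[[length(conflicts) + 1L]] <- data.frame(
              protocode = pc@name, aa = aa, codon = cd, target = target,
              rule = rule, reason = "target codon not free",
              stringsAsFactors = FALSE)
          } else {
            fused <- c(fused, target); rules <- c(rules, rule)
            taken <- c(taken, target)
          }
        }
      }
      addRow(pc, aa, orig, fused, rules)
    }
    # Complement-pair preservation: the first-and-third images of paired
    # originals must remain reverse complements.
    cp <- pc@complementPairs
    for (i in seq_len(nrow(cp))) {
      t1 <- mutateCodon(cp$codon1[i], c(1L, 3L))
      t2 <- mutateCodon(cp$codon2[i], c(1L, 3L))
      if (revcompCodon(t1) != t2)
        conflicts[[length(conflicts) + 1L]] <- data.frame(
          protocode = pc@name, aa = cp$aa1[i], codon = cp$codon1[i],
          target = t1, rule = "first-and-third",
          reason = "complement pairing violated", stringsAsFactors = FALSE)
    }
  }

  new("FusionResult",
      table = do.call(rbind, rows),
      conflicts = if (length(conflicts)) do.call(rbind, conflicts)
                  else data.frame(protocode = character(), aa = character(),
                                  codon = character(), target = character(),
                                  rule = character(), reason = character()))
}

#' Fusion result as a flat data.frame
#'
#' @param result A [FusionResult-class].
#' @return `data.frame` with one row per fused codon: `protocode`, `aa`,
#'   `dominant`, `deleted`, `codon`, `rule`.
#' @export
fusionTable <- function(result) {
  stopifnot(is(result, "FusionResult"))
  tab <- result@table
  do.call(rbind, lapply(seq_len(nrow(tab)), function(i) {
    data.frame(protocode = tab$protocode[i], aa = tab$aa[i],
               dominant = tab$dominant[i], deleted = tab$deleted[i],
               fused = tab$fused[[i]], rule = tab$rules[[i]],
               stringsAsFactors = FALSE)
  }))
}

#' Validate a fusion result against the standard genetic code
#'
#' Per fused codon, compares the fusion assignment with the SGC:
#'
#' * `"match"` - the SGC assigns the codon to the same amino acid;
#' * `"stop_emergent"` - a deleted placeholder's codon that is a stop codon
#'   in the SGC (the disappearance of X1 explains stops UAA and UAG, that
#'   of X2 explains UGA);
#' * `"late_entry"` - the SGC assigns the codon to Met (AUG) or Trp (UGG),
#'   which entered the code after fusion;
#' * `"reassigned"` - a deleted placeholder's codon taken over by a
#'   traveling amino acid (e.g. Leu at UUA/UUG after X1* disappeared);
#' * `"mismatch"` - anything else.
#'
#' An amino acid passes when none of its fused codons is a mismatch.
#'
#' @param result A [FusionResult-class].
#' @param sgc SGC table as returned by [sgcTable()].
#' @return An [SgcValidation-class] report.
#' @export
validateAgainstSgc <- function(result, sgc = sgcTable()) {
  stopifnot(is(result, "FusionResult"))
  tab <- result@table
  rows <- lapply(seq_len(nrow(tab)), function(i) {
    fused <- tab$fused[[i]]
    if (!length(fused)) return(NULL)
    sa <- unname(sgc[fused])
    status <- ifelse(sa == tab$aa[i], "match", "mismatch")
    if (tab$deleted[i]) {
      status[sa == "*"] <- "stop_emergent"
      status[status == "mismatch" & sa %in% c("M", "W")] <- "late_entry"
      status[status == "mismatch"] <- "reassigned"
    } else {
      status[status == "mismatch" & fused %in% names(.LATE_ENTRY)] <- "late_entry"
    }
    data.frame(protocode = tab$protocode[i], aa = tab$aa[i], codon = fused,
               sgc = sa, status = status, stringsAsFactors = FALSE)
  })
  codons <- do.call(rbind, rows)
  agg <- stats::aggregate(codons$status == "mismatch",
                          by = list(protocode = codons$protocode, aa = codons$aa),
                          FUN = sum)
  names(agg)[3L] <- "nMismatch"
  agg$passed <- agg$nMismatch == 0L
  agg <- agg[order(agg$protocode, agg$aa), c("protocode", "aa", "passed", "nMismatch")]
  rownames(agg) <- NULL
  new("SgcValidation", codons = codons, summary = agg)
}

#' Stop codons emerging from placeholder deletion
#'
#' Collects the fused codons of deleted placeholder members that the SGC
#' marks as stop codons.
#'
#' @param validation An [SgcValidation-class].
#' @return Character vector of emergent stop codons.
#' @examples
#' v <- validateAgainstSgc(applyFusion(loadProtocodes()))
#' emergentStops(v)   # UAA, UAG, UGA
#' @export
emergentStops <- function(validation) {
  stopifnot(is(validation, "SgcValidation"))
  cd <- validation@codons
  sort(unique(cd$codon[cd$status == "stop_emergent"]))
}
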