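# Fragment interaction scoring: R = mean(I)/sd(I) over the fluorescence
# signal set of every contiguous peptide fragment.

#' Enumerate contiguous fragments of a peptide
#'
#' All contiguous substrings with length in `[kMin, kMax]`, duplicates
#' collapsed (set semantics: a fragment occurring twice in a peptide is
#' listed once).
#'
#' @param sequence A single peptide sequence.
#' @param kMin,kMax Fragment length range
#'   (`1 <= kMin <= kMax <= nchar(sequence)`).
#' @return Character vector of unique fragments, ordered by length then
#'   position of first occurrence.
#' @examples
#' enumerateFragments("AECD", 1, 4)
#' # "A" "E" "C" "D" "AE" "EC" "CD" "AEC" "ECD" "AECD"
#' @export
enumerateFragments <- function(sequence, kMin = 1L, kMax = nchar(sequence)) {
  stopifnot(length(sequence) == 1L, nzchar(sequence))
  L <- nchar(sequence)
  kMin <- as.integer(kMin); kMax <- as.integer(kMax)
  if (is.na(kMin) || is.na(kMax) || kMin < 1L || kMax < kMin || kMax > L)
    stop(sprintf("invalid fragment length range [%s, %s] for a %d-mer",
                 kMin, kMax, L))
  out <- unlist(lapply(kMin:kMax, function(k)
    unique(substring(sequence, 1:(L - k + 1L), k:L))))
  unique(out)
}

# Fragment-peptide incidence for a vector of equal-length peptides.
# Set semantics: one row per (fragment, peptide) pair; occurrence = TRUE
# keeps one row per occurrence instead.
.fragmentIncidence <- function(peptides, kMin, kMax, occurrence = FALSE) {
  L <- nchar(peptides[1L])
  if (any(nchar(peptides) != L))
    stop("fragment scoring expects equal-length peptides within a library")
  pieces <- list()
  for (k in kMin:kMax) {
    for (s in 1:(L - k + 1L)) {
      pieces[[length(pieces) + 1L]] <- data.table::data.table(
        peptide = peptides,
        fragment = substr(peptides, s, s + k - 1L),
        len = k)
    }
  }
  inc <- data.table::rbindlist(pieces)
  if (!occurrence) inc <- unique(inc, by = c("peptide", "fragment"))
  inc
}

#' Score peptide fragments by R = mean/sd of their signal sets
#'
#' For every contiguous fragment m with length in `[kMin, kMax]` drawn
#' from one library, collects the signal set I_m of all signals from
#' peptides containing m and computes the interaction score
#' `R = mean(I_m) / sd(I_m)` (sample sd, n-1 denominator). The score
#' rises with the average signal of the fragment's peptides and falls
#' with their spread.
#'
#' Fragments with fewer than `minSupport` signals or with zero spread are
#' excluded from the ranking and reported in the `gated` slot (never
#' scored as infinite). Membership uses set semantics: a peptide
#' contributes its signals once however many times the fragment occurs in
#' it (`occurrence = TRUE` weights by occurrence count instead).
#'
#' @param dataset A [ScreenDataset-class].
#' @param channel RNA channel to score (one of `unique(signals(x)$rna)`).
#' @param libraryId Library to score; required when the dataset holds
#'   more than one library.
#' @param kMin,kMax Fragment length range; `kMax = NULL` uses the peptide
#'   length. The ranking convention starts at 3-mers; enumeration
#'   supports `kMin >= 1`.
#' @param minSupport Minimum number of signals per scored fragment.
#' @param level `"spot"` (default: every replicate spot is one signal) or
#'   `"peptide"` (aggregated intensities are the signals).
#' @param aggregate Aggregation statistic for `level = "peptide"`.
#' @param occurrence Count a peptide's signals once per fragment
#'   occurrence instead of once per peptide.
#' @return A [FragmentScores-class]; scores are ordered by descending R
#'   with deterministic tie-breaks (longer fragment first, then
#'   lexicographic).
#' @export
scoreFragments <- function(dataset, channel, libraryId = NULL,
                           kMin = 3L, kMax = NULL, minSupport = 3L,
                           level = c("spot", "peptide"),
                           aggregate = stats::median, occurrence = FALSE) {
  stopifnot(is(dataset, "ScreenDataset"))
  level <- match.arg(level)
  sig <- dataset@signals
  if (!nrow(sig)) stop("empty dataset")
  if (!channel %in% sig$rna)
    stop(sprintf("channel '%s' absent (have: %s)", channel,
                 paste(sort(unique(sig$rna)), collapse = ", ")))
  sig <- sig[sig$rna == channel, , drop = FALSE]
  libs <- unique(sig$library_id)
  if (is.null(libraryId)) {
    if (length(libs) > 1L)
      stop("dataset holds several libraries; pick one via `libraryId`: ",
           paste(libs, collapse = ", "))
    libraryId <- libs
  } else {
    if (!libraryId %in% libs) stop("no signals for library ", libraryId)
    sig <- sig[sig$library_id == libraryId, , drop = FALSE]
  }
  if (level == "peptide") {
    dt <- data.table::as.data.table(sig)
    intensity <- NULL
    sig <- as.data.frame(dt[, list(intensity = aggregate(intensity)),
                            by = "peptide"])
  }
  peps <- unique(sig$peptide)
  L <- nchar(peps[1L])
  kMin <- as.integer(kMin)
  kMax <- if (is.null(kMax)) L else as.integer(kMax)
  if (kMin < 1L || kMax < kMin || kMax > L)
    stop(sprintf("invalid fragment length range [%d, %d] for %d-mers",
                 kMin, kMax, L))

  inc <- .fragmentIncidence(peps, kMin, kMax, occurrence)
  sdt <- data.table::as.data.table(sig[, c("peptide", "intensity")])
  merged <- merge(inc, sdt, by = "peptide", allow.cartesian = TRUE)
  intensity <- len <- NULL
  stats <- merged[, list(length = len[1L], support = .N,
                         mean = mean(intensity), sd = stats::sd(intensity)),
                  by = "fragment"]
  gateLow <- stats$support < as.integer(minSupport)
  gateSd <- !gateLow & (!is.finite(stats$sd) | stats$sd <= 0)
  gated <- as.data.frame(stats[gateLow | gateSd])
  if (nrow(gated))
    gated$reason <- ifelse(gated$support < minSupport,
                           "support below minimum", "zero spread")
  else gated$reason <- character()
  scored <- stats[!(gateLow | gateSd)]
  scored[, "R" := mean / sd]
  data.table::setorderv(scored, c("R", "length", "fragment"),
                        order = c(-1L, -1L, 1L))
  scores <- as.data.frame(
    scored[, c("fragment", "length", "support", "mean", "sd", "R")])
  new("FragmentScores", scores = scores, gated = gated,
      channel = channel, libraryId = libraryId, level = level)
}

#' Build a signature table of cumulative-length fragment columns
#'
#' Column n holds all scored fragments with lengths `kMin..n`, ranked by
#' descending interaction score and cut at `topN`; the next column adds
#' the (n+1)-mers. Reading consecutive columns shows how longer fragments
#' displace shorter binding signatures.
#'
#' @param scores A [FragmentScores-class] (or its `data.frame`).
#' @param topN Fragments kept per column.
#' @param kMin First column's (and the candidate pool's) minimum length;
#'   `NULL` uses the smallest scored length.
#' @return A [SignatureTable-class]; column names are `"3mer"`,
#'   `"3-4mer"`, ...
#' @export
buildSignatureTable <- function(scores, topN = 25L, kMin = NULL) {
  df <- if (is(scores, "FragmentScores")) scores@scores else as.data.frame(scores)
  if (!nrow(df)) stop("no scored fragments")
  kMin <- as.integer(kMin %||% min(df$length))
  kMaxAll <- max(df$length)
  if (kMin > kMaxAll) stop("kMin exceeds the largest scored fragment length")
  topN <- as.integer(topN)
  cols <- list()
  for (n in kMin:kMaxAll) {
    cand <- df[df$length >= kMin & df$length <= n, , drop = FALSE]
    ord <- order(-cand$R, -cand$length, cand$fragment)
    cand <- cand[utils::head(ord, topN), c("fragment", "length", "R")]
    cand <- data.frame(rank = seq_len(nrow(cand)), cand, row.names = NULL)
    nm <- if (n == kMin) sprintf("%dmer", kMin) else sprintf("%d-%dmer", kMin, n)
    cols[[nm]] <- cand
  }
  new("SignatureTable", columns = cols, topN = topN, kMin = kMin)
}

#' Displacement of short signatures by longer fragments
#'
#' For each transition between consecutive signature columns, reports
#' which top-N fragments remain (`"stayed"`), drop out (`"displaced"`)
#' or newly enter (`"entered"`).
#'
#' @param table A [SignatureTable-class] with at least two columns.
#' @return `data.frame`: `from`, `to`, `fragment`, `length`, `status`.
#' @export
displacementAnalysis <- function(table) {
  stopifnot(is(table, "SignatureTable"))
  cols <- table@columns
  if (length(cols) < 2L) stop("displacement analysis needs >= 2 columns")
  out <- list()
  for (i in seq_len(length(cols) - 1L)) {
    a <- cols[[i]]; b <- cols[[i + 1L]]
    status <- ifelse(a$fragment %in% b$fragment, "stayed", "displaced")
    out[[length(out) + 1L]] <- data.frame(
      from = names(cols)[i], to = names(cols)[i + 1L],
      fragment = a$fragment, length = a$length, status = status,
      stringsAsFactors = FALSE)
    ent <- b[!(b$fragment %in% a$fragment), , drop = FALSE]
    if (nrow(ent))
      out[[length(out) + 1L]] <- data.frame(
        from = names(cols)[i], to = names(cols)[i + 1L],
        fragment = ent$fragment, length = ent$length, status = "entered",
        stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Residue composition trend across signature columns
#'
#' Mean count of the given residues among each column's top-N fragments
#' (e.g. the rise of Phe/Tyr content with signature length).
#'
#' @param table A [SignatureTable-class].
#' @param residues Character vector of residues to count (empty set gives
#'   zeros).
#' @return `data.frame`: `column`, `meanCount`.
#' @export
compositionTrend <- function(table, residues) {
  stopifnot(is(table, "SignatureTable"))
  residues <- as.character(residues)
  counts <- vapply(table@columns, function(col) {
    if (!nrow(col)) return(NA_real_)
    mean(vapply(strsplit(col$fragment, ""), function(r)
      sum(r %in% residues), numeric(1L)))
  }, numeric(1L))
  data.frame(column = names(table@columns), meanCount = unname(counts),
             stringsAsFactors = FALSE)
}

#' Export scored fragments as TSV
#'
#' Columns `fragment  length  support  mean  sd  R`.
#'
#' @param scores A [FragmentScores-class].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
writeFragmentScores <- function(scores, path) {
  stopifnot(is(scores, "FragmentScores"))
  data.table::fwrite(scores@scores, path, sep = "\t", eol = "\n", quote = FALSE)
  invisible(path)
}
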