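# Protocode loading, combinatorial fusion and SGC validation.

test_that("the bundled configuration loads four valid protocodes", {
  pcs <- loadProtocodes()
  expect_named(pcs, c("AU-dominant", "AU-recessive", "GC-dominant",
                      "GC-recessive"))
  for (p in pcs) expect_no_error(validObject(p))
  # membership as designed: dominant/recessive AU and GC sets
  expect_setequal(setdiff(names(assignments(pcs[["AU-dominant"]])),
                          c("X1", "X1*")), c("K", "F", "N", "I", "Y"))
  expect_setequal(names(assignments(pcs[["AU-recessive"]])),
                  c("E", "L", "D", "V", "Q", "H"))
  expect_setequal(names(assignments(pcs[["GC-dominant"]])),
                  c("G", "P", "A", "R"))
  expect_setequal(setdiff(names(assignments(pcs[["GC-recessive"]])), "X2"),
                  c("S", "T", "C", "R"))
  # text anchors: Phe at UUU, Tyr at UAU, Pro holds CCC, X1/X1* at UAA/UUA
  expect_equal(assignments(pcs[["AU-dominant"]])$F, "UUU")
  expect_equal(assignments(pcs[["AU-dominant"]])$Y, "UAU")
  expect_true("CCC" %in% assignments(pcs[["GC-dominant"]])$P)
  expect_equal(assignments(pcs[["AU-dominant"]])$X1, "UAA")
  expect_equal(assignments(pcs[["AU-dominant"]])[["X1*"]], "UUA")
  # dominant and recessive compete for the same codons (Phe/Leu at UUU,
  # Pro/Ser at CCC)
  expect_true("UUU" %in% assignments(pcs[["AU-recessive"]])$L)
  expect_true("CCC" %in% assignments(pcs[["GC-recessive"]])$S)
  # Arg sits in both GC protocodes
  expect_true("R" %in% names(assignments(pcs[["GC-dominant"]])))
  expect_true("R" %in% names(assignments(pcs[["GC-recessive"]])))
})

test_that("loading fails loudly on invariant violations", {
  base <- yaml::read_yaml(protocodeConfigFile())
  # codon using a base outside the two-base alphabet
  bad <- base
  bad[["GC-dominant"]]$members$P <- c("CCG", "ACC")
  expect_error(loadProtocodes(bad), "outside the protocode alphabet")
  # duplicate codon within one protocode
  bad <- base
  bad[["AU-dominant"]]$members$K <- c("AAA", "UUU")
  expect_error(loadProtocodes(bad), "assigned to two amino acids")
  # unknown amino-acid symbol
  bad <- base
  bad[["AU-dominant"]]$members$Z9 <- "AAA"
  expect_error(loadProtocodes(bad), "unknown amino-acid symbol")
  # complement pair whose codons are not reverse complements
  bad <- base
  bad[["AU-dominant"]]$complement_pairs[[1]] <- list("K", "AAA", "Y", "UAU")
  expect_error(loadProtocodes(bad), "not reverse complements")
})

test_that("dominant fusion keeps originals and adds third-position transitions", {
  fr <- applyFusion(loadProtocodes())
  tab <- fr@table
  getFused <- function(pc, aa)
    tab$fused[[which(tab$protocode == pc & tab$aa == aa)]]
  expect_setequal(getFused("AU-dominant", "F"), c("UUU", "UUC"))
  expect_setequal(getFused("GC-dominant", "P"), c("CCC", "CCG", "CCU", "CCA"))
  expect_true(all(c("CCC", "CCU") %in% getFused("GC-dominant", "P")))
  expect_setequal(getFused("AU-dominant", "K"), c("AAA", "AAG"))
  # originals are a subset of the fused set for every dominant amino acid
  dom <- tab[tab$dominant, ]
  for (i in seq_len(nrow(dom)))
    expect_true(all(dom$original[[i]] %in% dom$fused[[i]]))
  # each fused codon differs from an original only by transitions at the
  # allowed (third) position
  for (i in seq_len(nrow(dom))) {
    extra <- setdiff(dom$fused[[i]], dom$original[[i]])
    expect_true(all(extra %in% mutateCodon(dom$original[[i]], 3L)))
  }
})

test_that("fusion is idempotent on dominant sets (transitions are involutions)", {
  fr <- applyFusion(loadProtocodes())
  dom <- fr@table[fr@table$dominant, ]
  for (i in seq_len(nrow(dom))) {
    fused <- dom$fused[[i]]
    again <- union(fused, mutateCodon(fused, 3L))
    expect_setequal(again, fused)
  }
})

test_that("recessive re-assignment preserves complement pairing and finds free codons", {
  pcs <- loadProtocodes()
  fr <- applyFusion(pcs)
  expect_identical(nrow(fr@conflicts), 0L)
  tab <- fr@table
  # first-and-third images of complementary originals stay complementary
  for (pc in Filter(function(p) !isDominant(p), pcs)) {
    cp <- complementPairs(pc)
    for (i in seq_len(nrow(cp))) {
      t1 <- mutateCodon(cp$codon1[i], c(1L, 3L))
      t2 <- mutateCodon(cp$codon2[i], c(1L, 3L))
      expect_identical(revcompCodon(t1), t2)
    }
  }
  # recessive fused codons never collide with dominant fused codons
  domFused <- unlist(tab$fused[tab$dominant])
  recFused <- unlist(tab$fused[!tab$dominant])
  expect_length(intersect(domFused, recFused), 0L)
})

test_that("fused codon sets partition the 64-codon space with no double assignment", {
  fr <- applyFusion(loadProtocodes())
  allFused <- unlist(fr@table$fused)
  expect_identical(anyDuplicated(allFused), 0L)
  expect_setequal(allFused, names(sgcTable()))
})

test_that("validation against the SGC passes and explains the stop codons", {
  sgc <- sgcTable()
  expect_length(sgc, 64L)
  expect_setequal(names(sgc)[sgc == "*"], c("UAA", "UAG", "UGA"))

  val <- validateAgainstSgc(applyFusion(loadProtocodes()), sgc)
  expect_true(all(val@summary$passed))
  # deleting X1 creates the stop codons UAA and UAG
  x1 <- val@codons[val@codons$aa == "X1", ]
  expect_setequal(x1$codon[x1$status == "stop_emergent"], c("UAA", "UAG"))
  # X2's disappearance explains UGA; Trp later took UGG
  x2 <- val@codons[val@codons$aa == "X2", ]
  expect_identical(x2$codon[x2$status == "stop_emergent"], "UGA")
  expect_identical(x2$codon[x2$status == "late_entry"], "UGG")
  expect_setequal(emergentStops(val), c("UAA", "UAG", "UGA"))
  # Leu takes over X1*'s vacated codons
  x1s <- val@codons[val@codons$aa == "X1*", ]
  expect_setequal(x1s$codon[x1s$status == "reassigned"], c("UUA", "UUG"))
  expect_true(all(x1s$sgc[x1s$status == "reassigned"] == "L"))
})

test_that("a corrupted fusion is reported as a mismatch", {
  fr <- applyFusion(loadProtocodes())
  i <- which(fr@table$protocode == "AU-dominant" & fr@table$aa == "F")
  fr@table$fused[[i]] <- c("UUU", "UUA")  # UUA is Leu in the SGC
  val <- validateAgainstSgc(fr)
  s <- val@summary
  expect_false(s$passed[s$aa == "F" & s$protocode == "AU-dominant"])
  bad <- val@codons[val@codons$aa == "F" & val@codons$status == "mismatch", ]
  expect_identical(bad$codon, "UUA")
})

test_that("degenerate fusion inputs error", {
  broken <- new("Protocode", name = "broken", baseAlphabet = c("A", "U"),
                assignments = list(K = character()), deleted = character(),
                complementPairs = data.frame(aa1 = character(),
                                             codon1 = character(),
                                             aa2 = character(),
                                             codon2 = character()),
                dominant = TRUE)
  expect_error(applyFusion(list(broken = broken)), "empty codon set")
  expect_error(applyFusion(list()), "empty protocode set")
})
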