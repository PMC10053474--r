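# Fragment enumeration, the R = mean/sd interaction score, signature
# columns, displacement and composition trends.

test_that("fragment enumeration returns the contiguous substring set", {
  expect_setequal(enumerateFragments("AECD", 1, 4),
                  c("A", "E", "C", "D", "AE", "EC", "CD",
                    "AEC", "ECD", "AECD"))
  expect_setequal(enumerateFragments("PPP", 1, 3), c("P", "PP", "PPP"))
  expect_setequal(enumerateFragments("AECD", 3, 3), c("AEC", "ECD"))
  expect_error(enumerateFragments("AECD", 0, 4), "invalid fragment length")
  expect_error(enumerateFragments("AECD", 2, 5), "invalid fragment length")
  # count bound: at most L(L+1)/2 distinct fragments
  for (p in c("GPAR", "PPPPP", "KFNIYK")) {
    L <- nchar(p)
    expect_lte(length(enumerateFragments(p, 1, L)), L * (L + 1) / 2)
  }
})

test_that("R is the mean over the sample sd of the fragment's signal set", {
  spotTable <- data.frame(
    spot_id = paste0("S", 1:3),
    peptide = c("PPGA", "PPAG", "APPG"),   # all contain PP
    library_id = "toy", rna = "C12",
    intensity = c(10, 20, 30))
  ds <- toyDataset(spotTable)
  sc <- scoreFragments(ds, "C12", kMin = 2, kMax = 2, minSupport = 3)
  pp <- fragmentScores(sc)
  row <- pp[pp$fragment == "PP", ]
  expect_equal(row$mean, 20)
  expect_equal(row$sd, 10)
  expect_equal(row$R, 2)
  expect_identical(row$support, 3L)
})

test_that("constant or under-supported signal sets are gated, not scored", {
  spotTable <- data.frame(
    spot_id = paste0("S", 1:4),
    peptide = c("PPG", "PPA", "PPR", "GAR"),
    library_id = "toy", rna = "C12",
    intensity = c(5, 5, 5, 7))
  ds <- toyDataset(spotTable)
  sc <- scoreFragments(ds, "C12", kMin = 2, kMax = 2, minSupport = 3)
  gated <- gatedFragments(sc)
  expect_true("PP" %in% gated$fragment)              # {5,5,5}: sd = 0
  expect_identical(gated$reason[gated$fragment == "PP"], "zero spread")
  expect_true(all(c("GA", "AR") %in%
                    gated$fragment[gated$reason == "support below minimum"]))
  expect_false(any(is.infinite(fragmentScores(sc)$R)))
  expect_false("PP" %in% fragmentScores(sc)$fragment)
})

test_that("scoring matches a brute-force double loop to 1e-9", {
  ds <- simulatedDataset(c("G", "P", "A", "R"), 5, copies = 2, seed = 21,
                         baselines = c(C12 = 100),
                         effects = data.frame(motif = "PP", channel = "C12",
                                              effect = 1.5),
                         sigma = 0.3)
  # restrict to <= 500 peptides
  sig <- signals(ds)
  keep <- sig$peptide %in% unique(sig$peptide)[1:400]
  sub <- sig[keep, c("peptide", "intensity")]
  dsSub <- ds; dsSub@signals <- sig[keep, ]
  sc <- scoreFragments(dsSub, "C12", kMin = 3, kMax = 5, minSupport = 3)
  oracle <- bruteForceFragmentScores(sub, kMin = 3, kMax = 5, minSupport = 3)
  got <- fragmentScores(sc)
  oracle <- oracle[!is.na(oracle$R), ]
  expect_identical(sort(got$fragment), sort(oracle$fragment))
  m <- merge(got, oracle, by = "fragment")
  expect_identical(nrow(m), nrow(got))
  expect_lt(max(abs(m$R.x - m$R.y)), 1e-9)
  expect_lt(max(abs(m$mean.x - m$mean.y)), 1e-9)
  expect_lt(max(abs(m$sd.x - m$sd.y)), 1e-9)
  expect_identical(as.integer(m$support.x), as.integer(m$support.y))
})

test_that("set semantics count a peptide once however often the fragment recurs", {
  spotTable <- data.frame(
    spot_id = paste0("S", 1:3),
    peptide = c("PPPP", "PPGA", "GPPA"),   # PP occurs 3x in PPPP
    library_id = "toy", rna = "C12",
    intensity = c(12, 24, 36))
  ds <- toyDataset(spotTable)
  sc <- scoreFragments(ds, "C12", kMin = 2, kMax = 2, minSupport = 3)
  expect_identical(fragmentScores(sc)$support[
    fragmentScores(sc)$fragment == "PP"], 3L)
  # occurrence weighting is available but non-default
  sco <- scoreFragments(ds, "C12", kMin = 2, kMax = 2, minSupport = 3,
                        occurrence = TRUE)
  expect_identical(fragmentScores(sco)$support[
    fragmentScores(sco)$fragment == "PP"], 5L)
})

test_that("R is invariant to rescaling but not to additive offsets", {
  ds <- simulatedDataset(c("G", "P", "A"), 4, copies = 2, seed = 13,
                         baselines = c(C12 = 50), sigma = 0.25)
  sc1 <- scoreFragments(ds, "C12", kMin = 3, kMax = 4)
  ds2 <- ds; ds2@signals$intensity <- ds2@signals$intensity * 7.3
  sc2 <- scoreFragments(ds2, "C12", kMin = 3, kMax = 4)
  m <- merge(fragmentScores(sc1), fragmentScores(sc2), by = "fragment")
  expect_lt(max(abs(m$R.x - m$R.y) / abs(m$R.x)), 1e-12)
  ds3 <- ds; ds3@signals$intensity <- ds3@signals$intensity + 100
  sc3 <- scoreFragments(ds3, "C12", kMin = 3, kMax = 4)
  m3 <- merge(fragmentScores(sc1), fragmentScores(sc3), by = "fragment")
  expect_gt(max(abs(m3$R.x - m3$R.y)), 1e-6)
})

test_that("signature columns accumulate lengths and break ties deterministically", {
  scores <- data.frame(
    fragment = c("PPP", "PPA", "GGGG", "PPPPA", "AAA"),
    length = c(3, 3, 4, 5, 3),
    support = 10, mean = 1,
    sd = 1, R = c(3, 2.5, 2.5, 4, 1))
  sig <- buildSignatureTable(scores, topN = 3)
  expect_named(signatureColumns(sig), c("3mer", "3-4mer", "3-5mer"))
  c34 <- signatureColumns(sig)[["3-4mer"]]
  # tie at R = 2.5: the longer fragment (GGGG) ranks above PPA
  expect_identical(c34$fragment, c("PPP", "GGGG", "PPA"))
  c35 <- signatureColumns(sig)[["3-5mer"]]
  expect_identical(c35$fragment[1], "PPPPA")
  # equal R and length falls back to lexicographic order
  tie <- data.frame(fragment = c("BBB", "AAA"), length = 3, support = 5,
                    mean = 2, sd = 1, R = 2)
  expect_identical(signatureColumns(buildSignatureTable(tie, 2))[["3mer"]]$fragment,
                   c("AAA", "BBB"))
})

test_that("displacement reports stayed, displaced and entering fragments", {
  scores <- data.frame(
    fragment = c("PPP", "AAA", "PPPP"),
    length = c(3, 3, 4), support = 10, mean = 1, sd = 1,
    R = c(5, 2, 4))
  sig <- buildSignatureTable(scores, topN = 2)
  d <- displacementAnalysis(sig)
  expect_identical(d$status[d$fragment == "PPP"], "stayed")    # rank 1 twice
  expect_identical(d$status[d$fragment == "AAA"], "displaced")
  expect_identical(d$status[d$fragment == "PPPP"], "entered")
  one <- buildSignatureTable(scores[scores$length == 3, ], topN = 2)
  expect_error(displacementAnalysis(one), ">= 2 columns")
})

test_that("composition trends count the requested residues per column", {
  scores <- data.frame(
    fragment = c("FYF", "FY"), length = c(3, 2), support = 5,
    mean = 1, sd = 1, R = c(2, 3))
  sig <- buildSignatureTable(scores, topN = 2, kMin = 2)
  tr <- compositionTrend(sig, c("F", "Y"))
  expect_equal(tr$meanCount[tr$column == "2mer"], 2)        # {FY}
  expect_equal(tr$meanCount[tr$column == "2-3mer"], 2.5)    # {FYF, FY}
  expect_equal(compositionTrend(sig, character())$meanCount, c(0, 0))
})

test_that("a planted per-occurrence motif is displaced by its longer super-fragments", {
  ds <- simulatedDataset(c("G", "P", "A", "R"), 6, copies = 3, seed = 31,
                         baselines = c(C12 = 100),
                         effects = data.frame(motif = "P", channel = "C12",
                                              effect = 2, mode = "occurrence"),
                         sigma = 0.2)
  sc <- scoreFragments(ds, "C12", kMin = 3, kMax = 6)
  sig <- buildSignatureTable(sc, topN = 5)
  cols <- signatureColumns(sig)
  # the pure-P signature dominates the 3-mer column...
  expect_identical(cols[["3mer"]]$fragment[1], "PPP")
  # ...but is pushed out of the top ranks once longer fragments compete
  expect_false("PPP" %in% cols[["3-6mer"]]$fragment)
  expect_true(all(cols[["3-6mer"]]$length > 3))
  d <- displacementAnalysis(sig)
  expect_true("PPP" %in% d$fragment[d$status == "displaced"])
})
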