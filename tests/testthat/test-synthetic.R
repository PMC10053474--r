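# The synthetic screen generator.

test_that("noise-free simulation reproduces the closed-form intensities", {
  lib <- enumerateLibrary(c("G", "P"), 3, "toy")
  design <- layoutArray(lib, copies = 2, seed = 1)
  cfg <- simConfig(design, baselines = c(C12 = 100), sigma = 0)
  sim <- simulateScreen(cfg)
  expect_true(all(sim$intensity == 100))
  # per-presence effect: one multiplier however many matches
  cfg2 <- simConfig(design, baselines = c(C12 = 100),
                    effects = data.frame(motif = "PP", channel = "C12",
                                         effect = 2, mode = "presence"),
                    sigma = 0)
  sim2 <- simulateScreen(cfg2)
  ds <- buildScreenDataset(design, sim2)
  sig <- signals(ds)
  expect_true(all(sig$intensity[sig$peptide == "PPP"] == 200))
  expect_true(all(sig$intensity[sig$peptide == "GPG"] == 100))
  # per-occurrence counts overlapping matches; saturation caps them
  cfg3 <- simConfig(design, baselines = c(C12 = 100),
                    effects = data.frame(motif = "P", channel = "C12",
                                         effect = 2, mode = "occurrence",
                                         saturation = 2),
                    sigma = 0)
  sig3 <- signals(buildScreenDataset(design, simulateScreen(cfg3)))
  expect_true(all(sig3$intensity[sig3$peptide == "PPG"] == 400))
  expect_true(all(sig3$intensity[sig3$peptide == "PPP"] == 400))  # capped
  # position-anchored effect fires only at the anchor
  cfg4 <- simConfig(design, baselines = c(C12 = 100),
                    effects = data.frame(motif = "P", channel = "C12",
                                         effect = 3, mode = "presence",
                                         saturation = NA, position = 2),
                    sigma = 0)
  sig4 <- signals(buildScreenDataset(design, simulateScreen(cfg4)))
  expect_true(all(sig4$intensity[sig4$peptide == "GPG"] == 300))
  expect_true(all(sig4$intensity[sig4$peptide == "PGP"] == 100))
})

test_that("simulation is deterministic given the seed", {
  lib <- enumerateLibrary(c("G", "P", "A"), 3, "toy")
  design <- layoutArray(lib, copies = 2, seed = 3)
  cfg <- simConfig(design, baselines = c(C12 = 100, G12 = 40), sigma = 0.3)
  s1 <- simulateScreen(cfg, seed = 17)
  s2 <- simulateScreen(cfg, seed = 17)
  expect_identical(s1, s2)
  s3 <- simulateScreen(cfg, seed = 18)
  expect_false(identical(s1$intensity, s3$intensity))
})

test_that("config invariants are enforced", {
  lib <- enumerateLibrary(c("G", "P"), 2, "toy")
  design <- layoutArray(lib, seed = 1)
  expect_error(simConfig(design, baselines = c(C12 = -1)), "> 0")
  expect_error(simConfig(design, baselines = c(C12 = 10), sigma = -0.1),
               ">= 0")
  expect_error(simConfig(design, baselines = c(C12 = 10),
                         effects = data.frame(motif = "PW", channel = "C12",
                                              effect = 2)),
               "outside the design alphabet")
  expect_error(simConfig(design, baselines = c(C12 = 10),
                         effects = data.frame(motif = "P", channel = "Z",
                                              effect = 2)),
               "must have baselines")
})

test_that("log intensities of a no-effect screen are close to normal", {
  lib <- enumerateLibrary(c("G", "P", "A", "R"), 7, "toy")
  lib <- subsetLibrary(lib, 5000, seed = 2)
  design <- layoutArray(lib, copies = 2, seed = 2)
  cfg <- simConfig(design, baselines = c(C12 = 100), sigma = 0.3)
  sim <- simulateScreen(cfg, seed = 2)
  expect_identical(nrow(sim), 10000L)
  expect_lt(abs(skewness1(log(sim$intensity))), 0.2)
})

test_that("the AU preset orders channels and libraries as designed", {
  cfg <- presetPaperlike("AU", seed = 8, auSize = 4000)
  sim <- simulateScreen(cfg, seed = 8)
  ds <- buildScreenDataset(cfg@design, sim)
  cs <- channelSummary(ds)
  mA <- cs$mean[cs$rna == "A12"]; mU <- cs$mean[cs$rna == "U12"]
  expect_gt(mean(mA) / mean(mU), 10)   # adenine channel dominates uracil
  expect_gt(cs$mean[cs$library_id == "AU-dominant" & cs$rna == "A12"],
            cs$mean[cs$library_id == "AU-recessive" & cs$rna == "A12"])
})

test_that("the GC preset plants proline binding and keeps dominant above recessive", {
  cfg <- presetPaperlike("GC", seed = 6, positionBonus = FALSE)
  sim <- simulateScreen(cfg, seed = 6)
  ds <- buildScreenDataset(cfg@design, sim)
  cs <- channelSummary(ds)
  expect_gt(cs$mean[cs$library_id == "GC-dominant" & cs$rna == "C12"],
            cs$mean[cs$library_id == "GC-recessive" & cs$rna == "C12"])
  # recessive library carries no planted effects: its C/G ratio reflects
  # the ~3x baseline ordering
  ratio <- cs$mean[cs$library_id == "GC-recessive" & cs$rna == "C12"] /
    cs$mean[cs$library_id == "GC-recessive" & cs$rna == "G12"]
  expect_gt(ratio, 2); expect_lt(ratio, 4)
  sc <- scoreFragments(ds, "C12", libraryId = "GC-dominant")
  col3 <- signatureColumns(buildSignatureTable(sc, topN = 5))[["3mer"]]
  expect_true("PPP" %in% col3$fragment)
})

test_that("recovery of a planted presence motif degrades with noise", {
  rankOfPPP <- function(sigma, seed) {
    ds <- simulatedDataset(c("G", "P", "A", "R"), 5, copies = 2,
                           seed = seed, baselines = c(C12 = 100),
                           effects = data.frame(motif = "P",
                                                channel = "C12", effect = 2,
                                                mode = "occurrence"),
                           sigma = sigma)
    sc <- fragmentScores(scoreFragments(ds, "C12", kMin = 3, kMax = 3))
    which(sc$fragment == "PPP")
  }
  seeds <- 1:5
  low <- vapply(seeds, function(s) rankOfPPP(0.1, s), numeric(1))
  high <- vapply(seeds, function(s) rankOfPPP(2, s), numeric(1))
  expect_true(all(low <= 5))
  expect_gte(mean(high), mean(low))
})
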