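# Synthetic landscape: ground truth semantics, screen simulation, effect
# recovery, campaign trajectory bookkeeping.

test_that("wildtype reproduces baseline signals and unit objectives", {
  ls <- toyCampaignLandscape()
  gt <- groundTruthResponse(ls, id = "WT")
  expect_equal(unname(gt$signals),
               unname(ls@baselines[c("none", "lead", "zinc")]))
  expect_equal(unname(gt$objectives), c(1, 1))
  # by sequence too
  gtSeq <- groundTruthResponse(ls, sequence = ls@wildtype)
  expect_equal(gtSeq$objectives, gt$objectives)
  expect_error(groundTruthResponse(ls, sequence = "AC"), "length")
})

test_that("additive effects act multiplicatively on the right condition", {
  alpha <- c("A", "C", "D")
  wt <- "AAAA"
  zero <- matrix(0, 4, 3)
  lead <- zero; lead[2, 2] <- log(2)  # C at position 2 doubles lead signal
  ls <- landscapeSpec(wt, alpha,
                      effects = list(none = zero, lead = lead, zinc = zero),
                      baselines = c(none = 10, lead = 50, zinc = 100),
                      sigmaM = 0, sigmaA = 0)
  gt <- groundTruthTable(ls, c("WT", "A2C"))
  expect_equal(gt$signal_lead, c(50, 100))
  expect_equal(gt$signal_zinc, c(100, 100))   # zinc untouched
  expect_equal(gt$signal_none, c(10, 10))
  expect_equal(gt$norm_fc_pb, c(1, 2))

  # double mutant with zero epistasis: log-signals additive
  lead2 <- lead; lead2[3, 3] <- log(3)
  ls2 <- landscapeSpec(wt, alpha,
                       effects = list(none = zero, lead = lead2,
                                      zinc = zero),
                       baselines = c(none = 10, lead = 50, zinc = 100),
                       sigmaM = 0, sigmaA = 0)
  gt2 <- groundTruthTable(ls2, c("A2C", "A3D", "A2C_A3D"))
  expect_equal(gt2$signal_lead[3],
               50 * (gt2$signal_lead[1] / 50) * (gt2$signal_lead[2] / 50))

  # pairwise epistasis shifts only mutants carrying both substitutions
  epi <- data.frame(condition = "lead", pos1 = 2L, alt1 = "C",
                    pos2 = 3L, alt2 = "D", effect = log(0.5),
                    stringsAsFactors = FALSE)
  ls3 <- landscapeSpec(wt, alpha,
                       effects = list(none = zero, lead = lead2,
                                      zinc = zero),
                       epistasis = epi,
                       baselines = c(none = 10, lead = 50, zinc = 100),
                       sigmaM = 0, sigmaA = 0)
  gt3 <- groundTruthTable(ls3, c("A2C", "A3D", "A2C_A3D"))
  expect_equal(gt3$signal_lead[1:2], gt2$signal_lead[1:2])
  expect_equal(gt3$signal_lead[3], gt2$signal_lead[3] * 0.5)
})

test_that("noise-free simulation plus screen metrics recovers ground truth exactly", {
  ls <- toyGrammarLandscape()  # sigmaM = sigmaA = 0
  ids <- c("G6A", "F13K", "G6K_F13A")
  screen <- simulateScreen(ls, ids, seed = 1)
  # replicates equal noiseless values exactly
  gtSig <- groundTruthTable(ls, ids)
  for (i in seq_along(ids)) {
    lead <- screen$signal[screen$mutant_id == ids[i] &
                            screen$ligand == "lead"]
    expect_equal(lead, rep(gtSig$signal_lead[i], 3))
  }
  act <- activityTable(screen)
  m <- metricsFromActivity(act, ids)
  expect_equal(m$norm_fc_pb, gtSig$norm_fc_pb, tolerance = 1e-12)
  expect_equal(m$norm_fc_zn, gtSig$norm_fc_zn, tolerance = 1e-12)
})

test_that("simulation is reproducible under a seed and default n = 3 replicates", {
  ls <- toyCampaignLandscape()
  ids <- allSingleMutants(ls)[1:4]
  s1 <- simulateScreen(ls, ids, seed = 5)
  s2 <- simulateScreen(ls, ids, seed = 5)
  expect_identical(s1, s2)
  s3 <- simulateScreen(ls, ids, seed = 6)
  expect_false(identical(s1$signal, s3$signal))
  expect_equal(as.integer(table(s1$replicate)), rep(15L, 3))  # (4+WT) x 3 cond
  expect_true(all(s1$signal >= 0))
  expect_setequal(unique(s1$ligand), c("none", "lead", "zinc"))
})

test_that("noise-free labels match ground-truth delta signs exhaustively", {
  ls <- toyGrammarLandscape()
  ids <- grammarGenotypes()[1:20]
  gt <- groundTruthTable(ls, ids)
  seqs <- vapply(ids, function(i) {
    applySubstitutions(ls@wildtype, parseMutantId(i, ls@alphabet))
  }, character(1))
  pd <- buildPairedDataset(seqs, cbind(gt$norm_fc_zn, gt$norm_fc_pb),
                           defaultObjectives(tauZn = 0, tauPb = 0),
                           bothOrientations = TRUE)
  truthOf <- function(s) {
    r <- groundTruthResponse(ls, sequence = s)$objectives
    c(r["Zn"], r["Pb"])
  }
  for (i in seq_len(pairCount(pd))) {
    d <- truthOf(pd@target[i]) - truthOf(pd@source[i])
    expect_identical(unname(pd@labels[i, ]),
                     unname(ifelse(d > 0, "<inc>", "<dec>")))
  }
})

test_that("OLS on the known design matrix recovers additive effects", {
  ls <- toyCampaignLandscape()  # sigmaM = 0.1, n = 3
  ids <- unique(randomMutants(ls, 400, orders = 2L, seed = 99))
  expect_gte(length(ids), 300)
  screen <- simulateScreen(ls, ids, seed = 100)
  rmse <- olsEffectRmse(ls, screen)
  expect_lt(rmse, 0.1)
})

test_that("landscape YAML serialization round-trips", {
  ls <- toyCampaignLandscape(withEpistasis = TRUE)
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLandscapeYaml(ls, path)
  back <- readLandscapeYaml(path)
  expect_equal(back@wildtype, ls@wildtype)
  expect_equal(back@alphabet, ls@alphabet)
  expect_equal(back@effects$lead, ls@effects$lead, ignore_attr = TRUE)
  expect_equal(back@baselines, ls@baselines)
  expect_equal(back@epistasis$effect, ls@epistasis$effect)
  expect_equal(back@sigmaM, ls@sigmaM)
})

test_that("zero-round campaign returns the initial screen summary only", {
  ls <- toyCampaignLandscape()
  rep0 <- runCampaign(ls, rounds = 0L, seed = 4L)
  expect_equal(length(rep0$rounds), 0L)
  expect_gt(rep0$initial$n_mutants, 100L)
  expect_s3_class(rep0$initial$activity, "data.frame")
})

test_that("campaign rounds log the workflow quantities and honor capacities", {
  rep <- campaignFixture()
  expect_equal(length(rep$rounds), 3L)
  for (r in rep$rounds) {
    expect_lte(r$librarySize, 60L)
    expect_gt(r$pairsRetained, 0L)
    expect_equal(sum(r$categoryCounts > 0), length(r$categoryCounts))
    expect_gt(r$nSeeds, 0L)
    expect_true(all(c("norm_fc_pb", "norm_fc_zn") %in%
                      colnames(r$scatter) |
                      c("Zn", "Pb") %in% colnames(r$scatter)))
    # proposed mutants are never re-screens of earlier rounds
  }
  ids1 <- rep$rounds[[1]]$library$mutant_id
  ids2 <- rep$rounds[[2]]$library$mutant_id
  expect_equal(length(intersect(ids1, ids2)), 0L)
  expect_false(any(ids1 %in% rep$initial$library))
  # M grows round over round as screened libraries fold into training
  expect_true(all(diff(vapply(rep$rounds, `[[`, numeric(1), "M")) > 0))
})

test_that("mean ground-truth lead objective of proposed libraries does not collapse", {
  rep <- campaignFixture()
  mPb <- vapply(rep$rounds, `[[`, numeric(1), "meanPbObjective")
  # round-over-round trajectory on the additive landscape: later libraries
  # are at least as good as the first round's
  expect_true(all(mPb[-1] >= mPb[1] * 0.9))
  expect_gt(mPb[length(mPb)], 1)
})
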