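# Conditional sequence model: vocabulary, probability contracts, training
# behaviour, checkpointing, validity scoring.

test_that("vocabulary has residues plus 2 direction and 4 control tokens", {
  v20 <- buildVocabulary()
  expect_equal(vocabSize(v20), 26L)
  v4 <- buildVocabulary(c("A", "C", "G", "T"))
  expect_equal(vocabSize(v4), 10L)
  # direction tokens present and distinct, ids dense and deterministic
  expect_true(all(c("<inc>", "<dec>") %in% v4@tokens))
  expect_false(tokenIds(v4, "<inc>") == tokenIds(v4, "<dec>"))
  expect_identical(v4@tokens, buildVocabulary(c("A", "C", "G", "T"))@tokens)
  expect_error(buildVocabulary(c("A", "A")), "unique")
  expect_error(tokenIds(v4, "Z"), "outside vocabulary")
})

test_that("untrained model is exactly uniform; logprob matches closed form", {
  v <- buildVocabulary(c("A", "C", "D", "E"))
  m <- newSeq2SeqModel(v, 2L, trainConfig(seed = 3L))
  V <- vocabSize(v)
  # L * log(1/|V|) for a length-L target under uniform outputs
  lp <- sequenceLogprob(m, c("<inc>", "<dec>"), "ACD", "ACE")
  expect_equal(lp, 3 * log(1 / V), tolerance = 1e-12)
  expect_lte(lp, 0)
  expect_error(sequenceLogprob(m, c("<inc>", "<dec>"), "ACD", "ACZ"),
               "outside vocabulary")
})

test_that("per-step distributions sum to one; single-token continuations sum to one", {
  fx <- grammarFixture()
  m <- fx$model
  prompt <- c("<dec>", "<inc>")
  seed <- fx$seqs[[2]]
  prefix <- character()
  for (t in 1:5) {
    p <- decodeDistribution(m, prompt, seed, prefix)
    expect_equal(sum(p), 1, tolerance = 1e-6)
    expect_true(all(p >= 0))
    prefix <- c(prefix, names(which.max(p)))
  }
  # exp(logprob) over all single-token continuations of a length-1 decode
  v <- m@vocab
  total <- sum(vapply(v@alphabet, function(a) {
    exp(sequenceLogprob(m, prompt, seed, a))
  }, numeric(1)))
  nonResidue <- sum(decodeDistribution(m, prompt, seed)[
    setdiff(v@tokens, v@alphabet)])
  expect_equal(total + nonResidue, 1, tolerance = 1e-6)
})

test_that("logprob equals the sum of stepwise token log-probabilities", {
  fx <- grammarFixture()
  m <- fx$model
  prompt <- c("<dec>", "<inc>")
  src <- fx$seqs[[3]]
  tgt <- fx$seqs[[10]]
  stepSum <- 0
  tgtTok <- strsplit(tgt, "")[[1]]
  for (t in seq_along(tgtTok)) {
    p <- decodeDistribution(m, prompt, src, tgtTok[seq_len(t - 1)])
    stepSum <- stepSum + log(p[[tgtTok[t]]])
  }
  expect_equal(sequenceLogprob(m, prompt, src, tgt), stepSum,
               tolerance = 1e-9)
})

test_that("training is deterministic under a fixed seed and reduces loss", {
  withr::with_seed(7, {
    rs <- randomRecordSet(12, L = 8)
  })
  pd <- buildPairedDataset(rs$sequences, rs$metrics,
                           defaultObjectives(tauZn = 0.05, tauPb = 0.05))
  cfg <- trainConfig(lr = 5e-3, epochs = 6L, batchSize = 32L, seed = 21L)
  m1 <- trainModel(pd, cfg)
  m2 <- trainModel(pd, cfg)
  expect_identical(m1@history$trainLoss, m2@history$trainLoss)
  expect_identical(m1@params, m2@params)
  # loss after epoch 5 below loss after epoch 1
  expect_lt(m1@history$trainLoss[5], m1@history$trainLoss[1])
  expect_error(trainModel(pd, trainConfig(backbone = "pretrained-adapter")),
               "adapter")
})

test_that("training on one repeated example raises its log-probability", {
  src <- "ACDA"
  tgt <- "ACDC"
  lab <- matrix(rep(c("<inc>", "<dec>"), 8), 8, 2, byrow = TRUE)
  pd <- new("DirectionalPairs", source = rep(src, 8), target = rep(tgt, 8),
            labels = lab, deltas = matrix(rep(c(1, -1), 8), 8, 2,
                                          byrow = TRUE),
            objectives = c("Zn", "Pb"), taus = c(0, 0), nSource = 2L)
  vocab <- buildVocabulary(c("A", "C", "D"))
  cfg <- trainConfig(lr = 1e-2, epochs = 30L, batchSize = 8L, seed = 2L,
                     valFraction = 0)
  before <- sequenceLogprob(newSeq2SeqModel(vocab, 2L, cfg),
                            c("<inc>", "<dec>"), src, tgt)
  m <- trainModel(pd, cfg, vocab = vocab)
  after <- sequenceLogprob(m, c("<inc>", "<dec>"), src, tgt)
  expect_gt(after, before)
})

test_that("checkpoints round-trip bit-stably with a JSON sidecar", {
  fx <- grammarFixture()
  path <- withr::local_tempfile(fileext = ".ckpt")
  saveModel(fx$model, path)
  back <- loadModel(path)
  prompt <- c("<dec>", "<inc>")
  expect_identical(
    sequenceLogprob(back, prompt, fx$seqs[[5]], fx$seqs[[9]]),
    sequenceLogprob(fx$model, prompt, fx$seqs[[5]], fx$seqs[[9]]))
  expect_identical(back@params, fx$model@params)
  sidecar <- jsonlite::fromJSON(paste0(path, ".json"))
  expect_equal(sidecar$architecture$vocabSize, vocabSize(fx$model@vocab))
  expect_equal(sidecar$seed, fx$model@config@seed)
})

test_that("conditioning matters: prompt direction moves decode log-probabilities", {
  fx <- grammarFixture()
  m <- fx$model
  alpha <- fx$landscape@alphabet
  # targets consistent with (zinc down, lead up) from mid-ladder seeds
  seeds <- fx$seqs[fx$heldOut[1:6]]
  margins <- vapply(seeds, function(s) {
    tgt <- s
    substr(tgt, 6, 6) <- "K"   # top of the lead ladder
    substr(tgt, 13, 13) <- "A" # bottom of the zinc ladder
    sequenceLogprob(m, c("<dec>", "<inc>"), s, tgt) -
      sequenceLogprob(m, c("<inc>", "<dec>"), s, tgt)
  }, numeric(1))
  expect_gt(mean(margins), 0)
})

test_that("corpus validity score behaves like corpus BLEU", {
  expect_equal(corpusValidityScore(c("ACDE", "FGHK"), c("ACDE", "FGHK")),
               100)
  expect_equal(corpusValidityScore("AAAA", "CCCC"), 0)
  # manual 1-4-gram computation for ACDE vs ACDF:
  # p1 = 3/4, p2 = 2/3, p3 = 1/2, p4 smoothed to 1/(2*1); BP = 1
  manual <- 100 * ((3 / 4) * (2 / 3) * (1 / 2) * (1 / 2))^(1 / 4)
  expect_equal(corpusValidityScore("ACDE", "ACDF"), manual,
               tolerance = 1e-9)
  # brevity penalty kicks in for short hypotheses
  expect_lt(corpusValidityScore("AC", "ACAC"),
            corpusValidityScore("ACAC", "ACAC"))
  expect_error(corpusValidityScore(character(), character()), "empty")
})
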