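# Directional pair construction: thresholding, orientation handling,
# category balancing, encoding.

test_that("direction assignment follows the three-way threshold rule", {
  expect_equal(assignDirection(c(0.5, -0.5), c(0.1, 0.1)),
               c("<inc>", "<dec>"))
  # any sub-threshold objective excludes the pair
  expect_null(assignDirection(c(0.05, 0.5), c(0.1, 0.1)))
  expect_null(assignDirection(c(0.1, 0.5), c(0.1, 0.1)))  # boundary
  expect_error(assignDirection(c(1, 2), 0.1), "same length")
})

test_that("category count is 2^j and matches token-tuple enumeration", {
  expect_equal(categoryCount(2), 4L)
  expect_equal(categoryCount(1), 2L)
  expect_equal(categoryCount(3), 8L)
  for (j in 1:4) {
    tuples <- expand.grid(rep(list(c("<inc>", "<dec>")), j))
    expect_equal(categoryCount(j), nrow(tuples))
  }
})

test_that("label alphabet for two objectives is the four directional categories", {
  recs <- list(sequences = c("AAAA", "CCAA", "GGAA", "TTAA"),
               metrics = rbind(c(0, 0), c(1, 1), c(1, -1), c(-1, -1)))
  pd <- buildPairedDataset(recs$sequences,
                           recs$metrics, defaultObjectives(tauZn = 0.1,
                                                           tauPb = 0.1),
                           bothOrientations = TRUE)
  expect_setequal(names(categoryCounts(pd)),
                  c("inc/inc", "inc/dec", "dec/inc", "dec/dec"))
})

test_that("pair construction enumerates all unordered pairs within bounds", {
  objs <- defaultObjectives(tauZn = 0, tauPb = 0)
  # M = 1: no pairs, with a warning
  expect_warning(pd1 <- buildPairedDataset("AAAA", rbind(c(1, 2)), objs),
                 "fewer than 2")
  expect_equal(pairCount(pd1), 0L)

  # M = 3, all deltas confident, single orientation: C(3,2) = 3 pairs
  m3 <- rbind(c(0, 0), c(1, 1), c(2, 2))
  pd3 <- buildPairedDataset(c("AAAA", "CCCC", "GGGG"), m3, objs,
                            bothOrientations = FALSE)
  expect_equal(pairCount(pd3), 3L)
  expect_equal(pd3@nSource, 3L)

  # M = 5: at most C(5,2) = 10 single-orientation pairs
  withr::with_seed(9, {
    m5 <- matrix(rnorm(10), 5, 2)
    pd5 <- buildPairedDataset(replicate(5, paste(sample(c("A", "C"), 4,
                                                        TRUE),
                                                 collapse = "")),
                              m5, objs, bothOrientations = FALSE)
    expect_lte(pairCount(pd5), 10L)
  })

  # with tau = 0 and no ties, every unordered pair is retained
  withr::with_seed(10, {
    seqsU <- vapply(1:6, function(i) paste(sample(c("A", "C", "G"), 5,
                                                  TRUE), collapse = ""),
                    character(1))
    while (anyDuplicated(seqsU)) seqsU[duplicated(seqsU)] <- "CACAC"
    mU <- matrix(rnorm(12), 6, 2)
    pdU <- buildPairedDataset(seqsU, mU, objs, bothOrientations = FALSE)
    expect_equal(pairCount(pdU), choose(6, 2))
  })
})

test_that("pair construction matches the brute-force oracle exactly", {
  objs <- function(t1, t2) defaultObjectives(tauZn = t1, tauPb = t2)
  withr::with_seed(2024, {
    for (rep in 1:20) {
      M <- sample(3:50, 1)
      rs <- randomRecordSet(M)
      taus <- runif(2, 0, 0.8)
      both <- sample(c(TRUE, FALSE), 1)
      pd <- buildPairedDataset(rs$sequences, rs$metrics,
                               objs(taus[1], taus[2]),
                               bothOrientations = both)
      oracle <- bruteForcePairs(rs$sequences, rs$metrics, taus, both)
      expect_equal(pairCount(pd), length(oracle))
      got <- pairSignature(pd@source, pd@target, pd@labels)
      want <- pairSignature(
        vapply(oracle, `[[`, character(1), "src"),
        vapply(oracle, `[[`, character(1), "tgt"),
        do.call(rbind, lapply(oracle, `[[`, "lab")))
      expect_identical(got, want)
    }
  })
})

test_that("every retained pair clears tau in all objectives; labels match delta signs", {
  withr::with_seed(55, {
    rs <- randomRecordSet(30)
    taus <- c(0.3, 0.2)
    pd <- buildPairedDataset(rs$sequences, rs$metrics,
                             defaultObjectives(tauZn = taus[1],
                                               tauPb = taus[2]))
    expect_true(all(abs(pd@deltas) > rep(taus, each = pairCount(pd))))
    expect_true(all((pd@labels == "<inc>") == (pd@deltas > 0)))
  })
})

test_that("orientation flip inverts every label token", {
  withr::with_seed(66, {
    rs <- randomRecordSet(20)
    pd <- buildPairedDataset(rs$sequences, rs$metrics,
                             defaultObjectives(tauZn = 0.1, tauPb = 0.1),
                             bothOrientations = TRUE)
    key <- paste(pd@source, pd@target, sep = "|")
    revKey <- paste(pd@target, pd@source, sep = "|")
    m <- match(revKey, key)
    expect_false(anyNA(m))  # every pair's mirror is present
    flipped <- ifelse(pd@labels == "<inc>", "<dec>", "<inc>")
    expect_equal(pd@labels[m, , drop = FALSE],
                 flipped, ignore_attr = TRUE)
  })
})

test_that("duplicate sequences collapse to mean metrics; no self-pairs", {
  objs <- defaultObjectives(tauZn = 0, tauPb = 0)
  pd <- buildPairedDataset(c("AAAA", "AAAA", "CCCC"),
                           rbind(c(1, 1), c(3, 3), c(10, 10)), objs,
                           bothOrientations = FALSE)
  expect_equal(pd@nSource, 2L)
  expect_equal(pairCount(pd), 1L)
  expect_equal(as.numeric(pd@deltas), c(8, 8))  # vs the (1+3)/2 mean
  expect_true(all(pd@source != pd@target))
})

test_that("balancing downsamples to the smallest non-empty category", {
  mkpd <- function(counts) {
    labs <- list(c("<inc>", "<inc>"), c("<inc>", "<dec>"),
                 c("<dec>", "<inc>"), c("<dec>", "<dec>"))
    src <- character(); tgt <- character(); lab <- NULL; del <- NULL
    n <- 0L
    for (k in seq_along(counts)) {
      for (i in seq_len(counts[k])) {
        n <- n + 1L
        src <- c(src, sprintf("A%03d", n)); tgt <- c(tgt, sprintf("C%03d", n))
        lab <- rbind(lab, labs[[k]])
        del <- rbind(del, ifelse(labs[[k]] == "<inc>", 1, -1))
      }
    }
    new("DirectionalPairs", source = src, target = tgt, labels = lab,
        deltas = del, objectives = c("Zn", "Pb"), taus = c(0, 0),
        nSource = n)
  }
  pd <- mkpd(c(10L, 4L, 4L, 4L))
  bal <- balanceCategories(pd, seed = 1)
  expect_equal(unname(categoryCounts(bal)), rep(4L, 4))
  # balanced dataset is a subset of the input, order-stable
  expect_true(all(bal@source %in% pd@source))
  expect_false(is.unsorted(match(bal@source, pd@source)))

  # already balanced: unchanged
  pdEq <- mkpd(c(3L, 3L, 3L, 3L))
  balEq <- balanceCategories(pdEq, seed = 1)
  expect_identical(balEq@source, pdEq@source)

  # an empty category is reported, not fabricated
  pdMiss <- mkpd(c(6L, 0L, 3L, 3L))
  expect_warning(balMiss <- balanceCategories(pdMiss, seed = 1),
                 "empty directional categor")
  cc <- categoryCounts(balMiss)
  expect_equal(sum(cc == 0L), 1L)
  expect_equal(unname(cc[cc > 0L]), rep(3L, 3))

  # seeded: reproducible
  expect_identical(balanceCategories(pd, seed = 5)@source,
                   balanceCategories(pd, seed = 5)@source)
})

test_that("training-example encoding prepends direction tokens and round-trips", {
  enc <- encodeTrainingExample("ACD", "ACE", c("<inc>", "<dec>"))
  expect_equal(enc$source, c("<inc>", "<dec>", "A", "C", "D"))
  expect_equal(enc$target, c("A", "C", "E"))
  dec <- decodeTrainingExample(enc)
  expect_equal(dec$source, "ACD")
  expect_equal(dec$target, "ACE")
  expect_equal(dec$labels, c("<inc>", "<dec>"))

  # one objective prepends exactly one token
  enc1 <- encodeTrainingExample("AC", "AG", "<inc>")
  expect_equal(enc1$source[1], "<inc>")
  expect_equal(sum(enc1$source %in% c("<inc>", "<dec>")), 1L)
})

test_that("JSON-lines serialization round-trips a paired dataset", {
  withr::with_seed(88, {
    rs <- randomRecordSet(10)
    pd <- buildPairedDataset(rs$sequences, rs$metrics,
                             defaultObjectives(tauZn = 0.1, tauPb = 0.1))
    path <- withr::local_tempfile(fileext = ".jsonl")
    writePairsJsonl(pd, path)
    back <- readPairsJsonl(path)
    expect_equal(back@source, pd@source)
    expect_equal(back@target, pd@target)
    expect_equal(back@labels, pd@labels, ignore_attr = TRUE)
    expect_equal(back@deltas, pd@deltas, ignore_attr = TRUE)
    expect_equal(back@nSource, pd@nSource)
    # deterministic bytes
    path2 <- withr::local_tempfile(fileext = ".jsonl")
    writePairsJsonl(pd, path2)
    expect_identical(readLines(path), readLines(path2))
  })
})
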