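# Parsing, applying, comparing and enumerating point-substitution mutants.

test_that("mutant ids parse into position-sorted substitutions", {
  s <- parseMutantId("D64K_N83F")
  expect_equal(s$wt, c("D", "N"))
  expect_equal(s$pos, c(64L, 83L))
  expect_equal(s$alt, c("K", "F"))

  # input order is not preserved; the canonical form sorts by position
  expect_equal(mutantId(parseMutantId("N83F_D64K")), "D64K_N83F")

  six <- parseMutantId("D64K_N83I_I90A_K104T_H106A_P143R")
  expect_equal(nrow(six), 6L)
  expect_equal(six$pos, c(64L, 83L, 90L, 104L, 106L, 143L))

  # wildtype sentinels
  expect_equal(nrow(parseMutantId("")), 0L)
  expect_equal(nrow(parseMutantId("WT")), 0L)
  expect_equal(mutantId(parseMutantId("WT")), "WT")
})

test_that("malformed ids are rejected with specific errors", {
  expect_error(parseMutantId("D64"), "malformed")
  expect_error(parseMutantId("D64K_X"), "malformed")
  expect_error(parseMutantId("D64K_D64R"), "duplicate position")
  expect_error(parseMutantId("D64D"), "wildtype equals alternative")
  expect_error(parseMutantId("B64K"), "outside alphabet")
  expect_error(parseMutantId("D0K"), ">= 1")
})

test_that("parse/serialize round-trips on random substitution sets", {
  withr::with_seed(101, {
    for (rep in 1:50) {
      k <- sample(1:6, 1)
      pos <- sort(sample(1:200, k))
      wt <- sample(aminoAcids(), k, replace = TRUE)
      alt <- vapply(wt, function(w) sample(setdiff(aminoAcids(), w), 1),
                    character(1))
      subs <- data.frame(wt = unname(wt), pos = pos, alt = unname(alt),
                         stringsAsFactors = FALSE)
      back <- parseMutantId(mutantId(subs))
      expect_equal(back, subs)
    }
  })
})

test_that("substitutions apply onto the wildtype sequence", {
  expect_equal(applySubstitutions("ACDEF", parseMutantId("")), "ACDEF")
  expect_equal(applySubstitutions("ACDEF", parseMutantId("C2G")), "AGDEF")
  expect_error(applySubstitutions("ACDEF", parseMutantId("K2G")),
               "wildtype-residue mismatch")
  expect_error(applySubstitutions("ACDEF", parseMutantId("C9G")),
               "beyond sequence length")
})

test_that("hamming order counts mismatches and matches substitution count", {
  expect_equal(hammingOrder("ACDEF", "ACDEF"), 0L)
  expect_equal(hammingOrder("ACDEF", "ACDEK"), 1L)
  expect_error(hammingOrder("ACDEF", "ACDE"), "length mismatch")

  # applying k substitutions always yields hamming order k (positions are
  # unique by construction)
  wt <- syntheticPbrRScaffold()
  id <- "D64K_N83I_I90A_K104T_H106A_P143R"
  mut <- applySubstitutions(wt, parseMutantId(id))
  expect_equal(hammingOrder(wt, mut), 6L)
  expect_equal(sequenceToId(wt, mut), id)

  withr::with_seed(77, {
    for (rep in 1:20) {
      k <- sample(1:8, 1)
      pos <- sort(sample(seq_len(nchar(wt)), k))
      wc <- strsplit(wt, "")[[1]]
      alt <- vapply(pos, function(p) sample(setdiff(aminoAcids(), wc[p]),
                                            1), character(1))
      subs <- data.frame(wt = wc[pos], pos = pos, alt = alt)
      expect_equal(hammingOrder(wt, applySubstitutions(wt, subs)), k)
    }
  })
})

test_that("combinatorial enumeration is exhaustive, ordered and duplicate-free", {
  one <- enumerateCombinatorial(parseMutantId("D64K"), 1, 1)
  expect_equal(one$mutant_id, "D64K")

  # two sites with {2, 1} options, orders 1-2: 3 singles + 2 doubles
  opts <- rbind(data.frame(wt = "N", pos = 83L, alt = c("I", "F")),
                parseMutantId("K104V"))
  five <- enumerateCombinatorial(opts, 1, 2)
  expect_equal(nrow(five), 5L)
  expect_equal(five$order, c(1L, 1L, 1L, 2L, 2L))
  expect_setequal(five$mutant_id,
                  c("N83I", "N83F", "K104V", "N83I_K104V", "N83F_K104V"))

  # the recombination round's five sites / six mutations at orders 4-5
  round2b <- rbind(parseMutantId("D64K"),
                   data.frame(wt = "N", pos = 83L, alt = c("I", "F")),
                   parseMutantId("K104V"), parseMutantId("H106A"),
                   parseMutantId("P143R"))
  lib <- enumerateCombinatorial(round2b, 4, 5)
  expect_equal(nrow(lib), 11L)
  expect_equal(sum(lib$order == 4L), 9L)
  expect_equal(sum(lib$order == 5L), 2L)
  expect_true("D64K_N83I_K104V_H106A_P143R" %in% lib$mutant_id)
  expect_false(anyDuplicated(lib$mutant_id) > 0)
})

test_that("enumeration count matches the closed form on random designs", {
  withr::with_seed(303, {
    for (rep in 1:10) {
      nSites <- sample(2:5, 1)
      pos <- sort(sample(1:50, nSites))
      wt <- sample(aminoAcids(), nSites, replace = TRUE)
      opts <- do.call(rbind, lapply(seq_len(nSites), function(i) {
        nOpt <- sample(1:3, 1)
        data.frame(wt = wt[i], pos = pos[i],
                   alt = sample(setdiff(aminoAcids(), wt[i]), nOpt))
      }))
      minO <- sample(nSites, 1)
      maxO <- if (minO == nSites) nSites else sample(minO:nSites, 1)
      lib <- enumerateCombinatorial(opts, minO, maxO)
      nOptions <- table(opts$pos)[as.character(pos)]
      closed <- 0
      for (k in minO:maxO) {
        for (s in utils::combn(nSites, k, simplify = FALSE)) {
          closed <- closed + prod(nOptions[s])
        }
      }
      expect_equal(nrow(lib), as.integer(closed))
    }
  })
})

test_that("FASTA round-trips wrapped sequences", {
  seqs <- c(wt = syntheticPbrRScaffold(), m1 = "ACDEFGHIKL")
  path <- withr::local_tempfile(fileext = ".fasta")
  writeFastaAA(seqs, path)
  back <- readFastaAA(path)
  expect_equal(back, seqs)
})
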