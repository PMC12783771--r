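# Shared fixtures, built once per test run. The grammar model and the
# simulated campaign are comparatively expensive (tens of seconds), so they
# are memoized and reused across test files.

.fixtures <- new.env(parent = emptyenv())

# Toy-grammar setup: genotypes, ground truth, a held-out improvable seed
# set, and a model trained on exhaustive pairs among the remaining
# genotypes.
grammarFixture <- function() {
  if (!is.null(.fixtures$grammar)) return(.fixtures$grammar)
  landscape <- toyGrammarLandscape()
  ids <- grammarGenotypes()
  gt <- groundTruthTable(landscape, ids)
  seqs <- vapply(ids, function(i) {
    applySubstitutions(landscape@wildtype,
                       parseMutantId(i, landscape@alphabet))
  }, character(1))
  alpha <- landscape@alphabet
  r6 <- match(substr(seqs, 6, 6), alpha)
  r13 <- match(substr(seqs, 13, 13), alpha)
  # held-out seeds must be improvable in the prompted direction:
  # lead can still go up (position 6 below the ladder top) and zinc can
  # still go down (position 13 above the ladder bottom)
  improvable <- which(r6 <= 6 & r13 >= 3)
  heldOut <- withr::with_seed(42, sample(improvable, 12))
  trainIdx <- setdiff(seq_along(ids), heldOut)
  objs <- defaultObjectives(tauZn = 0, tauPb = 0)
  metrics <- cbind(Zn = gt$norm_fc_zn, Pb = gt$norm_fc_pb)
  pairs <- buildPairedDataset(seqs[trainIdx], metrics[trainIdx, ], objs,
                              bothOrientations = TRUE)
  model <- trainModel(pairs, toyTrainConfig(seed = 7L),
                      vocab = buildVocabulary(alpha, 2L))
  .fixtures$grammar <- list(landscape = landscape, ids = ids, seqs = seqs,
                            gt = gt, heldOut = heldOut,
                            trainIdx = trainIdx, pairs = pairs,
                            model = model)
  .fixtures$grammar
}

# Three-round simulated campaign on the default toy landscape.
campaignFixture <- function() {
  if (!is.null(.fixtures$campaign)) return(.fixtures$campaign)
  .fixtures$campaign <- runCampaign(toyCampaignLandscape(), rounds = 3L,
                                    roundSizes = 60L, seed = 11L)
  .fixtures$campaign
}

# Random direction-labeled record sets for property tests.
randomRecordSet <- function(M, j = 2L, L = 6L, alphabet = c("A", "C", "D",
                                                            "G")) {
  seqs <- vapply(seq_len(M), function(i) {
    paste(sample(alphabet, L, replace = TRUE), collapse = "")
  }, character(1))
  metrics <- matrix(rnorm(M * j), M, j)
  list(sequences = seqs, metrics = metrics)
}

# Independent brute-force oracle for pair construction: enumerate all
# unordered pairs and apply the three-way threshold rule directly.
bruteForcePairs <- function(sequences, metrics, taus,
                            bothOrientations = TRUE) {
  # collapse duplicate sequences to mean metrics, as the builder documents
  uniq <- unique(sequences)
  j <- ncol(metrics)
  met <- vapply(uniq, function(s) {
    colMeans(metrics[sequences == s, , drop = FALSE])
  }, numeric(j))
  met <- if (j == 1L) matrix(met, ncol = 1L) else t(met)
  out <- list()
  M <- length(uniq)
  if (M >= 2L) {
    for (a in seq_len(M - 1L)) {
      for (b in seq(a + 1L, M)) {
        d <- met[b, ] - met[a, ]
        if (all(abs(d) > taus)) {
          lab <- ifelse(d > 0, "<inc>", "<dec>")
          out[[length(out) + 1L]] <- list(src = uniq[a], tgt = uniq[b],
                                          lab = lab, delta = d)
          if (bothOrientations) {
            out[[length(out) + 1L]] <- list(src = uniq[b], tgt = uniq[a],
                                            lab = ifelse(d > 0, "<dec>",
                                                         "<inc>"),
                                            delta = -d)
          }
        }
      }
    }
  }
  out
}

pairSignature <- function(src, tgt, labels) {
  sort(paste(src, tgt, apply(labels, 1L, paste, collapse = ","),
             sep = "|"))
}

# Per-mutant normalized fold changes pulled out of an activity table.
metricsFromActivity <- function(activity, ids) {
  getVal <- function(id, lig) {
    mean(activity$norm_fc[activity$mutant_id == id &
                            activity$ligand == lig])
  }
  data.frame(
    mutant_id = ids,
    norm_fc_pb = vapply(ids, getVal, numeric(1), lig = "lead"),
    norm_fc_zn = vapply(ids, getVal, numeric(1), lig = "zinc"),
    stringsAsFactors = FALSE, row.names = NULL)
}

# Independent oracle for simulator parameter recovery: ordinary least
# squares of measured log lead-signal on the known substitution-indicator
# design matrix, compared to the landscape's true additive effects.
olsEffectRmse <- function(landscape, screen) {
  lead <- screen[screen$ligand == "lead", ]
  meanSig <- tapply(lead$signal, lead$mutant_id, mean)
  mids <- names(meanSig)
  subsList <- lapply(mids, parseMutantId, alphabet = landscape@alphabet)
  allSubs <- unique(do.call(rbind, subsList)[c("pos", "alt")])
  key <- paste(allSubs$pos, allSubs$alt)
  X <- matrix(0, length(mids), nrow(allSubs))
  for (i in seq_along(mids)) {
    s <- subsList[[i]]
    if (nrow(s)) X[i, match(paste(s$pos, s$alt), key)] <- 1
  }
  fit <- lm.fit(cbind(1, X), log(as.numeric(meanSig)))
  est <- fit$coefficients[-1]
  truth <- landscape@effects$lead[cbind(allSubs$pos,
                                        match(allSubs$alt,
                                              landscape@alphabet))]
  ok <- colSums(X) > 0 & !is.na(est)
  sqrt(mean((est[ok] - truth[ok])^2))
}
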