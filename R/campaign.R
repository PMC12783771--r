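# Simulated design-build-test-learn campaign: screen -> metrics -> pair ->
# train -> generate per round, with ground-truth bookkeeping so design
# enrichment can be measured against a matched random baseline.

stageError <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[stage: %s] %s", stage, conditionMessage(e)),
         call. = FALSE)
  })
}

# Per-mutant metric matrix (objective order) from an activity table,
# averaging across batches when a mutant was screened more than once.
metricMatrix <- function(activity, objectives) {
  ids <- unique(activity$mutant_id)
  out <- matrix(NA_real_, length(ids), length(objectives),
                dimnames = list(ids,
                                vapply(objectives, function(o) o@name,
                                       character(1))))
  for (k in seq_along(objectives)) {
    o <- objectives[[k]]
    sub <- activity[activity$ligand == o@ligand, , drop = FALSE]
    agg <- tapply(sub[[o@metric]], sub$mutant_id, mean)
    out[names(agg), k] <- as.numeric(agg)
  }
  out
}

#' Run a simulated multi-round design campaign
#'
#' Executes the full loop on a synthetic landscape: simulate the initial
#' screen, derive metrics, estimate noise thresholds, build and balance the
#' directional paired dataset, train the conditional model, select seeds,
#' generate and filter a round library, and "screen" it by simulation.
#' Per round it records the quantities the campaign narrative tracks: M
#' (distinct measured variants), retained pair count, category counts, seed
#' count, library size, and ground-truth enrichment of the proposed library
#' over a random baseline with the same mutation-order distribution.
#'
#' @param landscape A [LandscapeSpec-class].
#' @param rounds Number of model-guided rounds (0 = initial screen only).
#' @param roundSizes Library capacity per round (recycled; the campaign's
#'   own schedule was 382, 200, 108).
#' @param objectives List of [ObjectiveSpec-class]; `NA` taus are estimated
#'   from wildtype replicate scatter each round.
#' @param train A [TrainConfig-class] for the per-round model.
#' @param gen A [GenerationConfig-class]; its capacity/exclusions are
#'   overridden per round.
#' @param initialLibrary Mutant ids for round 0 (default: all single
#'   mutants plus `nInitialDoubles` random doubles).
#' @param nInitialDoubles Random double mutants added to the default
#'   initial library.
#' @param maxSeeds Cap on seeds taken per round (top of the sorted list).
#' @param maxPerCategory Cap per directional category when balancing.
#' @param baselineDraws Random mutants drawn for the enrichment baseline.
#' @param seed Master seed; all stage seeds derive from it.
#' @return A `campaignReport` list: `initial` summary and one entry per
#'   round with the logged quantities, libraries, and enrichment stats.
#' @export
runCampaign <- function(landscape, rounds = 3L,
                        roundSizes = 60L,
                        objectives = defaultObjectives(),
                        train = toyTrainConfig(),
                        gen = generationConfig(),
                        initialLibrary = NULL,
                        nInitialDoubles = 60L,
                        maxSeeds = 12L,
                        maxPerCategory = 400L,
                        baselineDraws = 300L,
                        seed = 1L) {
  roundSizes <- rep_len(as.integer(roundSizes), max(rounds, 1L))
  if (is.null(initialLibrary)) {
    initialLibrary <- c(allSingleMutants(landscape),
                        randomMutants(landscape, nInitialDoubles, 2L,
                                      seed = childSeed(seed, 1L)))
  }
  screened <- unique(initialLibrary)
  measurements <- stageError("screen", simulateScreen(
    landscape, screened, seed = childSeed(seed, 2L), batch = "round0"))
  vocab <- buildVocabulary(landscape@alphabet, length(objectives))
  report <- list(initial = list(library = screened,
                                n_mutants = length(screened)),
                 rounds = list())
  if (rounds == 0L) {
    activity <- stageError("metrics", activityTable(
      measurements, clampNegativeDr = TRUE))
    report$initial$activity <- activity
    class(report) <- "campaignReport"
    return(report)
  }
  for (r in seq_len(rounds)) {
    activity <- stageError("metrics", activityTable(
      measurements, clampNegativeDr = TRUE))
    objs <- lapply(objectives, function(o) {
      if (is.na(o@tau)) {
        o@tau <- stageError("tau", estimateNoiseThreshold(
          measurements, o@ligand, o@metric))
      }
      o
    })
    metrics <- stageError("metrics", metricMatrix(activity, objs))
    ids <- rownames(metrics)
    keep <- stats::complete.cases(metrics)
    ids <- ids[keep]
    metrics <- metrics[keep, , drop = FALSE]
    sequences <- vapply(ids, function(id) {
      applySubstitutions(landscape@wildtype,
                         parseMutantId(id, landscape@alphabet))
    }, character(1))
    pairs <- stageError("pair", buildPairedDataset(
      sequences, metrics, objs, bothOrientations = TRUE))
    balanced <- stageError("pair", balanceCategories(
      pairs, seed = childSeed(seed, 100L + r),
      maxPerCategory = maxPerCategory))
    rTrain <- train
    rTrain@seed <- childSeed(seed, 200L + r)
    model <- stageError("train", trainModel(balanced, rTrain,
                                            vocab = vocab))
    records <- data.frame(sequence = sequences, stringsAsFactors = FALSE)
    objNames <- vapply(objs, function(o) o@name, character(1))
    for (k in seq_along(objNames)) records[[objNames[k]]] <- metrics[, k]
    wtRow <- as.list(records[ids == "WT", , drop = FALSE])
    seeds <- stageError("seeds", selectSeeds(
      records[ids != "WT", , drop = FALSE], wtRow, objNames,
      directions = gen@directions))
    seeds <- utils::head(seeds, maxSeeds)
    rGen <- gen
    rGen@capacity <- roundSizes[r]
    rGen@seed <- childSeed(seed, 300L + r)
    rGen@exclude <- screened
    candidates <- stageError("generate", proposeCandidates(model, seeds,
                                                           rGen))
    library <- stageError("generate", filterLibrary(
      candidates, landscape@wildtype, rGen))
    if (nrow(library) == 0L) {
      stop(sprintf("[stage: generate] round %d produced an empty library",
                   r), call. = FALSE)
    }
    truth <- groundTruthTable(landscape, library$mutant_id)
    baselineIds <- randomMutants(landscape, baselineDraws,
                                 orders = rep_len(library$order,
                                                  baselineDraws),
                                 seed = childSeed(seed, 400L + r))
    baseTruth <- groundTruthTable(landscape, baselineIds)
    selFrac <- mean(truth$selective)
    baseFrac <- mean(baseTruth$selective)
    test <- stats::binom.test(sum(truth$selective), nrow(truth),
                              p = min(1, max(baseFrac, 1e-9) * 3),
                              alternative = "greater")
    report$rounds[[r]] <- list(
      round = r,
      M = length(ids),
      pairsRetained = pairCount(pairs),
      pairsBalanced = pairCount(balanced),
      categoryCounts = categoryCounts(balanced),
      taus = setNames(vapply(objs, function(o) o@tau, numeric(1)),
                      objNames),
      nSeeds = length(seeds),
      library = library,
      librarySize = nrow(library),
      meanPbObjective = mean(truth$norm_fc_pb),
      selectiveFraction = selFrac,
      baselineFraction = baseFrac,
      enrichment = if (baseFrac > 0) selFrac / baseFrac else Inf,
      enrichmentPValue = test$p.value,
      scatter = cbind(data.frame(mutant_id = ids,
                                 stringsAsFactors = FALSE),
                      as.data.frame(metrics)),
      trainLoss = model@history$trainLoss[nrow(model@history)])
    # "screen" the proposed library and fold it into the training data
    newMeas <- stageError("screen", simulateScreen(
      landscape, library$mutant_id, seed = childSeed(seed, 500L + r),
      batch = paste0("round", r)))
    measurements <- rbind(measurements, newMeas)
    screened <- unique(c(screened, library$mutant_id))
  }
  class(report) <- "campaignReport"
  report
}

#' @export
print.campaignReport <- function(x, ...) {
  cat(sprintf("Campaign: initial screen of %d mutants, %d round(s)\n",
              x$initial$n_mutants, length(x$rounds)))
  for (r in x$rounds) {
    cat(sprintf(
      " round %d: M=%d pairs=%d (balanced %d) seeds=%d library=%d selective=%.2f (baseline %.3f, %.1fx, p=%.2g)\n",
      r$round, r$M, r$pairsRetained, r$pairsBalanced, r$nSeeds,
      r$librarySize, r$selectiveFraction, r$baselineFraction,
      r$enrichment, r$enrichmentPValue))
  }
  invisible(x)
}
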