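# Single-step, seed-conditioned design: prompt the trained model with the
# desired direction tokens from experimentally validated seeds, sample
# candidates with top-k truncation in one generation pass (no iterative
# refinement), then filter to a round library sized to plate capacity.

#' Construct a GenerationConfig
#'
#' @param directions Direction prompt, one token per objective in objective
#'   order; default `c("<dec>", "<inc>")` = decrease zinc response,
#'   increase lead response.
#' @param topK Top-k cutoff (default 10).
#' @param candidatesPerSeed Samples per seed (default 20).
#' @param maxOrder Maximum mutation order kept (default 6).
#' @param capacity Library capacity (default 382: a 384-well plate with
#'   wells left open for controls).
#' @param seed RNG seed for sampling.
#' @param exclude Previously screened mutant ids, never re-proposed.
#' @return A [GenerationConfig-class].
#' @export
generationConfig <- function(directions = c(TOKEN_DEC, TOKEN_INC),
                             topK = 10L, candidatesPerSeed = 20L,
                             maxOrder = 6L, capacity = 382L, seed = 1L,
                             exclude = character()) {
  new("GenerationConfig", directions = directions, topK = as.integer(topK),
      candidatesPerSeed = as.integer(candidatesPerSeed),
      maxOrder = as.integer(maxOrder), capacity = as.integer(capacity),
      seed = as.integer(seed), exclude = as.character(exclude))
}

#' Select seed sequences for generation
#'
#' Seeds are all records strictly better than the wildtype in every
#' prompted direction (for the selective prompt: higher lead response and
#' lower zinc response than wildtype). Deterministic order: descending by
#' the first objective prompted `<inc>` (or the first objective if none).
#' An empty seed set falls back to the wildtype sequence with a warning
#' unless `hardFail`.
#'
#' @param records data.frame with a `sequence` column and one metric column
#'   per objective (in objective order, named as in `objectiveNames`).
#' @param wildtype List/row with `sequence` and the same metric columns.
#' @param objectiveNames Names of the metric columns, in objective order.
#' @param directions `<inc>`/`<dec>` per objective (the design prompt).
#' @param hardFail Error instead of falling back to wildtype.
#' @return Character vector of seed sequences.
#' @export
selectSeeds <- function(records, wildtype, objectiveNames,
                        directions = c(TOKEN_DEC, TOKEN_INC),
                        hardFail = FALSE) {
  stopifnot(length(objectiveNames) == length(directions))
  ok <- rep(TRUE, nrow(records))
  for (k in seq_along(objectiveNames)) {
    v <- records[[objectiveNames[k]]]
    w <- wildtype[[objectiveNames[k]]]
    ok <- ok & if (directions[k] == TOKEN_INC) v > w else v < w
  }
  ok[is.na(ok)] <- FALSE
  hits <- records[ok, , drop = FALSE]
  if (nrow(hits) == 0L) {
    if (hardFail) stop("no qualifying seed sequences", call. = FALSE)
    warning("no records beat wildtype in all prompted directions; ",
            "falling back to the wildtype seed", call. = FALSE)
    return(wildtype$sequence)
  }
  incIdx <- which(directions == TOKEN_INC)
  sortCol <- objectiveNames[if (length(incIdx) > 0L) incIdx[1L] else 1L]
  hits <- hits[order(-hits[[sortCol]], hits$sequence), , drop = FALSE]
  hits$sequence
}

#' Propose candidate sequences from seeds (single generation step)
#'
#' For each seed, `candidatesPerSeed` samples are decoded with top-k
#' truncation at each step (renormalized), prompted with the direction
#' tokens followed by the seed. Exactly one generation pass; reproducible
#' under the config seed.
#'
#' @param model A trained [Seq2SeqModel-class].
#' @param seeds Character vector of seed sequences.
#' @param config A [GenerationConfig-class].
#' @return data.frame: `sequence` (`NA` when a decode emitted a non-residue
#'   token), `seed_index`, `sample_index`; attribute `aborted` counts
#'   over-length decodes.
#' @export
proposeCandidates <- function(model, seeds, config = generationConfig()) {
  if (length(seeds) == 0L) stop("no seeds supplied", call. = FALSE)
  out <- vector("list", length(seeds))
  aborted <- 0L
  for (s in seq_along(seeds)) {
    samples <- sampleTopK(model, config@directions, seeds[s],
                          k = config@topK,
                          nSamples = config@candidatesPerSeed,
                          seed = childSeed(config@seed, s))
    aborted <- aborted + attr(samples, "aborted")
    seqs <- vapply(samples, function(t) tokensToSequence(model@vocab, t),
                   character(1))
    out[[s]] <- data.frame(sequence = seqs, seed_index = s,
                           sample_index = seq_along(seqs),
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "aborted") <- aborted
  res
}

#' Filter candidates into a round library
#'
#' Pipeline: drop decodes with non-residue tokens or changed length; drop
#' candidates identical to wildtype or above the maximum mutation order;
#' drop previously screened ids; deduplicate globally (summing sampling
#' frequency); truncate to capacity by sampling-frequency rank, then
#' first-seen order.
#'
#' @param candidates data.frame from [proposeCandidates()].
#' @param wildtype Wildtype sequence.
#' @param config A [GenerationConfig-class].
#' @return data.frame: `mutant_id`, `sequence`, `order`, `n_samples`,
#'   `seed_index` (first seed that produced it); attribute `dropped` is a
#'   named count per filtering stage. An empty library is allowed (flagged
#'   by a warning).
#' @export
filterLibrary <- function(candidates, wildtype, config = generationConfig()) {
  dropped <- c(invalid = 0L, length = 0L, wildtype = 0L, order = 0L,
               excluded = 0L, capacity = 0L)
  df <- candidates
  bad <- is.na(df$sequence)
  dropped["invalid"] <- sum(bad)
  df <- df[!bad, , drop = FALSE]
  wrongLen <- nchar(df$sequence) != nchar(wildtype)
  dropped["length"] <- sum(wrongLen)
  df <- df[!wrongLen, , drop = FALSE]
  if (nrow(df) > 0L) {
    df$mutant_id <- vapply(df$sequence, function(s)
      sequenceToId(wildtype, s), character(1))
    df$order <- vapply(df$sequence, function(s)
      hammingOrder(wildtype, s), integer(1))
    isWt <- df$order == 0L
    dropped["wildtype"] <- sum(isWt)
    df <- df[!isWt, , drop = FALSE]
    tooHigh <- df$order > config@maxOrder
    dropped["order"] <- sum(tooHigh)
    df <- df[!tooHigh, , drop = FALSE]
    excl <- df$mutant_id %in% config@exclude
    dropped["excluded"] <- sum(excl)
    df <- df[!excl, , drop = FALSE]
  }
  if (nrow(df) == 0L) {
    warning("library is empty after filtering", call. = FALSE)
    out <- data.frame(mutant_id = character(), sequence = character(),
                      order = integer(), n_samples = integer(),
                      seed_index = integer(), stringsAsFactors = FALSE)
    attr(out, "dropped") <- dropped
    return(out)
  }
  firstSeen <- !duplicated(df$mutant_id)
  counts <- table(df$mutant_id)
  uniq <- df[firstSeen, , drop = FALSE]
  uniq$n_samples <- as.integer(counts[uniq$mutant_id])
  uniq$first_seen <- which(firstSeen)
  uniq <- uniq[order(-uniq$n_samples, uniq$first_seen), , drop = FALSE]
  if (nrow(uniq) > config@capacity) {
    dropped["capacity"] <- nrow(uniq) - config@capacity
    uniq <- uniq[seq_len(config@capacity), , drop = FALSE]
  }
  out <- data.frame(mutant_id = uniq$mutant_id, sequence = uniq$sequence,
                    order = uniq$order, n_samples = uniq$n_samples,
                    seed_index = uniq$seed_index, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  out
}

#' Intersection of two proposed libraries
#'
#' Utility for the campaign tactic of screening only mutants proposed under
#' two different training metrics.
#'
#' @param idsA,idsB Character vectors of mutant ids.
#' @return Ids present in both, in `idsA` order.
#' @export
intersectLibraries <- function(idsA, idsB) {
  idsA[idsA %in% idsB]
}
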