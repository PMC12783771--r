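# Conditional sequence-to-sequence core. The model factorizes
#   P(target | d, source) = prod_t P(target_t | d, source, target_{<t})
# and is trained by token-level cross-entropy (maximizing conditional
# log-likelihood) with AdamW. The built-in "tiny" backbone is a
# position-aligned conditional decoder: at step t it conditions on the
# direction tokens d, the source residue aligned at position t, the
# position itself, and the previously emitted target token, through one
# hidden layer onto a softmax over the vocabulary. The diagonal alignment
# is the right inductive bias for the substitution-only regime (source and
# target differ only by point substitutions), and it keeps the model
# trainable from scratch on a CPU in seconds. Output weights start at zero,
# so an untrained model emits exactly the uniform distribution.

#' Build a model vocabulary
#'
#' Four control tokens (`<pad>`, `<s>`, `</s>`, `<unk>`), the two direction
#' tokens (`<inc>`, `<dec>`), then the residue alphabet; ids are dense and
#' assigned deterministically in that order.
#'
#' @param alphabet Character vector of residue letters (default 20 amino
#'   acids; reduced alphabets allowed for tests).
#' @param nObjectives Number of objectives the model will be prompted with
#'   (recorded for interface completeness; both direction tokens are shared
#'   across objectives).
#' @return A [Vocabulary-class].
#' @export
#' @examples
#' vocabSize(buildVocabulary())  # 20 + 2 special + 4 control = 26
buildVocabulary <- function(alphabet = aminoAcids(), nObjectives = 2L) {
  if (length(alphabet) == 0L || anyDuplicated(alphabet)) {
    stop("alphabet must be non-empty with unique letters", call. = FALSE)
  }
  stopifnot(nObjectives >= 1L)
  new("Vocabulary",
      tokens = c(TOKEN_PAD, TOKEN_START, TOKEN_END, TOKEN_UNK,
                 TOKEN_INC, TOKEN_DEC, alphabet),
      alphabet = as.character(alphabet))
}

#' @describeIn buildVocabulary Total number of tokens.
#' @param vocab A [Vocabulary-class].
#' @export
vocabSize <- function(vocab) length(vocab@tokens)

#' @describeIn buildVocabulary Map tokens to integer ids (error on unknown
#'   tokens).
#' @param tokens Character vector of tokens.
#' @export
tokenIds <- function(vocab, tokens) {
  ids <- match(tokens, vocab@tokens)
  if (anyNA(ids)) {
    stop(sprintf("token(s) outside vocabulary: %s",
                 paste(unique(tokens[is.na(ids)]), collapse = ", ")),
         call. = FALSE)
  }
  ids
}

#' @describeIn buildVocabulary Map integer ids back to tokens.
#' @param ids Integer token ids.
#' @export
idTokens <- function(vocab, ids) vocab@tokens[ids]

#' Convert decoded tokens to a residue sequence
#'
#' @param vocab A [Vocabulary-class].
#' @param tokens Decoded token vector (without the terminating `</s>`).
#' @return Sequence string, or `NA` if any token is not a residue.
#' @export
tokensToSequence <- function(vocab, tokens) {
  if (length(tokens) == 0L || !all(tokens %in% vocab@alphabet)) {
    return(NA_character_)
  }
  paste(tokens, collapse = "")
}

#' Construct a TrainConfig
#'
#' @param lr Learning rate (default 1e-4).
#' @param weightDecay Decoupled weight decay (default 1e-4).
#' @param batchSize Minibatch size in examples.
#' @param epochs Training epochs.
#' @param seed Seed for init, shuffling and the validation split.
#' @param valFraction Validation fraction by unordered-pair identity.
#' @param embDim,hiddenDim Embedding / hidden width of the tiny backbone.
#' @param maxLen Maximum decode length supported.
#' @param backbone "tiny" (default) or "pretrained-adapter".
#' @param loraRank,loraAlpha,loraDropout Low-rank adapter settings, used
#'   only by the pretrained path.
#' @param patience Early-stop patience on validation loss (`NA`: off).
#' @return A [TrainConfig-class].
#' @export
trainConfig <- function(lr = 1e-4, weightDecay = 1e-4, batchSize = 64L,
                        epochs = 20L, seed = 1L, valFraction = 0.1,
                        embDim = 24L, hiddenDim = 64L, maxLen = 64L,
                        backbone = "tiny", loraRank = 16L, loraAlpha = 32,
                        loraDropout = 0.05, patience = NA_integer_) {
  new("TrainConfig", lr = lr, weightDecay = weightDecay,
      batchSize = as.integer(batchSize), epochs = as.integer(epochs),
      seed = as.integer(seed), valFraction = valFraction,
      embDim = as.integer(embDim), hiddenDim = as.integer(hiddenDim),
      maxLen = as.integer(maxLen), backbone = backbone,
      loraRank = as.integer(loraRank), loraAlpha = loraAlpha,
      loraDropout = loraDropout, patience = as.integer(patience))
}

#' Training preset for toy-scale landscapes
#'
#' Settings under which the tiny backbone converges on reduced-alphabet,
#' length-20 problems in well under a minute on one CPU: a larger learning
#' rate than the campaign-scale default (the tiny model is trained from
#' scratch, not fine-tuned), 40 epochs, batch 256, hidden width 96.
#'
#' @param seed Training seed.
#' @param epochs Number of epochs (default 40).
#' @return A [TrainConfig-class].
#' @export
toyTrainConfig <- function(seed = 1L, epochs = 40L) {
  trainConfig(lr = 5e-3, weightDecay = 1e-4, batchSize = 256L,
              epochs = epochs, seed = seed, embDim = 24L, hiddenDim = 96L)
}

# ---- parameter initialisation ------------------------------------------

initParams <- function(vocab, nObjectives, config) {
  V <- vocabSize(vocab)
  d <- config@embDim
  h <- config@hiddenDim
  dIn <- d * (nObjectives + 3L)
  list(
    E = matrix(rnorm(V * d, sd = 0.1), V, d),
    Pos = matrix(rnorm(config@maxLen * d, sd = 0.1), config@maxLen, d),
    W1 = matrix(rnorm(dIn * h, sd = sqrt(1 / dIn)), dIn, h),
    b1 = numeric(h),
    # zero output layer: untrained model is exactly uniform over the vocab
    W2 = matrix(0, h, V),
    b2 = numeric(V)
  )
}

#' Create an untrained conditional sequence model
#'
#' @param vocab A [Vocabulary-class].
#' @param nObjectives Number of direction tokens in a prompt.
#' @param config A [TrainConfig-class].
#' @return An untrained [Seq2SeqModel-class]; its output distribution is
#'   exactly uniform over the vocabulary.
#' @export
newSeq2SeqModel <- function(vocab, nObjectives = 2L, config = trainConfig()) {
  if (config@backbone == "pretrained-adapter") {
    stop(paste("the pretrained-backbone adapter requires a user-supplied",
               "backbone implementation; use backbone = 'tiny'"),
         call. = FALSE)
  }
  params <- withSeed(config@seed, initParams(vocab, nObjectives, config))
  new("Seq2SeqModel", vocab = vocab, nObjectives = as.integer(nObjectives),
      params = params, config = config,
      history = data.frame(epoch = integer(), trainLoss = numeric(),
                           valLoss = numeric(), validity = numeric()))
}

setMethod("show", "Seq2SeqModel", function(object) {
  cat(sprintf("Seq2SeqModel (tiny backbone): |V| = %d, emb %d, hidden %d, %d objective(s)\n",
              vocabSize(object@vocab), object@config@embDim,
              object@config@hiddenDim, object@nObjectives))
  if (nrow(object@history) > 0L) {
    last <- object@history[nrow(object@history), ]
    cat(sprintf("trained %d epoch(s); final train loss %.4f, val loss %s\n",
                nrow(object@history), last$trainLoss,
                ifelse(is.na(last$valLoss), "NA",
                       sprintf("%.4f", last$valLoss))))
  } else {
    cat("untrained (uniform output distribution)\n")
  }
})

# ---- row-level encoding -------------------------------------------------
# An example (labels, source, target) is unrolled into target-length + 1
# rows (the +1 predicts the end token). Row features are token ids only;
# embeddings are gathered at forward time.

encodeExamples <- function(vocab, labelsMat, sources, targets) {
  n <- length(sources)
  j <- ncol(labelsMat)
  endId <- tokenIds(vocab, TOKEN_END)
  startId <- tokenIds(vocab, TOKEN_START)
  padId <- tokenIds(vocab, TOKEN_PAD)
  dirIds <- matrix(tokenIds(vocab, labelsMat), n, j)
  srcIds <- lapply(sources, function(s) tokenIds(vocab, seqChars(s)))
  tgtIds <- lapply(targets, function(s) tokenIds(vocab, seqChars(s)))
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    tg <- c(tgtIds[[i]], endId)
    Lt <- length(tg)
    src <- srcIds[[i]]
    pos <- seq_len(Lt)
    alig <- ifelse(pos <= length(src), src[pmin(pos, length(src))], padId)
    rows[[i]] <- cbind(example = i, pos = pos,
                       src = alig,
                       prev = c(startId, tg[-Lt]),
                       target = tg)
  }
  rows <- do.call(rbind, rows)
  maxPos <- max(rows[, "pos"])
  list(rows = rows, dirIds = dirIds, maxPos = maxPos)
}

# Forward pass over rows; returns probabilities and (optionally) the
# intermediates needed for backprop.
forwardRows <- function(params, dirIds, rows, wantGrad = FALSE) {
  d <- ncol(params$E)
  ex <- rows[, "example"]
  Fmat <- cbind(
    do.call(cbind, lapply(seq_len(ncol(dirIds)), function(k) {
      params$E[dirIds[ex, k], , drop = FALSE]
    })),
    params$E[rows[, "src"], , drop = FALSE],
    params$Pos[rows[, "pos"], , drop = FALSE],
    params$E[rows[, "prev"], , drop = FALSE]
  )
  Z <- sweep(Fmat %*% params$W1, 2L, params$b1, `+`)
  H <- Z * (Z > 0)
  logits <- sweep(H %*% params$W2, 2L, params$b2, `+`)
  mx <- apply(logits, 1L, max)
  expL <- exp(logits - mx)
  P <- expL / rowSums(expL)
  if (!wantGrad) return(list(P = P))
  list(P = P, H = H, F = Fmat)
}

backwardRows <- function(params, dirIds, rows, fwd) {
  n <- nrow(rows)
  d <- ncol(params$E)
  j <- ncol(dirIds)
  dL <- fwd$P
  dL[cbind(seq_len(n), rows[, "target"])] <-
    dL[cbind(seq_len(n), rows[, "target"])] - 1
  dL <- dL / n
  gW2 <- crossprod(fwd$H, dL)
  gb2 <- colSums(dL)
  dH <- tcrossprod(dL, params$W2)
  dH[fwd$H <= 0] <- 0
  gW1 <- crossprod(fwd$F, dH)
  gb1 <- colSums(dH)
  dF <- tcrossprod(dH, params$W1)
  gE <- matrix(0, nrow(params$E), d)
  gPos <- matrix(0, nrow(params$Pos), d)
  accumulate <- function(g, block, ids) {
    r <- rowsum(block, group = ids)
    uid <- as.integer(rownames(r))
    g[uid, ] <- g[uid, ] + r
    g
  }
  ex <- rows[, "example"]
  for (k in seq_len(j)) {
    cols <- ((k - 1L) * d + 1L):(k * d)
    gE <- accumulate(gE, dF[, cols, drop = FALSE], dirIds[ex, k])
  }
  off <- j * d
  gE <- accumulate(gE, dF[, (off + 1L):(off + d), drop = FALSE],
                   rows[, "src"])
  gPos <- accumulate(gPos, dF[, (off + d + 1L):(off + 2L * d), drop = FALSE],
                     rows[, "pos"])
  gE <- accumulate(gE, dF[, (off + 2L * d + 1L):(off + 3L * d), drop = FALSE],
                   rows[, "prev"])
  list(E = gE, Pos = gPos, W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2)
}

rowLoss <- function(P, targets) {
  -mean(log(pmax(P[cbind(seq_along(targets), targets)], 1e-300)))
}

# AdamW step with decoupled weight decay (biases excluded from decay).
adamwStep <- function(params, grads, state, lr, wd, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    decay <- if (nm %in% c("b1", "b2")) 0 else wd
    params[[nm]] <- params[[nm]] -
      lr * (mhat / (sqrt(vhat) + eps) + decay * params[[nm]])
  }
  list(params = params, state = state)
}

#' Train the conditional sequence model
#'
#' Teacher-forced training maximizing the conditional log-likelihood of
#' target sequences given the direction prompt and source (token-level
#' cross-entropy), optimized with AdamW. All randomness (initialisation,
#' the validation split, shuffling) flows from `config@seed`; two runs with
#' identical data, config and seed produce identical loss curves.
#'
#' @param pairs A non-empty [DirectionalPairs-class].
#' @param config A [TrainConfig-class].
#' @param vocab Optional [Vocabulary-class]; defaults to the letters
#'   observed in the data.
#' @param model Optional existing model to continue training.
#' @return A trained [Seq2SeqModel-class] with per-epoch loss history.
#' @export
trainModel <- function(pairs, config = trainConfig(), vocab = NULL,
                       model = NULL) {
  if (pairCount(pairs) == 0L) {
    stop("cannot train on an empty paired dataset", call. = FALSE)
  }
  if (config@backbone == "pretrained-adapter") {
    stop("pretrained-adapter backbone requires a user-supplied adapter",
         call. = FALSE)
  }
  if (config@loraRank != 16L || config@loraAlpha != 32 ||
      config@loraDropout != 0.05) {
    message("low-rank adapter settings are ignored by the tiny backbone ",
            "(it is fully trained)")
  }
  if (is.null(vocab)) {
    letters <- sort(unique(unlist(strsplit(c(pairs@source, pairs@target),
                                           ""))))
    vocab <- buildVocabulary(letters, length(pairs@objectives))
  }
  j <- length(pairs@objectives)
  if (is.null(model)) {
    model <- newSeq2SeqModel(vocab, j, config)
  }
  params <- model@params
  enc <- encodeExamples(vocab, pairs@labels, pairs@source, pairs@target)
  if (enc$maxPos > config@maxLen) {
    stop(sprintf("sequences need %d positions but maxLen is %d",
                 enc$maxPos, config@maxLen), call. = FALSE)
  }
  n <- pairCount(pairs)
  # Validation split by unordered-pair identity so both orientations of a
  # pair land on the same side (prevents orientation leakage).
  pairKey <- vapply(seq_len(n), function(i) {
    paste(sort(c(pairs@source[i], pairs@target[i])), collapse = "|")
  }, character(1))
  history <- model@history
  result <- withSeed(config@seed, {
    keys <- unique(pairKey)
    nVal <- floor(config@valFraction * length(keys))
    valKeys <- if (nVal > 0L) sample(keys, nVal) else character()
    isVal <- pairKey %in% valKeys
    trainEx <- which(!isVal)
    valEx <- which(isVal)
    rowsByEx <- split(seq_len(nrow(enc$rows)), enc$rows[, "example"])
    valRows <- unlist(rowsByEx[as.character(valEx)], use.names = FALSE)
    state <- list(t = 0L,
                  m = lapply(params, function(p) p * 0),
                  v = lapply(params, function(p) p * 0))
    bestVal <- Inf
    badEpochs <- 0L
    for (epoch in seq_len(config@epochs)) {
      perm <- sample(trainEx)
      batches <- split(perm, ceiling(seq_along(perm) / config@batchSize))
      lossNum <- 0
      lossDen <- 0
      for (b in batches) {
        rIdx <- unlist(rowsByEx[as.character(b)], use.names = FALSE)
        rows <- enc$rows[rIdx, , drop = FALSE]
        fwd <- forwardRows(params, enc$dirIds, rows, wantGrad = TRUE)
        loss <- rowLoss(fwd$P, rows[, "target"])
        if (!is.finite(loss)) {
          stop(sprintf(
            "NaN/Inf training loss at epoch %d (batch of %d examples); try a smaller learning rate",
            epoch, length(b)), call. = FALSE)
        }
        lossNum <- lossNum + loss * nrow(rows)
        lossDen <- lossDen + nrow(rows)
        grads <- backwardRows(params, enc$dirIds, rows, fwd)
        upd <- adamwStep(params, grads, state, config@lr, config@weightDecay)
        params <- upd$params
        state <- upd$state
      }
      valLoss <- NA_real_
      if (length(valRows) > 0L) {
        rows <- enc$rows[valRows, , drop = FALSE]
        fwd <- forwardRows(params, enc$dirIds, rows)
        valLoss <- rowLoss(fwd$P, rows[, "target"])
      }
      history <- rbind(history, data.frame(
        epoch = nrow(history) + 1L, trainLoss = lossNum / lossDen,
        valLoss = valLoss, validity = NA_real_))
      if (!is.na(config@patience) && !is.na(valLoss)) {
        if (valLoss < bestVal - 1e-6) {
          bestVal <- valLoss
          badEpochs <- 0L
        } else {
          badEpochs <- badEpochs + 1L
          if (badEpochs >= config@patience) break
        }
      }
    }
    params
  })
  model@params <- result
  model@vocab <- vocab
  model@config <- config
  model@history <- history
  model
}

# Distribution over the next token given a prompt state.
nextTokenProbs <- function(model, dirIds, srcIds, pos, prevIds) {
  padId <- tokenIds(model@vocab, TOKEN_PAD)
  n <- length(prevIds)
  rows <- cbind(example = seq_len(n), pos = pos,
                src = if (pos <= length(srcIds)) srcIds[pos] else padId,
                prev = prevIds, target = 1L)
  dirMat <- matrix(rep(dirIds, each = n), n, length(dirIds))
  forwardRows(model@params, dirMat, rows)$P
}

#' Per-step output distribution of the decoder
#'
#' @param model A [Seq2SeqModel-class].
#' @param labels Direction prompt (`<inc>`/`<dec>` per objective).
#' @param source Source sequence.
#' @param prefix Already-decoded target tokens (character vector; empty for
#'   the first step).
#' @return Named numeric vector over the vocabulary, summing to 1.
#' @export
decodeDistribution <- function(model, labels, source, prefix = character()) {
  checkPrompt(model, labels)
  dirIds <- tokenIds(model@vocab, labels)
  srcIds <- tokenIds(model@vocab, seqChars(source))
  prev <- if (length(prefix) == 0L) TOKEN_START else prefix[length(prefix)]
  p <- nextTokenProbs(model, dirIds, srcIds, length(prefix) + 1L,
                      tokenIds(model@vocab, prev))
  setNames(as.numeric(p[1L, ]), model@vocab@tokens)
}

checkPrompt <- function(model, labels) {
  if (length(labels) != model@nObjectives ||
      !all(labels %in% c(TOKEN_INC, TOKEN_DEC))) {
    stop(sprintf("prompt must be %d <inc>/<dec> token(s)",
                 model@nObjectives), call. = FALSE)
  }
}

#' Conditional log-probability of a target sequence
#'
#' Sum over target positions of per-token conditional log-probabilities
#' under teacher forcing; always <= 0.
#'
#' @param model A [Seq2SeqModel-class].
#' @param labels Direction prompt.
#' @param source,target Sequences.
#' @param includeStop Also score the terminating `</s>` step (default
#'   `FALSE`: exactly the residue positions are scored).
#' @return Scalar log-probability.
#' @export
sequenceLogprob <- function(model, labels, source, target,
                            includeStop = FALSE) {
  checkPrompt(model, labels)
  enc <- encodeExamples(model@vocab, matrix(labels, 1L), source, target)
  rows <- enc$rows
  if (!includeStop) rows <- rows[-nrow(rows), , drop = FALSE]
  fwd <- forwardRows(model@params, enc$dirIds, rows)
  sum(log(pmax(fwd$P[cbind(seq_len(nrow(rows)), rows[, "target"])],
               1e-300)))
}

#' Greedy decode from a seed sequence
#'
#' @param model A [Seq2SeqModel-class].
#' @param labels Direction prompt.
#' @param source Seed sequence.
#' @param maxSteps Maximum decode steps (default seed length + 2).
#' @return Character vector of emitted tokens (terminating `</s>` removed).
#' @export
decodeGreedy <- function(model, labels, source,
                         maxSteps = nchar(source) + 2L) {
  checkPrompt(model, labels)
  dirIds <- tokenIds(model@vocab, labels)
  srcIds <- tokenIds(model@vocab, seqChars(source))
  endId <- tokenIds(model@vocab, TOKEN_END)
  prev <- tokenIds(model@vocab, TOKEN_START)
  out <- integer()
  for (t in seq_len(min(maxSteps, model@config@maxLen))) {
    p <- nextTokenProbs(model, dirIds, srcIds, t, prev)
    nxt <- which.max(p[1L, ])
    if (nxt == endId) break
    out <- c(out, nxt)
    prev <- nxt
  }
  idTokens(model@vocab, out)
}

#' Top-k sampling from a seed sequence
#'
#' At each step the distribution is truncated to the k most probable
#' tokens, renormalized, and sampled. A sample that hits `maxSteps` without
#' emitting `</s>` is aborted (dropped) with a log entry attribute.
#'
#' @param model A [Seq2SeqModel-class].
#' @param labels Direction prompt.
#' @param source Seed sequence.
#' @param k Top-k cutoff.
#' @param nSamples Number of independent samples.
#' @param maxSteps Maximum decode steps per sample.
#' @param seed RNG seed.
#' @return List of token vectors (one per completed sample); attribute
#'   `aborted` counts over-length decodes.
#' @export
sampleTopK <- function(model, labels, source, k = 10L, nSamples = 20L,
                       maxSteps = nchar(source) + 2L, seed = 1L) {
  checkPrompt(model, labels)
  dirIds <- tokenIds(model@vocab, labels)
  srcIds <- tokenIds(model@vocab, seqChars(source))
  endId <- tokenIds(model@vocab, TOKEN_END)
  startId <- tokenIds(model@vocab, TOKEN_START)
  maxSteps <- min(maxSteps, model@config@maxLen)
  withSeed(seed, {
    prev <- rep(startId, nSamples)
    done <- logical(nSamples)
    toks <- vector("list", nSamples)
    for (t in seq_len(maxSteps)) {
      act <- which(!done)
      if (length(act) == 0L) break
      P <- nextTokenProbs(model, dirIds, srcIds, t, prev[act])
      for (i in seq_along(act)) {
        p <- P[i, ]
        topIdx <- order(p, decreasing = TRUE)[seq_len(min(k, length(p)))]
        pk <- p[topIdx] / sum(p[topIdx])
        nxt <- topIdx[sample.int(length(topIdx), 1L, prob = pk)]
        s <- act[i]
        if (nxt == endId) {
          done[s] <- TRUE
        } else {
          toks[[s]] <- c(toks[[s]], nxt)
          prev[s] <- nxt
        }
      }
    }
    aborted <- sum(!done)
    out <- lapply(which(done), function(s) idTokens(model@vocab, toks[[s]]))
    attr(out, "aborted") <- aborted
    out
  })
}

# ---- checkpointing ------------------------------------------------------

#' Save a model checkpoint
#'
#' Writes a versioned binary checkpoint plus a JSON sidecar (architecture,
#' vocabulary, config, seed, loss history). Reloading reproduces
#' log-probabilities bit-exactly.
#'
#' @param model A [Seq2SeqModel-class].
#' @param path Checkpoint file; the sidecar is written to `<path>.json`.
#' @export
saveModel <- function(model, path) {
  cfg <- model@config
  payload <- list(version = 1L, params = model@params,
                  tokens = model@vocab@tokens,
                  alphabet = model@vocab@alphabet,
                  nObjectives = model@nObjectives,
                  config = configAsList(cfg),
                  history = model@history)
  saveRDS(payload, path)
  sidecar <- list(format = "seqDirector-checkpoint", version = 1L,
                  architecture = list(backbone = cfg@backbone,
                                      embDim = cfg@embDim,
                                      hiddenDim = cfg@hiddenDim,
                                      maxLen = cfg@maxLen,
                                      vocabSize = vocabSize(model@vocab)),
                  vocabulary = model@vocab@tokens,
                  config = configAsList(cfg),
                  seed = cfg@seed,
                  lossHistory = model@history)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

configAsList <- function(cfg) {
  list(lr = cfg@lr, weightDecay = cfg@weightDecay,
       batchSize = cfg@batchSize, epochs = cfg@epochs, seed = cfg@seed,
       valFraction = cfg@valFraction, embDim = cfg@embDim,
       hiddenDim = cfg@hiddenDim, maxLen = cfg@maxLen,
       backbone = cfg@backbone, loraRank = cfg@loraRank,
       loraAlpha = cfg@loraAlpha, loraDropout = cfg@loraDropout,
       patience = cfg@patience)
}

configFromList <- function(x) {
  do.call(trainConfig, x)
}

#' Load a model checkpoint
#'
#' @param path File written by [saveModel()].
#' @return The reconstructed [Seq2SeqModel-class].
#' @export
loadModel <- function(path) {
  payload <- readRDS(path)
  if (!identical(payload$version, 1L)) {
    stop("unsupported checkpoint version", call. = FALSE)
  }
  vocab <- new("Vocabulary", tokens = payload$tokens,
               alphabet = payload$alphabet)
  new("Seq2SeqModel", vocab = vocab,
      nObjectives = as.integer(payload$nObjectives),
      params = payload$params, config = configFromList(payload$config),
      history = payload$history)
}

# ---- corpus validity (BLEU-style) --------------------------------------

ngramCounts <- function(tokens, n) {
  L <- length(tokens)
  if (L < n) return(integer(0))
  grams <- vapply(seq_len(L - n + 1L), function(i) {
    paste(tokens[i:(i + n - 1L)], collapse = "\r")
  }, character(1))
  table(grams)
}

#' Corpus validity score (BLEU-style n-gram overlap)
#'
#' Corpus-level modified n-gram precision (n up to 4) of generated
#' sequences against references, residues as tokens, with brevity penalty;
#' 100 for identical corpora. Used to monitor whether the model keeps
#' generating sequences consistent with the training distribution; it gates
#' nothing. Zero-count higher-order precisions are exponentially smoothed
#' (count replaced by 1/2^s with s doubling per zero order); a corpus with
#' no unigram overlap scores 0.
#'
#' @param generated Character vector of generated sequences.
#' @param references Character vector of reference sequences (same length,
#'   paired by position).
#' @param maxN Maximum n-gram order (default 4).
#' @return Score in `[0, 100]`.
#' @export
corpusValidityScore <- function(generated, references, maxN = 4L) {
  if (length(generated) == 0L || length(references) == 0L) {
    stop("empty corpus", call. = FALSE)
  }
  if (length(generated) != length(references)) {
    stop("generated and references must pair one-to-one", call. = FALSE)
  }
  hyp <- lapply(generated, seqChars)
  ref <- lapply(references, seqChars)
  matches <- numeric(maxN)
  totals <- numeric(maxN)
  for (n in seq_len(maxN)) {
    for (i in seq_along(hyp)) {
      hc <- ngramCounts(hyp[[i]], n)
      if (length(hc) == 0L) next
      rc <- ngramCounts(ref[[i]], n)
      shared <- intersect(names(hc), names(rc))
      matches[n] <- matches[n] + sum(pmin(hc[shared], rc[shared]))
      totals[n] <- totals[n] + sum(hc)
    }
  }
  use <- which(totals > 0)
  if (length(use) == 0L) return(0)
  if (matches[1L] == 0) return(0)
  smooth <- 1
  prec <- numeric(length(use))
  for (i in seq_along(use)) {
    n <- use[i]
    if (matches[n] > 0) {
      prec[i] <- matches[n] / totals[n]
    } else {
      smooth <- smooth * 2
      prec[i] <- 1 / (smooth * totals[n])
    }
  }
  hypLen <- sum(lengths(hyp))
  refLen <- sum(lengths(ref))
  bp <- if (hypLen >= refLen) 1 else exp(1 - refLen / hypLen)
  100 * bp * exp(mean(log(prec)))
}
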