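# S4 class definitions. Constructors with argument checking live next to the
# module code; validity methods here guard the invariants that must never be
# violated regardless of construction path.

TOKEN_INC <- "<inc>"
TOKEN_DEC <- "<dec>"
TOKEN_PAD <- "<pad>"
TOKEN_START <- "<s>"
TOKEN_END <- "</s>"
TOKEN_UNK <- "<unk>"

#' ObjectiveSpec: one screening objective
#'
#' Describes one objective of the multi-objective design problem: which
#' ligand it is measured under, which derived metric carries it
#' (wildtype-normalized fold change or dynamic range), and the experimental
#' noise threshold tau below which a change is not considered evidence.
#'
#' @slot name Short objective name (e.g. "Zn", "Pb").
#' @slot ligand Ligand column value in screen tables (e.g. "zinc", "lead").
#' @slot metric Metric selector: "norm_fc" or "norm_dr".
#' @slot tau Noise threshold on the metric scale; `NA` means estimate from
#'   wildtype replicate scatter (see [estimateNoiseThreshold()]).
#' @export
setClass("ObjectiveSpec",
  representation(name = "character", ligand = "character",
                 metric = "character", tau = "numeric"))

setValidity("ObjectiveSpec", function(object) {
  if (length(object@name) != 1L || !nzchar(object@name)) {
    return("'name' must be a single non-empty string")
  }
  if (!object@metric %in% c("norm_fc", "norm_dr")) {
    return("'metric' must be 'norm_fc' or 'norm_dr'")
  }
  if (length(object@tau) != 1L || (!is.na(object@tau) && object@tau < 0)) {
    return("'tau' must be a single value >= 0 (or NA to estimate)")
  }
  TRUE
})

#' DirectionalPairs: direction-labeled paired training data
#'
#' Ordered sequence pairs (source, target), each labeled per objective with a
#' `<inc>`/`<dec>` token recording the observed direction of change, retained
#' only when the measured change exceeds the per-objective noise threshold in
#' every objective.
#'
#' @slot source,target Character vectors of equal length: amino-acid
#'   sequences of each ordered pair.
#' @slot labels Character matrix (pairs x objectives) of `<inc>`/`<dec>`
#'   tokens.
#' @slot deltas Numeric matrix (pairs x objectives): metric differences
#'   f(target) - f(source).
#' @slot objectives Character vector of objective names (column order of
#'   `labels`/`deltas`).
#' @slot taus Numeric vector of the thresholds used at construction.
#' @slot nSource Number M of distinct source records the pairs were built
#'   from (the augmentation bound is choose(M, 2) per orientation).
#' @export
setClass("DirectionalPairs",
  representation(source = "character", target = "character",
                 labels = "matrix", deltas = "matrix",
                 objectives = "character", taus = "numeric",
                 nSource = "integer"))

setValidity("DirectionalPairs", function(object) {
  n <- length(object@source)
  j <- length(object@objectives)
  if (length(object@target) != n) return("source/target length mismatch")
  if (!identical(dim(object@labels), c(n, j)) && n > 0) {
    return("labels must be an n x j matrix")
  }
  if (!identical(dim(object@deltas), c(n, j)) && n > 0) {
    return("deltas must be an n x j matrix")
  }
  if (n > 0) {
    if (!all(object@labels %in% c(TOKEN_INC, TOKEN_DEC))) {
      return("labels must be <inc> or <dec>")
    }
    up <- object@labels == TOKEN_INC
    if (any(object@deltas[up] <= 0) || any(object@deltas[!up] >= 0)) {
      return("label tokens inconsistent with delta signs")
    }
    if (any(nchar(object@source) != nchar(object@target))) {
      return("paired sequences must have equal length")
    }
  }
  if (length(object@taus) != j) return("one tau per objective required")
  TRUE
})

#' Vocabulary: token inventory for the conditional model
#'
#' Dense, stable token ids: four control tokens (`<pad>`, `<s>`, `</s>`,
#' `<unk>`), the two direction tokens (`<inc>`, `<dec>`), then the residue
#' alphabet. Reduced alphabets are allowed for testing.
#'
#' @slot tokens All tokens; a token's id is its position in this vector.
#' @slot alphabet The residue alphabet.
#' @export
setClass("Vocabulary",
  representation(tokens = "character", alphabet = "character"))

setValidity("Vocabulary", function(object) {
  if (anyDuplicated(object@tokens)) return("duplicate tokens")
  if (anyDuplicated(object@alphabet)) return("duplicate alphabet letters")
  need <- c(TOKEN_PAD, TOKEN_START, TOKEN_END, TOKEN_UNK, TOKEN_INC, TOKEN_DEC)
  if (!all(need %in% object@tokens)) return("control/direction tokens missing")
  if (!all(object@alphabet %in% object@tokens)) {
    return("alphabet letters missing from tokens")
  }
  TRUE
})

#' TrainConfig: training hyper-parameters
#'
#' Optimizer settings follow decoupled-weight-decay Adam (AdamW) with the
#' defaults learning rate 1e-4 and weight decay 1e-4. The backbone selector
#' chooses between the built-in trainable model ("tiny") and a user-supplied
#' pretrained-backbone adapter ("pretrained-adapter"); low-rank-adapter
#' settings (rank 16, scaling 32, dropout 0.05) are configuration passed to
#' the adapter and are ignored, with a notice, by the tiny backbone, which is
#' fully trained.
#'
#' @slot lr,weightDecay AdamW learning rate and decoupled weight decay.
#' @slot batchSize,epochs Minibatch size and number of passes.
#' @slot seed Integer seed controlling init, shuffling and the split.
#' @slot valFraction Fraction of unordered pairs held out for validation
#'   (both orientations of a pair land on the same side).
#' @slot embDim,hiddenDim Embedding and hidden width of the tiny backbone.
#' @slot maxLen Maximum supported decode length (positional table size).
#' @slot backbone "tiny" or "pretrained-adapter".
#' @slot loraRank,loraAlpha,loraDropout Low-rank adapter settings for the
#'   pretrained path.
#' @slot patience Early-stop patience on validation loss; `NA` disables
#'   early stopping (the default; the validity score is monitoring-only).
#' @export
setClass("TrainConfig",
  representation(lr = "numeric", weightDecay = "numeric",
                 batchSize = "integer", epochs = "integer",
                 seed = "integer", valFraction = "numeric",
                 embDim = "integer", hiddenDim = "integer",
                 maxLen = "integer", backbone = "character",
                 loraRank = "integer", loraAlpha = "numeric",
                 loraDropout = "numeric", patience = "integer"))

setValidity("TrainConfig", function(object) {
  if (object@lr <= 0 || object@weightDecay < 0) {
    return("lr must be > 0 and weightDecay >= 0")
  }
  if (object@batchSize < 1L || object@epochs < 0L) {
    return("batchSize >= 1 and epochs >= 0 required")
  }
  if (object@valFraction < 0 || object@valFraction >= 1) {
    return("valFraction must be in [0, 1)")
  }
  if (!object@backbone %in% c("tiny", "pretrained-adapter")) {
    return("backbone must be 'tiny' or 'pretrained-adapter'")
  }
  TRUE
})

#' Seq2SeqModel: conditional encoder-decoder over residue + direction tokens
#'
#' Models P(target | direction labels, source) autoregressively: at each
#' decoding step the model emits a full probability distribution over the
#' vocabulary conditioned on the direction tokens, the position-aligned
#' source residue, the position, and the previously emitted target token.
#' Training maximizes conditional log-likelihood (token-level cross-entropy).
#'
#' @slot vocab A [Vocabulary-class].
#' @slot nObjectives Number of direction tokens expected in a prompt.
#' @slot params Named list of parameter matrices (embeddings, positional
#'   table, hidden and output layers).
#' @slot config The [TrainConfig-class] used (or to be used) for training.
#' @slot history Per-epoch data.frame: epoch, trainLoss, valLoss, validity.
#' @export
setClass("Seq2SeqModel",
  representation(vocab = "Vocabulary", nObjectives = "integer",
                 params = "list", config = "TrainConfig",
                 history = "data.frame"))

#' GenerationConfig: single-step candidate generation settings
#'
#' Defaults follow the campaign's generation recipe: top-k sampling with
#' k = 10, 20 candidates per seed, mutants up to 6th order, and a library
#' capacity of 382 (a 384-well plate with wells left open for controls).
#'
#' @slot directions Direction prompt, one `<inc>`/`<dec>` token per
#'   objective in objective order.
#' @slot topK Top-k truncation for sampling.
#' @slot candidatesPerSeed Samples drawn per seed sequence.
#' @slot maxOrder Maximum number of substitutions relative to wildtype.
#' @slot capacity Maximum library size after filtering.
#' @slot seed RNG seed for sampling.
#' @slot exclude Mutant ids never to propose again (previously screened).
#' @export
setClass("GenerationConfig",
  representation(directions = "character", topK = "integer",
                 candidatesPerSeed = "integer", maxOrder = "integer",
                 capacity = "integer", seed = "integer",
                 exclude = "character"))

setValidity("GenerationConfig", function(object) {
  if (object@topK < 1L) return("topK must be >= 1")
  if (object@capacity < 1L) return("capacity must be >= 1")
  if (object@maxOrder < 1L) return("maxOrder must be >= 1")
  if (object@candidatesPerSeed < 1L) return("candidatesPerSeed must be >= 1")
  if (!all(object@directions %in% c(TOKEN_INC, TOKEN_DEC))) {
    return("directions must be <inc>/<dec> tokens")
  }
  TRUE
})

#' LandscapeSpec: synthetic two-objective fitness landscape
#'
#' Ground-truth genotype-to-response map used to emulate the three-condition
#' plate screen (no ligand / lead / zinc). Per-mutation effects act
#' additively on log-signal (so fold change composes multiplicatively),
#' optional pairwise epistasis terms act on log-signal too, and measurement
#' noise is multiplicative lognormal plus an additive floor.
#'
#' @slot wildtype Wildtype sequence over `alphabet`.
#' @slot alphabet Residue alphabet (reduced alphabets allowed).
#' @slot effects Named list of L x |alphabet| matrices ("none", "lead",
#'   "zinc"): additive log-signal effect of placing a residue at a position
#'   (wildtype residues have effect 0).
#' @slot epistasis data.frame(condition, pos1, alt1, pos2, alt2, effect) of
#'   pairwise log-signal interaction terms (may have zero rows).
#' @slot baselines Named numeric: noiseless wildtype signal per condition.
#' @slot sigmaM Multiplicative noise sd on the log scale (lognormal sdlog).
#' @slot sigmaA Additive noise sd in signal units.
#' @slot replicates Replicates per mutant x condition (default 3).
#' @export
setClass("LandscapeSpec",
  representation(wildtype = "character", alphabet = "character",
                 effects = "list", epistasis = "data.frame",
                 baselines = "numeric", sigmaM = "numeric",
                 sigmaA = "numeric", replicates = "integer"))

setValidity("LandscapeSpec", function(object) {
  L <- nchar(object@wildtype)
  if (!all(seqChars(object@wildtype) %in% object@alphabet)) {
    return("wildtype contains letters outside the alphabet")
  }
  if (!all(c("none", "lead", "zinc") %in% names(object@effects))) {
    return("effects must have 'none', 'lead' and 'zinc' entries")
  }
  for (nm in names(object@effects)) {
    m <- object@effects[[nm]]
    if (!is.matrix(m) || nrow(m) != L || ncol(m) != length(object@alphabet)) {
      return("each effect table must be a L x |alphabet| matrix")
    }
    if (!all(is.finite(m))) return("effect tables must be finite")
  }
  if (!all(c("none", "lead", "zinc") %in% names(object@baselines))) {
    return("baselines must name 'none', 'lead' and 'zinc'")
  }
  if (any(object@baselines <= 0)) return("baselines must be > 0")
  if (object@sigmaM < 0 || object@sigmaA < 0) {
    return("noise parameters must be >= 0")
  }
  if (object@replicates < 1L) return("replicates must be >= 1")
  TRUE
})
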