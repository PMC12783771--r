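# Synthetic two-objective fitness landscape. Per-mutation effects act
# additively on log-signal per screening condition, so fold change composes
# multiplicatively and the ground truth stays analytically checkable. The
# simulator emits screen tables in the same CSV schema as real data, so
# every downstream stage is format-identical to a wet-lab campaign.

#' Construct a LandscapeSpec
#'
#' @param wildtype Wildtype sequence over `alphabet`.
#' @param alphabet Residue alphabet.
#' @param effects Named list ("none", "lead", "zinc") of L x |alphabet|
#'   log-signal effect matrices; wildtype residues are forced to effect 0.
#' @param epistasis data.frame(condition, pos1, alt1, pos2, alt2, effect);
#'   default none.
#' @param baselines Named numeric wildtype signals, e.g.
#'   `c(none = 100, lead = 120, zinc = 800)`.
#' @param sigmaM Multiplicative lognormal noise sd (log scale).
#' @param sigmaA Additive noise sd (signal units).
#' @param replicates Replicates per condition (default 3, the screening
#'   assay's biological triplicate).
#' @return A [LandscapeSpec-class].
#' @export
landscapeSpec <- function(wildtype, alphabet, effects, epistasis = NULL,
                          baselines = c(none = 100, lead = 120, zinc = 800),
                          sigmaM = 0.1, sigmaA = 1, replicates = 3L) {
  if (is.null(epistasis)) {
    epistasis <- data.frame(condition = character(), pos1 = integer(),
                            alt1 = character(), pos2 = integer(),
                            alt2 = character(), effect = numeric(),
                            stringsAsFactors = FALSE)
  }
  wtChars <- seqChars(wildtype)
  for (nm in names(effects)) {
    m <- effects[[nm]]
    colnames(m) <- alphabet
    m[cbind(seq_along(wtChars), match(wtChars, alphabet))] <- 0
    effects[[nm]] <- m
  }
  new("LandscapeSpec", wildtype = wildtype,
      alphabet = as.character(alphabet), effects = effects,
      epistasis = epistasis, baselines = baselines, sigmaM = sigmaM,
      sigmaA = sigmaA, replicates = as.integer(replicates))
}

setMethod("show", "LandscapeSpec", function(object) {
  cat(sprintf("LandscapeSpec: length %d over %d-letter alphabet\n",
              nchar(object@wildtype), length(object@alphabet)))
  cat(sprintf("baselines: none=%g lead=%g zinc=%g; noise sigmaM=%g sigmaA=%g; n=%d replicates\n",
              object@baselines["none"], object@baselines["lead"],
              object@baselines["zinc"], object@sigmaM, object@sigmaA,
              object@replicates))
  cat(sprintf("epistasis terms: %d\n", nrow(object@epistasis)))
})

landscapeConditions <- function() {
  data.frame(ligand = c("none", "lead", "zinc"),
             concentration_uM = c(0, 1, 30), stringsAsFactors = FALSE)
}

# Noiseless per-condition signals for a set of mutant ids.
groundTruthSignals <- function(landscape, ids) {
  conds <- c("none", "lead", "zinc")
  out <- matrix(NA_real_, length(ids), 3L,
                dimnames = list(ids, conds))
  for (i in seq_along(ids)) {
    subs <- parseMutantId(ids[i], alphabet = landscape@alphabet)
    for (cn in conds) {
      logSig <- log(landscape@baselines[[cn]])
      if (nrow(subs) > 0L) {
        altIdx <- match(subs$alt, landscape@alphabet)
        logSig <- logSig + sum(landscape@effects[[cn]][cbind(subs$pos,
                                                             altIdx)])
        epi <- landscape@epistasis
        epi <- epi[epi$condition == cn, , drop = FALSE]
        if (nrow(epi) > 0L && nrow(subs) > 1L) {
          present <- paste(subs$pos, subs$alt, sep = ":")
          hit <- paste(epi$pos1, epi$alt1, sep = ":") %in% present &
            paste(epi$pos2, epi$alt2, sep = ":") %in% present
          logSig <- logSig + sum(epi$effect[hit])
        }
      }
      out[i, cn] <- exp(logSig)
    }
  }
  out
}

#' Ground-truth objective table for mutants on a landscape
#'
#' Noiseless signals per condition, FC and DR against the noiseless leak,
#' wildtype-normalized values, and the selectivity flag (normalized FC to
#' lead > 1 and to zinc < 1).
#'
#' @param landscape A [LandscapeSpec-class].
#' @param ids Mutant ids (or `"WT"`).
#' @return data.frame, one row per id.
#' @export
groundTruthTable <- function(landscape, ids) {
  sig <- groundTruthSignals(landscape, ids)
  wt <- groundTruthSignals(landscape, "WT")[1L, ]
  fcPb <- sig[, "lead"] / sig[, "none"]
  fcZn <- sig[, "zinc"] / sig[, "none"]
  wtFcPb <- wt["lead"] / wt["none"]
  wtFcZn <- wt["zinc"] / wt["none"]
  drPb <- sig[, "lead"] - sig[, "none"]
  drZn <- sig[, "zinc"] - sig[, "none"]
  data.frame(
    mutant_id = ids,
    signal_none = sig[, "none"], signal_lead = sig[, "lead"],
    signal_zinc = sig[, "zinc"],
    fc_lead = fcPb, fc_zinc = fcZn,
    norm_fc_pb = fcPb / wtFcPb, norm_fc_zn = fcZn / wtFcZn,
    norm_dr_pb = drPb / (wt["lead"] - wt["none"]),
    norm_dr_zn = drZn / (wt["zinc"] - wt["none"]),
    selective = (fcPb / wtFcPb) > 1 & (fcZn / wtFcZn) < 1,
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Ground-truth response of one sequence or mutant id
#'
#' @param landscape A [LandscapeSpec-class].
#' @param sequence Full-length sequence (alternative to `id`).
#' @param id Mutant id (alternative to `sequence`).
#' @return List: `signals` (noiseless per condition), `objectives`
#'   (normalized FC to zinc and lead, objective order `[Zn, Pb]`), and the
#'   full ground-truth row.
#' @export
groundTruthResponse <- function(landscape, sequence = NULL, id = NULL) {
  if (is.null(id)) {
    if (is.null(sequence)) stop("give 'sequence' or 'id'", call. = FALSE)
    if (nchar(sequence) != nchar(landscape@wildtype)) {
      stop("sequence length does not match the landscape wildtype",
           call. = FALSE)
    }
    id <- sequenceToId(landscape@wildtype, sequence)
  }
  row <- groundTruthTable(landscape, id)
  list(signals = unlist(row[1L, c("signal_none", "signal_lead",
                                  "signal_zinc")]),
       objectives = c(Zn = row$norm_fc_zn[1L], Pb = row$norm_fc_pb[1L]),
       table = row)
}

#' Simulate the three-condition plate screen
#'
#' Each mutant is measured under no ligand, low lead (1 uM) and high zinc
#' (30 uM) in `replicates` replicates; each replicate signal is the
#' noiseless value times lognormal multiplicative noise plus additive
#' Gaussian noise, floored at zero. The wildtype is always included (the
#' batch normalization reference).
#'
#' @param landscape A [LandscapeSpec-class].
#' @param ids Mutant ids to screen.
#' @param seed RNG seed (same seed, same table).
#' @param batch Batch label for all rows.
#' @return data.frame in the screen CSV schema (`mutant_id`, `batch`,
#'   `ligand`, `concentration_uM`, `replicate`, `signal`).
#' @export
simulateScreen <- function(landscape, ids, seed = 1L, batch = "batch1") {
  ids <- unique(c("WT", ids))
  sig <- groundTruthSignals(landscape, ids)
  conds <- landscapeConditions()
  nrep <- landscape@replicates
  grid <- expand.grid(replicate = seq_len(nrep),
                      ligand = conds$ligand, mutant_id = ids,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$concentration_uM <- conds$concentration_uM[match(grid$ligand,
                                                        conds$ligand)]
  noiseless <- sig[cbind(match(grid$mutant_id, ids),
                         match(grid$ligand, colnames(sig)))]
  signal <- withSeed(seed, {
    n <- nrow(grid)
    pmax(noiseless * rlnorm(n, 0, landscape@sigmaM) +
           rnorm(n, 0, landscape@sigmaA), 0)
  })
  data.frame(mutant_id = grid$mutant_id, batch = batch,
             ligand = grid$ligand,
             concentration_uM = grid$concentration_uM,
             replicate = grid$replicate, signal = signal,
             stringsAsFactors = FALSE)
}

#' Draw random mutants from a landscape
#'
#' Uniform over positions and non-wildtype alternatives; used as the
#' matched random baseline when measuring design enrichment.
#'
#' @param landscape A [LandscapeSpec-class].
#' @param n Number of mutants.
#' @param orders Mutation order per mutant (recycled to length `n`).
#' @param seed RNG seed.
#' @return Character vector of mutant ids.
#' @export
randomMutants <- function(landscape, n, orders = 2L, seed = 1L) {
  orders <- rep_len(orders, n)
  wtChars <- seqChars(landscape@wildtype)
  L <- length(wtChars)
  withSeed(seed, {
    vapply(seq_len(n), function(i) {
      pos <- sort(sample.int(L, orders[i]))
      alt <- vapply(pos, function(p) {
        sample(setdiff(landscape@alphabet, wtChars[p]), 1L)
      }, character(1))
      mutantId(data.frame(wt = wtChars[pos], pos = pos, alt = alt,
                          stringsAsFactors = FALSE))
    }, character(1))
  })
}

# ---- presets ------------------------------------------------------------

toyAlphabet <- function() c("A", "C", "D", "E", "F", "G", "H", "K")

toyWildtype <- function() "ACDEFGHKACDEFGHKACDE"

#' Toy-grammar landscape (deterministic conditioning testbed)
#'
#' An 8-letter, length-20 landscape in which the lead objective is
#' controlled entirely by the residue at position 6 through a strictly
#' monotone effect ladder, and the zinc objective by position 13. The
#' "grammar" a conditional model must learn is therefore exact: under the
#' `<dec> <inc>` prompt (zinc down, lead up), move position 6 up its ladder
#' and position 13 down, and copy everything else. Noise-free.
#'
#' @return A [LandscapeSpec-class].
#' @seealso [grammarGenotypes()]
#' @export
toyGrammarLandscape <- function() {
  alpha <- toyAlphabet()
  wt <- toyWildtype()
  L <- nchar(wt)
  zero <- matrix(0, L, length(alpha))
  lead <- zero
  zinc <- zero
  # ladders: effect strictly increasing in alphabet index
  lead[6L, ] <- 0.45 * (seq_along(alpha) - match("G", alpha))
  zinc[13L, ] <- 0.40 * (seq_along(alpha) - match("F", alpha))
  landscapeSpec(wt, alpha,
                effects = list(none = zero, lead = lead, zinc = zinc),
                baselines = c(none = 100, lead = 250, zinc = 600),
                sigmaM = 0, sigmaA = 0, replicates = 3L)
}

#' All genotypes of the toy grammar
#'
#' The 64 mutants (including wildtype) obtained by setting positions 6 and
#' 13 to every alphabet letter.
#'
#' @return Character vector of 64 mutant ids.
#' @export
grammarGenotypes <- function() {
  alpha <- toyAlphabet()
  wtChars <- seqChars(toyWildtype())
  ids <- character()
  for (r6 in alpha) {
    for (r13 in alpha) {
      subs <- emptySubstitutions()
      if (r6 != wtChars[6L]) {
        subs <- rbind(subs, data.frame(wt = wtChars[6L], pos = 6L,
                                       alt = r6))
      }
      if (r13 != wtChars[13L]) {
        subs <- rbind(subs, data.frame(wt = wtChars[13L], pos = 13L,
                                       alt = r13))
      }
      ids <- c(ids, mutantId(subs))
    }
  }
  ids
}

#' Toy campaign landscape (hidden selective mutations)
#'
#' An 8-letter, length-20 landscape mimicking the campaign's starting
#' phenotype: low lead response (wildtype lead FC 1.2) and strong zinc
#' response (wildtype zinc FC 8), so "increase lead / decrease zinc" is the
#' nontrivial direction. Of the 140 possible point substitutions, 6 are
#' selective (lead up, zinc down, log-effect +/-0.95), 30 are deleterious
#' for both objectives, 20 increase both, and the remaining 84 are neutral.
#' The category layout is fixed (internal constant seed), so the landscape
#' is the same object in every session. Measurement noise: sigmaM = 0.1,
#' sigmaA = 1 (1% of leak), triplicate.
#'
#' @param withEpistasis Add two pairwise log-signal terms between selective
#'   sites (off by default; the default landscape is purely additive).
#' @return A [LandscapeSpec-class].
#' @export
toyCampaignLandscape <- function(withEpistasis = FALSE) {
  alpha <- toyAlphabet()
  wt <- toyWildtype()
  wtChars <- seqChars(wt)
  L <- nchar(wt)
  zero <- matrix(0, L, length(alpha))
  lead <- zero
  zinc <- zero
  selective <- data.frame(
    pos = c(2L, 5L, 8L, 11L, 14L, 18L),
    alt = c("A", "A", "A", "A", "A", "G"), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(selective))) {
    p <- selective$pos[i]
    a <- match(selective$alt[i], alpha)
    lead[p, a] <- 0.95
    zinc[p, a] <- -0.95
  }
  # remaining non-wildtype cells, deterministic category layout
  cells <- expand.grid(pos = seq_len(L), altIdx = seq_along(alpha),
                       KEEP.OUT.ATTRS = FALSE)
  cells <- cells[wtChars[cells$pos] != alpha[cells$altIdx], , drop = FALSE]
  selKey <- paste(selective$pos, selective$alt)
  cells <- cells[!(paste(cells$pos, alpha[cells$altIdx]) %in% selKey), ,
                 drop = FALSE]
  cats <- withSeed(913217L, {
    sample(rep(c("del", "up", "neutral"),
               c(30L, 20L, nrow(cells) - 50L)))
  })
  for (i in seq_len(nrow(cells))) {
    p <- cells$pos[i]; a <- cells$altIdx[i]
    if (cats[i] == "del") {
      lead[p, a] <- -2; zinc[p, a] <- -2
    } else if (cats[i] == "up") {
      lead[p, a] <- 0.8; zinc[p, a] <- 0.8
    }
  }
  epi <- NULL
  if (withEpistasis) {
    epi <- data.frame(
      condition = c("lead", "lead"),
      pos1 = c(2L, 8L), alt1 = c("A", "A"),
      pos2 = c(5L, 11L), alt2 = c("A", "A"),
      effect = c(0.2, -0.3), stringsAsFactors = FALSE)
  }
  landscapeSpec(wt, alpha,
                effects = list(none = zero, lead = lead, zinc = zinc),
                epistasis = epi,
                baselines = c(none = 100, lead = 120, zinc = 800),
                sigmaM = 0.1, sigmaA = 1, replicates = 3L)
}

#' The selective substitutions hidden in the toy campaign landscape
#'
#' @return data.frame(pos, alt) of the ground-truth "lead up / zinc down"
#'   substitutions.
#' @export
toyCampaignSelectiveSites <- function() {
  data.frame(pos = c(2L, 5L, 8L, 11L, 14L, 18L),
             alt = c("A", "A", "A", "A", "A", "G"),
             stringsAsFactors = FALSE)
}

#' All single mutants of a landscape
#'
#' @param landscape A [LandscapeSpec-class].
#' @return Character vector of all L x (|alphabet| - 1) single-mutant ids.
#' @export
allSingleMutants <- function(landscape) {
  wtChars <- seqChars(landscape@wildtype)
  ids <- character()
  for (p in seq_along(wtChars)) {
    for (a in setdiff(landscape@alphabet, wtChars[p])) {
      ids <- c(ids, paste0(wtChars[p], p, a))
    }
  }
  ids
}

#' Serialize a landscape to YAML
#'
#' @param landscape A [LandscapeSpec-class].
#' @param path Output file.
#' @export
writeLandscapeYaml <- function(landscape, path) {
  obj <- list(
    wildtype = landscape@wildtype,
    alphabet = landscape@alphabet,
    effects = lapply(landscape@effects, function(m) {
      lapply(seq_len(nrow(m)), function(i) as.numeric(m[i, ]))
    }),
    epistasis = if (nrow(landscape@epistasis) > 0L) {
      lapply(seq_len(nrow(landscape@epistasis)), function(i) {
        as.list(landscape@epistasis[i, ])
      })
    } else list(),
    baselines = as.list(landscape@baselines),
    sigmaM = landscape@sigmaM, sigmaA = landscape@sigmaA,
    replicates = landscape@replicates)
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' Read a landscape from YAML
#'
#' @param path File written by [writeLandscapeYaml()].
#' @return A [LandscapeSpec-class].
#' @export
readLandscapeYaml <- function(path) {
  obj <- yaml::read_yaml(path)
  effects <- lapply(obj$effects, function(rows) {
    do.call(rbind, lapply(rows, as.numeric))
  })
  epi <- NULL
  if (length(obj$epistasis) > 0L) {
    epi <- do.call(rbind, lapply(obj$epistasis, function(e) {
      data.frame(condition = e$condition, pos1 = as.integer(e$pos1),
                 alt1 = e$alt1, pos2 = as.integer(e$pos2), alt2 = e$alt2,
                 effect = as.numeric(e$effect), stringsAsFactors = FALSE)
    }))
  }
  landscapeSpec(obj$wildtype, unlist(obj$alphabet), effects, epi,
                baselines = unlist(obj$baselines), sigmaM = obj$sigmaM,
                sigmaA = obj$sigmaA, replicates = obj$replicates)
}
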