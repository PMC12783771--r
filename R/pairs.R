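# Directional paired training data. From M measured variants, up to
# choose(M, 2) unordered pairs can be formed (twice that with both
# orientations), each labeled per objective with <inc>/<dec> according to
# the sign of the metric change - but only when the change clears the
# experimental noise threshold tau in every objective. Labels, not the
# numeric values, are what the model sees.

#' Construct an ObjectiveSpec
#'
#' @param name Objective name (e.g. "Zn").
#' @param ligand Ligand column value in screen tables.
#' @param metric "norm_fc" or "norm_dr".
#' @param tau Noise threshold on the metric scale; `NA` to estimate later.
#' @return An [ObjectiveSpec-class].
#' @export
objectiveSpec <- function(name, ligand, metric = "norm_fc", tau = NA_real_) {
  new("ObjectiveSpec", name = name, ligand = ligand, metric = metric,
      tau = as.numeric(tau))
}

#' Default objective pair: zinc then lead
#'
#' The campaign's objective vector is `[f_Zn, f_Pb]`; label tuples follow
#' this order, so the selective design prompt is `<dec> <inc>` (decrease
#' zinc response, increase lead response).
#'
#' @param metric Metric selector applied to both objectives.
#' @param tauZn,tauPb Per-objective thresholds (`NA` = estimate).
#' @return List of two [ObjectiveSpec-class] objects.
#' @export
defaultObjectives <- function(metric = "norm_fc", tauZn = NA_real_,
                              tauPb = NA_real_) {
  list(objectiveSpec("Zn", "zinc", metric, tauZn),
       objectiveSpec("Pb", "lead", metric, tauPb))
}

#' Number of directional label categories
#'
#' @param j Number of objectives (>= 1).
#' @return `2^j`, the number of possible `<inc>`/`<dec>` label tuples.
#' @export
#' @examples
#' categoryCount(2)  # four directional categories
categoryCount <- function(j) {
  if (!is.numeric(j) || length(j) != 1L || j < 1 || j != round(j)) {
    stop("'j' must be a positive integer", call. = FALSE)
  }
  as.integer(2^j)
}

#' Assign a directional label to a metric delta vector
#'
#' Three-way rule per objective: `<inc>` when the change exceeds tau,
#' `<dec>` when it falls below -tau; if any objective's change is within
#' the noise band the pair carries no evidence-backed label and is excluded.
#'
#' @param delta Numeric vector of per-objective metric differences
#'   f(target) - f(source).
#' @param taus Numeric vector of per-objective thresholds (same length).
#' @return Character vector of `<inc>`/`<dec>` tokens, or `NULL` when the
#'   pair is excluded.
#' @export
#' @examples
#' assignDirection(c(0.5, -0.5), c(0.1, 0.1))
assignDirection <- function(delta, taus) {
  if (length(delta) != length(taus)) {
    stop("delta and taus must have the same length", call. = FALSE)
  }
  if (any(abs(delta) <= taus)) return(NULL)
  ifelse(delta > 0, TOKEN_INC, TOKEN_DEC)
}

labelKey <- function(labels) {
  # "inc/dec"-style category key for a label matrix row or vector
  if (is.matrix(labels)) {
    apply(labels, 1L, function(r) paste(gsub("[<>]", "", r), collapse = "/"))
  } else {
    paste(gsub("[<>]", "", labels), collapse = "/")
  }
}

allCategoryKeys <- function(j) {
  grids <- expand.grid(rep(list(c("inc", "dec")), j), KEEP.OUT.ATTRS = FALSE)
  grids <- grids[, rev(seq_len(j)), drop = FALSE]
  sort(apply(grids, 1L, paste, collapse = "/"))
}

newDirectionalPairs <- function(source, target, labels, deltas, objectives,
                                taus, nSource) {
  j <- length(objectives)
  if (length(source) == 0L) {
    labels <- matrix(character(), 0L, j, dimnames = list(NULL, objectives))
    deltas <- matrix(numeric(), 0L, j, dimnames = list(NULL, objectives))
  } else {
    colnames(labels) <- objectives
    colnames(deltas) <- objectives
  }
  new("DirectionalPairs", source = source, target = target, labels = labels,
      deltas = deltas, objectives = objectives, taus = as.numeric(taus),
      nSource = as.integer(nSource))
}

#' Build the direction-labeled paired dataset
#'
#' Enumerates all unordered pairs of records, collapses duplicate sequences
#' to their mean metrics first (preventing zero-edit pairs), labels each
#' pair with [assignDirection()], and optionally adds the reversed
#' orientation with every token flipped.
#'
#' @param sequences Character vector of M variant sequences (equal length).
#' @param metrics Numeric matrix (M x j) of per-objective metric values,
#'   columns in objective order.
#' @param objectives List of [ObjectiveSpec-class]; their `tau` slots must
#'   be set (use [estimateNoiseThreshold()] first if needed).
#' @param bothOrientations Include the reversed pair with flipped labels
#'   (default `TRUE`).
#' @return A [DirectionalPairs-class]. With fewer than 2 distinct records an
#'   empty dataset is returned with a warning.
#' @export
buildPairedDataset <- function(sequences, metrics, objectives,
                               bothOrientations = TRUE) {
  metrics <- as.matrix(metrics)
  j <- length(objectives)
  stopifnot(nrow(metrics) == length(sequences), ncol(metrics) == j)
  taus <- vapply(objectives, function(o) o@tau, numeric(1))
  if (any(is.na(taus))) {
    stop("objective tau values must be set before pairing", call. = FALSE)
  }
  objNames <- vapply(objectives, function(o) o@name, character(1))
  if (any(!is.finite(metrics))) {
    stop("metrics must be defined (finite) for all records and objectives",
         call. = FALSE)
  }
  # Collapse duplicate sequences to mean metrics.
  if (anyDuplicated(sequences)) {
    uniq <- unique(sequences)
    metrics <- t(vapply(uniq, function(s) {
      colMeans(metrics[sequences == s, , drop = FALSE])
    }, numeric(j)))
    sequences <- uniq
  }
  M <- length(sequences)
  if (M < 2L) {
    warning("fewer than 2 distinct records: empty paired dataset",
            call. = FALSE)
    return(newDirectionalPairs(character(), character(),
                               matrix(character(), 0, j),
                               matrix(numeric(), 0, j),
                               objNames, taus, M))
  }
  if (length(unique(nchar(sequences))) != 1L) {
    stop("all sequences must have equal length", call. = FALSE)
  }
  idx <- combn(M, 2L)
  i1 <- idx[1L, ]
  i2 <- idx[2L, ]
  delta <- metrics[i2, , drop = FALSE] - metrics[i1, , drop = FALSE]
  confident <- rowSums(abs(delta) > rep(taus, each = nrow(delta))) == j
  i1 <- i1[confident]; i2 <- i2[confident]
  delta <- delta[confident, , drop = FALSE]
  labels <- ifelse(delta > 0, TOKEN_INC, TOKEN_DEC)
  if (!is.matrix(labels)) labels <- matrix(labels, ncol = j)
  src <- sequences[i1]
  tgt <- sequences[i2]
  if (bothOrientations) {
    flip <- ifelse(labels == TOKEN_INC, TOKEN_DEC, TOKEN_INC)
    if (!is.matrix(flip)) flip <- matrix(flip, ncol = j)
    src <- c(src, tgt)
    tgt <- c(tgt, sequences[i1])
    labels <- rbind(labels, flip)
    delta <- rbind(delta, -delta)
  }
  newDirectionalPairs(src, tgt, labels, delta, objNames, taus, M)
}

#' @describeIn DirectionalPairs-class Number of retained pairs.
#' @param object,x A `DirectionalPairs` object.
#' @export
pairCount <- function(x) length(x@source)

#' Category counts of a paired dataset
#'
#' @param x A [DirectionalPairs-class].
#' @return Named integer vector over all `2^j` label tuples (zero for
#'   categories with no pairs).
#' @export
categoryCounts <- function(x) {
  keys <- allCategoryKeys(length(x@objectives))
  counts <- setNames(integer(length(keys)), keys)
  if (pairCount(x) > 0L) {
    tab <- table(labelKey(x@labels))
    counts[names(tab)] <- as.integer(tab)
  }
  counts
}

setMethod("show", "DirectionalPairs", function(object) {
  cat(sprintf("DirectionalPairs: %d pair(s) from %d source record(s)\n",
              pairCount(object), object@nSource))
  cat(sprintf("objectives: %s (tau = %s)\n",
              paste(object@objectives, collapse = ", "),
              paste(signif(object@taus, 3), collapse = ", ")))
  cc <- categoryCounts(object)
  cat("categories:", paste(sprintf("%s=%d", names(cc), cc), collapse = "  "),
      "\n")
})

#' Balance directional categories by downsampling
#'
#' Each non-empty category is downsampled without replacement to the size of
#' the smallest non-empty category (optionally capped), giving approximate
#' balance across all `2^j` label combinations. Empty categories are
#' reported with a warning, never fabricated. Retained pairs keep their
#' original order.
#'
#' @param x A [DirectionalPairs-class].
#' @param seed RNG seed for the downsampling.
#' @param maxPerCategory Optional cap on the per-category size.
#' @return A balanced [DirectionalPairs-class] (subset of the input).
#' @export
balanceCategories <- function(x, seed = 1L, maxPerCategory = Inf) {
  if (pairCount(x) == 0L) return(x)
  keys <- labelKey(x@labels)
  counts <- table(keys)
  allKeys <- allCategoryKeys(length(x@objectives))
  missing <- setdiff(allKeys, names(counts))
  if (length(missing) > 0L) {
    warning(sprintf("empty directional categor%s: %s",
                    if (length(missing) > 1L) "ies" else "y",
                    paste(missing, collapse = ", ")), call. = FALSE)
  }
  target <- min(min(counts), maxPerCategory)
  keep <- withSeed(seed, {
    unlist(lapply(names(counts), function(k) {
      ii <- which(keys == k)
      if (length(ii) > target) sort(sample(ii, target)) else ii
    }))
  })
  keep <- sort(keep)
  newDirectionalPairs(x@source[keep], x@target[keep],
                      x@labels[keep, , drop = FALSE],
                      x@deltas[keep, , drop = FALSE],
                      x@objectives, x@taus, x@nSource)
}

#' Encode a directional pair as token sequences
#'
#' Source tokens are the direction tokens (objective order) followed by the
#' source residues; target tokens are the target residues.
#'
#' @param source,target Sequences of the pair.
#' @param labels Character vector of `<inc>`/`<dec>` tokens (one per
#'   objective).
#' @return List with `source` and `target` token vectors.
#' @seealso [decodeTrainingExample()]
#' @export
encodeTrainingExample <- function(source, target, labels) {
  if (!all(labels %in% c(TOKEN_INC, TOKEN_DEC))) {
    stop("labels must be <inc>/<dec> tokens", call. = FALSE)
  }
  list(source = c(labels, seqChars(source)), target = seqChars(target))
}

#' Decode token sequences back to a directional pair
#'
#' @param encoded List as returned by [encodeTrainingExample()].
#' @return List with `source`, `target` (strings) and `labels`.
#' @export
decodeTrainingExample <- function(encoded) {
  src <- encoded$source
  isDir <- src %in% c(TOKEN_INC, TOKEN_DEC)
  nDir <- if (any(!isDir)) which(!isDir)[1L] - 1L else length(src)
  list(source = paste(src[-seq_len(nDir)], collapse = ""),
       target = paste(encoded$target, collapse = ""),
       labels = src[seq_len(nDir)])
}

#' Write a paired dataset as JSON-lines
#'
#' One JSON object per line: `source`, `target`, `labels`, `deltas`.
#' Deterministic ordering for reproducible training.
#'
#' @param x A [DirectionalPairs-class].
#' @param path Output file.
#' @export
writePairsJsonl <- function(x, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  # header line carries provenance
  writeLines(jsonlite::toJSON(list(
    type = "directional_pairs", n_source = x@nSource,
    objectives = x@objectives, taus = x@taus), auto_unbox = TRUE,
    digits = NA), con)
  for (i in seq_len(pairCount(x))) {
    writeLines(jsonlite::toJSON(list(
      source = x@source[i], target = x@target[i],
      labels = as.character(x@labels[i, ]),
      deltas = as.numeric(x@deltas[i, ])), auto_unbox = TRUE, digits = NA),
      con)
  }
  invisible(path)
}

#' Read a paired dataset from JSON-lines
#'
#' @param path File written by [writePairsJsonl()].
#' @return A [DirectionalPairs-class].
#' @export
readPairsJsonl <- function(path) {
  lines <- readLines(path)
  header <- jsonlite::fromJSON(lines[1L])
  if (!identical(header$type, "directional_pairs")) {
    stop("not a directional-pairs file", call. = FALSE)
  }
  j <- length(header$objectives)
  body <- lapply(lines[-1L], jsonlite::fromJSON)
  src <- vapply(body, `[[`, character(1), "source")
  tgt <- vapply(body, `[[`, character(1), "target")
  labels <- do.call(rbind, lapply(body, function(b) b$labels))
  deltas <- do.call(rbind, lapply(body, function(b) as.numeric(b$deltas)))
  if (length(body) == 0L) {
    labels <- matrix(character(), 0, j)
    deltas <- matrix(numeric(), 0, j)
  }
  newDirectionalPairs(src, tgt, labels, deltas, header$objectives,
                      header$taus, header$n_source)
}
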