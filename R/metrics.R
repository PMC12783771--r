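# Screen metrics: raw plate fluorescence -> fold change (FC), dynamic range
# (DR), wildtype-normalized values, selectivity calls, per-residue summaries.
#
# FC = mean(signal with ligand) / mean(no-ligand signal); DR = mean signal
# minus leak. Normalization pairs each mutant with the wildtype measured in
# the same batch, absorbing day-to-day assay drift.

#' Fold change: induced over uninduced signal
#'
#' @param signalWithLigand,signalNoLigand Mean fluorescence with and without
#'   ligand. Vectorized.
#' @return `signalWithLigand / signalNoLigand`; `NA` (flagged undefined,
#'   with a warning) where the denominator is not positive.
#' @export
foldChange <- function(signalWithLigand, signalNoLigand) {
  bad <- !is.na(signalNoLigand) & signalNoLigand <= 0
  if (any(bad)) {
    warning(sprintf("fold change undefined for %d record(s) with leak <= 0",
                    sum(bad)), call. = FALSE)
  }
  out <- signalWithLigand / signalNoLigand
  out[bad] <- NA_real_
  out
}

#' Dynamic range: induced signal minus leak
#'
#' May be negative at this stage; clamping happens only when normalized
#' values are prepared as training labels (see [normalizeToWildtype()]).
#'
#' @param signalWithLigand,leak Mean signals. Vectorized.
#' @return `signalWithLigand - leak`.
#' @export
dynamicRange <- function(signalWithLigand, leak) {
  signalWithLigand - leak
}

#' Normalize a metric to the same-batch wildtype value
#'
#' @param value Metric value(s).
#' @param wtValue Wildtype value of the same metric from the same batch;
#'   must be > 0.
#' @param clampNegative If `TRUE`, negative normalized values are set to
#'   zero (the rule applied when preparing model-training labels).
#' @return Normalized value(s).
#' @export
normalizeToWildtype <- function(value, wtValue, clampNegative = FALSE) {
  assertScalarNumber(wtValue, "wtValue", positive = TRUE)
  out <- value / wtValue
  if (clampNegative) out[!is.na(out) & out < 0] <- 0
  out
}

#' Classify selectivity from normalized fold changes
#'
#' A mutant is selective when its normalized FC to lead strictly exceeds 1
#' while its normalized FC to zinc is strictly below 1; boundaries are
#' excluded. Undefined inputs propagate as `NA` (unclassified).
#'
#' @param normFcPb,normFcZn Wildtype-normalized fold changes. Vectorized.
#' @return Character vector: "selective" / "non-selective" / `NA`.
#' @export
classifySelectivity <- function(normFcPb, normFcZn) {
  out <- ifelse(normFcPb > 1 & normFcZn < 1, "selective", "non-selective")
  out[is.na(normFcPb) | is.na(normFcZn)] <- NA_character_
  out
}

#' Convert a mass concentration to molarity
#'
#' @param ugPerL Concentration in micrograms per litre (ppb for water).
#' @param gPerMol Molar mass in g/mol.
#' @return Concentration in micromolar.
#' @export
#' @examples
#' massToMolar(10, 207.2)    # EPA lead action level, ~0.048 uM
massToMolar <- function(ugPerL, gPerMol) {
  assertScalarNumber(gPerMol, "gPerMol", positive = TRUE)
  ugPerL / gPerMol
}

#' Per-residue effect summary for heatmaps
#'
#' For each (position, alternative) substitution, the mean metric over all
#' mutants containing that substitution (a mutation inside a combinatorial
#' mutant contributes that mutant's value); per-position values are means
#' over all mutants touching the position.
#'
#' @param ids Character vector of mutant ids.
#' @param values Numeric metric per mutant (same length as `ids`).
#' @param alphabet Residue alphabet for the heatmap columns.
#' @return List with `perSubstitution` (data.frame pos, wt, alt,
#'   mean_value, n_mutants), `perPosition` (data.frame pos, mean_value,
#'   n_mutants) and `matrix` (positions x alphabet, `NA` where unobserved).
#' @export
residueEffectSummary <- function(ids, values, alphabet = aminoAcids()) {
  stopifnot(length(ids) == length(values))
  if (length(ids) == 0L) {
    empty <- data.frame(pos = integer(), wt = character(), alt = character(),
                        mean_value = numeric(), n_mutants = integer())
    return(list(perSubstitution = empty,
                perPosition = empty[c("pos", "mean_value", "n_mutants")],
                matrix = matrix(NA_real_, 0, length(alphabet),
                                dimnames = list(NULL, alphabet))))
  }
  subsList <- lapply(ids, parseMutantId, alphabet = alphabet)
  long <- do.call(rbind, lapply(seq_along(ids), function(i) {
    s <- subsList[[i]]
    if (nrow(s) == 0L) return(NULL)
    cbind(s, value = values[i])
  }))
  if (is.null(long)) {
    return(residueEffectSummary(character(), numeric(), alphabet))
  }
  key <- paste(long$pos, long$alt, sep = ":")
  perSub <- data.frame(
    pos = as.integer(tapply(long$pos, key, `[`, 1L)),
    wt = as.character(tapply(long$wt, key, `[`, 1L)),
    alt = as.character(tapply(long$alt, key, `[`, 1L)),
    mean_value = as.numeric(tapply(long$value, key, mean)),
    n_mutants = as.integer(tapply(long$value, key, length)),
    stringsAsFactors = FALSE)
  perSub <- perSub[order(perSub$pos, perSub$alt), , drop = FALSE]
  rownames(perSub) <- NULL
  perPos <- data.frame(
    pos = as.integer(names(tapply(long$value, long$pos, mean))),
    mean_value = as.numeric(tapply(long$value, long$pos, mean)),
    n_mutants = as.integer(tapply(long$value, long$pos, length)),
    stringsAsFactors = FALSE)
  perPos <- perPos[order(perPos$pos), , drop = FALSE]
  rownames(perPos) <- NULL
  positions <- sort(unique(perSub$pos))
  mat <- matrix(NA_real_, length(positions), length(alphabet),
                dimnames = list(positions, alphabet))
  mat[cbind(match(perSub$pos, positions), match(perSub$alt, alphabet))] <-
    perSub$mean_value
  list(perSubstitution = perSub, perPosition = perPos, matrix = mat)
}

#' Derive per-mutant activity records from screen measurements
#'
#' Aggregates replicate signals (arithmetic mean; replicate SD retained) per
#' mutant x batch x ligand, derives FC and DR against the same-batch
#' no-ligand leak, and normalizes both to the same-batch wildtype.
#'
#' @param measurements data.frame in the screen schema: `mutant_id`,
#'   `batch`, `ligand`, `concentration_uM`, `replicate`, `signal`
#'   (see [readScreenCsv()]). The no-ligand condition must use
#'   `ligand == "none"`; each batch must contain a wildtype (`"WT"`) row.
#' @param wildtypeId Id of the wildtype rows (default `"WT"`).
#' @param clampNegativeDr If `TRUE`, negative normalized DR is clamped to
#'   zero (use when preparing training labels).
#' @return data.frame with one row per mutant x batch x ligand (ligands
#'   other than "none"): `mutant_id`, `batch`, `ligand`, `n`, `mean_signal`,
#'   `sd_signal`, `leak`, `fc`, `dr`, `norm_fc`, `norm_dr`.
#' @export
activityTable <- function(measurements, wildtypeId = "WT",
                          clampNegativeDr = FALSE) {
  need <- c("mutant_id", "batch", "ligand", "signal")
  miss <- setdiff(need, names(measurements))
  if (length(miss) > 0L) {
    stop(sprintf("missing column(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  agg <- aggregate(signal ~ mutant_id + batch + ligand, measurements,
                   function(x) c(mean = mean(x), sd = sd(x), n = length(x)))
  agg <- cbind(agg[c("mutant_id", "batch", "ligand")],
               as.data.frame(agg$signal))
  agg$sd[is.na(agg$sd)] <- 0
  leak <- agg[agg$ligand == "none", c("mutant_id", "batch", "mean")]
  names(leak)[3L] <- "leak"
  out <- agg[agg$ligand != "none", , drop = FALSE]
  out <- merge(out, leak, by = c("mutant_id", "batch"), all.x = TRUE)
  if (any(is.na(out$leak))) {
    stop("no-ligand ('none') rows missing for some mutant/batch", call. = FALSE)
  }
  out$fc <- suppressWarnings(foldChange(out$mean, out$leak))
  out$dr <- dynamicRange(out$mean, out$leak)
  # Same-batch wildtype reference per ligand.
  wt <- out[out$mutant_id == wildtypeId, c("batch", "ligand", "fc", "dr")]
  if (nrow(wt) == 0L) {
    stop(sprintf("wildtype rows ('%s') absent; normalization needs a same-batch wildtype",
                 wildtypeId), call. = FALSE)
  }
  names(wt)[3:4] <- c("wt_fc", "wt_dr")
  out <- merge(out, wt, by = c("batch", "ligand"), all.x = TRUE)
  if (any(is.na(out$wt_fc) | out$wt_fc <= 0 | out$wt_dr <= 0)) {
    stop("wildtype FC/DR missing or non-positive in some batch", call. = FALSE)
  }
  out$norm_fc <- out$fc / out$wt_fc
  out$norm_dr <- out$dr / out$wt_dr
  if (clampNegativeDr) out$norm_dr[!is.na(out$norm_dr) & out$norm_dr < 0] <- 0
  res <- data.frame(mutant_id = out$mutant_id, batch = out$batch,
                    ligand = out$ligand, n = as.integer(out$n),
                    mean_signal = out$mean, sd_signal = out$sd,
                    leak = out$leak, fc = out$fc, dr = out$dr,
                    norm_fc = out$norm_fc, norm_dr = out$norm_dr,
                    stringsAsFactors = FALSE)
  res[order(res$mutant_id, res$batch, res$ligand), , drop = FALSE]
}

#' Estimate the per-objective noise threshold tau
#'
#' Default rule: tau = 2 x pooled replicate SD of the wildtype metric across
#' batches. Per batch, a per-replicate metric value is formed for the
#' wildtype (replicate signal against the batch-mean leak, normalized by the
#' batch wildtype value so the wildtype mean is 1), its replicate variance
#' taken, and variances pooled across batches.
#'
#' @param measurements Screen-schema data.frame (see [activityTable()]).
#' @param ligand Ligand of the objective (e.g. "lead").
#' @param metric "norm_fc" or "norm_dr".
#' @param wildtypeId Wildtype id (default "WT").
#' @param factor Multiplier on the pooled SD (default 2).
#' @return Single non-negative tau on the normalized-metric scale.
#' @export
estimateNoiseThreshold <- function(measurements, ligand,
                                   metric = c("norm_fc", "norm_dr"),
                                   wildtypeId = "WT", factor = 2) {
  metric <- match.arg(metric)
  wtRows <- measurements[measurements$mutant_id == wildtypeId, , drop = FALSE]
  if (nrow(wtRows) == 0L) stop("no wildtype rows", call. = FALSE)
  vars <- c()
  for (b in unique(wtRows$batch)) {
    sig <- wtRows$signal[wtRows$batch == b & wtRows$ligand == ligand]
    lk <- mean(wtRows$signal[wtRows$batch == b & wtRows$ligand == "none"])
    if (length(sig) < 2L || !is.finite(lk) || lk <= 0) next
    wtVal <- if (metric == "norm_fc") mean(sig) / lk else mean(sig) - lk
    if (!is.finite(wtVal) || wtVal <= 0) next
    perRep <- if (metric == "norm_fc") (sig / lk) / wtVal else
      (sig - lk) / wtVal
    vars <- c(vars, stats::var(perRep))
  }
  if (length(vars) == 0L) {
    stop("cannot estimate tau: need >= 2 wildtype replicates in some batch",
         call. = FALSE)
  }
  factor * sqrt(mean(vars))
}
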