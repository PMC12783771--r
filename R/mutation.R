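# Point-substitution mutants: parsing, application, comparison, enumeration.
# Mutant ids use the field's underscore-joined notation (e.g. "D64K_N83F"):
# wildtype residue, 1-based position, alternative residue. A set of
# substitutions is represented as a data.frame(wt, pos, alt) sorted by
# position; the empty set is the wildtype ("WT" or "" as sentinel).

emptySubstitutions <- function() {
  data.frame(wt = character(), pos = integer(), alt = character(),
             stringsAsFactors = FALSE)
}

#' Parse a mutant id into its substitutions
#'
#' @param id Underscore-joined substitution string such as `"D64K_N83F"`.
#'   The empty string and `"WT"` are wildtype sentinels.
#' @param alphabet Allowed residue letters (default the 20 amino acids).
#' @return data.frame with columns `wt`, `pos`, `alt`, sorted by ascending
#'   position. Zero rows for wildtype.
#' @seealso [mutantId()] for the inverse, [applySubstitutions()].
#' @export
#' @examples
#' parseMutantId("D64K_N83F")
#' parseMutantId("WT")
parseMutantId <- function(id, alphabet = aminoAcids()) {
  if (length(id) != 1L || !is.character(id) || is.na(id)) {
    stop("'id' must be a single string", call. = FALSE)
  }
  if (id == "" || id == "WT") {
    return(emptySubstitutions())
  }
  tokens <- strsplit(id, "_", fixed = TRUE)[[1L]]
  ok <- grepl("^[A-Za-z][0-9]+[A-Za-z]$", tokens)
  if (length(tokens) == 0L || !all(ok)) {
    stop(sprintf("malformed substitution token(s): %s",
                 paste(tokens[!ok], collapse = ", ")), call. = FALSE)
  }
  wt <- toupper(substr(tokens, 1L, 1L))
  alt <- toupper(substring(tokens, nchar(tokens)))
  pos <- as.integer(substr(tokens, 2L, nchar(tokens) - 1L))
  bad <- !(wt %in% alphabet) | !(alt %in% alphabet)
  if (any(bad)) {
    stop(sprintf("residue outside alphabet in token(s): %s",
                 paste(tokens[bad], collapse = ", ")), call. = FALSE)
  }
  if (any(pos < 1L)) stop("positions must be >= 1", call. = FALSE)
  if (any(wt == alt)) {
    stop(sprintf("wildtype equals alternative in token(s): %s",
                 paste(tokens[wt == alt], collapse = ", ")), call. = FALSE)
  }
  if (anyDuplicated(pos)) {
    stop(sprintf("duplicate position(s): %s",
                 paste(unique(pos[duplicated(pos)]), collapse = ", ")),
         call. = FALSE)
  }
  o <- order(pos)
  data.frame(wt = wt[o], pos = pos[o], alt = alt[o], stringsAsFactors = FALSE)
}

#' Canonical mutant id from a substitution table
#'
#' Substitutions are sorted by ascending position, so the id is canonical:
#' `parseMutantId(mutantId(s))` reproduces `s` for any valid table.
#'
#' @param subs data.frame with columns `wt`, `pos`, `alt`.
#' @return Canonical id string; `"WT"` for zero substitutions.
#' @export
mutantId <- function(subs) {
  if (nrow(subs) == 0L) return("WT")
  if (anyDuplicated(subs$pos)) stop("duplicate positions", call. = FALSE)
  if (any(subs$wt == subs$alt)) stop("wt equals alt", call. = FALSE)
  o <- order(subs$pos)
  paste0(subs$wt[o], subs$pos[o], subs$alt[o], collapse = "_")
}

#' Apply substitutions to a wildtype sequence
#'
#' Fails loudly when the recorded wildtype residue does not match the
#' sequence at that position (the signature of stale numbering).
#'
#' @param wildtype Wildtype amino-acid sequence (single string).
#' @param subs data.frame from [parseMutantId()].
#' @return Mutant sequence of the same length.
#' @export
#' @examples
#' applySubstitutions("ACDEF", parseMutantId("C2G"))
applySubstitutions <- function(wildtype, subs) {
  chars <- seqChars(wildtype)
  if (nrow(subs) == 0L) return(wildtype)
  if (any(subs$pos > length(chars))) {
    stop(sprintf("position(s) beyond sequence length %d: %s", length(chars),
                 paste(subs$pos[subs$pos > length(chars)], collapse = ", ")),
         call. = FALSE)
  }
  mismatch <- chars[subs$pos] != subs$wt
  if (any(mismatch)) {
    stop(sprintf(
      "wildtype-residue mismatch at position(s) %s (sequence has %s, id says %s)",
      paste(subs$pos[mismatch], collapse = ", "),
      paste(chars[subs$pos][mismatch], collapse = ", "),
      paste(subs$wt[mismatch], collapse = ", ")), call. = FALSE)
  }
  chars[subs$pos] <- subs$alt
  paste(chars, collapse = "")
}

#' Mutation order between two equal-length sequences
#'
#' Hamming distance; in the substitution-only regime this is the number of
#' mutations separating the two sequences.
#'
#' @param seqA,seqB Equal-length sequences.
#' @return Non-negative integer count of mismatching positions.
#' @export
hammingOrder <- function(seqA, seqB) {
  if (nchar(seqA) != nchar(seqB)) {
    stop(sprintf("length mismatch: %d vs %d", nchar(seqA), nchar(seqB)),
         call. = FALSE)
  }
  sum(seqChars(seqA) != seqChars(seqB))
}

#' Recover the mutant id of a sequence relative to wildtype
#'
#' @param wildtype,sequence Equal-length sequences.
#' @return Canonical mutant id (`"WT"` if identical).
#' @export
sequenceToId <- function(wildtype, sequence) {
  if (nchar(wildtype) != nchar(sequence)) {
    stop("length mismatch", call. = FALSE)
  }
  wc <- seqChars(wildtype)
  sc <- seqChars(sequence)
  pos <- which(wc != sc)
  if (length(pos) == 0L) return("WT")
  mutantId(data.frame(wt = wc[pos], pos = pos, alt = sc[pos],
                      stringsAsFactors = FALSE))
}

#' Enumerate a combinatorial mutant library
#'
#' Produces every mutant whose substituted-site set has size between
#' `minOrder` and `maxOrder`, choosing one allowed alternative per chosen
#' site. Output is deterministic: ordered by mutation order, then
#' lexicographically by id.
#'
#' @param options data.frame with columns `wt`, `pos`, `alt`: one row per
#'   allowed substitution. Multiple rows may share a position (several
#'   alternatives at one site); the wildtype residue must be consistent per
#'   position.
#' @param minOrder,maxOrder Inclusive bounds on the number of substituted
#'   sites.
#' @return data.frame with columns `mutant_id` and `order`; zero rows when
#'   no subset of sites qualifies.
#' @export
#' @examples
#' opts <- parseMutantId("D64K_N83I_K104V")
#' enumerateCombinatorial(opts, 2, 3)
enumerateCombinatorial <- function(options, minOrder, maxOrder) {
  if (nrow(options) == 0L) stop("no substitution options given", call. = FALSE)
  if (anyDuplicated(options[c("pos", "alt")])) {
    stop("duplicate (position, alternative) option", call. = FALSE)
  }
  wtByPos <- tapply(options$wt, options$pos, unique)
  if (any(lengths(wtByPos) > 1L)) {
    stop("inconsistent wildtype residue at a position", call. = FALSE)
  }
  sites <- sort(unique(options$pos))
  nSites <- length(sites)
  if (!(minOrder >= 1L && minOrder <= maxOrder && maxOrder <= nSites)) {
    stop("need 1 <= minOrder <= maxOrder <= number of sites", call. = FALSE)
  }
  optBySite <- lapply(sites, function(p) which(options$pos == p))
  ids <- character()
  orders <- integer()
  for (k in seq(minOrder, maxOrder)) {
    siteSets <- combn(nSites, k, simplify = FALSE)
    for (s in siteSets) {
      grids <- expand.grid(optBySite[s], KEEP.OUT.ATTRS = FALSE)
      for (r in seq_len(nrow(grids))) {
        rows <- as.integer(grids[r, ])
        ids <- c(ids, mutantId(options[rows, , drop = FALSE]))
        orders <- c(orders, k)
      }
    }
  }
  o <- order(orders, ids)
  out <- data.frame(mutant_id = ids[o], order = orders[o],
                    stringsAsFactors = FALSE)
  stopifnot(!anyDuplicated(out$mutant_id))
  out
}

#' Read amino-acid sequences from FASTA
#'
#' @param path FASTA file.
#' @return Named character vector of sequences.
#' @export
readFastaAA <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  setNames(as.character(set), names(set))
}

#' Write amino-acid sequences to FASTA (60-column wrapped)
#'
#' @param seqs Named character vector of sequences.
#' @param path Output file.
#' @export
writeFastaAA <- function(seqs, path) {
  set <- Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}
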