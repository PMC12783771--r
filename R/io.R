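# File formats, run configuration and the command-line surface. CSV
# dialect throughout: UTF-8, comma separator, '.' decimal, header required.
# Data files carry no timestamps; provenance lives in run manifests.

screenSchema <- function() {
  c("mutant_id", "batch", "ligand", "concentration_uM", "replicate",
    "signal")
}

#' Read a screen measurement table
#'
#' Validates the schema (`mutant_id`, `batch`, `ligand`,
#' `concentration_uM`, `replicate`, `signal`) and the value domains;
#' errors are row-addressed.
#'
#' @param path CSV file.
#' @return data.frame in the screen schema.
#' @export
readScreenCsv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(screenSchema(), names(df))
  if (length(miss) > 0L) {
    stop(sprintf("screen CSV is missing column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  sig <- suppressWarnings(as.numeric(df$signal))
  if (anyNA(sig)) {
    stop(sprintf("non-numeric signal at row(s): %s",
                 paste(which(is.na(sig)), collapse = ", ")), call. = FALSE)
  }
  df$signal <- sig
  conc <- suppressWarnings(as.numeric(df$concentration_uM))
  if (anyNA(conc) || any(conc < 0)) {
    bad <- which(is.na(conc) | conc < 0)
    stop(sprintf("invalid concentration_uM at row(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  df$concentration_uM <- conc
  if (any(df$signal < 0)) {
    stop(sprintf("negative signal at row(s): %s",
                 paste(which(df$signal < 0), collapse = ", ")),
         call. = FALSE)
  }
  df[screenSchema()]
}

#' Write a screen measurement table
#'
#' @param measurements data.frame in the screen schema.
#' @param path Output CSV.
#' @export
writeScreenCsv <- function(measurements, path) {
  write.csv(measurements[screenSchema()], path, row.names = FALSE,
            quote = FALSE)
  invisible(path)
}

#' Write an activity table (one row per mutant x ligand)
#'
#' @param activity data.frame from [activityTable()].
#' @param path Output CSV.
#' @export
writeActivityCsv <- function(activity, path) {
  write.csv(activity, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a per-residue heatmap matrix
#'
#' Rows are positions, columns the residue alphabet; empty cells are
#' unobserved substitutions.
#'
#' @param summary Output of [residueEffectSummary()].
#' @param path Output CSV.
#' @export
writeHeatmapCsv <- function(summary, path) {
  write.csv(summary$matrix, path, row.names = TRUE, quote = FALSE,
            na = "")
  invisible(path)
}

#' Write a round library
#'
#' @param library data.frame from [filterLibrary()].
#' @param path Output CSV.
#' @export
writeLibraryCsv <- function(library, path) {
  write.csv(library, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- run configuration --------------------------------------------------

runConfigSchema <- function() {
  list(
    landscape = c("preset", "path"),
    objectives = NULL,  # list of {name, ligand, metric, tau}
    pairing = c("both_orientations", "max_per_category"),
    train = c("lr", "weight_decay", "batch_size", "epochs", "emb_dim",
              "hidden_dim", "val_fraction"),
    generate = c("directions", "top_k", "candidates_per_seed", "max_order",
                 "capacity"),
    rounds = NULL,
    round_sizes = NULL,
    seed = NULL,
    out_dir = NULL)
}

#' Validate and resolve a run configuration
#'
#' Unknown keys are rejected; defaults are filled in so every run can emit
#' a fully resolved copy of its configuration.
#'
#' @param config Named list (parsed YAML/JSON).
#' @return Resolved configuration list.
#' @export
validateRunConfig <- function(config) {
  schema <- runConfigSchema()
  unknown <- setdiff(names(config), names(schema))
  if (length(unknown) > 0L) {
    stop(sprintf("unknown config key(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  for (key in names(schema)) {
    sub <- schema[[key]]
    if (!is.null(sub) && !is.null(config[[key]]) && key != "objectives") {
      bad <- setdiff(names(config[[key]]), sub)
      if (length(bad) > 0L) {
        stop(sprintf("unknown key(s) under '%s': %s", key,
                     paste(bad, collapse = ", ")), call. = FALSE)
      }
    }
  }
  defaults <- list(
    landscape = list(preset = "toy-campaign"),
    objectives = list(list(name = "Zn", ligand = "zinc",
                           metric = "norm_fc", tau = NA),
                      list(name = "Pb", ligand = "lead",
                           metric = "norm_fc", tau = NA)),
    pairing = list(both_orientations = TRUE, max_per_category = 400L),
    train = list(lr = 5e-3, weight_decay = 1e-4, batch_size = 128L,
                 epochs = 15L, emb_dim = 24L, hidden_dim = 64L,
                 val_fraction = 0.1),
    generate = list(directions = c("dec", "inc"), top_k = 10L,
                    candidates_per_seed = 20L, max_order = 6L,
                    capacity = 60L),
    rounds = 2L, round_sizes = 60L, seed = 1L, out_dir = ".")
  out <- defaults
  for (key in names(config)) {
    if (is.list(defaults[[key]]) && key != "objectives") {
      for (k2 in names(config[[key]])) out[[key]][[k2]] <- config[[key]][[k2]]
    } else {
      out[[key]] <- config[[key]]
    }
  }
  out
}

#' Read a run configuration file
#'
#' @param path YAML or JSON file.
#' @return Resolved configuration list (see [validateRunConfig()]).
#' @export
readRunConfig <- function(path) {
  config <- if (grepl("\\.json$", path)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  validateRunConfig(config)
}

resolveLandscape <- function(spec) {
  if (!is.null(spec$path)) return(readLandscapeYaml(spec$path))
  switch(spec$preset,
         "toy-campaign" = toyCampaignLandscape(),
         "toy-grammar" = toyGrammarLandscape(),
         stop(sprintf("unknown landscape preset '%s'", spec$preset),
              call. = FALSE))
}

resolveObjectives <- function(cfg) {
  lapply(cfg$objectives, function(o) {
    objectiveSpec(o$name, o$ligand, o$metric %||% "norm_fc",
                  o$tau %||% NA_real_)
  })
}

directionTokens <- function(words) {
  vapply(words, function(w) {
    switch(w, inc = TOKEN_INC, dec = TOKEN_DEC,
           "<inc>" = TOKEN_INC, "<dec>" = TOKEN_DEC,
           stop(sprintf("unknown direction '%s'", w), call. = FALSE))
  }, character(1), USE.NAMES = FALSE)
}

fileHash <- function(path) unname(tools::md5sum(path))

objectHash <- function(obj) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA), tmp)
  fileHash(tmp)
}

#' Write a run manifest
#'
#' Records the resolved configuration (and its hash), input file hashes,
#' package version and seed, so every artifact is reproducible from its
#' manifest.
#'
#' @param config Resolved configuration list.
#' @param inputs Named character vector of input file paths.
#' @param outputs Named character vector of output file paths.
#' @param path Manifest JSON path.
#' @export
writeManifest <- function(config, inputs, outputs, path) {
  manifest <- list(
    tool = "seqDirector",
    version = as.character(utils::packageVersion("seqDirector")),
    seed = config$seed,
    config = config,
    config_hash = objectHash(config),
    inputs = lapply(as.list(inputs), function(p)
      list(path = p, md5 = fileHash(p))),
    outputs = lapply(as.list(outputs), function(p)
      list(path = p, md5 = fileHash(p))),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

# ---- command-line dispatcher -------------------------------------------

cliUsage <- function() {
  paste(
    "usage: seqdirector <command> [--config FILE] [--seed N] [--out DIR]",
    "commands:",
    "  simulate   simulate the three-condition plate screen",
    "  metrics    derive FC/DR/normalized metrics from a screen CSV",
    "  pair       build the direction-labeled paired dataset",
    "  train      train the conditional model on a pair file",
    "  generate   propose and filter a round library",
    "  campaign   run the full multi-round loop",
    sep = "\n")
}

parseCliArgs <- function(args) {
  out <- list(command = NULL, config = NULL, seed = NULL, out = ".",
              rounds = NULL, input = NULL, model = NULL)
  if (length(args) == 0L) return(out)
  out$command <- args[1L]
  args <- args[-1L]
  i <- 1L
  while (i <= length(args)) {
    key <- args[i]
    if (!startsWith(key, "--")) stop(sprintf("unexpected argument '%s'", key),
                                     call. = FALSE)
    if (i == length(args)) stop(sprintf("missing value for %s", key),
                                call. = FALSE)
    val <- args[i + 1L]
    out[[substring(key, 3L)]] <- val
    i <- i + 2L
  }
  out
}

#' Command-line entry point
#'
#' Thin dispatcher behind the `inst/cli/seqdirector.R` script. Each command
#' writes its artifact plus a JSON run manifest and returns exit status 0
#' on success.
#'
#' @param args Character vector of command-line arguments.
#' @return Integer exit status (invisibly).
#' @export
cliMain <- function(args = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    opts <- parseCliArgs(args)
    if (is.null(opts$command) || opts$command %in% c("-h", "--help")) {
      message(cliUsage())
      return(invisible(0L))
    }
    config <- if (!is.null(opts$config)) readRunConfig(opts$config) else
      validateRunConfig(list())
    if (!is.null(opts$seed)) config$seed <- as.integer(opts$seed)
    if (!is.null(opts$rounds)) config$rounds <- as.integer(opts$rounds)
    outDir <- opts$out %||% config$out_dir
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    landscape <- resolveLandscape(config$landscape)
    objectives <- resolveObjectives(config)
    withinOut <- function(f) file.path(outDir, f)
    switch(opts$command,
      simulate = {
        ids <- c(allSingleMutants(landscape),
                 randomMutants(landscape, 60L, 2L,
                               seed = childSeed(config$seed, 1L)))
        screen <- simulateScreen(landscape, ids,
                                 seed = childSeed(config$seed, 2L),
                                 batch = "round0")
        writeScreenCsv(screen, withinOut("screen.csv"))
        writeManifest(config, character(),
                      c(screen = withinOut("screen.csv")),
                      withinOut("simulate.manifest.json"))
      },
      metrics = {
        input <- opts$input %||% withinOut("screen.csv")
        screen <- readScreenCsv(input)
        activity <- activityTable(screen, clampNegativeDr = TRUE)
        writeActivityCsv(activity, withinOut("activity.csv"))
        writeManifest(config, c(screen = input),
                      c(activity = withinOut("activity.csv")),
                      withinOut("metrics.manifest.json"))
      },
      pair = {
        input <- opts$input %||% withinOut("screen.csv")
        screen <- readScreenCsv(input)
        activity <- activityTable(screen, clampNegativeDr = TRUE)
        objs <- lapply(objectives, function(o) {
          if (is.na(o@tau)) {
            o@tau <- estimateNoiseThreshold(screen, o@ligand, o@metric)
          }
          o
        })
        metrics <- metricMatrix(activity, objs)
        keep <- stats::complete.cases(metrics)
        ids <- rownames(metrics)[keep]
        seqs <- vapply(ids, function(id) {
          applySubstitutions(landscape@wildtype,
                             parseMutantId(id, landscape@alphabet))
        }, character(1))
        pairs <- buildPairedDataset(
          seqs, metrics[keep, , drop = FALSE], objs,
          bothOrientations = isTRUE(config$pairing$both_orientations))
        pairs <- balanceCategories(
          pairs, seed = childSeed(config$seed, 3L),
          maxPerCategory = config$pairing$max_per_category)
        writePairsJsonl(pairs, withinOut("pairs.jsonl"))
        writeManifest(config, c(screen = input),
                      c(pairs = withinOut("pairs.jsonl")),
                      withinOut("pair.manifest.json"))
      },
      train = {
        input <- opts$input %||% withinOut("pairs.jsonl")
        pairs <- readPairsJsonl(input)
        tc <- trainConfig(lr = config$train$lr,
                          weightDecay = config$train$weight_decay,
                          batchSize = config$train$batch_size,
                          epochs = config$train$epochs,
                          embDim = config$train$emb_dim,
                          hiddenDim = config$train$hidden_dim,
                          valFraction = config$train$val_fraction,
                          seed = childSeed(config$seed, 4L))
        model <- trainModel(pairs, tc,
                            vocab = buildVocabulary(landscape@alphabet,
                                                    length(objectives)))
        saveModel(model, withinOut("model.ckpt"))
        histPath <- withinOut("training_log.jsonl")
        con <- file(histPath, "wt")
        for (i in seq_len(nrow(model@history))) {
          writeLines(jsonlite::toJSON(as.list(model@history[i, ]),
                                      auto_unbox = TRUE, digits = NA), con)
        }
        close(con)
        writeManifest(config, c(pairs = input),
                      c(model = withinOut("model.ckpt"),
                        log = histPath),
                      withinOut("train.manifest.json"))
      },
      generate = {
        modelPath <- opts$model %||% withinOut("model.ckpt")
        screenPath <- opts$input %||% withinOut("screen.csv")
        model <- loadModel(modelPath)
        screen <- readScreenCsv(screenPath)
        activity <- activityTable(screen, clampNegativeDr = TRUE)
        objs <- lapply(objectives, function(o) {
          if (is.na(o@tau)) {
            o@tau <- estimateNoiseThreshold(screen, o@ligand, o@metric)
          }
          o
        })
        metrics <- metricMatrix(activity, objs)
        ids <- rownames(metrics)
        seqs <- vapply(ids, function(id) {
          applySubstitutions(landscape@wildtype,
                             parseMutantId(id, landscape@alphabet))
        }, character(1))
        objNames <- vapply(objs, function(o) o@name, character(1))
        records <- data.frame(sequence = seqs, stringsAsFactors = FALSE)
        for (k in seq_along(objNames)) records[[objNames[k]]] <- metrics[, k]
        gc <- generationConfig(
          directions = directionTokens(config$generate$directions),
          topK = config$generate$top_k,
          candidatesPerSeed = config$generate$candidates_per_seed,
          maxOrder = config$generate$max_order,
          capacity = config$generate$capacity,
          seed = childSeed(config$seed, 5L),
          exclude = ids)
        seeds <- selectSeeds(records[ids != "WT", , drop = FALSE],
                             as.list(records[ids == "WT", , drop = FALSE]),
                             objNames, gc@directions)
        candidates <- proposeCandidates(model, seeds, gc)
        library <- filterLibrary(candidates, landscape@wildtype, gc)
        writeLibraryCsv(library, withinOut("library.csv"))
        writeFastaAA(setNames(library$sequence, library$mutant_id),
                     withinOut("library.fasta"))
        writeManifest(config, c(model = modelPath, screen = screenPath),
                      c(library = withinOut("library.csv"),
                        fasta = withinOut("library.fasta")),
                      withinOut("generate.manifest.json"))
      },
      campaign = {
        report <- runCampaign(
          landscape, rounds = config$rounds,
          roundSizes = config$round_sizes,
          objectives = objectives,
          train = trainConfig(lr = config$train$lr,
                              weightDecay = config$train$weight_decay,
                              batchSize = config$train$batch_size,
                              epochs = config$train$epochs,
                              embDim = config$train$emb_dim,
                              hiddenDim = config$train$hidden_dim,
                              valFraction = config$train$val_fraction),
          gen = generationConfig(
            directions = directionTokens(config$generate$directions),
            topK = config$generate$top_k,
            candidatesPerSeed = config$generate$candidates_per_seed,
            maxOrder = config$generate$max_order,
            capacity = config$generate$capacity),
          seed = config$seed)
        for (r in report$rounds) {
          libPath <- withinOut(sprintf("round%d_library.csv", r$round))
          writeLibraryCsv(r$library, libPath)
          writeManifest(config, character(), c(library = libPath),
                        withinOut(sprintf("round%d.manifest.json",
                                          r$round)))
        }
        summary <- lapply(report$rounds, function(r) {
          r[c("round", "M", "pairsRetained", "pairsBalanced", "nSeeds",
              "librarySize", "selectiveFraction", "baselineFraction",
              "enrichment")]
        })
        jsonlite::write_json(summary, withinOut("campaign_summary.json"),
                             auto_unbox = TRUE, digits = NA, pretty = TRUE)
      },
      stop(sprintf("unknown command '%s'\n%s", opts$command, cliUsage()),
           call. = FALSE))
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}

#' Synthetic length-145 scaffold with the campaign's wildtype residues
#'
#' A synthetic stand-in sequence (NOT the real PbrR / Uniprot Q58AJ5
#' sequence, which is not redistributed here) of the same length carrying
#' the wildtype residues referenced by the campaign's mutant ids (D64, N83,
#' I90, K104, H106, L107, P143, M60, P61, G128), so the published mutant
#' identifiers parse and apply cleanly for demonstrations and tests.
#'
#' @return A length-145 amino-acid string.
#' @export
syntheticPbrRScaffold <- function() {
  base <- rep("S", 145L)
  anchors <- c("60" = "M", "61" = "P", "64" = "D", "83" = "N", "90" = "I",
               "104" = "K", "106" = "H", "107" = "L", "128" = "G",
               "143" = "P")
  filler <- aminoAcids()
  idx <- seq_along(base)
  base <- filler[(idx %% 20L) + 1L]
  base[as.integer(names(anchors))] <- anchors
  paste(base, collapse = "")
}
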