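## Pipeline orchestration: a structured run configuration and a driver
## executing simulate -> build-dataset -> train -> predict -> prioritize
## -> evaluate with per-stage seeds fanned out from one global seed.

.CONFIG_KEYS <- list(
  top = c("seed", "out_dir", "stages", "simulate", "build_dataset",
          "train", "predict", "prioritize", "evaluate"),
  simulate = c("n_sequences", "length_range", "motif_length_range",
               "motifs_per_sequence", "motif_alphabet_bias",
               "energy_effect", "noise_sigma", "n_targets",
               "partners_per_target"),
  build_dataset = c("threshold", "min_identity", "fractions",
                    "forced_test", "window_length"),
  train = c("backend", "radius", "emb_dim", "num_blocks",
            "trainable_last_k", "hidden", "activation", "learning_rate",
            "batch_size", "max_epochs", "patience"),
  predict = character(),
  prioritize = c("target", "peptide_length", "top_n", "allow_overlap",
                 "policy"),
  evaluate = c("n", "tau", "average"))

.ALL_STAGES <- c("simulate", "build_dataset", "train", "predict",
                 "prioritize", "evaluate")

#' Read and validate a pipeline run configuration
#'
#' Accepts YAML (`.yml`/`.yaml`) or JSON. Unknown keys anywhere in the
#' configuration are rejected before any stage runs. See
#' [runPipeline()] for the recognized structure.
#'
#' @param path Config file path.
#' @return Validated configuration list.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("config file does not exist: ", path)
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  validateRunConfig(cfg)
}

#' @rdname readRunConfig
#' @param config Configuration list to validate.
#' @export
validateRunConfig <- function(config) {
  stopifnot(is.list(config))
  unknown <- setdiff(names(config), .CONFIG_KEYS$top)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  for (section in setdiff(.CONFIG_KEYS$top,
                          c("seed", "out_dir", "stages"))) {
    if (is.null(config[[section]])) next
    bad <- setdiff(names(config[[section]]), .CONFIG_KEYS[[section]])
    if (length(bad))
      stop("unknown key(s) in config section '", section, "': ",
           paste(bad, collapse = ", "))
  }
  if (is.null(config$seed)) config$seed <- 1L
  if (is.null(config$out_dir))
    stop("config must provide 'out_dir'")
  if (is.null(config$stages)) config$stages <- .ALL_STAGES
  bad <- setdiff(config$stages, .ALL_STAGES)
  if (length(bad))
    stop("unknown stage(s): ", paste(bad, collapse = ", "))
  config
}

.cfgGet <- function(config, section, key, default) {
  v <- config[[section]][[key]]
  if (is.null(v)) default else v
}

.backendFromConfig <- function(config, globalSeed) {
  kind <- .cfgGet(config, "train", "backend", "onehot")
  switch(kind,
         onehot = oneHotBackend(.cfgGet(config, "train", "radius", 7L)),
         tinytransformer = {
           b <- tinyTransformerBackend(
             embDim = .cfgGet(config, "train", "emb_dim", 16L),
             numBlocks = .cfgGet(config, "train", "num_blocks", 4L),
             seed = stageSeed(globalSeed, "backend"))
           setTrainable(b, .cfgGet(config, "train", "trainable_last_k",
                                   0L))
         },
         stop("unknown backend kind: ", kind))
}

#' Run the synthetic-data -> dataset -> training -> prioritization
#' pipeline
#'
#' Executes the requested stages in order, writing every intermediate
#' artifact under `out_dir`. A single global `seed` fans out to
#' per-stage seeds via [stageSeed()], so a rerun with an identical
#' configuration reproduces every output file byte-for-byte, and adding
#' or removing stages does not perturb the random streams of the others.
#' The validated configuration is serialized into `out_dir` for
#' provenance.
#'
#' Stages and their artifacts: `simulate` (corpus FASTA, window TSV,
#' label TSV, motif-truth TSV, PPI TSV, partner FASTA, partner-truth
#' TSV), `build_dataset` (per-position labeled dataset TSV + split TSV,
#' built from the window records through profile aggregation, duplicate
#' merging, thresholding and cluster splitting), `train` (model
#' checkpoint + training report JSON), `predict` (per-position
#' probability tracks for the test split), `prioritize` (ranked
#' candidate TSV over the simulated PPI partners), `evaluate` (metrics
#' JSON on the test split).
#'
#' @param config Configuration list (see [readRunConfig()]); must
#'   contain `out_dir`, may contain `seed`, `stages`, and per-stage
#'   sections.
#' @param verbose Emit progress messages (default `TRUE`).
#' @return Named list of artifact paths, invisibly.
#' @export
runPipeline <- function(config, verbose = TRUE) {
  config <- validateRunConfig(config)
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed)
  say <- function(...) if (verbose) message(...)
  paths <- list(
    fasta = file.path(out, "corpus.fasta"),
    windows = file.path(out, "windows.tsv"),
    corpusLabels = file.path(out, "corpus_labels.tsv"),
    motifs = file.path(out, "motif_truth.tsv"),
    ppi = file.path(out, "ppi.tsv"),
    partnerFasta = file.path(out, "partners.fasta"),
    partnerTruth = file.path(out, "partner_truth.tsv"),
    dataset = file.path(out, "labeled_dataset.tsv"),
    split = file.path(out, "split.tsv"),
    model = file.path(out, "model.ckpt"),
    trainReport = file.path(out, "train_report.json"),
    tracks = file.path(out, "predicted_tracks.tsv"),
    candidates = file.path(out, "candidates.tsv"),
    metrics = file.path(out, "metrics.json"))

  jsonlite::write_json(config, file.path(out, "run_config.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")

  stages <- config$stages

  if ("simulate" %in% stages) {
    say("stage simulate")
    cfg <- generatorConfig(
      nSequences = .cfgGet(config, "simulate", "n_sequences", 200L),
      lengthRange = .cfgGet(config, "simulate", "length_range",
                            c(60L, 120L)),
      motifLengthRange = .cfgGet(config, "simulate",
                                 "motif_length_range", c(8L, 12L)),
      motifsPerSequence = .cfgGet(config, "simulate",
                                  "motifs_per_sequence", 1L),
      motifAlphabetBias = .cfgGet(config, "simulate",
                                  "motif_alphabet_bias", 0.9),
      energyEffect = .cfgGet(config, "simulate", "energy_effect", -2),
      noiseSigma = .cfgGet(config, "simulate", "noise_sigma", 0.5),
      seed = stageSeed(seed, "simulate"))
    corpus <- generateLabeledCorpus(cfg)
    writeFasta(corpus$sequences, paths$fasta)
    windows <- generateWindowRecords(corpus)
    utils::write.table(
      transform(windows, reu = .fmtNum(reu)), paths$windows,
      sep = "\t", quote = FALSE, row.names = FALSE)
    writeLabeledDataset(corpus$labeled, paths$corpusLabels)
    utils::write.table(corpus$motifs, paths$motifs, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    ppi <- generatePpiTable(
      nTargets = .cfgGet(config, "simulate", "n_targets", 5L),
      partnersPerTarget = .cfgGet(config, "simulate",
                                  "partners_per_target", 3L),
      seed = stageSeed(seed, "ppi"))
    utils::write.table(ppi$records, paths$ppi, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    writeFasta(ppi$partnerSequences, paths$partnerFasta)
    utils::write.table(ppi$truth, paths$partnerTruth, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }

  if ("build_dataset" %in% stages) {
    say("stage build_dataset")
    sequences <- readFasta(paths$fasta)
    windows <- readDerivedPeptides(paths$windows)
    lens <- stats::setNames(Biostrings::width(sequences),
                            names(sequences))
    windows <- filterPeptideRecords(windows, lens)
    chars <- as.character(sequences)
    profiles <- lapply(names(chars), function(id) {
      recs <- windows[windows$sequence_id == id, , drop = FALSE]
      windowsToPositions(recs, chars[[id]], id)
    })
    profiles <- mergeDuplicateProfiles(profiles)
    labeled <- lapply(profiles, binarizeProfile,
                      threshold = .cfgGet(config, "build_dataset",
                                          "threshold", -1))
    writeLabeledDataset(labeled, paths$dataset, profiles = profiles)
    keepIds <- vapply(profiles, sequenceId, character(1))
    fr <- .cfgGet(config, "build_dataset", "fractions",
                  c(0.77, 0.10, 0.13))
    split <- clusterSplit(
      chars[keepIds],
      minIdentity = .cfgGet(config, "build_dataset", "min_identity",
                            0.25),
      fractions = fr,
      forcedTestIds = .cfgGet(config, "build_dataset", "forced_test",
                              character()),
      seed = stageSeed(seed, "build_dataset"))
    writeSplit(split, paths$split)
  }

  model <- NULL
  loadSets <- function() {
    labeled <- readLabeledDataset(paths$dataset)
    split <- readSplit(paths$split)
    ids <- function(s) split$sequence_id[split$split == s]
    list(train = labeled[intersect(names(labeled), ids("train"))],
         val = labeled[intersect(names(labeled), ids("val"))],
         test = labeled[intersect(names(labeled), ids("test"))])
  }

  if ("train" %in% stages) {
    say("stage train")
    sets <- loadSets()
    backend <- .backendFromConfig(config, seed)
    fit <- trainInterfaceModel(
      backend, sets$train, sets$val,
      hidden = .cfgGet(config, "train", "hidden", c(256L, 128L, 64L)),
      activation = .cfgGet(config, "train", "activation", "relu"),
      trainConfig = trainingConfig(
        learningRate = .cfgGet(config, "train", "learning_rate", 1e-3),
        batchSize = .cfgGet(config, "train", "batch_size", 8L),
        maxEpochs = .cfgGet(config, "train", "max_epochs", 30L),
        patience = .cfgGet(config, "train", "patience", 2L),
        seed = stageSeed(seed, "train")))
    saveModel(fit$model, paths$model)
    jsonlite::write_json(fit$report, paths$trainReport,
                         auto_unbox = TRUE, pretty = TRUE, digits = 10)
    say(sprintf("  best epoch %d (%s), val loss %.4f",
                fit$report$bestEpoch, fit$report$stopReason,
                min(fit$report$valLoss)))
  }

  getModel <- function() {
    if (is.null(model)) model <<- loadModel(paths$model)
    model
  }

  if ("predict" %in% stages) {
    say("stage predict")
    sets <- loadSets()
    rows <- lapply(sets$test, function(ls) {
      tr <- predict(getModel(), residues(ls), sequenceId = sequenceId(ls))
      data.frame(sequence_id = sequenceId(tr),
                 position = seq_along(probabilities(tr)),
                 value = .fmtNum(probabilities(tr)))
    })
    utils::write.table(do.call(rbind, rows), paths$tracks, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }

  if ("prioritize" %in% stages) {
    say("stage prioritize")
    records <- readPpiRecords(paths$ppi)
    filtered <- applyPolicy(records,
                            .cfgGet(config, "prioritize", "policy",
                                    "lenient"))
    table <- buildPartnerTable(filtered)
    partnerSequences <- readFasta(paths$partnerFasta)
    targets <- .cfgGet(config, "prioritize", "target",
                       sort(unique(records$protein_a)))
    targets <- setdiff(targets, "DECOY")
    cands <- do.call(rbind, lapply(targets, function(tg) {
      cc <- prioritizeForTarget(
        tg, table, getModel(), partnerSequences,
        L = .cfgGet(config, "prioritize", "peptide_length", 15L),
        topN = .cfgGet(config, "prioritize", "top_n", 6L),
        allowOverlap = .cfgGet(config, "prioritize", "allow_overlap",
                               FALSE))
      if (nrow(cc)) cbind(target = tg, cc) else NULL
    }))
    utils::write.table(
      transform(cands, score = .fmtNum(score)), paths$candidates,
      sep = "\t", quote = FALSE, row.names = FALSE)
  }

  if ("evaluate" %in% stages) {
    say("stage evaluate")
    sets <- loadSets()
    profiles <- .profilesFromDataset(paths$dataset)
    tracks <- lapply(sets$test, function(ls)
      predict(getModel(), residues(ls), sequenceId = sequenceId(ls)))
    metrics <- evaluateTracks(
      tracks, sets$test, profiles = profiles,
      n = .cfgGet(config, "evaluate", "n", 10L),
      tau = .cfgGet(config, "evaluate", "tau", -1),
      average = .cfgGet(config, "evaluate", "average", "macro"))
    jsonlite::write_json(metrics, paths$metrics, auto_unbox = TRUE,
                         pretty = TRUE, digits = 10)
    say(sprintf("  test AUROC %.3f, Spearman %.3f", metrics$auroc,
                metrics$spearman))
  }

  invisible(paths)
}

## Rebuild PositionEnergyProfile objects from a labeled-dataset TSV
## (energy column + mask -> coverage 0/1 marker).
.profilesFromDataset <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          na.strings = "NA")
  out <- lapply(split(df, factor(df$sequence_id,
                                 levels = unique(df$sequence_id))),
                function(d) {
    d <- d[order(d$position), , drop = FALSE]
    energy <- as.numeric(d$energy)
    PositionEnergyProfile(d$sequence_id[[1L]],
                          paste(d$residue, collapse = ""),
                          energy, as.integer(!is.na(energy)))
  })
  out
}
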