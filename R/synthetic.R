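## Seeded synthetic-data generators.
##
## The generators plant compositionally biased "binding motifs" into
## otherwise-uniform random protein sequences and assign every position a
## true binding energy: a negative shift at motif positions plus Gaussian
## noise. Window records, labels, and PPI tables derived from these
## energies carry the statistical structure the pipeline assumes, so
## every stage is testable without downloads. The motif signal is purely
## compositional (a biased residue alphabet), i.e. recoverable from
## sequence alone by a context-window classifier.

#' Configuration of the synthetic corpus generator
#'
#' Defaults describe the standard study conditions used throughout the
#' package's tests: 200 sequences of length 60-120, one motif of length
#' 8-12 per sequence, motif residues drawn with probability 0.9 from the
#' hydrophobic subset `AVLIFMWY` (uniform over the 20 amino acids
#' otherwise), a mean energy shift of -2 REU at motif positions and
#' Gaussian noise with standard deviation 0.5. Under these defaults a
#' background (non-motif) position is labeled binding with probability
#' `pnorm(-1, 0, 0.5)` = `pnorm(-2)`, about 2.3%.
#'
#' @param nSequences Number of sequences.
#' @param lengthRange Integer `(min, max)` sequence length.
#' @param motifLengthRange Integer `(min, max)` motif length.
#' @param motifsPerSequence Motifs planted per sequence (0 allowed).
#' @param motifAlphabetBias Probability mass placed on the hydrophobic
#'   subset inside motifs, in \[0, 1\].
#' @param energyEffect Mean REU shift at motif positions (default -2).
#' @param noiseSigma Gaussian noise SD on the true energy (>= 0;
#'   0 gives the deterministic noiseless limit).
#' @param seed Integer seed.
#' @return Validated configuration list.
#' @export
generatorConfig <- function(nSequences = 200L,
                            lengthRange = c(60L, 120L),
                            motifLengthRange = c(8L, 12L),
                            motifsPerSequence = 1L,
                            motifAlphabetBias = 0.9,
                            energyEffect = -2.0,
                            noiseSigma = 0.5,
                            seed = 1L) {
  stopifnot(nSequences >= 1L,
            length(lengthRange) == 2L, lengthRange[1L] <= lengthRange[2L],
            lengthRange[1L] >= 1L,
            length(motifLengthRange) == 2L,
            motifLengthRange[1L] <= motifLengthRange[2L],
            motifsPerSequence >= 0L,
            motifAlphabetBias >= 0, motifAlphabetBias <= 1,
            noiseSigma >= 0)
  if (motifsPerSequence > 0L && motifLengthRange[2L] > lengthRange[1L])
    stop("motifs may be longer than the shortest sequence")
  list(nSequences = as.integer(nSequences),
       lengthRange = as.integer(lengthRange),
       motifLengthRange = as.integer(motifLengthRange),
       motifsPerSequence = as.integer(motifsPerSequence),
       motifAlphabetBias = motifAlphabetBias,
       energyEffect = energyEffect,
       noiseSigma = noiseSigma,
       seed = as.integer(seed))
}

.sampleMotifResidues <- function(n, bias) {
  useHydro <- stats::runif(n) < bias
  out <- character(n)
  out[useHydro] <- sample(.HYDROPHOBIC, sum(useHydro), replace = TRUE)
  out[!useHydro] <- sample(.AA20, sum(!useHydro), replace = TRUE)
  out
}

## Non-overlapping motif placements within a length-n sequence; simple
## rejection sampling (motifsPerSequence is small).
.placeMotifs <- function(n, count, lenRange) {
  placed <- matrix(integer(0), ncol = 2L)
  for (m in seq_len(count)) {
    for (attempt in 1:200) {
      ml <- sample(lenRange[1L]:lenRange[2L], 1L)
      if (ml > n) stop("motif longer than sequence")
      st <- sample.int(n - ml + 1L, 1L)
      span <- c(st, st + ml - 1L)
      clash <- nrow(placed) && any(placed[, 1L] <= span[2L] &
                                   placed[, 2L] >= span[1L])
      if (!clash) {
        placed <- rbind(placed, span)
        break
      }
      if (attempt == 200L)
        stop("could not place ", count, " non-overlapping motifs in a ",
             "length-", n, " sequence")
    }
  }
  placed
}

#' Generate a labeled synthetic corpus
#'
#' Background residues are uniform over the 20 amino acids; motif
#' residues are drawn from the biased distribution. The true
#' per-position energy is `energyEffect * 1[motif] + N(0, noiseSigma)`,
#' and labels are derived by running that energy through
#' [binarizeProfile()] (threshold -1), so the generator and the dataset
#' builder share one labeling rule by construction. Fully deterministic
#' given the seed.
#'
#' @param cfg A [generatorConfig()] list.
#' @return List with components `sequences` (named `AAStringSet`),
#'   `labeled` (named list of [LabeledSequence-class]), `energies`
#'   (named list of numeric true-energy vectors), and `motifs`
#'   (`data.frame` of planted coordinates: `sequence_id`, `start`,
#'   `end`).
#' @export
generateLabeledCorpus <- function(cfg = generatorConfig()) {
  .withSeed(cfg$seed, {
    ids <- sprintf("syn%04d", seq_len(cfg$nSequences))
    seqs <- character(cfg$nSequences)
    energiesList <- vector("list", cfg$nSequences)
    motifRows <- list()
    for (i in seq_len(cfg$nSequences)) {
      n <- sample(cfg$lengthRange[1L]:cfg$lengthRange[2L], 1L)
      chars <- sample(.AA20, n, replace = TRUE)
      motifInd <- logical(n)
      placed <- .placeMotifs(n, cfg$motifsPerSequence,
                             cfg$motifLengthRange)
      for (r in seq_len(nrow(placed))) {
        span <- placed[r, 1L]:placed[r, 2L]
        chars[span] <- .sampleMotifResidues(length(span),
                                            cfg$motifAlphabetBias)
        motifInd[span] <- TRUE
        motifRows[[length(motifRows) + 1L]] <-
          data.frame(sequence_id = ids[i], start = placed[r, 1L],
                     end = placed[r, 2L])
      }
      noise <- if (cfg$noiseSigma > 0)
        stats::rnorm(n, 0, cfg$noiseSigma) else numeric(n)
      energiesList[[i]] <- cfg$energyEffect * motifInd + noise
      seqs[i] <- paste(chars, collapse = "")
    }
    sequences <- Biostrings::AAStringSet(seqs)
    names(sequences) <- ids
    labeled <- lapply(seq_len(cfg$nSequences), function(i) {
      prof <- PositionEnergyProfile(ids[i], seqs[i], energiesList[[i]],
                                    rep(1L, nchar(seqs[i])))
      binarizeProfile(prof)
    })
    names(labeled) <- ids
    names(energiesList) <- ids
    motifs <- if (length(motifRows)) do.call(rbind, motifRows)
      else data.frame(sequence_id = character(), start = integer(),
                      end = integer())
    list(sequences = sequences, labeled = labeled,
         energies = energiesList, motifs = motifs)
  })
}

#' Derive fixed-length window records from a synthetic corpus
#'
#' Each window's REU is the mean of the true per-position energies it
#' covers — the exact inverse of the builder's position-averaging, so in
#' the noiseless limit [windowsToPositions()] recovers the planted
#' energies up to boundary smoothing.
#'
#' @param corpus Output of [generateLabeledCorpus()].
#' @param windowLength Window length (default 10).
#' @return `data.frame` of window records (`sequence_id`,
#'   `window_start`, `window_length`, `reu`).
#' @export
generateWindowRecords <- function(corpus, windowLength = 10L) {
  rows <- lapply(names(corpus$energies), function(id) {
    e <- corpus$energies[[id]]
    n <- length(e)
    if (n < windowLength) return(NULL)
    starts <- seq_len(n - windowLength + 1L)
    csum <- cumsum(c(0, e))
    reu <- (csum[starts + windowLength] - csum[starts]) / windowLength
    data.frame(sequence_id = id, window_start = starts,
               window_length = as.integer(windowLength), reu = reu)
  })
  do.call(rbind, rows)
}

#' Generate a synthetic PPI table with motif-bearing partner sequences
#'
#' Creates `nTargets` target symbols, each with `partnersPerTarget`
#' partner proteins. Every partner sequence contains exactly one planted
#' motif, designated as its true interface with the target (coordinates
#' returned for measuring prioritizer recall). The interaction records
#' cycle through evidence classes spanning both filter policies — IMEX,
#' BIOGRID/LTP, BIOGRID/HTP, PROPER p = 0.005, PROPER p = 0.03 — all of
#' which survive the lenient policy; additional decoy records
#' (PROPER p = 0.5) survive neither.
#'
#' @param nTargets Number of target proteins.
#' @param partnersPerTarget Partners per target.
#' @param seed Integer seed.
#' @param partnerLengthRange Partner sequence length range.
#' @param motifLengthRange Planted-motif length range.
#' @param motifAlphabetBias Motif composition bias (as in
#'   [generatorConfig()]).
#' @param noiseSigma Noise SD on partner energies (default 0: noiseless).
#' @return List with `records` (PPI `data.frame`), `partnerSequences`
#'   (named `AAStringSet`), `truth` (`data.frame`: `target`,
#'   `partner_id`, `motif_start`, `motif_end`).
#' @export
generatePpiTable <- function(nTargets, partnersPerTarget, seed = 1L,
                             partnerLengthRange = c(60L, 120L),
                             motifLengthRange = c(8L, 12L),
                             motifAlphabetBias = 0.9,
                             noiseSigma = 0) {
  stopifnot(nTargets >= 1L, partnersPerTarget >= 1L)
  cfg <- generatorConfig(
    nSequences = nTargets * partnersPerTarget,
    lengthRange = partnerLengthRange,
    motifLengthRange = motifLengthRange,
    motifsPerSequence = 1L,
    motifAlphabetBias = motifAlphabetBias,
    noiseSigma = noiseSigma,
    seed = seed)
  corpus <- generateLabeledCorpus(cfg)
  partnerIds <- sprintf("P%04d", seq_len(nTargets * partnersPerTarget))
  partnerSequences <- corpus$sequences
  names(partnerSequences) <- partnerIds
  targets <- rep(sprintf("T%03d", seq_len(nTargets)),
                 each = partnersPerTarget)
  evidenceCycle <- data.frame(
    source = c("IMEX", "BIOGRID", "BIOGRID", "PROPER", "PROPER"),
    evidence = c(NA, "LTP", "HTP", NA, NA),
    p_value = c(NA, NA, NA, 0.005, 0.03))
  idx <- ((seq_along(partnerIds) - 1L) %% nrow(evidenceCycle)) + 1L
  records <- data.frame(protein_a = targets, protein_b = partnerIds,
                        source = evidenceCycle$source[idx],
                        evidence = evidenceCycle$evidence[idx],
                        p_value = evidenceCycle$p_value[idx],
                        stringsAsFactors = FALSE)
  ## decoys that survive no policy
  decoys <- data.frame(protein_a = unique(targets),
                       protein_b = "DECOY",
                       source = "PROPER", evidence = NA,
                       p_value = 0.5, stringsAsFactors = FALSE)
  truth <- corpus$motifs
  truth$partner_id <- partnerIds[match(truth$sequence_id,
                                       names(corpus$sequences))]
  truth <- data.frame(target = targets[match(truth$partner_id,
                                             partnerIds)],
                      partner_id = truth$partner_id,
                      motif_start = truth$start,
                      motif_end = truth$end,
                      stringsAsFactors = FALSE)
  list(records = rbind(records, decoys),
       partnerSequences = partnerSequences, truth = truth)
}
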