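## Guide-peptide prioritization: cut ranked fixed-length candidate
## peptides from a partner protein's predicted interface-probability
## curve, keeping only windows that are local maxima of the window-score
## profile.

#' Mean probability over every fixed-length window
#'
#' `s(i)` is the arithmetic mean of the per-position probabilities over
#' positions `i .. i + L - 1`, for every valid 1-based start
#' `i = 1 .. n - L + 1`. Masked positions are excluded from the mean; a
#' window whose positions are all masked gets a missing (`NA`) score.
#'
#' @param track A [PredictionTrack-class] (or numeric probability vector).
#' @param L Window (peptide) length; must not exceed the sequence length.
#' @param mask Optional logical per-position validity mask.
#' @return Numeric vector of window scores indexed by start position.
#' @export
#' @examples
#' p <- c(0.1, 0.9, 0.9, 0.9, 0.1, 0.1, 0.8, 0.8, 0.8, 0.1)
#' round(windowScores(PredictionTrack("s", p), 3), 4)
windowScores <- function(track, L, mask = NULL) {
  p <- if (methods::is(track, "PredictionTrack")) probabilities(track)
       else as.numeric(track)
  n <- length(p)
  L <- as.integer(L)
  if (L < 1L) stop("window length must be positive")
  if (L > n)
    stop("window length ", L, " exceeds sequence length ", n)
  if (is.null(mask)) mask <- rep(TRUE, n)
  stopifnot(length(mask) == n)
  ## direct per-window means (not a cumulative-sum trick): windows with
  ## identical contents must score bit-identically so that the
  ## smaller-start tie rule downstream is exact
  starts <- seq_len(n - L + 1L)
  vapply(starts, function(i) {
    idx <- i:(i + L - 1L)
    keep <- mask[idx]
    if (!any(keep)) return(NA_real_)
    mean(p[idx][keep])
  }, numeric(1))
}

#' Discrete local maxima of a window-score profile
#'
#' An index is a local maximum iff its score strictly exceeds both
#' neighbors. A plateau of equal values strictly above both flanking
#' values contributes its leftmost index; a boundary index qualifies if
#' it exceeds its single neighbor; a constant profile has a single
#' maximum at index 1. Missing (`NA`) scores rank below every finite
#' score and are never returned as maxima.
#'
#' @param scores Numeric vector of window scores (NA allowed).
#' @return Integer vector of maximum start positions, ascending.
#' @export
#' @examples
#' localMaxima(c(0.6333, 0.9, 0.6333, 0.3667, 0.3333, 0.5667, 0.8, 0.5667))
localMaxima <- function(scores) {
  stopifnot(length(scores) >= 1L)
  s <- ifelse(is.na(scores), -Inf, scores)
  r <- rle(s)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  vals <- r$values
  k <- length(vals)
  left <- c(-Inf, vals[-k])
  right <- c(vals[-1L], -Inf)
  isMax <- is.finite(vals) & vals > left & vals > right
  as.integer(starts[isMax])
}

#' Select ranked, non-overlapping candidate peptides from one track
#'
#' Windows at local maxima of the length-`L` window-score profile are
#' ranked by score descending (ties broken by smaller start). By default
#' a greedy pass then keeps a window only if it shares no position with
#' an already-kept one; `allowOverlap = TRUE` skips that filter. At most
#' `topN` candidates are returned; if fewer maxima exist, all are
#' returned with a note.
#'
#' @param track A [PredictionTrack-class] for the partner sequence.
#' @param sequence The partner residue string (character, `AAString`, or
#'   length-1 `AAStringSet`); its length must match the track.
#' @param L Peptide length (default 15).
#' @param topN Maximum number of candidates (>= 1).
#' @param allowOverlap Keep overlapping windows (default `FALSE`).
#' @param mask Optional per-position validity mask.
#' @return `data.frame` with columns `rank`, `partner_id`, `start`,
#'   `end`, `length`, `score`, `peptide`; ranks contiguous from 1.
#' @export
selectCandidates <- function(track, sequence, L = 15L, topN = 6L,
                             allowOverlap = FALSE, mask = NULL) {
  stopifnot(methods::is(track, "PredictionTrack"))
  if (topN < 1L) stop("topN must be at least 1")
  res <- .asResidues(sequence)
  if (nchar(res) != length(probabilities(track)))
    stop("sequence length does not match prediction track")
  s <- windowScores(track, L, mask = mask)
  maxima <- localMaxima(s)
  ord <- maxima[order(-s[maxima], maxima)]
  chosen <- integer(0)
  occupied <- logical(nchar(res))
  for (st in ord) {
    span <- st:(st + L - 1L)
    if (!allowOverlap && any(occupied[span])) next
    chosen <- c(chosen, st)
    occupied[span] <- TRUE
    if (length(chosen) == topN) break
  }
  if (length(chosen) < topN)
    message("selectCandidates: only ", length(chosen),
            " candidate(s) available for '", sequenceId(track),
            "' (requested ", topN, ")")
  if (!length(chosen))
    return(.emptyCandidates())
  data.frame(rank = seq_along(chosen),
             partner_id = sequenceId(track),
             start = as.integer(chosen),
             end = as.integer(chosen + L - 1L),
             length = L,
             score = s[chosen],
             peptide = substring(res, chosen, chosen + L - 1L),
             stringsAsFactors = FALSE)
}

.emptyCandidates <- function() {
  data.frame(rank = integer(), partner_id = character(),
             start = integer(), end = integer(), length = integer(),
             score = numeric(), peptide = character(),
             stringsAsFactors = FALSE)
}

#' Prioritize guide peptides for a target across all its partners
#'
#' Looks up the target's interaction partners, predicts an interface
#' probability track for each partner sequence, cuts candidates per
#' partner with [selectCandidates()], pools them, re-ranks globally by
#' score (ties by partner id, then start) and returns the overall top
#' `topN` with partner provenance. A target with no partners yields an
#' empty table and a warning.
#'
#' @param targetId Protein symbol of the degradation target.
#' @param partnerTable A [PartnerTable-class] from [buildPartnerTable()].
#' @param model A trained [InterfaceModel-class].
#' @param partnerSequences Named `AAStringSet` covering every partner.
#' @param L Peptide length.
#' @param topN Candidates returned after global pooling (also the
#'   per-partner cap before pooling).
#' @param allowOverlap Passed to [selectCandidates()].
#' @return Candidate `data.frame` as in [selectCandidates()].
#' @export
prioritizeForTarget <- function(targetId, partnerTable, model,
                                partnerSequences, L = 15L, topN = 6L,
                                allowOverlap = FALSE) {
  stopifnot(methods::is(partnerTable, "PartnerTable"))
  partners <- partnersOf(partnerTable, targetId)
  if (!length(partners)) {
    warning("target '", targetId, "' has no partners under the current ",
            "filter policy")
    return(.emptyCandidates())
  }
  if (methods::is(partnerSequences, "XStringSet"))
    partnerSequences <- as.character(partnerSequences)
  missing <- setdiff(partners, names(partnerSequences))
  if (length(missing))
    stop("no sequence provided for partner(s): ",
         paste(missing, collapse = ", "))
  pooled <- do.call(rbind, lapply(partners, function(pid) {
    tr <- predict(model, partnerSequences[[pid]], sequenceId = pid)
    suppressMessages(
      selectCandidates(tr, partnerSequences[[pid]], L = L, topN = topN,
                       allowOverlap = allowOverlap))
  }))
  if (is.null(pooled) || !nrow(pooled)) return(.emptyCandidates())
  pooled <- pooled[order(-pooled$score, pooled$partner_id,
                         pooled$start), , drop = FALSE]
  pooled <- utils::head(pooled, topN)
  pooled$rank <- seq_len(nrow(pooled))
  rownames(pooled) <- NULL
  pooled
}

#' Write candidate peptides as TSV (and optionally FASTA)
#'
#' @param candidates Candidate `data.frame`.
#' @param path Output TSV path.
#' @param fastaPath Optional FASTA path for the peptide sequences.
#' @return `path`, invisibly.
#' @export
writeCandidates <- function(candidates, path, fastaPath = NULL) {
  out <- candidates[, c("rank", "partner_id", "start", "end", "length",
                        "score", "peptide")]
  out$score <- .fmtNum(out$score)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(fastaPath) && nrow(candidates)) {
    seqs <- Biostrings::AAStringSet(candidates$peptide)
    names(seqs) <- sprintf("%s_%d_%d", candidates$partner_id,
                           candidates$start, candidates$end)
    Biostrings::writeXStringSet(seqs, fastaPath)
  }
  invisible(path)
}
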