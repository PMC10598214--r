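## Building per-position labels from derived-peptide window energies.
##
## The label source is a table of fixed-length linear peptides ("windows")
## scanned along each chain, each with a binding-energy score in Rosetta
## energy units (REU; lower = more favorable). The builder averages window
## scores onto residue positions, merges duplicate chains, thresholds the
## per-position energy into binary interface labels, and produces a
## homology-aware train/validation/test split.

#' Deduplicate interaction records by partner pair and buried surface area
#'
#' Two records of the same (unordered) partner pair describe the same
#' interaction unless their buried surface areas differ by more than
#' 100 A^2. Records are scanned greedily in input order; a record is
#' dropped iff an already-kept record of the same pair lies within
#' 100 A^2 of it. Records of distinct pairs are always kept.
#'
#' @param records `data.frame` with columns `partner_a`, `partner_b`,
#'   `bsa` (buried surface area, A^2, nonnegative) and `entry_id`.
#' @return The kept subset of `records`, original order preserved.
#' @export
#' @examples
#' recs <- data.frame(partner_a = c("A", "A", "A"),
#'                    partner_b = c("B", "B", "C"),
#'                    bsa = c(500, 550, 500),
#'                    entry_id = c("e1", "e2", "e3"))
#' dedupeInteractions(recs)  # drops e2 (|550 - 500| <= 100)
dedupeInteractions <- function(records) {
  .checkColumns(records, c("partner_a", "partner_b", "bsa", "entry_id"),
                "interaction table")
  if (any(is.na(records$bsa)) || any(records$bsa < 0))
    stop("buried surface area must be nonnegative")
  key <- ifelse(records$partner_a <= records$partner_b,
                paste(records$partner_a, records$partner_b, sep = "\r"),
                paste(records$partner_b, records$partner_a, sep = "\r"))
  kept <- logical(nrow(records))
  keptBsa <- split(numeric(0), character(0))  # pair key -> kept BSAs
  for (i in seq_len(nrow(records))) {
    prev <- keptBsa[[key[i]]]
    if (is.null(prev) || all(abs(prev - records$bsa[i]) > 100)) {
      kept[i] <- TRUE
      keptBsa[[key[i]]] <- c(prev, records$bsa[i])
    }
  }
  records[kept, , drop = FALSE]
}

#' Filter derived-peptide window records
#'
#' Applies the two record-level filters used when assembling the labeled
#' dataset: windows with REU below -1000 are discarded as numerical
#' artifacts, and every window of a sequence whose length falls outside
#' the open interval (50, 1023) is discarded (strict: lengths 51..1022
#' are kept). Counts dropped by each rule are reported via `message()`.
#'
#' @param records `data.frame` with columns `sequence_id`, `window_start`
#'   (1-based), `window_length`, `reu`.
#' @param seqLengths Named numeric vector mapping sequence id to length.
#' @return The surviving subset of `records`.
#' @export
filterPeptideRecords <- function(records, seqLengths) {
  .checkColumns(records,
                c("sequence_id", "window_start", "window_length", "reu"),
                "derived-peptide table")
  if (!nrow(records)) return(records)
  unknown <- setdiff(unique(records$sequence_id), names(seqLengths))
  if (length(unknown))
    stop("records reference sequences with unknown length: ",
         paste(unknown, collapse = ", "))
  len <- seqLengths[records$sequence_id]
  oob <- records$window_start < 1 |
    records$window_start + records$window_length - 1 > len
  if (any(oob)) {
    i <- which(oob)[1L]
    stop(sprintf(
      "window out of sequence bounds: %s start %d length %d (sequence length %d)",
      records$sequence_id[i], records$window_start[i],
      records$window_length[i], len[i]))
  }
  lowReu <- records$reu < -1000
  badLen <- len <= 50 | len >= 1023
  message(sprintf(
    "filterPeptideRecords: dropped %d record(s) with REU < -1000, %d on sequences of length outside 51..1022",
    sum(lowReu), sum(badLen & !lowReu)))
  records[!(lowReu | badLen), , drop = FALSE]
}

#' Average window energies onto residue positions
#'
#' Each record scores a contiguous window `[window_start,
#' window_start + window_length - 1]`. The per-position energy is the
#' arithmetic mean REU over all windows covering that position, and the
#' coverage is the number of such windows. Positions covered by no window
#' are explicitly missing (`NA` energy, coverage 0). Zero records yield an
#' all-missing profile, not an error.
#'
#' @param records `data.frame` of window records, all belonging to
#'   `sequence`.
#' @param sequence The sequence (character, `AAString`, or named length-1
#'   `AAStringSet`).
#' @param sequenceId Identifier; defaults to the `AAStringSet` name or the
#'   records' common `sequence_id`.
#' @return A [PositionEnergyProfile-class].
#' @export
#' @examples
#' recs <- data.frame(sequence_id = "s", window_start = 1:3,
#'                    window_length = 10, reu = c(-3, -2, -1))
#' prof <- windowsToPositions(recs, paste(rep("A", 12), collapse = ""), "s")
#' energies(prof)[c(1, 3, 12)]  # -3, -2, -1
windowsToPositions <- function(records, sequence, sequenceId = NULL) {
  res <- .asResidues(sequence)
  n <- nchar(res)
  if (is.null(sequenceId))
    sequenceId <- .sequenceIdOf(sequence,
                                if (nrow(records)) records$sequence_id[[1L]]
                                else NA_character_)
  if (nrow(records)) {
    .checkColumns(records,
                  c("sequence_id", "window_start", "window_length", "reu"),
                  "derived-peptide table")
    if (any(records$sequence_id != sequenceId))
      stop("all records must belong to sequence '", sequenceId, "'")
    if (any(records$window_start < 1) ||
        any(records$window_start + records$window_length - 1 > n))
      stop("window out of sequence bounds for '", sequenceId, "'")
  }
  sums <- numeric(n)
  cov <- integer(n)
  for (i in seq_len(nrow(records))) {
    idx <- records$window_start[i]:(records$window_start[i] +
                                    records$window_length[i] - 1L)
    sums[idx] <- sums[idx] + records$reu[i]
    cov[idx] <- cov[idx] + 1L
  }
  energy <- ifelse(cov > 0L, sums / cov, NA_real_)
  PositionEnergyProfile(sequenceId, res, energy, cov)
}

#' Merge profiles of identical residue strings
#'
#' The label dataset must not contain redundant entries: profiles whose
#' residue strings are exactly equal are merged into one. At each
#' position the merged energy is the unweighted mean of the member
#' energies that are non-missing there (a position missing in some
#' members takes the mean of the others); coverages are summed. The
#' merged profile carries the lexicographically smallest member id and
#' records all member ids in its `mergedIds` slot.
#'
#' @param profiles List of [PositionEnergyProfile-class] objects.
#' @return List of merged profiles, one per distinct residue string, in
#'   order of first appearance.
#' @export
mergeDuplicateProfiles <- function(profiles) {
  stopifnot(all(vapply(profiles, methods::is, logical(1),
                       "PositionEnergyProfile")))
  seqs <- vapply(profiles, function(p) p@residues, character(1))
  groups <- split(seq_along(profiles), factor(seqs, levels = unique(seqs)))
  lapply(groups, function(idx) {
    members <- profiles[idx]
    if (length(members) == 1L) return(members[[1L]])
    lens <- vapply(members, function(p) length(p@energy), integer(1))
    stopifnot(length(unique(lens)) == 1L)  # equal residues => equal length
    E <- do.call(rbind, lapply(members, function(p) p@energy))
    C <- do.call(rbind, lapply(members, function(p) p@coverage))
    cov <- as.integer(colSums(C))
    energy <- colMeans(E, na.rm = TRUE)
    energy[cov == 0L] <- NA_real_
    ids <- sort(vapply(members, function(p) p@sequenceId, character(1)))
    PositionEnergyProfile(ids[[1L]], members[[1L]]@residues, energy, cov,
                          mergedIds = ids)
  })
}

#' Threshold a per-position energy profile into binary interface labels
#'
#' A position is labeled 1 (binding) iff its mean energy is strictly below
#' `threshold` (default -1 REU). Positions with missing energy are labeled
#' 0 and flagged `FALSE` in the mask so they are excluded from loss and
#' metrics rather than treated as confident negatives.
#'
#' @param profile A [PositionEnergyProfile-class].
#' @param threshold Energy cutoff; strictly-less-than is binding.
#' @param weight Per-sequence loss weight carried into the label object.
#' @return A [LabeledSequence-class].
#' @export
#' @examples
#' p <- PositionEnergyProfile("s", "MKV", c(-1.5, -1, NA), c(1L, 1L, 0L))
#' siteLabels(binarizeProfile(p))  # 1 0 0
#' labelMask(binarizeProfile(p))   # TRUE TRUE FALSE
binarizeProfile <- function(profile, threshold = -1, weight = 1.0) {
  stopifnot(methods::is(profile, "PositionEnergyProfile"))
  e <- profile@energy
  labels <- as.integer(!is.na(e) & e < threshold)
  mask <- profile@coverage > 0L
  LabeledSequence(profile@sequenceId, profile@residues, labels, mask,
                  weight)
}

## ---------------------------------------------------------------------------
## Tabular readers/writers for the builder's interfaces
## ---------------------------------------------------------------------------

#' Read a derived-peptide window table
#'
#' @param path TSV with columns `sequence_id`, `window_start`,
#'   `window_length`, `reu`.
#' @return `data.frame` of window records.
#' @export
readDerivedPeptides <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  .checkColumns(df, c("sequence_id", "window_start", "window_length", "reu"),
                "derived-peptide table")
  df$window_start <- as.integer(df$window_start)
  df$window_length <- as.integer(df$window_length)
  df$reu <- as.numeric(df$reu)
  df
}

#' Write labeled sequences (and their energies) as a flat TSV
#'
#' One row per position with columns `sequence_id`, `position`, `residue`,
#' `energy`, `label`, `mask`.
#'
#' @param labeled List of [LabeledSequence-class].
#' @param path Output path.
#' @param profiles Optional list of [PositionEnergyProfile-class] matched
#'   by sequence id supplying the `energy` column (else `NA`).
#' @return `path`, invisibly.
#' @export
writeLabeledDataset <- function(labeled, path, profiles = NULL) {
  profIds <- if (!is.null(profiles))
    vapply(profiles, sequenceId, character(1)) else character()
  rows <- lapply(labeled, function(ls) {
    n <- nchar(ls@residues)
    energy <- rep(NA_real_, n)
    j <- match(ls@sequenceId, profIds)
    if (!is.na(j)) energy <- profiles[[j]]@energy
    data.frame(sequence_id = ls@sequenceId, position = seq_len(n),
               residue = strsplit(ls@residues, "")[[1L]],
               energy = .fmtNum(energy), label = ls@labels,
               mask = as.integer(ls@mask))
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a labeled dataset TSV back into LabeledSequence objects
#'
#' @param path TSV written by [writeLabeledDataset()].
#' @return Named list of [LabeledSequence-class].
#' @export
readLabeledDataset <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          na.strings = "NA")
  .checkColumns(df, c("sequence_id", "position", "residue", "label", "mask"),
                "labeled dataset")
  out <- lapply(split(df, factor(df$sequence_id,
                                 levels = unique(df$sequence_id))),
                function(d) {
    d <- d[order(d$position), , drop = FALSE]
    LabeledSequence(d$sequence_id[[1L]],
                    paste(d$residue, collapse = ""),
                    d$label, as.logical(d$mask))
  })
  out
}

#' Write / read a split assignment table
#'
#' @param split `data.frame` with columns `sequence_id`, `cluster_id`,
#'   `split` as produced by [clusterSplit()].
#' @param path TSV path.
#' @return `path` (write) or the split `data.frame` (read).
#' @export
writeSplit <- function(split, path) {
  .checkColumns(split, c("sequence_id", "cluster_id", "split"),
                "split table")
  utils::write.table(split, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeSplit
#' @export
readSplit <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  .checkColumns(df, c("sequence_id", "cluster_id", "split"), "split table")
  df
}
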