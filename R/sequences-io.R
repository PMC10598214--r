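## FASTA and score-track input/output.

#' Read protein sequences from a FASTA file
#'
#' Parses a (wrapped or unwrapped) multi-record FASTA file into an
#' `AAStringSet`. Residues are uppercased and the nonstandard one-letter
#' codes `B, J, O, U, Z, *` are remapped to `X` with a warning, so every
#' returned sequence lies in the 20-letter amino-acid alphabet plus `X`.
#' Record order is preserved.
#'
#' @param path Path to a FASTA file.
#' @return A [Biostrings::AAStringSet] named by FASTA headers (first
#'   whitespace-delimited token).
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">a", "MKV", ">b", "mkvw"), fa)
#' readFasta(fa)
readFasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file does not exist: ", path)
  lines <- readLines(path, warn = FALSE)
  headers <- grep("^>", lines)
  if (!length(headers)) stop("no sequences in FASTA file: ", path)
  set <- Biostrings::readAAStringSet(path)
  if (!length(set)) stop("no sequences in FASTA file: ", path)
  if (any(Biostrings::width(set) == 0L)) {
    bad <- headers[which(Biostrings::width(set) == 0L)[1L]]
    stop("malformed FASTA record (header without sequence) at line ", bad,
         " of ", path)
  }
  ## keep only the id token of each header
  names(set) <- sub("[[:space:]].*$", "", names(set))
  chars <- toupper(as.character(set))
  pat <- paste0("[", gsub("\\*", "\\\\*", paste(.NONSTANDARD, collapse = "")),
                "]")
  hit <- grepl(pat, chars)
  if (any(hit)) {
    warning("nonstandard residues (B/J/O/U/Z/*) mapped to 'X' in: ",
            paste(names(set)[hit], collapse = ", "))
    chars <- chartr("BJOUZ", "XXXXX", chars)
    chars <- gsub("*", "X", chars, fixed = TRUE)
  }
  out <- Biostrings::AAStringSet(chars)
  names(out) <- names(set)
  for (s in as.character(out)) .checkResidues(s)
  out
}

#' Write sequences to a FASTA file
#'
#' Thin wrapper over [Biostrings::writeXStringSet()] producing unwrapped
#' records so that `readFasta(writeFasta(x))` is the identity on canonical
#' sequence sets.
#'
#' @param sequences A named `AAStringSet` (or named character vector).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeFasta <- function(sequences, path) {
  if (is.character(sequences))
    sequences <- Biostrings::AAStringSet(sequences)
  if (is.null(names(sequences)))
    stop("sequences must be named")
  Biostrings::writeXStringSet(sequences, path,
                              width = max(Biostrings::width(sequences)))
  invisible(path)
}

#' Write a per-position score track as TSV
#'
#' Emits the columns `sequence_id`, `position` (1-based) and `value`, one
#' row per residue, with values printed at 6 significant digits. A track
#' written this way round-trips through [readTrack()] up to that precision.
#'
#' @param track A [ScoreTrack-class] (or [PredictionTrack-class], coerced
#'   to a probability track).
#' @param path Output path.
#' @param sequence Optional residue string to validate the track length
#'   against; a mismatch is an error.
#' @return `path`, invisibly.
#' @export
writeTrack <- function(track, path, sequence = NULL) {
  if (methods::is(track, "PredictionTrack"))
    track <- ScoreTrack(sequenceId(track), probabilities(track),
                        "probability")
  stopifnot(methods::is(track, "ScoreTrack"))
  methods::validObject(track)
  if (!is.null(sequence)) {
    res <- .asResidues(sequence)
    if (nchar(res) != length(track@values))
      stop("track length (", length(track@values),
           ") does not match sequence length (", nchar(res), ")")
  }
  df <- data.frame(sequence_id = track@sequenceId,
                   position = seq_along(track@values),
                   value = .fmtNum(track@values))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a per-position score track from TSV
#'
#' Inverse of [writeTrack()]. The file must contain one sequence; rows are
#' reordered by position.
#'
#' @param path TSV path with columns `sequence_id`, `position`, `value`.
#' @param kind Track kind of the stored values.
#' @return A [ScoreTrack-class].
#' @export
readTrack <- function(path, kind = c("probability", "energy")) {
  kind <- match.arg(kind)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  .checkColumns(df, c("sequence_id", "position", "value"), "track file")
  ids <- unique(df$sequence_id)
  if (length(ids) != 1L)
    stop("track file must contain exactly one sequence, found ",
         length(ids))
  df <- df[order(df$position), , drop = FALSE]
  if (!identical(as.integer(df$position), seq_len(nrow(df))))
    stop("track positions must be 1..n without gaps")
  ScoreTrack(ids, as.numeric(df$value), kind)
}

## Format numbers at 6 significant digits for text output; NA -> "NA".
.fmtNum <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "NA" else sprintf("%.6g", v)
  }, character(1))
  out
}
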