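## Shared constants and small internal helpers.

## 20 standard amino acids, alphabetical one-letter codes, plus 'X' for
## anything nonstandard or unknown.
.AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
.AA21 <- c(.AA20, "X")

## Residues treated as the "hydrophobic" subset by the synthetic motif
## generator (see generatorConfig()).
.HYDROPHOBIC <- c("A", "V", "L", "I", "F", "M", "W", "Y")

## Nonstandard one-letter codes that are remapped to 'X' on input.
.NONSTANDARD <- c("B", "J", "O", "U", "Z", "*")

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `code` with the global random-number generator seeded to `seed`,
#' restoring the caller's RNG state afterwards so library code never
#' perturbs a user's random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
.withSeed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

## Stable 31-bit string hash (polynomial rolling hash). Used to fan a single
## global seed out into per-stage seeds so that inserting a pipeline stage
## does not perturb the random stream of the others.
.hashString <- function(x) {
  codes <- utf8ToInt(x)
  h <- 0
  for (cc in codes) h <- (h * 31 + cc) %% 2147483647
  as.integer(h)
}

#' Derive a per-stage seed from a global seed
#'
#' Combines a global integer seed with a stable hash of the stage name,
#' yielding a seed below 2^31. Two stages with different names get
#' independent streams; the mapping does not depend on stage order.
#'
#' @param seed Global integer seed.
#' @param stage Character stage name.
#' @return An integer seed.
#' @export
#' @examples
#' stageSeed(1L, "train") != stageSeed(1L, "simulate")
stageSeed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L,
            is.character(stage), length(stage) == 1L)
  as.integer((as.numeric(seed) %% 2147483647 + .hashString(stage)) %% 2147483647)
}

## Coerce a sequence argument (character scalar, AAString, or an
## AAStringSet of length one) to a plain uppercase residue string, and
## validate it against the 21-letter alphabet.
.asResidues <- function(sequence) {
  if (methods::is(sequence, "AAStringSet")) {
    if (length(sequence) != 1L)
      stop("expected a single sequence, got an AAStringSet of length ",
           length(sequence))
    sequence <- as.character(sequence)[[1L]]
  } else if (methods::is(sequence, "AAString")) {
    sequence <- as.character(sequence)
  }
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence))
    stop("'sequence' must be a single character string, AAString, ",
         "or length-1 AAStringSet")
  sequence <- toupper(sequence)
  .checkResidues(sequence)
  sequence
}

.checkResidues <- function(residues) {
  chars <- strsplit(residues, "", fixed = TRUE)[[1L]]
  bad <- setdiff(unique(chars), .AA21)
  if (length(bad))
    stop("sequence contains symbols outside the amino-acid alphabet + 'X': ",
         paste(bad, collapse = ", "))
  invisible(TRUE)
}

## id of a sequence argument: the AAStringSet name when present, else fallback.
.sequenceIdOf <- function(sequence, default = NA_character_) {
  if (methods::is(sequence, "AAStringSet") && !is.null(names(sequence)))
    return(names(sequence)[[1L]])
  default
}

.checkColumns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop(what, " is missing required column(s): ",
         paste(missing, collapse = ", "))
  invisible(TRUE)
}
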