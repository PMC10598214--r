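#' Embed a protein sequence as one real vector per residue
#'
#' @param backend An [EmbeddingBackend-class].
#' @param sequence A character string, `AAString`, or length-1
#'   `AAStringSet` over the 20 amino acids plus `X`.
#' @param ... Backend-specific arguments.
#' @return Numeric matrix with one row per residue and `backendDim(backend)`
#'   columns.
#' @export
setGeneric("embed", function(backend, sequence, ...)
  standardGeneric("embed"))

#' Mark the final blocks of an embedding backend as trainable
#'
#' With `lastK = 0` the backend is frozen: training updates only the
#' classifier head and the backend output for any input is bit-identical
#' before and after a training run. With `lastK > 0` the final `lastK`
#' blocks are fine-tuned jointly with the head.
#'
#' @param backend An [EmbeddingBackend-class].
#' @param lastK Number of final blocks to fine-tune; must not exceed
#'   `nBlocks(backend)`.
#' @return A copy of the backend with the trainability flag set.
#' @export
setGeneric("setTrainable", function(backend, lastK)
  standardGeneric("setTrainable"))

#' @describeIn embed dimension of the per-residue embedding vectors.
#' @export
setGeneric("backendDim", function(backend) standardGeneric("backendDim"))

#' @describeIn setTrainable number of blocks the backend exposes for
#'   fine-tuning (0 for parameter-free backends).
#' @export
setGeneric("nBlocks", function(backend) standardGeneric("nBlocks"))

#' @describeIn setTrainable how many final blocks are currently trainable.
#' @export
setGeneric("trainableLastK", function(backend)
  standardGeneric("trainableLastK"))

#' Accessors for per-position objects
#'
#' `sequenceId()` returns the identifier; `trackValues()` the raw score
#' vector of a [ScoreTrack-class]; `energies()` and `positionCoverage()`
#' the per-position mean energy / window count of a
#' [PositionEnergyProfile-class]; `siteLabels()`, `labelMask()` and
#' `seqWeight()` the label vector, validity mask and loss weight of a
#' [LabeledSequence-class]; `probabilities()` the probability vector of a
#' [PredictionTrack-class]; `residues()` the residue string.
#'
#' @param x An object of the relevant class.
#' @return The slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("sequenceId", function(x) standardGeneric("sequenceId"))
#' @rdname accessors
#' @export
setGeneric("trackValues", function(x) standardGeneric("trackValues"))
#' @rdname accessors
#' @export
setGeneric("trackKind", function(x) standardGeneric("trackKind"))
#' @rdname accessors
#' @export
setGeneric("energies", function(x) standardGeneric("energies"))
#' @rdname accessors
#' @export
setGeneric("positionCoverage", function(x) standardGeneric("positionCoverage"))
#' @rdname accessors
#' @export
setGeneric("siteLabels", function(x) standardGeneric("siteLabels"))
#' @rdname accessors
#' @export
setGeneric("labelMask", function(x) standardGeneric("labelMask"))
#' @rdname accessors
#' @export
setGeneric("seqWeight", function(x) standardGeneric("seqWeight"))
#' @rdname accessors
#' @export
setGeneric("probabilities", function(x) standardGeneric("probabilities"))
#' @rdname accessors
#' @export
setGeneric("residues", function(x) standardGeneric("residues"))

#' Look up the heterogeneous partners of a protein symbol
#'
#' @param table A [PartnerTable-class].
#' @param symbol Protein symbol (matched case-insensitively by uppercasing).
#' @return Character vector of partner symbols (empty if none).
#' @export
setGeneric("partnersOf", function(table, symbol) standardGeneric("partnersOf"))

#' @describeIn partnersOf whether the symbol has a recorded
#'   self (homogeneous) interaction.
#' @export
setGeneric("isHomogeneous", function(table, symbol)
  standardGeneric("isHomogeneous"))
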