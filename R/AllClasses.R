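#' @import methods
NULL

## ---------------------------------------------------------------------------
## Per-position score containers
## ---------------------------------------------------------------------------

#' ScoreTrack: a per-residue score vector for one sequence
#'
#' Holds one real value per residue of a protein sequence, either a
#' predicted binding probability (`kind = "probability"`, values in
#' \[0, 1\]) or a per-position mean binding energy in Rosetta energy units
#' (`kind = "energy"`, lower = more favorable). Missing values are `NA`.
#'
#' @slot sequenceId Single identifier, no whitespace.
#' @slot values Numeric vector, one entry per residue (1-based positions).
#' @slot kind Either `"probability"` or `"energy"`.
#' @export
setClass("ScoreTrack",
  representation(sequenceId = "character", values = "numeric",
                 kind = "character"))

setValidity("ScoreTrack", function(object) {
  msg <- character()
  if (length(object@sequenceId) != 1L || is.na(object@sequenceId) ||
      grepl("[[:space:]]", object@sequenceId))
    msg <- c(msg, "sequenceId must be a single string without whitespace")
  if (length(object@values) < 1L)
    msg <- c(msg, "values must have length >= 1")
  if (length(object@kind) != 1L ||
      !object@kind %in% c("probability", "energy"))
    msg <- c(msg, "kind must be 'probability' or 'energy'")
  if (identical(object@kind, "probability")) {
    v <- object@values[!is.na(object@values)]
    if (length(v) && (any(v < 0) || any(v > 1)))
      msg <- c(msg, "probability values must lie in [0, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a ScoreTrack
#'
#' @param sequenceId Sequence identifier (no whitespace).
#' @param values Numeric vector, one value per residue.
#' @param kind `"probability"` or `"energy"`.
#' @return A [ScoreTrack-class] object.
#' @export
#' @examples
#' ScoreTrack("a", c(0.1, 0.9, 0.5), "probability")
ScoreTrack <- function(sequenceId, values, kind = c("probability", "energy")) {
  kind <- match.arg(kind)
  new("ScoreTrack", sequenceId = as.character(sequenceId),
      values = as.numeric(values), kind = kind)
}

#' PositionEnergyProfile: per-position mean energies with window coverage
#'
#' The product of aggregating fixed-length peptide-window energies onto
#' individual residue positions: at each position the arithmetic mean REU
#' of every window covering it, together with the number of windows that
#' were averaged. Positions covered by no window carry `NA` energy and
#' coverage 0 -- never a silent 0.0.
#'
#' @slot sequenceId Sequence identifier.
#' @slot residues Residue string (21-letter alphabet).
#' @slot energy Numeric per-position mean REU, `NA` where uncovered.
#' @slot coverage Integer per-position window count.
#' @slot mergedIds Identifiers of duplicate profiles merged into this one
#'   (including its own), set by [mergeDuplicateProfiles()].
#' @export
setClass("PositionEnergyProfile",
  representation(sequenceId = "character", residues = "character",
                 energy = "numeric", coverage = "integer",
                 mergedIds = "character"))

setValidity("PositionEnergyProfile", function(object) {
  msg <- character()
  n <- nchar(object@residues)
  if (length(object@residues) != 1L || n < 1L)
    msg <- c(msg, "residues must be a single non-empty string")
  if (length(object@energy) != n || length(object@coverage) != n)
    msg <- c(msg, "energy and coverage must have one entry per residue")
  if (any(object@coverage < 0L))
    msg <- c(msg, "coverage must be nonnegative")
  if (!identical(is.na(object@energy), object@coverage == 0L))
    msg <- c(msg, "energy must be NA exactly where coverage is 0")
  if (length(msg)) msg else TRUE
})

#' Construct a PositionEnergyProfile
#'
#' @param sequenceId Sequence identifier.
#' @param residues Residue string.
#' @param energy Numeric per-position energy (`NA` = no covering window).
#' @param coverage Integer per-position covering-window count.
#' @param mergedIds Ids merged into this profile; defaults to `sequenceId`.
#' @return A [PositionEnergyProfile-class] object.
#' @export
PositionEnergyProfile <- function(sequenceId, residues, energy, coverage,
                                  mergedIds = as.character(sequenceId)) {
  new("PositionEnergyProfile", sequenceId = as.character(sequenceId),
      residues = toupper(as.character(residues)),
      energy = as.numeric(energy), coverage = as.integer(coverage),
      mergedIds = as.character(mergedIds))
}

#' LabeledSequence: per-residue binary interface labels
#'
#' The training target of the interface classifier: a residue string with a
#' binary label per position (1 = interface / binding residue), a validity
#' mask (positions with no energy evidence are labeled 0 but masked out of
#' loss and metrics), and a per-sequence loss weight.
#'
#' @slot sequenceId Sequence identifier.
#' @slot residues Residue string.
#' @slot labels Integer 0/1 per position.
#' @slot mask Logical per position; `FALSE` positions are excluded from
#'   loss and metrics.
#' @slot weight Positive per-sequence loss multiplier.
#' @export
setClass("LabeledSequence",
  representation(sequenceId = "character", residues = "character",
                 labels = "integer", mask = "logical", weight = "numeric"))

setValidity("LabeledSequence", function(object) {
  msg <- character()
  n <- nchar(object@residues)
  if (length(object@residues) != 1L || n < 1L)
    msg <- c(msg, "residues must be a single non-empty string")
  if (length(object@labels) != n)
    msg <- c(msg, "labels must have one entry per residue")
  if (length(object@mask) != n)
    msg <- c(msg, "mask must have one entry per residue")
  if (any(!object@labels %in% c(0L, 1L)))
    msg <- c(msg, "labels must be 0 or 1")
  if (length(object@weight) != 1L || is.na(object@weight) ||
      object@weight <= 0)
    msg <- c(msg, "weight must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' Construct a LabeledSequence
#'
#' @param sequenceId Sequence identifier.
#' @param residues Residue string.
#' @param labels 0/1 vector, one per residue.
#' @param mask Logical vector, one per residue; defaults to all `TRUE`.
#' @param weight Positive per-sequence loss weight (default 1).
#' @return A [LabeledSequence-class] object.
#' @export
LabeledSequence <- function(sequenceId, residues, labels,
                            mask = rep(TRUE, nchar(residues)),
                            weight = 1.0) {
  new("LabeledSequence", sequenceId = as.character(sequenceId),
      residues = toupper(as.character(residues)),
      labels = as.integer(labels), mask = as.logical(mask),
      weight = as.numeric(weight))
}

#' PredictionTrack: per-residue interface probabilities
#'
#' The classifier's output for one sequence: the predicted probability
#' `p` of each residue belonging to a protein-binding interface.
#'
#' @slot sequenceId Sequence identifier.
#' @slot p Numeric in \[0, 1\], one per residue.
#' @export
setClass("PredictionTrack",
  representation(sequenceId = "character", p = "numeric"))

setValidity("PredictionTrack", function(object) {
  msg <- character()
  if (length(object@sequenceId) != 1L || is.na(object@sequenceId))
    msg <- c(msg, "sequenceId must be a single string")
  if (length(object@p) < 1L || anyNA(object@p) ||
      any(object@p < 0) || any(object@p > 1))
    msg <- c(msg, "p must be non-empty, non-NA and within [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Construct a PredictionTrack
#'
#' @param sequenceId Sequence identifier.
#' @param p Probabilities in \[0, 1\], one per residue.
#' @return A [PredictionTrack-class] object.
#' @export
PredictionTrack <- function(sequenceId, p) {
  new("PredictionTrack", sequenceId = as.character(sequenceId),
      p = as.numeric(p))
}

## ---------------------------------------------------------------------------
## Interactome
## ---------------------------------------------------------------------------

#' PartnerTable: symmetric protein-partner lookup
#'
#' Maps each protein symbol to the set of its heterogeneous interaction
#' partners surviving an evidence-filter policy. Self-interactions are
#' tracked separately as "homogeneous" binders and never appear in the
#' heterogeneous partner sets. The mapping is symmetric by construction.
#'
#' @slot partners Named list: symbol -> character vector of partner symbols.
#' @slot homogeneous Character vector of self-interacting symbols.
#' @export
setClass("PartnerTable",
  representation(partners = "list", homogeneous = "character"))

setValidity("PartnerTable", function(object) {
  p <- object@partners
  if (length(p) && is.null(names(p)))
    return("partners must be a named list")
  for (a in names(p)) {
    for (b in p[[a]]) {
      if (a == b) return("self-partners must live in 'homogeneous'")
      if (!a %in% p[[b]])
        return(sprintf("partner table not symmetric: %s -> %s", a, b))
    }
  }
  TRUE
})

## ---------------------------------------------------------------------------
## Embedding backends and the classifier
## ---------------------------------------------------------------------------

#' Virtual parent of per-residue embedding backends
#'
#' A backend turns a protein sequence into one fixed-dimension real vector
#' per residue, deterministically for fixed parameters and input. Concrete
#' backends: [oneHotBackend()] (windowed one-hot encoding, no parameters)
#' and [tinyTransformerBackend()] (a small seeded self-attention encoder
#' whose final blocks can be marked trainable for fine-tuning). An adapter
#' for a pretrained protein language model can be plugged in by subclassing
#' and providing `embed` / `nBlocks` / `setTrainable` methods.
#'
#' @slot name Backend name.
#' @export
setClass("EmbeddingBackend", representation("VIRTUAL", name = "character"))

#' @rdname oneHotBackend
#' @export
setClass("OneHotBackend", contains = "EmbeddingBackend",
  representation(radius = "integer"))

#' @rdname tinyTransformerBackend
#' @export
setClass("TinyTransformerBackend", contains = "EmbeddingBackend",
  representation(embDim = "integer", blocks = "list",
                 tokenEmbedding = "matrix", trainableLastK = "integer",
                 seed = "integer"))

setValidity("TinyTransformerBackend", function(object) {
  msg <- character()
  if (object@trainableLastK < 0L ||
      object@trainableLastK > length(object@blocks))
    msg <- c(msg, "trainableLastK must lie in [0, number of blocks]")
  if (nrow(object@tokenEmbedding) != 21L)
    msg <- c(msg, "tokenEmbedding must have 21 rows (20 amino acids + X)")
  if (length(msg)) msg else TRUE
})

#' InterfaceModel: trained per-position interface classifier
#'
#' Couples an embedding backend with a four-layer fully connected head
#' (three hidden layers plus a one-unit sigmoid output) applied
#' independently at every residue position. Produced by
#' [trainInterfaceModel()]; consumed by `predict()` and the prioritizer.
#'
#' @slot backend The [EmbeddingBackend-class] (possibly fine-tuned).
#' @slot head List with elements `W` and `b`: four weight matrices and
#'   four bias vectors.
#' @slot headConfig List: `hidden` (three integers) and `activation`.
#' @slot seed Integer seed the model was trained under.
#' @export
setClass("InterfaceModel",
  representation(backend = "EmbeddingBackend", head = "list",
                 headConfig = "list", seed = "integer"))

setValidity("InterfaceModel", function(object) {
  if (length(object@head$W) != 4L || length(object@head$b) != 4L)
    return("head must contain exactly four weight layers")
  TRUE
})
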