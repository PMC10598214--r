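## Accessors and show() methods for the S4 containers.

#' @rdname accessors
setMethod("sequenceId", "ScoreTrack", function(x) x@sequenceId)
#' @rdname accessors
setMethod("sequenceId", "PositionEnergyProfile", function(x) x@sequenceId)
#' @rdname accessors
setMethod("sequenceId", "LabeledSequence", function(x) x@sequenceId)
#' @rdname accessors
setMethod("sequenceId", "PredictionTrack", function(x) x@sequenceId)

#' @rdname accessors
setMethod("trackValues", "ScoreTrack", function(x) x@values)
#' @rdname accessors
setMethod("trackKind", "ScoreTrack", function(x) x@kind)

#' @rdname accessors
setMethod("energies", "PositionEnergyProfile", function(x) x@energy)
#' @rdname accessors
setMethod("positionCoverage", "PositionEnergyProfile", function(x) x@coverage)
#' @rdname accessors
setMethod("residues", "PositionEnergyProfile", function(x) x@residues)

#' @rdname accessors
setMethod("siteLabels", "LabeledSequence", function(x) x@labels)
#' @rdname accessors
setMethod("labelMask", "LabeledSequence", function(x) x@mask)
#' @rdname accessors
setMethod("seqWeight", "LabeledSequence", function(x) x@weight)
#' @rdname accessors
setMethod("residues", "LabeledSequence", function(x) x@residues)

#' @rdname accessors
setMethod("probabilities", "PredictionTrack", function(x) x@p)

#' @rdname partnersOf
setMethod("partnersOf", "PartnerTable", function(table, symbol) {
  symbol <- toupper(symbol)
  p <- table@partners[[symbol]]
  if (is.null(p)) character() else p
})

#' @rdname partnersOf
setMethod("isHomogeneous", "PartnerTable", function(table, symbol) {
  toupper(symbol) %in% table@homogeneous
})

setMethod("show", "ScoreTrack", function(object) {
  cat(sprintf("ScoreTrack '%s' (%s), %d positions\n", object@sequenceId,
              object@kind, length(object@values)))
})

setMethod("show", "PositionEnergyProfile", function(object) {
  n <- length(object@energy)
  cov <- sum(object@coverage > 0L)
  cat(sprintf(
    "PositionEnergyProfile '%s': %d positions, %d covered (%.1f%%)\n",
    object@sequenceId, n, cov, 100 * cov / n))
  if (cov)
    cat(sprintf("  mean energy (covered): %.3f REU\n",
                mean(object@energy, na.rm = TRUE)))
  if (length(object@mergedIds) > 1L)
    cat("  merged ids:", paste(object@mergedIds, collapse = ", "), "\n")
})

setMethod("show", "LabeledSequence", function(object) {
  cat(sprintf(
    "LabeledSequence '%s': %d positions, %d positive, %d masked, weight %g\n",
    object@sequenceId, length(object@labels), sum(object@labels),
    sum(!object@mask), object@weight))
})

setMethod("show", "PredictionTrack", function(object) {
  cat(sprintf("PredictionTrack '%s': %d positions, mean p = %.3f\n",
              object@sequenceId, length(object@p), mean(object@p)))
})

setMethod("show", "PartnerTable", function(object) {
  cat(sprintf("PartnerTable: %d proteins with partners, %d self-binders\n",
              length(object@partners), length(object@homogeneous)))
})

setMethod("show", "OneHotBackend", function(object) {
  cat(sprintf("OneHotBackend: context radius %d, dim %d (frozen)\n",
              object@radius, backendDim(object)))
})

setMethod("show", "TinyTransformerBackend", function(object) {
  cat(sprintf(
    "TinyTransformerBackend: dim %d, %d blocks (%d trainable), seed %d\n",
    object@embDim, length(object@blocks), object@trainableLastK,
    object@seed))
})

setMethod("show", "InterfaceModel", function(object) {
  hid <- vapply(object@head$W[1:3], ncol, integer(1))
  cat(sprintf(
    "InterfaceModel: %s backend (dim %d) + head [%s] -> 1, activation %s\n",
    object@backend@name, backendDim(object@backend),
    paste(hid, collapse = ", "), object@headConfig$activation))
})
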