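## Model evaluation: AUROC against binary interface labels, Spearman
## correlation against per-position energies, and top-n energy summaries
## that proxy the downstream laboratory task (are the highest-predicted
## residues actually low-energy binders?).

#' Area under the ROC curve (Mann-Whitney formulation)
#'
#' Equals the probability that a uniformly drawn positive outscores a
#' uniformly drawn negative, with half credit for ties; computed from
#' average ranks rather than by explicit pair enumeration.
#'
#' @param labels Binary 0/1 vector.
#' @param scores Numeric scores, higher = more positive.
#' @return AUROC in \[0, 1\].
#' @export
#' @examples
#' aurocScore(c(1, 1, 0, 0), c(0.8, 0.4, 0.6, 0.2))  # 0.75
aurocScore <- function(labels, scores) {
  stopifnot(length(labels) == length(scores))
  ok <- !is.na(labels) & !is.na(scores)
  labels <- labels[ok]; scores <- scores[ok]
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0L || n0 == 0L)
    stop("AUROC undefined: both classes must be present")
  r <- rank(scores)  # average ranks handle ties with half credit
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Spearman rank correlation
#'
#' Pearson correlation of average ranks (ties get their mean rank),
#' delegated to [stats::cor()]. Errors on constant input, where the
#' metric is undefined.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return Correlation in \[-1, 1\].
#' @export
spearmanRho <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L)
    stop("Spearman correlation requires at least 3 paired values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("Spearman correlation undefined for constant input")
  stats::cor(x, y, method = "spearman")
}

#' Spearman correlation between predicted probability and binding energy
#'
#' Sign convention: the energy is negated before correlating, so that
#' better binding (lower REU) aligned with higher predicted probability
#' yields a positive correlation.
#'
#' @param p Predicted probabilities.
#' @param energy Per-position energies (REU, lower = better binding).
#' @return Correlation in \[-1, 1\]; positive = probabilities track
#'   favorable energies.
#' @export
spearmanVsEnergy <- function(p, energy) spearmanRho(p, -energy)

#' Energy summary of the top-scoring positions
#'
#' Selects the `n` positions with the highest score (ties resolved by
#' position order) and reports their mean energy and the percentage with
#' energy strictly below the binding threshold `tau`.
#'
#' @param scores Numeric prediction scores.
#' @param energyVals Numeric per-position energies, aligned with `scores`.
#' @param n How many top positions to take; at most `length(scores)`.
#' @param tau Binding-energy threshold (default -1 REU).
#' @return List with `meanEnergy` and `pctBelow` (0-100).
#' @export
#' @examples
#' topNEnergy(c(0.9, 0.8, 0.1), c(-2, -0.5, -3), n = 2)
topNEnergy <- function(scores, energyVals, n, tau = -1) {
  stopifnot(length(scores) == length(energyVals))
  if (n < 1L || n > length(scores))
    stop("n must lie in [1, ", length(scores), "]")
  top <- order(-scores, seq_along(scores))[seq_len(n)]
  e <- energyVals[top]
  list(meanEnergy = mean(e), pctBelow = 100 * mean(e < tau))
}

#' Evaluate prediction tracks against labels (and optionally energies)
#'
#' Computes, over unmasked positions only: AUROC of the predicted
#' probabilities against the binary labels, Spearman correlation of the
#' probabilities against negated energies (when profiles are supplied),
#' and the top-`n` energy summary. `average = "macro"` computes each
#' metric per sequence and averages across sequences (sequences where a
#' metric is undefined, e.g. single-class, are skipped for that metric);
#' `"micro"` pools all positions first.
#'
#' @param tracks Named list of [PredictionTrack-class].
#' @param labeled Named list of [LabeledSequence-class] (matched by id).
#' @param profiles Optional named list of [PositionEnergyProfile-class]
#'   supplying energies.
#' @param n Top-n for the energy summary (default 10; capped per
#'   sequence at the number of unmasked positions).
#' @param tau Binding-energy threshold (default -1).
#' @param average `"macro"` (default) or `"micro"`.
#' @return List: `auroc`, `spearman`, `topNMeanEnergy`,
#'   `pctTopBelowThreshold`, `nPositions`.
#' @export
evaluateTracks <- function(tracks, labeled, profiles = NULL, n = 10L,
                           tau = -1, average = c("macro", "micro")) {
  average <- match.arg(average)
  trackIds <- vapply(tracks, sequenceId, character(1))
  labIds <- vapply(labeled, sequenceId, character(1))
  common <- intersect(trackIds, labIds)
  if (!length(common))
    stop("no sequence ids shared between tracks and labels")
  profIds <- if (!is.null(profiles))
    vapply(profiles, sequenceId, character(1)) else character()

  per <- lapply(common, function(id) {
    tr <- tracks[[match(id, trackIds)]]
    ls <- labeled[[match(id, labIds)]]
    mask <- labelMask(ls)
    p <- probabilities(tr)[mask]
    y <- siteLabels(ls)[mask]
    e <- NULL
    j <- match(id, profIds)
    if (!is.na(j)) e <- energies(profiles[[j]])[mask]
    list(p = p, y = y, e = e)
  })

  metricOn <- function(p, y, e) {
    auc <- tryCatch(aurocScore(y, p), error = function(err) NA_real_)
    rho <- if (!is.null(e))
      tryCatch(spearmanVsEnergy(p, e), error = function(err) NA_real_)
    else NA_real_
    tne <- if (!is.null(e) && length(p)) {
      nn <- min(n, length(p))
      topNEnergy(p, e, nn, tau)
    } else list(meanEnergy = NA_real_, pctBelow = NA_real_)
    c(auroc = auc, spearman = rho, topNMeanEnergy = tne$meanEnergy,
      pctTopBelowThreshold = tne$pctBelow)
  }

  nPositions <- sum(vapply(per, function(x) length(x$p), integer(1)))
  if (average == "micro") {
    p <- unlist(lapply(per, `[[`, "p"))
    y <- unlist(lapply(per, `[[`, "y"))
    hasE <- all(vapply(per, function(x) !is.null(x$e), logical(1)))
    e <- if (hasE) unlist(lapply(per, `[[`, "e")) else NULL
    m <- metricOn(p, y, e)
  } else {
    M <- do.call(rbind, lapply(per, function(x)
      metricOn(x$p, x$y, x$e)))
    m <- colMeans(M, na.rm = TRUE)
    m[apply(M, 2L, function(col) all(is.na(col)))] <- NA_real_
  }
  list(auroc = unname(m["auroc"]), spearman = unname(m["spearman"]),
       topNMeanEnergy = unname(m["topNMeanEnergy"]),
       pctTopBelowThreshold = unname(m["pctTopBelowThreshold"]),
       nPositions = nPositions)
}
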