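## Interactome curation: filter protein-protein interaction evidence
## tables under two policies of differing stringency, build a symmetric
## partner lookup, and compute proteome coverage.
##
## Evidence model: records come from one of three source databases —
## IMEX (curated physical interactions, always trusted), BIOGRID
## (carrying a low-throughput LTP or high-throughput HTP physical
## evidence class), and PROPER (proximity-ligation screen hits carrying
## a p-value).

#' Filter PPI records under a stringency policy
#'
#' The stringent (least inclusive) policy keeps all IMEX records,
#' BIOGRID records with LTP evidence, and PROPER records with p < 0.01.
#' The lenient (most inclusive) policy keeps all IMEX records, BIOGRID
#' records with LTP or HTP evidence, and PROPER records with p < 0.05.
#' Both p-value comparisons are strict. Every stringent-surviving record
#' also survives the lenient policy.
#'
#' @param records `data.frame` with columns `protein_a`, `protein_b`,
#'   `source` (`IMEX`/`BIOGRID`/`PROPER`), `evidence` (`LTP`/`HTP`/`NA`),
#'   `p_value` (required for PROPER records).
#' @param policy `"stringent"` or `"lenient"`.
#' @return The surviving subset of `records`.
#' @export
applyPolicy <- function(records, policy = c("stringent", "lenient")) {
  policy <- match.arg(policy)
  .checkColumns(records, c("protein_a", "protein_b", "source", "evidence"),
                "PPI table")
  if (!"p_value" %in% names(records)) records$p_value <- NA_real_
  bad <- !records$source %in% c("IMEX", "BIOGRID", "PROPER")
  if (any(bad))
    stop("unknown PPI source(s): ",
         paste(unique(records$source[bad]), collapse = ", "))
  proper <- records$source == "PROPER"
  if (any(proper & is.na(records$p_value)))
    stop("PROPER records must carry a p_value")
  biogrid <- records$source == "BIOGRID"
  if (any(biogrid & !records$evidence %in% c("LTP", "HTP")))
    stop("BIOGRID records must carry LTP or HTP evidence")
  keep <- records$source == "IMEX"
  if (policy == "stringent") {
    keep <- keep | (biogrid & records$evidence == "LTP") |
      (proper & records$p_value < 0.01)
  } else {
    keep <- keep | (biogrid & records$evidence %in% c("LTP", "HTP")) |
      (proper & records$p_value < 0.05)
  }
  records[keep, , drop = FALSE]
}

#' Build a symmetric partner table from filtered PPI records
#'
#' Symbols are uppercased, duplicate pairs (in either orientation)
#' collapsed, and self-interactions routed to the homogeneous
#' (self-binding) set rather than the heterogeneous partner lists.
#'
#' @param records Policy-filtered PPI `data.frame` with `protein_a`,
#'   `protein_b`.
#' @return A [PartnerTable-class].
#' @export
#' @examples
#' tab <- buildPartnerTable(data.frame(protein_a = c("A", "B", "C"),
#'                                     protein_b = c("B", "A", "C")))
#' partnersOf(tab, "A")      # "B"
#' isHomogeneous(tab, "C")   # TRUE
buildPartnerTable <- function(records) {
  .checkColumns(records, c("protein_a", "protein_b"), "PPI table")
  a <- toupper(records$protein_a)
  b <- toupper(records$protein_b)
  self <- a == b
  homogeneous <- sort(unique(a[self]))
  a2 <- a[!self]; b2 <- b[!self]
  partners <- list()
  if (length(a2)) {
    sym <- unique(data.frame(x = c(a2, b2), y = c(b2, a2)))
    partners <- lapply(split(sym$y, sym$x), function(v) sort(unique(v)))
  }
  new("PartnerTable", partners = partners, homogeneous = homogeneous)
}

#' Percentage of a proteome with at least one known partner
#'
#' @param table A [PartnerTable-class].
#' @param proteome Character vector of protein symbols (non-empty).
#' @param includeHomogeneous Count proteins whose only recorded
#'   interaction is self-binding (default `FALSE`: heterogeneous
#'   partners only).
#' @return Percentage in \[0, 100\].
#' @export
#' @examples
#' tab <- buildPartnerTable(data.frame(protein_a = "A", protein_b = "B"))
#' proteomeCoverage(tab, c("A", "B", "C"))  # 66.67
proteomeCoverage <- function(table, proteome,
                             includeHomogeneous = FALSE) {
  stopifnot(methods::is(table, "PartnerTable"))
  if (!length(proteome)) stop("proteome must be non-empty")
  proteome <- unique(toupper(proteome))
  covered <- proteome %in% names(table@partners)
  if (includeHomogeneous)
    covered <- covered | proteome %in% table@homogeneous
  100 * sum(covered) / length(proteome)
}

#' Read a PPI evidence table
#'
#' @param path TSV with columns `protein_a`, `protein_b`, `source`,
#'   `evidence`, `p_value` (empty/NA where not applicable).
#' @return `data.frame` of PPI records.
#' @export
readPpiRecords <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  .checkColumns(df, c("protein_a", "protein_b", "source", "evidence"),
                "PPI table")
  if (!"p_value" %in% names(df)) df$p_value <- NA_real_
  df$p_value <- as.numeric(df$p_value)
  df
}
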