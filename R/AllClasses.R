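#' CodonCounts: per-gene codon count matrix
#'
#' The central container of the package: a genes x 64 matrix of codon counts
#' in reading frame 0 of each coding sequence. Stop-codon columns are kept
#' (they enter overall base composition) but are excluded from every
#' synonymous-codon statistic. Rows are named by gene/accession id.
#'
#' @slot counts numeric matrix, genes x 64, non-negative integers, columns
#'   named by the 64 codons in the order of [codons()].
#'
#' @seealso [countCodons()], [codonCounts()], [senseCounts()]
#' @export
setClass("CodonCounts", representation(counts = "matrix"))

setValidity("CodonCounts", function(object) {
  m <- object@counts
  msg <- character()
  if (!is.numeric(m))
    msg <- c(msg, "counts must be a numeric matrix")
  else {
    if (ncol(m) != 64L || !identical(colnames(m), .cs_codons))
      msg <- c(msg, "counts must have the 64 codons as column names, in standard order")
    if (is.null(rownames(m)) || anyDuplicated(rownames(m)))
      msg <- c(msg, "rows must carry unique gene ids")
    if (any(!is.finite(m)) || any(m < 0) || any(m != round(m)))
      msg <- c(msg, "counts must be finite non-negative integers")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a CodonCounts object from a count matrix
#'
#' @param counts genes x 64 matrix with codon column names (any column order;
#'   missing codon columns are zero-filled).
#' @return A [CodonCounts-class] object.
#' @export
CodonCounts <- function(counts) {
  counts <- as.matrix(counts)
  if (is.null(colnames(counts)))
    stop("'counts' must have codon column names")
  colnames(counts) <- toupper(chartr("U", "T", colnames(counts)))
  bad <- setdiff(colnames(counts), .cs_codons)
  if (length(bad))
    stop("unknown codon column(s): ", paste(bad, collapse = ", "))
  full <- matrix(0, nrow(counts), 64L,
                 dimnames = list(rownames(counts), .cs_codons))
  full[, colnames(counts)] <- counts
  if (is.null(rownames(full)))
    rownames(full) <- paste0("gene", seq_len(nrow(full)))
  methods::new("CodonCounts", counts = full)
}

#' @describeIn CodonCounts-class number of genes
#' @param x,object a `CodonCounts` object
#' @export
setMethod("length", "CodonCounts", function(x) nrow(x@counts))

#' @describeIn CodonCounts-class compact summary
#' @export
setMethod("show", "CodonCounts", function(object) {
  m <- object@counts
  cat(sprintf("CodonCounts: %d gene(s) x 64 codons\n", nrow(m)))
  tot <- rowSums(m)
  cat(sprintf("  codons per gene: %s\n",
              if (nrow(m)) paste0(min(tot), "-", max(tot)) else "-"))
  ids <- rownames(m)
  if (length(ids) > 6L) ids <- c(ids[1:5], "...")
  cat("  genes: ", paste(ids, collapse = ", "), "\n", sep = "")
})

#' @param i index or gene ids
#' @describeIn CodonCounts-class subset genes
#' @export
setMethod("[", "CodonCounts", function(x, i) {
  methods::new("CodonCounts", counts = x@counts[i, , drop = FALSE])
})

setGeneric("codonCounts", function(x) standardGeneric("codonCounts"))
setGeneric("geneIDs", function(x) standardGeneric("geneIDs"))
setGeneric("senseCounts", function(x) standardGeneric("senseCounts"))
setGeneric("totalCodons", function(x) standardGeneric("totalCodons"))
setGeneric("senseLengths", function(x) standardGeneric("senseLengths"))
setGeneric("poolCounts", function(x) standardGeneric("poolCounts"))

#' Accessors for CodonCounts
#'
#' `codonCounts()` returns the full genes x 64 matrix; `senseCounts()` drops
#' the three stop-codon columns; `totalCodons()` is the per-gene codon total
#' including stops (L); `senseLengths()` counts sense codons only;
#' `poolCounts()` sums counts over all genes into one named 64-vector
#' (dataset-level pooling, the substrate for dataset RSCU).
#'
#' @param x a [CodonCounts-class] object
#' @return matrix or named numeric vector, as described.
#' @name codonCounts
#' @aliases codonCounts,CodonCounts-method geneIDs geneIDs,CodonCounts-method
#'   senseCounts senseCounts,CodonCounts-method totalCodons
#'   totalCodons,CodonCounts-method senseLengths
#'   senseLengths,CodonCounts-method poolCounts poolCounts,CodonCounts-method
#' @export codonCounts geneIDs senseCounts totalCodons senseLengths poolCounts
NULL

setMethod("codonCounts", "CodonCounts", function(x) x@counts)
setMethod("geneIDs", "CodonCounts", function(x) rownames(x@counts))
setMethod("senseCounts", "CodonCounts",
          function(x) x@counts[, .cs_sense, drop = FALSE])
setMethod("totalCodons", "CodonCounts", function(x) rowSums(x@counts))
setMethod("senseLengths", "CodonCounts",
          function(x) rowSums(x@counts[, .cs_sense, drop = FALSE]))
setMethod("poolCounts", "CodonCounts", function(x) colSums(x@counts))
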