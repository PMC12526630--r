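#' Per-gene nucleotide composition panel
#'
#' Computes, for each gene, overall base percentages (over the full CDS,
#' stop codon included), GC content at codon positions 1 and 2 (sense codons
#' only), and the synonymous third-position panel: A3s/T3s/C3s/G3s and GC3s
#' are computed over third positions of codons whose amino acid has
#' degeneracy >= 2 (Met, Trp and stops excluded). AT3 follows, by default,
#' the convention of computing over third positions of all sense codons
#' (`convention = "caical"`); `convention = "codonw"` restricts AT3 to the
#' synonymous codon set like the other "3s" metrics.
#'
#' @param x a [CodonCounts-class] object (or anything [countCodons()] accepts).
#' @param convention `"caical"` (default) or `"codonw"`; see Details.
#' @return `data.frame` with one row per gene and columns `accession`,
#'   `A_pct`, `T_pct`, `C_pct`, `G_pct`, `GC_pct`, `AT_pct`, `GC1_pct`,
#'   `GC2_pct`, `GC3s_pct`, `A3s_pct`, `T3s_pct`, `C3s_pct`, `G3s_pct`,
#'   `AT3_pct`, `GC12_pct`. All values are percentages at full precision.
#' @export
#' @examples
#' compositionProfile(countCodons(c(toy = "ATGGCAGCAGCGTGGTAA")))
compositionProfile <- function(x, convention = c("caical", "codonw")) {
  convention <- match.arg(convention)
  if (!methods::is(x, "CodonCounts")) x <- countCodons(x)
  m <- codonCounts(x)
  if (nrow(m) == 0L) stop("no genes")
  sm <- m[, .cs_sense, drop = FALSE]
  Lall <- rowSums(m)
  Lsen <- rowSums(sm)
  if (any(Lsen < 1))
    stop("gene(s) with no sense codons: ",
         paste(rownames(m)[Lsen < 1], collapse = ", "))

  ## overall base content over all codons incl. stops
  base <- m %*% .cs_base_content          # genes x ACGT occurrences
  basePct <- base / (3 * Lall) * 100

  gcInd <- function(b) as.numeric(b %in% c("G", "C"))
  gc1 <- as.vector(sm %*% gcInd(.cs_pos1[.cs_sense])) / Lsen * 100
  gc2 <- as.vector(sm %*% gcInd(.cs_pos2[.cs_sense])) / Lsen * 100

  ## synonymous third positions: degenerate families only
  syn <- unlist(codonFamilies(degenerateOnly = TRUE), use.names = FALSE)
  ssm <- m[, syn, drop = FALSE]
  Lsyn <- rowSums(ssm)
  if (any(Lsyn < 1))
    stop("gene(s) with no synonymous codons (undefined 3s metrics): ",
         paste(rownames(m)[Lsyn < 1], collapse = ", "))
  third <- .cs_pos3[syn]
  p3 <- function(b) as.vector(ssm %*% as.numeric(third == b)) / Lsyn * 100
  a3s <- p3("A"); t3s <- p3("T"); c3s <- p3("C"); g3s <- p3("G")

  at3 <- if (convention == "caical") {
    thirdAll <- .cs_pos3[.cs_sense]
    as.vector(sm %*% as.numeric(thirdAll %in% c("A", "T"))) / Lsen * 100
  } else a3s + t3s

  data.frame(
    accession = rownames(m),
    A_pct = basePct[, "A"], T_pct = basePct[, "T"],
    C_pct = basePct[, "C"], G_pct = basePct[, "G"],
    GC_pct = basePct[, "G"] + basePct[, "C"],
    AT_pct = basePct[, "A"] + basePct[, "T"],
    GC1_pct = gc1, GC2_pct = gc2,
    GC3s_pct = g3s + c3s,
    A3s_pct = a3s, T3s_pct = t3s, C3s_pct = c3s, G3s_pct = g3s,
    AT3_pct = at3,
    GC12_pct = (gc1 + gc2) / 2,
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Unweighted dataset means of composition profiles
#'
#' Arithmetic mean of every numeric column across genes (per-gene averages,
#' not length-weighted).
#'
#' @param profiles data.frame from [compositionProfile()].
#' @param label value for the `accession` column of the result.
#' @return One-row data.frame with the same columns.
#' @export
datasetMeans <- function(profiles, label = "mean") {
  if (nrow(profiles) == 0L) stop("empty profile list")
  num <- vapply(profiles, is.numeric, logical(1))
  out <- profiles[1, , drop = FALSE]
  out[num] <- lapply(profiles[num], mean)
  out$accession <- label
  rownames(out) <- NULL
  out
}

#' Write a composition table in study column order
#'
#' TSV with a two-line header (column names, then units/convention), columns
#' ordered accession, T3s, C3s, A3s, G3s, GC, AT, GC3s, AT3, GC1, GC2.
#'
#' @param profiles data.frame from [compositionProfile()].
#' @param path output path.
#' @param digits rounding for display (default 2; internal values are full
#'   precision).
#' @return `path`, invisibly.
#' @export
writeCompositionTSV <- function(profiles, path, digits = 2) {
  cols <- c("accession", "T3s_pct", "C3s_pct", "A3s_pct", "G3s_pct",
            "GC_pct", "AT_pct", "GC3s_pct", "AT3_pct", "GC1_pct", "GC2_pct")
  tab <- profiles[, cols]
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], round, digits = digits)
  .writeTSV2(tab, path,
             units = c("id", rep("percent", sum(num))))
}

## two-line-header TSV writer shared by the pipeline outputs
.writeTSV2 <- function(tab, path, units = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(colnames(tab), collapse = "\t"), con)
  if (!is.null(units))
    writeLines(paste0("#unit\t", paste(units[-1], collapse = "\t")), con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
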