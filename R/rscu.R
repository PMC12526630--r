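#' Relative synonymous codon usage (RSCU) and family share (RFSC)
#'
#' For codon j of amino acid i with counts `X_ij` and degeneracy `n_i`:
#' `RSCU_ij = X_ij / ((1/n_i) * sum_j X_ij)` (1 = no bias, >1 preferred) and
#' `RFSC_ij = X_ij / sum_j X_ij` (family shares summing to 1). Families with
#' zero total count yield NA (missing, not 0). Stop codons are excluded.
#'
#' @param x a [CodonCounts-class] object, or a named numeric vector of codon
#'   counts (e.g. from [poolCounts()]).
#' @param pool logical; for a multi-gene `CodonCounts`, pool counts across
#'   genes (dataset-level table, the default) rather than erroring.
#' @param scope label stored in the `scope` attribute of the result.
#' @return data.frame with one row per sense codon: `codon`, `aa`, `count`,
#'   `rscu`, `rfsc`.
#' @export
#' @examples
#' rscu(c(GCA = 2, GCG = 1, GCT = 0, GCC = 0))
rscu <- function(x, pool = TRUE, scope = "dataset") {
  v <- .asCountVector(x, pool = pool)
  sense <- v[.cs_sense]
  out <- data.frame(codon = .cs_sense, aa = .cs_aa[.cs_sense],
                    count = unname(sense),
                    rscu = NA_real_, rfsc = NA_real_,
                    row.names = NULL, stringsAsFactors = FALSE)
  for (fam in codonFamilies()) {
    i <- match(fam, out$codon)
    tot <- sum(out$count[i])
    if (tot > 0) {
      out$rfsc[i] <- out$count[i] / tot
      out$rscu[i] <- out$count[i] / (tot / length(fam))
    }
  }
  attr(out, "scope") <- scope
  out
}

.asCountVector <- function(x, pool = TRUE) {
  if (methods::is(x, "CodonCounts")) {
    if (length(x) > 1L && !pool)
      stop("multiple genes: set pool = TRUE or subset to one gene")
    return(poolCounts(x))
  }
  if (is.numeric(x) && !is.null(names(x))) {
    names(x) <- toupper(chartr("U", "T", names(x)))
    v <- stats::setNames(numeric(64L), .cs_codons)
    known <- intersect(names(x), .cs_codons)
    if (length(known) == 0L) stop("no recognisable codon names")
    v[known] <- x[known]
    return(v)
  }
  stop("x must be a CodonCounts object or a named codon count vector")
}

#' Per-gene RSCU matrix
#'
#' @param x a [CodonCounts-class] object.
#' @param codons59 logical; restrict columns to the 59 informative codons
#'   (degenerate families only: ATG, TGG and stops dropped), the
#'   conventional input for correspondence analysis.
#' @return genes x codons numeric matrix of RSCU values (NA where a gene
#'   lacks a family).
#' @export
rscuMatrix <- function(x, codons59 = TRUE) {
  sm <- senseCounts(x)
  cods <- if (codons59)
    unlist(codonFamilies(degenerateOnly = TRUE), use.names = FALSE)
  else .cs_sense
  out <- matrix(NA_real_, nrow(sm), length(cods),
                dimnames = list(rownames(sm), cods))
  for (fam in codonFamilies(degenerateOnly = codons59)) {
    fam <- intersect(fam, cods)
    if (!length(fam)) next
    tot <- rowSums(sm[, fam, drop = FALSE])
    sc <- sm[, fam, drop = FALSE] * length(fam) / tot
    sc[tot == 0, ] <- NA_real_
    out[, fam] <- sc
  }
  out
}

#' Classify codons by RSCU/RFSC thresholds
#'
#' Preferred codons have RSCU > 1; over-represented RSCU > 1.6;
#' under-represented RSCU < 0.6. High-frequency codons follow one of two
#' published operationalisations: `"rfsc60"` flags codons whose family share
#' exceeds 60% (RFSC > 0.60); `"avg150"` flags codons whose share exceeds
#' the family average by more than 50% (RFSC > 1.5/n_i, equivalently
#' RSCU > 1.5).
#'
#' @param table data.frame from [rscu()] on pooled dataset counts.
#' @param hf_rule `"rfsc60"` (default) or `"avg150"`.
#' @return List of class `CodonClassification`: character sets `preferred`,
#'   `over`, `under`, `high_freq`, plus `hf_rule` and the input `table`.
#' @export
classifyCodons <- function(table, hf_rule = c("rfsc60", "avg150")) {
  hf_rule <- match.arg(hf_rule)
  stopifnot(all(c("codon", "rscu", "rfsc") %in% names(table)))
  ok <- !is.na(table$rscu)
  deg <- .cs_degeneracy[table$aa] >= 2  # Met/Trp trivially have RFSC = 1
  hf <- deg & if (hf_rule == "rfsc60") table$rfsc > 0.60
              else table$rfsc > 1.5 / .cs_degeneracy[table$aa]
  structure(list(
    preferred = table$codon[ok & table$rscu > 1],
    over      = table$codon[ok & table$rscu > 1.6],
    under     = table$codon[ok & table$rscu < 0.6],
    high_freq = table$codon[ok & hf],
    hf_rule   = hf_rule,
    table     = table), class = "CodonClassification")
}

#' @export
print.CodonClassification <- function(x, ...) {
  cat("Codon classification (pooled RSCU/RFSC)\n")
  cat(sprintf("  preferred (RSCU>1):   %d\n", length(x$preferred)))
  cat(sprintf("  over-rep. (RSCU>1.6): %s\n", paste(x$over, collapse = " ")))
  cat(sprintf("  under-rep.(RSCU<0.6): %s\n", paste(x$under, collapse = " ")))
  cat(sprintf("  high-frequency [%s]:  %d (%s)\n", x$hf_rule,
              length(x$high_freq), paste(x$high_freq, collapse = " ")))
  invisible(x)
}

## round-half-up decile size, minimum one gene
.decileSize <- function(n, quantile) max(1L, as.integer(floor(n * quantile + 0.5)))

#' Optimal codon discovery by the delta-RSCU method
#'
#' Genes are ranked by ENC (ascending; ties broken by gene id for
#' determinism). The lowest-ENC decile is taken as the high-expression
#' (high-bias) set and the highest-ENC decile as the low-expression set;
#' counts are pooled within each set and `dRSCU = RSCU_high - RSCU_low`.
#' A codon is optimal when `dRSCU >= 0.08`, `RSCU_high > 1` and
#' `RSCU_low < 1`.
#'
#' @param x a [CodonCounts-class] object with at least 2 genes.
#' @param quantile extreme-decile fraction (default 0.10); decile size is
#'   rounded half up with a minimum of one gene.
#' @return List of class `OptimalCodons`: `optimal` (character set),
#'   `delta_rscu` (named vector over sense codons), `rscu_high`, `rscu_low`
#'   ([rscu()] tables), `high_genes`, `low_genes`, `enc`.
#' @export
optimalCodons <- function(x, quantile = 0.10) {
  n <- length(x)
  if (n < 2L) stop("need at least 2 genes")
  if (n < 2 / quantile)
    warning("fewer than ", ceiling(2 / quantile),
            " genes; extreme deciles are very small")
  e <- enc(x)
  ord <- order(e, geneIDs(x))
  k <- .decileSize(n, quantile)
  high <- geneIDs(x)[ord[seq_len(k)]]            # low ENC = high bias
  low  <- geneIDs(x)[ord[seq(n - k + 1L, n)]]
  rh <- rscu(x[high], scope = "high-expression")
  rl <- rscu(x[low],  scope = "low-expression")
  d <- stats::setNames(rh$rscu - rl$rscu, rh$codon)
  opt <- rh$codon[!is.na(d) & d >= 0.08 & rh$rscu > 1 & rl$rscu < 1]
  structure(list(optimal = opt, delta_rscu = d,
                 rscu_high = rh, rscu_low = rl,
                 high_genes = high, low_genes = low, enc = e),
            class = "OptimalCodons")
}

#' @export
print.OptimalCodons <- function(x, ...) {
  cat(sprintf("Optimal codons (dRSCU >= 0.08): %d\n", length(x$optimal)))
  cat("  ", paste(x$optimal, collapse = " "), "\n")
  cat(sprintf("  high-bias set (ENC %.2f-%.2f): %s\n",
              min(x$enc[x$high_genes]), max(x$enc[x$high_genes]),
              paste(x$high_genes, collapse = ", ")))
  cat(sprintf("  low-bias set  (ENC %.2f-%.2f): %s\n",
              min(x$enc[x$low_genes]), max(x$enc[x$low_genes]),
              paste(x$low_genes, collapse = ", ")))
  invisible(x)
}
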