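## Standard nuclear genetic code (translation table 1) and derived lookup
## tables shared by every statistic in the package. Only table 1 is shipped;
## all species handled here are plants with nuclear genes.

#' The 64 codons in Biostrings order
#'
#' @return Character vector of the 64 DNA trinucleotides.
#' @export
#' @examples
#' length(codons())
codons <- function() .cs_codons

#' Sense codons of the standard genetic code
#'
#' @return The 61 codons that encode an amino acid under translation table 1.
#' @export
senseCodons <- function() .cs_sense

#' Stop codons of the standard genetic code
#'
#' @return TAA, TAG, TGA.
#' @export
stopCodons <- function() .cs_stops

#' Synonymous-codon families
#'
#' The standard code partitions the 61 sense codons into 20 amino-acid
#' families; 18 of those have degeneracy >= 2 (Met and Trp are single-codon
#' families). All synonymous statistics (RSCU, ENC, SCUO, "3s" composition)
#' operate on the degenerate families only.
#'
#' @param degenerateOnly logical; drop the Met and Trp families.
#' @return Named list mapping one-letter amino-acid symbol to its codons.
#' @export
#' @examples
#' codonFamilies()[["A"]]   # the four alanine codons
codonFamilies <- function(degenerateOnly = FALSE) {
  if (degenerateOnly) .cs_families[.cs_degeneracy >= 2L] else .cs_families
}

#' Degeneracy of each amino-acid family
#'
#' @return Named integer vector (n_i in 1,2,3,4,6) summing to 61.
#' @export
codonDegeneracy <- function() .cs_degeneracy

#' Translate codons to one-letter amino acids
#'
#' @param codon character vector of DNA codons.
#' @return One-letter symbols, `"*"` for stops.
#' @export
codonToAA <- function(codon) unname(.cs_aa[toupper(codon)])

## ---- internal constant tables (built once at install time) ----

.cs_aa      <- Biostrings::GENETIC_CODE
.cs_codons  <- names(.cs_aa)
.cs_stops   <- .cs_codons[.cs_aa == "*"]
.cs_sense   <- .cs_codons[.cs_aa != "*"]
.cs_families <- split(.cs_sense, factor(.cs_aa[.cs_sense],
                                        levels = sort(unique(.cs_aa[.cs_sense]))))
.cs_degeneracy <- lengths(.cs_families)

## degeneracy classes used by Wright's ENC: 9 two-fold, 1 three-fold (Ile),
## 5 four-fold, 3 six-fold families
.cs_class_families <- lapply(c(`2` = 2L, `3` = 3L, `4` = 4L, `6` = 6L),
                             function(k) .cs_families[.cs_degeneracy == k])

## per-codon base indicators, position by position
.cs_base_at <- function(pos) {
  b <- substr(.cs_codons, pos, pos)
  names(b) <- .cs_codons
  b
}
.cs_pos1 <- .cs_base_at(1L)
.cs_pos2 <- .cs_base_at(2L)
.cs_pos3 <- .cs_base_at(3L)

## 64 x 4 matrix: number of occurrences of each base in each codon
.cs_base_content <- local({
  m <- sapply(c("A", "C", "G", "T"), function(b)
    (.cs_pos1 == b) + (.cs_pos2 == b) + (.cs_pos3 == b))
  rownames(m) <- .cs_codons
  m
})

## Kyte-Doolittle hydropathy (one decimal, as published)
.cs_kd <- c(A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
            Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
            L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
            S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2)

.cs_aromatic <- c("F", "Y", "W")
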