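#' Relative adaptiveness weights for CAI/CBI
#'
#' Builds a `ReferenceWeights` object from per-codon usage of a reference
#' (ideally highly expressed) gene set: within each synonymous family,
#' `w = usage / max(usage)`, so the most used codon of every family has
#' weight 1. The `optimal` set (used by CBI) holds the argmax codon of each
#' degenerate family; ties break alphabetically for determinism.
#'
#' @param usage named numeric vector over (at least the) 61 sense codons:
#'   counts, per-1000 frequencies, or already-computed weights; or a
#'   `HostUsageTable` from [readCusp()].
#' @return List of class `ReferenceWeights` with elements `w` (named
#'   61-vector in (0,1]) and `optimal` (character set of codons).
#' @export
referenceWeights <- function(usage) {
  if (inherits(usage, "HostUsageTable")) {
    u <- usage$per1000
    names(u) <- usage$codon
    usage <- u
  }
  names(usage) <- toupper(chartr("U", "T", names(usage)))
  w <- rep(NA_real_, length(.cs_sense))
  names(w) <- .cs_sense
  have <- intersect(names(usage), .cs_sense)
  if (length(have) < 59L)
    stop("reference usage must cover the sense codons (",
         length(have), " provided)")
  w[have] <- as.numeric(usage[have])
  if (anyNA(w) || any(w < 0)) stop("reference usage must be non-negative")
  optimal <- character()
  for (fam in codonFamilies()) {
    mx <- max(w[fam])
    if (mx <= 0) {
      w[fam] <- 1  # unobserved family: uninformative, weight 1
      mx <- 1
    }
    w[fam] <- w[fam] / mx
    if (length(fam) > 1L) {
      top <- sort(fam[w[fam] == max(w[fam])])[1L]
      optimal <- c(optimal, top)
    }
  }
  structure(list(w = w, optimal = optimal), class = "ReferenceWeights")
}

#' Default CAI/CBI reference weights
#'
#' Derived from the packaged synthetic E. coli-style usage table (see
#' [packagedHostTables()]); a stand-in for a genuine highly-expressed-gene
#' reference, adequate for relative comparisons within a dataset. Supply
#' your own table via [readReferenceWeights()] to reproduce values computed
#' against a specific published reference.
#'
#' @return A `ReferenceWeights` object.
#' @export
defaultReferenceWeights <- function() {
  path <- system.file("extdata", "hosts", "synthetic_Escherichia_coli.cusp",
                      package = "codonscope")
  referenceWeights(readCusp(path, host = "Escherichia coli (synthetic)"))
}

## family homozygosity F-hat = (n * sum p^2 - 1) / (n - 1); NA if n <= 1 or
## F-hat <= 0 (Wright's estimator, CodonW edge rules)
.familyF <- function(v) {
  n <- sum(v)
  if (n <= 1) return(NA_real_)
  p <- v / n
  f <- (n * sum(p^2) - 1) / (n - 1)
  if (f <= 1e-10) NA_real_ else f   # drop F of 0 (up to rounding) like F<0
}

.encOne <- function(sense) {
  Fbar <- vapply(.cs_class_families, function(fams) {
    fs <- vapply(fams, function(fam) .familyF(sense[fam]), numeric(1))
    if (all(is.na(fs))) NA_real_ else mean(fs, na.rm = TRUE)
  }, numeric(1))
  if (all(is.na(Fbar))) return(NA_real_)
  ## Ile (the only three-fold class) imputed from neighbours when unusable
  if (is.na(Fbar["3"]) && !is.na(Fbar["2"]) && !is.na(Fbar["4"]))
    Fbar["3"] <- (Fbar["2"] + Fbar["4"]) / 2
  if (anyNA(Fbar)) return(NA_real_)
  enc <- 2 + 9 / Fbar["2"] + 1 / Fbar["3"] + 5 / Fbar["4"] + 3 / Fbar["6"]
  unname(min(enc, 61))
}

#' Effective number of codons (ENC)
#'
#' Wright's ENC: per-family codon homozygosity `F = (n*sum(p^2)-1)/(n-1)`,
#' averaged within each degeneracy class (2-, 3-, 4-, 6-fold), then
#' `ENC = 2 + 9/F2 + 1/F3 + 5/F4 + 3/F6`, capped at 61. Families with a
#' single observation or non-positive F are dropped from their class
#' average; a missing three-fold class (Ile) is imputed as the mean of the
#' 2- and 4-fold averages. Ranges from 20 (one codon per amino acid) to 61
#' (uniform synonymous usage).
#'
#' @param x a [CodonCounts-class] object.
#' @return Named numeric vector of ENC per gene; NA (with a warning) where a
#'   gene is too short for a class average.
#' @export
enc <- function(x) {
  sm <- senseCounts(x)
  out <- apply(sm, 1L, .encOne)
  if (all(is.na(out))) stop("ENC undefined for every gene (genes too short)")
  if (anyNA(out))
    warning("ENC undefined for: ",
            paste(names(out)[is.na(out)], collapse = ", "))
  out
}

#' Codon adaptation index (CAI)
#'
#' Geometric mean of relative adaptiveness weights over the sense codons of
#' a gene, excluding the single-codon families Met and Trp (and stops), per
#' the classical definition. Codons with zero reference weight are floored
#' (default 0.01) with a warning.
#'
#' @param x a [CodonCounts-class] object.
#' @param ref a `ReferenceWeights` object; defaults to
#'   [defaultReferenceWeights()].
#' @param floor lower bound substituted for zero weights.
#' @return Named numeric vector of CAI in (0, 1] per gene.
#' @export
cai <- function(x, ref = defaultReferenceWeights(), floor = 0.01) {
  stopifnot(inherits(ref, "ReferenceWeights"))
  w <- ref$w
  if (any(w <= 0)) {
    warning(sum(w <= 0), " reference weight(s) are zero; floored at ", floor)
    w[w <= 0] <- floor
  }
  syn <- unlist(codonFamilies(degenerateOnly = TRUE), use.names = FALSE)
  sm <- senseCounts(x)[, syn, drop = FALSE]
  tot <- rowSums(sm)
  if (any(tot < 1)) stop("gene(s) with no synonymous codons")
  exp(as.vector(sm %*% log(w[syn])) / tot)
}

#' Codon bias index (CBI)
#'
#' Bennetzen-Hall CBI over degenerate families:
#' `(Nopt - Nran) / (Ntot - Nran)`, where `Nopt` counts codons from the
#' reference optimal set, `Ntot` the codons of degenerate families, and
#' `Nran` the optimal count expected under uniform synonymous usage. 1 means
#' only optimal codons are used; values near 0 indicate random usage.
#'
#' @inheritParams cai
#' @return Named numeric vector of CBI per gene.
#' @export
cbi <- function(x, ref = defaultReferenceWeights()) {
  stopifnot(inherits(ref, "ReferenceWeights"))
  sm <- senseCounts(x)
  fams <- codonFamilies(degenerateOnly = TRUE)
  out <- vapply(seq_len(nrow(sm)), function(i) {
    v <- sm[i, ]
    nOpt <- 0; nTot <- 0; nRan <- 0
    for (fam in fams) {
      nf <- sum(v[fam])
      opt <- intersect(ref$optimal, fam)
      nOpt <- nOpt + sum(v[opt])
      nTot <- nTot + nf
      nRan <- nRan + nf * length(opt) / length(fam)
    }
    if (abs(nTot - nRan) < .Machine$double.eps * nTot * 4 || nTot == 0)
      stop("CBI undefined (degenerate denominator) for gene ",
           rownames(sm)[i])
    (nOpt - nRan) / (nTot - nRan)
  }, numeric(1))
  names(out) <- rownames(sm)
  out
}

#' GRAVY and aromaticity of the encoded protein
#'
#' GRAVY is the mean Kyte-Doolittle hydropathy of the encoded residues;
#' AROMA the fraction of aromatic residues (Phe, Tyr, Trp).
#'
#' @param x a [CodonCounts-class] object.
#' @return data.frame with columns `accession`, `gravy`, `aroma`.
#' @export
gravyAroma <- function(x) {
  sm <- senseCounts(x)
  tot <- rowSums(sm)
  if (any(tot < 1)) stop("gene(s) with no sense codons")
  kd <- .cs_kd[.cs_aa[.cs_sense]]
  arom <- as.numeric(.cs_aa[.cs_sense] %in% .cs_aromatic)
  data.frame(accession = rownames(sm),
             gravy = as.vector(sm %*% kd) / tot,
             aroma = as.vector(sm %*% arom) / tot,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Codon-usage bias index panel
#'
#' Convenience wrapper assembling the per-gene index table: ENC, CBI, CAI,
#' GRAVY and AROMA.
#'
#' @inheritParams cai
#' @return data.frame with columns `accession`, `enc`, `cbi`, `cai`,
#'   `gravy`, `aroma`.
#' @export
biasIndices <- function(x, ref = defaultReferenceWeights()) {
  ga <- gravyAroma(x)
  data.frame(accession = ga$accession,
             enc = unname(enc(x)),
             cbi = unname(cbi(x, ref)),
             cai = unname(cai(x, ref)),
             gravy = ga$gravy, aroma = ga$aroma,
             row.names = NULL, stringsAsFactors = FALSE)
}
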