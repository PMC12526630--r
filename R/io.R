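#' Read coding sequences from a FASTA file
#'
#' Sequences are upper-cased and U is normalised to T, so mRNA records can be
#' mixed with DNA. Record ids are the first whitespace-delimited token of
#' each header.
#'
#' @param path path to a (multi-record) FASTA file.
#' @return A [Biostrings::DNAStringSet] named by record id; empty set for an
#'   empty file.
#' @export
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">g1 demo", "ATGGCAGCAGCGTGGTAA"), f)
#' readCDS(f)
readCDS <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  if (file.size(path) == 0L)
    return(Biostrings::DNAStringSet())
  raw <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("malformed FASTA in ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  chr <- toupper(chartr("Uu", "Tt", as.character(raw)))
  bad <- grepl("[^ACGTN]", chr)
  if (any(bad))
    stop("malformed FASTA record(s) with non-ACGTN characters: ",
         paste(sub("\\s.*", "", names(raw)[bad]), collapse = ", "))
  out <- Biostrings::DNAStringSet(chr)
  names(out) <- sub("\\s.*", "", names(raw))
  out
}

#' Write coding sequences to FASTA
#'
#' @param x a named [Biostrings::DNAStringSet] (or named character vector).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeCDS <- function(x, path) {
  if (is.character(x)) x <- Biostrings::DNAStringSet(x)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Validate coding sequences
#'
#' Checks reading frame 0 of each sequence. Under `"strict"` policy a length
#' not divisible by 3, an internal stop codon, or any ambiguous base (N) is
#' an error naming the gene and position. Under `"lenient"` a trailing
#' overhang of 1-2 nt is truncated and codons containing N are left in place
#' (they are skipped by [countCodons()]), with a warning. A single trailing
#' stop codon is always legitimate; it is kept in the sequence, recorded by
#' the counter and excluded from all synonymous statistics downstream.
#'
#' @param x [Biostrings::DNAStringSet] or named character vector.
#' @param policy `"strict"` or `"lenient"`.
#' @return A validated [Biostrings::DNAStringSet].
#' @export
validateCDS <- function(x, policy = c("strict", "lenient")) {
  policy <- match.arg(policy)
  if (is.character(x)) {
    if (is.null(names(x))) names(x) <- paste0("gene", seq_along(x))
    x <- Biostrings::DNAStringSet(toupper(chartr("U", "T", x)))
  }
  chr <- toupper(as.character(x))
  ids <- names(x)
  if (is.null(ids)) ids <- paste0("gene", seq_along(chr))
  out <- character(length(chr))
  for (k in seq_along(chr)) {
    s <- chr[[k]]
    over <- nchar(s) %% 3L
    if (over != 0L) {
      if (policy == "strict")
        stop(sprintf("gene %s: length %d not divisible by 3", ids[k], nchar(s)))
      warning(sprintf("gene %s: truncating %d-nt overhang", ids[k], over))
      s <- substr(s, 1L, nchar(s) - over)
    }
    if (nchar(s) == 0L) stop(sprintf("gene %s: empty sequence", ids[k]))
    cod <- substring(s, seq(1L, nchar(s), 3L), seq(3L, nchar(s), 3L))
    hasN <- grepl("N", cod, fixed = TRUE)
    if (any(hasN)) {
      if (policy == "strict")
        stop(sprintf("gene %s: ambiguous base in codon %d", ids[k],
                     which(hasN)[1]))
      warning(sprintf("gene %s: %d codon(s) contain N and will be skipped",
                      ids[k], sum(hasN)))
    }
    isStop <- !hasN & cod %in% .cs_stops
    nC <- length(cod)
    internal <- which(isStop[-nC])
    if (length(internal))
      stop(sprintf("gene %s: internal stop codon at codon %d", ids[k],
                   internal[1]))
    out[k] <- s
  }
  res <- Biostrings::DNAStringSet(out)
  names(res) <- ids
  res
}

#' Count codons in reading frame 0
#'
#' Produces the exact codon multiset of each sequence as a
#' [CodonCounts-class] object. Codons containing ambiguous bases are skipped
#' (never imputed); stop codons are recorded in their own columns.
#'
#' @param x [Biostrings::DNAStringSet] or named character vector of validated
#'   CDS.
#' @return A [CodonCounts-class] object, one row per gene.
#' @export
#' @examples
#' countCodons(c(toy = "ATGGCAGCAGCGTGGTAA"))
countCodons <- function(x) {
  if (is.character(x)) {
    if (is.null(names(x))) names(x) <- paste0("gene", seq_along(x))
    x <- Biostrings::DNAStringSet(toupper(chartr("U", "T", x)))
  }
  keep <- Biostrings::width(x) - Biostrings::width(x) %% 3L
  x <- Biostrings::subseq(x, 1L, keep)
  m <- Biostrings::oligonucleotideFrequency(x, width = 3L, step = 3L)
  rownames(m) <- names(x)
  methods::new("CodonCounts", counts = m[, .cs_codons, drop = FALSE])
}

#' Read a cusp-style codon usage frequency table
#'
#' Parses the EMBOSS `cusp` output format: comment lines starting with `#`,
#' an optional `Codon AA Fraction Frequency Number` header, then one row per
#' codon with the usage frequency per 1000 codons in the `Frequency` column.
#' A minimal two-column `codon<TAB>per-1000` table is also accepted.
#'
#' @param path path to the table.
#' @param host optional host name; defaults to the file base name.
#' @return A `data.frame` (class `HostUsageTable`) with columns `codon`,
#'   `aa`, `per1000`, and attribute `host`.
#' @export
readCusp <- function(path, host = NULL) {
  if (!file.exists(path)) stop("codon usage table not found: ", path)
  ln <- readLines(path, warn = FALSE)
  ln <- ln[!grepl("^\\s*(#|$)", ln)]
  ln <- ln[!grepl("^\\s*Codon\\b", ln, ignore.case = TRUE)]
  fields <- strsplit(trimws(ln), "\\s+")
  nf <- lengths(fields)
  if (!length(fields) || any(nf < 2L))
    stop("unparseable codon usage table: ", path)
  cod <- toupper(chartr("U", "T", vapply(fields, `[[`, "", 1L)))
  per1000 <- if (all(nf >= 4L))
    as.numeric(vapply(fields, `[[`, "", 4L))  # cusp: Fraction Frequency Number
  else
    as.numeric(vapply(fields, `[[`, "", 2L))
  if (anyNA(per1000)) stop("non-numeric frequency values in ", path)
  bad <- setdiff(cod, .cs_codons)
  if (length(bad)) stop("unknown codons in ", path, ": ",
                        paste(bad, collapse = ", "))
  if (anyDuplicated(cod)) stop("duplicated codons in ", path)
  tot <- sum(per1000)
  if (abs(tot - 1000) > 1)
    warning(sprintf("frequencies in %s sum to %.2f, not 1000; renormalising",
                    basename(path), tot))
  out <- data.frame(codon = cod, aa = codonToAA(cod),
                    per1000 = per1000 / tot * 1000,
                    stringsAsFactors = FALSE)
  attr(out, "host") <- if (is.null(host))
    tools::file_path_sans_ext(basename(path)) else host
  class(out) <- c("HostUsageTable", "data.frame")
  out
}

#' Packaged host codon usage tables
#'
#' Lists (or loads) the codon usage tables shipped with the package. These
#' are synthetic emulations of six common heterologous expression hosts
#' (E. coli, S. cerevisiae, A. thaliana, N. tabacum, T. aestivum, Z. mays)
#' generated from a compositional model of each genome's third-position GC
#' preference; they are NOT database snapshots (see the packaged
#' MANIFEST.json and the vignette). Substitute genuine cusp tables via
#' [readCusp()] for production host screening.
#'
#' @param load logical; if TRUE return a named list of `HostUsageTable`s,
#'   otherwise the file paths.
#' @return Named character vector of paths, or list of tables.
#' @export
packagedHostTables <- function(load = TRUE) {
  dir <- system.file("extdata", "hosts", package = "codonscope")
  files <- list.files(dir, pattern = "\\.cusp$", full.names = TRUE)
  names(files) <- sub("^synthetic_", "", tools::file_path_sans_ext(basename(files)))
  if (!load) return(files)
  lapply(files, readCusp)
}

#' Read a two-column codon/weight reference table
#'
#' @param path TSV with columns codon and relative adaptiveness weight.
#' @return A `ReferenceWeights` object (see [referenceWeights()]).
#' @export
readReferenceWeights <- function(path) {
  tab <- utils::read.table(path, header = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("reference table must have >= 2 columns")
  w <- as.numeric(tab[[2L]])
  names(w) <- toupper(chartr("U", "T", tab[[1L]]))
  referenceWeights(w)
}
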