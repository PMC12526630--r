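#' Synonymous codon usage order (SCUO)
#'
#' Entropy-based bias measure in \[0, 1\]. For each degenerate family i with
#' within-family codon probabilities p: `H_i = -sum(p log p)`,
#' `Hmax_i = log(n_i)`, and the normalised entropy deficit
#' `O_i = (Hmax_i - H_i) / Hmax_i`. SCUO is the weighted mean of the `O_i`
#' with weights proportional to the family's codon count among all
#' degenerate-family codons. 0 = uniform synonymous usage, 1 = a single
#' codon per family.
#'
#' @param x a [CodonCounts-class] object.
#' @return Named numeric vector of SCUO per gene.
#' @export
scuo <- function(x) {
  sm <- senseCounts(x)
  fams <- codonFamilies(degenerateOnly = TRUE)
  out <- vapply(seq_len(nrow(sm)), function(i) {
    v <- sm[i, ]
    num <- 0; den <- 0
    for (fam in fams) {
      nf <- sum(v[fam])
      if (nf == 0) next
      p <- v[fam] / nf
      p <- p[p > 0]
      H <- -sum(p * log(p))
      Hmax <- log(length(fam))
      num <- num + nf * (Hmax - H) / Hmax
      den <- den + nf
    }
    if (den == 0)
      stop("SCUO undefined for gene ", rownames(sm)[i],
           " (no degenerate-family codons)")
    num / den
  }, numeric(1))
  names(out) <- rownames(sm)
  out
}

#' MILC: measure independent of length and composition
#'
#' Per amino acid a with observed codon counts O_c, within-family observed
#' frequencies f_c and expected frequencies g_c, the goodness-of-fit
#' contribution is `M_a = 2 * sum_c O_c * ln(f_c / g_c)` (zero-count codons
#' contribute 0). `MILC = sum_a(M_a) / L - C` with gene length L in sense
#' codons and the length correction `C = sum_a(n_a - 1) / L - 0.5`, summed
#' over amino acids observed in the gene. Larger values mean stronger
#' deviation from the expected codon distribution; when observed matches
#' expected exactly, MILC equals `-C`.
#'
#' @param x a [CodonCounts-class] object.
#' @param expected `"uniform"` (equal use within each family, default) or
#'   `"dataset"` (pooled dataset family shares as the expectation).
#' @return Named numeric vector of MILC per gene.
#' @export
milc <- function(x, expected = c("uniform", "dataset")) {
  expected <- match.arg(expected)
  sm <- senseCounts(x)
  fams <- codonFamilies()
  g <- lapply(fams, function(fam) {
    if (expected == "uniform")
      stats::setNames(rep(1 / length(fam), length(fam)), fam)
    else {
      tot <- sum(poolCounts(x)[fam])
      if (tot == 0) stats::setNames(rep(1 / length(fam), length(fam)), fam)
      else poolCounts(x)[fam] / tot
    }
  })
  out <- vapply(seq_len(nrow(sm)), function(i) {
    v <- sm[i, ]
    L <- sum(v)
    if (L < 1) stop("empty gene ", rownames(sm)[i])
    Msum <- 0; corr <- 0
    for (k in seq_along(fams)) {
      fam <- fams[[k]]
      nf <- sum(v[fam])
      if (nf == 0) next
      f <- v[fam] / nf
      gg <- g[[k]]
      obsPos <- v[fam] > 0
      if (any(gg[obsPos] == 0))
        stop("expected frequency 0 for an observed codon (",
             paste(fam[obsPos & gg == 0], collapse = ","), ")")
      Msum <- Msum + 2 * sum(v[fam][obsPos] * log(f[obsPos] / gg[obsPos]))
      corr <- corr + (length(fam) - 1)
    }
    Msum / L - (corr / L - 0.5)
  }, numeric(1))
  names(out) <- rownames(sm)
  out
}

#' Pooled amino-acid usage frequencies
#'
#' Residue frequencies over the sense codons of all genes pooled;
#' percentages sum to 100.
#'
#' @param x a [CodonCounts-class] object.
#' @return Named numeric vector (percent per amino acid, 20 entries).
#' @export
aaUsage <- function(x) {
  v <- poolCounts(x)[.cs_sense]
  byAA <- tapply(v, .cs_aa[.cs_sense], sum)
  out <- stats::setNames(as.vector(100 * byAA / sum(byAA)), names(byAA))
  out[order(names(out))]
}

#' Compare gene codon usage frequencies with a host table
#'
#' Gene usage is scaled to per-1000 codons over the 61 sense codons and the
#' per-codon ratio gene/host is formed (the host table is renormalised over
#' sense codons too). A codon is divergent when the ratio is <= 0.5 or >= 2
#' (boundaries inclusive); a host frequency of 0 against nonzero gene usage
#' gives an infinite ratio, flagged divergent. Codons unused by both are
#' reported with ratio NA and are not divergent.
#'
#' @param x a [CodonCounts-class] object (counts are pooled) or a named
#'   codon count vector.
#' @param host a `HostUsageTable` from [readCusp()].
#' @return List of class `HostComparison`: `host`, `table` (codon,
#'   gene_per1000, host_per1000, ratio, divergent), `divergent` (codon set),
#'   `n_divergent`.
#' @export
hostCompare <- function(x, host) {
  stopifnot(inherits(host, "HostUsageTable"))
  v <- .asCountVector(x)[.cs_sense]
  gene1000 <- v / sum(v) * 1000
  h <- stats::setNames(host$per1000, host$codon)[.cs_sense]
  if (anyNA(h)) stop("host table does not cover all 61 sense codons")
  h <- h / sum(h) * 1000
  ratio <- ifelse(h > 0, gene1000 / h,
                  ifelse(gene1000 > 0, Inf, NA_real_))
  div <- !is.na(ratio) & (ratio <= 0.5 | ratio >= 2)
  tab <- data.frame(codon = .cs_sense, aa = .cs_aa[.cs_sense],
                    gene_per1000 = unname(gene1000),
                    host_per1000 = unname(h),
                    ratio = unname(ratio), divergent = unname(div),
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(host = attr(host, "host"), table = tab,
                 divergent = .cs_sense[div], n_divergent = sum(div)),
            class = "HostComparison")
}

#' @export
print.HostComparison <- function(x, ...) {
  cat(sprintf("Host comparison vs %s: %d divergent codon(s)\n",
              x$host, x$n_divergent))
  if (x$n_divergent)
    cat("  ", paste(x$divergent, collapse = " "), "\n")
  invisible(x)
}

#' Rank candidate hosts by codon usage divergence
#'
#' Runs [hostCompare()] for each gene against each host and summarises the
#' per-gene divergent-codon counts as a min-max range per host (the form in
#' which host suitability is conventionally reported), ranked by mean.
#'
#' @param x a [CodonCounts-class] object.
#' @param hosts named list of `HostUsageTable`s (default: the packaged
#'   synthetic tables, see [packagedHostTables()]).
#' @return data.frame: `host`, `min_divergent`, `max_divergent`,
#'   `mean_divergent`, ordered best (fewest divergent) first.
#' @export
rankHosts <- function(x, hosts = packagedHostTables()) {
  res <- lapply(names(hosts), function(h) {
    nd <- vapply(seq_len(length(x)),
                 function(i) hostCompare(x[i], hosts[[h]])$n_divergent,
                 numeric(1))
    data.frame(host = h, min_divergent = min(nd), max_divergent = max(nd),
               mean_divergent = mean(nd), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out <- out[order(out$mean_divergent, out$max_divergent, out$host), ]
  rownames(out) <- NULL
  out
}

#' Spearman correlation panel
#'
#' Spearman rank correlations (two-sided) between requested column pairs of
#' a per-gene metric table, with exact p-values below 10 observations and
#' the t-approximation otherwise. Constant columns yield NA with a note in
#' the result.
#'
#' @param data data.frame of per-gene metrics (>= 4 rows).
#' @param xvars,yvars column names; all x-y combinations are tested. If
#'   `pairs` is given it overrides them.
#' @param pairs optional 2-column matrix/data.frame of (x, y) name pairs.
#' @param alpha significance level for the `significant` flag.
#' @return data.frame: `x`, `y`, `rho`, `p`, `significant`.
#' @export
correlationPanel <- function(data, xvars = NULL, yvars = NULL, pairs = NULL,
                             alpha = 0.05) {
  if (nrow(data) < 4L) stop("need at least 4 genes")
  if (is.null(pairs)) {
    if (is.null(xvars) || is.null(yvars))
      stop("supply xvars/yvars or pairs")
    pairs <- expand.grid(x = xvars, y = yvars, stringsAsFactors = FALSE)
  } else {
    pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
    colnames(pairs)[1:2] <- c("x", "y")
  }
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    xn <- pairs$x[i]; yn <- pairs$y[i]
    xv <- data[[xn]]; yv <- data[[yn]]
    if (is.null(xv) || is.null(yv)) stop("unknown column: ", xn, "/", yn)
    ok <- is.finite(xv) & is.finite(yv)
    if (sum(ok) < 4L || stats::var(xv[ok]) == 0 || stats::var(yv[ok]) == 0)
      return(data.frame(x = xn, y = yn, rho = NA_real_, p = NA_real_,
                        significant = NA, stringsAsFactors = FALSE))
    ct <- suppressWarnings(
      stats::cor.test(xv[ok], yv[ok], method = "spearman",
                      exact = sum(ok) < 10))
    data.frame(x = xn, y = yn, rho = unname(ct$estimate), p = ct$p.value,
               significant = ct$p.value < alpha, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
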