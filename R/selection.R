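#' Expected ENC under mutation pressure alone
#'
#' Wright's expected effective number of codons for a gene whose third-
#' position composition is governed only by GC content:
#' `ENCexp = 2 + s + 29 / (s^2 + (1 - s)^2)` with `s` the GC3s fraction.
#'
#' @param gc3s numeric vector of GC3s fractions in \[0, 1\].
#' @return Expected ENC values.
#' @export
#' @examples
#' encExpected(c(0, 0.5, 1))   # 31, 60.5, 32
encExpected <- function(gc3s) {
  if (any(!is.finite(gc3s)) || any(gc3s < 0 | gc3s > 1))
    stop("gc3s must lie in [0, 1]")
  2 + gc3s + 29 / (gc3s^2 + (1 - gc3s)^2)
}

#' ENC-plot data (observed vs expected ENC against GC3s)
#'
#' Genes on or near the expected curve are compatible with mutation pressure
#' alone; genes well below it indicate additional (selective) constraints.
#' A gene exactly on the curve is not flagged as below.
#'
#' @param x a [CodonCounts-class] object.
#' @return data.frame: `accession`, `gc3s` (fraction), `enc_obs`, `enc_exp`,
#'   `below_curve`.
#' @export
encPlotData <- function(x) {
  comp <- compositionProfile(x)
  e <- enc(x)
  s <- comp$GC3s_pct / 100
  data.frame(accession = comp$accession,
             gc3s = s, enc_obs = unname(e),
             enc_exp = encExpected(s),
             below_curve = unname(e) < encExpected(s),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' PR2 (parity rule 2) bias plot data
#'
#' Third-codon-position base counts per gene, by default over all sense
#' codons, give `at_bias = A3/(A3+T3)` and `gc_bias = G3/(G3+C3)`; the point
#' (0.5, 0.5) marks strand-parity equilibrium (A = T, G = C). Quadrants are
#' numbered counter-clockwise from (+,+) with `gc_bias` on x and `at_bias`
#' on y; boundary points fall in the higher quadrant index direction of the
#' `>= 0.5` side.
#'
#' @param x a [CodonCounts-class] object.
#' @param fourfoldOnly logical; restrict to third positions of fourfold-
#'   degenerate families only (an alternative convention).
#' @return data.frame: `accession`, `at_bias`, `gc_bias`, `quadrant` (NA
#'   where a denominator is zero).
#' @export
pr2PlotData <- function(x, fourfoldOnly = FALSE) {
  cods <- if (fourfoldOnly)
    unlist(.cs_families[.cs_degeneracy == 4L], use.names = FALSE)
  else .cs_sense
  m <- codonCounts(x)[, cods, drop = FALSE]
  third <- .cs_pos3[cods]
  cnt <- function(b) as.vector(m %*% as.numeric(third == b))
  A3 <- cnt("A"); T3 <- cnt("T"); G3 <- cnt("G"); C3 <- cnt("C")
  at <- ifelse(A3 + T3 > 0, A3 / (A3 + T3), NA_real_)
  gc <- ifelse(G3 + C3 > 0, G3 / (G3 + C3), NA_real_)
  quad <- ifelse(is.na(at) | is.na(gc), NA_integer_,
          ifelse(gc >= 0.5 & at >= 0.5, 1L,
          ifelse(gc <  0.5 & at >= 0.5, 2L,
          ifelse(gc <  0.5 & at <  0.5, 3L, 4L))))
  data.frame(accession = rownames(m), at_bias = at, gc_bias = gc,
             quadrant = quad, row.names = NULL, stringsAsFactors = FALSE)
}

#' Neutrality regression of GC12 on GC3s
#'
#' Ordinary least squares of GC12 (mean GC at codon positions 1-2, %) on
#' GC3s (%). The slope estimates the fraction of codon-usage variation
#' attributable to mutation pressure (`100 * slope` percent), the remainder
#' to selection and other constraints. Pearson r and its two-sided p-value
#' are reported (the conventional companion of the OLS slope); Spearman rho
#' is included for comparability with rank-based correlation panels.
#'
#' @param profiles data.frame from [compositionProfile()] (>= 3 genes), or a
#'   [CodonCounts-class] object.
#' @return List of class `NeutralityFit`: `slope`, `intercept`, `r`,
#'   `p_value`, `spearman_rho`, `spearman_p`, `mutation_pct`,
#'   `selection_pct`, `n`, `slope_se`.
#' @export
neutralityFit <- function(profiles) {
  if (methods::is(profiles, "CodonCounts"))
    profiles <- compositionProfile(profiles)
  if (nrow(profiles) < 3L) stop("need at least 3 genes")
  x <- profiles$GC3s_pct
  y <- profiles$GC12_pct
  if (stats::var(x) == 0) stop("zero variance in GC3s; slope undefined")
  fit <- stats::lm(y ~ x)
  ct <- stats::cor.test(x, y, method = "pearson")
  sp <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman",
                    exact = length(x) < 10))
  slope <- unname(stats::coef(fit)[2L])
  structure(list(
    slope = slope,
    intercept = unname(stats::coef(fit)[1L]),
    r = unname(ct$estimate), p_value = ct$p.value,
    spearman_rho = unname(sp$estimate), spearman_p = sp$p.value,
    mutation_pct = 100 * slope, selection_pct = 100 * (1 - slope),
    n = length(x),
    slope_se = summary(fit)$coefficients[2L, 2L]),
    class = "NeutralityFit")
}

#' @export
print.NeutralityFit <- function(x, ...) {
  cat(sprintf("Neutrality regression (GC12 ~ GC3s, n = %d)\n", x$n))
  cat(sprintf("  slope %.3f (SE %.3f), intercept %.2f\n",
              x$slope, x$slope_se, x$intercept))
  cat(sprintf("  Pearson r = %.3f (p = %.3g); Spearman rho = %.3f\n",
              x$r, x$p_value, x$spearman_rho))
  cat(sprintf("  mutation %.1f%% vs selection %.1f%%\n",
              x$mutation_pct, x$selection_pct))
  invisible(x)
}

#' Correspondence analysis of a gene x codon RSCU matrix
#'
#' Standard chi-square-metric correspondence analysis: the non-negative
#' matrix is scaled to a correspondence table P, standardised residuals
#' `(P - r c') / sqrt(r c')` are decomposed by SVD, per-axis inertia is the
#' squared singular value, and principal coordinates are mass-rescaled
#' singular vectors. Conventionally applied to the genes x 59 RSCU matrix
#' (single-codon families and stops excluded); missing-family RSCU entries
#' are set to 0 with a warning.
#'
#' @param x a [CodonCounts-class] object, or a non-negative genes x codons
#'   matrix (e.g. [rscuMatrix()] output).
#' @param tol singular values below `tol * max(d)` are treated as null axes.
#' @return List of class `COAResult`: `row_coords`, `col_coords` (principal
#'   coordinates, axes as columns), `inertia_pct` (sums to 100 over retained
#'   axes), `inertia` (raw per-axis), `total_inertia` (= chi-square / grand
#'   total of the input).
#' @export
codonCA <- function(x, tol = 1e-10) {
  M <- if (methods::is(x, "CodonCounts")) rscuMatrix(x) else as.matrix(x)
  if (anyNA(M)) {
    warning(sum(is.na(M)), " missing entries set to 0 (families absent ",
            "from some genes)")
    M[is.na(M)] <- 0
  }
  if (nrow(M) < 2L) stop("need at least 2 rows")
  if (any(M < 0)) stop("matrix must be non-negative")
  tot <- sum(M)
  if (tot <= 0) stop("matrix has zero grand total")
  P <- M / tot
  r <- rowSums(P); cc <- colSums(P)
  keepR <- r > 0; keepC <- cc > 0
  P <- P[keepR, keepC, drop = FALSE]
  r <- r[keepR]; cc <- cc[keepC]
  E <- outer(r, cc)
  S <- (P - E) / sqrt(E)
  sv <- svd(S)
  d <- sv$d
  keep <- d > tol * max(d, 1e-300)
  kmax <- min(nrow(P), ncol(P)) - 1L
  keep[seq_along(keep) > kmax] <- FALSE
  if (!any(keep)) {
    return(structure(list(
      row_coords = matrix(0, nrow(P), 0, dimnames = list(rownames(P), NULL)),
      col_coords = matrix(0, ncol(P), 0, dimnames = list(colnames(P), NULL)),
      inertia_pct = numeric(0), inertia = numeric(0), total_inertia = 0),
      class = "COAResult"))
  }
  d <- d[keep]
  U <- sv$u[, keep, drop = FALSE]
  V <- sv$v[, keep, drop = FALSE]
  rowC <- sweep(U, 1L, sqrt(r), "/") %*% diag(d, length(d))
  colC <- sweep(V, 1L, sqrt(cc), "/") %*% diag(d, length(d))
  dimnames(rowC) <- list(rownames(P), paste0("Axis", seq_along(d)))
  dimnames(colC) <- list(colnames(P), paste0("Axis", seq_along(d)))
  structure(list(row_coords = rowC, col_coords = colC,
                 inertia = d^2,
                 inertia_pct = 100 * d^2 / sum(d^2),
                 total_inertia = sum(d^2)),
            class = "COAResult")
}

#' @export
print.COAResult <- function(x, ...) {
  k <- length(x$inertia_pct)
  cat(sprintf("Correspondence analysis: %d axes, total inertia %.4g\n",
              k, x$total_inertia))
  if (k)
    cat("  inertia %: ",
        paste(sprintf("%.2f", utils::head(x$inertia_pct, 5)), collapse = ", "),
        if (k > 5) ", ..." else "", "\n", sep = "")
  invisible(x)
}
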