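## Shared fixtures: all built in code, no files.

toy_cds <- "ATGGCAGCAGCGTGGTAA"   # M A A A W + stop

## one gene using every sense codon exactly k times: RSCU exactly 1 in every
## family, maximal-entropy synonymous usage
uniform_gene <- function(k = 30, id = "uniform") {
  m <- matrix(k, 1, 61, dimnames = list(id, senseCodons()))
  CodonCounts(m)
}

## random codon-count gene over all 61 sense codons
random_gene <- function(n = 500, id = "rnd", prob = NULL) {
  cod <- sample(senseCodons(), n, replace = TRUE, prob = prob)
  tab <- table(factor(cod, levels = senseCodons()))
  CodonCounts(matrix(as.numeric(tab), 1, 61,
                     dimnames = list(id, senseCodons())))
}

## sample one CDS (character) with per-family codon weights from wfun(fam)
biased_gene_seq <- function(wfun, L = 500,
                            aaW = codonscope:::.cs_default_aaw) {
  sense <- senseCodons()
  w <- stats::setNames(numeric(61), sense)
  for (fam in codonFamilies()) w[fam] <- wfun(fam)
  prob <- (aaW / sum(aaW))[codonToAA(sense)] * w
  prob <- prob / sum(prob)
  paste0(paste(sample(sense, L, TRUE, prob), collapse = ""), "TAA")
}

## 30-gene corpus with 10 planted optimal codons: 3 strongly biased genes
## over-use them, 3 near-uniform genes under-use them, 24 mid-bias genes are
## noise; returns the recovered sensitivity
planted_codons <- c("GCT", "GGT", "CCT", "ACT", "GTT",
                    "CTT", "TCT", "CGT", "ATT", "AAA")

planted_optimal_sensitivity <- function(rep_seed) {
  set.seed(rep_seed)
  seqs <- character(30)
  for (i in 1:3)
    seqs[i] <- biased_gene_seq(function(fam) {
      p <- intersect(planted_codons, fam)
      if (length(p)) {
        w <- rep(0.3 / (length(fam) - 1), length(fam)); names(w) <- fam
        w[p] <- 0.7
      } else {
        w <- rep(1, length(fam)); w[1] <- 6
      }
      w / sum(w)
    })
  for (i in 4:27)
    seqs[i] <- biased_gene_seq(function(fam)
      codonscope:::.rdirichlet1(rep(3, length(fam))))
  for (i in 28:30)
    seqs[i] <- biased_gene_seq(function(fam) {
      w <- rep(1, length(fam))
      p <- intersect(planted_codons, fam)
      if (length(p)) w[match(p, fam)] <- 0.55
      w / sum(w)
    })
  names(seqs) <- sprintf("g%02d", 1:30)
  oc <- optimalCodons(countCodons(seqs))
  length(intersect(oc$optimal, planted_codons)) / length(planted_codons)
}

## neutrality-slope planting: amino-acid profiles mixed along a GC3s
## gradient so expected GC12 is (nearly) linear in expected GC3s; the
## planted slope is the regression of the generator's expected values
neutrality_replicate <- function(rep_seed, n = 20, L = 700) {
  aaBase <- codonscope:::.cs_default_aaw
  aaLow <- aaBase
  aaLow[c("K", "N", "I", "F", "Y")] <- aaLow[c("K", "N", "I", "F", "Y")] * 1.6
  aaHigh <- aaBase
  aaHigh[c("A", "G", "P", "R")] <- aaHigh[c("A", "G", "P", "R")] * 1.6
  gc3 <- seq(0.32, 0.68, length.out = n)
  m <- (gc3 - min(gc3)) / diff(range(gc3))
  seqs <- character(n); eg12 <- eg3 <- numeric(n)
  for (i in seq_len(n)) {
    g <- generateCDS(syntheticSpec(1, L,
                                   aaWeights = (1 - m[i]) * aaLow + m[i] * aaHigh,
                                   biasMode = "uniform", gc3Target = gc3[i],
                                   seed = rep_seed * 1000L + i),
                     prefix = sprintf("G%02d_", i))
    seqs[i] <- as.character(g$sequences)
    eg12[i] <- (g$truth$expected$gc1 + g$truth$expected$gc2) / 2 * 100
    eg3[i] <- g$truth$expected$gc3s * 100
  }
  names(seqs) <- sprintf("G%02d", seq_len(n))
  beta <- unname(stats::coef(stats::lm(eg12 ~ eg3))[2])
  fit <- neutralityFit(countCodons(seqs))
  list(beta_true = beta, fit = fit,
       covered = abs(fit$slope - beta) <= 2 * fit$slope_se)
}

## independent ENC-family oracle: homozygosity as the probability that two
## codons drawn without replacement from the family are identical,
## enumerated over ordered pairs
pair_identity_F <- function(counts) {
  n <- sum(counts)
  if (n <= 1) return(NA_real_)
  same <- sum(counts * (counts - 1))
  f <- same / (n * (n - 1))
  if (f <= 0) NA_real_ else f
}
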