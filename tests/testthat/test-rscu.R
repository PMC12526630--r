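test_that("RSCU and RFSC match the hand-evaluated alanine example", {
  t <- rscu(c(GCA = 2, GCG = 1, GCT = 0, GCC = 0))
  ala <- t[t$aa == "A", ]
  expect_equal(ala$rscu[match("GCA", ala$codon)], 8 / 3, tolerance = 1e-12)
  expect_equal(ala$rscu[match("GCG", ala$codon)], 4 / 3, tolerance = 1e-12)
  expect_equal(ala$rscu[match("GCT", ala$codon)], 0)
  expect_equal(ala$rfsc[match("GCA", ala$codon)], 2 / 3, tolerance = 1e-12)
  expect_equal(ala$rfsc[match("GCG", ala$codon)], 1 / 3, tolerance = 1e-12)
  ## families with no observations are missing, not zero
  expect_true(all(is.na(t$rscu[t$aa == "L"])))
  ## single-codon family: RFSC identically 1
  m <- rscu(c(ATG = 7))
  expect_equal(m$rfsc[m$codon == "ATG"], 1)
  ## two-fold family split 50/50
  f <- rscu(c(TTT = 5, TTC = 5))
  expect_equal(f$rscu[f$aa == "F"], c(1, 1))
  expect_equal(f$rfsc[f$aa == "F"], c(0.5, 0.5))
})

test_that("per-family sums obey the RSCU/RFSC algebra exactly", {
  set.seed(31)
  for (i in 1:10) {
    t <- rscu(random_gene(120))
    for (fam in codonFamilies()) {
      rows <- t[t$codon %in% fam, ]
      if (all(is.na(rows$rscu))) next
      expect_equal(sum(rows$rscu), length(fam), tolerance = 1e-12)
      expect_equal(sum(rows$rfsc), 1, tolerance = 1e-12)
      expect_equal(rows$rscu, rows$rfsc * length(fam), tolerance = 1e-12)
    }
  }
})

test_that("pooled RSCU equals RSCU of summed counts", {
  set.seed(32)
  cc <- countCodons(stats::setNames(
    replicate(4, biased_gene_seq(function(fam)
      codonscope:::.rdirichlet1(rep(1, length(fam))), L = 200)),
    paste0("g", 1:4)))
  direct <- rscu(poolCounts(cc))
  pooled <- rscu(cc)
  expect_equal(pooled$rscu, direct$rscu, tolerance = 1e-12)
  ## and is invariant to gene order
  perm <- rscu(cc[c(3, 1, 4, 2)])
  expect_equal(perm$rscu, pooled$rscu)
})

test_that("RSCU agrees with an independent implementation", {
  set.seed(35)
  for (i in 1:3) {
    g <- biased_gene_seq(function(fam)
      codonscope:::.rdirichlet1(rep(1.5, length(fam))), L = 400)
    mine <- rscu(countCodons(c(g = g)))
    sq <- seqinr::uco(strsplit(tolower(g), "")[[1]], index = "rscu")
    names(sq) <- toupper(names(sq))
    ok <- !is.na(mine$rscu)
    expect_equal(mine$rscu[ok], unname(sq[mine$codon[ok]]),
                 tolerance = 1e-9)
  }
})

test_that("uniform usage classifies as fully unbiased", {
  cls <- classifyCodons(rscu(uniform_gene(25)))
  expect_length(cls$preferred, 0)
  expect_length(cls$over, 0)
  expect_length(cls$under, 0)
})

test_that("classification thresholds and the avg150 identity hold", {
  set.seed(33)
  for (i in 1:25) {
    t <- rscu(random_gene(400, prob = {
      p <- stats::rgamma(61, shape = 0.8); p / sum(p)
    }))
    c60 <- classifyCodons(t, "rfsc60")
    c150 <- classifyCodons(t, "avg150")
    expect_true(all(c60$over %in% c60$preferred))
    expect_length(intersect(c60$over, c60$under), 0)
    ## RSCU = RFSC * n_i makes the avg150 rule equal {RSCU > 1.5} exactly
    expect_setequal(c150$high_freq,
                    t$codon[!is.na(t$rscu) & t$rscu > 1.5])
    deg <- codonDegeneracy()[t$aa] >= 2
    expect_setequal(c60$high_freq,
                    t$codon[!is.na(t$rfsc) & t$rfsc > 0.60 & deg])
    ## single-codon families are never "high-frequency"
    expect_false(any(c("ATG", "TGG") %in% c60$high_freq))
  }
})

test_that("identical genes yield no optimal codons", {
  g <- paste0(strrep(paste(senseCodons(), collapse = ""), 2), "TAA")
  cc <- countCodons(c(a = g, b = g))
  oc <- suppressWarnings(optimalCodons(cc))
  expect_length(oc$optimal, 0)
  expect_true(all(oc$delta_rscu == 0, na.rm = TRUE))
  expect_error(optimalCodons(cc[1]), "at least 2")
})

test_that("a codon over-used in the low-ENC decile is declared optimal", {
  ## hand-built 10-gene set with exact pooled RSCU: the biased gene gives
  ## GCT RSCU 1.8 in the high-bias decile, the uniform-ish gene 0.4 in the
  ## low-bias decile
  sense <- senseCodons()
  base <- matrix(4, 10, 61, dimnames = list(sprintf("g%02d", 1:10), sense))
  ## genes 2-9: moderate shared bias so they sit between the extremes
  for (fam in codonFamilies()) base[2:9, fam[1]] <- 10
  ## gene 1: strong bias everywhere (low ENC), Ala counts 45/19/18/18 ->
  ## RSCU(GCT) = 4*45/100 = 1.8
  base[1, ] <- 1
  for (fam in codonFamilies()) base[1, fam[1]] <- 30
  base[1, c("GCT", "GCA", "GCC", "GCG")] <- c(45, 19, 18, 18)
  ## gene 10: near-uniform (high ENC) with GCT at RSCU 4*10/100 = 0.4
  base[10, ] <- 12
  base[10, c("GCT", "GCA", "GCC", "GCG")] <- c(10, 30, 30, 30)
  oc <- suppressWarnings(optimalCodons(CodonCounts(base)))
  expect_identical(oc$high_genes, "g01")
  expect_identical(oc$low_genes, "g10")
  expect_equal(oc$rscu_high$rscu[oc$rscu_high$codon == "GCT"], 1.8)
  expect_equal(oc$rscu_low$rscu[oc$rscu_low$codon == "GCT"], 0.4)
  expect_true("GCT" %in% oc$optimal)
})

test_that("decile sizing rounds half up with a floor of one gene", {
  expect_identical(codonscope:::.decileSize(24, 0.10), 2L)
  expect_identical(codonscope:::.decileSize(30, 0.10), 3L)
  expect_identical(codonscope:::.decileSize(25, 0.10), 3L)
  expect_identical(codonscope:::.decileSize(5, 0.10), 1L)
})
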