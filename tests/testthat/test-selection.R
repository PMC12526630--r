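test_that("expected-ENC curve evaluates exactly and peaks mid-range", {
  expect_equal(encExpected(0.5), 60.5)
  expect_equal(encExpected(0), 31)
  expect_equal(encExpected(1), 32)
  expect_error(encExpected(1.2), "0, 1")
  s <- seq(0, 1, by = 0.001)
  expect_true(abs(s[which.max(encExpected(s))] - 0.5) < 0.02)
})

test_that("ENC plot separates mutation-only from selected regimes", {
  uni <- generateCDS(syntheticSpec(8, 3000, biasMode = "uniform",
                                   gc3Target = 0.5, seed = 51))
  pts <- encPlotData(countCodons(uni$sequences))
  ## unbiased genes sit on/above the curve up to sampling error
  expect_true(all(pts$enc_obs > pts$enc_exp - 2))
  det <- generateCDS(syntheticSpec(4, 2000, biasMode = "deterministic",
                                   seed = 52))
  dpts <- encPlotData(countCodons(det$sequences))
  expect_true(all(dpts$below_curve))
  ## boundary convention: a point exactly on the curve is not below
  fake <- pts; fake$enc_obs <- fake$enc_exp
  expect_false(any(fake$enc_obs < fake$enc_exp))
})

test_that("PR2 biases match direct third-position ratios", {
  ## glycine-only gene with thirds {A:1, T:3, G:3, C:1}
  g <- c(g = paste0("GGA", strrep("GGT", 3), strrep("GGG", 3), "GGC"))
  p <- pr2PlotData(countCodons(g))
  expect_equal(p$at_bias, 0.25)
  expect_equal(p$gc_bias, 0.75)
  expect_identical(p$quadrant, 4L)
  ## parity: A=T and G=C lands exactly on the center
  bal <- c(g = "GGAGGTGGGGGC")
  pb <- pr2PlotData(countCodons(bal))
  expect_equal(pb$at_bias, 0.5)
  expect_equal(pb$gc_bias, 0.5)
  expect_identical(pb$quadrant, 1L)
  ## zero denominator reported missing
  gg <- pr2PlotData(countCodons(c(g = strrep("GGG", 5))))
  expect_true(is.na(gg$at_bias) && is.na(gg$quadrant))
  ## fourfold-only mode drops two-fold third positions
  mix <- countCodons(c(g = paste0("TTT", "GGA")))
  p4 <- pr2PlotData(mix, fourfoldOnly = TRUE)
  expect_equal(p4$at_bias, 1)        # only GGA remains
})

test_that("neutrality regression recovers the analytic limits", {
  prof <- data.frame(GC3s_pct = c(30, 40, 50, 60, 70),
                     GC12_pct = c(30, 40, 50, 60, 70))
  fit <- suppressWarnings(neutralityFit(prof))
  expect_equal(fit$slope, 1, tolerance = 1e-12)
  expect_equal(fit$r, 1, tolerance = 1e-12)
  expect_equal(fit$mutation_pct + fit$selection_pct, 100)
  flat <- data.frame(GC3s_pct = c(30, 40, 50, 60, 70),
                     GC12_pct = rep(45, 5))
  expect_equal(suppressWarnings(neutralityFit(flat))$slope, 0,
               tolerance = 1e-12)
  degen <- data.frame(GC3s_pct = rep(50, 5), GC12_pct = 1:5 * 10)
  expect_error(neutralityFit(degen), "variance")
  expect_error(neutralityFit(prof[1:2, ]), "at least 3")
})

test_that("correspondence analysis reproduces the chi-square decomposition", {
  M <- matrix(c(10, 2, 3, 5, 1, 8, 2, 4, 6, 6, 6, 6), 3, 4, byrow = TRUE,
              dimnames = list(paste0("g", 1:3), paste0("c", 1:4)))
  ca <- codonCA(M)
  chi2 <- suppressWarnings(unname(stats::chisq.test(M)$statistic))
  expect_equal(ca$total_inertia, chi2 / sum(M), tolerance = 1e-10)
  expect_equal(sum(ca$inertia_pct), 100, tolerance = 1e-9)
  expect_true(all(diff(ca$inertia) <= 1e-12))     # axes ordered
  ## scaling the whole matrix changes nothing
  ca2 <- codonCA(M * 7)
  expect_equal(ca2$inertia_pct, ca$inertia_pct, tolerance = 1e-9)
  expect_equal(abs(ca2$row_coords), abs(ca$row_coords), tolerance = 1e-9)
  ## identical rows: zero inertia, no axes
  flat <- matrix(rep(c(4, 3, 2, 1), each = 3), 3, 4,
                 dimnames = list(paste0("g", 1:3), paste0("c", 1:4)))
  caf <- codonCA(flat)
  expect_equal(caf$total_inertia, 0, tolerance = 1e-12)
  expect_length(caf$inertia_pct, 0)
  ## a matrix with two distinct row profiles has one non-null axis
  two <- rbind(a = c(8, 2, 1, 1), b = c(8, 2, 1, 1) * 3, d = c(1, 1, 2, 8))
  colnames(two) <- paste0("c", 1:4)
  cat2 <- codonCA(two)
  expect_equal(cat2$inertia_pct[1], 100, tolerance = 1e-9)
})

test_that("CA of RSCU matches vegan's correspondence analysis", {
  set.seed(53)
  cc <- countCodons(stats::setNames(
    replicate(6, biased_gene_seq(function(fam)
      codonscope:::.rdirichlet1(rep(1.5, length(fam))), L = 300)),
    paste0("g", 1:6)))
  M <- rscuMatrix(cc)
  M[is.na(M)] <- 0
  ca <- codonCA(M)
  cca <- vegan::cca(as.data.frame(M))
  eig <- cca$CA$eig
  expect_equal(unname(ca$inertia[seq_along(eig)]), unname(eig),
               tolerance = 1e-8)
})

test_that("genes x 59 RSCU input drops single-codon families", {
  set.seed(54)
  cc <- countCodons(stats::setNames(
    replicate(3, biased_gene_seq(function(fam) rep(1 / length(fam),
                                                   length(fam)), L = 200)),
    paste0("g", 1:3)))
  M <- rscuMatrix(cc)
  expect_identical(ncol(M), 59L)
  expect_false(any(c("ATG", "TGG") %in% colnames(M)))
})
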