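test_that("SCUO spans its entropy limits", {
  det <- generateCDS(syntheticSpec(1, 2000, biasMode = "deterministic",
                                   seed = 61))
  expect_equal(unname(scuo(countCodons(det$sequences))), 1)
  expect_equal(unname(scuo(uniform_gene(20))), 0, tolerance = 1e-12)
  expect_error(scuo(countCodons(c(g = "ATGTGG"))), "SCUO undefined")
})

test_that("SCUO and ENC are anti-correlated across bias strengths", {
  set.seed(62)
  concs <- rep(c(0.3, 1, 3, 10, 40), each = 20)
  cc <- countCodons(stats::setNames(vapply(concs, function(a)
    biased_gene_seq(function(fam) codonscope:::.rdirichlet1(
      rep(a, length(fam))), L = 300), character(1)),
    sprintf("g%03d", seq_along(concs))))
  expect_lt(stats::cor(scuo(cc), enc(cc), method = "spearman"), -0.8)
})

test_that("MILC equals -C when observed matches expected exactly", {
  g <- uniform_gene(12)
  L <- sum(senseCounts(g))
  C <- sum(codonDegeneracy() - 1) / L - 0.5
  expect_equal(unname(milc(g)), -C, tolerance = 1e-12)
  ## lower bound: deviation term is a G-statistic, never negative
  set.seed(63)
  for (i in 1:10) {
    r <- random_gene(150)
    Lr <- sum(senseCounts(r))
    pres <- unique(codonToAA(senseCodons()[senseCounts(r)[1, ] > 0]))
    Cr <- sum(codonDegeneracy()[pres] - 1) / Lr - 0.5
    expect_gte(milc(r), -Cr - 1e-12)
  }
})

test_that("MILC is insensitive to count doubling at O(1/L)", {
  set.seed(64)
  g <- random_gene(800)
  doubled <- CodonCounts(codonCounts(g) * 2)
  expect_lt(abs(milc(g) - milc(doubled)), 30 / sum(senseCounts(g)))
  ## dataset-mean expectation: pooled usage scores itself near -C
  cc <- countCodons(c(a = biased_gene_seq(function(fam)
    rep(1 / length(fam), length(fam)), L = 400)))
  expect_true(is.finite(milc(cc, "dataset")))
})

test_that("amino-acid usage frequencies pool and normalise", {
  polyA <- aaUsage(countCodons(c(g = strrep("GCT", 30))))
  expect_equal(unname(polyA["A"]), 100)
  toy <- aaUsage(countCodons(c(toy = toy_cds)))
  expect_equal(unname(toy[c("M", "A", "W")]), c(20, 60, 20))
  set.seed(65)
  expect_equal(sum(aaUsage(random_gene(500))), 100, tolerance = 1e-9)
})

test_that("host comparison flags divergence with inclusive boundaries", {
  set.seed(66)
  g <- random_gene(3000)
  ## a gene against its own usage: no divergence
  v <- senseCounts(g)[1, ]
  self <- data.frame(codon = names(v), aa = codonToAA(names(v)),
                     per1000 = v / sum(v) * 1000)
  class(self) <- c("HostUsageTable", "data.frame")
  attr(self, "host") <- "self"
  expect_identical(hostCompare(g, self)$n_divergent, 0L)
  ## boundary: host at exactly half the gene rate -> ratio 2, divergent
  ## (mass moved to GCA so the host still sums to 1000: no renormalisation)
  h2 <- self
  half <- h2$per1000[h2$codon == "GCT"] / 2
  h2$per1000[h2$codon == "GCT"] <- half
  h2$per1000[h2$codon == "GCA"] <- h2$per1000[h2$codon == "GCA"] + half
  cmpr <- hostCompare(g, h2)
  expect_equal(cmpr$table$ratio[cmpr$table$codon == "GCT"], 2,
               tolerance = 1e-9)
  expect_true("GCT" %in% cmpr$divergent)
})

test_that("host comparison divergent set is symmetric under role swap", {
  set.seed(67)
  a <- random_gene(2000, id = "a")
  b <- random_gene(2000, id = "b",
                   prob = { p <- stats::rgamma(61, 1); p / sum(p) })
  asHost <- function(cc, nm) {
    v <- senseCounts(cc)[1, ]
    h <- data.frame(codon = names(v), aa = codonToAA(names(v)),
                    per1000 = v / sum(v) * 1000)
    class(h) <- c("HostUsageTable", "data.frame")
    attr(h, "host") <- nm
    h
  }
  ab <- hostCompare(a, asHost(b, "b"))
  ba <- hostCompare(b, asHost(a, "a"))
  expect_setequal(ab$divergent, ba$divergent)
})

test_that("packaged host tables load and rank consistently", {
  hosts <- packagedHostTables()
  expect_length(hosts, 6)
  for (h in hosts) expect_equal(sum(h$per1000), 1000, tolerance = 1.5)
  ## a GC3-rich gene set should sit closer to the GC3-rich monocot tables
  g <- generateCDS(syntheticSpec(4, 1200, biasMode = "uniform",
                                 gc3Target = 0.62, seed = 68))
  rk <- rankHosts(countCodons(g$sequences), hosts)
  expect_identical(sort(rk$host), sort(names(hosts)))
  monocots <- c("Triticum_aestivum", "Zea_mays")
  expect_true(all(rk$host[1:2] %in% c(monocots, "Escherichia_coli")))
})

test_that("Spearman panel matches a rank-then-Pearson oracle", {
  set.seed(69)
  d <- data.frame(x = stats::rnorm(20))
  d$y <- d$x^3 + stats::rnorm(20, sd = 0.4)
  d$z <- -d$x
  d$const <- 5
  pan <- correlationPanel(d, xvars = "x", yvars = c("x", "z", "y", "const"))
  expect_equal(pan$rho[pan$y == "x"], 1)
  expect_equal(pan$rho[pan$y == "z"], -1)
  oracle <- stats::cor(rank(d$x), rank(d$y))
  expect_equal(pan$rho[pan$y == "y"], oracle, tolerance = 1e-12)
  expect_true(is.na(pan$rho[pan$y == "const"]))
  expect_error(correlationPanel(d[1:3, ], xvars = "x", yvars = "y"),
               "at least 4")
  ## exact p-values below 10 observations
  small <- correlationPanel(d[1:8, ], xvars = "x", yvars = "y")
  expect_true(small$p > 0 && small$p <= 1)
})
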