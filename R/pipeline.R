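#' Run the full codon-usage-bias analysis and write all tables
#'
#' Orchestrates every stage of the package on one CDS set: composition
#' panel, bias indices, pooled RSCU/RFSC with high-frequency and optimal
#' codon classification, host screening, ENC plot, PR2 plot, neutrality
#' regression, correspondence analysis, SCUO/MILC, amino-acid usage and the
#' Spearman correlation panels. Outputs are TSV files with a two-line
#' header (names, then units), JSON for scalar summaries, a run manifest
#' and a log. Any stage failure aborts with the stage name in the message.
#'
#' @param input path to a CDS FASTA file, or a [Biostrings::DNAStringSet],
#'   or a [CodonCounts-class] object.
#' @param outdir output directory (created if needed).
#' @param hf_rule high-frequency rule for [classifyCodons()].
#' @param quantile extreme-decile fraction for [optimalCodons()].
#' @param reference `ReferenceWeights` for CAI/CBI, or a path readable by
#'   [readReferenceWeights()]; default [defaultReferenceWeights()].
#' @param milc_expected expected distribution for [milc()].
#' @param hosts named list of host tables (default packaged synthetic set).
#' @param convention AT3 convention for [compositionProfile()].
#' @param policy validation policy for [validateCDS()].
#' @param label dataset label used in summary rows.
#' @return Invisibly, a named list of written file paths.
#' @export
runPipeline <- function(input, outdir,
                        hf_rule = c("rfsc60", "avg150"),
                        quantile = 0.10,
                        reference = NULL,
                        milc_expected = c("uniform", "dataset"),
                        hosts = packagedHostTables(),
                        convention = c("caical", "codonw"),
                        policy = c("lenient", "strict"),
                        label = "dataset") {
  hf_rule <- match.arg(hf_rule)
  milc_expected <- match.arg(milc_expected)
  convention <- match.arg(convention)
  policy <- match.arg(policy)
  if (quantile <= 0 || quantile > 0.5) stop("quantile must be in (0, 0.5]")
  if (is.null(reference)) reference <- defaultReferenceWeights()
  if (is.character(reference)) reference <- readReferenceWeights(reference)

  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  logPath <- file.path(outdir, "run.log")
  logCon <- file(logPath, "w")
  on.exit(close(logCon))
  logmsg <- function(...) {
    writeLines(paste0(format(Sys.time(), "%H:%M:%S"), " ", sprintf(...)),
               logCon)
  }
  stage <- function(name, expr) {
    logmsg("stage %s", name)
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  paths <- list()
  put <- function(key, file) { paths[[key]] <<- file.path(outdir, file); paths[[key]] }

  cc <- stage("input", {
    if (methods::is(input, "CodonCounts")) input
    else {
      s <- if (is.character(input)) readCDS(input) else input
      countCodons(validateCDS(s, policy))
    }
  })

  comp <- stage("composition", compositionProfile(cc, convention))
  writeCompositionTSV(rbind(comp,
                            datasetMeans(comp, paste0(label, "_mean"))),
                      put("composition", "composition.tsv"))

  idx <- stage("indices", biasIndices(cc, reference))
  .writeTSV2(idx, put("indices", "indices.tsv"),
             units = c("id", "ENC[20-61]", "CBI[-1,1]", "CAI(0,1]",
                       "kyte-doolittle", "fraction"))

  rs <- stage("rscu", rscu(cc, scope = label))
  cls <- classifyCodons(rs, hf_rule)
  rsOut <- rs
  rsOut$preferred <- rsOut$codon %in% cls$preferred
  rsOut$over <- rsOut$codon %in% cls$over
  rsOut$under <- rsOut$codon %in% cls$under
  rsOut$high_freq <- rsOut$codon %in% cls$high_freq
  .writeTSV2(rsOut, put("rscu", "rscu.tsv"),
             units = c("codon", "aa", "count", "rscu", "rfsc",
                       "rscu>1", "rscu>1.6", "rscu<0.6", hf_rule))
  .writeTSV2(data.frame(dataset = label,
                        n_hf = length(cls$high_freq),
                        hf_codons = paste(cls$high_freq, collapse = ","),
                        stringsAsFactors = FALSE),
             put("hf_codons", "hf_codons.tsv"),
             units = c("id", "count", "codons"))

  opt <- stage("optimal", optimalCodons(cc, quantile))
  .writeTSV2(data.frame(codon = names(opt$delta_rscu),
                        delta_rscu = unname(opt$delta_rscu),
                        rscu_high = opt$rscu_high$rscu,
                        rscu_low = opt$rscu_low$rscu,
                        optimal = names(opt$delta_rscu) %in% opt$optimal,
                        stringsAsFactors = FALSE),
             put("optimal", "optimal_codons.tsv"),
             units = c("codon", "rscu_diff", "rscu", "rscu", "flag"))

  hostRank <- stage("hosts", rankHosts(cc, hosts))
  .writeTSV2(hostRank, put("hosts", "host_comparison.tsv"),
             units = c("host", "codons", "codons", "codons"))

  encTab <- stage("enc_plot", encPlotData(cc))
  .writeTSV2(encTab, put("enc_plot", "enc_plot.tsv"),
             units = c("id", "fraction", "enc", "enc", "flag"))

  pr2 <- stage("pr2", pr2PlotData(cc))
  .writeTSV2(pr2, put("pr2", "pr2.tsv"),
             units = c("id", "A3/(A3+T3)", "G3/(G3+C3)", "1-4"))

  neu <- stage("neutrality", neutralityFit(comp))
  jsonlite::write_json(unclass(neu), put("neutrality", "neutrality.json"),
                       auto_unbox = TRUE, digits = NA)

  ca <- stage("coa", codonCA(cc))
  k <- min(2L, length(ca$inertia_pct))
  coaTab <- if (k > 0)
    data.frame(item = c(rownames(ca$row_coords), rownames(ca$col_coords)),
               type = rep(c("gene", "codon"),
                          c(nrow(ca$row_coords), nrow(ca$col_coords))),
               axis1 = c(ca$row_coords[, 1], ca$col_coords[, 1]),
               axis2 = if (k >= 2) c(ca$row_coords[, 2], ca$col_coords[, 2])
                       else NA_real_,
               stringsAsFactors = FALSE)
  else data.frame(item = character(), type = character(),
                  axis1 = numeric(), axis2 = numeric())
  attr(coaTab, "inertia_pct") <- ca$inertia_pct
  .writeTSV2(coaTab, put("coa", "coa.tsv"),
             units = c("id", "gene|codon", "principal", "principal"))

  exprTab <- stage("expression", data.frame(
    accession = geneIDs(cc),
    scuo = unname(scuo(cc)),
    milc = unname(milc(cc, milc_expected)),
    stringsAsFactors = FALSE))
  .writeTSV2(exprTab, put("expression", "expression.tsv"),
             units = c("id", "scuo[0,1]", "milc"))

  aau <- stage("aa_usage", aaUsage(cc))
  .writeTSV2(data.frame(aa = names(aau), pct = unname(aau),
                        stringsAsFactors = FALSE),
             put("aa_usage", "aa_usage.tsv"), units = c("aa", "percent"))

  corr <- stage("correlations", {
    tab <- cbind(comp, idx[match(comp$accession, idx$accession),
                           c("enc", "cbi", "cai", "gravy", "aroma")],
                 scuo = exprTab$scuo[match(comp$accession,
                                           exprTab$accession)],
                 milc = exprTab$milc[match(comp$accession,
                                           exprTab$accession)])
    compVars <- c("GC_pct", "GC1_pct", "GC2_pct", "GC3s_pct", "A3s_pct",
                  "T3s_pct", "C3s_pct", "G3s_pct", "AT3_pct")
    rbind(correlationPanel(tab, xvars = c("enc", "cai"), yvars = compVars),
          correlationPanel(tab, xvars = c("gravy", "aroma"),
                           yvars = c("enc", "A3s_pct", "T3s_pct", "C3s_pct",
                                     "G3s_pct", "GC3s_pct")),
          correlationPanel(tab, xvars = "scuo", yvars = "milc"))
  })
  .writeTSV2(corr, put("correlations", "correlations.tsv"),
             units = c("var", "var", "spearman", "two-sided", "p<0.05"))

  manifest <- list(
    package = "codonscope",
    version = as.character(utils::packageVersion("codonscope")),
    label = label,
    n_genes = length(cc),
    config = list(hf_rule = hf_rule, quantile = quantile,
                  milc_expected = milc_expected, convention = convention,
                  policy = policy, hosts = names(hosts)),
    outputs = vapply(paths, basename, character(1)))
  jsonlite::write_json(manifest, put("manifest", "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  logmsg("done: %d outputs", length(paths))
  invisible(paths)
}
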