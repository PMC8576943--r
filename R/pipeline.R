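#' @include simdata.R vcf-io.R heterogeneity.R clonality.R neutrality.R phylo.R ihc.R
NULL

## tiny polynomial rolling hash so every artifact can embed a config
## fingerprint (stability across runs matters, cryptography does not)
.configDigest <- function(config) {
  s <- jsonlite::toJSON(config, auto_unbox = TRUE)
  h <- 0
  for (b in utf8ToInt(as.character(s)))
    h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

.runHeader <- function(config, seed) {
  list(tool = "clonescape",
       version = as.character(utils::packageVersion("clonescape")),
       seed = seed, config_digest = .configDigest(config))
}

## load a (possibly already filtered) table from config$input VCF
.pipelineTable <- function(config) {
  stopifnot(!is.null(config$input))
  if (!file.exists(config$input))
    stop(sprintf("input file '%s' does not exist", config$input))
  vt <- readVcf(config$input)
  rules <- if (!is.null(config$rules)) do.call(filterRules, config$rules)
           else filterRules()
  recoverVariants(applyFilters(vt, rules))
}

#' Run one pipeline stage
#'
#' Drives the package end-to-end with a reproducible configuration:
#' \describe{
#'   \item{simulate}{generate a synthetic tumor (\code{config$sim} holds
#'     [simConfig()] fields) and write VCF + truth TSV.}
#'   \item{filter}{read \code{config$input} VCF, apply [filterRules()]
#'     (\code{config$rules}) and recovery, write filtered VCF, TSV and log.}
#'   \item{het}{sharing spectrum, miss rates and multi-hit genes.}
#'   \item{clonality}{per-sample and per-patient CCF, clonal-illusion
#'     report, apparent-clonal curve, balance factor and samples needed.}
#'   \item{neutrality}{the 1/f panel.}
#'   \item{phylo}{maximum-parsimony tree(s), newick output.}
#'   \item{ihc}{H-scores for \code{config$input} staining TSV.}
#'   \item{report}{all per-patient analyses aggregated into one JSON.}
#' }
#' Every stage writes \code{<stage>_summary.json} embedding tool version,
#' seed and a config digest. On error, files written by the failed stage are
#' removed.
#'
#' @param subcommand one of simulate, filter, het, clonality, neutrality,
#'   phylo, ihc, report.
#' @param config named list of stage parameters (or path to a JSON file).
#' @param out_dir output directory (created if needed).
#' @param seed integer seed for every stochastic step.
#' @return (invisibly) the stage summary list.
#' @export
runPipeline <- function(subcommand, config = list(), out_dir = ".",
                        seed = 1L) {
  cmds <- c("simulate", "filter", "het", "clonality", "neutrality",
            "phylo", "ihc", "report")
  if (!is.character(subcommand) || !subcommand %in% cmds)
    stop("usage: runPipeline(<", paste(cmds, collapse = "|"), ">, config, out_dir, seed)")
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  out <- function(name) {
    p <- file.path(out_dir, name)
    written <<- c(written, p)
    p
  }
  summary <- .runHeader(config, seed)
  res <- tryCatch({
    switch(subcommand,
      simulate = {
        sim <- do.call(simConfig, c(config$sim, list(seed = seed)))
        vt <- simulateTumor(sim)
        writeVcf(vt, out("simulated.vcf"))
        writeSimTruth(vt, out("truth.tsv"))
        summary$n_variants <- nrow(vt)
        summary$n_samples <- length(tumorSamples(vt))
        summary
      },
      filter = {
        vt <- .pipelineTable(config)
        writeVcf(vt, out("filtered.vcf"))
        writeVariantTsv(vt, out("filtered.tsv"))
        utils::write.table(filterLog(vt), out("filter_log.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
        summary$n_passing <- sum(rowSums(presence(vt)) > 0)
        summary$n_removed_calls <- nrow(filterLog(vt))
        summary
      },
      het = {
        vt <- .pipelineTable(config)
        sp <- sharingSpectrum(vt)
        miss <- singleSampleMissRate(vt)
        summary$sharing_counts <- sp@counts
        summary$sharing_percent <- sharingPercentages(sp)
        summary$fraction_ubiquitous <- fractionUbiquitous(sp)
        summary$miss_rate_per_sample <- as.list(miss$per_sample)
        summary$multihit_genes <- multihitGenes(vt)$gene
        summary
      },
      clonality = {
        vt <- .pipelineTable(config)
        ps <- perSampleClonality(vt)
        pp <- perPatientClonality(vt)
        utils::write.table(as.data.frame(ps), out("ccf_per_sample.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        utils::write.table(as.data.frame(pp), out("ccf_per_patient.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        set.seed(seed)
        curve <- apparentClonalCurve(vt)
        fit <- fitBalanceFactor(curve)
        jsonlite::write_json(list(g = fit@g, c_inf = fit@c_inf,
                                  curve = fit@curve),
                             out("balance_fit.json"), auto_unbox = TRUE,
                             digits = NA)
        summary$tally <- clonalityTally(pp$status)
        summary$illusion <- clonalIllusionReport(ps, pp)$variant_id
        summary$g <- fit@g
        p_target <- if (is.null(config$p_target)) 0.90 else config$p_target
        summary$samples_needed <- samplesNeeded(fit@g, p_target)
        summary
      },
      neutrality = {
        vt <- .pipelineTable(config)
        cfg <- if (is.null(config$neutrality)) neutralityConfig()
               else do.call(neutralityConfig, config$neutrality)
        panel <- neutralityPanel(vt, cfg,
                                 exclude = config$exclude %||% character())
        tabl <- neutralityTable(panel, patientID(vt))
        utils::write.table(tabl, out("neutrality.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
        summary$pooled_verdict <- verdict(panel$pooled)
        summary$mean_ks <- panel$summary$mean_ks
        summary$sd_ks <- panel$summary$sd_ks
        summary
      },
      phylo = {
        vt <- .pipelineTable(config)
        bm <- buildMatrix(vt)
        trees <- maxParsimony(bm)
        writeNewick(trees[[1]], out("parsimony.nwk"))
        summary$score <- parsimonyScore(trees[[1]])
        summary$n_cooptimal <- length(trees)
        summary$newick <- trees[[1]]@newick
        summary
      },
      ihc = {
        stopifnot(!is.null(config$input))
        prof <- utils::read.delim(config$input, stringsAsFactors = FALSE)
        scored <- ihcScoreTable(prof)
        utils::write.table(scored, out("ihc_scores.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
        summary$n_cases <- nrow(scored)
        summary
      },
      report = {
        vt <- .pipelineTable(config)
        sp <- sharingSpectrum(vt)
        pp <- perPatientClonality(vt)
        set.seed(seed)
        fit <- fitBalanceFactor(apparentClonalCurve(vt))
        panel <- neutralityPanel(vt)
        trees <- maxParsimony(buildMatrix(vt))
        writeNewick(trees[[1]], out("parsimony.nwk"))
        summary$patient <- patientID(vt)
        summary$total_variants <- sum(rowSums(presence(vt)) > 0)
        summary$sharing_counts <- sp@counts
        summary$clonality <- clonalityTally(pp$status)
        summary$g <- fit@g
        summary$samples_needed <- samplesNeeded(fit@g, 0.90)
        summary$neutrality <- list(pooled_verdict = verdict(panel$pooled),
                                   mean_ks = panel$summary$mean_ks,
                                   sd_ks = panel$summary$sd_ks)
        summary$parsimony_score <- parsimonyScore(trees[[1]])
        summary
      })
  }, error = function(e) {
    unlink(written)
    stop(sprintf("pipeline '%s' failed: %s", subcommand,
                 conditionMessage(e)), call. = FALSE)
  })
  jsonlite::write_json(res, file.path(out_dir,
                                      paste0(subcommand, "_summary.json")),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
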