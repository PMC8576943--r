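#' @include VariantTable-methods.R
NULL

## canonical rule order; the first failing rule is the one logged
FILTER_RULE_ORDER <- c("min_af", "min_depth", "min_alt_reads", "strand_bias",
                       "blacklist", "homopolymer", "max_population_af",
                       "effect", "census")

#' Somatic variant filtering rules
#'
#' Thresholds of the retention filter applied per variant and tumor sample:
#' allele fraction >= \code{min_af}, total depth >= \code{min_depth} in the
#' tumor \emph{or} the matched normal sample, >= \code{min_alt_reads}
#' variant-supporting reads, no strand bias, not blacklisted, AF strictly
#' above \code{homopolymer_min_af} when the site lies in a homopolymer run,
#' population (ExAC-style) AF below \code{max_population_af}, optionally a
#' non-synonymous effect, and optionally (\code{census_rescue}) membership in
#' COSMIC/ICGC or a Cancer Gene Census gene for otherwise unknown variants.
#'
#' @param min_af minimum allele fraction (default 0.05).
#' @param min_depth minimum total depth in tumor or matched normal (10).
#' @param min_alt_reads minimum variant-supporting reads in the tumor (2).
#' @param homopolymer_min_af AF that homopolymer-region calls must exceed (0.10).
#' @param max_population_af maximum population allele frequency (0.01).
#' @param require_nonsynonymous drop synonymous/other effects when TRUE.
#' @param census_rescue when TRUE, calls neither known somatic nor in a
#'   census gene are dropped.
#' @return a \code{FilterRules} list.
#' @export
filterRules <- function(min_af = 0.05, min_depth = 10, min_alt_reads = 2,
                        homopolymer_min_af = 0.10, max_population_af = 0.01,
                        require_nonsynonymous = FALSE, census_rescue = FALSE) {
  stopifnot(min_af >= 0, min_af <= 1, min_depth >= 0, min_alt_reads >= 0,
            homopolymer_min_af >= 0, homopolymer_min_af <= 1,
            max_population_af >= 0, max_population_af <= 1,
            is.logical(require_nonsynonymous), is.logical(census_rescue))
  structure(list(min_af = min_af, min_depth = min_depth,
                 min_alt_reads = min_alt_reads,
                 homopolymer_min_af = homopolymer_min_af,
                 max_population_af = max_population_af,
                 require_nonsynonymous = require_nonsynonymous,
                 census_rescue = census_rescue),
            class = c("FilterRules", "list"))
}

#' @rdname filterRules
#' @param path JSON file.
#' @export
readFilterRules <- function(path) {
  do.call(filterRules, jsonlite::read_json(path, simplifyVector = TRUE))
}

#' @rdname filterRules
#' @param rules a \code{FilterRules} object.
#' @export
writeFilterRules <- function(rules, path) {
  jsonlite::write_json(unclass(rules), path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

## per-rule failure matrices (variants x tumor samples), in canonical order
.ruleFailures <- function(table, rules) {
  ts <- tumorSamples(table)
  af <- .tumorAssay(table, "af")
  depth <- .tumorAssay(table, "depth")
  alt <- .tumorAssay(table, "alt")
  rd <- SummarizedExperiment::rowData(table)
  nsamp <- length(ts)
  rowmat <- function(v) matrix(v, nrow(table), nsamp)
  nd <- .normalSample(table)
  depth_ok <- depth >= rules$min_depth
  if (!is.null(nd))
    depth_ok <- depth_ok |
      rowmat(SummarizedExperiment::assay(table, "depth")[, nd] >= rules$min_depth)
  list(
    min_af = af < rules$min_af,
    min_depth = !depth_ok,
    min_alt_reads = alt < rules$min_alt_reads,
    strand_bias = rowmat(rd$strand_bias),
    blacklist = rowmat(rd$blacklist),
    homopolymer = rowmat(rd$homopolymer) & af <= rules$homopolymer_min_af,
    max_population_af = rowmat(rd$population_af >= rules$max_population_af),
    effect = rowmat(rules$require_nonsynonymous & !rd$effect %in% NONSYN_EFFECTS),
    census = rowmat(rules$census_rescue & !(rd$known_somatic | rd$census_gene)))
}

#' Apply the retention filter
#'
#' Evaluates every rule of \code{rules} for every variant in every tumor
#' sample. A call passes iff no rule fails; the \code{filter} assay records
#' \code{"PASS"} or the first failing rule (in the canonical order min_af,
#' min_depth, min_alt_reads, strand_bias, blacklist, homopolymer,
#' max_population_af, effect, census), and the filter log records every
#' removal. The union of passing calls and logged removals is exactly the
#' input call set.
#'
#' @param table a \linkS4class{VariantTable}.
#' @param rules a [filterRules()] object.
#' @return the table with \code{filter} and \code{present} assays set and
#'   \code{filterLog(x)} available.
#' @seealso [recoverVariants()] for the cross-sample recovery pass.
#' @export
applyFilters <- function(table, rules = filterRules()) {
  stopifnot(methods::is(table, "VariantTable"))
  methods::validObject(table)
  ts <- tumorSamples(table)
  fails <- .ruleFailures(table, rules)
  first <- matrix("PASS", nrow(table), length(ts),
                  dimnames = list(rownames(table), ts))
  for (rule in rev(FILTER_RULE_ORDER))
    first[fails[[rule]]] <- rule
  nfail <- Reduce(`+`, lapply(fails, function(m) m * 1L))
  filt <- matrix("NORMAL", nrow(table), ncol(table),
                 dimnames = dimnames(table))
  filt[, ts] <- first
  present <- filt == "PASS"
  SummarizedExperiment::assay(table, "filter") <- filt
  SummarizedExperiment::assay(table, "present") <- present
  rem <- which(first != "PASS", arr.ind = TRUE)
  metadata(table)$filter_log <- data.frame(
    variant_id = rownames(table)[rem[, 1]],
    sample = ts[rem[, 2]],
    rule = first[rem])
  metadata(table)$fail_only_min_af <- (nfail == 1L) & fails$min_af
  metadata(table)$filter_rules <- rules
  table
}

#' Cross-sample variant recovery
#'
#' For every variant passing in at least one tumor sample at
#' AF >= \code{min_af}, re-marks as present (\code{"RESCUED"}) any other
#' sample of the same patient where the call was removed solely because its
#' AF fell below \code{min_af} — all other rules still binding. Never removes
#' calls; idempotent.
#'
#' @param table a filtered \linkS4class{VariantTable}.
#' @return the table with recovered calls marked present.
#' @export
recoverVariants <- function(table) {
  if (!isFiltered(table)) stop("run applyFilters() first")
  rules <- metadata(table)$filter_rules
  ts <- tumorSamples(table)
  af <- .tumorAssay(table, "af")
  pres <- presence(table)
  anchor <- rowSums(pres & af >= rules$min_af) > 0
  resc <- metadata(table)$fail_only_min_af & anchor
  if (any(resc)) {
    filt <- SummarizedExperiment::assay(table, "filter")
    prall <- SummarizedExperiment::assay(table, "present")
    filt[, ts][resc] <- "RESCUED"
    prall[, ts][resc] <- TRUE
    SummarizedExperiment::assay(table, "filter") <- filt
    SummarizedExperiment::assay(table, "present") <- prall
    log <- metadata(table)$filter_log
    key <- paste(log$variant_id, log$sample)
    ridx <- which(resc, arr.ind = TRUE)
    rkey <- paste(rownames(table)[ridx[, 1]], ts[ridx[, 2]])
    metadata(table)$filter_log <- log[!key %in% rkey, , drop = FALSE]
    metadata(table)$fail_only_min_af <- metadata(table)$fail_only_min_af & !resc
  }
  table
}

#' Per-call presence status
#'
#' Classifies every variant/tumor-sample pair as \code{"present"} (passing,
#' including rescued), \code{"absent"} (covered but filtered out or
#' reference) or \code{"not_assessable"} (zero depth).
#'
#' @param table a filtered \linkS4class{VariantTable}.
#' @return character matrix, variants x tumor samples.
#' @export
presenceStatus <- function(table) {
  pres <- presence(table)
  depth <- .tumorAssay(table, "depth")
  out <- ifelse(pres, "present", ifelse(depth > 0, "absent", "not_assessable"))
  out
}

#' Tumor mutational burden
#'
#' Number of passing non-synonymous variants (missense, nonsense, frameshift)
#' per megabase of targeted exome, per tumor sample.
#'
#' @param table a filtered \linkS4class{VariantTable}.
#' @param panel_size_mb exome panel size in megabases.
#' @return named numeric vector, mutations per Mb.
#' @export
tmb <- function(table, panel_size_mb) {
  if (!is.numeric(panel_size_mb) || panel_size_mb <= 0)
    stop("panel_size_mb must be > 0")
  pres <- presence(table)
  nonsyn <- SummarizedExperiment::rowData(table)$effect %in% NONSYN_EFFECTS
  colSums(pres & nonsyn) / panel_size_mb
}

#' Microsatellite instability classification
#'
#' Classifies an instability score (percentage of unstable microsatellite
#' sites) into MSS (< 10), MSI-L (10 to 30, closed interval) or MSI-H (> 30).
#' The published boundary sentence is internally inconsistent about where
#' exactly MSI-L starts and ends; the closed interval [10, 30] is this
#' package's resolution, chosen so the three classes partition [0, 100].
#'
#' @param score_percent score(s) in [0, 100].
#' @return character vector in \code{c("MSS", "MSI-L", "MSI-H")}.
#' @examples
#' classifyMsi(c(5, 20, 35))
#' @export
classifyMsi <- function(score_percent) {
  if (any(is.na(score_percent)) ||
      any(score_percent < 0 | score_percent > 100))
    stop("score_percent must lie in [0, 100]")
  ifelse(score_percent < 10, "MSS",
         ifelse(score_percent > 30, "MSI-H", "MSI-L"))
}
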