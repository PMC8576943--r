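#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- SimpleList
#' @import SummarizedExperiment
NULL

## effect classes counted as non-synonymous throughout
NONSYN_EFFECTS <- c("missense", "nonsense", "frameshift")
VALID_EFFECTS <- c("synonymous", NONSYN_EFFECTS, "other")
VALID_TISSUES <- c("primary", "lymph_node", "normal")

REQUIRED_ROWDATA <- c("chrom", "pos", "ref", "alt", "gene", "effect",
                      "homopolymer", "strand_bias", "blacklist",
                      "population_af", "known_somatic", "census_gene")

#' Multi-sample somatic variant table
#'
#' A \code{VariantTable} holds the somatic variants of one patient across all
#' regional tumor samples (and the matched normal) as a
#' \linkS4class{SummarizedExperiment}: rows are variants, columns are samples.
#' Assays \code{depth}, \code{alt} and \code{af} carry per-sample read support;
#' after [applyFilters()] the assays \code{filter} (first failing rule or
#' \code{"PASS"}/\code{"RESCUED"}) and \code{present} (logical) record the
#' filter state. \code{colData} carries per-sample tumor purity and tissue
#' type (\code{primary}, \code{lymph_node} or \code{normal}); \code{rowData}
#' carries the variant annotations the filtering rules consume.
#'
#' @slot .. see \linkS4class{SummarizedExperiment}; no additional slots.
#' @seealso [VariantTable()], [applyFilters()], [recoverVariants()]
#' @exportClass VariantTable
setClass("VariantTable", contains = "SummarizedExperiment")

setValidity("VariantTable", function(object) {
  msg <- character()
  an <- SummarizedExperiment::assayNames(object)
  need <- c("depth", "alt", "af")
  if (!all(need %in% an))
    msg <- c(msg, paste("missing assays:", paste(setdiff(need, an), collapse = ", ")))
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("purity", "tissue") %in% colnames(cd)))
    msg <- c(msg, "colData must contain 'purity' and 'tissue'")
  else {
    if (!all(cd$tissue %in% VALID_TISSUES))
      msg <- c(msg, "tissue must be one of primary/lymph_node/normal")
    tum <- cd$tissue != "normal"
    if (any(is.na(cd$purity[tum])) || any(cd$purity[tum] <= 0 | cd$purity[tum] > 1))
      msg <- c(msg, "tumor purity must lie in (0, 1]")
  }
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "sample ids must be unique")
  rd <- SummarizedExperiment::rowData(object)
  miss <- setdiff(REQUIRED_ROWDATA, colnames(rd))
  if (length(miss))
    msg <- c(msg, paste("missing rowData columns:", paste(miss, collapse = ", ")))
  if (length(msg) == 0L && nrow(object) > 0L) {
    d <- SummarizedExperiment::assay(object, "depth")
    a <- SummarizedExperiment::assay(object, "alt")
    if (any(a < 0 | d < 0, na.rm = TRUE)) msg <- c(msg, "negative read counts")
    if (any(a > d, na.rm = TRUE)) msg <- c(msg, "alt reads exceed depth")
    if (any(rd$pos < 1)) msg <- c(msg, "positions must be >= 1")
    if (!all(rd$effect %in% VALID_EFFECTS)) msg <- c(msg, "unknown effect class")
  }
  if (length(msg)) msg else TRUE
})

#' Simulated subclone phylogeny
#'
#' The clone tree of one simulated tumor: each clone has a parent, a private
#' mutation count, and a per-region cell fraction. The root (founding) clone
#' has fraction 1 in every region; along any root-to-leaf path mutation sets
#' are nested, so a cell of a child clone carries all ancestral mutations.
#'
#' @slot clones data.frame with columns \code{clone}, \code{parent} (NA for
#'   the root), \code{n_private}.
#' @slot fractions numeric matrix, clones x regions, cell fraction of each
#'   clone (cells belonging to the clone or any descendant) per region.
#' @slot mutations \link[S4Vectors]{DataFrame} of every simulated mutation:
#'   \code{variant_id}, \code{clone}, \code{phi} (intra-clone frequency; 1 for
#'   clone-defining mutations, < 1 possible for neutral-tail mutations),
#'   \code{multiplicity}, \code{class} (\code{trunk}/\code{branch}/\code{tail}).
#' @slot config the [simConfig()] list that generated the tree.
#' @exportClass SubcloneTree
setClass("SubcloneTree",
         representation(clones = "data.frame", fractions = "matrix",
                        mutations = "DataFrame", config = "list"))

setValidity("SubcloneTree", function(object) {
  msg <- character()
  cl <- object@clones
  fr <- object@fractions
  if (!all(cl$clone == rownames(fr))) msg <- c(msg, "fraction rows must match clones")
  if (any(fr < 0 | fr > 1)) msg <- c(msg, "cell fractions must lie in [0, 1]")
  root <- cl$clone[is.na(cl$parent)]
  if (length(root) != 1L) msg <- c(msg, "exactly one root clone required")
  else if (any(fr[root, ] != 1)) msg <- c(msg, "root fraction must be 1 in every region")
  ## parent fraction must cover the sum of its children's fractions
  for (p in cl$clone) {
    kids <- cl$clone[!is.na(cl$parent) & cl$parent == p]
    if (length(kids)) {
      resid <- fr[p, ] - colSums(fr[kids, , drop = FALSE])
      if (any(resid < -1e-9))
        msg <- c(msg, sprintf("children of clone '%s' exceed its fraction", p))
    }
  }
  if (length(msg)) msg else TRUE
})

#' Neutral-evolution test result
#'
#' Result of fitting the cumulative mutation count M(f) against 1/f (the
#' neutral expectation) for one VAF set: the through-origin slope (an
#' estimate of the effective mutation rate mu/beta), the coefficient of
#' determination, the Kolmogorov distance between the normalized empirical
#' and theoretical cumulative distributions, and the verdict.
#'
#' @slot sample sample id, or \code{"pooled"}.
#' @slot n_in_window mutations inside the fit window.
#' @slot mu_eff_hat,r2,ks_distance fit statistics (NA when insufficient).
#' @slot verdict \code{"neutral"}, \code{"non_neutral"} or \code{"insufficient"}.
#' @slot config the [neutralityConfig()] used.
#' @exportClass NeutralityResult
setClass("NeutralityResult",
         representation(sample = "character", n_in_window = "integer",
                        mu_eff_hat = "numeric", r2 = "numeric",
                        ks_distance = "numeric", verdict = "character",
                        config = "list"))

setValidity("NeutralityResult", function(object) {
  msg <- character()
  if (!object@verdict %in% c("neutral", "non_neutral", "insufficient"))
    msg <- c(msg, "invalid verdict")
  if (!is.na(object@r2) && (object@r2 > 1 + 1e-12))
    msg <- c(msg, "r2 must be <= 1")
  if (!is.na(object@ks_distance) &&
      (object@ks_distance < 0 || object@ks_distance > 1))
    msg <- c(msg, "ks_distance must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Balance-factor fit
#'
#' Fit of the apparent-clonal curve C(n) (mean number of variants shared by
#' all members of a random n-sample subset) to the geometric model
#' C(n) = c_inf + (C(1) - c_inf) g^(n-1). The balance factor g in (0,1)
#' summarizes how evenly the phylogeny partitions the tumor mass; c_inf is
#' the asymptotic apparent-clonal count.
#'
#' @slot g balance factor.
#' @slot c_inf asymptotic apparent-clonal count.
#' @slot curve observed C(n), n = 1..n_samples.
#' @slot residual residual sum of squares of the fit.
#' @exportClass BalanceFit
setClass("BalanceFit",
         representation(g = "numeric", c_inf = "numeric",
                        curve = "numeric", residual = "numeric"))

setValidity("BalanceFit", function(object) {
  msg <- character()
  if (object@g <= 0 || object@g >= 1) msg <- c(msg, "g must lie in (0, 1)")
  if (object@c_inf < 0) msg <- c(msg, "c_inf must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Reconstructed tree over tumor regions
#'
#' An (outgroup-rooted) maximum-parsimony tree over the regional samples of
#' one patient, with per-branch assigned variant counts and the total
#' parsimony score (number of state changes) under Fitch scoring.
#'
#' @slot phylo an \link[ape]{ape} \code{phylo} object (tips = samples plus
#'   the all-zero outgroup).
#' @slot score integer parsimony length.
#' @slot branch_mutations integer vector of variant counts assigned to each
#'   edge of \code{phylo} (same order as \code{phylo$edge}).
#' @slot newick canonical newick string (used for deterministic ordering of
#'   co-optimal trees).
#' @exportClass SampleTree
setClass("SampleTree",
         representation(phylo = "ANY", score = "integer",
                        branch_mutations = "integer", newick = "character"))
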