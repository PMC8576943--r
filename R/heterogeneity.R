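#' @include filters.R
NULL

#' Variant sharing spectrum
#'
#' Distribution of variants over the number of regional samples in which each
#' is present: \code{counts[k]} is the number of variants detected in exactly
#' k of the n tumor samples of one patient.
#'
#' @slot counts integer vector of length n_samples (k = 1..n).
#' @slot n_samples number of tumor samples.
#' @slot total sum of counts.
#' @exportClass SharingSpectrum
setClass("SharingSpectrum",
         representation(counts = "integer", n_samples = "integer",
                        total = "integer"))

setValidity("SharingSpectrum", function(object) {
  msg <- character()
  if (length(object@counts) != object@n_samples)
    msg <- c(msg, "counts must have one entry per sample count k = 1..n")
  if (any(object@counts < 0)) msg <- c(msg, "counts must be >= 0")
  if (sum(object@counts) != object@total)
    msg <- c(msg, "total must equal sum(counts)")
  if (length(msg)) msg else TRUE
})

#' @describeIn SharingSpectrum-class Construct a spectrum directly from
#'   occupancy counts (e.g. a published tally): \code{counts[k]} = variants
#'   in exactly k samples.
#' @param counts integer vector of occupancy counts, k = 1..n.
#' @export
SharingSpectrum <- function(counts) {
  methods::new("SharingSpectrum", counts = as.integer(counts),
               n_samples = length(counts), total = as.integer(sum(counts)))
}

setMethod("show", "SharingSpectrum", function(object) {
  cat(sprintf("SharingSpectrum over %d samples, %d variants\n",
              object@n_samples, object@total))
  if (object@total > 0) {
    pct <- sprintf("%.1f%%", 100 * object@counts / object@total)
    cat(paste(sprintf("  %d sample(s): %d (%s)", seq_along(object@counts),
                      object@counts, pct), collapse = "\n"), "\n")
  }
})

#' Compute the sharing spectrum of a patient
#'
#' Tallies post-recovery presence: how many variants are found in exactly
#' 1, 2, ..., n tumor samples. Variants present in no sample do not count.
#'
#' @param table a filtered (and typically [recoverVariants()]-recovered)
#'   \linkS4class{VariantTable}.
#' @param effect which variants to tally: non-synonymous (missense/nonsense/
#'   frameshift), synonymous, or all.
#' @return a \linkS4class{SharingSpectrum}.
#' @export
sharingSpectrum <- function(table,
                            effect = c("nonsynonymous", "synonymous", "all")) {
  effect <- match.arg(effect)
  pres <- presence(table)
  keep <- switch(effect,
    nonsynonymous = SummarizedExperiment::rowData(table)$effect %in% NONSYN_EFFECTS,
    synonymous = SummarizedExperiment::rowData(table)$effect == "synonymous",
    all = rep(TRUE, nrow(table)))
  occ <- rowSums(pres[keep, , drop = FALSE])
  n <- ncol(pres)
  SharingSpectrum(tabulate(occ[occ > 0], nbins = n))
}

#' @rdname sharingFractions
#' @export
fractionUbiquitous <- function(spectrum) {
  stopifnot(methods::is(spectrum, "SharingSpectrum"))
  if (spectrum@total == 0) return(NA_real_)
  spectrum@counts[spectrum@n_samples] / spectrum@total
}

#' Ubiquity fractions of a sharing spectrum
#'
#' \code{fractionUbiquitous}: fraction of variants present in every sample
#' (counts[n]/total). \code{fractionNotUbiquitous}: its complement — the
#' fraction a single-sample analysis can miss. \code{sharingPercentages}:
#' all counts as percentages rounded to one decimal (report convention).
#' All return \code{NA} for an empty spectrum.
#'
#' @param spectrum a \linkS4class{SharingSpectrum}.
#' @name sharingFractions
#' @export
fractionNotUbiquitous <- function(spectrum) {
  f <- fractionUbiquitous(spectrum)
  if (is.na(f)) NA_real_ else 1 - f
}

#' @rdname sharingFractions
#' @export
sharingPercentages <- function(spectrum) {
  stopifnot(methods::is(spectrum, "SharingSpectrum"))
  if (spectrum@total == 0) return(rep(NA_real_, spectrum@n_samples))
  round(100 * spectrum@counts / spectrum@total, 1)
}

#' Single-sample miss rates
#'
#' Per tumor sample: the fraction of the patient's variant union that the
#' sample does not carry. Also the patient-level not-ubiquitous fraction
#' (variants absent from at least one sample).
#'
#' @param table a filtered \linkS4class{VariantTable}.
#' @param effect variant class to tally (see [sharingSpectrum()]).
#' @return list with \code{per_sample} (named vector), \code{not_ubiquitous},
#'   \code{n_variants}.
#' @export
singleSampleMissRate <- function(table, effect = "nonsynonymous") {
  sp <- sharingSpectrum(table, effect)
  pres <- presence(table)
  keep <- switch(effect,
    nonsynonymous = SummarizedExperiment::rowData(table)$effect %in% NONSYN_EFFECTS,
    synonymous = SummarizedExperiment::rowData(table)$effect == "synonymous",
    all = rep(TRUE, nrow(table)))
  pres <- pres[keep & rowSums(presence(table)[keep, , drop = FALSE]) > 0, ,
               drop = FALSE]
  nv <- nrow(pres)
  per <- if (nv > 0) 1 - colSums(pres) / nv else
    stats::setNames(rep(NA_real_, ncol(pres)), colnames(pres))
  list(per_sample = per, not_ubiquitous = fractionNotUbiquitous(sp),
       n_variants = nv)
}

#' Cohort range of single-sample miss rates
#'
#' @param tables list of filtered \linkS4class{VariantTable}s (one patient
#'   each); patients without variants are excluded.
#' @param effect variant class to tally.
#' @return list with per-patient not-ubiquitous fractions and their
#'   \code{min}/\code{max}.
#' @export
missRateSummary <- function(tables, effect = "nonsynonymous") {
  fr <- vapply(tables, function(t)
    singleSampleMissRate(t, effect)$not_ubiquitous, numeric(1))
  names(fr) <- vapply(tables, patientID, character(1))
  fr <- fr[!is.na(fr)]
  list(per_patient = fr, min = min(fr), max = max(fr))
}

#' Compare variant sets of two sample groups
#'
#' Counts variants private to group A (e.g. the primary tumor samples),
#' private to group B (e.g. lymph-node metastases), and shared, where a
#' group carries a variant if any member sample does.
#'
#' @param table a filtered \linkS4class{VariantTable}.
#' @param group_a,group_b disjoint character vectors of tumor sample ids.
#' @return named integer vector \code{c(private_a, private_b, shared)}.
#' @export
compareSets <- function(table, group_a, group_b) {
  if (length(intersect(group_a, group_b)))
    stop("sample groups must be disjoint")
  pres <- presence(table)
  stopifnot(all(c(group_a, group_b) %in% colnames(pres)))
  ina <- rowSums(pres[, group_a, drop = FALSE]) > 0
  inb <- rowSums(pres[, group_b, drop = FALSE]) > 0
  c(private_a = sum(ina & !inb), private_b = sum(!ina & inb),
    shared = sum(ina & inb))
}

#' Genes hit by multiple distinct variants
#'
#' Genes carrying two or more distinct non-synonymous variants (keyed on
#' chrom/pos/ref/alt) in the same patient — candidates for parallel
#' evolution when the variants occupy disjoint sample sets.
#'
#' @param table a filtered \linkS4class{VariantTable}.
#' @return data.frame with \code{gene}, \code{n_variants} and
#'   \code{disjoint_pattern} (TRUE when some pair of the gene's variants is
#'   found in non-overlapping sample sets).
#' @export
multihitGenes <- function(table) {
  pres <- presence(table)
  rd <- SummarizedExperiment::rowData(table)
  keep <- rd$effect %in% NONSYN_EFFECTS & rowSums(pres) > 0
  pres <- pres[keep, , drop = FALSE]
  key <- sprintf("%s:%d_%s>%s", rd$chrom[keep], rd$pos[keep],
                 rd$ref[keep], rd$alt[keep])
  gene <- rd$gene[keep]
  ## distinct variants only
  dup <- duplicated(key)
  pres <- pres[!dup, , drop = FALSE]; gene <- gene[!dup]
  tab <- table(gene)
  hits <- names(tab)[tab >= 2]
  if (!length(hits))
    return(data.frame(gene = character(), n_variants = integer(),
                      disjoint_pattern = logical()))
  res <- lapply(hits, function(g) {
    p <- pres[gene == g, , drop = FALSE]
    disj <- FALSE
    for (i in seq_len(nrow(p) - 1L)) for (j in (i + 1L):nrow(p))
      if (!any(p[i, ] & p[j, ])) disj <- TRUE
    data.frame(gene = g, n_variants = nrow(p), disjoint_pattern = disj)
  })
  out <- do.call(rbind, res)
  out[order(out$gene), , drop = FALSE]
}

#' Classify copy-number calls and their heterogeneity
#'
#' Per gene and sample: deletion iff total copy number is 0, amplification
#' iff total copy number is at least 6, otherwise neutral. A gene with any
#' non-neutral call is a CNV gene; it is homogeneous iff every tumor sample
#' of the patient shows the same non-neutral class.
#'
#' @param cnv data.frame with columns \code{gene}, \code{sample},
#'   \code{cn_total}, \code{cn_major}, \code{cn_minor}.
#' @return list with \code{calls} (the input plus a \code{class} column) and
#'   \code{genes} (per gene: \code{any_cnv}, \code{homogeneous}), plus counts
#'   \code{n_cnv_genes} and \code{n_homogeneous}.
#' @examples
#' cnv <- data.frame(gene = "CD274", sample = paste0("R", 1:3),
#'                   cn_total = c(8, 2, 2), cn_major = c(7, 1, 1),
#'                   cn_minor = c(1, 1, 1))
#' classifyCnv(cnv)$genes
#' @export
classifyCnv <- function(cnv) {
  stopifnot(all(c("gene", "sample", "cn_total", "cn_major", "cn_minor") %in%
                colnames(cnv)))
  if (any(cnv$cn_total < 0 | cnv$cn_major < 0 | cnv$cn_minor < 0))
    stop("copy numbers must be >= 0")
  if (any(cnv$cn_total != cnv$cn_major + cnv$cn_minor))
    stop("cn_total must equal cn_major + cn_minor")
  cnv$class <- ifelse(cnv$cn_total == 0, "deletion",
                      ifelse(cnv$cn_total >= 6, "amplification", "neutral"))
  genes <- do.call(rbind, lapply(split(cnv, cnv$gene), function(d) {
    nonneutral <- d$class[d$class != "neutral"]
    data.frame(gene = d$gene[1], any_cnv = length(nonneutral) > 0,
               homogeneous = length(nonneutral) > 0 &&
                 length(nonneutral) == nrow(d) &&
                 length(unique(nonneutral)) == 1L)
  }))
  rownames(genes) <- NULL
  list(calls = cnv, genes = genes,
       n_cnv_genes = sum(genes$any_cnv),
       n_homogeneous = sum(genes$homogeneous))
}

#' Read a per-gene copy-number TSV
#'
#' Expected columns: gene, sample, cn_total, cn_major, cn_minor.
#'
#' @param path TSV file.
#' @return data.frame suitable for [classifyCnv()].
#' @export
readCnvTsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
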