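#' @include AllClasses.R AllGenerics.R
NULL

#' Construct a VariantTable
#'
#' Assemble the per-patient variants x samples container from read-count
#' matrices and annotation tables. Variant ids (rownames) are derived from
#' \code{chrom:pos_ref>alt} when not supplied; \code{af} is computed as
#' \code{alt/depth} (0 where depth is 0) when not supplied.
#'
#' @param depth,alt integer matrices (variants x samples) of total and
#'   variant-supporting read counts.
#' @param rowData data.frame/DataFrame of variant annotations; must contain
#'   \code{chrom, pos, ref, alt, gene, effect, homopolymer, strand_bias,
#'   blacklist, population_af, known_somatic, census_gene}.
#' @param colData data.frame/DataFrame of per-sample metadata with columns
#'   \code{purity} and \code{tissue} (\code{primary}, \code{lymph_node} or
#'   \code{normal}); rownames are the sample ids.
#' @param patient patient identifier.
#' @param af optional numeric matrix of allele fractions.
#' @return a validated \linkS4class{VariantTable}.
#' @examples
#' vt <- VariantTable(
#'   depth = cbind(s1 = c(100L, 80L), s2 = c(90L, 85L), N = c(60L, 70L)),
#'   alt   = cbind(s1 = c(40L, 8L),  s2 = c(0L, 30L),  N = c(0L, 0L)),
#'   rowData = data.frame(chrom = "1", pos = c(100L, 200L), ref = "A",
#'     alt = "T", gene = c("TP53", "SMAD4"), effect = "missense",
#'     homopolymer = FALSE, strand_bias = FALSE, blacklist = FALSE,
#'     population_af = 0, known_somatic = TRUE, census_gene = TRUE),
#'   colData = data.frame(purity = c(0.8, 0.7, NA),
#'     tissue = c("primary", "primary", "normal"), row.names = c("s1", "s2", "N")),
#'   patient = "case1")
#' tumorSamples(vt)
#' @export
VariantTable <- function(depth, alt, rowData, colData, patient = "patient",
                         af = NULL) {
  depth <- as.matrix(depth); alt <- as.matrix(alt)
  storage.mode(depth) <- "integer"; storage.mode(alt) <- "integer"
  if (is.null(af)) {
    af <- ifelse(depth > 0, alt / depth, 0)
  }
  af <- as.matrix(af)
  rowData <- S4Vectors::DataFrame(rowData)
  colData <- S4Vectors::DataFrame(colData)
  rn <- rownames(depth)
  if (is.null(rn))
    rn <- sprintf("%s:%d_%s>%s", rowData$chrom, rowData$pos,
                  rowData$ref, rowData$alt)
  dimnames(depth) <- dimnames(alt) <- dimnames(af) <-
    list(rn, colnames(depth))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = S4Vectors::SimpleList(depth = depth, alt = alt, af = af),
    rowData = rowData, colData = colData)
  metadata(se)$patient <- patient
  vt <- methods::new("VariantTable", se)
  methods::validObject(vt)
  vt
}

#' @rdname accessors
setMethod("patientID", "VariantTable", function(x) metadata(x)$patient)

#' @rdname accessors
setMethod("purity", "VariantTable", function(x) {
  stats::setNames(colData(x)$purity, colnames(x))
})

#' @rdname accessors
setMethod("tissueType", "VariantTable", function(x) {
  stats::setNames(as.character(colData(x)$tissue), colnames(x))
})

#' @rdname accessors
setMethod("tumorSamples", "VariantTable", function(x) {
  colnames(x)[colData(x)$tissue != "normal"]
})

#' @rdname accessors
setMethod("isFiltered", "VariantTable", function(x) {
  "present" %in% SummarizedExperiment::assayNames(x)
})

#' @rdname accessors
setMethod("presence", "VariantTable", function(x) {
  if (!isFiltered(x))
    stop("run applyFilters() before asking for presence")
  SummarizedExperiment::assay(x, "present")[, tumorSamples(x), drop = FALSE]
})

#' @rdname accessors
setMethod("filterLog", "VariantTable", function(x) {
  if (!isFiltered(x))
    stop("run applyFilters() before asking for the filter log")
  metadata(x)$filter_log
})

setMethod("show", "VariantTable", function(object) {
  cat(sprintf("VariantTable for patient '%s': %d variants x %d samples (%d tumor)\n",
              patientID(object), nrow(object), ncol(object),
              length(tumorSamples(object))))
  if (isFiltered(object)) {
    pr <- presence(object)
    cat(sprintf("  filtered: %d variants present in >= 1 tumor sample\n",
                sum(rowSums(pr) > 0)))
  } else cat("  not yet filtered\n")
})

## internal: tumor-sample read matrices
.tumorAssay <- function(x, name) {
  SummarizedExperiment::assay(x, name)[, tumorSamples(x), drop = FALSE]
}

## internal: normal column (or NULL)
.normalSample <- function(x) {
  nm <- colnames(x)[colData(x)$tissue == "normal"]
  if (length(nm)) nm[1] else NULL
}
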