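#' @include VariantTable-methods.R
NULL

## INFO keys carrying the row annotations through VCF
.INFO_KEYS <- c(GENE = "gene", EFF = "effect", HP = "homopolymer",
                SB = "strand_bias", BL = "blacklist", PAF = "population_af",
                KS = "known_somatic", CGC = "census_gene")

#' Write a VariantTable as multi-sample VCF v4.2
#'
#' One record per variant; per-sample FORMAT fields \code{DP} (depth),
#' \code{AD} (ref,alt read counts) and \code{AF}. Variant annotations travel
#' in INFO (\code{GENE}, \code{EFF}, flags \code{HP/SB/BL} as 0/1,
#' \code{PAF}, \code{KS}, \code{CGC}); per-sample purity and tissue type in
#' \code{##SAMPLE} header lines, the patient id and any simulation seed in
#' their own header lines.
#'
#' @param table a \linkS4class{VariantTable}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeVcf <- function(table, path) {
  stopifnot(methods::is(table, "VariantTable"))
  rd <- SummarizedExperiment::rowData(table)
  depth <- SummarizedExperiment::assay(table, "depth")
  alt <- SummarizedExperiment::assay(table, "alt")
  af <- SummarizedExperiment::assay(table, "af")
  cd <- SummarizedExperiment::colData(table)
  hdr <- c("##fileformat=VCFv4.2",
           paste0("##source=clonescape_", as.character(utils::packageVersion("clonescape"))),
           paste0("##patient=", patientID(table)),
           if (!is.null(metadata(table)$seed))
             paste0("##seed=", metadata(table)$seed),
           '##INFO=<ID=GENE,Number=1,Type=String,Description="Gene symbol">',
           '##INFO=<ID=EFF,Number=1,Type=String,Description="Effect class">',
           '##INFO=<ID=HP,Number=1,Type=Integer,Description="Homopolymer region flag">',
           '##INFO=<ID=SB,Number=1,Type=Integer,Description="Strand bias flag">',
           '##INFO=<ID=BL,Number=1,Type=Integer,Description="Blacklisted region flag">',
           '##INFO=<ID=PAF,Number=1,Type=Float,Description="Population allele frequency">',
           '##INFO=<ID=KS,Number=1,Type=Integer,Description="Known somatic (COSMIC/ICGC) flag">',
           '##INFO=<ID=CGC,Number=1,Type=Integer,Description="Cancer Gene Census gene flag">',
           '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Total read depth">',
           '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Ref,alt read counts">',
           '##FORMAT=<ID=AF,Number=1,Type=Float,Description="Allele fraction">',
           sprintf('##SAMPLE=<ID=%s,Purity=%s,Tissue=%s>', rownames(cd),
                   ifelse(is.na(cd$purity), ".", as.character(cd$purity)),
                   cd$tissue),
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", colnames(table)), collapse = "\t"))
  info <- sprintf("GENE=%s;EFF=%s;HP=%d;SB=%d;BL=%d;PAF=%s;KS=%d;CGC=%d",
                  rd$gene, rd$effect, rd$homopolymer, rd$strand_bias,
                  rd$blacklist, as.character(rd$population_af),
                  rd$known_somatic, rd$census_gene)
  gt <- matrix(sprintf("%d:%d,%d:%s", depth, depth - alt, alt,
                       as.character(af)),
               nrow = nrow(table))
  recs <- paste(rd$chrom, rd$pos, rownames(table), rd$ref, rd$alt, ".",
                "PASS", info, "DP:AD:AF",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, recs), path)
  invisible(path)
}

#' Read a multi-sample VCF into a VariantTable
#'
#' Parses a VCF v4.2 (as written by [writeVcf()], or any VCF carrying
#' per-sample \code{DP} and \code{AD}) via \pkg{vcfR}. A missing FORMAT
#' \code{AF} is recomputed as alt reads / depth; missing annotation INFO keys
#' default to benign values (no flags, population AF 0). Sample purity and
#' tissue are taken from \code{##SAMPLE} header lines when present.
#'
#' @param path VCF file.
#' @return a \linkS4class{VariantTable}.
#' @export
readVcf <- function(path) {
  l1 <- readLines(path, n = 1L)
  if (!startsWith(l1, "##fileformat=VCF"))
    stop(sprintf("%s: parse error at line 1: missing ##fileformat header", path))
  v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                error = function(e) stop(sprintf("%s: parse error: %s",
                                                 path, conditionMessage(e))))
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  samples <- colnames(v@gt)[-1]
  dp <- vcfR::extract.gt(v, "DP", as.numeric = TRUE)
  ad <- vcfR::extract.gt(v, "AD")
  altm <- matrix(as.integer(vapply(strsplit(as.vector(ad), ","), `[`, "",
                                   2L)),
                 nrow = nrow(ad), ncol = ncol(ad))
  afs <- tryCatch(vcfR::extract.gt(v, "AF", as.numeric = TRUE),
                  error = function(e) NULL, warning = function(w) NULL)
  if (is.null(afs) || all(is.na(afs)))
    afs <- ifelse(dp > 0, altm / dp, 0)
  grab <- function(key, default) {
    x <- vcfR::extract.info(v, key)
    if (is.null(x) || all(is.na(x))) rep(default, nrow(fix)) else x
  }
  rowData <- data.frame(
    chrom = fix$CHROM, pos = as.integer(fix$POS), ref = fix$REF,
    alt = fix$ALT,
    gene = grab("GENE", NA_character_),
    effect = grab("EFF", "other"),
    homopolymer = grab("HP", "0") == "1",
    strand_bias = grab("SB", "0") == "1",
    blacklist = grab("BL", "0") == "1",
    population_af = as.numeric(grab("PAF", "0")),
    known_somatic = grab("KS", "1") == "1",
    census_gene = grab("CGC", "0") == "1",
    stringsAsFactors = FALSE)
  meta <- v@meta
  patient <- sub("^##patient=", "", grep("^##patient=", meta, value = TRUE))
  if (!length(patient)) patient <- "patient"
  sm <- grep("^##SAMPLE=", meta, value = TRUE)
  purity <- stats::setNames(rep(NA_real_, length(samples)), samples)
  tissue <- stats::setNames(rep("primary", length(samples)), samples)
  for (line in sm) {
    id <- sub('.*ID=([^,>]+).*', "\\1", line)
    if (!id %in% samples) next
    p <- sub(".*Purity=([^,>]+).*", "\\1", line)
    purity[id] <- suppressWarnings(as.numeric(p))
    tissue[id] <- sub(".*Tissue=([^,>]+).*", "\\1", line)
  }
  dimnames(dp) <- dimnames(altm) <- dimnames(afs) <-
    list(fix$ID, samples)
  vt <- VariantTable(depth = dp, alt = altm, af = afs, rowData = rowData,
                     colData = data.frame(purity = purity, tissue = tissue,
                                          row.names = samples),
                     patient = patient)
  sd <- sub("^##seed=", "", grep("^##seed=", meta, value = TRUE))
  if (length(sd)) metadata(vt)$seed <- as.integer(sd)
  vt
}

#' Flat TSV mirror of a VariantTable
#'
#' One row per variant x tumor sample with read support, annotations and
#' (when filtered) the filter state.
#'
#' @param table a \linkS4class{VariantTable}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeVariantTsv <- function(table, path) {
  ts <- tumorSamples(table)
  rd <- as.data.frame(SummarizedExperiment::rowData(table))
  long <- do.call(rbind, lapply(ts, function(s) {
    data.frame(patient = patientID(table), variant_id = rownames(table),
               sample = s, rd,
               depth = SummarizedExperiment::assay(table, "depth")[, s],
               alt_reads = SummarizedExperiment::assay(table, "alt")[, s],
               af = SummarizedExperiment::assay(table, "af")[, s],
               filter = if (isFiltered(table))
                 SummarizedExperiment::assay(table, "filter")[, s]
               else NA_character_,
               row.names = NULL)
  }))
  utils::write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
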