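library(SummarizedExperiment)
library(S4Vectors)

## minimal hand-built variant table: nv variants x samples with free fields
makeTable <- function(depth, alt, effect = "missense", gene = NULL,
                      homopolymer = FALSE, strand_bias = FALSE,
                      blacklist = FALSE, population_af = 0,
                      known_somatic = TRUE, census_gene = FALSE,
                      purity = 0.8, tissue = NULL, patient = "caseX",
                      normal_depth = 100L) {
  depth <- as.matrix(depth); alt <- as.matrix(alt)
  nv <- nrow(depth)
  if (is.null(colnames(depth)))
    colnames(depth) <- colnames(alt) <- paste0("s", seq_len(ncol(depth)))
  ## append a matched normal column
  depth <- cbind(depth, N = rep(as.integer(normal_depth), nv))
  alt <- cbind(alt, N = rep(0L, nv))
  ns <- ncol(depth)
  if (is.null(tissue)) tissue <- c(rep("primary", ns - 1L), "normal")
  if (is.null(gene)) gene <- sprintf("G%03d", seq_len(nv))
  rd <- data.frame(chrom = rep("1", nv), pos = 1000L * seq_len(nv),
                   ref = rep("A", nv), alt = rep("T", nv), gene = gene,
                   effect = rep_len(effect, nv),
                   homopolymer = rep_len(homopolymer, nv),
                   strand_bias = rep_len(strand_bias, nv),
                   blacklist = rep_len(blacklist, nv),
                   population_af = rep_len(population_af, nv),
                   known_somatic = rep_len(known_somatic, nv),
                   census_gene = rep_len(census_gene, nv))
  cd <- data.frame(purity = c(rep_len(purity, ns - 1L), NA),
                   tissue = tissue, row.names = colnames(depth))
  VariantTable(depth, alt, rowData = rd, colData = cd, patient = patient)
}

## table from allele fractions at a fixed depth
makeTableAf <- function(af, depth = 100L, ...) {
  af <- as.matrix(af)
  d <- matrix(as.integer(depth), nrow(af), ncol(af),
              dimnames = dimnames(af))
  makeTable(d, round(af * depth), ...)
}

filteredTable <- function(...) recoverVariants(applyFilters(makeTable(...)))
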