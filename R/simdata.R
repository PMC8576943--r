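#' @include VariantTable-methods.R
NULL

#' Configuration for the multiregional tumor simulator
#'
#' Collects every knob of the synthetic tumor: number of regions, truncal
#' mutation count, subclone splits, the neutral 1/f mutation tail, sequencing
#' depth, per-region purity and declared copy-number events. The defaults
#' describe a mid-size gastric-cancer-like case: five regions, a clonal trunk,
#' two region-restricted subclones, a neutral tail with effective mutation
#' rate mu/beta = 10 per frequency unit over the detectable window, 200x mean
#' depth and purity 0.8.
#'
#' @param n_regions number of tumor samples (3-10 typical).
#' @param n_clonal number of truncal (founding-clone) mutations.
#' @param tree_splits list of subclone splits; each a list with \code{parent}
#'   (clone id, root is \code{"C0"}), \code{fraction} (the child clone's cell
#'   fraction in (0,1) within the listed regions), \code{regions} (integer
#'   region indices; \code{NULL} = all regions) and \code{n_private}
#'   (clone-defining mutations, default 25). Children are named C1, C2, ...
#'   in list order. The default (two subclones splitting the regions in
#'   half) adapts to \code{n_regions}.
#' @param mu_eff effective mutation rate mu/beta of the neutral tail
#'   (mutations per unit of inverse frequency).
#' @param f_min,f_max frequency window of the neutral tail, 0 < f_min < f_max <= 1.
#' @param depth_mean mean sequencing depth (reads); Poisson per site/sample.
#' @param purity per-region tumor purity rho in (0,1]; recycled to n_regions.
#' @param cn_events list of copy-number events; each a list with \code{gene},
#'   \code{regions} (indices), \code{cn_total}, \code{cn_major} and optional
#'   \code{n_variants} (simulated mutations placed in that gene, default 2).
#' @param seed integer RNG seed; all simulator draws are reproducible from it.
#' @return a validated \code{SimConfig} list.
#' @export
simConfig <- function(n_regions = 5L, n_clonal = 40L, tree_splits = NULL,
                      mu_eff = 10, f_min = 0.05, f_max = 0.4,
                      depth_mean = 200, purity = 0.8,
                      cn_events = list(), seed = 1L) {
  stopifnot(n_regions >= 1, n_clonal >= 0, depth_mean > 0,
            f_min > 0, f_max <= 1, mu_eff >= 0)
  if (is.null(tree_splits)) {
    half <- floor(n_regions / 2)
    tree_splits <- if (n_regions >= 2) list(
      list(parent = "C0", fraction = 0.45, regions = seq_len(half),
           n_private = 25L),
      list(parent = "C0", fraction = 0.35,
           regions = seq.int(half + 1L, n_regions), n_private = 25L))
    else list()
  }
  if (f_min >= f_max) stop("f_min must be < f_max")
  purity <- rep_len(purity, n_regions)
  if (any(purity <= 0 | purity > 1)) stop("purity must lie in (0, 1]")
  for (sp in tree_splits) {
    if (is.null(sp$fraction) || sp$fraction <= 0 || sp$fraction >= 1)
      stop(sprintf("split under clone '%s': fraction must lie in (0, 1)",
                   if (is.null(sp$parent)) "?" else sp$parent))
  }
  cfg <- list(n_regions = as.integer(n_regions), n_clonal = as.integer(n_clonal),
              tree_splits = tree_splits, mu_eff = mu_eff,
              f_min = f_min, f_max = f_max, depth_mean = depth_mean,
              purity = purity, cn_events = cn_events, seed = as.integer(seed))
  class(cfg) <- c("SimConfig", "list")
  cfg
}

#' Draw variant frequencies from the neutral 1/f^2 density
#'
#' Under neutral tumor growth the number of mutations with frequency above f
#' grows as M(f) = mu_eff (1/f - 1/f_max): site frequencies follow a density
#' proportional to 1/f^2 truncated to \code{[f_min, f_max]}. Frequencies are
#' drawn by inverse-CDF: \code{f(u) = 1 / (1/f_max + u (1/f_min - 1/f_max))},
#' so u = 0 maps to f_max and u = 1 to f_min. The number of draws is Poisson
#' with mean \code{mu_eff (1/f_min - 1/f_max)} unless \code{n} fixes it.
#'
#' Uses the current RNG stream; call \code{set.seed()} for reproducibility.
#'
#' @param mu_eff effective mutation rate mu/beta.
#' @param f_min,f_max truncation window, 0 < f_min < f_max <= 1.
#' @param n optional fixed number of draws (overrides the Poisson count).
#' @return numeric vector of frequencies in \code{[f_min, f_max]}.
#' @examples
#' set.seed(1)
#' f <- sampleNeutralVafs(10, 0.1, 0.25)
#' length(f)   # expectation 10 * (1/0.1 - 1/0.25) = 60
#' @export
sampleNeutralVafs <- function(mu_eff, f_min, f_max, n = NULL) {
  if (f_min >= f_max) stop("f_min must be < f_max")
  if (is.null(n)) n <- stats::rpois(1L, mu_eff * (1 / f_min - 1 / f_max))
  u <- stats::runif(n)
  1 / (1 / f_max + u * (1 / f_min - 1 / f_max))
}

#' Simulate a subclone phylogeny
#'
#' Builds the clone tree declared by \code{tree_splits}: a founding clone C0
#' with fraction 1 in every region carrying the \code{n_clonal} truncal
#' mutations, child clones with the declared cell fractions (0 outside their
#' listed regions) each carrying private clone-defining mutations, and a
#' neutral 1/f mutation tail attached to the founding clone as
#' region-independent intra-clone frequency draws.
#'
#' @param config a [simConfig()].
#' @return a \linkS4class{SubcloneTree}.
#' @export
simulateTree <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  set.seed(config$seed)
  nr <- config$n_regions
  regions <- paste0("R", seq_len(nr))
  clones <- data.frame(clone = "C0", parent = NA_character_,
                       n_private = config$n_clonal, stringsAsFactors = FALSE)
  fr <- matrix(1, nrow = 1, ncol = nr, dimnames = list("C0", regions))
  for (i in seq_along(config$tree_splits)) {
    sp <- config$tree_splits[[i]]
    id <- paste0("C", i)
    if (!sp$parent %in% clones$clone)
      stop(sprintf("split %d references unknown parent clone '%s'", i, sp$parent))
    reg <- if (is.null(sp$regions)) seq_len(nr) else as.integer(sp$regions)
    if (any(reg < 1 | reg > nr))
      stop(sprintf("split for clone '%s': region index out of range", id))
    row <- stats::setNames(numeric(nr), regions)
    row[reg] <- sp$fraction
    fr <- rbind(fr, matrix(row, nrow = 1, dimnames = list(id, regions)))
    np <- if (is.null(sp$n_private)) 25L else as.integer(sp$n_private)
    clones <- rbind(clones, data.frame(clone = id, parent = sp$parent,
                                       n_private = np))
  }
  ## per parent and region the children may not exceed the parent's fraction
  for (p in clones$clone) {
    kids <- clones$clone[!is.na(clones$parent) & clones$parent == p]
    if (length(kids)) {
      resid <- fr[p, ] - colSums(fr[kids, , drop = FALSE])
      if (any(resid < -1e-9))
        stop(sprintf("invalid split fractions: children of clone '%s' sum above its fraction in region %s",
                     p, regions[which(resid < -1e-9)[1]]))
    }
  }
  ## clone-defining mutations (phi = 1)
  mut <- list()
  for (i in seq_len(nrow(clones))) {
    np <- clones$n_private[i]
    if (np > 0)
      mut[[length(mut) + 1L]] <- data.frame(
        clone = clones$clone[i], phi = 1,
        class = if (is.na(clones$parent[i])) "trunk" else "branch",
        stringsAsFactors = FALSE)[rep(1, np), ]
  }
  ## neutral tail hosted by the founding clone
  tail_f <- sampleNeutralVafs(config$mu_eff, config$f_min, config$f_max)
  if (length(tail_f))
    mut[[length(mut) + 1L]] <- data.frame(clone = "C0", phi = tail_f,
                                          class = "tail")
  mut <- do.call(rbind, mut)
  rownames(mut) <- NULL
  mut$variant_id <- sprintf("v%04d", seq_len(nrow(mut)))
  mut$multiplicity <- 1L
  mut$gene <- sprintf("GENE%04d", seq_len(nrow(mut)))
  ## place variants inside declared CN events; multiplicity = major CN there
  used <- 0L
  for (ev in config$cn_events) {
    nv <- if (is.null(ev$n_variants)) 2L else as.integer(ev$n_variants)
    idx <- used + seq_len(min(nv, nrow(mut) - used))
    mut$gene[idx] <- ev$gene
    mut$multiplicity[idx] <- max(1L, as.integer(ev$cn_major))
    used <- used + length(idx)
  }
  ## effect classes: tail half synonymous, clone-defining mostly missense
  eff <- character(nrow(mut))
  istail <- mut$class == "tail"
  eff[!istail] <- sample(c("missense", "nonsense", "frameshift"),
                         sum(!istail), replace = TRUE, prob = c(0.8, 0.1, 0.1))
  eff[istail] <- sample(c("missense", "synonymous"), sum(istail),
                        replace = TRUE, prob = c(0.5, 0.5))
  mut$effect <- eff
  methods::new("SubcloneTree", clones = clones, fractions = fr,
               mutations = S4Vectors::DataFrame(mut), config = unclass(config))
}

#' Ground truth of a simulated tumor
#'
#' Per simulated variant: the true cell fraction in every region (intra-clone
#' frequency times the host clone's regional fraction), the host clone, the
#' multiplicity, and whether the variant is truly clonal (founding-clone
#' mutation carried by every tumor cell, i.e. intra-clone frequency 1).
#'
#' @param tree a \linkS4class{SubcloneTree}.
#' @return \link[S4Vectors]{DataFrame} with columns \code{variant_id},
#'   \code{clone}, \code{truly_clonal}, \code{multiplicity} and a matrix
#'   column \code{cell_fraction} (regions).
#' @export
simTruth <- function(tree) {
  stopifnot(methods::is(tree, "SubcloneTree"))
  mut <- tree@mutations
  cf <- tree@fractions[mut$clone, , drop = FALSE] * mut$phi
  rownames(cf) <- mut$variant_id
  root <- tree@clones$clone[is.na(tree@clones$parent)]
  S4Vectors::DataFrame(variant_id = mut$variant_id, clone = mut$clone,
                       truly_clonal = mut$clone == root & mut$phi == 1,
                       multiplicity = mut$multiplicity,
                       cell_fraction = I(cf))
}

## per-variant per-region expected AF, total CN and multiplicity
.simExpectedAf <- function(tree, config) {
  mut <- tree@mutations
  nr <- config$n_regions
  regions <- colnames(tree@fractions)
  cn_t <- matrix(2, nrow(mut), nr, dimnames = list(mut$variant_id, regions))
  m <- matrix(1, nrow(mut), nr, dimnames = list(mut$variant_id, regions))
  for (ev in config$cn_events) {
    hit <- mut$gene == ev$gene
    if (any(hit)) {
      reg <- as.integer(ev$regions)
      cn_t[hit, reg] <- ev$cn_total
      m[hit, reg] <- max(1L, as.integer(ev$cn_major))
    }
  }
  fcell <- tree@fractions[mut$clone, , drop = FALSE] * mut$phi
  rho <- matrix(config$purity, nrow(mut), nr, byrow = TRUE)
  eaf <- fcell * m * rho / (rho * cn_t + (1 - rho) * 2)
  list(eaf = pmin(eaf, 1), cn_t = cn_t, m = m)
}

#' Draw sequencing reads for a simulated tumor
#'
#' Emulates the sequenced multiregional cohort: per region the expected
#' observed allele fraction of a variant is
#' \deqn{AF = f_{cell} m \rho / (\rho CN_t + (1-\rho) 2)}
#' with \eqn{f_{cell}} the clone's cell fraction, m the multiplicity,
#' \eqn{\rho} the purity and \eqn{CN_t} the local tumor copy number. Total
#' depth is Poisson(\code{depth_mean}) and alt reads Binomial(depth, AF).
#' A matched normal column (all-reference) is appended. The ground truth
#' ([simTruth()]) travels in the table's metadata.
#'
#' @param tree a \linkS4class{SubcloneTree} from [simulateTree()].
#' @param config the same [simConfig()].
#' @return a \linkS4class{VariantTable} with \code{metadata()} entries
#'   \code{truth}, \code{sim_config} and \code{seed}.
#' @export
sampleReads <- function(tree, config) {
  stopifnot(methods::is(tree, "SubcloneTree"), inherits(config, "SimConfig"))
  set.seed(config$seed + 1L)
  mut <- tree@mutations
  nv <- nrow(mut)
  nr <- config$n_regions
  ex <- .simExpectedAf(tree, config)
  depth <- matrix(stats::rpois(nv * (nr + 1L), config$depth_mean),
                  nrow = nv, ncol = nr + 1L)
  alt <- matrix(0L, nv, nr + 1L)
  for (r in seq_len(nr))
    alt[, r] <- stats::rbinom(nv, depth[, r], ex$eaf[, r])
  samples <- c(colnames(tree@fractions), "N")
  colnames(depth) <- colnames(alt) <- samples
  rowData <- data.frame(
    chrom = "1", pos = 10000L * seq_len(nv), ref = "A", alt = "T",
    gene = mut$gene, effect = mut$effect,
    homopolymer = FALSE, strand_bias = FALSE, blacklist = FALSE,
    population_af = 0, known_somatic = TRUE, census_gene = FALSE,
    stringsAsFactors = FALSE)
  rownames(depth) <- rownames(alt) <- mut$variant_id
  colData <- data.frame(purity = c(config$purity, NA),
                        tissue = c(rep("primary", nr), "normal"),
                        row.names = samples)
  vt <- VariantTable(depth, alt, rowData = rowData, colData = colData,
                     patient = sprintf("sim_seed%d", config$seed))
  metadata(vt)$truth <- simTruth(tree)
  metadata(vt)$sim_config <- unclass(config)
  metadata(vt)$seed <- config$seed
  vt
}

#' Simulate a complete multiregional tumor
#'
#' Convenience wrapper: [simulateTree()] then [sampleReads()].
#'
#' @param config a [simConfig()].
#' @return a \linkS4class{VariantTable} with ground truth in its metadata.
#' @examples
#' vt <- simulateTumor(simConfig(seed = 7))
#' vt
#' @export
simulateTumor <- function(config = simConfig()) {
  sampleReads(simulateTree(config), config)
}

#' Write the simulation ground truth as TSV
#'
#' @param truth a [simTruth()] DataFrame (or a simulated
#'   \linkS4class{VariantTable}, whose metadata truth is used).
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeSimTruth <- function(truth, path) {
  if (methods::is(truth, "VariantTable")) truth <- metadata(truth)$truth
  cf <- truth$cell_fraction
  df <- data.frame(variant_id = truth$variant_id, clone_id = truth$clone,
                   truly_clonal = truth$truly_clonal,
                   multiplicity = truth$multiplicity)
  colnames(cf) <- paste0("cell_fraction_", colnames(cf))
  utils::write.table(cbind(df, as.data.frame(cf)), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
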