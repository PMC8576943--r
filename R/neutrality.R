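#' @include filters.R
NULL

#' Configuration of the neutral-evolution test
#'
#' The test compares the cumulative number of subclonal mutations M(f)
#' against the neutral expectation M(f) = mu_eff (1/f - 1/f_upper) inside a
#' frequency window below the clonal peak. The window defaults to
#' [0.1, 0.25]; agreement is declared at R-squared >= 0.98. VAFs are used
#' without purity correction (purity scales all frequencies of a sample
#' equally, so correcting does not sharpen the test).
#'
#' @param f_lower,f_upper fit window bounds, 0 < f_lower < f_upper <= 1.
#' @param r2_threshold R-squared at or above which a sample is called
#'   neutral (default 0.98).
#' @param min_mutations minimum in-window mutation count for a verdict
#'   (default 12); below it the result is \code{"insufficient"}.
#' @return a \code{NeutralityConfig} list.
#' @export
neutralityConfig <- function(f_lower = 0.1, f_upper = 0.25,
                             r2_threshold = 0.98, min_mutations = 12L) {
  stopifnot(f_lower > 0, f_upper <= 1, f_lower < f_upper,
            r2_threshold > 0, r2_threshold <= 1, min_mutations >= 2)
  structure(list(f_lower = f_lower, f_upper = f_upper,
                 r2_threshold = r2_threshold,
                 min_mutations = as.integer(min_mutations),
                 use_purity_correction = FALSE),
            class = c("NeutralityConfig", "list"))
}

#' Extract the VAF set for the neutrality test
#'
#' Collects the raw allele fractions of all passing variants — synonymous
#' and non-synonymous alike — for one sample, or the pooled per-variant mean
#' AF across all tumor samples (zeros included) to dampen regional sampling
#' bias. Variants whose mutated allele has likely undergone gene doubling
#' (multiplicity >= 2) are removed, since doubling inflates the frequency
#' without any clonal growth. No purity correction is applied.
#'
#' @param table a filtered \linkS4class{VariantTable}.
#' @param sample a tumor sample id, or \code{"pooled"}.
#' @param multiplicity per-variant multiplicity used for the gene-doubling
#'   exclusion; defaults to the simulation truth when the table carries one,
#'   else 1 for all variants.
#' @return numeric vector of VAFs.
#' @export
prepareVafs <- function(table, sample = "pooled", multiplicity = NULL) {
  ts <- tumorSamples(table)
  if (is.null(multiplicity)) {
    tr <- metadata(table)$truth
    multiplicity <- if (!is.null(tr))
      tr$multiplicity[match(rownames(table), tr$variant_id)]
    else rep(1L, nrow(table))
  }
  keep <- multiplicity < 2
  pres <- presence(table)
  af <- .tumorAssay(table, "af")
  if (identical(sample, "pooled")) {
    keep <- keep & rowSums(pres) > 0
    rowMeans(af[keep, , drop = FALSE])
  } else {
    stopifnot(sample %in% ts)
    keep <- keep & pres[, sample]
    af[keep, sample]
  }
}

#' Cumulative mutation count above a frequency
#'
#' M(f) = number of mutations with VAF >= f; the neutral model predicts M(f)
#' linear in 1/f.
#'
#' @param vafs numeric vector of allele fractions.
#' @param f frequency threshold(s).
#' @return integer vector, one count per element of \code{f}.
#' @export
cumulativeM <- function(vafs, f) {
  vapply(f, function(x) sum(vafs >= x), integer(1))
}

#' Fit the 1/f neutral model to a VAF set
#'
#' Evaluates M(f) at the observed VAFs inside the fit window, regresses it
#' through the origin on x(f) = 1/f - 1/f_upper (so the theoretical M
#' vanishes at f_upper), and reports the slope (an estimate of the effective
#' mutation rate mu/beta), the coefficient of determination about the mean
#' of M, and the Kolmogorov distance between the empirical and theoretical
#' cumulative distributions, both normalized to 1 at f_lower. The verdict is
#' \code{"neutral"} iff R-squared meets the configured threshold,
#' \code{"insufficient"} below the minimum in-window mutation count.
#'
#' @param vafs numeric vector of allele fractions.
#' @param config a [neutralityConfig()].
#' @param sample label stored in the result.
#' @return a \linkS4class{NeutralityResult}.
#' @examples
#' set.seed(1)
#' f <- sampleNeutralVafs(40, 0.05, 0.4, n = 500)
#' fitNeutralModel(f)
#' @export
fitNeutralModel <- function(vafs, config = neutralityConfig(),
                            sample = "sample") {
  w <- sort(vafs[vafs >= config$f_lower & vafs <= config$f_upper])
  n_in <- length(w)
  if (n_in < config$min_mutations)
    return(methods::new("NeutralityResult", sample = sample,
                        n_in_window = n_in, mu_eff_hat = NA_real_,
                        r2 = NA_real_, ks_distance = NA_real_,
                        verdict = "insufficient", config = unclass(config)))
  x <- 1 / w - 1 / config$f_upper
  y <- cumulativeM(w, w)
  slope <- sum(x * y) / sum(x^2)
  ss_res <- sum((y - slope * x)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) max(0, 1 - ss_res / ss_tot) else 1
  x_low <- 1 / config$f_lower - 1 / config$f_upper
  ks <- max(abs(y / n_in - x / x_low))
  methods::new("NeutralityResult", sample = sample, n_in_window = n_in,
               mu_eff_hat = slope, r2 = r2, ks_distance = ks,
               verdict = if (r2 >= config$r2_threshold) "neutral"
                         else "non_neutral",
               config = unclass(config))
}

#' @rdname accessors
setMethod("verdict", "NeutralityResult", function(x) x@verdict)
#' @rdname accessors
setMethod("ksDistance", "NeutralityResult", function(x) x@ks_distance)

setMethod("show", "NeutralityResult", function(object) {
  cat(sprintf("NeutralityResult [%s]: %s (n = %d in window", object@sample,
              object@verdict, object@n_in_window))
  if (!is.na(object@r2))
    cat(sprintf(", R2 = %.3f, D = %.3f, mu/beta = %.1f",
                object@r2, object@ks_distance, object@mu_eff_hat))
  cat(")\n")
})

#' Neutrality panel for one patient
#'
#' Runs the 1/f test on every tumor sample and on the pooled (mean) VAFs,
#' and summarizes the across-sample heterogeneity in deviation from
#' neutrality as the mean and standard deviation of the Kolmogorov distance.
#'
#' @param table a filtered \linkS4class{VariantTable}.
#' @param config a [neutralityConfig()].
#' @param exclude sample ids to leave out (e.g. a hypermutated MSI sample
#'   whose clonal peak covers the whole frequency range).
#' @param multiplicity see [prepareVafs()].
#' @return list with \code{per_sample} (named list of
#'   \linkS4class{NeutralityResult}), \code{pooled}, and \code{summary}
#'   (\code{mean_ks}, \code{sd_ks} across samples with a distance).
#' @export
neutralityPanel <- function(table, config = neutralityConfig(),
                            exclude = character(), multiplicity = NULL) {
  ts <- setdiff(tumorSamples(table), exclude)
  per <- lapply(ts, function(s)
    fitNeutralModel(prepareVafs(table, s, multiplicity), config, sample = s))
  names(per) <- ts
  pooled <- fitNeutralModel(prepareVafs(table, "pooled", multiplicity),
                            config, sample = "pooled")
  ks <- vapply(per, ksDistance, numeric(1))
  ks <- ks[!is.na(ks)]
  list(per_sample = per, pooled = pooled,
       summary = list(mean_ks = if (length(ks)) mean(ks) else NA_real_,
                      sd_ks = if (length(ks) > 1) stats::sd(ks) else NA_real_))
}

#' Tabulate a neutrality panel
#'
#' @param panel result of [neutralityPanel()].
#' @param patient patient id column value.
#' @return data.frame, one row per sample plus the pooled row.
#' @export
neutralityTable <- function(panel, patient = "patient") {
  rows <- c(panel$per_sample, list(pooled = panel$pooled))
  do.call(rbind, lapply(rows, function(r)
    data.frame(patient = patient, sample = r@sample,
               n_in_window = r@n_in_window, mu_eff_hat = r@mu_eff_hat,
               r2 = r@r2, ks_distance = r@ks_distance, verdict = r@verdict,
               row.names = NULL)))
}
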