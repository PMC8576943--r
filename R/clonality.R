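#' @include filters.R
NULL

#' Cancer cell fraction with exact binomial confidence interval
#'
#' Adjusts the variant allele fraction for tumor purity and local copy
#' number. With purity \eqn{\rho}, tumor copy number \eqn{CN_t}, normal copy
#' number \eqn{CN_n} and multiplicity m (copies of the mutated allele per
#' tumor cell),
#' \deqn{CCF = VAF (\rho CN_t + (1-\rho) CN_n) / (\rho m)}
#' where m is estimated by the nearest-integer rule
#' \code{clamp(round(VAF (rho CNt + (1-rho) CNn) / rho), 1, CNt)}. The 95\%
#' interval is Clopper-Pearson exact binomial on alt/depth, transformed by
#' the same linear map. A mutation is \code{subclonal} iff the upper CI bound
#' falls below 0.95, \code{clonal} otherwise, and \code{not_assessable} at
#' zero depth. CCF and CI bounds are clamped to [0, 1.5] for reporting; the
#' classification uses the (capped) upper bound only.
#'
#' @param alt_reads,depth variant-supporting and total read counts
#'   (vectorized).
#' @param purity tumor purity rho in (0, 1].
#' @param cn_tumor total copy number in tumor cells (>= 1, default 2).
#' @param cn_normal copy number in normal cells (1 or 2, default 2).
#' @param threshold clonality threshold on the CI upper bound (default 0.95).
#' @param conf_level confidence level of the interval (default 0.95).
#' @return \link[S4Vectors]{DataFrame} with \code{vaf}, \code{multiplicity},
#'   \code{ccf}, \code{ci_low}, \code{ci_high}, \code{status}.
#' @examples
#' computeCcf(30, 100, purity = 0.8)   # vaf 0.3 -> ccf 0.75
#' @export
computeCcf <- function(alt_reads, depth, purity, cn_tumor = 2, cn_normal = 2,
                       threshold = 0.95, conf_level = 0.95) {
  n <- max(length(alt_reads), length(depth))
  alt_reads <- rep_len(alt_reads, n); depth <- rep_len(depth, n)
  purity <- rep_len(purity, n); cn_tumor <- rep_len(cn_tumor, n)
  cn_normal <- rep_len(cn_normal, n)
  if (any(purity <= 0 | purity > 1, na.rm = TRUE))
    stop("purity must lie in (0, 1]")
  if (any(cn_tumor < 1, na.rm = TRUE)) stop("cn_tumor must be >= 1")
  if (any(alt_reads > depth, na.rm = TRUE)) stop("alt_reads must be <= depth")
  ok <- depth > 0 & !is.na(depth) & !is.na(purity) & !is.na(cn_tumor)
  vaf <- ifelse(ok, alt_reads / depth, NA_real_)
  denom <- purity * cn_tumor + (1 - purity) * cn_normal
  m <- pmin(pmax(round(vaf * denom / purity), 1), cn_tumor)
  scale <- denom / (purity * m)
  alpha <- 1 - conf_level
  lo_p <- ifelse(alt_reads == 0, 0,
                 stats::qbeta(alpha / 2, alt_reads, depth - alt_reads + 1))
  hi_p <- ifelse(alt_reads == depth, 1,
                 stats::qbeta(1 - alpha / 2, alt_reads + 1, depth - alt_reads))
  clamp <- function(x) pmin(pmax(x, 0), 1.5)
  ccf <- clamp(vaf * scale)
  ci_low <- clamp(lo_p * scale)
  ci_high <- clamp(hi_p * scale)
  status <- ifelse(!ok, "not_assessable",
                   ifelse(ci_high < threshold, "subclonal", "clonal"))
  S4Vectors::DataFrame(vaf = vaf, multiplicity = ifelse(ok, m, NA_integer_),
                       ccf = ccf, ci_low = ci_low, ci_high = ci_high,
                       status = status)
}

## resolve a per-variant-per-sample tumor copy-number matrix
.cnMatrix <- function(table, cn_total) {
  ts <- tumorSamples(table)
  if (is.null(cn_total)) cn_total <- 2
  if (is.matrix(cn_total)) cn_total[, ts, drop = FALSE]
  else matrix(cn_total, nrow(table), length(ts),
              dimnames = list(rownames(table), ts))
}

#' Per-sample clonality of every variant
#'
#' Applies [computeCcf()] to every present variant/tumor-sample pair of a
#' patient, using the per-sample purity from the table's metadata.
#'
#' @param table a filtered \linkS4class{VariantTable}.
#' @param cn_total tumor copy number: scalar or variants x samples matrix
#'   (default diploid).
#' @param cn_normal copy number in normal cells (default 2).
#' @return \link[S4Vectors]{DataFrame}: one row per variant x tumor sample
#'   with the [computeCcf()] columns plus \code{variant_id}, \code{sample}
#'   and \code{present}.
#' @export
perSampleClonality <- function(table, cn_total = NULL, cn_normal = 2) {
  ts <- tumorSamples(table)
  cn <- .cnMatrix(table, cn_total)
  rho <- purity(table)[ts]
  out <- do.call(rbind, lapply(ts, function(s) {
    ccf <- computeCcf(.tumorAssay(table, "alt")[, s],
                      .tumorAssay(table, "depth")[, s],
                      purity = rho[s], cn_tumor = cn[, s],
                      cn_normal = cn_normal)
    S4Vectors::DataFrame(variant_id = rownames(table), sample = s,
                         present = presence(table)[, s], ccf)
  }))
  out
}

#' Per-patient (pooled) clonality
#'
#' Combines all tumor samples of the patient into a single pseudo-sample:
#' read counts are summed over samples (zeros included for covered-but-absent
#' samples), purity and copy number are pooled as depth-weighted means, and
#' [computeCcf()] is applied to the pooled values. Variants with no coverage
#' in any sample are \code{not_assessable}.
#'
#' @inheritParams perSampleClonality
#' @return \link[S4Vectors]{DataFrame}: one row per variant.
#' @export
perPatientClonality <- function(table, cn_total = NULL, cn_normal = 2) {
  ts <- tumorSamples(table)
  alt <- .tumorAssay(table, "alt")
  depth <- .tumorAssay(table, "depth")
  cn <- .cnMatrix(table, cn_total)
  rho <- matrix(purity(table)[ts], nrow(table), length(ts), byrow = TRUE)
  dtot <- rowSums(depth)
  w <- ifelse(dtot > 0, 1 / dtot, 0)
  rho_pool <- rowSums(depth * rho) * w
  cn_pool <- rowSums(depth * cn) * w
  rho_pool[dtot == 0] <- NA_real_
  cn_pool[dtot == 0] <- NA_real_
  ccf <- computeCcf(rowSums(alt), dtot, purity = rho_pool,
                    cn_tumor = pmax(cn_pool, 1), cn_normal = cn_normal)
  S4Vectors::DataFrame(variant_id = rownames(table), ccf)
}

#' Tally clonality calls
#'
#' Percentages of clonal / subclonal / not-assessable calls in a status
#' vector, rounded to one decimal.
#'
#' @param status character vector of \code{computeCcf} statuses.
#' @return named list with counts and percentages.
#' @export
clonalityTally <- function(status) {
  n <- length(status)
  cnt <- vapply(c("clonal", "subclonal", "not_assessable"),
                function(s) sum(status == s), integer(1))
  list(counts = cnt, total = n,
       percent = if (n > 0) round(100 * cnt / n, 1) else rep(NA_real_, 3))
}

#' Clonal-illusion report
#'
#' Variants that look clonal in at least one individual sample but are
#' subclonal when all samples of the patient are pooled — the mutations a
#' single-sample analysis would mis-annotate.
#'
#' @param per_sample result of [perSampleClonality()].
#' @param per_patient result of [perPatientClonality()] on the same table.
#' @return data.frame with \code{variant_id} and \code{samples_clonal}
#'   (comma-separated sample ids where the variant appeared clonal).
#' @export
clonalIllusionReport <- function(per_sample, per_patient) {
  if (!setequal(unique(per_sample$variant_id), per_patient$variant_id))
    stop("per-sample and per-patient results cover different variant sets")
  sub_pat <- per_patient$variant_id[per_patient$status == "subclonal"]
  cl <- per_sample[per_sample$status == "clonal" & per_sample$present &
                     per_sample$variant_id %in% sub_pat, , drop = FALSE]
  if (nrow(cl) == 0)
    return(data.frame(variant_id = character(), samples_clonal = character()))
  sp <- split(cl$sample, cl$variant_id)
  data.frame(variant_id = names(sp),
             samples_clonal = vapply(sp, paste, "", collapse = ","),
             row.names = NULL)
}

#' Apparent-clonal curve
#'
#' C(n): the expected number of variants that appear clonal-by-ubiquity when
#' only n of the patient's samples are examined, estimated as the mean over
#' random size-n sample subsets (exhaustive when at most \code{max_exact}
#' subsets exist) of the count of variants present in every subset member.
#' C(n) is non-increasing in n; its decay toward the truly clonal count is
#' what [fitBalanceFactor()] summarizes.
#'
#' @param x a filtered \linkS4class{VariantTable}, or a logical variants x
#'   samples presence matrix.
#' @param n_subsets Monte-Carlo subsets per n when exhaustive enumeration
#'   would exceed \code{max_exact}.
#' @param max_exact enumerate exhaustively when choose(N, n) <= this.
#' @return numeric vector C(1..N).
#' @export
apparentClonalCurve <- function(x, n_subsets = 100L, max_exact = 200L) {
  pres <- if (methods::is(x, "VariantTable")) presence(x) else as.matrix(x)
  N <- ncol(pres)
  if (N < 2) stop("need at least 2 samples")
  vapply(seq_len(N), function(n) {
    if (choose(N, n) <= max_exact) {
      subs <- utils::combn(N, n, simplify = FALSE)
    } else {
      subs <- replicate(n_subsets, sample.int(N, n), simplify = FALSE)
    }
    mean(vapply(subs, function(s)
      sum(rowSums(pres[, s, drop = FALSE]) == n), numeric(1)))
  }, numeric(1))
}

#' Fit the balance factor g
#'
#' Least-squares fit of the geometric decay model
#' \deqn{C(n) = c_\infty + (C(1) - c_\infty) g^{n-1}}
#' to an apparent-clonal curve, with 0 < g < 1 and 0 <= c_inf <= C(1).
#' For fixed g the optimal c_inf is closed-form, so the fit is a 1-D
#' optimization over g. A (near-)constant curve is returned with g at the
#' lower boundary and c_inf = C(1).
#'
#' @param curve numeric vector C(1..N) from [apparentClonalCurve()]
#'   (>= 3 points).
#' @return a \linkS4class{BalanceFit}.
#' @examples
#' fitBalanceFactor(100 + 50 * 0.5^(0:4))   # g = 0.5, c_inf = 100
#' @export
fitBalanceFactor <- function(curve) {
  if (length(curve) < 3) stop("need at least 3 points to fit g")
  N <- length(curve); C1 <- curve[1]
  idx <- seq_len(N) - 1
  if (max(curve) - min(curve) < 1e-9 * max(1, abs(C1)))
    return(methods::new("BalanceFit", g = 1e-6, c_inf = C1,
                        curve = curve, residual = 0))
  cinf_of <- function(g) {
    a <- g^idx
    ci <- sum((1 - a) * (curve - C1 * a)) / sum((1 - a)^2)
    min(max(ci, 0), C1)
  }
  rss <- function(g) {
    a <- g^idx
    ci <- cinf_of(g)
    sum((curve - (ci + (C1 - ci) * a))^2)
  }
  opt <- stats::optimize(rss, c(1e-6, 1 - 1e-9), tol = 1e-12)
  methods::new("BalanceFit", g = opt$minimum, c_inf = cinf_of(opt$minimum),
               curve = curve, residual = opt$objective)
}

#' @rdname accessors
setMethod("balanceG", "BalanceFit", function(x) x@g)

setMethod("show", "BalanceFit", function(object) {
  cat(sprintf("BalanceFit: g = %.3f, c_inf = %.1f over %d points (rss %.3g)\n",
              object@g, object@c_inf, length(object@curve), object@residual))
})

#' Probability of correct clonal identification
#'
#' Under the one-parameter sampling model, the probability that n regional
#' samples suffice to pin down the truly clonal mutation set of a tumor with
#' balance factor g is \eqn{P(n) = 1 - g^n}: each additional sample reduces
#' the residual risk geometrically, faster for unbalanced tumors (small g).
#'
#' @param g balance factor in (0, 1).
#' @param n number of samples (>= 1).
#' @return probability in (0, 1).
#' @export
pCorrect <- function(g, n) {
  if (any(g <= 0 | g >= 1)) stop("g must lie strictly in (0, 1)")
  1 - g^n
}

#' Number of samples needed for reliable clonal identification
#'
#' Smallest n with \eqn{P_{correct}(n) = 1 - g^n \ge p_{target}}, i.e.
#' \code{ceiling(log(1 - p_target) / log(g))} (at least 1).
#'
#' @param g balance factor in (0, 1).
#' @param p_target target probability in (0, 1).
#' @return list with \code{n} and the achieved \code{p_correct}.
#' @examples
#' samplesNeeded(0.56, 0.90)
#' @export
samplesNeeded <- function(g, p_target) {
  if (g <= 0 || g >= 1) stop("g must lie strictly in (0, 1)")
  if (p_target <= 0 || p_target >= 1) stop("p_target must lie in (0, 1)")
  n <- max(1L, as.integer(ceiling(log(1 - p_target) / log(g))))
  list(n = n, p_correct = pCorrect(g, n))
}
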