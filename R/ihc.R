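#' Immunohistochemistry H-score
#'
#' Semi-quantitative staining score combining the percentages of tumor cells
#' at each staining intensity:
#' H = 0 x pct(0) + 1 x pct(1+) + 2 x pct(2+) + 3 x pct(3+), range 0-300.
#' Percentages must sum to 100 (all tumor cells accounted for).
#'
#' @param pct0,pct1,pct2,pct3 percentages of immunonegative, weakly,
#'   intermediately and strongly stained tumor cells. Alternatively pass a
#'   length-4 vector as \code{pct0}.
#' @return H-score in [0, 300].
#' @examples
#' hScore(0, 0, 0, 100)   # all-strong staining: 300
#' hScore(c(0, 50, 50, 0))
#' @export
hScore <- function(pct0, pct1 = NULL, pct2 = NULL, pct3 = NULL) {
  if (is.null(pct1)) {
    stopifnot(length(pct0) == 4)
    p <- as.numeric(pct0)
  } else p <- c(pct0, pct1, pct2, pct3)
  if (any(p < 0)) stop("percentages must be >= 0")
  if (abs(sum(p) - 100) > 1e-9)
    stop("staining percentages must sum to 100")
  sum(p * 0:3)
}

#' p53 quartile grouping of H-scores
#'
#' Joins the outer quartiles (Q1: H <= 15, Q4: H >= 189 — the pattern of
#' complete loss or strong overexpression expected with mutant TP53) into
#' \code{"Q1/Q4"} and the inner quartiles (Q2: 16-91, Q3: 92-188) into
#' \code{"Q2/Q3"}. The two groups partition [0, 300].
#'
#' @param h H-score(s) in [0, 300].
#' @return character vector, \code{"Q1/Q4"} or \code{"Q2/Q3"}.
#' @examples
#' p53QuartileGroup(c(15, 92, 189))
#' @export
p53QuartileGroup <- function(h) {
  if (any(is.na(h)) || any(h < 0 | h > 300))
    stop("H-score must lie in [0, 300]")
  ifelse(h <= 15 | h >= 189, "Q1/Q4", "Q2/Q3")
}

#' Score an immunohistochemistry staining table
#'
#' @param profiles data.frame with columns \code{case}, \code{marker},
#'   \code{pct0}, \code{pct1}, \code{pct2}, \code{pct3} (as read from TSV).
#' @return the input with \code{h_score} appended, plus \code{group} for
#'   p53 rows (quartile grouping; NA for other markers).
#' @export
ihcScoreTable <- function(profiles) {
  stopifnot(all(c("case", "marker", "pct0", "pct1", "pct2", "pct3") %in%
                colnames(profiles)))
  profiles$h_score <- vapply(seq_len(nrow(profiles)), function(i)
    hScore(as.numeric(profiles[i, c("pct0", "pct1", "pct2", "pct3")])),
    numeric(1))
  profiles$group <- ifelse(tolower(profiles$marker) == "p53",
                           p53QuartileGroup(profiles$h_score), NA_character_)
  profiles
}
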