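#' @include AllClasses.R
NULL

#' Accessors for clonescape classes
#'
#' Small camelCase accessors for the package's S4 containers; use these
#' instead of reaching into slots or assays.
#'
#' @param x a \linkS4class{VariantTable}, \linkS4class{SubcloneTree},
#'   \linkS4class{NeutralityResult}, \linkS4class{BalanceFit} or
#'   \linkS4class{SampleTree}.
#' @return See the individual generic: \code{patientID} the patient id,
#'   \code{purity}/\code{tissueType} per-sample metadata vectors,
#'   \code{tumorSamples} the ids of the non-normal columns, \code{presence}
#'   the post-filter logical variants x tumor-samples matrix,
#'   \code{filterLog} the per-variant record of applied rules,
#'   \code{isFiltered} whether [applyFilters()] has been run,
#'   \code{verdict}/\code{ksDistance} neutrality results,
#'   \code{balanceG} the fitted balance factor, \code{parsimonyScore} the
#'   Fitch length of a reconstructed tree.
#' @name accessors
#' @aliases patientID purity tissueType tumorSamples presence filterLog
#'   isFiltered verdict ksDistance balanceG parsimonyScore
NULL

#' @rdname accessors
#' @export
setGeneric("patientID", function(x) standardGeneric("patientID"))
#' @rdname accessors
#' @export
setGeneric("purity", function(x) standardGeneric("purity"))
#' @rdname accessors
#' @export
setGeneric("tissueType", function(x) standardGeneric("tissueType"))
#' @rdname accessors
#' @export
setGeneric("tumorSamples", function(x) standardGeneric("tumorSamples"))
#' @rdname accessors
#' @export
setGeneric("presence", function(x) standardGeneric("presence"))
#' @rdname accessors
#' @export
setGeneric("filterLog", function(x) standardGeneric("filterLog"))
#' @rdname accessors
#' @export
setGeneric("isFiltered", function(x) standardGeneric("isFiltered"))
#' @rdname accessors
#' @export
setGeneric("verdict", function(x) standardGeneric("verdict"))
#' @rdname accessors
#' @export
setGeneric("ksDistance", function(x) standardGeneric("ksDistance"))
#' @rdname accessors
#' @export
setGeneric("balanceG", function(x) standardGeneric("balanceG"))
#' @rdname accessors
#' @export
setGeneric("parsimonyScore", function(x) standardGeneric("parsimonyScore"))
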