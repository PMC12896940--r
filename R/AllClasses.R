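#' @import methods
#' @importFrom S4Vectors DataFrame SimpleList metadata
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData
NULL

#' SlideCountSet: per-slide stereological point counts
#'
#' A container for point-grid hit counts from stereological readings of
#' ovarian histology slides. It extends
#' \linkS4class{SummarizedExperiment}: the single assay `"hits"` is a
#' 19 x n integer matrix whose rows are the canonical structure codes (see
#' [structureCodes()]) and whose columns are slides; `colData` carries
#' `slide_id`, `fish_id`, `ovary` (`"D"` dorsal / `"V"` ventral),
#' `position` (1, 2, 3 along the gonad) and `total_points` (grid size,
#' typically 500-600 points).
#'
#' Validity requires non-negative integer hits with
#' `colSums(hits) == total_points` for every slide: the grid partitions the
#' section, with the `"v"` (unnatural emptiness) and `"i"` (undetermined)
#' categories absorbing unclassifiable points. Counts are always stored as
#' grid hits; percentages are derived by [fractionEstimates()].
#'
#' @seealso [SlideCountSet()] the constructor, [readCountsCSV()],
#'   [fractionEstimates()], [classifySlide()].
#' @aliases SlideCountSet-class
#' @exportClass SlideCountSet
setClass("SlideCountSet", contains = "SummarizedExperiment")

.validSlideCountSet <- function(object) {
  msg <- NULL
  if (!"hits" %in% names(assays(object)))
    return("assay 'hits' is required")
  h <- assay(object, "hits")
  if (!identical(rownames(h), structureCodes()))
    msg <- c(msg, "assay rows must be the 19 canonical structure codes, in order")
  if (any(h < 0) || any(h != round(h)))
    msg <- c(msg, "hit counts must be non-negative integers")
  cd <- colData(object)
  need <- c("slide_id", "fish_id", "ovary", "position", "total_points")
  miss <- setdiff(need, colnames(cd))
  if (length(miss))
    return(paste0("colData lacks column(s): ", paste(miss, collapse = ", ")))
  if (any(duplicated(cd$slide_id)))
    msg <- c(msg, "duplicated slide_id")
  if (any(cd$total_points <= 0))
    msg <- c(msg, "total_points must be positive")
  if (!all(cd$ovary %in% c("D", "V")))
    msg <- c(msg, "ovary must be 'D' or 'V'")
  if (!all(cd$position %in% 1:3))
    msg <- c(msg, "position must be 1, 2 or 3")
  if (is.null(msg) && ncol(object) > 0) {
    bad <- which(colSums(h) != cd$total_points)
    if (length(bad))
      msg <- c(msg, paste0("hit counts do not sum to total_points for slide(s): ",
                           paste(cd$slide_id[bad], collapse = ", ")))
  }
  if (is.null(msg)) TRUE else msg
}
setValidity("SlideCountSet", .validSlideCountSet)

#' RaterReadingSet: aligned multi-rater point labels for one slide
#'
#' Holds the categorical readings of the same grid points on one slide by
#' `n >= 2` raters: a character matrix of N points x n raters whose entries
#' are canonical structure codes. All raters label the same, aligned grid
#' points, which is the itemization under which per-slide percentage
#' agreement and Fleiss' kappa are computed.
#'
#' @slot slideId single slide identifier.
#' @slot labels character matrix, N points x n raters, canonical codes;
#'   column names identify the raters.
#' @seealso [RaterReadingSet()], [percentAgreement()], [fleissKappa()],
#'   [simulateRaters()].
#' @aliases RaterReadingSet-class
#' @exportClass RaterReadingSet
setClass("RaterReadingSet",
         representation(slideId = "character", labels = "matrix"))

setValidity("RaterReadingSet", function(object) {
  msg <- NULL
  if (length(object@slideId) != 1L)
    msg <- c(msg, "slideId must be a single string")
  lab <- object@labels
  if (!is.character(lab))
    msg <- c(msg, "labels must be a character matrix")
  if (nrow(lab) < 1L)
    msg <- c(msg, "at least one grid point is required")
  if (ncol(lab) < 2L)
    msg <- c(msg, "at least two raters are required")
  if (is.character(lab) && !all(lab %in% structureCodes()))
    msg <- c(msg, "labels must be canonical structure codes")
  if (is.null(msg)) TRUE else msg
})

#' ConfusionMatrix: stereological phase x macroscopic stage cross-tabulation
#'
#' A 5 x 4 contingency table counting fish by stereologically determined
#' maturity phase (rows A, B, C, D, E) and macroscopic stage (columns 1-4).
#' Fish present in only one of the two input tables are recorded in
#' `excluded`, never silently dropped.
#'
#' @slot counts 5 x 4 integer matrix with dimnames `phase`, `stage`.
#' @slot excluded character vector of fish ids present in only one input.
#' @seealso [buildConfusion()], [overallAccuracy()],
#'   [conditionalPercentages()].
#' @aliases ConfusionMatrix-class
#' @exportClass ConfusionMatrix
setClass("ConfusionMatrix",
         representation(counts = "matrix", excluded = "character"))

setValidity("ConfusionMatrix", function(object) {
  cm <- object@counts
  msg <- NULL
  if (!identical(dim(cm), c(5L, 4L)))
    msg <- c(msg, "counts must be a 5 x 4 matrix")
  if (!identical(rownames(cm), .PHASES) || !identical(colnames(cm), .STAGES))
    msg <- c(msg, "dimnames must be phases A-E x stages 1-4")
  if (any(cm < 0) || any(cm != round(cm)))
    msg <- c(msg, "entries must be non-negative integers")
  if (is.null(msg)) TRUE else msg
})

#' OgiveFit: logistic maturity ogive
#'
#' The result of fitting the length-dependent maturity ogive
#' \eqn{P(\mathrm{mature}) = \mathrm{logit}^{-1}(\beta_0 + \beta_1 L)}
#' by iteratively reweighted least squares, with
#' \eqn{L_{50} = -\beta_0/\beta_1} and a nonparametric bootstrap percentile
#' confidence interval for \eqn{L_{50}}.
#'
#' @slot beta0,beta1 intercept and slope (per cm) of the logistic fit.
#' @slot L50 length at 50\% maturity, cm; equals `-beta0/beta1`.
#' @slot ciLow,ciHigh bootstrap percentile CI for L50, cm (`NA` if
#'   `nBoot = 0`).
#' @slot r2 Nagelkerke pseudo-R-squared on `[0, 1]`.
#' @slot n number of fish; @slot nBoot bootstrap resamples; @slot seed RNG
#'   seed used for the bootstrap.
#' @slot converged logical, IRLS convergence flag.
#' @slot separation logical, `TRUE` when the data are (quasi-)completely
#'   separated so the MLE is unbounded and only the bootstrap CI is
#'   meaningful.
#' @slot bootL50 numeric vector of bootstrap L50 draws.
#' @slot logLikTrace per-iteration log-likelihood (non-decreasing).
#' @seealso [fitOgive()], [compareOgives()], [toBinaryMaturity()].
#' @aliases OgiveFit-class
#' @exportClass OgiveFit
setClass("OgiveFit",
         representation(beta0 = "numeric", beta1 = "numeric", L50 = "numeric",
                        ciLow = "numeric", ciHigh = "numeric", r2 = "numeric",
                        n = "integer", nBoot = "integer", seed = "integer",
                        converged = "logical", separation = "logical",
                        bootL50 = "numeric", logLikTrace = "numeric"))
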