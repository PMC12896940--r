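#' @rdname fractionEstimates
#' @export
setGeneric("fractionEstimates",
           function(x, ...) standardGeneric("fractionEstimates"))

#' @rdname germlineCounts
#' @export
setGeneric("germlineCounts", function(x) standardGeneric("germlineCounts"))

#' @rdname percentAgreement
#' @export
setGeneric("percentAgreement",
           function(x, ...) standardGeneric("percentAgreement"))

#' @rdname fleissKappa
#' @export
setGeneric("fleissKappa", function(x, ...) standardGeneric("fleissKappa"))

#' @rdname readingErrorIndex
#' @export
setGeneric("readingErrorIndex",
           function(x, ...) standardGeneric("readingErrorIndex"))

# ---- simple accessors -------------------------------------------------------

#' Accessors for StereoMaturity objects
#'
#' `hitCounts()` returns the structure x slide integer count matrix of a
#' [SlideCountSet-class]; `totalPoints()` its per-slide grid sizes.
#' `raterLabels()` returns the point x rater label matrix of a
#' [RaterReadingSet-class] and `nRaters()` its number of raters.
#' `confusionCounts()` returns the 5 x 4 matrix of a
#' [ConfusionMatrix-class] and `excludedFish()` the unmatched fish ids.
#' `L50()` extracts the length at 50\% maturity (with its bootstrap CI as
#' attribute `"ci"`) from an [OgiveFit-class].
#'
#' @param x the object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("hitCounts", function(x) standardGeneric("hitCounts"))
#' @rdname accessors
#' @export
setGeneric("totalPoints", function(x) standardGeneric("totalPoints"))
#' @rdname accessors
#' @export
setGeneric("raterLabels", function(x) standardGeneric("raterLabels"))
#' @rdname accessors
#' @export
setGeneric("nRaters", function(x) standardGeneric("nRaters"))
#' @rdname accessors
#' @export
setGeneric("confusionCounts", function(x) standardGeneric("confusionCounts"))
#' @rdname accessors
#' @export
setGeneric("excludedFish", function(x) standardGeneric("excludedFish"))
#' @rdname accessors
#' @export
setGeneric("L50", function(x) standardGeneric("L50"))

#' @rdname accessors
#' @export
setMethod("hitCounts", "SlideCountSet", function(x) assay(x, "hits"))

#' @rdname accessors
#' @export
setMethod("totalPoints", "SlideCountSet", function(x) {
  stats::setNames(colData(x)$total_points, colData(x)$slide_id)
})

#' @rdname accessors
#' @export
setMethod("raterLabels", "RaterReadingSet", function(x) x@labels)

#' @rdname accessors
#' @export
setMethod("nRaters", "RaterReadingSet", function(x) ncol(x@labels))

#' @rdname accessors
#' @export
setMethod("confusionCounts", "ConfusionMatrix", function(x) x@counts)

#' @rdname accessors
#' @export
setMethod("excludedFish", "ConfusionMatrix", function(x) x@excluded)

#' @rdname accessors
#' @export
setMethod("L50", "OgiveFit", function(x) {
  structure(x@L50, ci = c(x@ciLow, x@ciHigh))
})

# ---- show methods -----------------------------------------------------------

setMethod("show", "SlideCountSet", function(object) {
  cat("SlideCountSet with", ncol(object), "slide(s) over",
      nrow(object), "structures\n")
  if (ncol(object)) {
    tp <- totalPoints(object)
    cat("  grid points per slide:", min(tp), "-", max(tp), "\n")
    cat("  fish:", length(unique(colData(object)$fish_id)), "\n")
  }
})

setMethod("show", "RaterReadingSet", function(object) {
  cat("RaterReadingSet for slide", object@slideId, ":",
      nrow(object@labels), "points x", ncol(object@labels), "raters\n")
})

setMethod("show", "ConfusionMatrix", function(object) {
  cat("ConfusionMatrix (stereological phase x macroscopic stage), n =",
      sum(object@counts), "\n")
  print(object@counts)
  if (length(object@excluded))
    cat("excluded (unmatched) fish:", length(object@excluded), "\n")
})

setMethod("show", "OgiveFit", function(object) {
  cat(sprintf("OgiveFit: logit P(mature) = %.4f + %.4f * length (n = %d)\n",
              object@beta0, object@beta1, object@n))
  cat(sprintf("  L50 = %.2f cm [%.2f, %.2f] (%d bootstrap resamples)\n",
              object@L50, object@ciLow, object@ciHigh, object@nBoot))
  cat(sprintf("  Nagelkerke R2 = %.3f%s%s\n", object@r2,
              if (!object@converged) "; NOT converged" else "",
              if (object@separation) "; separation detected" else ""))
})
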