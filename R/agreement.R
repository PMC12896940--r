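#' Construct a RaterReadingSet
#'
#' @param labels character matrix of structure codes, N grid points x n
#'   raters (n >= 2); aliases are resolved. Column names identify raters
#'   (defaults `R1..Rn`).
#' @param slideId slide identifier.
#' @return a [RaterReadingSet-class].
#' @export
RaterReadingSet <- function(labels, slideId = "slide") {
  labels <- as.matrix(labels)
  if (nrow(labels) == 0L)
    stop("empty reading: no grid points", call. = FALSE)
  labels[] <- resolveStructureCodes(labels)
  if (is.null(colnames(labels)))
    colnames(labels) <- paste0("R", seq_len(ncol(labels)))
  new("RaterReadingSet", slideId = as.character(slideId), labels = labels)
}

#' Read a multi-rater readings CSV
#'
#' Long format with columns `slide_id, point_index, rater_id, structure`;
#' all raters must label the same aligned points of one slide.
#'
#' @param path file path.
#' @return a [RaterReadingSet-class].
#' @export
readRaterCSV <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("slide_id", "point_index", "rater_id", "structure")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("readings CSV lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (length(unique(df$slide_id)) != 1L)
    stop("readings CSV must contain a single slide", call. = FALSE)
  raters <- sort(unique(df$rater_id))
  pts <- sort(unique(df$point_index))
  lab <- matrix(NA_character_, length(pts), length(raters),
                dimnames = list(NULL, raters))
  lab[cbind(match(df$point_index, pts), match(df$rater_id, raters))] <-
    df$structure
  if (anyNA(lab))
    stop("raters do not cover identical point sets", call. = FALSE)
  RaterReadingSet(lab, slideId = df$slide_id[1L])
}

# N x k tally: raters assigning each code to each point.
.pointTally <- function(labels, codes = sort(unique(as.vector(labels)))) {
  k <- length(codes)
  out <- vapply(seq_len(nrow(labels)), function(i)
    tabulate(match(labels[i, ], codes), k), integer(k))
  matrix(out, ncol = k, byrow = TRUE, dimnames = list(NULL, codes))
}

#' Percentage agreement between raters
#'
#' Mean pairwise agreement over aligned grid points: for each point, the
#' proportion of the `n(n-1)/2` rater pairs assigning the same structure
#' code, averaged over points and expressed as a percentage. With two raters
#' this degrades to simple percent matching (reported, though the index is
#' conventionally quoted for three or more readers). Set `allAgree = TRUE`
#' for the stricter all-raters-identical variant.
#'
#' @param x a [RaterReadingSet-class].
#' @param allAgree if `TRUE`, a point scores 1 only when every rater agrees.
#' @param ... unused.
#' @return a percentage in `[0, 100]`.
#' @rdname percentAgreement
#' @export
setMethod("percentAgreement", "RaterReadingSet", function(x, allAgree = FALSE, ...) {
  lab <- x@labels
  n <- ncol(lab)
  tal <- .pointTally(lab)
  if (allAgree)
    return(100 * mean(apply(tal, 1L, max) == n))
  agreePairs <- rowSums(tal * (tal - 1)) / 2
  100 * mean(agreePairs / (n * (n - 1) / 2))
})

#' Fleiss' kappa for multiple raters
#'
#' Chance-corrected agreement for `n` raters assigning categorical labels
#' to `N` aligned items. With `n_ij` the number of raters assigning code `j`
#' to point `i`:
#' \deqn{P_i = \frac{\sum_j n_{ij}^2 - n}{n(n-1)}, \quad
#'   \bar P = \frac{1}{N}\sum_i P_i, \quad
#'   p_j = \frac{\sum_i n_{ij}}{Nn}, \quad
#'   \bar P_e = \sum_j p_j^2, \quad
#'   \kappa = 100\,\frac{\bar P - \bar P_e}{1 - \bar P_e}.}
#' When every rater uses one single code on every point, the chance
#' agreement is 1 and kappa is undefined: `NA_real_` is returned with a
#' classed warning (`"kappaUndefinedWarning"`) rather than propagating NaN.
#'
#' The matrix method accepts a pre-aggregated `N x k` tally of
#' raters-per-code, so alternative itemizations can be fed in directly.
#'
#' @param x a [RaterReadingSet-class], or an N x k integer tally matrix
#'   with constant row sums (raters per item).
#' @param ... unused.
#' @return kappa as a percentage, or `NA_real_` when undefined.
#' @rdname fleissKappa
#' @export
setMethod("fleissKappa", "RaterReadingSet", function(x, ...) {
  fleissKappa(.pointTally(x@labels))
})

#' @rdname fleissKappa
#' @export
setMethod("fleissKappa", "matrix", function(x, ...) {
  n <- unique(rowSums(x))
  if (length(n) != 1L)
    stop("tally matrix must have constant row sums (raters per item)",
         call. = FALSE)
  if (n < 2) stop("at least two raters are required", call. = FALSE)
  N <- nrow(x)
  Pi <- (rowSums(x^2) - n) / (n * (n - 1))
  Pbar <- mean(Pi)
  pj <- colSums(x) / (N * n)
  Pe <- sum(pj^2)
  if (1 - Pe < .Machine$double.eps * 8) {
    warning(warningCondition(
      "Fleiss' kappa undefined: a single code was used for every rating",
      class = "kappaUndefinedWarning"))
    return(NA_real_)
  }
  100 * (Pbar - Pe) / (1 - Pe)
})

#' Per-structure reading-error index
#'
#' For two or more readings of the same slide, the maximum absolute pairwise
#' difference in each structure's estimated area fraction (percentage
#' points). Structures whose difference strictly exceeds `flagThreshold`
#' (default 3 percentage points) are flagged for review, the trigger used to
#' revise slides and set up identification rules during reader calibration.
#'
#' @param x a 19 x r matrix of fraction estimates (columns = readers, as
#'   returned by [fractionEstimates()]), or a [RaterReadingSet-class] from
#'   which each rater's fractions are derived.
#' @param slideIds optional per-column slide ids for the matrix method;
#'   readings from different slides are a cross-slide error.
#' @param flagThreshold flag cut in percentage points; strict `>`.
#' @param ... unused.
#' @return list with `per_structure_max_diff` (named numeric over the 19
#'   codes) and `flagged_structures` (character).
#' @rdname readingErrorIndex
#' @export
setMethod("readingErrorIndex", "matrix",
          function(x, flagThreshold = 3, slideIds = NULL, ...) {
  if (ncol(x) < 2L)
    stop("at least two fraction estimates are required", call. = FALSE)
  if (!is.null(slideIds) && length(unique(slideIds)) != 1L)
    stop("cross-slide error: fraction estimates are from different slides (",
         paste(unique(slideIds), collapse = ", "), ")", call. = FALSE)
  rownames(x) <- resolveStructureCodes(rownames(x))
  x <- x[structureCodes(), , drop = FALSE]
  d <- apply(x, 1L, function(r) max(r) - min(r))
  list(per_structure_max_diff = d,
       flagged_structures = names(d)[d > flagThreshold])
})

#' @rdname readingErrorIndex
#' @export
setMethod("readingErrorIndex", "RaterReadingSet",
          function(x, flagThreshold = 3, ...) {
  lab <- x@labels
  fr <- vapply(seq_len(ncol(lab)), function(j) {
    fractionEstimates(table2counts(lab[, j]))
  }, numeric(19L))
  dimnames(fr) <- list(structureCodes(), colnames(lab))
  readingErrorIndex(fr, flagThreshold = flagThreshold)
})

# labels -> named count vector over canonical codes
table2counts <- function(labels) {
  stats::setNames(tabulate(match(labels, structureCodes()), 19L),
                  structureCodes())
}

#' Agreement report for one slide
#'
#' Bundles the calibration statistics for a multi-rater reading of one
#' slide: mean pairwise percentage agreement, Fleiss' kappa, and the
#' per-structure reading-error index with its flags.
#'
#' @param readings a [RaterReadingSet-class].
#' @param flagThreshold percentage-point cut for the reading-error flag.
#' @return a list with `slide_id`, `n_raters`, `percent_agreement`,
#'   `fleiss_kappa`, `per_structure_max_diff`, `flagged_structures`.
#' @export
agreementReport <- function(readings, flagThreshold = 3) {
  rei <- readingErrorIndex(readings, flagThreshold = flagThreshold)
  kap <- withCallingHandlers(
    fleissKappa(readings),
    kappaUndefinedWarning = function(w) invokeRestart("muffleWarning"))
  list(slide_id = readings@slideId,
       n_raters = nRaters(readings),
       percent_agreement = percentAgreement(readings),
       fleiss_kappa = kap,
       per_structure_max_diff = rei$per_structure_max_diff,
       flagged_structures = rei$flagged_structures)
}

#' Summarize calibration statistics over slides
#'
#' Mean, sample standard deviation (n-1 denominator), minimum and maximum of
#' each agreement index over the slides where it is defined; undefined
#' (`NA`) entries are excluded and counted. Accepts either a list of
#' [agreementReport()] results or a data.frame with columns
#' `percent_agreement` and/or `fleiss_kappa` (e.g. a transcribed published
#' calibration table, see [calibrationFixture()]).
#'
#' @param reports list of agreement reports, or a data.frame.
#' @return a data.frame with one row per index: `index, n_defined,
#'   n_undefined, mean, sd, min, max` (`sd` is `NA` for a single value).
#' @export
summarizeCalibration <- function(reports) {
  if (is.data.frame(reports)) df <- reports
  else df <- data.frame(
    percent_agreement = vapply(reports, function(r)
      as.numeric(r$percent_agreement %||% NA_real_), numeric(1)),
    fleiss_kappa = vapply(reports, function(r)
      as.numeric(r$fleiss_kappa %||% NA_real_), numeric(1)))
  idx <- intersect(c("percent_agreement", "fleiss_kappa"), colnames(df))
  if (!length(idx)) stop("no agreement index columns found", call. = FALSE)
  do.call(rbind, lapply(idx, function(nm) {
    v <- df[[nm]]
    ok <- v[!is.na(v)]
    data.frame(index = nm, n_defined = length(ok),
               n_undefined = sum(is.na(v)),
               mean = if (length(ok)) mean(ok) else NA_real_,
               sd = if (length(ok) > 1) stats::sd(ok) else NA_real_,
               min = if (length(ok)) min(ok) else NA_real_,
               max = if (length(ok)) max(ok) else NA_real_)
  }))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
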