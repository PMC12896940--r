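#' Build a phase x stage confusion matrix
#'
#' Cross-tabulates each fish's stereologically determined maturity phase
#' (A-E) against its macroscopic stage (1-4). Fish present in only one of
#' the two tables are listed in the result's `excluded` slot; an empty
#' intersection is an error.
#'
#' @param phases named character vector (names = fish ids, values = phases)
#'   or a data.frame with columns `fish_id` and `phase`.
#' @param stages named vector (values in 1-4) or a data.frame with columns
#'   `fish_id` and `stage`.
#' @return a [ConfusionMatrix-class].
#' @export
buildConfusion <- function(phases, stages) {
  asNamed <- function(x, valueCol) {
    if (is.data.frame(x)) stats::setNames(as.character(x[[valueCol]]),
                                          as.character(x$fish_id))
    else stats::setNames(as.character(x), names(x))
  }
  ph <- asNamed(phases, "phase")
  st <- asNamed(stages, "stage")
  common <- intersect(names(ph), names(st))
  if (!length(common))
    stop("no fish ids shared between the phase and stage tables",
         call. = FALSE)
  badP <- setdiff(unique(ph[common]), .PHASES)
  badS <- setdiff(unique(st[common]), .STAGES)
  if (length(badP) || length(badS))
    stop("invalid label(s): ", paste(c(badP, badS), collapse = ", "),
         call. = FALSE)
  cm <- table(factor(ph[common], levels = .PHASES),
              factor(st[common], levels = .STAGES))
  cm <- matrix(as.integer(cm), 5L, 4L, dimnames = list(.PHASES, .STAGES))
  new("ConfusionMatrix", counts = cm,
      excluded = sort(union(setdiff(names(ph), common),
                            setdiff(names(st), common))))
}

#' Overall agreement between the macroscopic and stereological methods
#'
#' Percentage of fish whose macroscopic stage matches their stereological
#' phase under the rank correspondence A-1, B-2, C-3, D-4. Omitted spawning
#' (E) has no macroscopic counterpart and can never be matched.
#'
#' @param cm a [ConfusionMatrix-class].
#' @return percentage in `[0, 100]`.
#' @examples
#' overallAccuracy(confusionFixture())  # 40.4 on the packaged cohort table
#' @export
overallAccuracy <- function(cm) {
  m <- confusionCounts(cm)
  n <- sum(m)
  if (n == 0) stop("empty confusion matrix", call. = FALSE)
  100 * (m["A", "1"] + m["B", "2"] + m["C", "3"] + m["D", "4"]) / n
}

#' Conditional percentages of a confusion matrix
#'
#' Distribution of one method's labels conditional on the other's:
#' `given = "macroscopic"` divides each cell by its column (stage) total —
#' e.g. the share of macroscopically immature fish that stereology places
#' in each phase — and `given = "stereology"` divides by row (phase)
#' totals. Margins with zero total yield `NA` columns/rows rather than a
#' division error; every defined margin sums to 100.
#'
#' @param cm a [ConfusionMatrix-class].
#' @param given conditioning method.
#' @return 5 x 4 numeric matrix of percentages (with `NA` for empty
#'   margins).
#' @export
conditionalPercentages <- function(cm,
                                   given = c("macroscopic", "stereology")) {
  given <- match.arg(given)
  m <- confusionCounts(cm)
  if (given == "macroscopic") {
    tot <- colSums(m)
    out <- sweep(m, 2L, tot, "/") * 100
    out[, tot == 0] <- NA_real_
  } else {
    tot <- rowSums(m)
    out <- sweep(m, 1L, tot, "/") * 100
    out[tot == 0, ] <- NA_real_
  }
  out
}

#' Read and write confusion-matrix CSV
#'
#' CSV with a `phase` column (A-E) and columns `1..4` of counts.
#'
#' @param path file path.
#' @return a [ConfusionMatrix-class].
#' @export
readConfusionCSV <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, .STAGES])
  rownames(m) <- df$phase
  m <- m[.PHASES, , drop = FALSE]
  storage.mode(m) <- "integer"
  new("ConfusionMatrix", counts = m, excluded = character(0))
}

# ---- packaged fixtures ------------------------------------------------------

#' Packaged cohort fixtures transcribed from the published study tables
#'
#' `confusionFixture()` returns the published 5 x 4 confusion matrix of 151
#' female plaice (stereological phase x macroscopic stage) as a
#' [ConfusionMatrix-class]. `calibrationFixture()` returns the published
#' per-slide calibration table (20 slides; percentage agreement for the 12
#' three-rater slides, Fleiss' kappa for all 20) as a data.frame with
#' columns `slide_id, n_raters, percent_agreement, fleiss_kappa`.
#'
#' @return see above.
#' @examples
#' overallAccuracy(confusionFixture())
#' summarizeCalibration(calibrationFixture())
#' @export
confusionFixture <- function() {
  readConfusionCSV(system.file("extdata", "table4_confusion.csv",
                               package = "StereoMaturity", mustWork = TRUE))
}

#' @rdname confusionFixture
#' @export
calibrationFixture <- function() {
  utils::read.csv(system.file("extdata", "table3_agreement.csv",
                              package = "StereoMaturity", mustWork = TRUE),
                  stringsAsFactors = FALSE)
}
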