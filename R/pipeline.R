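#' Recompute the published summary statistics from the packaged fixtures
#'
#' Runs the comparison and calibration modules over the packaged cohort
#' tables: overall macroscopic-vs-stereology agreement and its conditional
#' percentages from the confusion-matrix fixture, and the mean/sd of the
#' percentage agreement and Fleiss' kappa from the calibration fixture.
#'
#' @return a list with elements `confusion` ([ConfusionMatrix-class]),
#'   `overall_accuracy`, `conditional_given_macro` (5 x 4 matrix),
#'   `calibration` (data.frame from [summarizeCalibration()]).
#' @examples
#' rp <- reproducePaper()
#' round(rp$overall_accuracy, 1)
#' @export
reproducePaper <- function() {
  cm <- confusionFixture()
  cal <- summarizeCalibration(calibrationFixture())
  list(confusion = cm,
       overall_accuracy = overallAccuracy(cm),
       conditional_given_macro = conditionalPercentages(cm, "macroscopic"),
       calibration = cal)
}

#' Run the simulate-classify-compare pipeline
#'
#' Generates a synthetic cohort, classifies every fish's designated staging
#' slide, cross-tabulates stereological phases against the simulated
#' macroscopic stages, and (optionally) fits maturity ogives from both
#' label sources. When `outDir` is given, writes `counts.csv`, `macro.csv`,
#' `truth.csv`, `phases.csv`, `confusion.json` and a provenance record
#' (`provenance.json`: config echo, package version, seed) there.
#'
#' @param config a [cohortConfig()].
#' @param classifier a [classifierConfig()].
#' @param fitOgives fit macroscopic and stereological ogives as well?
#' @param nBoot bootstrap resamples for the ogive fits.
#' @param outDir optional output directory.
#' @return list with `sim`, `phases`, `confusion`, `accuracy` and, when
#'   requested, `ogives` (list of two [OgiveFit-class]) and `deltaL50`.
#' @export
runPipeline <- function(config = cohortConfig(),
                        classifier = classifierConfig(),
                        fitOgives = FALSE, nBoot = 200L, outDir = NULL) {
  sim <- simulateCohort(config)
  cls <- classifyCohort(sim$counts, classifier)
  cm <- buildConfusion(
    stats::setNames(cls$phases$phase, cls$phases$fish_id),
    stats::setNames(sim$fish$stage, sim$fish$fish_id))
  out <- list(sim = sim, phases = cls$phases, confusion = cm,
              accuracy = overallAccuracy(cm))
  if (fitOgives) {
    stereo <- fitOgive(sim$fish$length_cm,
                       toBinaryMaturity(cls$phases$phase[
                         match(sim$fish$fish_id, cls$phases$fish_id)]),
                       nBoot = nBoot, seed = config$seed)
    macro <- fitOgive(sim$fish$length_cm, toBinaryMaturity(sim$fish$stage),
                      nBoot = nBoot, seed = config$seed)
    out$ogives <- list(stereology = stereo, macroscopic = macro)
    out$deltaL50 <- compareOgives(macro, stereo)
  }
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    writeCountsCSV(sim$counts, file.path(outDir, "counts.csv"))
    utils::write.csv(sim$fish, file.path(outDir, "macro.csv"),
                     row.names = FALSE)
    utils::write.csv(sim$truth, file.path(outDir, "truth.csv"),
                     row.names = FALSE)
    utils::write.csv(cls$phases, file.path(outDir, "phases.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(counts = confusionCounts(cm),
           n = sum(confusionCounts(cm)),
           overall_accuracy = out$accuracy),
      file.path(outDir, "confusion.json"), auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(
      list(package = "StereoMaturity",
           version = as.character(utils::packageVersion("StereoMaturity")),
           seed = config$seed, n_fish = config$nFish,
           atresia_threshold = classifier$atresiaThreshold),
      file.path(outDir, "provenance.json"), auto_unbox = TRUE, digits = NA)
  }
  out
}
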