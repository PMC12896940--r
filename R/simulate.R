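#' Phase-conditional composition templates
#'
#' Mean slide compositions (proportions over the 19 structures, summing to
#' 1) for each maturity phase, used as the Dirichlet centres of the
#' synthetic cohort generator. The templates are hand-set to sit well inside
#' each phase's rule region — structures a phase's rule requires present
#' have proportion at least 0.02, structures a rule requires absent have
#' proportion exactly 0 (so sampling can never create them) — and oogonia
#' are kept rare (0.5\%) because they are small and easily missed on real
#' slides. Template rule-consistency is asserted at construction: the
#' expected counts of each template classify to its own phase.
#'
#' @return named list of 5 numeric vectors (phases A-E), each over the 19
#'   canonical codes and summing to 1.
#' @export
phaseTemplates <- function() {
  tpl <- list(
    A = c(og = .005, po1 = .45, po2 = .25,
          tc = .12, pg = .06, ei = .06, cs = .03, v = .01, i = .015),
    B = c(po1 = .20, po2 = .10, cao = .15, vit1 = .10, vit2 = .05, oaA = .02,
          tc = .14, pg = .06, ei = .10, cs = .04, L = .02, v = .01, i = .01),
    C = c(po1 = .15, vit2 = .10, vit3 = .15, pho = .05, ho = .10,
          POF = .02, oaA = .01,
          tc = .14, pg = .05, ei = .14, cs = .04, L = .02, v = .01, i = .02),
    D = c(po1 = .10, cao = .05, vit3 = .05, ho = .02, POF = .15,
          oaA = .02, oaB = .05,
          tc = .20, pg = .08, ei = .16, cs = .05, L = .04, v = .01, i = .02),
    E = c(po1 = .15, po2 = .05, oaA = .50,
          tc = .10, pg = .05, ei = .08, cs = .03, L = .02, v = .01, i = .01))
  out <- lapply(tpl, function(p) {
    v <- stats::setNames(numeric(19L), structureCodes())
    v[names(p)] <- p
    stopifnot(abs(sum(v) - 1) < 1e-12)
    v
  })
  # rule-consistency: expected counts at a 550-point grid recover the phase
  for (ph in .PHASES) {
    got <- classifySlide(.roundCounts(out[[ph]], 550L))$phase
    if (got != ph)
      stop("template for phase ", ph, " classifies as ", got, call. = FALSE)
  }
  out
}

# largest-remainder rounding of proportions to integer counts summing to n
.roundCounts <- function(p, n) {
  raw <- p * n
  cnt <- floor(raw)
  left <- n - sum(cnt)
  if (left > 0) {
    ord <- order(raw - cnt, decreasing = TRUE)
    cnt[ord[seq_len(left)]] <- cnt[ord[seq_len(left)]] + 1L
  }
  stats::setNames(as.integer(cnt), names(p))
}

#' Cohort simulation configuration
#'
#' Defaults emulate the published 151-fish cohort: phase probabilities
#' proportional to the stereological phase totals (23, 53, 9, 65, 1),
#' sampling months weighted by the study's sampling calendar, 500-600 grid
#' points per slide, and a macroscopic-staging error matrix equal to the
#' published confusion matrix's phase-conditional rows (so the published
#' confusion structure is the generative truth). Per-phase length models
#' are loose synthetic defaults (plaice-scale, cm); true phase-conditional
#' length distributions are not published.
#'
#' @param nFish number of fish.
#' @param seed RNG seed for [simulateCohort()].
#' @param phaseProbabilities named 5-vector over phases A-E, summing to 1.
#' @param lengthModel data.frame `phase, mean, sd` (cm).
#' @param monthWeights named integer vector, sampling weight per month.
#' @param gridPointsRange integer range for total grid points per slide.
#' @param macroError 5 x 4 row-stochastic matrix, `P(stage | phase)`.
#' @param concentration Dirichlet concentration for composition jitter
#'   around the phase template; `Inf` gives noise-free template
#'   compositions with deterministic (largest-remainder rounded) counts.
#' @param templates phase composition templates, see [phaseTemplates()].
#' @return a list of class `CohortConfig`.
#' @export
cohortConfig <- function(nFish = 151L, seed = 1L,
                         phaseProbabilities = c(A = 23, B = 53, C = 9,
                                                D = 65, E = 1) / 151,
                         lengthModel = data.frame(
                           phase = c("A", "B", "C", "D", "E"),
                           mean = c(17, 26, 30, 32, 30),
                           sd = c(2.5, 3, 3, 4, 4)),
                         monthWeights = c("1" = 29, "2" = 23, "3" = 40,
                                          "6" = 12, "8" = 18, "11" = 14,
                                          "12" = 15),
                         gridPointsRange = c(500L, 600L),
                         macroError = NULL,
                         concentration = 300,
                         templates = phaseTemplates()) {
  if (is.null(macroError)) {
    m <- confusionCounts(confusionFixture())
    macroError <- sweep(m, 1L, rowSums(m), "/")
  }
  if (abs(sum(phaseProbabilities) - 1) > 1e-9)
    stop("phaseProbabilities must sum to 1", call. = FALSE)
  if (any(abs(rowSums(macroError) - 1) > 1e-9))
    stop("macroError rows must sum to 1", call. = FALSE)
  if (concentration <= 0)
    stop("concentration must be positive", call. = FALSE)
  structure(list(nFish = as.integer(nFish), seed = as.integer(seed),
                 phaseProbabilities = phaseProbabilities,
                 lengthModel = lengthModel, monthWeights = monthWeights,
                 gridPointsRange = as.integer(gridPointsRange),
                 macroError = macroError, concentration = concentration,
                 templates = templates),
            class = "CohortConfig")
}

#' Simulate a synthetic fish cohort
#'
#' For each fish: draw a true maturity phase, sampling month and length;
#' draw the slide composition from a Dirichlet centred on the phase
#' template (`concentration x template`); draw the grid size uniformly on
#' `gridPointsRange` and the hit counts from a multinomial; and draw the
#' macroscopic stage from the phase's row of `macroError`. One designated
#' staging slide (ventral ovary, position 2) is generated per fish. The
#' output is deterministic given the config seed.
#'
#' @param config a [cohortConfig()].
#' @return list with `fish` (data.frame `fish_id, length_cm, month, stage`),
#'   `counts` (a [SlideCountSet-class]) and `truth` (data.frame
#'   `fish_id, phase`).
#' @examples
#' sim <- simulateCohort(cohortConfig(nFish = 20, seed = 7))
#' table(sim$truth$phase)
#' @export
simulateCohort <- function(config = cohortConfig()) {
  set.seed(config$seed)
  n <- config$nFish
  fishId <- sprintf("fish_%04d", seq_len(n))
  phase <- sample(.PHASES, n, replace = TRUE,
                  prob = config$phaseProbabilities[.PHASES])
  month <- as.integer(sample(names(config$monthWeights), n, replace = TRUE,
                             prob = config$monthWeights))
  lm <- config$lengthModel
  mu <- lm$mean[match(phase, lm$phase)]
  sdv <- lm$sd[match(phase, lm$phase)]
  len <- pmax(round(stats::rnorm(n, mu, sdv), 1), 5)
  total <- sample(seq(config$gridPointsRange[1], config$gridPointsRange[2]),
                  n, replace = TRUE)
  hits <- matrix(0L, 19L, n, dimnames = list(structureCodes(), NULL))
  for (k in seq_len(n)) {
    tpl <- config$templates[[phase[k]]]
    if (is.finite(config$concentration)) {
      g <- stats::rgamma(19L, shape = config$concentration * tpl)
      comp <- if (sum(g) > 0) g / sum(g) else tpl
      hits[, k] <- stats::rmultinom(1L, total[k], comp)
    } else {
      hits[, k] <- .roundCounts(tpl, total[k])
    }
  }
  stage <- vapply(phase, function(p) {
    sample(.STAGES, 1L, prob = config$macroError[p, ])
  }, character(1))
  counts <- SlideCountSet(hits, totalPoints = total,
                          slideId = paste0(fishId, "_V2"),
                          fishId = fishId, ovary = "V", position = 2L)
  list(fish = data.frame(fish_id = fishId, length_cm = len, month = month,
                         stage = stage, stringsAsFactors = FALSE),
       counts = counts,
       truth = data.frame(fish_id = fishId, phase = phase,
                          stringsAsFactors = FALSE))
}

#' Rater confusion matrix for reading noise
#'
#' A simple per-point misclassification model: each grid point's true
#' structure label is kept with probability `1 - rate` and otherwise
#' relabeled to `target` (default `"i"`, undetermined). Any 19 x 19
#' row-stochastic matrix can be supplied to [simulateRaters()] instead.
#'
#' @param rate misclassification probability in `[0, 1]`.
#' @param target code the mislabeled points are assigned to.
#' @return 19 x 19 row-stochastic matrix over the canonical codes.
#' @export
raterConfusionMatrix <- function(rate = 0.05, target = "i") {
  if (rate < 0 || rate > 1)
    stop("rate must be in [0, 1]", call. = FALSE)
  target <- resolveStructureCodes(target)
  codes <- structureCodes()
  m <- diag(1 - rate, 19L)
  dimnames(m) <- list(codes, codes)
  m[, target] <- m[, target] + rate
  m[target, target] <- 1
  m[target, setdiff(codes, target)] <- 0
  m
}

#' Simulate a multi-rater reading of one slide
#'
#' Expands a slide's hit counts to individually labeled grid points, then
#' perturbs each rater's labels independently point by point through a
#' structure-confusion matrix. Zero noise yields identical raters.
#'
#' @param slide a single-slide [SlideCountSet-class] or named count vector.
#' @param nRaters number of raters (>= 2).
#' @param noise 19 x 19 row-stochastic confusion matrix, e.g.
#'   [raterConfusionMatrix()].
#' @param seed RNG seed.
#' @return a [RaterReadingSet-class].
#' @export
simulateRaters <- function(slide, nRaters = 3L,
                           noise = raterConfusionMatrix(), seed = 1L) {
  if (nRaters < 2L) stop("at least two raters are required", call. = FALSE)
  if (is(slide, "SlideCountSet")) {
    cnt <- hitCounts(slide)[, 1L]
    sid <- colData(slide)$slide_id[1L]
  } else {
    v <- stats::setNames(integer(19L), structureCodes())
    names(slide) <- resolveStructureCodes(names(slide))
    v[names(slide)] <- as.integer(slide)
    cnt <- v
    sid <- "slide"
  }
  if (any(noise < 0) || any(noise > 1) ||
      any(abs(rowSums(noise) - 1) > 1e-9))
    stop("noise must be a row-stochastic matrix with entries in [0, 1]",
         call. = FALSE)
  truth <- rep(structureCodes(), cnt)
  set.seed(seed)
  lab <- vapply(seq_len(nRaters), function(r) {
    out <- truth
    for (code in unique(truth)) {
      idx <- which(truth == code)
      out[idx] <- sample(structureCodes(), length(idx), replace = TRUE,
                         prob = noise[code, ])
    }
    out
  }, character(length(truth)))
  colnames(lab) <- paste0("R", seq_len(nRaters))
  RaterReadingSet(lab, slideId = sid)
}
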