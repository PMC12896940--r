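#' Classifier configuration
#'
#' Tunable parameters of the rule-based maturity classifier.
#'
#' @param atresiaThreshold percentage in (0, 100); the alpha-atresia cut
#'   separating phases B/C from omitted spawning E. Default 50: at most half
#'   of the quantified follicles may be alpha-atretic for a developing or
#'   spawning call, and strictly more than half is required for E (the
#'   boundary case stays in B/C by rule order).
#' @param follicleDenominator structure codes forming "total follicles
#'   quantified", the denominator of the alpha-atresia percentage. Default:
#'   all 12 germline codes.
#' @param requiredPresenceMinHits minimum grid hits for a structure to count
#'   as "present" in a presence rule. Default 1 (presence/absence on counted
#'   structures).
#' @param pofComparisonCodes structure codes whose summed count bounds the
#'   number of post-ovulatory follicles in the late-spawning rule. Default
#'   `"ho"` (hydrated oocytes only).
#' @return a list of class `ClassifierConfig`.
#' @export
classifierConfig <- function(atresiaThreshold = 50,
                             follicleDenominator = germlineCodes(),
                             requiredPresenceMinHits = 1L,
                             pofComparisonCodes = "ho") {
  if (atresiaThreshold <= 0 || atresiaThreshold >= 100)
    stop("atresiaThreshold must be in (0, 100)", call. = FALSE)
  follicleDenominator <- resolveStructureCodes(follicleDenominator)
  if (!length(follicleDenominator) ||
      !all(follicleDenominator %in% germlineCodes()))
    stop("follicleDenominator must be a non-empty subset of the germline codes",
         call. = FALSE)
  structure(list(atresiaThreshold = atresiaThreshold,
                 follicleDenominator = follicleDenominator,
                 requiredPresenceMinHits = as.integer(requiredPresenceMinHits),
                 pofComparisonCodes = resolveStructureCodes(pofComparisonCodes)),
            class = "ClassifierConfig")
}

# Core rule engine, vectorized over the columns of a 19 x n count matrix.
# Rules are evaluated in fixed order A, B, C, E with D as fallback; exactly
# one phase is returned per slide.
.classifyMatrix <- function(h, config) {
  m <- config$requiredPresenceMinHits
  thr <- config$atresiaThreshold
  cnt <- function(code) h[code, ]
  G <- colSums(h[config$follicleDenominator, , drop = FALSE])
  atresia <- ifelse(G > 0, 100 * cnt("oaA") / G, 0)
  otherGerm <- setdiff(germlineCodes(), c("og", "po1", "po2"))

  isA <- colSums(h[otherGerm, , drop = FALSE]) == 0 &
    (cnt("og") >= m | cnt("po1") >= m | cnt("po2") >= m)
  isB <- (cnt("cao") >= m | cnt("vit1") >= m | cnt("vit2") >= m) &
    atresia <= thr &
    cnt("POF") == 0 & cnt("oaB") == 0 &
    cnt("vit3") == 0 & cnt("pho") == 0 & cnt("ho") == 0
  pofBound <- colSums(h[config$pofComparisonCodes, , drop = FALSE])
  isC <- (cnt("vit3") >= m | cnt("pho") >= m | cnt("ho") >= m) &
    atresia <= thr & cnt("oaB") == 0 & cnt("POF") <= pofBound
  isE <- cnt("POF") == 0 & atresia > thr

  phase <- rep("D", ncol(h))
  rule <- rep("fallback", ncol(h))
  sel <- isE;               phase[sel] <- "E"; rule[sel] <- "E"
  sel <- isC;               phase[sel] <- "C"
  rule[isC & cnt("POF") == 0] <- "C-early"
  rule[isC & cnt("POF") > 0] <- "C-late"
  sel <- isB;               phase[sel] <- "B"; rule[sel] <- "B"
  sel <- isA;               phase[sel] <- "A"; rule[sel] <- "A"
  data.frame(phase = phase, rule_fired = rule,
             atresia_pct = unname(atresia), stringsAsFactors = FALSE)
}

#' Classify one slide into a maturity phase
#'
#' Maps a slide's stereological counts to a maturity phase by
#' presence/absence and atresia-percentage rules, evaluated in fixed order
#' with D (regressing/regenerating) as the fallback for anything the
#' positive rules do not capture:
#' \describe{
#'   \item{A (immature)}{every germline hit is an oogonium (`og`) or
#'     primary oocyte (`po1`, `po2`), and at least one of these is present.}
#'   \item{B (developing)}{cortical alveoli (`cao`) or early/zona-radiata
#'     vitellogenic oocytes (`vit1`, `vit2`) present; alpha atresia at most
#'     the threshold; no `POF`, `oaB`, `vit3`, `pho` or `ho`.}
#'   \item{C (spawning)}{late vitellogenic, partially hydrated or hydrated
#'     oocytes (`vit3`, `pho`, `ho`) present; alpha atresia at most the
#'     threshold; no `oaB`; and post-ovulatory follicles not exceeding the
#'     hydrated-oocyte count (`rule_fired` distinguishes `"C-early"`,
#'     `POF = 0`, from `"C-late"`). More `POF` than `ho` means spawning has
#'     finished, so the slide falls through to D.}
#'   \item{E (omitted spawning)}{no `POF` and strictly more than the
#'     threshold percentage of alpha-atretic follicles.}
#' }
#' The alpha-atresia percentage is `100 * oaA / G` with `G` the hit sum over
#' `follicleDenominator` (0 when `G = 0`). Every valid count vector maps to
#' exactly one phase.
#'
#' @param slide a named numeric vector of hit counts (aliases resolved,
#'   absent structures 0), or a single-slide [SlideCountSet-class].
#' @param config a [classifierConfig()].
#' @param totalPoints optional; validated against `sum(slide)` for the
#'   vector method.
#' @return a list with elements `phase` (one of `"A".."E"`), `rule_fired`
#'   and `atresia_pct`.
#' @examples
#' classifySlide(c(po1 = 400, cao = 50, vit1 = 30, oaA = 10, tc = 30))$phase  # B
#' classifySlide(c(po1 = 100, oaA = 400, tc = 50))$phase                      # E
#' @export
classifySlide <- function(slide, config = classifierConfig(),
                          totalPoints = NULL) {
  if (is(slide, "SlideCountSet")) {
    if (ncol(slide) != 1L)
      stop("classifySlide() expects a single slide; see classifyCohort()",
           call. = FALSE)
    h <- hitCounts(slide)
  } else {
    v <- stats::setNames(numeric(19L), structureCodes())
    if (length(slide)) {
      names(slide) <- resolveStructureCodes(names(slide))
      if (any(slide < 0)) stop("negative hit counts", call. = FALSE)
      for (k in seq_along(slide))
        v[names(slide)[k]] <- v[names(slide)[k]] + slide[[k]]
    }
    if (!is.null(totalPoints) && sum(v) != totalPoints)
      stop("hit counts do not sum to total_points", call. = FALSE)
    if (sum(v) <= 0)
      stop("invalid slide: no grid points counted", call. = FALSE)
    h <- matrix(v, ncol = 1L, dimnames = list(structureCodes(), NULL))
  }
  res <- .classifyMatrix(h, config)
  list(phase = res$phase, rule_fired = res$rule_fired,
       atresia_pct = res$atresia_pct)
}

#' Classify a cohort, one designated slide per fish
#'
#' Applies [classifySlide()] to each fish's designated staging slide
#' (by default the median section of the ventral ovary, `ovary = "V"`,
#' `position = 2`). Fish in the set with no designated slide are reported
#' in the `missing` element, never silently dropped; duplicate designated
#' slides for a fish are an ambiguity error.
#'
#' @param slides a [SlideCountSet-class].
#' @param config a [classifierConfig()].
#' @param ovary,position selectors for the designated slide.
#' @return a list with `phases` (data.frame `fish_id, slide_id, phase,
#'   rule_fired`) and `missing` (character vector of fish ids lacking a
#'   designated slide).
#' @export
classifyCohort <- function(slides, config = classifierConfig(),
                           ovary = "V", position = 2) {
  cd <- colData(slides)
  sel <- cd$ovary == ovary & cd$position == position
  fishAll <- unique(cd$fish_id)
  fishSel <- cd$fish_id[sel]
  dup <- unique(fishSel[duplicated(fishSel)])
  if (length(dup))
    stop("ambiguous designated slide (ovary ", ovary, ", position ",
         position, ") for fish: ", paste(dup, collapse = ", "),
         call. = FALSE)
  sub <- slides[, sel]
  res <- .classifyMatrix(hitCounts(sub), config)
  phases <- data.frame(fish_id = colData(sub)$fish_id,
                       slide_id = colData(sub)$slide_id,
                       phase = res$phase, rule_fired = res$rule_fired,
                       stringsAsFactors = FALSE)
  list(phases = phases, missing = setdiff(fishAll, fishSel))
}
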