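# Independent, literal transcription of the phase-classification rules,
# written as scalar if/else over one count vector. Deliberately coded
# separately from the package's vectorized rule engine so the two can be
# compared on random inputs.
oracleClassify <- function(counts, threshold = 50) {
  germ <- c("og", "po1", "po2", "cao", "vit1", "vit2", "vit3", "pho", "ho",
            "POF", "oaA", "oaB")
  G <- sum(counts[germ])
  atresia <- if (G > 0) 100 * counts[["oaA"]] / G else 0
  present <- function(s) counts[[s]] >= 1
  absent <- function(s) counts[[s]] == 0

  # immature: only oogonia / primary oocytes among the germline cells
  if (sum(counts[setdiff(germ, c("og", "po1", "po2"))]) == 0 &&
      (present("og") || present("po1") || present("po2")))
    return("A")
  # developing: cao/vit1/vit2 present; atresia <= 50%; no POF, oaB,
  # vit3, pho, ho
  if ((present("cao") || present("vit1") || present("vit2")) &&
      atresia <= threshold &&
      absent("POF") && absent("oaB") && absent("vit3") &&
      absent("pho") && absent("ho"))
    return("B")
  # spawning: vit3/pho/ho present; atresia <= 50%; no oaB; POF does not
  # exceed the hydrated-oocyte count (0 POF = start of spawning)
  if ((present("vit3") || present("pho") || present("ho")) &&
      atresia <= threshold && absent("oaB") &&
      counts[["POF"]] <= counts[["ho"]])
    return("C")
  # omitted spawning: no POF, more than 50% alpha atresia
  if (absent("POF") && atresia > threshold)
    return("E")
  # everything else regresses/regenerates
  "D"
}

# Random count vectors exercising the rule space, including boundary
# constructions (exact-threshold atresia, POF == ho ties, empty germline).
randomCountVectors <- function(n, seed) {
  set.seed(seed)
  codes <- structureCodes()
  lapply(seq_len(n), function(i) {
    v <- setNames(integer(19L), codes)
    k <- sample(1:8, 1)
    on <- sample(codes, k)
    v[on] <- sample(0:200, k, replace = TRUE)
    kind <- sample(1:5, 1)
    if (kind == 2) {           # atresia exactly at the 50% boundary
      v[setdiff(codes, "oaA")][] <- 0
      v["oaA"] <- sample(1:50, 1)
      other <- sample(c("po1", "cao", "vit3", "ho"), 1)
      v[other] <- v[["oaA"]]
      v["tc"] <- sample(0:100, 1)
    } else if (kind == 3) {    # POF == ho tie
      v["POF"] <- sample(0:20, 1)
      v["ho"] <- v[["POF"]]
    } else if (kind == 4) {    # no germline at all
      v[germlineCodes()] <- 0L
      v["tc"] <- sample(1:100, 1)
    }
    if (sum(v) == 0) v["i"] <- 1L
    v
  })
}

# Convenience: a small valid SlideCountSet built in code.
makeSlideSet <- function(vectors, fishId = NULL, ovary = "V", position = 2) {
  hits <- vapply(vectors, function(v) {
    out <- setNames(integer(19L), structureCodes())
    out[names(v)] <- as.integer(v)
    out
  }, integer(19L))
  colnames(hits) <- sprintf("s%03d", seq_along(vectors))
  suppressWarnings(SlideCountSet(
    hits, slideId = colnames(hits),
    fishId = if (is.null(fishId)) sprintf("f%03d", seq_along(vectors))
             else fishId,
    ovary = ovary, position = position))
}
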