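test_that("the rule model stages the canonical example slides", {
  cases <- list(
    list(c(og = 5, po1 = 300, po2 = 200, tc = 20), "A", "A"),
    list(c(po1 = 400, cao = 50, vit1 = 30, oaA = 10, tc = 30), "B", "B"),
    list(c(po1 = 200, vit2 = 80, vit3 = 100, ho = 20, POF = 10, tc = 90),
         "C", "C-late"),
    list(c(po1 = 200, vit3 = 50, ho = 10, POF = 30, tc = 210),
         "D", "fallback"),          # POF exceed ho: spawning is over
    list(c(po1 = 100, oaA = 400, tc = 50), "E", "E"),
    list(c(po1 = 100, cao = 1, ei = 399), "B", "B"),  # single hit = presence
    list(c(po1 = 100, vit3 = 80, pho = 10, tc = 310), "C", "C-early"))
  for (cs in cases) {
    r <- classifySlide(cs[[1]])
    expect_identical(r$phase, cs[[2]])
    expect_identical(r$rule_fired, cs[[3]])
  }
})

test_that("atresia exactly at the threshold stays in B/C, never E", {
  # 50 oaA against 50 cao: atresia% = 50 exactly
  r <- classifySlide(c(cao = 50, oaA = 50, tc = 400))
  expect_identical(r$phase, "B")
  expect_equal(r$atresia_pct, 50)
  r2 <- classifySlide(c(ho = 50, oaA = 50, tc = 400))
  expect_identical(r2$phase, "C")
  # one more atretic follicle tips it over
  r3 <- classifySlide(c(cao = 50, oaA = 51, tc = 399))
  expect_identical(r3$phase, "E")
})

test_that("a single post-ovulatory follicle flips a developing slide", {
  base <- c(po1 = 300, cao = 100, tc = 99)
  expect_identical(classifySlide(base)$phase, "B")
  expect_false(classifySlide(c(base, POF = 1))$phase == "B")
})

test_that("classification is total and order-insensitive", {
  vecs <- randomCountVectors(500, seed = 31)
  for (v in vecs) {
    r <- classifySlide(v)
    expect_true(r$phase %in% c("A", "B", "C", "D", "E"))
    perm <- v[sample(names(v))]
    expect_identical(classifySlide(perm)$phase, r$phase)
  }
})

test_that("the atresia denominator and POF comparison set are configurable", {
  v <- c(cao = 40, oaA = 30, po1 = 30, tc = 400)
  # default denominator: all 12 germline codes -> atresia = 30/100 = 30%
  expect_identical(classifySlide(v)$phase, "B")
  # drop the primary oocytes from the denominator: 30/70 = 42.9%, still B
  cfg <- classifierConfig(follicleDenominator =
                            setdiff(germlineCodes(), c("og", "po1", "po2")))
  expect_identical(classifySlide(v, cfg)$phase, "B")
  # a denominator excluding cao makes every follicle counted atretic
  cfg2 <- classifierConfig(follicleDenominator = c("oaA", "vit1"))
  expect_identical(classifySlide(v, cfg2)$phase, "E")    # 30/30 = 100%
  # lowering the threshold below the observed 30% reroutes B to E
  cfg3 <- classifierConfig(atresiaThreshold = 25)
  expect_identical(classifySlide(v, cfg3)$phase, "E")
  # POF-comparison set including pho admits more late-spawning slides
  w <- c(vit3 = 50, pho = 30, ho = 5, POF = 20, po1 = 100, tc = 295)
  expect_identical(classifySlide(w)$phase, "D")           # POF 20 > ho 5
  cfg4 <- classifierConfig(pofComparisonCodes = c("ho", "pho"))
  expect_identical(classifySlide(w, cfg4)$phase, "C")     # 20 <= 35
})

test_that("empty or negative slides are invalid", {
  expect_error(classifySlide(c(po1 = 0, tc = 0)), "no grid points")
  expect_error(classifySlide(c(po1 = -2, tc = 10)), "negative")
  expect_error(classifierConfig(atresiaThreshold = 0))
  expect_error(classifierConfig(follicleDenominator = c("tc")))
})

test_that("classifyCohort designates one ventral median slide per fish", {
  vecs <- list(c(po1 = 500), c(cao = 100, po1 = 400), c(ho = 50, tc = 450))
  s <- makeSlideSet(vecs, fishId = c("f1", "f2", "f3"))
  out <- classifyCohort(s)
  expect_identical(out$phases$phase, c("A", "B", "C"))
  expect_length(out$missing, 0L)

  # a fish whose designated slide is absent is reported missing
  s2 <- makeSlideSet(vecs, fishId = c("f1", "f2", "f3"),
                     position = c(2, 2, 1))
  out2 <- classifyCohort(s2)
  expect_identical(sort(out2$phases$fish_id), c("f1", "f2"))
  expect_identical(out2$missing, "f3")

  # duplicate designated slides are ambiguous
  s3 <- makeSlideSet(vecs, fishId = c("f1", "f1", "f2"))
  expect_error(classifyCohort(s3), "ambiguous.*f1")
})

test_that("the vectorized engine matches the literal rule transcription", {
  vecs <- randomCountVectors(2000, seed = 41)
  got <- vapply(vecs, function(v) classifySlide(v)$phase, character(1))
  want <- vapply(vecs, function(v) {
    full <- setNames(numeric(19L), structureCodes())
    full[names(v)] <- v
    oracleClassify(full)
  }, character(1))
  expect_identical(got, want)
})
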