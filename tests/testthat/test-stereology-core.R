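test_that("the fraction estimator matches the point-count formula", {
  # (100 / total_points) * hit_points
  expect_equal(fractionEstimates(c(po1 = 100, tc = 400))[["po1"]], 20)
  f <- fractionEstimates(c(og = 0, po1 = 300, tc = 250), totalPoints = 550)
  expect_equal(f[["og"]], 0)
  # exact rational arithmetic case
  f2 <- fractionEstimates(c(po1 = 250, po2 = 125, tc = 125))
  expect_identical(unname(f2[c("po1", "po2", "tc")]), c(50, 25, 25))
  expect_length(f2, 19L)  # keyed over all structures, absent = 0
})

test_that("fractions sum to 100 and are scale-invariant in the counts", {
  set.seed(11)
  for (i in 1:20) {
    v <- setNames(sample(0:60, 19, replace = TRUE), structureCodes())
    v["tc"] <- v[["tc"]] + 1L  # ensure nonempty
    f1 <- fractionEstimates(v)
    expect_equal(sum(f1), 100, tolerance = 1e-12)
    expect_equal(fractionEstimates(v * 2L), f1)  # homogeneous of degree 0
  }
})

test_that("invalid slides are rejected with informative errors", {
  expect_error(fractionEstimates(c(po1 = 10), totalPoints = 0),
               "total_points")
  expect_error(fractionEstimates(c(po1 = 10), totalPoints = 500),
               "sum")
  expect_error(SlideCountSet(matrix(5L, 1, 1, dimnames = list("xyz", "s1"))),
               "unknown structure")
  hits <- matrix(0L, 19, 1, dimnames = list(structureCodes(), "s1"))
  hits["po1", 1] <- 500L
  expect_error(SlideCountSet(hits, totalPoints = 520, slideId = "s1"),
               "s1")
  expect_warning(SlideCountSet(c(po1 = 100), slideId = "tiny"),
                 "expected range")
})

test_that("aliases resolve deterministically and germline set is fixed", {
  expect_identical(resolveStructureCodes(c("aoA", "aoB", "po1")),
                   c("oaA", "oaB", "po1"))
  expect_length(structureCodes(), 19L)
  expect_length(germlineCodes(), 12L)
  expect_identical(sum(isGermline(structureCodes())), 12L)
  # aliased counts land on the canonical rows
  s <- SlideCountSet(c(aoA = 200, po1 = 300), slideId = "s1")
  expect_equal(hitCounts(s)["oaA", 1], 200)
})

test_that("germline counts restrict the partition", {
  s <- makeSlideSet(list(c(po1 = 10, tc = 490),
                         c(tc = 300, pg = 200, ei = 50)))
  g <- germlineCounts(s)
  expect_identical(rownames(g), germlineCodes())
  expect_equal(g["po1", 1], 10)
  expect_true(all(g[, 2] == 0))
  # germline + non-germline hits partition the grid
  expect_equal(colSums(g) + colSums(hitCounts(s)[!isGermline(structureCodes()), ]),
               unname(totalPoints(s)), ignore_attr = TRUE)
})

test_that("counts tables round-trip through CSV bit-identically", {
  set.seed(21)
  vecs <- lapply(1:5, function(i) {
    v <- setNames(sample(0:80, 19, replace = TRUE), structureCodes())
    v["tc"] <- v[["tc"]] + 400L
    v
  })
  s <- makeSlideSet(vecs)
  path <- withr::local_tempfile(fileext = ".csv")
  writeCountsCSV(s, path)
  s2 <- suppressWarnings(readCountsCSV(path))
  expect_identical(hitCounts(s2), hitCounts(s))
  expect_identical(fractionEstimates(s2), fractionEstimates(s))
})

test_that("the wide-format reader normalizes to the same object", {
  df <- data.frame(slide_id = c("w1", "w2"), fish_id = c("f1", "f2"),
                   ovary = "V", position = 2,
                   po1 = c(300L, 250L), cao = c(100L, 0L),
                   aoA = c(0L, 50L), tc = c(150L, 250L),
                   total_points = c(550L, 550L))
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE)
  s <- readCountsCSV(path, format = "wide")
  expect_equal(hitCounts(s)["oaA", "w2"], 50)  # alias column resolved
  expect_equal(unname(totalPoints(s)), c(550L, 550L))
})

test_that("corrupt counts CSV errors name the offending row", {
  df <- data.frame(slide_id = "s1", fish_id = "f1", ovary = "V",
                   position = 2, structure = c("po1", "tc"),
                   hit_points = c(-5L, 505L), total_points = 500L)
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE)
  expect_error(readCountsCSV(path), "row\\(s\\) 2")
})
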