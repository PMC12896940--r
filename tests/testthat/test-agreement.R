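test_that("percentage agreement enumerates rater pairs", {
  # all three raters identical -> 100
  lab <- matrix(rep(c("po1", "cao", "tc", "po1"), 3), ncol = 3)
  expect_equal(percentAgreement(RaterReadingSet(lab)), 100)
  # pairwise-distinct labels on every point -> 0
  lab2 <- cbind(rep("po1", 6), rep("cao", 6), rep("tc", 6))
  expect_equal(percentAgreement(RaterReadingSet(lab2)), 0)
  # raters 1-2 always agree, rater 3 never: 1 of 3 pairs agree
  lab3 <- cbind(rep("po1", 10), rep("po1", 10), rep("tc", 10))
  expect_equal(percentAgreement(RaterReadingSet(lab3)), 100 / 3)
  # the strict all-agree variant is harsher
  expect_equal(percentAgreement(RaterReadingSet(lab3), allAgree = TRUE), 0)
})

test_that("Fleiss' kappa matches a hand-evaluated fixture", {
  # 5 points x 3 raters x 3 codes; hand computation:
  # P_i = (1, 1/3, 1/3, 1/3, 1), Pbar = 0.6; p = (0.4, 0.4, 0.2),
  # Pe = 0.36; kappa = 100 * (0.6 - 0.36) / 0.64 = 37.5
  lab <- rbind(c("po1", "po1", "po1"),
               c("po1", "cao", "cao"),
               c("tc",  "tc",  "cao"),
               c("po1", "po1", "tc"),
               c("cao", "cao", "cao"))
  rr <- RaterReadingSet(lab)
  expect_equal(fleissKappa(rr), 37.5)
  expect_equal(percentAgreement(rr), 60)
})

test_that("kappa handles perfect and degenerate agreement", {
  lab <- matrix(rep(c("po1", "cao", "tc", "po1"), 3), ncol = 3)
  expect_equal(fleissKappa(RaterReadingSet(lab)), 100)
  # one single code everywhere: chance agreement is 1, kappa undefined
  one <- matrix("po1", 8, 3)
  expect_warning(k <- fleissKappa(RaterReadingSet(one)),
                 class = "kappaUndefinedWarning")
  expect_true(is.na(k))
})

test_that("agreement indices are invariant to relabeling and reordering", {
  set.seed(51)
  codes <- c("po1", "cao", "vit1", "tc", "pg")
  lab <- matrix(sample(codes, 200 * 3, replace = TRUE), ncol = 3)
  rr <- RaterReadingSet(lab)
  a0 <- percentAgreement(rr); k0 <- fleissKappa(rr)
  # permute category labels
  perm <- setNames(sample(codes), codes)
  rrP <- RaterReadingSet(matrix(perm[lab], ncol = 3))
  expect_equal(percentAgreement(rrP), a0)
  expect_equal(fleissKappa(rrP), k0)
  # reorder points and raters
  rrO <- RaterReadingSet(lab[sample(nrow(lab)), sample(3)])
  expect_equal(percentAgreement(rrO), a0)
  expect_equal(fleissKappa(rrO), k0)
})

test_that("duplicating a rater never decreases percentage agreement", {
  set.seed(52)
  for (i in 1:10) {
    lab <- matrix(sample(c("po1", "cao", "tc"), 50 * 3, replace = TRUE),
                  ncol = 3)
    a <- percentAgreement(RaterReadingSet(lab))
    aDup <- percentAgreement(RaterReadingSet(cbind(lab, lab[, 1])))
    expect_gte(aDup, a)
  }
})

test_that("the reading-error index flags >3 point differences strictly", {
  fr <- matrix(0, 19, 2, dimnames = list(structureCodes(), c("r1", "r2")))
  fr["po1", ] <- c(40, 43.5); fr["tc", ] <- c(60, 56.5)
  rei <- readingErrorIndex(fr)
  expect_equal(unname(rei$per_structure_max_diff["po1"]), 3.5)
  expect_setequal(rei$flagged_structures, c("po1", "tc"))
  # exactly 3 points: not flagged ("over 3%" is strict)
  fr2 <- fr; fr2["po1", 2] <- 43; fr2["tc", 2] <- 57
  expect_length(readingErrorIndex(fr2)$flagged_structures, 0L)
  # identical estimates: no flags, all diffs zero
  fr3 <- fr[, c(1, 1)]
  rei3 <- readingErrorIndex(fr3)
  expect_true(all(rei3$per_structure_max_diff == 0))
  # mismatched slides are a cross-slide error
  expect_error(readingErrorIndex(fr, slideIds = c("s1", "s2")),
               "cross-slide")
})

test_that("agreement reports summarize over slides with undefined handling", {
  lab <- rbind(c("po1", "po1", "po1"), c("cao", "cao", "tc"))
  rep1 <- agreementReport(RaterReadingSet(lab, slideId = "s1"))
  expect_identical(rep1$n_raters, 3L)
  sm <- summarizeCalibration(list(rep1))
  expect_true(is.na(sm$sd[1]))          # single slide: sd undefined
  expect_identical(sm$n_defined[1], 1L)
  # degenerate kappa excluded with its count reported
  one <- matrix("po1", 4, 3)
  rep2 <- agreementReport(RaterReadingSet(one, slideId = "s2"))
  sm2 <- summarizeCalibration(list(rep1, rep2))
  krow <- sm2[sm2$index == "fleiss_kappa", ]
  expect_identical(krow$n_undefined, 1L)
})

test_that("rater readings round-trip through the long CSV format", {
  set.seed(53)
  lab <- matrix(sample(c("po1", "cao", "tc"), 30, replace = TRUE), ncol = 3,
                dimnames = list(NULL, c("alice", "bob", "carol")))
  df <- data.frame(slide_id = "s9",
                   point_index = rep(1:10, 3),
                   rater_id = rep(c("alice", "bob", "carol"), each = 10),
                   structure = as.vector(lab))
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE)
  rr <- readRaterCSV(path)
  expect_equal(percentAgreement(rr),
               percentAgreement(RaterReadingSet(lab)))
})
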