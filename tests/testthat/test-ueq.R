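test_that("scale scoring: midpoint, ceiling, arithmetic, missing rule", {
  map <- ueq_item_map()
  s0 <- score_ueq(rep(4, 26))
  expect_true(all(abs(as.numeric(s0[1, ])) < 1e-12))
  # ceiling: 7 on normal items, 1 on reversed
  ans <- ifelse(map$reversed[order(map$item)], 1, 7)
  s3 <- score_ueq(ans)
  expect_true(all(abs(as.numeric(s3[1, ]) - 3) < 1e-12))
  # one attractiveness item at 6 (normal polarity), rest of scale neutral
  att_items <- map$item[map$scale == "attractiveness"]
  norm_att <- att_items[!map$reversed[match(att_items, map$item)]][1]
  ans2 <- rep(4L, 26)
  ans2[norm_att] <- 6L
  expect_equal(score_ueq(ans2)$attractiveness, 2 / 6, tolerance = 1e-12)
  # a scale answered below half its items is missing
  ans3 <- rep(NA_integer_, 26)
  ans3[att_items[1]] <- 5L
  expect_true(is.na(score_ueq(ans3)$attractiveness))
  expect_error(score_ueq(c(rep(4, 25), 9)), "1..7")
})

test_that("recode is involution-consistent and permutation-invariant", {
  map <- ueq_item_map()
  set.seed(55)
  ans <- sample(1:7, 26, TRUE)
  base <- score_ueq(ans, map)
  # flip an item's polarity and its answer: contribution unchanged
  for (i in c(1, 7, 20)) {
    map2 <- map
    map2$reversed[map2$item == i] <- !map2$reversed[map2$item == i]
    ans2 <- ans
    ans2[i] <- 8 - ans2[i]
    expect_equal(score_ueq(ans2, map2), base, tolerance = 1e-12)
  }
  # item order within the map is irrelevant
  perm <- sample(26)
  expect_equal(score_ueq(ans, map[perm, ]), base, tolerance = 1e-12)
  # constant-k response: (k-4) on normal items, (4-k) on reversed
  for (k in c(1, 3, 6)) {
    sk <- score_ueq(rep(k, 26), map)
    for (sc in c("perspicuity", "novelty")) {
      items <- map$item[map$scale == sc]
      rev_frac <- mean(map$reversed[match(items, map$item)])
      expect_equal(sk[[sc]],
                   (1 - rev_frac) * (k - 4) + rev_frac * (4 - k),
                   tolerance = 1e-12)
    }
  }
})

score_and_classify_top <- function() {
  map <- ueq_item_map()
  ans <- ifelse(map$reversed[order(map$item)], 1, 7)
  classify_benchmark(score_ueq(ans), ueq_benchmark())$category[1]
}

test_that("benchmark classification respects bands and the strict tie rule", {
  bm <- data.frame(scale = "attractiveness", excellent = 2, good = 1,
                   above_average = 0, below_average = -1)
  cls <- function(v) classify_benchmark(list(attractiveness = v), bm)$category
  expect_equal(cls(3), "excellent")
  expect_equal(cls(1.5), "good")
  expect_equal(cls(1), "above average")   # exactly at a threshold: lower band
  expect_equal(cls(0.5), "above average")
  expect_equal(cls(-0.5), "below average")
  expect_equal(cls(-2), "poor")
  expect_equal(score_and_classify_top(), "excellent")
  bad <- tempfile(fileext = ".csv")
  writeLines(c("scale,excellent,good,above_average,below_average",
               "attractiveness,1,2,0,-1"), bad)
  expect_error(ueq_benchmark(bad), "decreasing")
})

test_that("group comparison reproduces the published follow-up effect sizes", {
  es <- compare_groups(study_ueq_table())
  got <- setNames(round(es$cohen_d, 2), es$scale)
  expect_equal(got[["attractiveness"]], 0.64)
  expect_equal(got[["efficiency"]], 0.20)
  expect_equal(got[["novelty"]], 0.29)
  expect_equal(got[["perspicuity"]], 0.08)
  # identical summaries give zero
  eq <- data.frame(scale = "x", mean1 = 1, sd1 = 1, n1 = 10,
                   mean2 = 1, sd2 = 1, n2 = 10)
  expect_equal(compare_groups(eq)$cohen_d, 0)
})
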