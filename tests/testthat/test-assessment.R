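test_that("combination is the maximum-severity join", {
  expect_equal(combine_categories("EN", "CR"), "CR")
  expect_equal(combine_categories("LC", "LC"), "LC")
  cats <- c("CR", "EN", "VU", "NT", "LC")
  pairs <- expand.grid(a = cats, b = cats, stringsAsFactors = FALSE)
  got <- combine_categories(pairs$a, pairs$b)
  expected <- rank_to_category(pmax(category_rank(pairs$a),
                                    category_rank(pairs$b)))
  expect_equal(got, expected)
  # commutative and idempotent on the severity lattice
  expect_equal(got, combine_categories(pairs$b, pairs$a))
  expect_equal(combine_categories(cats, cats), cats)
  # associative
  set.seed(2)
  for (rep in 1:20) {
    abc <- sample(cats, 3, replace = TRUE)
    expect_equal(
      combine_categories(combine_categories(abc[1], abc[2]), abc[3]),
      combine_categories(abc[1], combine_categories(abc[2], abc[3])))
  }
})

test_that("DD defers to the informative criterion; double DD stays DD", {
  expect_equal(combine_categories("DD", "EN"), "EN")
  expect_equal(combine_categories("VU", "DD"), "VU")
  expect_equal(combine_categories("DD", "DD"), "DD")
})

test_that("combine_assessments flags threatened taxa", {
  a <- data.frame(taxon = c("x", "y", "z"),
                  category_A = c("LC", "CR", "DD"))
  b <- data.frame(taxon = c("x", "y", "z"),
                  category_B = c("NT", "EN", "VU"))
  out <- combine_assessments(a, b)
  expect_equal(out$category_combined, c("NT", "CR", "VU"))
  expect_equal(out$threatened, c(FALSE, TRUE, TRUE))
})

test_that("validation reproduces closed-form confusion metrics", {
  # a fixture with known counts: TP=50, TN=30, FP=15, FN=5
  taxa <- sprintf("t%03d", 1:100)
  ref_t <- rep(c(TRUE, FALSE), c(55, 45))
  pred_t <- ref_t
  pred_t[which(ref_t)[1:5]] <- FALSE     # 5 false negatives
  pred_t[which(!ref_t)[1:15]] <- TRUE    # 15 false positives
  predicted <- data.frame(taxon = taxa,
                          category_combined = ifelse(pred_t, "EN", "LC"))
  reference <- data.frame(taxon = taxa,
                          category = ifelse(ref_t, "VU", "NT"))
  v <- validate_assessments(predicted, reference)
  expect_equal(c(v$TP, v$TN, v$FP, v$FN), c(50, 30, 15, 5))
  expect_equal(v$accuracy, 0.80)
  expect_equal(v$sensitivity, 50 / 55)
})

test_that("perfect agreement gives accuracy and sensitivity 1", {
  d <- data.frame(taxon = c("a", "b"), category_combined = c("CR", "LC"))
  r <- data.frame(taxon = c("a", "b"), category = c("EN", "NT"))
  v <- validate_assessments(d, r)  # same binary classes
  expect_equal(v$accuracy, 1)
  expect_equal(v$sensitivity, 1)
})

test_that("random label sets match the tally oracle and caret", {
  skip_if_not_installed("caret")
  set.seed(14)
  cats <- c("CR", "EN", "VU", "NT", "LC")
  for (rep in 1:10) {
    taxa <- sprintf("t%02d", 1:100)
    predicted <- data.frame(taxon = taxa,
                            category_combined = sample(cats, 100, TRUE))
    reference <- data.frame(taxon = taxa,
                            category = sample(cats, 100, TRUE))
    v <- validate_assessments(predicted, reference)
    pred_t <- category_rank(predicted$category_combined) >= 3
    ref_t <- category_rank(reference$category) >= 3
    tally <- oracle_tally(pred_t, ref_t)
    expect_equal(c(v$TP, v$FP, v$TN, v$FN), unname(tally))
    expect_equal(v$accuracy, (tally["TP"] + tally["TN"]) / 100,
                 ignore_attr = TRUE)
    cm <- caret::confusionMatrix(
      factor(pred_t, c(TRUE, FALSE)), factor(ref_t, c(TRUE, FALSE)),
      positive = "TRUE")
    expect_equal(v$accuracy, unname(cm$overall["Accuracy"]))
    expect_equal(v$sensitivity, unname(cm$byClass["Sensitivity"]))
  }
})

test_that("validation is order-invariant and NA-safe without threatened
           reference taxa", {
  taxa <- sprintf("t%02d", 1:40)
  predicted <- data.frame(taxon = taxa,
                          category_combined = rep(c("CR", "LC"), 20))
  reference <- data.frame(taxon = taxa, category = rep("LC", 40))
  v <- validate_assessments(predicted, reference)
  expect_true(is.na(v$sensitivity))
  shuffled <- reference[sample(40), ]
  v2 <- validate_assessments(predicted, shuffled)
  expect_equal(v2$accuracy, v$accuracy)
})

test_that("DD and unmatched taxa leave the confusion matrix", {
  predicted <- data.frame(taxon = c("a", "b", "c"),
                          category_combined = c("CR", "DD", "LC"))
  reference <- data.frame(taxon = c("a", "b", "d"),
                          category = c("CR", "EN", "LC"))
  v <- validate_assessments(predicted, reference)
  expect_equal(v$n_reference, 1)   # only "a" comparable
  expect_equal(v$n_dd_excluded, 1)
  expect_equal(v$n_unmatched, 1)
})

test_that("category summaries give percentages that sum to 100", {
  assess <- data.frame(taxon = c("a", "b", "c", "d"),
                       category_A = c("CR", "LC", "EN", "LC"),
                       category_B = c("CR", "CR", "LC", "LC"),
                       category_combined = c("CR", "CR", "EN", "LC"))
  s <- category_summaries(assess)
  expect_equal(s$overall$percent[s$overall$category == "CR"], 50)
  expect_equal(s$overall$percent[s$overall$category == "EN"], 25)
  expect_equal(sum(s$overall$percent), 100)
  for (crit in unique(s$by_criterion$criterion))
    expect_equal(sum(s$by_criterion$percent[s$by_criterion$criterion == crit]),
                 100)
})

test_that("small families are excluded from ranked group tables", {
  set.seed(6)
  n <- 50
  assess <- data.frame(taxon = sprintf("t%02d", 1:n),
                       category_A = "LC", category_B = "LC",
                       category_combined = sample(c("CR", "LC"), n, TRUE))
  taxonomy <- data.frame(taxon = assess$taxon,
                         family = rep(c("big", "small"), c(45, 5)),
                         genus = rep(c("g1", "g2"), c(25, 25)))
  s <- category_summaries(assess, taxonomy, min_n = 10)
  expect_equal(unique(s$by_family$group), "big")
  expect_setequal(unique(s$by_genus$group), c("g1", "g2"))
  for (g in unique(s$by_genus$group))
    expect_equal(sum(s$by_genus$percent[s$by_genus$group == g]), 100)
})
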