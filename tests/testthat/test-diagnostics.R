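test_that("AUC equals exhaustive pair enumeration, ties included", {
  for (seed in c(201, 202, 203, 204)) {
    tab <- random_feature_table(40, seed)
    r <- roc(tab, "score")
    expect_equal(r$auc, oracle_auc(tab$score, tab$label == "malignant"),
                 tolerance = 1e-12)
    expect_gt(r$se_auc, 0)
    expect_true(all(r$ci95 >= 0 & r$ci95 <= 1))
    # curve sensitivity is nonincreasing as the threshold rises
    expect_true(all(diff(r$curve$sensitivity) <= 0))
  }
})

test_that("AUC symmetry and monotone-transform invariance hold", {
  set.seed(205)
  tab <- data.frame(label = rep(c("benign", "malignant"), each = 25),
                    score = rnorm(50))  # continuous: tie-free
  a1 <- roc(tab, "score")$auc
  tab$score <- -tab$score
  expect_equal(roc(tab, "score")$auc, 1 - a1, tolerance = 1e-12)
  tab$score <- exp(-tab$score)  # strictly monotone of original
  expect_equal(roc(tab, "score")$auc, a1, tolerance = 1e-12)
})

test_that("AUC hits its extremes and its null", {
  tab <- data.frame(label = rep(c("benign", "malignant"), each = 10),
                    score = c(1:10, 101:110))
  expect_equal(roc(tab, "score")$auc, 1.0)
  set.seed(206)
  null_tab <- data.frame(
    label = sample(rep(c("benign", "malignant"), 1000)),
    score = rnorm(2000))
  expect_equal(roc(null_tab, "score")$auc, 0.5, tolerance = 0.05)
  expect_error(roc(data.frame(label = rep("benign", 5), score = 1:5),
                   "score"), "both classes")
})

test_that("AUC agrees with an established implementation", {
  tab <- random_feature_table(60, 207)
  r <- roc(tab, "score")
  ref <- suppressMessages(pROC::auc(pROC::roc(
    response = tab$label, predictor = tab$score,
    levels = c("benign", "malignant"), direction = "<")))
  expect_equal(r$auc, as.numeric(ref), tolerance = 1e-12)
})

test_that("auto-flip makes benign-coded scores explicit", {
  set.seed(208)
  tab <- data.frame(label = rep(c("benign", "malignant"), each = 30),
                    score = c(rnorm(30, 2), rnorm(30, 0)))  # benign higher
  r <- roc(tab, "score", orientation_policy = "auto_flip")
  expect_true(r$flipped)
  expect_gte(r$auc, 0.5)
  r_as <- roc(tab, "score", orientation_policy = "as_given")
  expect_equal(r$auc, 1 - r_as$auc, tolerance = 1e-12)
})

test_that("published 2x2 tables reproduce their statistics", {
  # coagulation necrosis sign: 1/71 benign vs 6/61 malignant
  cns <- two_by_two_test(1, 71, 6, 61)
  expect_equal(round(cns$p_value, 3), 0.031)
  orc <- oracle_chisq(matrix(c(1, 70, 6, 55), 2, 2, byrow = TRUE))
  expect_equal(cns$statistic, orc$statistic, tolerance = 1e-9)
  expect_equal(cns$p_value, orc$p_value, tolerance = 1e-9)
  # combined PET/CT criterion counts
  comb <- two_by_two_test(15, 51, 40, 52)
  expect_equal(round(comb$pct_benign, 1), 29.4)
  expect_equal(round(comb$pct_malignant, 1), 76.9)
  # identical distributions give chi-squared zero, p = 1
  eq <- two_by_two_test(10, 40, 10, 40)
  expect_equal(eq$statistic, 0, tolerance = 1e-12)
  expect_equal(eq$p_value, 1)
})

test_that("summarize_table routes types correctly and matches oracles", {
  set.seed(209)
  tab <- data.frame(
    label = rep(c("benign", "malignant"), c(30, 25)),
    size = c(rnorm(30, 11, 4), rnorm(25, 16, 6)),
    marker = c(runif(30) < 0.2, runif(25) < 0.6),
    constant = rep(TRUE, 55)
  )
  s <- summarize_table(tab, c("size", "marker", "constant"))
  expect_equal(s$type, c("continuous", "binary", "binary"))
  expect_equal(s$mean_benign[1], mean(tab$size[1:30]))
  expect_equal(s$pct_malignant[2], 100 * mean(tab$marker[31:55]))
  # binary p matches the textbook chi-squared oracle
  t2 <- matrix(c(sum(tab$marker[1:30]), 30 - sum(tab$marker[1:30]),
                 sum(tab$marker[31:55]), 25 - sum(tab$marker[31:55])),
               2, 2, byrow = TRUE)
  expect_equal(s$p_value[2], oracle_chisq(t2)$p_value, tolerance = 1e-9)
  # constant feature: test undefined
  expect_true(is.na(s$p_value[3]))
  expect_error(summarize_table(tab, "nope"), "unknown feature")
})

test_that("pooled t-test agrees with a permutation oracle", {
  set.seed(210)
  tab <- data.frame(label = rep(c("benign", "malignant"), c(20, 20)),
                    v = c(rnorm(20, 0), rnorm(20, 0.3)))
  p_t <- summarize_table(tab, "v")$p_value
  diff_obs <- abs(mean(tab$v[21:40]) - mean(tab$v[1:20]))
  perm <- replicate(4000, {
    sh <- sample(tab$v)
    abs(mean(sh[21:40]) - mean(sh[1:20]))
  })
  p_perm <- mean(perm >= diff_obs)
  expect_lt(abs(p_t - p_perm), 0.05)
})

test_that("cutoff sensitivity/specificity match hand counts", {
  tab <- random_feature_table(35, 211)
  thr <- median(tab$score)
  got <- cutoff_performance(tab, "score", thr, "ge")
  want <- oracle_confusion(tab$score, tab$label == "malignant", thr)
  expect_equal(got$sensitivity, want$sensitivity)
  expect_equal(got$specificity, want$specificity)
  # extremal thresholds
  lo <- cutoff_performance(tab, "score", min(tab$score) - 1, "ge")
  expect_equal(lo$sensitivity, 100)
  expect_equal(lo$specificity, 0)
  hi <- cutoff_performance(tab, "score", max(tab$score) + 1, "ge")
  expect_equal(hi$sensitivity, 0)
  expect_equal(hi$specificity, 100)
})

test_that("combined criterion boundaries are >= SUV and < HU exactly", {
  rec <- data.frame(suv_max = c(2.5, 2.49, 10), max_hu = c(69, 0, 70))
  expect_equal(combined_criterion(rec), c(TRUE, FALSE, FALSE))
  expect_error(combined_criterion(data.frame(suv_max = 1)),
               "missing field 'max_hu'")
  expect_error(combined_criterion(data.frame(max_hu = 1)),
               "missing field 'suv_max'")
})

test_that("the stump split equals an exhaustive threshold search", {
  for (seed in c(212, 213, 214)) {
    tab <- random_feature_table(50, seed)
    st <- cart_stump(tab, "score")
    orc <- oracle_stump(tab$score, tab$label == "malignant")
    expect_equal(st$threshold, orc$threshold)
    expect_equal(st$impurity_decrease, orc$impurity_decrease,
                 tolerance = 1e-12)
    expect_gte(st$relative_risk, 1)
    expect_true(st$threshold >= min(tab$score) &&
                  st$threshold <= max(tab$score))
  }
})

test_that("stump extremes: perfect separation and constant features", {
  tab <- data.frame(label = rep(c("benign", "malignant"), each = 12),
                    v = c(1:12, 101:112))
  st <- cart_stump(tab, "v")
  orc <- oracle_stump(tab$v, tab$label == "malignant")
  expect_equal(st$impurity_decrease, orc$parent)  # all impurity removed
  expect_true(is.finite(st$relative_risk))        # 0.5-count guard
  cst <- cart_stump(data.frame(label = tab$label, v = rep(7, 24)), "v")
  expect_true(is.na(cst$threshold))
  expect_equal(cst$impurity_decrease, 0)
})

test_that("stump gains vanish on label-shuffled data", {
  set.seed(215)
  tab <- data.frame(label = rep(c("benign", "malignant"), each = 100),
                    v = c(rnorm(100, 0), rnorm(100, 1.5)))
  observed <- cart_stump(tab, "v")$impurity_decrease
  null_gain <- replicate(40, {
    sh <- tab
    sh$label <- sample(sh$label)
    cart_stump(sh, "v")$impurity_decrease
  })
  expect_gt(observed, 10 * mean(null_gain))
})

test_that("stump threshold agrees with rpart's root split", {
  set.seed(216)
  tab <- data.frame(label = rep(c("benign", "malignant"), c(40, 35)),
                    v = c(rnorm(40, 10, 3), rnorm(35, 14, 3)))
  st <- cart_stump(tab, "v")
  fit <- rpart::rpart(factor(label) ~ v, tab, method = "class",
                      control = rpart::rpart.control(
                        maxdepth = 1, cp = 0, minsplit = 2,
                        minbucket = 1, xval = 0))
  expect_equal(st$threshold, unname(fit$splits[1, "index"]),
               tolerance = 1e-9)
})

test_that("the Youden point maximizes Se + Sp over all thresholds", {
  tab <- random_feature_table(45, 217)
  r <- roc(tab, "score")
  yj <- youden(r)
  best <- max(vapply(unique(tab$score), function(t) {
    cp <- cutoff_performance(tab, "score", t, "ge")
    cp$sensitivity + cp$specificity
  }, 1))
  expect_equal(yj$sensitivity + yj$specificity, best)
})

test_that("the panel is internally consistent with its parts", {
  co <- generate_cohort(n_benign = 40, n_malignant = 40, seed = 218,
                        with_images = FALSE)
  tab <- co$records
  pan <- evaluate_panel(tab, list(
    list(name = "suv5", feature = "suv_max", threshold = 5),
    list(name = "combined",
         all_of = list(list(feature = "suv_max", threshold = 2.5),
                       list(feature = "max_hu", threshold = 70,
                            direction = "lt"))),
    list(name = "echo", feature = "heterogeneous_echo"),
    list(name = "suv_cont", feature = "suv_max", continuous = TRUE)
  ))
  expect_equal(nrow(pan), 4)
  # dichotomized row equals the direct cutoff computation
  cp <- cutoff_performance(tab, "suv_max", 5, "ge")
  expect_equal(pan$sensitivity[1], cp$sensitivity)
  expect_equal(pan$specificity[1], cp$specificity)
  # binary-classifier identity: AUC = (Se + Sp) / 2
  expect_equal(pan$auc[1], (cp$sensitivity + cp$specificity) / 200,
               tolerance = 1e-12)
  # AND-combination is never more sensitive than either arm
  suv_arm <- cutoff_performance(tab, "suv_max", 2.5, "ge")$sensitivity
  hu_arm <- cutoff_performance(tab, "max_hu", 70, "lt")$sensitivity
  expect_lte(pan$sensitivity[2], min(suv_arm, hu_arm))
  # combined row equals combined_criterion counts
  ind <- combined_criterion(tab)
  mal <- tab$label == "malignant"
  expect_equal(pan$sensitivity[2], 100 * mean(ind[mal]))
  # continuous row equals roc() directly
  r <- roc(tab, "suv_max", orientation_policy = "auto_flip")
  expect_equal(pan$auc[4], r$auc)
  expect_error(evaluate_panel(tab, list(list(name = "x", feature = "zz"))),
               "available")
})
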