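roi <- function(values, spacing = 1) {
  structure(list(values = values, n = length(values), spacing = spacing,
                 excluded = NULL), class = "roi_pixels")
}

test_that("every first-order feature matches the explicit-loop oracle", {
  for (seed in c(101, 102, 103)) {
    set.seed(seed)
    v <- round(rnorm(500, 60, 35))  # integer HU with ties
    fo <- first_order(roi(v))
    or <- oracle_moments(v)
    expect_equal(fo$mean_hu, or$mean, tolerance = 1e-9)
    expect_equal(fo$sd_hu, or$sd, tolerance = 1e-9)
    expect_equal(fo$skewness, or$skewness, tolerance = 1e-9)
    expect_equal(fo$kurtosis, or$kurtosis, tolerance = 1e-9)
    expect_equal(fo$kurtosis_excess, or$kurtosis - 3, tolerance = 1e-9)
    expect_equal(fo$entropy_bits, oracle_entropy_bits(v), tolerance = 1e-9)
    expect_equal(fo$normalized_sd, log(or$sd) / log(length(v)),
                 tolerance = 1e-9)
    for (pr in c(0.10, 0.25, 0.50, 0.75, 0.90, 0.95)) {
      expect_equal(unname(fo$percentiles[paste0("p", pr * 100)]),
                   oracle_percentile(v, pr), tolerance = 1e-9)
    }
  }
})

test_that("hand-calculable value sets give their known statistics", {
  fo <- first_order(roi(rep(c(-1, 1), 10)))
  expect_equal(fo$skewness, 0)
  expect_equal(fo$kurtosis, 1)
  expect_equal(fo$kurtosis_excess, -2)
  fo2 <- first_order(roi(c(0, 0, 0, 1)))
  expect_equal(fo2$skewness, 2 / sqrt(3), tolerance = 1e-9)  # = 1.1547
})

test_that("a constant ROI takes the degenerate path deliberately", {
  fo <- first_order(roi(rep(42, 25)))
  expect_equal(fo$mean_hu, 42)
  expect_equal(fo$sd_hu, 0)
  expect_equal(fo$entropy_bits, 0)
  expect_true(is.na(fo$skewness))
  expect_true(is.na(fo$kurtosis))
  expect_true(is.na(fo$normalized_sd))
  expect_equal(unname(fo$percentiles["p50"]), 42)
})

test_that("normalized SD identities and preconditions hold", {
  expect_equal(normalized_sd(10, 100), 0.5)
  expect_equal(normalized_sd(1, 37), 0)
  expect_true(is.na(normalized_sd(0, 10)))
  expect_true(is.na(normalized_sd(-3, 10)))
  expect_error(normalized_sd(10, 1), "n must be")
  # strictly increasing in sd (sd > 1), strictly decreasing in n
  sds <- c(1.5, 2, 5, 20)
  expect_true(all(diff(vapply(sds, normalized_sd, 1, n = 50)) > 0))
  ns <- c(10, 50, 200, 1000)
  expect_true(all(diff(vapply(ns, function(n) normalized_sd(7, n), 1)) < 0))
})

test_that("entropy obeys its bounds and closed forms", {
  # one occupied bin <-> zero entropy
  expect_equal(first_order(roi(rep(5.2, 9)))$entropy_bits, 0)
  # uniform occupancy over k bins -> exactly log2(k)
  for (k in c(2, 8, 32)) {
    v <- rep(seq(0.5, k - 0.5), each = 7)
    expect_equal(first_order(roi(v))$entropy_bits, log2(k))
  }
  # never exceeds log2(n)
  set.seed(104)
  for (i in 1:5) {
    v <- rnorm(50, 0, 200)
    expect_lte(first_order(roi(v))$entropy_bits, log2(50))
  }
  # wider bins can only lose resolution, never gain entropy
  set.seed(105)
  v <- rnorm(300, 60, 40)
  e1 <- first_order(roi(v), bin_spec(1))$entropy_bits
  e8 <- first_order(roi(v), bin_spec(8))$entropy_bits
  expect_lte(e8, e1)
})

test_that("percentiles are monotone and order-free", {
  set.seed(106)
  v <- rnorm(101, 50, 30)
  fo <- first_order(roi(v))
  expect_true(all(diff(fo$percentiles) >= 0))
  fo2 <- first_order(roi(sample(v)))
  expect_equal(fo$percentiles, fo2$percentiles)
  expect_equal(unname(fo$percentiles["p50"]), median(v))
})

test_that("skewness/kurtosis respond correctly to affine maps", {
  set.seed(107)
  v <- rgamma(400, 2, 0.1)
  fo <- first_order(roi(v))
  fo_aff <- first_order(roi(3.7 * v + 100))
  expect_equal(fo_aff$skewness, fo$skewness, tolerance = 1e-9)
  expect_equal(fo_aff$kurtosis, fo$kurtosis, tolerance = 1e-9)
  fo_neg <- first_order(roi(-v))
  expect_equal(fo_neg$skewness, -fo$skewness, tolerance = 1e-9)
  expect_equal(fo_neg$kurtosis, fo$kurtosis, tolerance = 1e-9)
})

test_that("exclusion rules drop exactly the offending pixels", {
  img <- matrix(c(10, 20, 30, 900, 50, -10), 2, 3)
  msk <- matrix(c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE), 2, 3)
  px <- extract_pixels(img, msk, exclusion_rules(300))
  expect_equal(px$n, 4)
  expect_false(900 %in% px$values)
  expect_equal(nrow(px$excluded), 1)
  # no exclusions: identity, raster (storage) order
  px0 <- extract_pixels(img, msk, exclusion_rules(1000))
  expect_equal(px0$values, img[msk])
  expect_equal(px0$n, 5)
  # the two empty conditions are distinct errors
  expect_error(extract_pixels(img, matrix(FALSE, 2, 3)), "mask is empty")
  expect_error(extract_pixels(img, msk, exclusion_rules(-2000)),
               "exclusion rules")
  expect_error(extract_pixels(img, matrix(TRUE, 3, 2)), "dimensions")
})

test_that("excluded calcification pixels match the generator's truth", {
  p <- default_profiles()$benign
  p$calcification_prob <- 1
  set.seed(108)
  nd <- generate_node(p)
  px <- extract_pixels(nd$image, nd$mask, exclusion_rules(300))
  got <- px$excluded[order(px$excluded[, 1], px$excluded[, 2]), ]
  want <- nd$truth$calcification
  want <- want[order(want[, 1], want[, 2]), ]
  expect_equal(unname(got), unname(want))
})

test_that("extract_all yields one stable, deterministic row per node", {
  co <- generate_cohort(n_benign = 4, n_malignant = 3, seed = 109)
  f1 <- extract_all(co)
  f2 <- extract_all(co)
  expect_equal(nrow(f1), 7)
  expect_identical(f1, f2)
  expect_equal(f1$node_id, co$records$node_id)
  expect_true(all(c("normalized_sd", "entropy_bits", "circularity")
                  %in% names(f1)))
  expect_equal(attr(f1, "n_failed"), 0)
})

test_that("size contrast drives normalized SD below benign levels", {
  # larger malignant ROIs mean larger N, hence smaller ln(SD)/ln(N)
  co <- generate_cohort(n_benign = 30, n_malignant = 30, seed = 110)
  f <- extract_all(co)
  nsd_b <- mean(f$normalized_sd[f$label == "benign"])
  nsd_m <- mean(f$normalized_sd[f$label == "malignant"])
  expect_gt(nsd_b, nsd_m)
})
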