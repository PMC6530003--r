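#' ROI exclusion rules
#'
#' Pixels with attenuation above `calcification_hu_threshold` are dropped
#' from the ROI before any histogram statistic is computed (calcifications
#' would otherwise dominate the upper tail); an optional same-shape binary
#' `exclusion_mask` removes further pixels (vessels, beam-hardening
#' artifacts). The post-exclusion pixel count is the `N` used by the
#' size-normalized SD.
#'
#' @param calcification_hu_threshold HU; pixels strictly above are excluded.
#' @param exclusion_mask optional logical matrix, same shape as the image;
#'   `TRUE` pixels are excluded.
#' @return object of class `exclusion_rules`.
#' @export
exclusion_rules <- function(calcification_hu_threshold = 300,
                            exclusion_mask = NULL) {
  stopifnot(is.finite(calcification_hu_threshold))
  structure(list(calcification_hu_threshold = calcification_hu_threshold,
                 exclusion_mask = exclusion_mask),
            class = "exclusion_rules")
}

#' Extract ROI pixel values after exclusion rules
#'
#' @param image numeric matrix of HU values.
#' @param mask logical (or 0/1) matrix, same shape; the ROI.
#' @param rules an [exclusion_rules()] object.
#' @param spacing pixel spacing in mm, attached to the result.
#' @return object of class `roi_pixels`: `values` (HU at retained pixels,
#'   in matrix storage order), `n`, `spacing`, and `excluded` (n x 2 matrix
#'   of (row, col) indices removed by the rules).
#' @export
extract_pixels <- function(image, mask, rules = exclusion_rules(),
                           spacing = 1) {
  mask <- mask > 0
  if (!all(dim(image) == dim(mask))) {
    stop("image and mask must have identical dimensions")
  }
  if (!any(mask)) stop("mask is empty: no ROI pixels")
  keep <- mask & image <= rules$calcification_hu_threshold
  if (!is.null(rules$exclusion_mask)) {
    if (!all(dim(rules$exclusion_mask) == dim(mask))) {
      stop("exclusion_mask must match the image dimensions")
    }
    keep <- keep & !(rules$exclusion_mask > 0)
  }
  if (!any(keep)) {
    stop("all ROI pixels removed by exclusion rules (mask was nonempty)")
  }
  structure(list(
    values = image[keep],
    n = sum(keep),
    spacing = spacing,
    excluded = which(mask & !keep, arr.ind = TRUE)
  ), class = "roi_pixels")
}

#' Histogram bin specification
#'
#' Bins for the entropy histogram. Breaks are aligned to multiples of
#' `width` (HU), so the binning is independent of the ROI's exact minimum.
#'
#' @param width bin width in HU (> 0). The 1-HU default resolves every
#'   integer attenuation level a CT reconstruction can produce.
#' @return object of class `bin_spec`.
#' @export
bin_spec <- function(width = 1) {
  stopifnot(is.numeric(width), length(width) == 1, width > 0)
  structure(list(width = width), class = "bin_spec")
}

bin_counts <- function(values, binning) {
  idx <- floor(values / binning$width)
  table(idx)
}

#' First-order histogram features of an ROI
#'
#' Computes the intensity-histogram feature set: mean attenuation, SD,
#' size-normalized SD ln(SD)/ln(N), skewness m3/sigma^3, kurtosis
#' m4/sigma^4 (and its excess form, minus 3), Shannon entropy in bits over
#' occupied histogram bins, and the 10/25/50/75/90/95th percentiles by
#' linear interpolation.
#'
#' Central moments always use the population convention (divisor N), as in
#' the expectation-form definitions of skewness and kurtosis;
#' `sd_divisor = "sample"` switches only the reported SD (and hence the
#' normalized SD) to the n-1 divisor.
#'
#' A constant ROI has sigma = 0: skewness, kurtosis and normalized SD are
#' then undefined and reported as `NA` (a deliberate sentinel, not an
#' arithmetic accident); entropy is 0 and mean/percentiles equal the
#' constant.
#'
#' @param pixels an [extract_pixels()] result (or any object with
#'   `values`/`n`).
#' @param binning a [bin_spec()]; entropy's histogram resolution.
#' @param sd_divisor `"population"` (N, default) or `"sample"` (N-1).
#' @return object of class `first_order_features`: `mean_hu`, `sd_hu`,
#'   `normalized_sd`, `skewness`, `kurtosis`, `kurtosis_excess`,
#'   `entropy_bits`, `percentiles` (named, HU), `n`, and the binning /
#'   divisor metadata.
#' @export
first_order <- function(pixels, binning = bin_spec(),
                        sd_divisor = c("population", "sample")) {
  sd_divisor <- match.arg(sd_divisor)
  v <- pixels$values
  n <- length(v)
  stopifnot(n >= 1, n == pixels$n)
  mu <- mean(v)
  pr <- c(10, 25, 50, 75, 90, 95)
  pct <- quantile(v, pr / 100, type = 7, names = FALSE)
  names(pct) <- paste0("p", pr)

  cnt <- as.numeric(bin_counts(v, binning))
  p <- cnt / n
  entropy <- -sum(p * log2(p))

  if (n < 2) {
    sdv <- skw <- krt <- nsd <- NA_real_
  } else {
    m2 <- mean((v - mu)^2)
    sig <- sqrt(m2)
    sdv <- if (sd_divisor == "sample") sqrt(m2 * n / (n - 1)) else sig
    if (sig == 0) {
      skw <- krt <- nsd <- NA_real_
    } else {
      skw <- mean((v - mu)^3) / sig^3
      krt <- mean((v - mu)^4) / sig^4
      nsd <- normalized_sd(sdv, n)
    }
  }
  structure(list(
    mean_hu = mu, sd_hu = sdv, normalized_sd = nsd,
    skewness = skw, kurtosis = krt,
    kurtosis_excess = if (is.na(krt)) NA_real_ else krt - 3,
    entropy_bits = entropy,
    percentiles = pct,
    n = n,
    bin_width = binning$width,
    sd_divisor = sd_divisor
  ), class = "first_order_features")
}

#' Size-normalized standard deviation
#'
#' nSD = ln(SD) / ln(N), where N is the post-exclusion ROI pixel count.
#' Dividing by ln(N) removes the lesion-size dependence of the raw SD in
#' small ROIs. SD = 1 gives exactly 0; SD <= 0 is undefined and returns
#' the `NA` sentinel.
#'
#' @param sd ROI standard deviation, HU.
#' @param n ROI pixel count; must be >= 2 (ln(1) = 0 would divide by zero).
#' @return dimensionless scalar, or `NA` when SD <= 0.
#' @export
normalized_sd <- function(sd, n) {
  if (!is.numeric(n) || n < 2) stop("n must be >= 2 (ln(n) > 0 required)")
  if (!is.finite(sd) || sd <= 0) return(NA_real_)
  log(sd) / log(n)
}
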