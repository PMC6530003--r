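#' Construct a lymph-node class profile
#'
#' A class profile bundles every generative parameter for one pathology
#' class (benign or malignant): nodal geometry, CT attenuation texture,
#' FDG-PET uptake, and the prevalences of the categorical EBUS findings.
#' Continuous mean/SD pairs are interpreted as the *observed* cohort
#' moments; the sampler moment-matches the underlying truncated normals so
#' simulated cohorts recover them (see [match_tnorm()]).
#'
#' @param label `"benign"` or `"malignant"`.
#' @param short_axis_mean,short_axis_sd short-axis diameter, mm.
#' @param axis_ratio_mean mean long/short axis ratio (>= 1).
#' @param hu_mean,hu_sd within-ROI pixel attenuation, HU: mean level and
#'   pixel-to-pixel SD of the base texture field.
#' @param heterogeneity weight in \[0, 1\] of a spatially correlated low-HU
#'   component emulating heterogeneous echotexture / necrosis.
#' @param calcification_prob per-node probability of an embedded high-HU
#'   calcification speck.
#' @param max_hu_mean,max_hu_sd maximal nodal HU on the non-enhanced
#'   attenuation-correction CT (the PET/CT criterion input).
#' @param suvmax_mean,suvmax_sd SUVmax distribution (SUV units).
#' @param suvpeak_ratio SUVpeak / SUVmax, fixed per profile, in (0, 1].
#' @param ebus_probs named list of Bernoulli prevalences for the EBUS
#'   categorical findings: `round_shape`, `distinct_margin`,
#'   `heterogeneous_echo`, `chs_present`, `cns_present`. (Size >= 1 cm is
#'   not a free probability: it is derived from the drawn short axis.)
#' @return object of class `class_profile`.
#' @seealso [default_profiles()] for the study-parameterized defaults.
#' @export
class_profile <- function(label,
                          short_axis_mean, short_axis_sd,
                          axis_ratio_mean,
                          hu_mean, hu_sd,
                          heterogeneity,
                          calcification_prob,
                          max_hu_mean, max_hu_sd,
                          suvmax_mean, suvmax_sd,
                          suvpeak_ratio,
                          ebus_probs) {
  label <- match.arg(label, c("benign", "malignant"))
  need <- c("round_shape", "distinct_margin", "heterogeneous_echo",
            "chs_present", "cns_present")
  if (!all(need %in% names(ebus_probs))) {
    stop("ebus_probs must name: ", paste(need, collapse = ", "))
  }
  p <- unlist(ebus_probs[need])
  stopifnot(
    short_axis_mean > 0, short_axis_sd > 0,
    axis_ratio_mean >= 1,
    hu_sd > 0, suvmax_sd > 0, max_hu_sd > 0,
    heterogeneity >= 0, heterogeneity <= 1,
    calcification_prob >= 0, calcification_prob <= 1,
    suvpeak_ratio > 0, suvpeak_ratio <= 1,
    all(p >= 0), all(p <= 1)
  )
  structure(list(
    label = label,
    short_axis_mean = short_axis_mean, short_axis_sd = short_axis_sd,
    axis_ratio_mean = axis_ratio_mean,
    hu_mean = hu_mean, hu_sd = hu_sd,
    heterogeneity = heterogeneity,
    calcification_prob = calcification_prob,
    max_hu_mean = max_hu_mean, max_hu_sd = max_hu_sd,
    suvmax_mean = suvmax_mean, suvmax_sd = suvmax_sd,
    suvpeak_ratio = suvpeak_ratio,
    ebus_probs = as.list(p)
  ), class = "class_profile")
}

#' Default benign and malignant profiles
#'
#' Continuous parameters equal the published cohort summaries (short axis
#' 11.2 +/- 4.2 mm benign vs 15.7 +/- 6.3 mm malignant; SUVmax 3.4 +/- 2.4
#' vs 6.3 +/- 3.8; within-ROI mean HU 69.6 vs 68.3 with pixel SD 43.2 vs
#' 38.0; maximal non-enhanced HU 119.1 +/- 283.5 vs 80.4 +/- 147.3), the
#' axis ratio is the ratio of the published long- to short-axis means, and
#' the EBUS prevalences equal the published counts (e.g. malignant
#' coagulation necrosis sign 6/61). The image heterogeneity weight mirrors
#' the heterogeneous-echogenicity prevalence of each class; the
#' calcification probabilities are package defaults (granulomatous benign
#' nodes calcify more often than metastatic ones).
#'
#' @return named list with elements `benign` and `malignant`, each a
#'   [class_profile()].
#' @export
default_profiles <- function() {
  benign <- class_profile(
    label = "benign",
    short_axis_mean = 11.2, short_axis_sd = 4.2,
    axis_ratio_mean = 16.2 / 11.2,
    hu_mean = 69.6, hu_sd = 43.2,
    heterogeneity = 8 / 71,
    calcification_prob = 0.10,
    max_hu_mean = 119.1, max_hu_sd = 283.5,
    suvmax_mean = 3.4, suvmax_sd = 2.4,
    suvpeak_ratio = 0.82,
    ebus_probs = list(
      round_shape = 28 / 71,
      distinct_margin = 67 / 71,
      heterogeneous_echo = 8 / 71,
      chs_present = 48 / 71,
      cns_present = 1 / 71
    )
  )
  malignant <- class_profile(
    label = "malignant",
    short_axis_mean = 15.7, short_axis_sd = 6.3,
    axis_ratio_mean = 22.2 / 15.7,
    hu_mean = 68.3, hu_sd = 38.0,
    heterogeneity = 23 / 61,
    calcification_prob = 0.04,
    max_hu_mean = 80.4, max_hu_sd = 147.3,
    suvmax_mean = 6.3, suvmax_sd = 3.8,
    suvpeak_ratio = 0.82,
    ebus_probs = list(
      round_shape = 36 / 61,
      distinct_margin = 60 / 61,
      heterogeneous_echo = 23 / 61,
      chs_present = 32 / 61,
      cns_present = 6 / 61
    )
  )
  list(benign = benign, malignant = malignant)
}

#' @export
print.class_profile <- function(x, ...) {
  cat("<class_profile:", x$label, ">\n")
  cat(sprintf("  short axis %.1f +/- %.1f mm (ratio %.2f), HU %.1f +/- %.1f\n",
              x$short_axis_mean, x$short_axis_sd, x$axis_ratio_mean,
              x$hu_mean, x$hu_sd))
  cat(sprintf("  SUVmax %.1f +/- %.1f (peak ratio %.2f), heterogeneity %.2f, calcif. p %.2f\n",
              x$suvmax_mean, x$suvmax_sd, x$suvpeak_ratio,
              x$heterogeneity, x$calcification_prob))
  cat("  EBUS prevalences:",
      paste(sprintf("%s=%.3f", names(x$ebus_probs), unlist(x$ebus_probs)),
            collapse = ", "), "\n")
  invisible(x)
}
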