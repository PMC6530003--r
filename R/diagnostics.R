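check_feature_table <- function(table) {
  stopifnot(is.data.frame(table), "label" %in% names(table))
  if (!all(table$label %in% c("benign", "malignant"))) {
    stop("label must be 'benign' or 'malignant'")
  }
  if ("node_id" %in% names(table) && anyDuplicated(table$node_id)) {
    stop("duplicated node_id in feature table")
  }
  invisible(table)
}

#' Pearson chi-squared comparison of a 2x2 prevalence table
#'
#' Builds the benign/malignant 2x2 from positive counts and class sizes
#' and tests it with Pearson's chi-squared *without* continuity
#' correction (the convention that reproduces the published p-values;
#' Yates' correction is deliberately off). Percentages are carried at full
#' precision; rendering rounds to one decimal.
#'
#' @param pos_benign,n_benign positives and class size among benign nodes.
#' @param pos_malignant,n_malignant same for malignant nodes.
#' @param fisher use Fisher's exact test instead (for sparse tables).
#' @return list: `pct_benign`, `pct_malignant` (percent), `statistic`,
#'   `p_value`, `test`.
#' @export
two_by_two_test <- function(pos_benign, n_benign, pos_malignant,
                            n_malignant, fisher = FALSE) {
  stopifnot(pos_benign <= n_benign, pos_malignant <= n_malignant,
            pos_benign >= 0, pos_malignant >= 0)
  tab <- matrix(c(pos_benign, n_benign - pos_benign,
                  pos_malignant, n_malignant - pos_malignant),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("benign", "malignant"),
                                c("positive", "negative")))
  if (fisher) {
    ht <- fisher.test(tab)
    stat <- NA_real_
    test <- "fisher"
  } else {
    ht <- suppressWarnings(chisq.test(tab, correct = FALSE))
    stat <- unname(ht$statistic)
    test <- "chisq"
  }
  list(pct_benign = 100 * pos_benign / n_benign,
       pct_malignant = 100 * pos_malignant / n_malignant,
       statistic = stat, p_value = ht$p.value, test = test)
}

#' Per-feature group summaries and tests
#'
#' For each requested feature: continuous features get per-class
#' mean +/- SD and a two-sample t-test (pooled-variance Student's t by
#' default); logical features get per-class count (%) and Pearson's
#' chi-squared without continuity correction. A feature constant across
#' all nodes yields `NA` statistics (test undefined).
#'
#' @param table data.frame with a `label` column (benign/malignant) and
#'   feature columns.
#' @param features character vector of columns to summarize; default all
#'   numeric/logical columns except identifiers.
#' @param welch use Welch's t-test instead of pooled-variance Student's t.
#' @return data.frame, one row per feature: type, per-class n, mean/sd or
#'   count/pct, statistic, `p_value`.
#' @export
summarize_table <- function(table, features = NULL, welch = FALSE) {
  check_feature_table(table)
  if (is.null(features)) {
    features <- setdiff(names(table)[vapply(table, function(x)
      is.numeric(x) || is.logical(x), logical(1))], c("node_id"))
  }
  missing <- setdiff(features, names(table))
  if (length(missing)) {
    stop("unknown feature(s): ", paste(missing, collapse = ", "))
  }
  is_b <- table$label == "benign"
  rows <- lapply(features, function(f) {
    x <- table[[f]]
    out <- data.frame(feature = f, type = NA_character_,
                      n_benign = sum(is_b & !is.na(x)),
                      n_malignant = sum(!is_b & !is.na(x)),
                      mean_benign = NA_real_, sd_benign = NA_real_,
                      mean_malignant = NA_real_, sd_malignant = NA_real_,
                      count_benign = NA_real_, pct_benign = NA_real_,
                      count_malignant = NA_real_, pct_malignant = NA_real_,
                      statistic = NA_real_, p_value = NA_real_,
                      stringsAsFactors = FALSE)
    if (is.logical(x)) {
      out$type <- "binary"
      out$count_benign <- sum(x[is_b], na.rm = TRUE)
      out$count_malignant <- sum(x[!is_b], na.rm = TRUE)
      tt <- tryCatch(
        two_by_two_test(out$count_benign, out$n_benign,
                        out$count_malignant, out$n_malignant),
        error = function(e) NULL)
      if (length(unique(x[!is.na(x)])) > 1 && !is.null(tt)) {
        out$statistic <- tt$statistic
        out$p_value <- tt$p_value
      }
      out$pct_benign <- 100 * out$count_benign / out$n_benign
      out$pct_malignant <- 100 * out$count_malignant / out$n_malignant
    } else {
      out$type <- "continuous"
      xb <- x[is_b]; xm <- x[!is_b]
      out$mean_benign <- mean(xb, na.rm = TRUE)
      out$sd_benign <- sd(xb, na.rm = TRUE)
      out$mean_malignant <- mean(xm, na.rm = TRUE)
      out$sd_malignant <- sd(xm, na.rm = TRUE)
      if (length(unique(x[!is.na(x)])) > 1 &&
          out$n_benign >= 2 && out$n_malignant >= 2) {
        ht <- t.test(xm, xb, var.equal = !welch)
        out$statistic <- unname(ht$statistic)
        out$p_value <- ht$p.value
      }
    }
    out
  })
  do.call(rbind, rows)
}

#' ROC curve and AUC with Hanley-McNeil standard error
#'
#' AUC is the Mann-Whitney probability that a random positive-class score
#' exceeds a random negative-class score, with half credit for ties
#' (computed from midranks). SE follows Hanley & McNeil; the 95% CI is
#' AUC +/- 1.96 SE clipped to \[0, 1\]. With
#' `orientation_policy = "auto_flip"`, a score that runs the "wrong way"
#' (AUC < 0.5 as given) is negated and the flip is recorded — this makes
#' benign-coded analyses (e.g. normalized SD, which is *lower* in
#' malignant nodes) explicit rather than silent.
#'
#' @param table feature table with a `label` column.
#' @param feature numeric score column name.
#' @param positive_class class treated as positive (default malignant).
#' @param orientation_policy `"as_given"` or `"auto_flip"`.
#' @return object of class `roc_result`: `feature`, `positive_class`,
#'   `flipped`, `auc`, `se_auc`, `ci95`, `n_pos`, `n_neg`, and `curve`
#'   (data.frame threshold/sensitivity/specificity for the rule
#'   "score >= threshold is positive", on the possibly flipped score).
#' @export
roc <- function(table, feature,
                positive_class = c("malignant", "benign"),
                orientation_policy = c("as_given", "auto_flip")) {
  check_feature_table(table)
  positive_class <- match.arg(positive_class)
  orientation_policy <- match.arg(orientation_policy)
  if (!feature %in% names(table)) stop("unknown feature: ", feature)
  x <- as.numeric(table[[feature]])
  pos <- table$label == positive_class
  keep <- !is.na(x)
  x <- x[keep]; pos <- pos[keep]
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")

  auc_of <- function(score) {
    r <- rank(score)                    # midranks give ties half credit
    (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  flipped <- FALSE
  auc <- auc_of(x)
  if (orientation_policy == "auto_flip" && auc < 0.5) {
    x <- -x
    auc <- auc_of(x)
    flipped <- TRUE
  }
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt((auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) +
                (n0 - 1) * (q2 - auc^2)) / (n1 * n0))
  ci <- pmin(1, pmax(0, auc + c(-1, 1) * 1.96 * se))

  thr <- sort(unique(x))
  curve <- data.frame(
    threshold = thr,
    sensitivity = vapply(thr, function(t) 100 * mean(x[pos] >= t), 1),
    specificity = vapply(thr, function(t) 100 * mean(x[!pos] < t), 1)
  )
  structure(list(feature = feature, positive_class = positive_class,
                 flipped = flipped, auc = auc, se_auc = se, ci95 = ci,
                 n_pos = n1, n_neg = n0, curve = curve),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc %s%s: AUC %.3f (SE %.3f, 95%% CI %.3f-%.3f), n=%d/%d>\n",
              x$feature, if (x$flipped) " [flipped]" else "",
              x$auc, x$se_auc, x$ci95[1], x$ci95[2], x$n_pos, x$n_neg))
  invisible(x)
}

#' Youden-optimal operating point of a ROC curve
#'
#' @param r a [roc()] result.
#' @return one row of the curve maximizing sensitivity + specificity - 100.
#' @export
youden <- function(r) {
  stopifnot(inherits(r, "roc_result"))
  j <- r$curve$sensitivity + r$curve$specificity
  r$curve[which.max(j), , drop = FALSE]
}

#' Sensitivity and specificity at a fixed cutoff
#'
#' @param table feature table with `label`.
#' @param feature numeric column.
#' @param threshold cutoff value.
#' @param direction `"ge"`: score >= threshold is test-positive;
#'   `"lt"`: score < threshold is test-positive.
#' @return list with `sensitivity` and `specificity`, in percent.
#' @export
cutoff_performance <- function(table, feature, threshold,
                               direction = c("ge", "lt")) {
  check_feature_table(table)
  direction <- match.arg(direction)
  stopifnot(is.finite(threshold))
  x <- as.numeric(table[[feature]])
  pos_test <- if (direction == "ge") x >= threshold else x < threshold
  mal <- table$label == "malignant"
  if (!any(mal) || !any(!mal)) stop("both classes must be present")
  list(sensitivity = 100 * mean(pos_test[mal]),
       specificity = 100 * mean(!pos_test[!mal]))
}

#' Combined PET/CT positivity criterion
#'
#' A node is called positive when SUVmax >= `suv_cut` AND maximal HU <
#' `hu_cut` (defaults 2.5 and 70). Boundary semantics are exactly `>=`
#' and `<`: SUVmax 2.5 counts, HU 70 does not — high-attenuation nodes
#' with avid uptake are typically calcified benign nodes, which the HU
#' bound screens out.
#'
#' @param record data.frame (or list) with `suv_max` and `max_hu`.
#' @param suv_cut,hu_cut the two cutoffs.
#' @return logical vector, one element per row.
#' @export
combined_criterion <- function(record, suv_cut = 2.5, hu_cut = 70) {
  for (f in c("suv_max", "max_hu")) {
    if (is.null(record[[f]])) stop("missing field '", f, "'")
  }
  record[["suv_max"]] >= suv_cut & record[["max_hu"]] < hu_cut
}

#' Single-split CART (decision stump) on one feature
#'
#' Exhaustive search over midpoints of consecutive sorted unique values;
#' the split maximizing the Gini impurity decrease is selected, ties
#' broken toward the lower threshold. The reported `relative_risk` is the
#' malignancy-rate ratio of the malignant-enriched side over the other
#' side; when a side has zero malignant (or zero total) count the rates
#' use a 0.5-count (Haldane-Anscombe) correction so the ratio stays
#' finite.
#'
#' @param table feature table with `label`.
#' @param feature numeric column.
#' @return object of class `stump_split`: `feature`, `threshold`,
#'   `direction` (`"ge"` means score >= threshold is the
#'   malignant-enriched side), `rate_positive_side`, `rate_negative_side`
#'   (malignancy rates), `relative_risk`, `impurity_decrease`; or, for a
#'   constant feature, the same object with `threshold = NA` and zero
#'   impurity decrease (no-split sentinel).
#' @export
cart_stump <- function(table, feature) {
  check_feature_table(table)
  x <- as.numeric(table[[feature]])
  y <- table$label == "malignant"
  keep <- !is.na(x)
  x <- x[keep]; y <- y[keep]
  if (!any(y) || !any(!y)) stop("both classes must be present")
  n <- length(x)
  gini <- function(m, tot) {
    if (tot == 0) return(0)
    p <- m / tot
    2 * p * (1 - p)
  }
  parent <- gini(sum(y), n)
  u <- sort(unique(x))
  if (length(u) < 2) {
    return(structure(list(feature = feature, threshold = NA_real_,
                          direction = NA_character_,
                          rate_positive_side = NA_real_,
                          rate_negative_side = NA_real_,
                          relative_risk = NA_real_,
                          impurity_decrease = 0, n = n),
                     class = "stump_split"))
  }
  cand <- (u[-1] + u[-length(u)]) / 2
  best <- NULL
  for (t in cand) {
    right <- x >= t
    nr <- sum(right); nl <- n - nr
    dec <- parent - (nl / n) * gini(sum(y[!right]), nl) -
      (nr / n) * gini(sum(y[right]), nr)
    if (is.null(best) || dec > best$dec + 1e-12) {
      best <- list(t = t, dec = dec)
    }
  }
  right <- x >= best$t
  rate <- function(side) {
    m <- sum(y[side]); tot <- sum(side)
    if (m == 0 || m == tot || tot == 0) (m + 0.5) / (tot + 1) else m / tot
  }
  r_ge <- rate(right); r_lt <- rate(!right)
  ge_enriched <- r_ge >= r_lt
  structure(list(
    feature = feature, threshold = best$t,
    direction = if (ge_enriched) "ge" else "lt",
    rate_positive_side = max(r_ge, r_lt),
    rate_negative_side = min(r_ge, r_lt),
    relative_risk = max(r_ge, r_lt) / min(r_ge, r_lt),
    impurity_decrease = best$dec, n = n
  ), class = "stump_split")
}

#' @export
print.stump_split <- function(x, ...) {
  if (is.na(x$threshold)) {
    cat("<stump_split ", x$feature, ": no split (constant feature)>\n",
        sep = "")
  } else {
    cat(sprintf(
      "<stump_split %s %s %.4g: RR %.2f, Gini decrease %.4f, n=%d>\n",
      x$feature, if (x$direction == "ge") ">=" else "<", x$threshold,
      x$relative_risk, x$impurity_decrease, x$n))
  }
  invisible(x)
}

#' Default diagnostic panel
#'
#' The cutoff panel evaluated by the pipeline: SUVmax at 2.5 and 5,
#' SUVpeak at 4, short axis at 10 mm, the combined SUVmax/HU criterion,
#' the EBUS categoricals, and the continuous CTTA discriminators
#' (normalized SD — benign-coded, so auto-flipped — and compactness).
#'
#' @return list of panel entries for [evaluate_panel()].
#' @export
default_panel <- function() {
  list(
    list(name = "suv_max_ge_2.5", feature = "suv_max", threshold = 2.5),
    list(name = "suv_max_ge_5", feature = "suv_max", threshold = 5),
    list(name = "suv_peak_ge_4", feature = "suv_peak", threshold = 4),
    list(name = "short_axis_ge_10mm", feature = "short_axis_mm",
         threshold = 10),
    list(name = "suvmax2.5_and_hu70",
         all_of = list(list(feature = "suv_max", threshold = 2.5),
                       list(feature = "max_hu", threshold = 70,
                            direction = "lt"))),
    list(name = "heterogeneous_echo", feature = "heterogeneous_echo"),
    list(name = "cns_present", feature = "cns_present"),
    list(name = "normalized_sd", feature = "normalized_sd",
         continuous = TRUE),
    list(name = "compactness", feature = "compactness", continuous = TRUE)
  )
}

panel_indicator <- function(table, entry) {
  one <- function(e) {
    if (is.null(e$feature) || !e$feature %in% names(table)) {
      stop("unknown column '", e$feature, "'; available: ",
           paste(names(table), collapse = ", "))
    }
    x <- table[[e$feature]]
    if (is.null(e$threshold)) {
      if (!is.logical(x)) stop("entry for '", e$feature,
                               "' needs a threshold or a logical column")
      x
    } else if (!is.null(e$direction) && e$direction == "lt") {
      x < e$threshold
    } else {
      x >= e$threshold
    }
  }
  if (!is.null(entry$all_of)) {
    Reduce(`&`, lapply(entry$all_of, one))
  } else {
    one(entry)
  }
}

#' Evaluate a diagnostic panel (ROC table)
#'
#' One row per entry. Dichotomous entries (threshold rules, logical
#' columns, or AND-combinations of rules) are scored as 0/1 classifiers:
#' AUC, Hanley-McNeil SE and CI of the indicator, and count-based
#' sensitivity/specificity. Entries marked `continuous = TRUE` are scored
#' on the raw feature (auto-flipped if benign-coded) with the operating
#' point at the Youden-optimal threshold.
#'
#' @param table feature table with `label`.
#' @param panel list of entries: `list(name=, feature=, threshold=,
#'   direction=)`, `list(name=, feature=, continuous=TRUE)`, or
#'   `list(name=, all_of=list(...))` for AND-combinations.
#' @return data.frame: name, auc, se_auc, ci_lo, ci_hi, sensitivity,
#'   specificity, flipped, threshold.
#' @export
evaluate_panel <- function(table, panel = default_panel()) {
  check_feature_table(table)
  rows <- lapply(panel, function(entry) {
    name <- entry$name %||% entry$feature
    if (isTRUE(entry$continuous)) {
      r <- roc(table, entry$feature, orientation_policy = "auto_flip")
      yj <- youden(r)
      data.frame(name = name, auc = r$auc, se_auc = r$se_auc,
                 ci_lo = r$ci95[1], ci_hi = r$ci95[2],
                 sensitivity = yj$sensitivity, specificity = yj$specificity,
                 flipped = r$flipped,
                 threshold = if (r$flipped) -yj$threshold else yj$threshold,
                 stringsAsFactors = FALSE)
    } else {
      ind <- panel_indicator(table, entry)
      tab2 <- data.frame(label = table$label, ind = as.numeric(ind))
      r <- roc(tab2, "ind")
      mal <- table$label == "malignant"
      data.frame(name = name, auc = r$auc, se_auc = r$se_auc,
                 ci_lo = r$ci95[1], ci_hi = r$ci95[2],
                 sensitivity = 100 * mean(ind[mal]),
                 specificity = 100 * mean(!ind[!mal]),
                 flipped = FALSE,
                 threshold = entry$threshold %||% NA_real_,
                 stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
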