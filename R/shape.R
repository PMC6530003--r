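# 2D shape descriptors of a binary ROI mask. Perimeter uses a
# marching-squares contour at the 0.5 level (vertices at pixel-edge
# midpoints); diameters use pixel centers plus one pixel of extent.

label_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  comp <- 0L
  idx <- which(mask)
  nr <- nrow(mask)
  for (start in idx) {
    if (lab[start] != 0L) next
    comp <- comp + 1L
    queue <- start
    lab[start] <- comp
    while (length(queue)) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      r <- (cur - 1L) %% nr + 1L
      cc <- (cur - 1L) %/% nr + 1L
      for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
        r2 <- r + d[1]; c2 <- cc + d[2]
        if (r2 >= 1L && r2 <= nr && c2 >= 1L && c2 <= ncol(mask)) {
          j <- (c2 - 1L) * nr + r2
          if (mask[j] && lab[j] == 0L) {
            lab[j] <- comp
            queue <- c(queue, j)
          }
        }
      }
    }
  }
  comp
}

# Marching-squares contour length of the 0.5-level set, in pixel units.
# The binary mask is first mollified with a 3x3 box mean (zero-padded);
# linear interpolation of the crossing positions then recovers subpixel
# boundary geometry, so straight edges measure their Euclidean length and
# smooth contours are not inflated by staircase artifacts.
ms_perimeter_px <- function(mask) {
  pad <- 2L
  f <- matrix(0, nrow(mask) + 2L * pad, ncol(mask) + 2L * pad)
  f[(pad + 1L):(pad + nrow(mask)), (pad + 1L):(pad + ncol(mask))] <- mask * 1
  # 3x3 box mean via shifted sums
  nr <- nrow(f); nc <- ncol(f)
  g <- matrix(0, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    g[2:(nr - 1), 2:(nc - 1)] <- g[2:(nr - 1), 2:(nc - 1)] +
      f[(2 + dr):(nr - 1 + dr), (2 + dc):(nc - 1 + dc)]
  }
  f <- g / 9
  lvl <- 0.5
  inside <- f >= lvl
  # cells whose 2x2 corners disagree
  a <- inside[-nr, -nc]; b <- inside[-nr, -1]
  d <- inside[-1, -nc]; e <- inside[-1, -1]
  s <- a + b + d + e
  cells <- which(s > 0 & s < 4, arr.ind = TRUE)
  total <- 0
  for (k in seq_len(nrow(cells))) {
    i <- cells[k, 1]; j <- cells[k, 2]
    v00 <- f[i, j]; v01 <- f[i, j + 1]
    v10 <- f[i + 1, j]; v11 <- f[i + 1, j + 1]
    ins <- c(v00, v01, v10, v11) >= lvl
    cross <- function(p1, v1, p2, v2) p1 + (lvl - v1) / (v2 - v1) * (p2 - p1)
    pts <- list()
    if (ins[1] != ins[2]) {  # top edge
      pts <- c(pts, list(c(i, cross(j, v00, j + 1, v01))))
    }
    if (ins[3] != ins[4]) {  # bottom edge
      pts <- c(pts, list(c(i + 1, cross(j, v10, j + 1, v11))))
    }
    if (ins[1] != ins[3]) {  # left edge
      pts <- c(pts, list(c(cross(i, v00, i + 1, v10), j)))
    }
    if (ins[2] != ins[4]) {  # right edge
      pts <- c(pts, list(c(cross(i, v01, i + 1, v11), j + 1)))
    }
    if (length(pts) == 2) {
      total <- total + sqrt(sum((pts[[1]] - pts[[2]])^2))
    } else if (length(pts) == 4) {
      # saddle: pair crossings according to the cell-center value
      ctr <- mean(c(v00, v01, v10, v11)) >= lvl
      # pts order: top, bottom, left, right
      pairs <- if (ctr == ins[1]) {
        list(c(1, 4), c(2, 3))  # connect top-right and bottom-left
      } else {
        list(c(1, 3), c(2, 4))  # connect top-left and bottom-right
      }
      for (pr in pairs) {
        total <- total + sqrt(sum((pts[[pr[1]]] - pts[[pr[2]]])^2))
      }
    }
  }
  total
}

feret_diameters <- function(mask, spacing) {
  pts <- which(mask, arr.ind = TRUE)
  if (nrow(pts) == 1) {
    return(list(max = spacing, min = spacing))
  }
  hull <- pts[chull(pts[, 1], pts[, 2]), , drop = FALSE]
  dmat <- as.matrix(stats::dist(hull))
  dmax <- max(dmat) * spacing + spacing       # + one pixel of extent
  theta <- seq(0, pi, length.out = 181)[-181]
  widths <- vapply(theta, function(t) {
    proj <- hull[, 1] * cos(t) + hull[, 2] * sin(t)
    diff(range(proj))
  }, numeric(1))
  dmin <- min(widths) * spacing + spacing
  list(max = dmax, min = dmin)
}

#' Shape descriptors of a binary ROI mask
#'
#' Area is pixel count times spacing squared; perimeter is the
#' marching-squares contour length of the mask's 0.5-level set; the
#' maximal (Feret) diameter is the largest caliper distance across the
#' region. From these: circularity 4*pi*A/P^2 (1 for a disk), roundness
#' 4*A/(pi*dmax^2), and compactness sqrt(4*A/pi)/dmax (the equivalent-area
#' disk diameter over the maximal diameter — a 2D convention; published
#' single-slice "compactness" values from commercial software follow
#' unpublished definitions and are not replicated here). Discretization
#' makes circularity of a digitized disk approach 1 from below at a rate
#' set by the pixel size; values may exceed 1 by a small allowance for
#' coarse masks.
#'
#' @param mask logical (or 0/1) matrix; must be one 4-connected component.
#' @param spacing pixel edge length, mm.
#' @return object of class `shape_features`: `area_mm2`, `perimeter_mm`,
#'   `max_diameter_mm`, `min_diameter_mm`, `circularity`, `compactness`,
#'   `roundness`.
#' @export
shape <- function(mask, spacing = 1) {
  mask <- mask > 0
  if (!any(mask)) stop("mask is empty")
  stopifnot(spacing > 0)
  ncomp <- label_components(mask)
  if (ncomp != 1L) {
    stop("mask must be a single connected component (found ", ncomp, ")")
  }
  area <- sum(mask) * spacing^2
  perim <- ms_perimeter_px(mask) * spacing
  fer <- feret_diameters(mask, spacing)
  structure(list(
    area_mm2 = area,
    perimeter_mm = perim,
    max_diameter_mm = fer$max,
    min_diameter_mm = fer$min,
    circularity = 4 * pi * area / perim^2,
    compactness = sqrt(4 * area / pi) / fer$max,
    roundness = 4 * area / (pi * fer$max^2)
  ), class = "shape_features")
}

#' Full CTTA feature row(s) for phantom nodes
#'
#' Applies exclusion rules, first-order histogram features, and shape
#' descriptors to each node and binds the results into one data frame row
#' per node (stable column order). Nodes whose extraction fails are
#' skipped with a warning; the number skipped is attached as attribute
#' `n_failed`.
#'
#' @param nodes a `phantom_cohort`, a list of `phantom_node`, or a single
#'   node.
#' @param rules an [exclusion_rules()].
#' @param binning a [bin_spec()].
#' @param sd_divisor passed to [first_order()].
#' @return data.frame keyed by `node_id` with `label` and all feature
#'   columns.
#' @export
extract_all <- function(nodes, rules = exclusion_rules(),
                        binning = bin_spec(),
                        sd_divisor = "population") {
  if (inherits(nodes, "phantom_cohort")) nodes <- nodes$nodes
  if (inherits(nodes, "phantom_node")) nodes <- list(nodes)
  rows <- lapply(nodes, function(nd) {
    tryCatch({
      px <- extract_pixels(nd$image, nd$mask, rules, spacing = nd$spacing)
      fo <- first_order(px, binning, sd_divisor)
      sh <- shape(nd$mask, nd$spacing)
      data.frame(
        node_id = nd$node_id, label = nd$label,
        n_pixels = fo$n,
        mean_hu = fo$mean_hu, sd_hu = fo$sd_hu,
        normalized_sd = fo$normalized_sd,
        skewness = fo$skewness, kurtosis = fo$kurtosis,
        kurtosis_excess = fo$kurtosis_excess,
        entropy_bits = fo$entropy_bits,
        p10 = fo$percentiles[["p10"]], p25 = fo$percentiles[["p25"]],
        p50 = fo$percentiles[["p50"]], p75 = fo$percentiles[["p75"]],
        p90 = fo$percentiles[["p90"]], p95 = fo$percentiles[["p95"]],
        area_mm2 = sh$area_mm2, perimeter_mm = sh$perimeter_mm,
        max_diameter_mm = sh$max_diameter_mm,
        min_diameter_mm = sh$min_diameter_mm,
        circularity = sh$circularity, compactness = sh$compactness,
        roundness = sh$roundness,
        stringsAsFactors = FALSE
      )
    }, error = function(e) {
      warning("node ", nd$node_id, " skipped: ", conditionMessage(e),
              call. = FALSE)
      NULL
    })
  })
  failed <- sum(vapply(rows, is.null, logical(1)))
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  attr(out, "n_failed") <- failed
  attr(out, "bin_width") <- binning$width
  attr(out, "sd_divisor") <- sd_divisor
  attr(out, "calcification_hu_threshold") <- rules$calcification_hu_threshold
  out
}
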