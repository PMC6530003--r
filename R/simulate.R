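# Phantom generation: elliptical ROI, Gaussian base HU field, spatially
# correlated low-HU blobs for heterogeneity, optional calcification speck.

# Separable Gaussian smoothing with replicate-padded edges.
smooth_field <- function(m, sigma_px) {
  r <- max(1L, ceiling(3 * sigma_px))
  k <- dnorm(seq(-r, r), sd = sigma_px)
  k <- k / sum(k)
  pad_conv <- function(x) {
    xp <- c(rep(x[1], r), x, rep(x[length(x)], r))
    out <- stats::filter(xp, k, sides = 2)
    out[(r + 1):(r + length(x))]
  }
  m <- apply(m, 2, pad_conv)
  t(apply(t(m), 2, pad_conv))
}

#' Generate one lymph-node phantom
#'
#' Draws an elliptical ROI whose short axis comes from the profile's
#' moment-matched truncated normal (floor `short_axis_floor`), fills it
#' with an i.i.d. Gaussian HU field at the profile's `hu_mean`/`hu_sd`,
#' blends in a spatially correlated low-HU blob component weighted by the
#' profile's `heterogeneity`, and, with probability `calcification_prob`,
#' embeds a small high-HU speck whose coordinates are recorded in the
#' ground truth. Uses the current RNG stream: call `set.seed()` first for
#' reproducible nodes.
#'
#' @param profile a [class_profile()].
#' @param spacing pixel edge length, mm (> 0).
#' @param node_id identifier stored on the node.
#' @param short_axis_floor minimum drawn short axis, mm.
#' @param necrosis_depth HU depth of the heterogeneity blobs at weight 1.
#' @param necrosis_scale_mm correlation length of the blob field, mm.
#' @param calcification_hu HU value of the embedded speck; must exceed any
#'   exclusion threshold in use (default 600 vs the 300 HU default rule).
#' @param background_hu HU outside the ROI.
#' @return object of class `phantom_node`: `node_id`, `label`, `image`
#'   (HU matrix), `mask` (logical matrix), `spacing`, `truth` (list with
#'   `short_axis_mm`, `long_axis_mm`, `angle_rad`, `hu_mean`,
#'   `heterogeneity`, `calcification` — an n x 2 matrix of (row, col)
#'   1-based pixel indices, or NULL).
#' @export
generate_node <- function(profile, spacing = 0.8, node_id = "node",
                          short_axis_floor = 4,
                          necrosis_depth = 60,
                          necrosis_scale_mm = 2.5,
                          calcification_hu = 600,
                          background_hu = -50) {
  if (!inherits(profile, "class_profile")) {
    stop("profile must be a class_profile")
  }
  if (!is.numeric(spacing) || length(spacing) != 1 || spacing <= 0) {
    stop("spacing must be a positive scalar (mm)")
  }
  short_mm <- rtnorm_matched(1, profile$short_axis_mean,
                             profile$short_axis_sd, short_axis_floor)
  generate_node_at(profile, short_mm, spacing = spacing, node_id = node_id,
                   necrosis_depth = necrosis_depth,
                   necrosis_scale_mm = necrosis_scale_mm,
                   calcification_hu = calcification_hu,
                   background_hu = background_hu)
}

#' @export
print.phantom_node <- function(x, ...) {
  cat(sprintf("<phantom_node %s: %s, %dx%d px @ %.2f mm, short axis %.1f mm>\n",
              x$node_id, x$label, nrow(x$image), ncol(x$image), x$spacing,
              x$truth$short_axis_mm))
  invisible(x)
}

draw_records <- function(profile, n, prefix, short_axis_floor = 4,
                         max_hu_floor = -100) {
  short <- rtnorm_matched(n, profile$short_axis_mean,
                          profile$short_axis_sd, short_axis_floor)
  suv_max <- rtnorm_matched(n, profile$suvmax_mean, profile$suvmax_sd, 0)
  # Maximal HU is dominated by a heavy calcification tail (cohort SD far
  # exceeds mean - floor), which no truncated normal can represent; a
  # floor-shifted gamma matches the observed mean/SD exactly.
  shp <- ((profile$max_hu_mean - max_hu_floor) / profile$max_hu_sd)^2
  scl <- profile$max_hu_sd^2 / (profile$max_hu_mean - max_hu_floor)
  max_hu <- max_hu_floor + stats::rgamma(n, shape = shp, scale = scl)
  p <- profile$ebus_probs
  data.frame(
    node_id = sprintf("%s%04d", prefix, seq_len(n)),
    label = profile$label,
    short_axis_mm = short,
    size_ge_1cm = short >= 10,
    round_shape = runif(n) < p$round_shape,
    distinct_margin = runif(n) < p$distinct_margin,
    heterogeneous_echo = runif(n) < p$heterogeneous_echo,
    chs_present = runif(n) < p$chs_present,
    cns_present = runif(n) < p$cns_present,
    suv_max = suv_max,
    suv_peak = profile$suvpeak_ratio * suv_max,
    max_hu = max_hu,
    stringsAsFactors = FALSE
  )
}

#' Generate a benign/malignant phantom cohort
#'
#' Draws `n_benign` + `n_malignant` nodes. Per node, the EBUS categoricals
#' are independent Bernoulli draws from the profile prevalences — except
#' size >= 1 cm, which is derived from the drawn short axis — and SUVmax,
#' SUVpeak and maximal HU are drawn from the profile's moment-matched
#' truncated normals (SUV truncated at 0). The raster phantom of each node
#' is built to be consistent with the same short-axis draw.
#'
#' @param benign,malignant [class_profile()] objects (defaults:
#'   [default_profiles()]).
#' @param n_benign,n_malignant node counts (> 0).
#' @param spacing pixel spacing, mm.
#' @param seed optional integer seed; if given, the cohort is a pure
#'   function of (profiles, counts, spacing, seed).
#' @param with_images if `FALSE`, skip raster synthesis and return records
#'   only — the scalar draws are identical either way, which makes large
#'   parameter-recovery runs cheap.
#' @param ... passed to [generate_node()].
#' @return list of class `phantom_cohort`: `nodes` (list of
#'   `phantom_node`, or NULL when `with_images = FALSE`), `records`
#'   (data.frame, one row per node), `seed`, `spacing`.
#' @export
generate_cohort <- function(benign = default_profiles()$benign,
                            malignant = default_profiles()$malignant,
                            n_benign = 71, n_malignant = 61,
                            spacing = 0.8, seed = NULL,
                            with_images = TRUE, ...) {
  if (n_benign <= 0 || n_malignant <= 0) {
    stop("n_benign and n_malignant must both be > 0")
  }
  if (!is.null(seed)) set.seed(seed)
  rec_b <- draw_records(benign, n_benign, "B")
  rec_m <- draw_records(malignant, n_malignant, "M")
  records <- rbind(rec_b, rec_m)
  nodes <- NULL
  if (with_images) {
    # each raster reuses the short-axis value already drawn for its record
    nodes <- vector("list", nrow(records))
    k <- 0L
    for (part in list(list(p = benign, r = rec_b),
                      list(p = malignant, r = rec_m))) {
      for (i in seq_len(nrow(part$r))) {
        k <- k + 1L
        nodes[[k]] <- generate_node_at(part$p, part$r$short_axis_mm[i],
                                       spacing = spacing,
                                       node_id = part$r$node_id[i], ...)
      }
    }
  }
  structure(list(nodes = nodes, records = records,
                 seed = seed, spacing = spacing),
            class = "phantom_cohort")
}

# generate_node with the short axis fixed instead of drawn; shares all
# texture machinery with generate_node.
generate_node_at <- function(profile, short_mm, spacing = 0.8,
                             node_id = "node",
                             necrosis_depth = 60,
                             necrosis_scale_mm = 2.5,
                             calcification_hu = 600,
                             background_hu = -50) {
  long_mm <- short_mm * profile$axis_ratio_mean
  angle <- runif(1, 0, pi)
  half_mm <- long_mm / 2 + 2 * spacing
  n_px <- 2L * ceiling(half_mm / spacing) + 1L
  ctr <- (n_px + 1L) / 2
  xy <- (seq_len(n_px) - ctr) * spacing
  X <- matrix(xy, n_px, n_px, byrow = TRUE)
  Y <- matrix(xy, n_px, n_px)
  Xr <- cos(angle) * X + sin(angle) * Y
  Yr <- -sin(angle) * X + cos(angle) * Y
  mask <- (Xr / (long_mm / 2))^2 + (Yr / (short_mm / 2))^2 <= 1
  image <- matrix(background_hu, n_px, n_px)
  image[mask] <- profile$hu_mean + profile$hu_sd * rnorm(sum(mask))
  if (profile$heterogeneity > 0) {
    blob <- smooth_field(matrix(rnorm(n_px * n_px), n_px, n_px),
                         sigma_px = necrosis_scale_mm / spacing)
    blob <- (blob - mean(blob)) / stats::sd(as.vector(blob))
    image[mask] <- image[mask] -
      profile$heterogeneity * necrosis_depth * pmax(blob[mask], 0)
  }
  calc_coords <- NULL
  if (runif(1) < profile$calcification_prob) {
    idx <- which(mask, arr.ind = TRUE)
    seed_px <- idx[sample.int(nrow(idx), 1L), ]
    near <- abs(idx[, 1] - seed_px[1]) <= 1 & abs(idx[, 2] - seed_px[2]) <= 1
    calc_coords <- idx[near, , drop = FALSE]
    image[calc_coords] <- calcification_hu
  }
  structure(list(
    node_id = node_id, label = profile$label, image = image, mask = mask,
    spacing = spacing,
    truth = list(short_axis_mm = short_mm, long_axis_mm = long_mm,
                 angle_rad = angle, hu_mean = profile$hu_mean,
                 heterogeneity = profile$heterogeneity,
                 calcification = calc_coords)
  ), class = "phantom_node")
}

#' Serialize a cohort to disk
#'
#' Writes one NIfTI image and mask per node (pixel spacing carried in the
#' NIfTI header), the record table as CSV, and a JSON manifest with the
#' seed, spacing, file inventory, and per-node scalar ground truth, so a
#' written cohort is self-describing and regenerable.
#'
#' @param cohort a [generate_cohort()] result with images.
#' @param out_dir output directory (created if needed).
#' @return path of the manifest JSON, invisibly.
#' @seealso [read_cohort()]
#' @export
write_cohort <- function(cohort, out_dir) {
  stopifnot(inherits(cohort, "phantom_cohort"))
  if (is.null(cohort$nodes)) stop("cohort has no images (with_images = FALSE)")
  dir.create(file.path(out_dir, "images"), recursive = TRUE,
             showWarnings = FALSE)
  files <- lapply(cohort$nodes, function(nd) {
    img_f <- file.path(out_dir, "images", paste0(nd$node_id, ".nii.gz"))
    msk_f <- file.path(out_dir, "images", paste0(nd$node_id, "_mask.nii.gz"))
    ok <- tryCatch({
      RNifti::writeNifti(RNifti::asNifti(nd$image,
                                         pixdim = rep(nd$spacing, 2)),
                         img_f, datatype = "double")
      RNifti::writeNifti(RNifti::asNifti(array(as.integer(nd$mask),
                                               dim = dim(nd$mask)),
                                         pixdim = rep(nd$spacing, 2)), msk_f)
      TRUE
    }, error = function(e) {
      stop("failed writing ", img_f, ": ", conditionMessage(e))
    })
    list(node_id = nd$node_id, image = basename(img_f), mask = basename(msk_f),
         truth = nd$truth[c("short_axis_mm", "long_axis_mm", "angle_rad")])
  })
  rec_f <- file.path(out_dir, "records.csv")
  write.csv(cohort$records, rec_f, row.names = FALSE)
  manifest <- list(
    seed = cohort$seed, spacing = cohort$spacing,
    n_benign = sum(cohort$records$label == "benign"),
    n_malignant = sum(cohort$records$label == "malignant"),
    records = basename(rec_f),
    nodes = files,
    package_version = as.character(packageVersion("nodetex"))
  )
  man_f <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, man_f, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(man_f)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir directory containing `manifest.json`.
#' @return a `phantom_cohort` (truth restricted to the serialized scalar
#'   fields).
#' @export
read_cohort <- function(dir) {
  man_f <- file.path(dir, "manifest.json")
  if (!file.exists(man_f)) stop("no manifest.json in ", dir)
  manifest <- jsonlite::read_json(man_f, simplifyVector = FALSE)
  records <- read.csv(file.path(dir, manifest$records),
                      stringsAsFactors = FALSE)
  nodes <- lapply(manifest$nodes, function(entry) {
    img <- RNifti::readNifti(file.path(dir, "images", entry$image))
    msk <- RNifti::readNifti(file.path(dir, "images", entry$mask))
    structure(list(
      node_id = entry$node_id,
      label = records$label[records$node_id == entry$node_id][1],
      image = matrix(as.numeric(img), nrow = dim(img)[1]),
      mask = matrix(as.integer(msk) > 0L, nrow = dim(msk)[1]),
      spacing = manifest$spacing,
      truth = entry$truth
    ), class = "phantom_node")
  })
  structure(list(nodes = nodes, records = records,
                 seed = manifest$seed, spacing = manifest$spacing),
            class = "phantom_cohort")
}
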