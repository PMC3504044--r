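# Lesion quantification on stained muscle sections: point-count stereology,
# collagen area fraction, calcified-fiber counting with total-fiber
# extrapolation, fiber morphometry, slow-fiber fractions, immune-cell
# densities.

#' Superimpose a square point-count grid on a section
#'
#' Places grid intercepts at spacing `sqrt(cell_area)` (100 um for the
#' default 10,000 um^2 cells), offset half a spacing from the image origin so
#' no intercept falls on the border.
#'
#' @param section A `grmd_section`.
#' @param cell_area Grid cell area in um^2 (> 0); default 10,000.
#' @return Tibble of intercept coordinates `x_um`, `y_um` (pixel-centred,
#'   origin at the image corner).
#' @export
overlay_grid <- function(section, cell_area = 10000) {
  stopifnot(inherits(section, "grmd_section"))
  assert_scalar_num(cell_area, "cell_area", positive = TRUE)
  s <- sqrt(cell_area)
  d <- dim(section$img)
  w_um <- d[2] * section$um_per_px
  h_um <- d[1] * section$um_per_px
  if (w_um <= s / 2 || h_um <= s / 2) {
    stop_grmd("empty_grid",
              "section (%.0f x %.0f um) smaller than one %.0f um grid cell",
              w_um, h_um, s)
  }
  xs <- seq(s / 2, w_um, by = s)
  ys <- seq(s / 2, h_um, by = s)
  xs <- xs[xs < w_um]
  ys <- ys[ys < h_um]
  if (length(xs) == 0 || length(ys) == 0) {
    stop_grmd("empty_grid",
              "section (%.0f x %.0f um) smaller than one %.0f um grid cell",
              w_um, h_um, s)
  }
  tibble(x_um = rep(xs, times = length(ys)),
         y_um = rep(ys, each = length(xs)),
         spacing_um = s)
}

um_to_px <- function(u, scale, n) pmin(pmax(floor(u / scale) + 1L, 1L), n)

#' Classify grid intercepts into lesion categories
#'
#' In truth-mask mode the category of each intercept is the ground-truth
#' label of the pixel under it. In manual mode a caption table (one row per
#' intercept: `x_um`, `y_um`, `category`) is tallied instead.
#'
#' @param section A `grmd_section` (used for the scale).
#' @param intercepts Tibble from [overlay_grid()] (truth mode), or `NULL` in
#'   manual mode.
#' @param truth A `grmd_section_truth` (truth-mask mode), or `NULL`.
#' @param manual Data frame with columns `x_um`, `y_um`, `category`
#'   (manual-caption mode).
#' @return An object of class `point_count_result`: list with `counts`
#'   (named integer vector over [lesion_categories()]), `total`, and
#'   `spacing_um`.
#' @export
classify_intercepts <- function(section, intercepts = NULL, truth = NULL,
                                manual = NULL) {
  cats <- lesion_categories()
  if (!is.null(manual)) {
    req <- c("x_um", "y_um", "category")
    if (!all(req %in% names(manual))) {
      stop_grmd("parse_error", "manual caption table needs columns %s",
                paste(req, collapse = ", "))
    }
    bad <- which(!manual$category %in% cats)
    if (length(bad)) {
      stop_grmd("parse_error",
                "unknown categories in manual caption rows: %s",
                paste(head(bad, 10), collapse = ", "))
    }
    counts <- table(factor(manual$category, levels = cats))
    spacing <- if (!is.null(intercepts)) intercepts$spacing_um[1] else NA_real_
  } else {
    stopifnot(inherits(section, "grmd_section"),
              inherits(truth, "grmd_section_truth"),
              !is.null(intercepts))
    d <- dim(truth$category_mask)
    px <- um_to_px(intercepts$x_um, truth$scale, d[2])
    py <- um_to_px(intercepts$y_um, truth$scale, d[1])
    lab <- truth$category_mask[cbind(py, px)]
    counts <- table(factor(cats[lab], levels = cats))
    spacing <- intercepts$spacing_um[1]
  }
  structure(
    list(counts = setNames(as.integer(counts), cats),
         total = sum(counts), spacing_um = spacing),
    class = "point_count_result"
  )
}

#' Pathological index from a point-count result
#'
#' Percentage of grid intercepts, among those over tissue (artifact
#' intercepts excluded), that do not fall on normal-shape muscle fibers.
#'
#' @param pc A `point_count_result`.
#' @return Percentage in `[0, 100]`.
#' @export
pathological_index <- function(pc) {
  stopifnot(inherits(pc, "point_count_result"))
  n_tissue <- pc$total - pc$counts[["artifact"]]
  if (n_tissue <= 0) {
    stop_grmd("undefined_index",
              "all %d intercepts are artifact; pathological index undefined",
              pc$total)
  }
  unname(100 * (n_tissue - pc$counts[["normal_fiber"]]) / n_tissue)
}

#' Collagen (fibrosis) area fraction of a picrosirius-stained section
#'
#' Classifies pixels in hue-saturation space using the fixed picrosirius
#' thresholds from [seg_config()] and returns red (collagen) area divided by
#' total tissue area.
#'
#' @param section A `grmd_section` with `stain == "psr"`.
#' @return Fraction in `[0, 1]`.
#' @export
fibrosis_fraction <- function(section) {
  stopifnot(inherits(section, "grmd_section"))
  if (section$stain != "psr") {
    stop_grmd("invalid_spec", "fibrosis_fraction requires a picrosirius section")
  }
  cfg <- seg_config()$psr
  hsv <- img_hsv(section$img)
  red <- (hsv$h <= cfg$red_hue_max | hsv$h >= cfg$red_hue_min_wrap) &
    hsv$s >= cfg$red_sat_min
  n_tissue <- length(red)
  if (n_tissue == 0) stop_grmd("empty_section", "no tissue pixels")
  sum(red) / n_tissue
}

#' Count calcium-overloaded fibers on an alizarin-stained section
#'
#' Segments calcified cytoplasm in hue-saturation space, labels connected
#' components (one per fiber, since fibers are separated by the unstained
#' boundary network), and classifies each component as moderate (deep pink)
#' or severe (red). A component containing both bands is severe if at least
#' `severe_min_red_frac` of its calcified pixels are in the red band.
#'
#' @param section A `grmd_section` with `stain == "ars"`.
#' @return List with `n_moderate` and `n_severe`.
#' @export
count_calcified <- function(section) {
  stopifnot(inherits(section, "grmd_section"))
  if (section$stain != "ars") {
    stop_grmd("invalid_spec", "count_calcified requires an alizarin section")
  }
  cfg <- seg_config()$ars
  hsv <- img_hsv(section$img)
  calc <- hsv$s >= cfg$calcified_sat_min
  lab <- EBImage::bwlabel(calc)
  lab <- EBImage::imageData(lab)
  n <- max(lab)
  if (n == 0) return(list(n_moderate = 0L, n_severe = 0L))
  sev_px <- hsv$s >= cfg$severe_sat_min
  tot <- tabulate(lab[lab > 0], n)
  sev <- tabulate(lab[lab > 0 & sev_px], n)
  keep <- tot >= cfg$min_fiber_px
  is_sev <- (sev / tot) >= cfg$severe_min_red_frac
  list(n_moderate = sum(keep & !is_sev), n_severe = sum(keep & is_sev))
}

#' Estimate the total fiber count of a section from sampled fields
#'
#' Extrapolates the fiber count of randomly selected fields of known area to
#' the whole section: `round(sum(counts) * section_area / sum(field_areas))`.
#'
#' @param field_counts Fiber counts of the sampled fields (>= 1 field).
#' @param field_area Area of each field, um^2 (scalar or per-field vector).
#' @param section_area Whole-section area, um^2.
#' @return Estimated total fiber count (integer).
#' @export
estimate_total_fibers <- function(field_counts, field_area, section_area) {
  if (length(field_counts) < 1) {
    stop_grmd("invalid_spec", "need at least one sampled field")
  }
  field_area <- rep_len(field_area, length(field_counts))
  if (any(field_area <= 0)) stop_grmd("division_error", "zero field area")
  if (sum(field_area) > section_area) {
    stop_grmd("invalid_spec", "total field area exceeds section area")
  }
  as.integer(round(sum(field_counts) * section_area / sum(field_area)))
}

#' Segment fibers on an ATPase-stained section
#'
#' Detects the dark fiber outlines by value thresholding, labels the enclosed
#' interiors as connected components, and returns per-fiber areas and
#' equivalent diameters (diameter of the equal-area circle,
#' `2 * sqrt(area / pi)`).
#'
#' @param section A `grmd_section` with `stain == "atpase"`.
#' @param min_area_um2 Components smaller than this are discarded as
#'   segmentation debris.
#' @return An object of class `fiber_map`: tibble with `fiber_id`,
#'   `area_um2`, `equiv_diameter_um`.
#' @export
segment_fibers <- function(section, min_area_um2 = 40) {
  stopifnot(inherits(section, "grmd_section"))
  if (section$stain != "atpase") {
    stop_grmd("invalid_spec", "segment_fibers requires an ATPase section")
  }
  cfg <- seg_config()$atpase
  v <- (section$img[, , 1] + section$img[, , 2] + section$img[, , 3]) / 3
  interior <- v > cfg$boundary_value_max
  lab <- EBImage::imageData(EBImage::bwlabel(interior))
  n <- max(lab)
  if (n == 0) stop_grmd("empty_section", "no fiber interiors detected")
  areas_px <- tabulate(lab[lab > 0], n)
  areas <- areas_px * section$um_per_px^2
  keep <- areas >= min_area_um2
  fiber_map(areas[keep])
}

#' Build a fiber map from per-fiber areas
#'
#' @param area_um2 Per-fiber cross-sectional areas, um^2 (> 0).
#' @return An object of class `fiber_map`.
#' @export
fiber_map <- function(area_um2) {
  if (any(area_um2 <= 0)) stop_grmd("invalid_spec", "fiber areas must be > 0")
  structure(
    tibble(fiber_id = seq_along(area_um2), area_um2 = area_um2,
           equiv_diameter_um = 2 * sqrt(area_um2 / pi)),
    class = c("fiber_map", "tbl_df", "tbl", "data.frame")
  )
}

#' Fiber morphometry: mean equivalent diameter and its coefficient of variation
#'
#' @param fibers A `fiber_map`.
#' @param min_fibers Minimum number of fibers required (default 400, the
#'   minimum counted per ATPase section).
#' @return List with `mean_diameter_um`, `cv` (SD/mean, dimensionless) and
#'   `n_fibers`.
#' @export
fiber_morphometry <- function(fibers, min_fibers = 400) {
  stopifnot(inherits(fibers, "fiber_map"))
  n <- nrow(fibers)
  if (n < min_fibers) {
    stop_grmd("insufficient_sample",
              "only %d fibers measured; at least %d required", n, min_fibers)
  }
  d <- fibers$equiv_diameter_um
  list(mean_diameter_um = mean(d), cv = sd(d) / mean(d), n_fibers = n)
}

#' Slow-fiber (type I) percentage from sampled zones
#'
#' @param zone_counts Data frame with one row per sampled zone and columns
#'   `positive`, `total`.
#' @param min_total Minimum total fiber count across zones (default 300, the
#'   minimum counted per immunostained section).
#' @return Percentage `100 * sum(positive) / sum(total)`.
#' @export
slow_fiber_fraction <- function(zone_counts, min_total = 300) {
  stopifnot(all(c("positive", "total") %in% names(zone_counts)))
  if (any(zone_counts$positive > zone_counts$total) ||
      any(zone_counts$positive < 0)) {
    stop_grmd("invalid_spec", "positive counts must be in [0, total]")
  }
  tot <- sum(zone_counts$total)
  if (tot < min_total) {
    stop_grmd("insufficient_sample",
              "only %d fibers counted across zones; at least %d required",
              tot, min_total)
  }
  100 * sum(zone_counts$positive) / tot
}

#' Sample zone counts of slow-myosin-positive fibers from a section truth
#'
#' Draws `n_zones` random square fields and counts, per zone, the fibers
#' (by centroid) that are slow-myosin positive and the total fibers.
#'
#' @param truth A `grmd_section_truth` from an `"mhc"` section.
#' @param n_zones Number of sampled zones (default 5).
#' @param zone_frac Side length of each square zone as a fraction of the
#'   section side.
#' @param seed Integer seed.
#' @return Tibble with columns `positive`, `total` (one row per zone).
#' @export
sample_slow_zones <- function(truth, n_zones = 5, zone_frac = 0.35, seed = 1L) {
  stopifnot(inherits(truth, "grmd_section_truth"))
  d <- dim(truth$fiber_labels)
  n_fib <- length(truth$slow_positive)
  idx <- which(truth$fiber_labels > 0L)
  fib <- truth$fiber_labels[idx]
  ry <- (idx - 1L) %% d[1] + 1L
  rx <- (idx - 1L) %/% d[1] + 1L
  cy <- tapply(ry, fib, mean)
  cx <- tapply(rx, fib, mean)
  zw <- round(zone_frac * d[2]); zh <- round(zone_frac * d[1])
  with_seed(seed, {
    out <- lapply(seq_len(n_zones), function(z) {
      x0 <- sample.int(d[2] - zw, 1); y0 <- sample.int(d[1] - zh, 1)
      inz <- cx >= x0 & cx < x0 + zw & cy >= y0 & cy < y0 + zh
      ids <- as.integer(names(cx))[inz]
      tibble(positive = sum(truth$slow_positive[ids]), total = length(ids))
    })
    dplyr::bind_rows(out)
  })
}

#' Inflammatory-cell density per marker
#'
#' @param points Tibble of marker-positive cell coordinates with a `marker`
#'   column (e.g. the `immune_points` of a section truth).
#' @param section_area_mm2 Section area in mm^2 (> 0).
#' @return Tibble with `marker`, `n_cells`, `density_per_mm2`.
#' @export
immune_cell_density <- function(points, section_area_mm2) {
  if (!is.numeric(section_area_mm2) || section_area_mm2 <= 0) {
    stop_grmd("division_error", "section area must be > 0")
  }
  markers <- c("CD4", "CD8", "CD11b")
  counts <- table(factor(points$marker, levels = markers))
  tibble(marker = markers, n_cells = as.integer(counts),
         density_per_mm2 = as.numeric(counts) / section_area_mm2)
}
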