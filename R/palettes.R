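#' Lesion categories used for point-count stereology
#'
#' The fixed vocabulary used to caption grid intercepts on H&E-stained
#' sections. `normal_fiber` is the reference class of the pathological index;
#' `artifact` marks mounting/staining defects and is excluded from the index
#' denominator.
#'
#' @return Character vector of the seven category names, in canonical order.
#' @export
lesion_categories <- function() {
  c("normal_fiber", "abnormal_fiber", "connective", "inflammatory",
    "adipose", "other_structure", "artifact")
}

#' Fixed RGB palettes for the synthetic stain dialects
#'
#' Each stain dialect renders tissue classes with a fixed reference colour so
#' that colour-based segmentation has a well-defined, testable target. Values
#' are sRGB in `[0, 1]`.
#'
#' @param stain One of `"he"`, `"psr"`, `"ars"`, `"atpase"`, `"mhc"`, `"cd"`.
#' @return Named list of length-3 RGB vectors.
#' @export
stain_palette <- function(stain = c("he", "psr", "ars", "atpase", "mhc", "cd")) {
  stain <- match.arg(stain)
  switch(stain,
    he = list(
      normal_fiber    = c(0.91, 0.56, 0.66),  # eosin pink
      abnormal_fiber  = c(0.58, 0.36, 0.68),  # basophilic purple
      connective      = c(0.95, 0.86, 0.90),
      inflammatory    = c(0.28, 0.20, 0.55),
      adipose         = c(0.97, 0.95, 0.96),
      other_structure = c(0.72, 0.64, 0.70),
      artifact        = c(0.18, 0.18, 0.18)
    ),
    psr = list(
      collagen  = c(0.78, 0.10, 0.14),  # sirius red
      cytoplasm = c(0.22, 0.60, 0.32)   # fast green
    ),
    ars = list(
      normal   = c(0.95, 0.80, 0.85),  # pale pink
      moderate = c(0.85, 0.30, 0.55),  # deep pink
      severe   = c(0.75, 0.07, 0.10),  # red
      boundary = c(0.90, 0.86, 0.88)
    ),
    atpase = list(
      fiber    = c(0.55, 0.45, 0.33),
      boundary = c(0.10, 0.09, 0.08)
    ),
    mhc = list(
      positive = c(0.45, 0.27, 0.10),  # DAB brown
      negative = c(0.90, 0.87, 0.82),
      boundary = c(0.74, 0.71, 0.68)
    ),
    cd = list(
      tissue = c(0.93, 0.90, 0.88),
      cell   = c(0.35, 0.20, 0.08)
    )
  )
}

#' Segmentation thresholds for the synthetic stain dialects
#'
#' Colour segmentation operates in hue-saturation space with fixed per-dialect
#' thresholds. Hue is in `[0, 1]` (R `rgb2hsv` convention); hue bands that
#' wrap zero are expressed as two intervals.
#'
#' @return Nested list of thresholds; see the picrosirius and alizarin
#'   quantification functions for how each entry is used.
#' @export
seg_config <- function() {
  list(
    psr = list(
      red_hue_max = 0.08, red_hue_min_wrap = 0.90, red_sat_min = 0.35,
      green_hue = c(0.20, 0.48), green_sat_min = 0.25
    ),
    ars = list(
      # pale pink: low saturation; deep pink: mid saturation; red: high
      moderate_sat = c(0.42, 0.75), severe_sat_min = 0.80,
      calcified_sat_min = 0.42,
      # a fiber with both bands is severe if >= this fraction of its
      # calcified pixels fall in the severe band
      severe_min_red_frac = 0.25,
      min_fiber_px = 8
    ),
    atpase = list(boundary_value_max = 0.30),
    mhc = list(positive_sat_min = 0.45, positive_value_max = 0.70),
    cd = list(cell_value_max = 0.55, min_cell_px = 2
    )
  )
}

# Convert an H x W x 3 array to hue/saturation/value matrices.
img_hsv <- function(img) {
  d <- dim(img)
  m <- rbind(
    r = as.vector(img[, , 1]),
    g = as.vector(img[, , 2]),
    b = as.vector(img[, , 3])
  )
  hsv <- rgb2hsv(m, maxColorValue = 1)
  list(
    h = matrix(hsv["h", ], d[1], d[2]),
    s = matrix(hsv["s", ], d[1], d[2]),
    v = matrix(hsv["v", ], d[1], d[2])
  )
}
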