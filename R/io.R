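# Plain-file interfaces: section images with JSON sidecars, force-trace
# CSVs with epoch sidecars, the serialized gait reference model, and manual
# intercept-annotation tables.

#' Write a section image (PNG + JSON sidecar, plus truth masks)
#'
#' Writes `<prefix>.png` (8-bit RGB), `<prefix>.json` (`stain`, `um_per_px`,
#' `seed`) and, when a truth is given, `<prefix>_mask.png` and
#' `<prefix>_fibers.png` (16-bit label images).
#'
#' @param pair List with `section` and optionally `truth` (as returned by
#'   [gen_section()]), or a bare `grmd_section`.
#' @param prefix Output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_section <- function(pair, prefix) {
  section <- if (inherits(pair, "grmd_section")) pair else pair$section
  truth <- if (inherits(pair, "grmd_section")) NULL else pair$truth
  png::writePNG(section$img, paste0(prefix, ".png"))
  jsonlite::write_json(
    list(stain = section$stain, um_per_px = section$um_per_px,
         seed = section$seed),
    paste0(prefix, ".json"), auto_unbox = TRUE
  )
  if (!is.null(truth)) {
    png::writePNG(label_to_rg(unclass(truth$category_mask)),
                  paste0(prefix, "_mask.png"))
    png::writePNG(label_to_rg(truth$fiber_labels),
                  paste0(prefix, "_fibers.png"))
  }
  invisible(prefix)
}

#' Read a section image written by [write_section()]
#'
#' @param prefix Path prefix used at write time.
#' @return A list with `section` (class `grmd_section`) and, if the mask
#'   files exist, `truth` containing `category_mask` and `fiber_labels`
#'   (pixel labels only; generator-side truths carry more fields).
#' @export
read_section <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"))
  img <- png::readPNG(paste0(prefix, ".png"))
  section <- structure(
    list(img = img, stain = meta$stain, um_per_px = meta$um_per_px,
         seed = meta$seed),
    class = "grmd_section"
  )
  out <- list(section = section)
  mask_f <- paste0(prefix, "_mask.png")
  if (file.exists(mask_f)) {
    cats <- lesion_categories()
    mask <- rg_to_label(png::readPNG(mask_f))
    fl <- rg_to_label(png::readPNG(paste0(prefix, "_fibers.png")))
    out$truth <- structure(
      list(category_mask = structure(mask, levels = cats),
           fiber_labels = fl,
           scale = meta$um_per_px),
      class = "grmd_section_truth"
    )
  }
  out
}

# 16-bit labels stored losslessly in the red (high byte) and green (low
# byte) channels of an 8-bit RGB PNG.
label_to_rg <- function(lab) {
  stopifnot(max(lab) < 65536)
  out <- array(0, c(nrow(lab), ncol(lab), 3))
  out[, , 1] <- (lab %/% 256L) / 255
  out[, , 2] <- (lab %% 256L) / 255
  out
}

rg_to_label <- function(img) {
  hi <- round(img[, , 1] * 255)
  lo <- round(img[, , 2] * 255)
  matrix(as.integer(hi * 256 + lo), nrow = dim(img)[1])
}

#' Write a force session as CSV trace + JSON epoch sidecar
#'
#' `<prefix>.csv` has columns `t_s`, `force_N`; `<prefix>.json` carries
#' `stim` (list of `[t_on, t_off]` pairs with phases), `body_weight_kg` and
#' `side`.
#'
#' @param session A `force_session`.
#' @param prefix Output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_trace <- function(session, prefix) {
  stopifnot(inherits(session, "force_session"))
  write.csv(data.frame(t_s = session$time, force_N = session$force),
            paste0(prefix, ".csv"), row.names = FALSE)
  jsonlite::write_json(
    list(stim = unname(Map(c, session$epochs$t_on, session$epochs$t_off)),
         phase = session$epochs$phase, index = session$epochs$index,
         body_weight_kg = session$body_weight, side = session$side,
         sampling_rate = session$sampling_rate),
    paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA
  )
  invisible(prefix)
}

#' Read a force session written by [write_trace()]
#' @param prefix Path prefix used at write time.
#' @return A `force_session`.
#' @export
read_trace <- function(prefix) {
  tr <- read.csv(paste0(prefix, ".csv"))
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  structure(
    list(time = tr$t_s, force = tr$force_N,
         epochs = tibble(t_on = meta$stim[, 1], t_off = meta$stim[, 2],
                         phase = meta$phase, index = meta$index),
         body_weight = meta$body_weight_kg, side = meta$side,
         sampling_rate = meta$sampling_rate, truth = NULL),
    class = "force_session"
  )
}

#' Serialize / restore a fitted gait reference model as JSON
#'
#' @param model A `gait_reference`.
#' @param path JSON file path.
#' @return `path` (write) or the restored `gait_reference` (read).
#' @export
write_reference_json <- function(model, path) {
  stopifnot(inherits(model, "gait_reference"))
  jsonlite::write_json(
    list(variables = model$variables, means = unname(model$means),
         sds = unname(model$sds),
         loadings = as.vector(model$loadings),  # column-major, 7 x 2
         explained = model$explained, centroids = model$centroids,
         healthy_by_age = model$healthy_by_age, n_ref = model$n_ref),
    path, auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(path)
}

#' @rdname write_reference_json
#' @export
read_reference_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  loadings <- matrix(unlist(j$loadings), ncol = 2)
  rownames(loadings) <- j$variables
  structure(
    list(variables = j$variables,
         means = setNames(j$means, j$variables),
         sds = setNames(j$sds, j$variables),
         loadings = loadings, explained = j$explained,
         centroids = lapply(j$centroids, as.numeric),
         healthy_by_age = if (is.null(j$healthy_by_age)) NULL else
           as_tibble(j$healthy_by_age),
         n_ref = j$n_ref),
    class = "gait_reference"
  )
}

#' Read a manual intercept-annotation table
#'
#' CSV with columns `x_um`, `y_um`, `category`; categories must belong to
#' [lesion_categories()].
#'
#' @param path CSV file path.
#' @return Tibble of annotations.
#' @export
read_annotation_csv <- function(path) {
  d <- as_tibble(read.csv(path, stringsAsFactors = FALSE))
  req <- c("x_um", "y_um", "category")
  if (!all(req %in% names(d))) {
    stop_grmd("parse_error", "annotation CSV needs columns %s",
              paste(req, collapse = ", "))
  }
  bad <- which(!d$category %in% lesion_categories())
  if (length(bad)) {
    stop_grmd("parse_error", "unknown category at rows: %s",
              paste(head(bad, 10), collapse = ", "))
  }
  d
}
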