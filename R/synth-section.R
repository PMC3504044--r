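# Synthetic stained muscle cross-sections with pixel-level ground truth.
#
# Sections are rendered as jittered-lattice Voronoi tessellations of fiber
# interiors separated by a 2 px dark/endomysial boundary network. Lesion
# classes are carved as smooth blobs (thresholded Gaussian random fields) so
# target area fractions are met exactly at pixel quantization.

# Nearest-seed tessellation on a jittered lattice. Each pixel is assigned to
# the nearest of the 3x3 neighbourhood of lattice seeds; with jitter bounded
# at 0.35 cells this is the true nearest seed for all but a vanishing set of
# pixels, and is in any case the defining rule of the tessellation.
fiber_tessellation <- function(size_px, spacing_px, jitter = 0.35) {
  H <- size_px; W <- size_px
  nx <- max(2L, floor(W / spacing_px))
  ny <- max(2L, floor(H / spacing_px))
  sp_x <- W / nx
  sp_y <- H / ny
  sx <- outer(rep(1, ny), (seq_len(nx) - 0.5) * sp_x) +
    matrix(runif(nx * ny, -jitter, jitter) * sp_x, ny, nx)
  sy <- outer((seq_len(ny) - 0.5) * sp_y, rep(1, nx)) +
    matrix(runif(nx * ny, -jitter, jitter) * sp_y, ny, nx)
  sx <- as.vector(t(sx))  # index k = (j - 1) * nx + i
  sy <- as.vector(t(sy))

  xs <- rep(seq_len(W), each = H)
  ys <- rep(seq_len(H), W)
  i0 <- pmin(pmax(ceiling(xs / sp_x), 1L), nx)
  j0 <- pmin(pmax(ceiling(ys / sp_y), 1L), ny)
  best_d2 <- rep(Inf, H * W)
  best_k <- integer(H * W)
  for (dj in -1:1) {
    for (di in -1:1) {
      ii <- pmin(pmax(i0 + di, 1L), nx)
      jj <- pmin(pmax(j0 + dj, 1L), ny)
      k <- (jj - 1L) * nx + ii
      d2 <- (xs - sx[k])^2 + (ys - sy[k])^2
      upd <- d2 < best_d2
      best_d2[upd] <- d2[upd]
      best_k[upd] <- k[upd]
    }
  }
  lab <- matrix(best_k, H, W)

  # boundary = pixel with a 4-neighbour in a different cell
  bnd <- matrix(FALSE, H, W)
  bnd[-H, ] <- bnd[-H, ] | (lab[-H, ] != lab[-1, ])
  bnd[-1, ] <- bnd[-1, ] | (lab[-1, ] != lab[-H, ])
  bnd[, -W] <- bnd[, -W] | (lab[, -W] != lab[, -1])
  bnd[, -1] <- bnd[, -1] | (lab[, -1] != lab[, -W])
  lab[bnd] <- 0L

  # relabel interiors consecutively
  keep <- sort(unique(as.vector(lab[lab > 0L])))
  remap <- integer(max(keep))
  remap[keep] <- seq_along(keep)
  lab[lab > 0L] <- remap[lab[lab > 0L]]
  lab
}

# Pick exactly `k` pixels among `available` (logical matrix) as a smooth blob
# mask: top-k values of a Gaussian-blurred white-noise field.
blob_mask <- function(available, k, sigma = 8) {
  H <- nrow(available); W <- ncol(available)
  out <- matrix(FALSE, H, W)
  if (k <= 0) return(out)
  sigma <- min(sigma, (min(H, W) - 1) / 8)  # keep the blur kernel inside tiny images
  field <- EBImage::imageData(EBImage::gblur(matrix(rnorm(H * W), H, W),
                                             sigma = sigma))
  field[!available] <- -Inf
  idx <- order(field, decreasing = TRUE)[seq_len(min(k, sum(available)))]
  out[idx] <- TRUE
  out
}

default_lesion_fractions <- function(stain) {
  if (stain == "he") {
    c(abnormal_fiber = 0.15, connective = 0.06, inflammatory = 0.03,
      adipose = 0.02, other_structure = 0, artifact = 0)
  } else {
    c(abnormal_fiber = 0, connective = 0, inflammatory = 0,
      adipose = 0, other_structure = 0, artifact = 0)
  }
}

#' Generate a synthetic stained muscle section with known ground truth
#'
#' Renders a muscle cross-section in one of six stain dialects (H&E,
#' picrosirius-fast green, alizarin red S, ATPase, slow-myosin immunostain,
#' CD-marker immunostain) together with a pixel-level ground-truth object.
#' Fibers are Voronoi-like polygons on a jittered lattice, separated by a
#' thin endomysial boundary; lesion classes (abnormal fibers, connective
#' tissue, inflammatory foci, adipose, artifacts) are placed as smooth blobs
#' whose realized area fractions are stored in the truth. The picrosirius
#' dialect is a two-class collagen/cytoplasm image whose collagen area
#' fraction matches `collagen_fraction` exactly at pixel quantization.
#'
#' @param stain Stain dialect: `"he"`, `"psr"`, `"ars"`, `"atpase"`,
#'   `"mhc"`, or `"cd"`.
#' @param size_px Image side length in pixels (square image).
#' @param um_per_px Physical scale, micrometres per pixel (> 0).
#' @param fiber_diameter_um Approximate target mean fiber equivalent
#'   diameter, micrometres.
#' @param lesion_fractions Named vector of target area fractions for the
#'   carved lesion classes (`abnormal_fiber`, `connective`, `inflammatory`,
#'   `adipose`, `other_structure`, `artifact`). Must sum to at most 1.
#'   `NULL` uses H&E defaults for `"he"` and zero for other stains. Realized
#'   fractions (which for `connective` additionally include the boundary
#'   network) are stored in the truth.
#' @param collagen_fraction Collagen area fraction for the `"psr"` dialect.
#' @param n_moderate,n_severe Number of moderately / severely
#'   calcium-overloaded fibers for the `"ars"` dialect.
#' @param slow_fraction Per-fiber probability of being slow-myosin positive
#'   for the `"mhc"` dialect.
#' @param immune_density Named vector, expected marker-positive cells per
#'   mm^2 for the `"cd"` dialect (`CD4`, `CD8`, `CD11b`).
#' @param noise_sd Additive Gaussian pixel noise SD (sRGB units).
#' @param seed Integer seed; identical arguments and seed give bit-identical
#'   output.
#' @return A list with elements `section` (class `grmd_section`: `img`
#'   H x W x 3 array in `[0,1]`, `stain`, `um_per_px`, `seed`) and `truth`
#'   (class `grmd_section_truth`: `category_mask`, `fiber_labels`,
#'   `calc_class`, `slow_positive`, `immune_points`, `collagen_fraction`,
#'   realized `category_fractions`, `fiber_area_um2`, `scale`).
#' @examples
#' sec <- gen_section("psr", size_px = 128, collagen_fraction = 0.25, seed = 7)
#' sec$truth$collagen_fraction
#' @export
gen_section <- function(stain = c("he", "psr", "ars", "atpase", "mhc", "cd"),
                        size_px = 384, um_per_px = 3,
                        fiber_diameter_um = 45,
                        lesion_fractions = NULL,
                        collagen_fraction = 0.15,
                        n_moderate = 0, n_severe = 0,
                        slow_fraction = 0.25,
                        immune_density = c(CD4 = 25, CD8 = 25, CD11b = 60),
                        noise_sd = 0.015,
                        seed = 1L) {
  stain <- match.arg(stain)
  assert_scalar_num(size_px, "size_px", positive = TRUE)
  assert_scalar_num(um_per_px, "um_per_px", positive = TRUE)
  assert_scalar_num(noise_sd, "noise_sd", nonneg = TRUE)
  if (size_px < 16) stop_grmd("invalid_spec", "image too small (size_px = %d)", size_px)
  lesion_fractions <- lesion_fractions %||% default_lesion_fractions(stain)
  if (any(lesion_fractions < 0) || sum(lesion_fractions) > 1) {
    stop_grmd("invalid_spec", "lesion fractions must be >= 0 and sum to <= 1")
  }
  if (stain == "psr" &&
      (collagen_fraction < 0 || collagen_fraction > 1)) {
    stop_grmd("invalid_spec", "collagen_fraction must be in [0, 1]")
  }

  with_seed(seed, {
    H <- W <- as.integer(size_px)
    npx <- H * W
    cats <- lesion_categories()
    cat_code <- setNames(seq_along(cats), cats)

    if (stain == "psr") {
      k <- round(collagen_fraction * npx)
      col_mask <- blob_mask(matrix(TRUE, H, W), k, sigma = max(4, size_px / 48))
      category_mask <- matrix(cat_code[["normal_fiber"]], H, W)
      category_mask[col_mask] <- cat_code[["connective"]]
      fiber_labels <- matrix(0L, H, W)
      pal <- stain_palette("psr")
      img <- render_classes(list(pal$cytoplasm, pal$collagen),
                            1L + col_mask, H, W)
      truth_collagen <- k / npx
      n_fibers <- 0L
      calc_class <- character(0)
      slow_positive <- logical(0)
      immune_points <- empty_immune_points()
    } else {
      d_px <- fiber_diameter_um / um_per_px
      sp <- max(6, 0.886 * d_px + 2)
      fiber_labels <- fiber_tessellation(H, sp)
      category_mask <- matrix(cat_code[["normal_fiber"]], H, W)
      category_mask[fiber_labels == 0L] <- cat_code[["connective"]]

      # carve non-fiber lesion classes from fiber interiors, exact pixel counts
      avail <- fiber_labels > 0L
      for (cl in c("connective", "inflammatory", "adipose",
                   "other_structure", "artifact")) {
        f <- lesion_fractions[[cl]] %||% 0
        if (is.na(f) || f <= 0) next
        m <- blob_mask(avail, round(f * npx), sigma = max(4, size_px / 48))
        category_mask[m] <- cat_code[[cl]]
        fiber_labels[m] <- 0L
        avail <- avail & !m
      }
      # drop fibers reduced to nothing, relabel consecutively
      fiber_labels <- relabel(fiber_labels)
      n_fibers <- max(fiber_labels, 0L)

      # abnormal fibers: whole-fiber assignment until the target area is met
      f_ab <- lesion_fractions[["abnormal_fiber"]] %||% 0
      abnormal_ids <- integer(0)
      if (f_ab > 0 && n_fibers > 0) {
        areas <- tabulate(fiber_labels[fiber_labels > 0L], n_fibers)
        ord <- sample.int(n_fibers)
        cum <- cumsum(areas[ord])
        n_take <- sum(cum <= f_ab * npx)
        if (n_take == 0 && f_ab * npx > 0) n_take <- 1L
        abnormal_ids <- ord[seq_len(n_take)]
        category_mask[fiber_labels %in% abnormal_ids] <-
          cat_code[["abnormal_fiber"]]
      }

      calc_class <- rep("none", n_fibers)
      if (stain == "ars") {
        n_mod <- as.integer(n_moderate); n_sev <- as.integer(n_severe)
        if (n_mod < 0 || n_sev < 0) {
          stop_grmd("invalid_spec", "calcified fiber counts must be >= 0")
        }
        if (n_mod + n_sev > n_fibers) {
          stop_grmd("invalid_spec",
                    "requested %d calcified fibers but section has only %d",
                    n_mod + n_sev, n_fibers)
        }
        pick <- sample.int(n_fibers, n_mod + n_sev)
        calc_class[pick[seq_len(n_mod)]] <- "moderate"
        if (n_sev > 0) calc_class[pick[n_mod + seq_len(n_sev)]] <- "severe"
      }

      slow_positive <- if (stain == "mhc" && n_fibers > 0) {
        runif(n_fibers) < slow_fraction
      } else rep(FALSE, n_fibers)

      immune_points <- if (stain == "cd") {
        gen_immune_points(immune_density, H, W, um_per_px)
      } else empty_immune_points()

      img <- render_section(stain, category_mask, fiber_labels, calc_class,
                            slow_positive, immune_points, um_per_px, cat_code)
      truth_collagen <- NA_real_
    }

    if (noise_sd > 0) {
      img <- img + array(rnorm(length(img), 0, noise_sd), dim(img))
      img[img < 0] <- 0
      img[img > 1] <- 1
    }

    frac <- tabulate(category_mask, length(cats)) / npx
    names(frac) <- cats
    non_artifact <- npx - sum(category_mask == cat_code[["artifact"]])
    path_idx <- if (non_artifact > 0) {
      100 * (non_artifact - sum(category_mask == cat_code[["normal_fiber"]])) /
        non_artifact
    } else NA_real_

    section <- structure(
      list(img = img, stain = stain, um_per_px = um_per_px, seed = seed),
      class = "grmd_section"
    )
    truth <- structure(
      list(
        category_mask = structure(category_mask, levels = cats),
        fiber_labels = fiber_labels,
        calc_class = calc_class,
        slow_positive = slow_positive,
        immune_points = immune_points,
        collagen_fraction = truth_collagen,
        category_fractions = frac,
        pathological_index = path_idx,
        fiber_area_um2 = if (n_fibers > 0) {
          tabulate(fiber_labels[fiber_labels > 0L], n_fibers) * um_per_px^2
        } else numeric(0),
        scale = um_per_px
      ),
      class = "grmd_section_truth"
    )
    list(section = section, truth = truth)
  })
}

relabel <- function(lab) {
  keep <- sort(unique(as.vector(lab[lab > 0L])))
  if (length(keep) == 0) return(lab)
  remap <- integer(max(keep))
  remap[keep] <- seq_along(keep)
  lab[lab > 0L] <- remap[lab[lab > 0L]]
  lab
}

empty_immune_points <- function() {
  tibble(x_um = numeric(0), y_um = numeric(0), marker = character(0))
}

gen_immune_points <- function(density_per_mm2, H, W, um_per_px) {
  area_mm2 <- H * W * um_per_px^2 / 1e6
  out <- lapply(names(density_per_mm2), function(m) {
    n <- rpois(1, density_per_mm2[[m]] * area_mm2)
    tibble(x_um = runif(n, 0, W * um_per_px),
           y_um = runif(n, 0, H * um_per_px),
           marker = rep(m, n))
  })
  dplyr::bind_rows(out)
}

render_classes <- function(palette_list, class_idx, H, W) {
  img <- array(0, c(H, W, 3))
  for (ch in 1:3) {
    lut <- vapply(palette_list, `[`, numeric(1), ch)
    img[, , ch] <- matrix(lut[class_idx], H, W)
  }
  img
}

render_section <- function(stain, category_mask, fiber_labels, calc_class,
                           slow_positive, immune_points, um_per_px, cat_code) {
  H <- nrow(category_mask); W <- ncol(category_mask)
  pal <- stain_palette(stain)
  if (stain == "he") {
    img <- render_classes(unname(stain_palette("he")[lesion_categories()]),
                          category_mask, H, W)
  } else if (stain == "ars") {
    cls <- matrix(4L, H, W)                       # boundary
    cls[fiber_labels > 0L] <- 1L                  # normal pale pink
    if (length(calc_class)) {
      mod_ids <- which(calc_class == "moderate")
      sev_ids <- which(calc_class == "severe")
      cls[matrix(fiber_labels %in% mod_ids, H, W)] <- 2L
      cls[matrix(fiber_labels %in% sev_ids, H, W)] <- 3L
    }
    img <- render_classes(list(pal$normal, pal$moderate, pal$severe,
                               pal$boundary), cls, H, W)
  } else if (stain == "atpase") {
    img <- render_classes(list(pal$fiber, pal$boundary),
                          1L + (fiber_labels == 0L), H, W)
    # per-fiber tone variation so adjacent fibers are visually distinct
    n_fib <- max(fiber_labels, 0L)
    if (n_fib > 0) {
      tone <- c(1, pmax(0.75, pmin(1.25, rnorm(n_fib, 1, 0.08))))
      tm <- matrix(tone[fiber_labels + 1L], H, W)
      inf <- fiber_labels > 0L
      for (ch in 1:3) {
        plane <- img[, , ch]
        plane[inf] <- pmin(1, plane[inf] * tm[inf])
        img[, , ch] <- plane
      }
    }
  } else if (stain == "mhc") {
    cls <- matrix(3L, H, W)                       # boundary
    neg <- fiber_labels > 0L
    cls[neg] <- 2L
    if (length(slow_positive)) {
      pos_ids <- which(slow_positive)
      cls[matrix(fiber_labels %in% pos_ids, H, W)] <- 1L
    }
    img <- render_classes(list(pal$positive, pal$negative, pal$boundary),
                          cls, H, W)
  } else if (stain == "cd") {
    img <- render_classes(list(pal$tissue), matrix(1L, H, W), H, W)
    if (nrow(immune_points) > 0) {
      r_px <- max(1, round(3 / um_per_px))        # ~3 um cell radius
      cx <- pmin(pmax(round(immune_points$x_um / um_per_px), 1), W)
      cy <- pmin(pmax(round(immune_points$y_um / um_per_px), 1), H)
      for (i in seq_along(cx)) {
        xr <- max(1, cx[i] - r_px):min(W, cx[i] + r_px)
        yr <- max(1, cy[i] - r_px):min(H, cy[i] + r_px)
        for (ch in 1:3) img[yr, xr, ch] <- pal$cell[ch]
      }
    }
  } else {
    stop_grmd("invalid_spec", "unknown stain dialect '%s'", stain)
  }
  img
}

#' Physical area of a section in square micrometres
#' @param section A `grmd_section`.
#' @return Area in um^2.
#' @export
section_area_um2 <- function(section) {
  d <- dim(section$img)
  d[1] * d[2] * section$um_per_px^2
}
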