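# Point-count stereology, colour segmentation, morphometry.

test_that("grid overlay uses sqrt(cell_area) spacing with half-cell offset", {
  sec <- gen_section("he", size_px = 500, um_per_px = 2, seed = 1)$section
  g <- overlay_grid(sec)                      # 10,000 um^2 cells
  expect_equal(unique(g$spacing_um), 100)
  # 1000 x 1000 um image: a 10 x 10 lattice offset at 50 um
  expect_equal(nrow(g), 100)
  expect_equal(sort(unique(g$x_um)), seq(50, 950, by = 100))
  g2 <- overlay_grid(sec, cell_area = 2500)
  expect_equal(unique(g2$spacing_um), 50)
  small <- gen_section("he", size_px = 20, um_per_px = 2, seed = 1)$section
  expect_error(overlay_grid(small), class = "empty_grid")
})

test_that("intercept classification matches the truth mask and manual tallies", {
  sec <- gen_section("he", size_px = 256, um_per_px = 3, seed = 2)
  g <- overlay_grid(sec$section, cell_area = 2500)
  pc <- classify_intercepts(sec$section, g, truth = sec$truth)
  expect_equal(pc$total, nrow(g))
  expect_equal(sum(pc$counts), pc$total)
  # manual CSV mode tallies the caption rows verbatim
  manual <- data.frame(
    x_um = seq_len(100), y_um = seq_len(100),
    category = rep(c("normal_fiber", "abnormal_fiber", "connective",
                     "artifact"), c(60, 25, 10, 5))
  )
  pcm <- classify_intercepts(NULL, manual = manual)
  expect_equal(unname(pcm$counts[c("normal_fiber", "abnormal_fiber",
                                   "connective", "artifact")]),
               c(60L, 25L, 10L, 5L))
  bad <- manual
  bad$category[3] <- "not_a_category"
  expect_error(classify_intercepts(NULL, manual = bad), class = "parse_error")
})

test_that("pathological index is the non-normal share of tissue intercepts", {
  mk <- function(counts) {
    full <- setNames(rep(0L, 7), lesion_categories())
    full[names(counts)] <- counts
    structure(list(counts = full, total = sum(full), spacing_um = 100),
              class = "point_count_result")
  }
  expect_equal(pathological_index(mk(c(normal_fiber = 50))), 0)
  expect_equal(pathological_index(
    mk(c(normal_fiber = 60, abnormal_fiber = 25, connective = 15))), 40)
  # artifact intercepts are excluded from the denominator
  expect_equal(pathological_index(mk(c(normal_fiber = 90, artifact = 10))), 0)
  expect_error(pathological_index(mk(c(artifact = 10))),
               class = "undefined_index")
})

test_that("stereological sampling error shrinks as the grid is refined", {
  sec <- gen_section("he", size_px = 400, um_per_px = 3, seed = 13)
  err <- vapply(c(200, 100, 50, 25), function(sp) {
    pc <- classify_intercepts(sec$section,
                              overlay_grid(sec$section, cell_area = sp^2),
                              truth = sec$truth)
    abs(pathological_index(pc) - sec$truth$pathological_index)
  }, numeric(1))
  expect_lt(err[4], err[1])           # finest grid beats the coarsest
  expect_lt(err[4], 1)                # and converges onto the census value
})

test_that("fibrosis fraction recovers the collagen truth by segmentation", {
  sec <- gen_section("psr", size_px = 192, collagen_fraction = 0.25, seed = 4)
  expect_lt(abs(fibrosis_fraction(sec$section) - 0.25), 0.01)
  zero <- gen_section("psr", size_px = 128, collagen_fraction = 0, seed = 4)
  expect_equal(fibrosis_fraction(zero$section), 0)
  # two-class sections: red fraction + green fraction = 1
  cfg <- seg_config()$psr
  hsv <- grmdpheno:::img_hsv(sec$section$img)
  red <- (hsv$h <= cfg$red_hue_max | hsv$h >= cfg$red_hue_min_wrap) &
    hsv$s >= cfg$red_sat_min
  green <- hsv$h >= cfg$green_hue[1] & hsv$h <= cfg$green_hue[2] &
    hsv$s >= cfg$green_sat_min
  expect_equal(mean(red) + mean(green), 1, tolerance = 5e-3)
  # segmentation vs truth-mask census over random sections
  set.seed(71)
  errs <- vapply(1:8, function(s) {
    cf <- runif(1, 0.05, 0.4)
    sc <- gen_section("psr", size_px = 160, collagen_fraction = cf, seed = 100 + s)
    abs(fibrosis_fraction(sc$section) - sc$truth$collagen_fraction)
  }, numeric(1))
  expect_lt(mean(errs), 0.02)
  he <- gen_section("he", size_px = 128, seed = 1)$section
  expect_error(fibrosis_fraction(he), class = "invalid_spec")
})

test_that("calcified-fiber counting classifies moderate and severe correctly", {
  sec <- gen_section("ars", size_px = 256, um_per_px = 3, n_moderate = 12,
                     n_severe = 3, seed = 5)
  cc <- count_calcified(sec$section)
  expect_equal(cc$n_moderate, 12)
  expect_equal(cc$n_severe, 3)
  none <- gen_section("ars", size_px = 128, seed = 5)
  expect_equal(count_calcified(none$section), list(n_moderate = 0L,
                                                   n_severe = 0L))
  # per-fiber agreement with the truth labels across sections
  set.seed(72)
  agree <- vapply(1:10, function(s) {
    sc <- gen_section("ars", size_px = 192, um_per_px = 3,
                      n_moderate = sample(3:10, 1), n_severe = sample(1:5, 1),
                      seed = 200 + s)
    cc <- count_calcified(sc$section)
    truth_m <- sum(sc$truth$calc_class == "moderate")
    truth_s <- sum(sc$truth$calc_class == "severe")
    (min(cc$n_moderate, truth_m) + min(cc$n_severe, truth_s)) /
      max(1, truth_m + truth_s)
  }, numeric(1))
  expect_gte(mean(agree), 0.95)
})

test_that("total-fiber extrapolation is exact under tiling and unbiased under sampling", {
  # 5 fields covering 6% of the section, 60 fibers counted -> 1000
  expect_equal(estimate_total_fibers(rep(12, 5), 1200, 1e5), 1000)
  # exhaustive tiling returns the exact count
  expect_equal(estimate_total_fibers(c(40, 60), c(5e4, 5e4), 1e5), 100)
  expect_error(estimate_total_fibers(numeric(0), 10, 100),
               class = "invalid_spec")
  expect_error(estimate_total_fibers(5, 0, 100), class = "division_error")
  # Monte-Carlo: random fields on a synthetic section, small relative bias
  sec <- gen_section("ars", size_px = 320, um_per_px = 3, seed = 6)
  area <- section_area_um2(sec$section)
  est <- vapply(1:200, function(s) {
    ff <- sample_fiber_fields(sec$truth, seed = s)
    estimate_total_fibers(ff$counts, ff$field_area_um2, area)
  }, numeric(1))
  true_n <- length(sec$truth$fiber_area_um2)
  expect_lt(abs(mean(est) - true_n) / true_n, 0.02)
})

test_that("fiber morphometry uses the equal-area-circle diameter", {
  disks <- fiber_map(rep(pi * 50^2, 400))
  m <- fiber_morphometry(disks)
  expect_equal(m$mean_diameter_um, 100)
  expect_equal(m$cv, 0)
  squares <- fiber_map(rep(30^2, 400))
  expect_equal(fiber_morphometry(squares)$mean_diameter_um, 2 * 30 / sqrt(pi))
  err <- expect_error(fiber_morphometry(fiber_map(rep(100, 399))),
                      class = "insufficient_sample")
  expect_match(conditionMessage(err), "399")
})

test_that("ATPase segmentation recovers the truth fiber areas", {
  sec <- gen_section("atpase", size_px = 448, um_per_px = 2,
                     fiber_diameter_um = 40, seed = 7)
  fm <- segment_fibers(sec$section)
  m <- fiber_morphometry(fm, min_fibers = 200)
  truth_mean <- mean(2 * sqrt(sec$truth$fiber_area_um2 / pi))
  expect_lt(abs(m$mean_diameter_um - truth_mean) / truth_mean, 0.03)
})

test_that("slow-fiber fraction pools zones and enforces the sample minimum", {
  zc <- data.frame(positive = c(10, 5, 5, 6, 4), total = c(60, 60, 60, 60, 60))
  expect_equal(slow_fiber_fraction(zc), 10)
  expect_equal(slow_fiber_fraction(data.frame(positive = 300, total = 300)), 100)
  expect_error(slow_fiber_fraction(data.frame(positive = 10, total = 100)),
               class = "insufficient_sample")
  # zone sampling is an unbiased estimator of the section's true fraction
  sec <- gen_section("mhc", size_px = 448, um_per_px = 2, slow_fraction = 0.2,
                     seed = 8)
  true_pct <- 100 * mean(sec$truth$slow_positive)
  ests <- vapply(1:100, function(s) {
    slow_fiber_fraction(sample_slow_zones(sec$truth, seed = s),
                        min_total = 50)
  }, numeric(1))
  se <- sd(ests) / sqrt(length(ests))
  expect_lt(abs(mean(ests) - true_pct), 3 * se + 0.5)
})

test_that("immune-cell density is count per area", {
  pts <- tibble::tibble(x_um = runif(50), y_um = runif(50),
                        marker = rep("CD8", 50))
  d <- immune_cell_density(pts, 2)
  expect_equal(d$density_per_mm2[d$marker == "CD8"], 25)
  expect_equal(d$n_cells[d$marker == "CD4"], 0L)
  sec <- gen_section("cd", size_px = 192, um_per_px = 3, seed = 9)
  area <- section_area_um2(sec$section) / 1e6
  dd <- immune_cell_density(sec$truth$immune_points, area)
  tab <- table(factor(sec$truth$immune_points$marker,
                      levels = c("CD4", "CD8", "CD11b")))
  expect_equal(dd$density_per_mm2, as.numeric(tab) / area)
  expect_error(immune_cell_density(pts, 0), class = "division_error")
})
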