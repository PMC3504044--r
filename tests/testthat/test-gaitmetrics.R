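# Normalizations, reference PCA, supplementary projection, GQI.

test_that("record normalization follows the stated variable definitions", {
  r <- tibble::tibble(
    speed_ms = 1.6, stride_freq_hz = 2, stride_len_m = 0.8, regularity = 250,
    power_dv = 2, power_cc = 1, power_ml = 1, total_power = 4, height_m = 0.5
  )
  n <- normalize_record(r)
  expect_equal(n$stride_len_norm, 1.6)
  expect_equal(c(n$rel_power_dv, n$rel_power_cc, n$rel_power_ml),
               c(0.5, 0.25, 0.25))
  expect_equal(n$speed_norm, 3.2)
  r2 <- r
  r2$power_dv <- 4; r2$power_cc <- 0; r2$power_ml <- 0
  n2 <- normalize_record(r2)
  expect_equal(c(n2$rel_power_dv, n2$rel_power_cc, n2$rel_power_ml),
               c(1, 0, 0))
  r3 <- r; r3$height_m <- 0
  expect_error(normalize_record(r3), class = "normalization_error")
})

test_that("force index is total power over speed and is scale-free", {
  r <- tibble::tibble(total_power = 6, speed_ms = 2)
  expect_equal(force_index(r), 3)
  r2 <- tibble::tibble(total_power = 12, speed_ms = 4)
  expect_equal(force_index(r2), 3)
  expect_error(force_index(tibble::tibble(total_power = 1, speed_ms = 0)),
               class = "division_error")
})

test_that("reference PCA matches an independent eigen-decomposition", {
  ref <- gen_gait_cohort(tiny_gait_specs(10, 14), seed = 31)
  m <- fit_reference(ref)
  # oracle: prcomp on the same standardized matrix
  X <- as.matrix(normalize_record(ref)[gait_pca_variables()])
  pr <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  for (k in 1:2) {
    expect_lt(min(sum(abs(m$loadings[, k] - pr$rotation[, k])),
                  sum(abs(m$loadings[, k] + pr$rotation[, k]))), 1e-10)
  }
  expect_equal(m$explained,
               (pr$sdev^2 / sum(pr$sdev^2))[1:2], tolerance = 1e-12)
  expect_gte(m$explained[1], m$explained[2])
  # orthonormal loadings
  expect_equal(crossprod(m$loadings), diag(2), tolerance = 1e-12,
               ignore_attr = TRUE)
  # healthy centroid left of the GRMD centroid on component 1
  expect_lt(m$centroids$healthy[1], m$centroids$grmd_ctrl[1])
  # duplicated data -> identical model
  m2 <- fit_reference(ref)
  expect_identical(m, m2)
  # constant variable is refused by name
  ref0 <- ref
  ref0$regularity <- 250
  err <- expect_error(fit_reference(ref0), class = "degenerate_variable")
  expect_match(conditionMessage(err), "regularity")
})

test_that("supplementary projection reproduces fitted scores and centering", {
  ref <- gen_gait_cohort(tiny_gait_specs(), seed = 32)
  m <- fit_reference(ref)
  # reference individuals land exactly on their fitted scores
  X <- as.matrix(normalize_record(ref)[gait_pca_variables()])
  Z <- scale(X, center = m$means, scale = m$sds)
  fitted <- Z %*% m$loadings
  proj <- project_supplementary(m, ref)
  expect_equal(cbind(proj$pc1, proj$pc2), unname(fitted), tolerance = 1e-12)
  # a record at the reference means projects to the origin
  at_mean <- tibble::tibble(
    speed_ms = 1, stride_freq_hz = m$means[["stride_freq_hz"]],
    stride_len_m = m$means[["stride_len_norm"]], regularity = m$means[["regularity"]],
    power_dv = m$means[["rel_power_dv"]] * m$means[["total_power"]],
    power_cc = m$means[["rel_power_cc"]] * m$means[["total_power"]],
    power_ml = m$means[["rel_power_ml"]] * m$means[["total_power"]],
    total_power = m$means[["total_power"]], height_m = 1
  )
  pm <- project_supplementary(m, at_mean)
  expect_equal(c(pm$pc1, pm$pc2), c(0, 0), tolerance = 1e-10)
})

test_that("GQI is a Euclidean distance with the contracted identities", {
  ref <- gen_gait_cohort(tiny_gait_specs(), seed = 33)
  m <- fit_reference(ref)
  cen <- m$centroids$healthy
  coords <- tibble::tibble(pc1 = cen[1] + c(0, 3), pc2 = cen[2] + c(0, 4))
  g <- gqi(m, coords)
  expect_equal(g$gqi, c(0, 5))
  # plane distance never exceeds the full 7-D standardized distance
  ev <- gen_gait_cohort(cohort_spec("grmd_ctrl", 10), seed = 34)
  Z <- scale(as.matrix(normalize_record(ev)[gait_pca_variables()]),
             center = m$means, scale = m$sds)
  Zc <- scale(as.matrix(normalize_record(ref[ref$group == "healthy", ])[gait_pca_variables()]),
              center = m$means, scale = m$sds)
  full_d <- sqrt(rowSums(sweep(Z, 2, colMeans(Zc))^2))
  g2 <- gqi(m, project_supplementary(m, ev))
  # healthy centroid in score space is the projection of the mean standardized
  # healthy record, so compare against distance to that point
  expect_true(all(g2$gqi <= full_d + 1e-8))
})

test_that("GQI is invariant to raw-unit rescaling and loading signs", {
  ref <- gen_gait_cohort(tiny_gait_specs(), seed = 35)
  ev <- gen_gait_cohort(cohort_spec("grmd_treated", 6), seed = 36)
  m <- fit_reference(ref)
  g <- gqi(m, project_supplementary(m, ev))$gqi
  # express regularity in milli-units everywhere: GQI unchanged
  ref2 <- ref; ref2$regularity <- ref2$regularity * 1000
  ev2 <- ev; ev2$regularity <- ev2$regularity * 1000
  m2 <- fit_reference(ref2)
  g2 <- gqi(m2, project_supplementary(m2, ev2))$gqi
  expect_equal(g, g2, tolerance = 1e-8)
  # flipping both loading columns leaves distances unchanged
  m3 <- m
  m3$loadings <- -m3$loadings
  m3$centroids <- lapply(m$centroids, function(x) -x)
  g3 <- gqi(m3, project_supplementary(m3, ev))$gqi
  expect_equal(g, g3, tolerance = 1e-12)
})

test_that("held-out healthy dogs project into the healthy cloud", {
  ref <- gen_gait_cohort(tiny_gait_specs(12, 16), seed = 37)
  m <- fit_reference(ref)
  held <- gen_gait_cohort(cohort_spec("healthy", 300), seed = 38)
  g <- gqi(m, project_supplementary(m, held))
  # healthy reference scores have unit-order SD; 3-SD radius around the
  # centroid should contain nearly all held-out healthy dogs
  sc <- project_supplementary(m, ref[ref$group == "healthy", ])
  r3 <- 3 * sqrt(mean((sc$pc1 - m$centroids$healthy[1])^2 +
                        (sc$pc2 - m$centroids$healthy[2])^2))
  expect_gte(mean(g$gqi <= r3), 0.95)
})

test_that("GQI trajectories follow the treated drift without interpolation", {
  ref <- gen_gait_cohort(tiny_gait_specs(12, 16), seed = 39)
  m <- fit_reference(ref)
  ages <- seq(2, 9, by = 0.5)
  tr <- gen_gait_cohort(cohort_spec("grmd_treated", 6, ages = ages), seed = 40)
  one <- tr[tr$dog_id == tr$dog_id[1], ]
  traj <- gqi_trajectory(m, one)
  expect_equal(nrow(traj), length(ages))
  expect_equal(traj$age_months, ages)
  # drift towards healthy: late GQI clearly below early GQI (cohort mean)
  allg <- gqi(m, project_supplementary(m, tr))
  early <- mean(allg$gqi[allg$age_months <= 3])
  late <- mean(allg$gqi[allg$age_months >= 6])
  expect_lt(late, early)
})
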