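# Generators: determinism, self-consistent ground truth, degenerate cases.

test_that("section generation is deterministic and writes its own truth", {
  a <- gen_section("psr", size_px = 128, collagen_fraction = 0.25, seed = 7)
  b <- gen_section("psr", size_px = 128, collagen_fraction = 0.25, seed = 7)
  expect_identical(a$section$img, b$section$img)
  expect_identical(a$truth$category_mask, b$truth$category_mask)
  # realized collagen fraction matches the requested one at pixel quantization
  expect_lt(abs(a$truth$collagen_fraction - 0.25), 1 / 128^2 + 1e-12)
  px_census <- mean(unclass(a$truth$category_mask) == 3L)  # connective code
  expect_equal(px_census, a$truth$collagen_fraction)

  c1 <- gen_section("he", size_px = 160, seed = 3)
  c2 <- gen_section("he", size_px = 160, seed = 3)
  expect_identical(c1$section$img, c2$section$img)
  c3 <- gen_section("he", size_px = 160, seed = 4)
  expect_false(identical(c1$section$img, c3$section$img))
})

test_that("section truth is exactly recoverable by pixel census", {
  he <- gen_section("he", size_px = 256, um_per_px = 3, seed = 11)
  cats <- lesion_categories()
  census <- tabulate(unclass(he$truth$category_mask), length(cats)) / 256^2
  expect_equal(unname(he$truth$category_fractions), census)
  non_art <- sum(census) - census[7]
  expect_equal(he$truth$pathological_index,
               100 * (non_art - census[1]) / non_art)
  # fiber areas match a label census
  n_fib <- length(he$truth$fiber_area_um2)
  expect_equal(he$truth$fiber_area_um2,
               tabulate(he$truth$fiber_labels[he$truth$fiber_labels > 0],
                        n_fib) * 9)
})

test_that("degenerate and invalid section specs behave as contracted", {
  ars0 <- gen_section("ars", size_px = 128, n_moderate = 0, n_severe = 0,
                      seed = 1)
  expect_true(all(ars0$truth$calc_class == "none"))
  expect_error(gen_section("he", size_px = 128,
                           lesion_fractions = c(abnormal_fiber = 0.6,
                                                connective = 0.5,
                                                inflammatory = 0, adipose = 0,
                                                other_structure = 0,
                                                artifact = 0), seed = 1),
               class = "invalid_spec")
  expect_error(gen_section("he", size_px = 0, seed = 1),
               class = "invalid_spec")
  expect_error(gen_section("ars", size_px = 64, n_moderate = 1e5, seed = 1),
               class = "invalid_spec")
})

test_that("force trace generator honours its truth parameters", {
  p <- short_protocol(n_fatigue = 2)
  # noiseless plateau equals the requested force; near-instant relaxation
  # with no offset returns the trace to baseline
  tr <- trace_truth(30, relax_tau = 1e-4, residual_offset = 0, noise_sd = 0)
  ses <- gen_force_session(tr, p, body_weight = 15, seed = 1)
  expect_equal(tetanic_force(ses, "tetanic", 1), 30, tolerance = 1e-6)
  t_off1 <- ses$epochs$t_off[1]
  post <- ses$time > t_off1 + 0.01 & ses$time < t_off1 + 1.9
  expect_lt(max(abs(ses$force[post])), 1e-8)
  # constant amplitude schedule: all fatigue tetani equal
  tr2 <- trace_truth(10, relax_tau = 0.05, fatigue_schedule = rep(10, 40))
  ses2 <- gen_force_session(tr2, short_protocol(n_fatigue = 40), seed = 2)
  f <- vapply(c(1, 20, 40), function(i) tetanic_force(ses2, "fatigue", i),
              numeric(1))
  expect_equal(f, rep(10, 3), tolerance = 1e-6)
  # determinism with noise
  s1 <- gen_force_session(trace_truth(20, noise_sd = 0.5), p, seed = 9)
  s2 <- gen_force_session(trace_truth(20, noise_sd = 0.5), p, seed = 9)
  expect_identical(s1$force, s2$force)
  expect_error(gen_force_session(tr, force_protocol(sampling_rate = 100)),
               class = "invalid_protocol")
})

test_that("gait cohort rows are internally consistent", {
  g <- gen_gait_cohort(tiny_gait_specs(), seed = 5)
  expect_equal(nrow(g), 18)
  rel_sum <- (g$power_dv + g$power_cc + g$power_ml) / g$total_power
  expect_equal(rel_sum, rep(1, nrow(g)))
  expect_true(all(g$total_power > 0) && all(g$height_m > 0))
  # SD = 0 everywhere: all rows of the group identical to the spec means
  h0 <- gen_gait_cohort(cohort_spec("healthy", 5, params = zero_sd_params()),
                        seed = 1)
  for (v in setdiff(names(h0), "dog_id")) {
    expect_length(unique(h0[[v]]), 1)
  }
  pr <- zero_sd_params()
  expect_equal(h0$stride_len_m[1] / h0$height_m[1],
               unname(pr$mean["stride_len_norm"]))
})

test_that("cohort means converge to the spec means for large n", {
  g <- gen_gait_cohort(cohort_spec("healthy", 400), seed = 8)
  pr <- grmdpheno:::group_gait_params("healthy")
  se <- pr$sd[["stride_freq"]] / sqrt(400)
  expect_lt(abs(mean(g$stride_freq_hz) - pr$mean[["stride_freq"]]), 3 * se)
  se_reg <- pr$sd[["regularity"]] / sqrt(400)
  expect_lt(abs(mean(g$regularity) - pr$mean[["regularity"]]), 3 * se_reg)
})

test_that("CK and motor-score generators follow the group trajectories", {
  clin <- gen_ck_and_scores(list(cohort_spec("grmd_treated", 4),
                                 cohort_spec("grmd_ctrl", 4),
                                 cohort_spec("healthy", 3)), seed = 21)
  expect_true(all(clin$ck$ck_ui_l > 0))
  # weekly CK over 2-9 months
  expect_equal(sum(clin$ck$dog_id == "grmd_treated_01"), 31)
  # healthy sheets are exactly zero
  healthy_items <- clin$scores |>
    dplyr::filter(group == "healthy") |>
    dplyr::select(dplyr::starts_with("item_"))
  expect_true(all(as.matrix(healthy_items) == 0L))
  # reproducibility
  clin2 <- gen_ck_and_scores(list(cohort_spec("grmd_treated", 4),
                                  cohort_spec("grmd_ctrl", 4),
                                  cohort_spec("healthy", 3)), seed = 21)
  expect_identical(clin$ck, clin2$ck)
  expect_identical(clin$scores, clin2$scores)
})
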