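# End-to-end study simulation and reporting: generate a synthetic cohort,
# run every quantification module, and compute the group statistics.

# Per-group force-trace ground-truth parameters. Treated dogs: lower plateau
# (atrophy), heavier body weight (overweight under treatment), faster and
# more complete relaxation, steeper fatigue decline. Fatigue ratio r gives a
# 40-tetanus fatigue index of 100 * r^39.
force_param_table <- function() {
  list(
    healthy = list(plateau = c(45, 5), bw = c(12, 1), relax_tau = 0.11,
                   residual_frac = 0.01, fatigue_ratio = 0.85^(1 / 39)),
    grmd_ctrl = list(plateau = c(25, 4), bw = c(10, 1), relax_tau = 0.18,
                     residual_frac = 0.08, fatigue_ratio = 0.70^(1 / 39)),
    grmd_treated = list(plateau = c(16, 3), bw = c(12, 1.2), relax_tau = 0.08,
                        residual_frac = 0.005, fatigue_ratio = 0.45^(1 / 39))
  )
}

# Per-group histology generator parameters. Treated biopsies: many more
# calcified fibers, smaller fibers, fewer slow-type fibers; pathological
# index and fibrosis essentially unchanged.
histology_param_table <- function() {
  list(
    healthy = list(fiber_diameter_um = 55, n_moderate = 0, n_severe = 0,
                   slow_fraction = 0.30, collagen_fraction = 0.05,
                   lesions = c(abnormal_fiber = 0.02, connective = 0.02,
                               inflammatory = 0.005, adipose = 0.005,
                               other_structure = 0, artifact = 0)),
    grmd_ctrl = list(fiber_diameter_um = 42, n_moderate = 6, n_severe = 2,
                     slow_fraction = 0.30, collagen_fraction = 0.20,
                     lesions = c(abnormal_fiber = 0.20, connective = 0.08,
                                 inflammatory = 0.04, adipose = 0.01,
                                 other_structure = 0, artifact = 0)),
    grmd_treated = list(fiber_diameter_um = 32, n_moderate = 25, n_severe = 10,
                        slow_fraction = 0.12, collagen_fraction = 0.20,
                        lesions = c(abnormal_fiber = 0.20, connective = 0.08,
                                    inflammatory = 0.04, adipose = 0.01,
                                    other_structure = 0, artifact = 0))
  )
}

#' Pipeline configuration
#'
#' Problem sizes and options of the demo study scenario. Defaults mirror the
#' study design (treated cohort followed 2-9 months; untreated GRMD and
#' healthy controls; adult reference cohorts of 18 GRMD + 11 healthy dogs
#' for the gait PCA) at desk-scale section sizes.
#'
#' @param n_treated,n_ctrl,n_healthy Dogs per group in the longitudinal
#'   cohorts.
#' @param n_ref_grmd,n_ref_healthy Adult reference cohort sizes for the PCA.
#' @param gait_ages Gait session ages, months.
#' @param score_timepoints Ages at which group comparisons are run, months.
#' @param biopsy_ages Histology timepoints, months.
#' @param sections_per_group Biopsies per group per timepoint.
#' @param n_force_dogs Dogs per group undergoing force measurement (both
#'   sides each).
#' @param section_size_px,atpase_size_px Section raster sizes.
#' @param alpha Significance level for all comparisons.
#' @param make_figures Write figure PNGs when an output directory is given.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(n_treated = 5, n_ctrl = 8, n_healthy = 8,
                            n_ref_grmd = 18, n_ref_healthy = 11,
                            gait_ages = seq(2, 9, by = 0.5),
                            score_timepoints = 2:9,
                            biopsy_ages = c(6, 9),
                            sections_per_group = 2,
                            n_force_dogs = 3,
                            section_size_px = 320,
                            atpase_size_px = 512,
                            alpha = 0.05,
                            make_figures = TRUE) {
  structure(as.list(environment()), class = "pipeline_config")
}

histology_metrics_one <- function(group, age, rep, size_px, atpase_px, seed) {
  hp <- histology_param_table()[[group]]
  # per-biopsy variability around the group parameters
  hp <- with_seed(sub_seed(seed, 99), {
    hp$n_moderate <- rpois(1, hp$n_moderate)
    hp$n_severe <- rpois(1, hp$n_severe)
    hp$fiber_diameter_um <- max(15, rnorm(1, hp$fiber_diameter_um, 2))
    hp$slow_fraction <- min(0.95, max(0.01, rnorm(1, hp$slow_fraction, 0.03)))
    hp$collagen_fraction <- min(0.9, max(0.01, rnorm(1, hp$collagen_fraction, 0.03)))
    hp$lesions[["abnormal_fiber"]] <-
      min(0.6, max(0, rnorm(1, hp$lesions[["abnormal_fiber"]], 0.03)))
    hp
  })
  # H&E: pathological index by point counting
  he <- gen_section("he", size_px = size_px, um_per_px = 3,
                    fiber_diameter_um = hp$fiber_diameter_um,
                    lesion_fractions = hp$lesions, seed = sub_seed(seed, 1))
  pc <- classify_intercepts(he$section, overlay_grid(he$section),
                            truth = he$truth)
  path_idx <- pathological_index(pc)
  # picrosirius: fibrosis fraction
  psr <- gen_section("psr", size_px = size_px, um_per_px = 3,
                     collagen_fraction = hp$collagen_fraction,
                     seed = sub_seed(seed, 2))
  fib <- fibrosis_fraction(psr$section)
  # alizarin: calcified counts normalized by the extrapolated fiber total
  ars <- gen_section("ars", size_px = size_px, um_per_px = 3,
                     fiber_diameter_um = hp$fiber_diameter_um,
                     n_moderate = hp$n_moderate, n_severe = hp$n_severe,
                     seed = sub_seed(seed, 3))
  cc <- count_calcified(ars$section)
  ff <- sample_fiber_fields(ars$truth, seed = sub_seed(seed, 4))
  n_tot <- estimate_total_fibers(ff$counts, ff$field_area_um2,
                                 section_area_um2(ars$section))
  calc <- calcification_result(cc$n_moderate, cc$n_severe, n_tot)
  # ATPase: fiber morphometry
  atp <- gen_section("atpase", size_px = atpase_px, um_per_px = 2,
                     fiber_diameter_um = hp$fiber_diameter_um,
                     seed = sub_seed(seed, 5))
  fm <- fiber_morphometry(segment_fibers(atp$section))
  # slow-myosin immunostain: zone-sampled positive fraction
  mhc <- gen_section("mhc", size_px = atpase_px, um_per_px = 2,
                     fiber_diameter_um = hp$fiber_diameter_um,
                     slow_fraction = hp$slow_fraction,
                     seed = sub_seed(seed, 6))
  zc <- sample_slow_zones(mhc$truth, seed = sub_seed(seed, 7))
  slow_pct <- slow_fiber_fraction(zc)
  # CD immunostains: cell densities from the whole section
  cd <- gen_section("cd", size_px = size_px, um_per_px = 3,
                    seed = sub_seed(seed, 8))
  dens <- immune_cell_density(cd$truth$immune_points,
                              section_area_um2(cd$section) / 1e6)
  tibble(
    group = group, age_months = age, biopsy = rep,
    pathological_index = path_idx,
    fibrosis_fraction = fib,
    calcified_fraction_pct = calc$fraction_total * 100,
    n_calcified_moderate = cc$n_moderate,
    n_calcified_severe = cc$n_severe,
    mean_fiber_diameter_um = fm$mean_diameter_um,
    fiber_diameter_cv = fm$cv,
    slow_fiber_pct = slow_pct,
    cd4_per_mm2 = dens$density_per_mm2[dens$marker == "CD4"],
    cd8_per_mm2 = dens$density_per_mm2[dens$marker == "CD8"],
    cd11b_per_mm2 = dens$density_per_mm2[dens$marker == "CD11b"]
  )
}

force_metrics_cohort <- function(groups, n_dogs, seed,
                                 protocol = force_protocol()) {
  fp <- force_param_table()
  rows <- list()
  for (g in groups) {
    p <- fp[[g]]
    for (d in seq_len(n_dogs)) {
      s_dog <- sub_seed(seed, match(g, names(fp)) * 100 + d)
      par <- with_seed(s_dog, list(
        plateau = max(1, rnorm(1, p$plateau[1], p$plateau[2])),
        bw = max(4, rnorm(1, p$bw[1], p$bw[2])),
        side_fac = c(left = 1, right = exp(rnorm(1, 0.02, 0.01)))
      ))
      for (side in c("left", "right")) {
        tr <- trace_truth(par$plateau * par$side_fac[[side]],
                          relax_tau = p$relax_tau,
                          residual_offset = p$residual_frac * par$plateau,
                          noise_sd = 0.15,
                          fatigue_ratio = p$fatigue_ratio)
        ses <- gen_force_session(tr, protocol, body_weight = par$bw,
                                 side = side,
                                 seed = sub_seed(s_dog, match(side, c("left", "right"))))
        rows[[length(rows) + 1]] <- dplyr::bind_cols(
          tibble(dog_id = sprintf("%s_f%02d", g, d), group = g),
          force_session_summary(ses)
        )
      }
    }
  }
  dplyr::bind_rows(rows)
}

#' Run the full phenotyping pipeline on a synthetic study
#'
#' Generates the demo scenario (treated GRMD, untreated GRMD and healthy
#' cohorts with the study's group trajectories), runs every quantification
#' module (histology, force, gait/GQI, motor score, CK), computes the group
#' statistics, and optionally writes metrics CSVs, comparison tables and
#' figures to `out_dir`. Deterministic for a fixed config and seed.
#'
#' @param config A [pipeline_config()].
#' @param seed Integer master seed.
#' @param out_dir Output directory (`NULL` = return results only).
#' @return Invisibly, a list: `ck`, `motor`, `gait` (with GQI), `force`,
#'   `histology` tibbles; `stats` (list of comparison tables); `reference`
#'   (the fitted gait PCA); `config`; `seed`.
#' @export
run_pipeline <- function(config = pipeline_config(), seed = 1L,
                         out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  log_lines <- c(sprintf("grmdpheno %s | seed %d | %s",
                         as.character(utils::packageVersion("grmdpheno")),
                         seed, format(Sys.time(), "%Y-%m-%d %H:%M:%S")))
  say <- function(fmt, ...) {
    log_lines <<- c(log_lines, sprintf(fmt, ...))
  }

  # --- clinical + biochemical cohorts -----------------------------------
  specs <- list(
    cohort_spec("grmd_treated", config$n_treated),
    cohort_spec("grmd_ctrl", config$n_ctrl),
    cohort_spec("healthy", config$n_healthy)
  )
  clin <- gen_ck_and_scores(specs, seed = sub_seed(seed, 11))
  motor <- motor_total(clin$scores)
  say("clinical: %d CK samples, %d score sheets", nrow(clin$ck), nrow(motor))

  ck_stats <- timepoint_scan(
    dplyr::rename(clin$ck, value = "ck_ui_l"), "value",
    config$score_timepoints, alpha = config$alpha
  )
  ck_stats$variable <- "ck_ui_l"
  motor_stats <- timepoint_scan(
    dplyr::rename(motor, value = "percent"), "value",
    config$score_timepoints, alpha = config$alpha
  )
  motor_stats$variable <- "motor_score_pct"

  # --- gait: reference plane, supplementary projection, GQI -------------
  ref_records <- gen_gait_cohort(list(
    cohort_spec("healthy", config$n_ref_healthy),
    cohort_spec("grmd_ctrl", config$n_ref_grmd)
  ), seed = sub_seed(seed, 21))
  reference <- fit_reference(ref_records)
  say("gait reference: %d records, component variances %.1f%% / %.1f%%",
      reference$n_ref, 100 * reference$explained[1],
      100 * reference$explained[2])

  eval_records <- gen_gait_cohort(list(
    cohort_spec("grmd_treated", config$n_treated, ages = config$gait_ages),
    cohort_spec("grmd_ctrl", config$n_ctrl, ages = config$gait_ages),
    cohort_spec("healthy", config$n_healthy, ages = config$gait_ages)
  ), seed = sub_seed(seed, 22))
  gait <- gqi(reference, project_supplementary(reference, eval_records))
  gait$force_index <- force_index(eval_records)
  gqi_stats <- timepoint_scan(
    dplyr::rename(gait, value = "gqi"), "value",
    config$score_timepoints, alpha = config$alpha
  )
  gqi_stats$variable <- "gqi"

  # --- in vivo force -----------------------------------------------------
  force <- force_metrics_cohort(c("grmd_treated", "grmd_ctrl"),
                                config$n_force_dogs,
                                seed = sub_seed(seed, 31))
  say("force: %d sessions", nrow(force))
  force_long <- tidyr::pivot_longer(
    force, c("relative_force_n_kg", "fatigue_index_pct", "r100_pct",
             "residual_contraction_pct"),
    names_to = "variable", values_to = "value"
  )
  force_stats <- force_long |>
    dplyr::group_by(.data$variable) |>
    dplyr::group_modify(function(d, key) {
      mixed_anova_side(d, alpha = config$alpha)
    }) |>
    dplyr::ungroup()

  # --- histology ---------------------------------------------------------
  hist_rows <- list()
  for (age in config$biopsy_ages) {
    for (g in c("grmd_treated", "grmd_ctrl")) {
      for (r in seq_len(config$sections_per_group)) {
        hist_rows[[length(hist_rows) + 1]] <- histology_metrics_one(
          g, age, r, config$section_size_px, config$atpase_size_px,
          seed = sub_seed(seed, 41 + 1000 * age + 100 * r +
                            match(g, c("grmd_treated", "grmd_ctrl")))
        )
      }
    }
  }
  histology <- dplyr::bind_rows(hist_rows)
  say("histology: %d biopsies quantified", nrow(histology))

  hist_vars <- c("pathological_index", "fibrosis_fraction",
                 "calcified_fraction_pct", "mean_fiber_diameter_um",
                 "slow_fiber_pct")
  hist_stats <- dplyr::bind_rows(lapply(config$biopsy_ages, function(age) {
    dplyr::bind_rows(lapply(hist_vars, function(v) {
      a <- histology[[v]][histology$group == "grmd_treated" &
                            histology$age_months == age]
      b <- histology[[v]][histology$group == "grmd_ctrl" &
                            histology$age_months == age]
      if (length(a) < 2 || length(b) < 2) return(NULL)
      two_group_t(a, b, alpha = config$alpha, variable = v, timepoint = age)
    }))
  }))

  stats <- list(ck = ck_stats, motor = motor_stats, gqi = gqi_stats,
                force = force_stats, histology = hist_stats)
  res <- list(ck = clin$ck, motor = motor, gait = gait, force = force,
              histology = histology, stats = stats, reference = reference,
              config = config, seed = seed)

  if (!is.null(out_dir)) {
    write_report_bundle(res, out_dir, log_lines)
  }
  invisible(res)
}

#' Treated-versus-control effect directions from a pipeline run
#'
#' Summarizes, from a [run_pipeline()] result, the group means of the
#' headline variables at the 6-month evaluation point (CK, motor score, GQI,
#' relative force, fatigue index, calcified-fiber fraction, mean fiber
#' diameter, slow-fiber percentage) and the sign of the treated-minus-control
#' difference.
#'
#' @param res A [run_pipeline()] result.
#' @return Tibble with `variable`, `mean_treated`, `mean_ctrl`, `direction`
#'   (sign of treated minus control).
#' @export
treatment_effect_summary <- function(res) {
  gm <- function(data, var, group, age = NULL) {
    sel <- data$group == group
    if (!is.null(age)) sel <- sel & abs(data$age_months - age) <= 0.5
    mean(data[[var]][sel])
  }
  vars <- list(
    ck_ui_l = function(g) gm(res$ck, "ck_ui_l", g, 6),
    motor_score_pct = function(g) gm(res$motor, "percent", g, 6),
    gqi = function(g) gm(res$gait, "gqi", g, 6),
    relative_force_n_kg = function(g) gm(res$force, "relative_force_n_kg", g),
    fatigue_index_pct = function(g) gm(res$force, "fatigue_index_pct", g),
    calcified_fraction_pct = function(g)
      gm(res$histology, "calcified_fraction_pct", g, 6),
    mean_fiber_diameter_um = function(g)
      gm(res$histology, "mean_fiber_diameter_um", g, 6),
    slow_fiber_pct = function(g) gm(res$histology, "slow_fiber_pct", g, 6)
  )
  dplyr::bind_rows(lapply(names(vars), function(v) {
    a <- vars[[v]]("grmd_treated")
    b <- vars[[v]]("grmd_ctrl")
    tibble(variable = v, mean_treated = a, mean_ctrl = b,
           direction = sign(a - b))
  }))
}

write_report_bundle <- function(res, out_dir, log_lines) {
  dir.create(file.path(out_dir, "metrics"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(out_dir, "stats"), showWarnings = FALSE)
  wr <- function(x, sub, name) {
    write.csv(x, file.path(out_dir, sub, paste0(name, ".csv")),
              row.names = FALSE)
  }
  wr(res$ck, "metrics", "ck")
  wr(res$motor, "metrics", "motor_scores")
  wr(res$gait, "metrics", "gait_gqi")
  wr(res$force, "metrics", "force")
  wr(res$histology, "metrics", "histology")
  for (nm in names(res$stats)) wr(res$stats[[nm]], "stats", nm)
  write_reference_json(res$reference,
                       file.path(out_dir, "metrics", "gait_reference.json"))

  if (isTRUE(res$config$make_figures)) {
    dir.create(file.path(out_dir, "figures"), showWarnings = FALSE)
    save_fig <- function(p, name, w = 6, h = 4) {
      ggplot2::ggsave(file.path(out_dir, "figures", paste0(name, ".png")),
                      p, width = w, height = h, dpi = 120)
    }
    save_fig(plot_trajectory(res$ck, "ck_ui_l", log_y = TRUE) +
               ggplot2::labs(y = "serum CK (UI/L)"), "ck_trajectory")
    save_fig(plot_trajectory(res$motor, "percent") +
               ggplot2::labs(y = "motor score (% of 22)"), "motor_trajectory")
    save_fig(plot_trajectory(res$gait, "gqi") +
               ggplot2::labs(y = "gait quality index"), "gqi_trajectory")
    save_fig(plot_reference_plane(res$reference, res$gait), "pca_plane", 6, 5)
  }
  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(out_dir)
}

#' Group-mean trajectory plot of a longitudinal variable
#'
#' @param data Tibble with `group`, `age_months` and the plotted column.
#' @param var Column name to plot.
#' @param log_y Use a log10 y scale.
#' @return A ggplot object.
#' @export
plot_trajectory <- function(data, var, log_y = FALSE) {
  summ <- data |>
    dplyr::group_by(.data$group, .data$age_months) |>
    dplyr::summarise(m = mean(.data[[var]]), s = sd(.data[[var]]),
                     .groups = "drop")
  p <- ggplot2::ggplot(summ, ggplot2::aes(.data$age_months, .data$m,
                                          colour = .data$group,
                                          fill = .data$group)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$m - .data$s,
                                      ymax = .data$m + .data$s),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "age (months)") +
    ggplot2::theme_minimal()
  if (log_y) p <- p + ggplot2::scale_y_log10()
  p
}

#' Reference-plane scatter with projected individuals
#'
#' @param model A `gait_reference`.
#' @param coords Projected records with `pc1`, `pc2`, `group`.
#' @return A ggplot object.
#' @export
plot_reference_plane <- function(model, coords) {
  cen <- tibble(
    group = names(model$centroids),
    pc1 = vapply(model$centroids, `[`, numeric(1), 1),
    pc2 = vapply(model$centroids, `[`, numeric(1), 2)
  )
  ggplot2::ggplot(coords, ggplot2::aes(.data$pc1, .data$pc2,
                                       colour = .data$group)) +
    ggplot2::geom_point(alpha = 0.5, size = 1) +
    ggplot2::geom_point(data = cen, shape = 4, size = 4, stroke = 2) +
    ggplot2::labs(
      x = sprintf("component 1 (%.1f%%)", 100 * model$explained[1]),
      y = sprintf("component 2 (%.1f%%)", 100 * model$explained[2])
    ) +
    ggplot2::theme_minimal()
}

#' Calcified-fiber fractions from counts and an estimated fiber total
#'
#' @param n_moderate,n_severe Manual counts of moderately / severely
#'   overloaded fibers.
#' @param n_total_est Estimated total fiber count of the section (> 0).
#' @return List with the counts, `n_total_est`, and `fraction_moderate`,
#'   `fraction_severe`, `fraction_total` (counts / total).
#' @export
calcification_result <- function(n_moderate, n_severe, n_total_est) {
  if (n_total_est <= 0) {
    stop_grmd("division_error", "estimated fiber total must be > 0")
  }
  list(
    n_moderate = n_moderate, n_severe = n_severe, n_total_est = n_total_est,
    fraction_moderate = n_moderate / n_total_est,
    fraction_severe = n_severe / n_total_est,
    fraction_total = (n_moderate + n_severe) / n_total_est
  )
}

#' Sample random fields of a section and count fibers per field
#'
#' Used for the total-fiber extrapolation: draws `n_fields` random square
#' fields jointly covering about `total_frac` of the section area and counts
#' fibers by centroid location.
#'
#' @param truth A `grmd_section_truth` with fiber labels.
#' @param n_fields Number of fields (default 5).
#' @param total_frac Fraction of the section area covered by all fields
#'   together (default 0.06).
#' @param seed Integer seed.
#' @return List with `counts` (per field), `field_area_um2` (each field) and
#'   `true_total` (the section's true fiber count).
#' @export
sample_fiber_fields <- function(truth, n_fields = 5, total_frac = 0.06,
                                seed = 1L) {
  stopifnot(inherits(truth, "grmd_section_truth"))
  d <- dim(truth$fiber_labels)
  idx <- which(truth$fiber_labels > 0L)
  fib <- truth$fiber_labels[idx]
  cy <- tapply((idx - 1L) %% d[1] + 1L, fib, mean)
  cx <- tapply((idx - 1L) %/% d[1] + 1L, fib, mean)
  side <- round(sqrt(total_frac / n_fields) * sqrt(d[1] * d[2]))
  with_seed(seed, {
    counts <- vapply(seq_len(n_fields), function(f) {
      x0 <- sample.int(d[2] - side, 1)
      y0 <- sample.int(d[1] - side, 1)
      sum(cx >= x0 & cx < x0 + side & cy >= y0 & cy < y0 + side)
    }, numeric(1))
    list(counts = counts,
         field_area_um2 = rep(side^2 * truth$scale^2, n_fields),
         true_total = length(cx))
  })
}
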