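# Synthetic cohorts: gait variables, serum CK trajectories, motor scores,
# and the per-group parameter tables that define the simulated study
# conditions (healthy, untreated GRMD, immunosuppressed GRMD).

.groups <- c("healthy", "grmd_ctrl", "grmd_treated")

# Fraction of the GRMD-to-healthy span covered by treated dogs once the
# treatment effect is established (implied by the reported group GQI means:
# (3.62 - 2.09) / (3.62 - 0.78) ~ 0.54 of the way back towards healthy).
.treated_blend <- 0.54

# Primitive gait parameters per group (adult / established phenotype).
# stride_len_norm is stride length / height at withers; rel_* are relative
# axial powers (dorso-ventral, cranio-caudal, medio-lateral); total_power in
# W/kg-equivalent accelerometric units; regularity is the dimensionless
# Locometrix-style regularity score.
gait_param_table <- function() {
  list(
    healthy = list(
      mean = c(stride_freq = 2.0, stride_len_norm = 1.80, regularity = 280,
               total_power = 12, rel_dv = 0.55, rel_cc = 0.30, rel_ml = 0.15,
               height = 0.55),
      sd = c(stride_freq = 0.18, stride_len_norm = 0.15, regularity = 25,
             total_power = 1.8, rel_dv = 0.05, rel_cc = 0.04, rel_ml = 0.03,
             height = 0.03)
    ),
    grmd_ctrl = list(
      mean = c(stride_freq = 2.35, stride_len_norm = 1.00, regularity = 170,
               total_power = 4.5, rel_dv = 0.33, rel_cc = 0.32, rel_ml = 0.35,
               height = 0.50),
      sd = c(stride_freq = 0.25, stride_len_norm = 0.14, regularity = 35,
             total_power = 1.1, rel_dv = 0.06, rel_cc = 0.05, rel_ml = 0.06,
             height = 0.03)
    )
  )
}

# Group means at a given age. Treated dogs start on the GRMD trajectory and
# drift towards an intermediate position between 3 and 5 months of age,
# where they remain (blend fraction .treated_blend).
group_gait_params <- function(group, age_months = NULL) {
  tab <- gait_param_table()
  if (group == "healthy") return(tab$healthy)
  if (group == "grmd_ctrl") return(tab$grmd_ctrl)
  if (group != "grmd_treated") {
    stop_grmd("invalid_spec", "unknown group '%s'", group)
  }
  lambda <- if (is.null(age_months)) .treated_blend else {
    pmin(pmax((age_months - 3) / 2, 0), 1) * .treated_blend
  }
  m <- tab$grmd_ctrl$mean + lambda * (tab$healthy$mean - tab$grmd_ctrl$mean)
  s <- tab$grmd_ctrl$sd + lambda * (tab$healthy$sd - tab$grmd_ctrl$sd)
  list(mean = m, sd = s)
}

# Height at withers during growth: linear to ~8 months, capped at the adult
# value; GRMD dogs show mild growth retardation.
height_at_age <- function(adult_height, age_months) {
  if (is.null(age_months)) return(adult_height)
  adult_height * pmin(0.45 + 0.07 * age_months, 1)
}

#' Specify one synthetic cohort
#'
#' @param group `"healthy"`, `"grmd_ctrl"` or `"grmd_treated"`.
#' @param n_dogs Number of dogs (>= 1).
#' @param ages Session ages in months (`NULL` = single adult session).
#' @param params Optional list with named `mean` and `sd` vectors overriding
#'   the group defaults (see `grmdpheno:::gait_param_table` for names).
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(group, n_dogs, ages = NULL, params = NULL) {
  group <- match.arg(group, .groups)
  if (!is.numeric(n_dogs) || n_dogs < 1) {
    stop_grmd("invalid_spec", "n_dogs must be >= 1")
  }
  if (!is.null(params)) {
    if (any(params$sd < 0)) stop_grmd("invalid_spec", "all SDs must be >= 0")
  }
  structure(list(group = group, n_dogs = as.integer(n_dogs), ages = ages,
                 params = params),
            class = "cohort_spec")
}

#' Generate a synthetic gait-variable cohort
#'
#' Draws per-dog, per-session gait records from per-group Gaussian
#' distributions of the primitive variables (stride frequency, normalized
#' stride length, regularity, total power, relative axial powers, height at
#' withers). Relative powers are renormalized to sum to one; raw axial powers
#' are `relative x total power`; stride length is `normalized x height` and
#' speed is `stride length x stride frequency`, so each row is internally
#' consistent.
#'
#' @param specs A [cohort_spec()] or list of them.
#' @param seed Integer seed.
#' @return Tibble with one row per dog per session: `dog_id`, `group`,
#'   `age_months`, `speed_ms`, `stride_freq_hz`, `stride_len_m`,
#'   `regularity`, `power_dv`, `power_cc`, `power_ml`, `total_power`,
#'   `height_m`.
#' @export
gen_gait_cohort <- function(specs, seed = 1L) {
  if (inherits(specs, "cohort_spec")) specs <- list(specs)
  stopifnot(all(vapply(specs, inherits, logical(1), "cohort_spec")))
  with_seed(seed, {
    rows <- lapply(seq_along(specs), function(si) {
      sp <- specs[[si]]
      ages <- sp$ages %||% NA_real_
      out <- vector("list", sp$n_dogs * length(ages))
      k <- 0
      for (d in seq_len(sp$n_dogs)) {
        dog <- sprintf("%s_%02d", sp$group, d)
        # dog-level consistent height draw
        adult_h <- NULL
        for (a in ages) {
          pr <- sp$params %||%
            group_gait_params(sp$group, if (is.na(a)) NULL else a)
          mu <- pr$mean; sdv <- pr$sd
          if (is.null(adult_h)) adult_h <- rnorm(1, mu[["height"]], sdv[["height"]])
          h <- height_at_age(adult_h, if (is.na(a)) NULL else a)
          sln <- max(0.05, rnorm(1, mu[["stride_len_norm"]], sdv[["stride_len_norm"]]))
          freq <- max(0.2, rnorm(1, mu[["stride_freq"]], sdv[["stride_freq"]]))
          reg <- max(1, rnorm(1, mu[["regularity"]], sdv[["regularity"]]))
          tot <- max(0.2, rnorm(1, mu[["total_power"]], sdv[["total_power"]]))
          rel <- c(rnorm(1, mu[["rel_dv"]], sdv[["rel_dv"]]),
                   rnorm(1, mu[["rel_cc"]], sdv[["rel_cc"]]),
                   rnorm(1, mu[["rel_ml"]], sdv[["rel_ml"]]))
          rel <- pmax(rel, 0.01)
          rel <- rel / sum(rel)
          len <- sln * h
          k <- k + 1
          out[[k]] <- tibble(
            dog_id = dog, group = sp$group, age_months = a,
            speed_ms = len * freq, stride_freq_hz = freq, stride_len_m = len,
            regularity = reg,
            power_dv = rel[1] * tot, power_cc = rel[2] * tot,
            power_ml = rel[3] * tot, total_power = tot, height_m = h
          )
        }
      }
      dplyr::bind_rows(out)
    })
    dplyr::bind_rows(rows)
  })
}

# CK trajectory parameters (UI/L). Log-normal noise: CK spans orders of
# magnitude and cannot be negative. meanlog trajectories interpolate the
# group means; sdlog split into a dog-level and a week-level component.
ck_param_table <- function() {
  list(
    healthy = list(mean = c(`2` = 200, `4` = 200, `6` = 200, `9` = 200),
                   sdlog_dog = 0.35, sdlog_week = 0.15),
    grmd_ctrl = list(mean = c(`2` = 24000, `4` = 26000, `6` = 27326.7, `9` = 25000),
                     sdlog_dog = 0.60, sdlog_week = 0.25),
    grmd_treated = list(mean = c(`2` = 24000, `4` = 1600, `6` = 1445.8, `9` = 1500),
                        sdlog_dog = 0.68, sdlog_week = 0.28)
  )
}

# Motor-score trajectory: group mean total score as a percentage of 22.
motor_param_table <- function() {
  list(
    healthy = list(mean = c(`2` = 0, `4` = 0, `6` = 0, `9` = 0), sd = 0),
    grmd_ctrl = list(mean = c(`2` = 28, `4` = 48, `6` = 63.8, `9` = 72), sd = 20),
    grmd_treated = list(mean = c(`2` = 28, `4` = 34, `6` = 32.6, `9` = 35), sd = 15.7)
  )
}

interp_traj <- function(tab, ages) {
  knots <- as.numeric(names(tab))
  stats::approx(knots, as.numeric(tab), xout = pmin(pmax(ages, min(knots)),
                                                    max(knots)))$y
}

#' Generate longitudinal serum CK and motor-score tables
#'
#' CK is sampled weekly and motor scores monthly over the 2-9 month study
#' window. CK values are strictly positive (log-normal noise with a dog-level
#' and a week-level component); healthy motor-score sheets are all-zero.
#' Motor-score sheets carry 11 items each scored 0-2; the per-dog target
#' total (group trajectory mean plus Gaussian dog noise, clamped to
#' `[0, 22]`) is distributed randomly over items.
#'
#' @param specs A [cohort_spec()] or list of them.
#' @param seed Integer seed.
#' @return List with `ck` (tibble `dog_id`, `group`, `age_months`,
#'   `ck_ui_l`) and `scores` (tibble `dog_id`, `group`, `age_months`,
#'   `item_01` ... `item_11`).
#' @export
gen_ck_and_scores <- function(specs, seed = 1L) {
  if (inherits(specs, "cohort_spec")) specs <- list(specs)
  ck_tab <- ck_param_table()
  mo_tab <- motor_param_table()
  week <- 7 / 30.44
  ck_ages <- seq(2, 9, by = week)
  score_ages <- 2:9
  with_seed(seed, {
    ck_rows <- list(); sc_rows <- list()
    for (sp in specs) {
      ckp <- ck_tab[[sp$group]]
      mop <- mo_tab[[sp$group]]
      mu_ck <- log(interp_traj(ckp$mean, ck_ages)) -
        (ckp$sdlog_dog^2 + ckp$sdlog_week^2) / 2
      mu_mo <- interp_traj(mop$mean, score_ages)
      for (d in seq_len(sp$n_dogs)) {
        dog <- sprintf("%s_%02d", sp$group, d)
        z_dog <- rnorm(1)
        ck <- exp(mu_ck + ckp$sdlog_dog * z_dog +
                    rnorm(length(ck_ages), 0, ckp$sdlog_week))
        ck_rows[[length(ck_rows) + 1]] <- tibble(
          dog_id = dog, group = sp$group, age_months = ck_ages, ck_ui_l = ck
        )
        dog_shift <- rnorm(1, 0, mop$sd)
        for (ai in seq_along(score_ages)) {
          pct <- mu_mo[ai] + dog_shift + rnorm(1, 0, mop$sd / 3)
          total <- if (sp$group == "healthy") 0L else {
            as.integer(pmin(22, pmax(0, round(pct / 100 * 22))))
          }
          items <- distribute_items(total)
          sc_rows[[length(sc_rows) + 1]] <- tibble(
            dog_id = dog, group = sp$group, age_months = score_ages[ai],
            !!!setNames(as.list(items), sprintf("item_%02d", 1:11))
          )
        }
      }
    }
    list(ck = dplyr::bind_rows(ck_rows), scores = dplyr::bind_rows(sc_rows))
  })
}

# Randomly distribute `total` points over 11 items capped at 2 each.
distribute_items <- function(total) {
  items <- integer(11)
  while (sum(items) < total) {
    open <- which(items < 2L)
    pick <- if (length(open) == 1L) open else sample(open, 1)
    items[pick] <- items[pick] + 1L
  }
  items
}
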