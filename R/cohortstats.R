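# Group-comparison statistics: pooled-variance t tests per timepoint and the
# repeated-measures ANOVA with side (left/right) as the within-subject
# factor.

#' Two-group comparison by Student t test
#'
#' Two-sided two-sample t test, pooled-variance by default (the classical
#' Student dialect); a Welch variant is available behind `var_equal =
#' FALSE`. Significance is declared at `p <= alpha`.
#'
#' @param a,b Numeric vectors of per-dog values (>= 2 each).
#' @param alpha Significance level (default 0.05).
#' @param var_equal Pooled-variance test if `TRUE` (default), Welch
#'   otherwise.
#' @param variable,timepoint Optional labels carried into the result.
#' @return One-row tibble (a group comparison): group means/SDs/n, `statistic`
#'   (t), `df`, `p_value`, `significant`.
#' @export
two_group_t <- function(a, b, alpha = 0.05, var_equal = TRUE,
                        variable = NA_character_, timepoint = NA_real_) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2) {
    stop_grmd("insufficient_n",
              "each group needs n >= 2 (got %d and %d)", length(a), length(b))
  }
  tt <- t.test(a, b, var.equal = var_equal)
  tibble(
    variable = variable, timepoint = timepoint,
    mean_a = mean(a), sd_a = sd(a), n_a = length(a),
    mean_b = mean(b), sd_b = sd(b), n_b = length(b),
    statistic = unname(tt$statistic), df = unname(tt$parameter),
    p_value = tt$p.value, significant = tt$p.value <= alpha
  )
}

#' Repeated-measures ANOVA with side as the within-subject factor
#'
#' Left and right measurements of each dog are the within-subject factor;
#' the dog's group is the between-subject factor. The reported p-value is
#' the group main effect, tested against the between-dog stratum.
#'
#' @param data Tibble with columns `dog_id`, `group`, `side`, `value`; every
#'   dog must have both sides.
#' @param alpha Significance level.
#' @return One-row tibble with the group main-effect `statistic` (F), `df1`,
#'   `df2`, `p_value`, `significant`, plus the side-effect p-value
#'   (`p_side`).
#' @export
mixed_anova_side <- function(data, alpha = 0.05) {
  req <- c("dog_id", "group", "side", "value")
  stopifnot(all(req %in% names(data)))
  sides <- tapply(data$side, data$dog_id, function(s) length(unique(s)))
  if (any(sides < 2)) {
    stop_grmd("incomplete_pair", "dogs missing one side: %s",
              paste(names(sides)[sides < 2], collapse = ", "))
  }
  d <- data.frame(
    y = data$value,
    group = factor(data$group),
    side = factor(data$side),
    dog = factor(data$dog_id)
  )
  fit <- aov(y ~ group * side + Error(dog / side), data = d)
  s <- summary(fit)
  between <- s[["Error: dog"]][[1]]
  within <- s[["Error: dog:side"]][[1]]
  gi <- grep("^group\\s*$", rownames(between))
  si <- grep("^side\\s*$", rownames(within))
  tibble(
    effect = "group",
    statistic = between[gi, "F value"],
    df1 = between[gi, "Df"],
    df2 = between[nrow(between), "Df"],
    p_value = between[gi, "Pr(>F)"],
    significant = between[gi, "Pr(>F)"] <= alpha,
    p_side = within[si, "Pr(>F)"]
  )
}

#' Per-timepoint two-group scan of a longitudinal variable
#'
#' Runs a pooled-variance t test between two groups at each timepoint, with
#' per-dog averaging inside an age window around the timepoint. No
#' multiplicity correction is applied to `p_value`; a Holm-adjusted column
#' (`p_holm`) is emitted alongside as supplementary information.
#'
#' @param data Long tibble with `dog_id`, `group`, `age_months` and the
#'   value column named by `variable`.
#' @param variable Name of the value column.
#' @param timepoints Numeric vector of ages (months) to test at.
#' @param groups Length-2 character vector: the two groups to compare
#'   (difference reported as first minus second).
#' @param window Half-width of the per-timepoint age window, months
#'   (default 0.5, i.e. +/- 2 weeks).
#' @param alpha Significance level.
#' @return Tibble of comparisons (one row per testable timepoint) with a
#'   `p_holm` column appended. Timepoints where either group has fewer than
#'   two dogs are skipped with a warning.
#' @export
timepoint_scan <- function(data, variable, timepoints,
                           groups = c("grmd_treated", "grmd_ctrl"),
                           window = 0.5, alpha = 0.05) {
  stopifnot(variable %in% names(data), length(groups) == 2)
  rows <- list()
  for (tp in timepoints) {
    sel <- data$age_months >= tp - window & data$age_months <= tp + window &
      data$group %in% groups
    d <- data[sel, ]
    if (nrow(d) == 0) {
      warning(sprintf("timepoint %.1f months: no data, skipped", tp))
      next
    }
    per_dog <- d |>
      dplyr::group_by(.data$group, .data$dog_id) |>
      dplyr::summarise(v = mean(.data[[variable]]), .groups = "drop")
    va <- per_dog$v[per_dog$group == groups[1]]
    vb <- per_dog$v[per_dog$group == groups[2]]
    if (length(va) < 2 || length(vb) < 2) {
      warning(sprintf("timepoint %.1f months: fewer than 2 dogs per group, skipped",
                      tp))
      next
    }
    rows[[length(rows) + 1]] <-
      two_group_t(va, vb, alpha = alpha, variable = variable, timepoint = tp)
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out)) out$p_holm <- p.adjust(out$p_value, method = "holm")
  out
}
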