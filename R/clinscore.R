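# 11-item clinical motor scoring and longitudinal serum CK summaries.

item_columns <- function() sprintf("item_%02d", 1:11)

#' Total motor score of one or more scoring sheets
#'
#' Each sheet carries 11 items scored 0 (normal) to 2 (worst), giving a
#' total on 22 points; the percentage is `100 * total / 22`. A healthy dog
#' scores 0/22 and the worst clinical situation 22/22.
#'
#' @param sheets Either a numeric vector of 11 item scores, or a data frame
#'   with columns `item_01` ... `item_11` (identifier columns carried
#'   through).
#' @return Tibble with `total` and `percent` columns (plus identifiers).
#' @export
motor_total <- function(sheets) {
  if (is.numeric(sheets) && is.null(dim(sheets))) {
    sheets <- tibble(!!!setNames(as.list(sheets),
                                 sprintf("item_%02d", seq_along(sheets))))
  }
  sheets <- as_tibble(sheets)
  items <- intersect(item_columns(), names(sheets))
  got <- names(sheets)[grepl("^item_", names(sheets))]
  if (length(got) != 11 || length(items) != 11) {
    stop_grmd("validation_error",
              "a motor score sheet must have exactly 11 items, found %d",
              length(got))
  }
  m <- as.matrix(sheets[items])
  if (any(is.na(m)) || any(m != round(m)) || any(m < 0) || any(m > 2)) {
    stop_grmd("validation_error", "item scores must be integers in {0, 1, 2}")
  }
  total <- as.integer(rowSums(m))
  keep <- setdiff(names(sheets), items)
  dplyr::bind_cols(sheets[keep],
                   tibble(total = total, percent = 100 * total / 22))
}

#' Group summary of serum CK in an age window
#'
#' For each dog, the mean of its CK samples falling inside the window is
#' taken (duplicate timestamps deduplicated, first kept); group mean, SD and
#' n are then computed over these per-dog values.
#'
#' @param ck Tibble with `dog_id`, `group`, `age_months`, `ck_ui_l`.
#' @param window Length-2 numeric, the age window in months (inclusive).
#' @return Tibble with one row per group: `group`, `mean_ck_ui_l`,
#'   `sd_ck_ui_l`, `n_dogs`.
#' @export
ck_group_summary <- function(ck, window) {
  stopifnot(length(window) == 2, all(c("dog_id", "group", "age_months",
                                       "ck_ui_l") %in% names(ck)))
  if (any(ck$ck_ui_l <= 0)) {
    stop_grmd("validation_error", "CK activities must be > 0 UI/L")
  }
  sel <- ck$age_months >= window[1] & ck$age_months <= window[2]
  if (!any(sel)) {
    stop_grmd("no_data", "no CK samples in the window [%.2f, %.2f] months",
              window[1], window[2])
  }
  ck[sel, ] |>
    dplyr::distinct(.data$dog_id, .data$age_months, .keep_all = TRUE) |>
    dplyr::group_by(.data$group, .data$dog_id) |>
    dplyr::summarise(dog_mean = mean(.data$ck_ui_l), .groups = "drop") |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      mean_ck_ui_l = mean(.data$dog_mean),
      sd_ck_ui_l = if (dplyr::n() > 1) sd(.data$dog_mean) else 0,
      n_dogs = dplyr::n(),
      .groups = "drop"
    )
}
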