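# Accelerometric gait variables: normalization, 7-variable reference PCA,
# supplementary projection, and the gait quality index (GQI).

#' The seven variables entering the reference PCA
#' @return Character vector of normalized-variable names.
#' @export
gait_pca_variables <- function() {
  c("stride_freq_hz", "stride_len_norm", "regularity",
    "rel_power_dv", "rel_power_cc", "rel_power_ml", "total_power")
}

raw_gait_columns <- function() {
  c("speed_ms", "stride_freq_hz", "stride_len_m", "regularity",
    "power_dv", "power_cc", "power_ml", "total_power", "height_m")
}

#' Normalize raw gait records
#'
#' Speed and stride length are normalized by the height at withers; axial
#' powers become relative powers (axial / total power). Returns the seven
#' PCA variables plus `speed_norm` (kept outside the PCA vector).
#'
#' @param records Tibble of raw gait records (columns of
#'   `gen_gait_cohort()` output).
#' @return Tibble with the normalized variables, any identifier columns
#'   (`dog_id`, `group`, `age_months`) carried through.
#' @export
normalize_record <- function(records) {
  records <- as_tibble(records)
  miss <- setdiff(raw_gait_columns(), names(records))
  if (length(miss)) {
    stop_grmd("incomplete_record", "missing gait columns: %s",
              paste(miss, collapse = ", "))
  }
  if (any(records$height_m <= 0) || any(records$total_power <= 0)) {
    stop_grmd("normalization_error",
              "height at withers and total power must be > 0")
  }
  keep <- intersect(c("dog_id", "group", "age_months"), names(records))
  dplyr::bind_cols(
    records[keep],
    tibble(
      stride_freq_hz = records$stride_freq_hz,
      stride_len_norm = records$stride_len_m / records$height_m,
      regularity = records$regularity,
      rel_power_dv = records$power_dv / records$total_power,
      rel_power_cc = records$power_cc / records$total_power,
      rel_power_ml = records$power_ml / records$total_power,
      total_power = records$total_power,
      speed_norm = records$speed_ms / records$height_m
    )
  )
}

#' Accelerometric force index
#'
#' Total power divided by speed; insensitive to speed differences, so it
#' isolates the power the gait produces per unit of speed.
#'
#' @param records Tibble with `total_power` and `speed_ms`.
#' @return Numeric vector of force-index values.
#' @export
force_index <- function(records) {
  if (any(records$speed_ms <= 0)) {
    stop_grmd("division_error", "speed must be > 0 to compute the force index")
  }
  records$total_power / records$speed_ms
}

#' Fit the 7-variable reference PCA plane
#'
#' Standardizes the seven normalized gait variables by the reference cohort's
#' means and SDs, extracts the first two principal axes of the standardized
#' matrix, and stores per-group centroids. Sign convention: the healthy
#' centroid has the smaller component-1 coordinate; component 2 is oriented
#' so its largest-magnitude loading is positive. If `age_months` is present,
#' healthy centroids are additionally binned by month for age-matched GQI.
#'
#' @param records Reference cohort (raw gait records with a `group` column
#'   containing `"healthy"` and at least one GRMD group; >= 3 records per
#'   group).
#' @return An object of class `gait_reference`: `variables`, `means`, `sds`,
#'   `loadings` (7 x 2), `explained` (2), `centroids` (per group),
#'   `healthy_by_age` (tibble or NULL).
#' @export
fit_reference <- function(records) {
  norm <- normalize_record(records)
  if (!"group" %in% names(norm)) {
    stop_grmd("invalid_spec", "reference records need a `group` column")
  }
  tab <- table(norm$group)
  if (length(tab) < 2 || any(tab < 3)) {
    stop_grmd("invalid_spec",
              "need >= 3 records in each of >= 2 reference groups")
  }
  if (!"healthy" %in% names(tab)) {
    stop_grmd("invalid_spec", "reference cohort must include a healthy group")
  }
  vars <- gait_pca_variables()
  X <- as.matrix(norm[vars])
  mu <- colMeans(X)
  sdv <- apply(X, 2, sd)
  if (any(sdv == 0)) {
    stop_grmd("degenerate_variable", "constant reference variable: %s",
              paste(vars[sdv == 0], collapse = ", "))
  }
  Z <- sweep(sweep(X, 2, mu), 2, sdv, "/")
  eg <- eigen(cov(Z), symmetric = TRUE)
  loadings <- eg$vectors[, 1:2, drop = FALSE]
  explained <- eg$values[1:2] / sum(eg$values)
  scores <- Z %*% loadings

  grmd_groups <- setdiff(names(tab), "healthy")
  cen <- lapply(split(as.data.frame(scores), norm$group), colMeans)
  # component 1: healthy on the left of the GRMD cloud
  if (cen[["healthy"]][1] > mean(vapply(cen[grmd_groups], `[`, numeric(1), 1))) {
    loadings[, 1] <- -loadings[, 1]
  }
  # component 2: deterministic orientation
  if (loadings[which.max(abs(loadings[, 2])), 2] < 0) {
    loadings[, 2] <- -loadings[, 2]
  }
  rownames(loadings) <- vars
  scores <- Z %*% loadings
  cen <- lapply(split(as.data.frame(scores), norm$group),
                function(d) unname(colMeans(d)))

  healthy_by_age <- NULL
  if ("age_months" %in% names(norm) && !all(is.na(norm$age_months))) {
    hh <- norm$group == "healthy" & !is.na(norm$age_months)
    if (any(hh)) {
      bins <- round(norm$age_months[hh])
      sc <- scores[hh, , drop = FALSE]
      healthy_by_age <- tibble(
        age_bin = as.integer(names(table(bins))),
        c1 = as.numeric(tapply(sc[, 1], bins, mean)),
        c2 = as.numeric(tapply(sc[, 2], bins, mean)),
        n = as.integer(table(bins))
      )
    }
  }

  structure(
    list(variables = vars, means = mu, sds = sdv, loadings = loadings,
         explained = explained, centroids = cen,
         healthy_by_age = healthy_by_age, n_ref = nrow(X)),
    class = "gait_reference"
  )
}

#' Project records onto the reference plane as supplementary individuals
#'
#' Standardizes each record by the reference means/SDs and applies the
#' reference loadings; the projected records never influence the plane.
#' Reference individuals projected this way reproduce their fitted scores
#' exactly.
#'
#' @param model A `gait_reference`.
#' @param records Raw gait records.
#' @return Tibble with identifier columns, `pc1` and `pc2`.
#' @export
project_supplementary <- function(model, records) {
  stopifnot(inherits(model, "gait_reference"))
  norm <- normalize_record(records)
  vars <- model$variables
  if (any(vapply(norm[vars], function(x) any(is.na(x)), logical(1)))) {
    stop_grmd("incomplete_record", "records contain missing gait variables")
  }
  Z <- sweep(sweep(as.matrix(norm[vars]), 2, model$means), 2, model$sds, "/")
  sc <- Z %*% model$loadings
  keep <- intersect(c("dog_id", "group", "age_months"), names(norm))
  dplyr::bind_cols(norm[keep], tibble(pc1 = sc[, 1], pc2 = sc[, 2]))
}

healthy_centroid_for_age <- function(model, age_months) {
  if (is.null(model$healthy_by_age) || is.null(age_months) ||
      is.na(age_months)) {
    return(model$centroids[["healthy"]])
  }
  hb <- model$healthy_by_age
  i <- which.min(abs(hb$age_bin - age_months))  # nearest non-empty bin
  c(hb$c1[i], hb$c2[i])
}

#' Gait quality index
#'
#' Euclidean distance, on the reference plane, between each projected record
#' and the (age-matched, when ages are available) healthy centroid. Zero iff
#' the projection coincides with the centroid.
#'
#' @param model A `gait_reference`.
#' @param coords Tibble from [project_supplementary()] (columns `pc1`,
#'   `pc2`, optionally `age_months`).
#' @return `coords` with a `gqi` column appended.
#' @export
gqi <- function(model, coords) {
  stopifnot(inherits(model, "gait_reference"),
            all(c("pc1", "pc2") %in% names(coords)))
  ages <- if ("age_months" %in% names(coords)) coords$age_months else
    rep(NA_real_, nrow(coords))
  g <- vapply(seq_len(nrow(coords)), function(i) {
    cen <- healthy_centroid_for_age(model, ages[i])
    sqrt((coords$pc1[i] - cen[1])^2 + (coords$pc2[i] - cen[2])^2)
  }, numeric(1))
  dplyr::bind_cols(coords, tibble(gqi = g))
}

#' GQI trajectory of a dog across sessions
#'
#' Projects each session of one dog and computes its GQI, returned in age
#' order; sessions are never interpolated.
#'
#' @param model A `gait_reference`.
#' @param records Raw gait records of one dog, with `age_months`.
#' @return Tibble `age_months`, `pc1`, `pc2`, `gqi`, in increasing age order.
#' @export
gqi_trajectory <- function(model, records) {
  if (!"age_months" %in% names(records)) {
    stop_grmd("invalid_spec", "gqi_trajectory needs an age_months column")
  }
  coords <- project_supplementary(model, records)
  out <- gqi(model, coords)
  out[order(out$age_months), ]
}
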