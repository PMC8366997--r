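# Longitudinal feature derivation, outlier handling, imputation and scaling.

#' Derive trajectory features from one longitudinal series
#'
#' For a single patient x variable series of timestamped measurements, computes
#' the five trajectory summaries used throughout the package: overall maximum,
#' overall minimum, ordinary-least-squares slope versus time, maximum increase
#' within a three-month window and maximum decrease within the same window.
#' Duplicate timestamps are averaged before derivation.
#'
#' @param t Numeric vector of times (days from therapy start).
#' @param v Numeric vector of values, same length as `t`.
#' @param window_days Window defining "within 3 months" (default 92 days, the
#'   longest calendar quarter).
#' @return Named numeric vector `c(max, min, slope, max_increase_3mo,
#'   max_decrease_3mo)`. Slope is `NA` with fewer than two distinct times; the
#'   window features are `NA` when no ordered pair falls within the window and
#'   are floored at 0 otherwise. An empty series yields all `NA`.
#' @export
#' @examples
#' derive_longitudinal_features(c(0, 30, 60), c(0, 1, 2))
derive_longitudinal_features <- function(t, v, window_days = 92) {
  out <- c(max = NA_real_, min = NA_real_, slope = NA_real_,
           max_increase_3mo = NA_real_, max_decrease_3mo = NA_real_)
  ok <- is.finite(t) & is.finite(v)
  t <- t[ok]; v <- v[ok]
  if (!length(t)) return(out)
  if (anyDuplicated(t)) {
    v <- tapply(v, t, mean)
    t <- as.numeric(names(v))
    v <- unname(v)
  }
  o <- order(t)
  t <- t[o]; v <- v[o]
  out["max"] <- max(v)
  out["min"] <- min(v)
  n <- length(t)
  if (n >= 2) {
    tc <- t - mean(t)
    out["slope"] <- sum(tc * (v - mean(v))) / sum(tc^2)
    dt <- outer(t, t, "-")        # dt[j, i] = t_j - t_i
    dv <- outer(v, v, "-")
    qual <- dt > 0 & dt <= window_days
    if (any(qual)) {
      out["max_increase_3mo"] <- max(0, max(dv[qual]))
      out["max_decrease_3mo"] <- max(0, max(-dv[qual]))
    }
  }
  out
}

#' Build the patient x feature matrix from long-format measurements
#'
#' Expands every longitudinal variable into its five derived trajectory
#' features and appends numeric encodings of the static variables (age, sex,
#' tumor class, tumor stage). Values are left un-imputed (`NA` where a patient
#' has no data for a feature); the missingness mask is preserved through
#' [impute_and_scale()].
#'
#' @param measurements Data frame with columns `patient_id`, `variable`,
#'   `value`, `days_from_therapy_start`.
#' @param static Optional data frame with `patient_id` and any of `age`,
#'   `sex`, `tumor_class`, `tumor_stage`.
#' @param window_days Passed to [derive_longitudinal_features()].
#' @return Object of class `feature_matrix`: list with numeric matrix `x`
#'   (patients x features), `ids`, `feature_info` (base variable and kind per
#'   column) and `scaled = FALSE`.
#' @export
build_feature_matrix <- function(measurements, static = NULL, window_days = 92) {
  req <- c("patient_id", "variable", "value", "days_from_therapy_start")
  if (!all(req %in% names(measurements)))
    stop("measurements must have columns: ", paste(req, collapse = ", "))
  ids <- if (!is.null(static)) as.character(static$patient_id)
         else sort(unique(as.character(measurements$patient_id)))
  vars <- sort(unique(as.character(measurements$variable)))
  kinds <- c("max", "min", "slope", "max_increase_3mo", "max_decrease_3mo")
  feat_names <- as.vector(t(outer(vars, kinds, paste, sep = "_")))
  x <- matrix(NA_real_, length(ids), length(feat_names),
              dimnames = list(ids, feat_names))
  key <- paste(measurements$patient_id, measurements$variable, sep = "\r")
  split_idx <- split(seq_len(nrow(measurements)), key)
  for (k in names(split_idx)) {
    rows <- split_idx[[k]]
    pv <- strsplit(k, "\r", fixed = TRUE)[[1]]
    if (!pv[1] %in% ids) next
    f <- derive_longitudinal_features(measurements$days_from_therapy_start[rows],
                                      measurements$value[rows], window_days)
    x[pv[1], paste(pv[2], kinds, sep = "_")] <- f
  }
  info <- data.frame(feature = feat_names,
                     base_variable = rep(vars, each = length(kinds)),
                     kind = rep(kinds, length(vars)),
                     stringsAsFactors = FALSE)
  if (!is.null(static)) {
    sid <- as.character(static$patient_id)
    add <- NULL
    if ("age" %in% names(static)) add <- cbind(add, age = static$age)
    if ("sex" %in% names(static))
      add <- cbind(add, sex_male = as.numeric(static$sex == "M"))
    if ("tumor_class" %in% names(static))
      add <- cbind(add, tumor_hematologic = as.numeric(static$tumor_class == "hematologic"))
    if ("tumor_stage" %in% names(static))
      add <- cbind(add, tumor_stage = as.numeric(static$tumor_stage))
    if (!is.null(add)) {
      rownames(add) <- sid
      x <- cbind(x, add[ids, , drop = FALSE])
      info <- rbind(info, data.frame(feature = colnames(add),
                                     base_variable = colnames(add),
                                     kind = "static", stringsAsFactors = FALSE))
    }
  }
  out <- list(x = x, ids = ids, feature_info = info, scaled = FALSE)
  class(out) <- "feature_matrix"
  out
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("Feature matrix: %d patients x %d features (%s)\n",
              nrow(x$x), ncol(x$x),
              if (isTRUE(x$scaled)) "imputed + z-scored" else "raw"))
  cat(sprintf("  missing entries: %d (%.1f%%)\n", sum(is.na(x$x)),
              100 * mean(is.na(x$x))))
  invisible(x)
}

#' Flag gross outliers as missing
#'
#' Entries whose robust column z-score exceeds `z_limit` in absolute value are
#' set to missing; they are then filled by mean imputation in
#' [impute_and_scale()]. The robust centre is the column median; the robust
#' scale is the MAD floored at the classical sd, so genuinely multimodal
#' columns (e.g. a biomarker with distinct patient subpopulations) are not
#' censored of their minority mode, while gross errors -- which inflate both
#' scales but dwarf them -- are still flagged. Columns with zero scale are
#' left untouched.
#'
#' @param fm A `feature_matrix` (pre-imputation).
#' @param z_limit Robust z threshold (default 4); `Inf` disables removal.
#' @return The `feature_matrix` with outliers set to `NA`; the removal count is
#'   stored in `fm$n_outliers` and the per-column centre/scale in
#'   `fm$outlier_stats` so the identical rule can be applied to held-out data.
#' @export
remove_outliers <- function(fm, z_limit = 4) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (isTRUE(fm$scaled)) stop("remove_outliers expects a pre-imputation matrix")
  med <- apply(fm$x, 2, stats::median, na.rm = TRUE)
  mad_ <- pmax(apply(fm$x, 2, stats::mad, na.rm = TRUE),
               apply(fm$x, 2, stats::sd, na.rm = TRUE))
  fm$outlier_stats <- data.frame(feature = colnames(fm$x), median = med,
                                 mad = mad_, z_limit = z_limit,
                                 stringsAsFactors = FALSE)
  if (!is.finite(z_limit)) { fm$n_outliers <- 0L; return(fm) }
  n_rm <- 0L
  for (j in seq_len(ncol(fm$x))) {
    if (!is.finite(mad_[j]) || mad_[j] <= 0) next
    z <- abs(fm$x[, j] - med[j]) / mad_[j]
    bad <- which(z > z_limit)
    n_rm <- n_rm + length(bad)
    if (length(bad)) fm$x[bad, j] <- NA_real_
  }
  fm$n_outliers <- n_rm
  message(sprintf("remove_outliers: %d entries flagged missing (|robust z| > %g)",
                  n_rm, z_limit))
  fm
}

#' Mean-impute missing values and z-score every column
#'
#' Missing entries are replaced by the column mean of observed values; each
#' column is then centred and scaled, so imputed entries equal exactly 0 after
#' scaling. Columns that are entirely missing are dropped with a warning;
#' zero-variance columns are centred but not scaled and flagged.
#'
#' @param fm A `feature_matrix`.
#' @param sd_type `"population"` (divide by n, the default) or `"sample"`
#'   (divide by n-1).
#' @return The `feature_matrix` with `scaled = TRUE`, the pre-imputation mask
#'   in `$mask`, and per-column `$center`/`$scale` (and observed-value means in
#'   `$impute_means`) so the identical transform can be applied to held-out
#'   patients via [apply_preprocess()].
#' @export
impute_and_scale <- function(fm, sd_type = c("population", "sample")) {
  stopifnot(inherits(fm, "feature_matrix"))
  sd_type <- match.arg(sd_type)
  x <- fm$x
  all_missing <- colSums(!is.na(x)) == 0
  if (any(all_missing)) {
    warning("dropping ", sum(all_missing), " all-missing column(s): ",
            paste(colnames(x)[all_missing], collapse = ", "))
    x <- x[, !all_missing, drop = FALSE]
    fm$feature_info <- fm$feature_info[fm$feature_info$feature %in% colnames(x), ]
  }
  mask <- is.na(x)
  mu <- colMeans(x, na.rm = TRUE)
  for (j in seq_len(ncol(x))) x[mask[, j], j] <- mu[j]
  center <- colMeans(x)
  n <- nrow(x)
  ss <- colSums(sweep(x, 2, center)^2)
  sdv <- sqrt(ss / if (sd_type == "population") n else max(n - 1, 1))
  zero_var <- sdv < 1e-12
  scale_ <- ifelse(zero_var, 1, sdv)
  x <- sweep(sweep(x, 2, center), 2, scale_, "/")
  fm$x <- x
  fm$mask <- mask
  fm$impute_means <- mu
  fm$center <- center
  fm$scale <- scale_
  fm$zero_variance <- colnames(x)[zero_var]
  fm$sd_type <- sd_type
  fm$scaled <- TRUE
  fm
}

#' Apply a fitted preprocessing transform to held-out patients
#'
#' Uses the training set's outlier bounds, imputation means and scaling
#' statistics, so no test-set information leaks into the transform.
#'
#' @param fm_new A raw (unscaled) `feature_matrix` for new patients.
#' @param fitted A `feature_matrix` returned by [impute_and_scale()] (after
#'   [remove_outliers()], if used in training).
#' @return The transformed `feature_matrix`, column space aligned to training.
#' @export
apply_preprocess <- function(fm_new, fitted) {
  stopifnot(inherits(fm_new, "feature_matrix"), isTRUE(fitted$scaled))
  feats <- colnames(fitted$x)
  x <- matrix(NA_real_, nrow(fm_new$x), length(feats),
              dimnames = list(rownames(fm_new$x), feats))
  common <- intersect(feats, colnames(fm_new$x))
  x[, common] <- fm_new$x[, common]
  if (!is.null(fitted$outlier_stats)) {
    os <- fitted$outlier_stats
    zl <- os$z_limit[1]
    if (is.finite(zl)) {
      for (j in seq_along(feats)) {
        k <- match(feats[j], os$feature)
        if (is.na(k) || !is.finite(os$mad[k]) || os$mad[k] <= 0) next
        bad <- which(abs(x[, j] - os$median[k]) / os$mad[k] > zl)
        if (length(bad)) x[bad, j] <- NA_real_
      }
    }
  }
  mask <- is.na(x)
  for (j in seq_along(feats)) x[mask[, j], j] <- fitted$impute_means[j]
  x <- sweep(sweep(x, 2, fitted$center), 2, fitted$scale, "/")
  out <- list(x = x, ids = rownames(x),
              feature_info = fitted$feature_info, mask = mask,
              center = fitted$center, scale = fitted$scale,
              impute_means = fitted$impute_means, scaled = TRUE)
  class(out) <- "feature_matrix"
  out
}

#' Write a feature matrix and its transform metadata
#' @param fm A scaled `feature_matrix`.
#' @param path_csv Output csv (patients x features).
#' @param path_meta Optional JSON path for per-column center/scale/means.
#' @return Invisibly, the csv path.
#' @export
write_features <- function(fm, path_csv, path_meta = NULL) {
  stopifnot(inherits(fm, "feature_matrix"))
  df <- data.frame(patient_id = rownames(fm$x), fm$x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path_csv, row.names = FALSE)
  if (!is.null(path_meta) && isTRUE(fm$scaled)) {
    meta <- list(feature = colnames(fm$x), impute_mean = unname(fm$impute_means),
                 center = unname(fm$center), scale = unname(fm$scale),
                 sd_type = fm$sd_type %||% "population")
    writeLines(jsonlite::toJSON(meta, digits = NA, auto_unbox = TRUE), path_meta)
  }
  invisible(path_csv)
}
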