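# Clinical validation of patient subgroups: event classification, KM and
# Nelson-Aalen curves, log-rank with BH adjustment, Cox hazard ratios,
# chi-squared enrichment, longitudinal period breakdowns, biomarker-bin KM.

#' Classify cardiac events relative to therapy start
#'
#' Splits each patient's cardiac events (AF, CAD, HF, MI, stroke) into
#' preexisting (dated before therapy start, day < 0) and de novo (dated on or
#' after therapy start, day >= 0; the boundary day counts as de novo), and
#' derives the survival quantities used downstream.
#'
#' @param events Data frame with columns `patient_id`, `event_type`,
#'   `days_from_therapy_start`, `is_death`, `is_censor`; exactly one terminal
#'   (death or censor) row per patient.
#' @return Object of class `outcome_table` (a data frame): per patient,
#'   `os_years` and `death` (overall survival), `preexisting`,
#'   `de_novo_ctrcd`, `denovo_years` (time to first de novo event, censored at
#'   end of observation otherwise, i.e. cause-specific with death treated as
#'   censoring), and first de novo time per event type (`t_AF`, ..., years;
#'   `NA` if none).
#' @export
classify_events <- function(events) {
  req <- c("patient_id", "event_type", "days_from_therapy_start", "is_death", "is_censor")
  if (!all(req %in% names(events)))
    stop("events must have columns: ", paste(req, collapse = ", "))
  term <- events[events$is_death == 1 | events$is_censor == 1, ]
  if (anyDuplicated(term$patient_id) || !setequal(term$patient_id, events$patient_id))
    stop("each patient must have exactly one terminal death/censor row")
  ev <- events[events$is_death == 0 & events$is_censor == 0, ]
  bad_type <- setdiff(unique(ev$event_type), .psn_event_types)
  if (length(bad_type)) stop("unknown event types: ", paste(bad_type, collapse = ", "))
  end_day <- stats::setNames(term$days_from_therapy_start, term$patient_id)
  late <- ev$days_from_therapy_start > end_day[ev$patient_id]
  if (any(late))
    stop("event after end of observation for patient(s): ",
         paste(unique(ev$patient_id[late]), collapse = ", "))
  ids <- term$patient_id
  first_denovo <- function(sub) if (nrow(sub)) min(sub$days_from_therapy_start) else NA_real_
  dn <- ev[ev$days_from_therapy_start >= 0, ]
  pre_ids <- unique(ev$patient_id[ev$days_from_therapy_start < 0])
  t_first <- tapply(dn$days_from_therapy_start, factor(dn$patient_id, levels = ids), min)
  per_type <- sapply(.psn_event_types, function(ty) {
    sub <- dn[dn$event_type == ty, ]
    as.numeric(tapply(sub$days_from_therapy_start,
                      factor(sub$patient_id, levels = ids), min)) / 365.25
  })
  os_years <- unname(end_day[ids]) / 365.25
  has_dn <- !is.na(t_first)
  out <- data.frame(
    patient_id = ids,
    os_years = os_years,
    death = as.integer(term$is_death == 1),
    preexisting = ids %in% pre_ids,
    de_novo_ctrcd = unname(has_dn),
    denovo_years = ifelse(has_dn, as.numeric(t_first) / 365.25, os_years),
    stringsAsFactors = FALSE
  )
  colnames(per_type) <- paste0("t_", .psn_event_types)
  out <- cbind(out, as.data.frame(per_type))
  rownames(out) <- NULL
  class(out) <- c("outcome_table", "data.frame")
  out
}

# Pairwise log-rank tests with BH adjustment over all group pairs.
.pairwise_logrank <- function(time, status, group) {
  lv <- levels(group)
  pairs <- utils::combn(lv, 2)
  p_raw <- apply(pairs, 2, function(pr) {
    keep <- group %in% pr
    sd_fit <- survival::survdiff(survival::Surv(time[keep], status[keep]) ~
                                   droplevels(group[keep]))
    survdiff_p(sd_fit)
  })
  data.frame(group1 = pairs[1, ], group2 = pairs[2, ], p_raw = p_raw,
             p_bh = stats::p.adjust(p_raw, method = "BH"),
             stringsAsFactors = FALSE)
}

.survival_by_group <- function(time, status, group, type = c("km", "na")) {
  type <- match.arg(type)
  stopifnot(length(time) == length(status), length(time) == length(group),
            all(time >= 0))
  if (!is.factor(group)) group <- factor(group)
  empty <- levels(group)[table(group) == 0]
  if (length(empty)) {
    warning("dropping empty group(s): ", paste(empty, collapse = ", "))
    group <- droplevels(group)
  }
  fit <- survival::survfit(survival::Surv(time, status) ~ group, conf.type = "log")
  strata_names <- if (is.null(fit$strata)) levels(group)[1]
    else sub("^group=", "", names(fit$strata))
  grp_col <- if (is.null(fit$strata)) rep(strata_names, length(fit$time))
    else rep(strata_names, fit$strata)
  curves <- data.frame(
    group = grp_col, time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
    surv = fit$surv, lower = fit$lower, upper = fit$upper,
    cumhaz = fit$cumhaz, stringsAsFactors = FALSE
  )
  omnibus_p <- NA_real_
  pairwise <- NULL
  if (nlevels(group) >= 2) {
    omnibus_p <- survdiff_p(survival::survdiff(survival::Surv(time, status) ~ group))
    pairwise <- .pairwise_logrank(time, status, group)
  }
  out <- list(curves = curves, omnibus_p = omnibus_p, pairwise = pairwise,
              type = type, groups = levels(group), fit = fit)
  class(out) <- "surv_by_group"
  out
}

#' Kaplan-Meier survival curves by group with log-rank tests
#'
#' Product-limit estimate per group with Greenwood-based 95% bands, the
#' omnibus log-rank test across all groups and all pairwise log-rank tests
#' with Benjamini-Hochberg adjustment.
#'
#' @param time Follow-up times (years, >= 0).
#' @param status Event indicator (1 = event, 0 = censored).
#' @param group Group labels; empty groups are dropped with a warning.
#' @return Object of class `surv_by_group`: `curves` data frame (group, time,
#'   n_risk, n_event, surv, lower, upper, cumhaz), `omnibus_p`, `pairwise`
#'   (group1, group2, p_raw, p_bh).
#' @export
km_by_group <- function(time, status, group) {
  .survival_by_group(time, status, group, type = "km")
}

#' Nelson-Aalen cumulative hazard by group
#'
#' Step-sum estimator `H(t) = sum over event times of d_i / n_i`. For a
#' cause-specific endpoint, code competing deaths as censored in `status`.
#' The log-rank machinery is shared with [km_by_group()].
#'
#' @inheritParams km_by_group
#' @return A `surv_by_group` whose `curves$cumhaz` column is the Nelson-Aalen
#'   estimate (`-log` Kaplan-Meier is available as `-log(curves$surv)`).
#' @export
cumulative_hazard_by_group <- function(time, status, group) {
  .survival_by_group(time, status, group, type = "na")
}

#' @export
print.surv_by_group <- function(x, ...) {
  cat(sprintf("%s estimate, %d group(s)\n",
              if (x$type == "km") "Kaplan-Meier" else "Nelson-Aalen",
              length(x$groups)))
  if (!is.na(x$omnibus_p))
    cat(sprintf("  omnibus log-rank p = %.3g\n", x$omnibus_p))
  if (!is.null(x$pairwise))
    cat(sprintf("  %d pairwise tests; max BH-adjusted p = %.3g\n",
                nrow(x$pairwise), max(x$pairwise$p_bh)))
  invisible(x)
}

#' @export
plot.surv_by_group <- function(x, ..., col = NULL) {
  col <- col %||% seq_along(x$groups)
  graphics::plot(x$fit, col = col, xlab = "Years", lwd = 2,
                 ylab = if (x$type == "km") "Survival probability"
                        else "Cumulative hazard",
                 fun = if (x$type == "na") "cumhaz" else NULL, ...)
  graphics::legend("bottomleft", legend = x$groups, col = col, lwd = 2, bty = "n")
  invisible(x)
}

#' Cox proportional-hazards ratios with Wald intervals
#'
#' Fits a proportional-hazards model and reports per-coefficient hazard
#' ratios, Wald 95% confidence intervals and p-values. When `cluster` is among
#' the covariates it should be a factor; use `relevel_lowest_risk()` to set
#' the lowest-risk cluster as the reference. Rank deficiency (e.g. a
#' duplicated covariate) is an error.
#'
#' @param data Data frame containing the variables.
#' @param time,status Column names for follow-up time and event indicator.
#' @param covariates Character vector of covariate column names.
#' @return Object of class `hazard_estimates`: a data frame with columns
#'   `term`, `hr`, `lo`, `hi`, `p`, plus the `coxph` fit as attribute `fit`.
#' @export
cox_hr <- function(data, time, status, covariates) {
  stopifnot(all(c(time, status, covariates) %in% names(data)))
  f <- stats::as.formula(paste0("survival::Surv(", time, ", ", status, ") ~ ",
                                paste(covariates, collapse = " + ")))
  fit <- tryCatch(
    survival::coxph(f, data = data, singular.ok = FALSE),
    error = function(e) stop("Cox model failed: ", conditionMessage(e))
  )
  if (anyNA(stats::coef(fit))) stop("Cox model is rank deficient")
  s <- summary(fit)
  out <- data.frame(
    term = rownames(s$coefficients),
    hr = s$coefficients[, "exp(coef)"],
    lo = s$conf.int[, "lower .95"],
    hi = s$conf.int[, "upper .95"],
    p = s$coefficients[, "Pr(>|z|)"],
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("hazard_estimates", "data.frame")
  attr(out, "fit") <- fit
  out
}

#' Relevel a cluster factor to the lowest-risk reference
#'
#' Sets the reference level to the cluster with the lowest observed event
#' rate, the package's convention for reporting subgroup hazard ratios.
#'
#' @param cluster Cluster labels.
#' @param event Binary event indicator aligned to `cluster`.
#' @return A factor with the lowest-event-rate cluster as first level.
#' @export
relevel_lowest_risk <- function(cluster, event) {
  cluster <- factor(cluster)
  rates <- tapply(event, cluster, mean)
  stats::relevel(cluster, ref = names(which.min(rates)))
}

#' Per-cluster outcome enrichment by chi-squared test
#'
#' For each cluster, a 2x2 cluster-versus-rest table is tested with Pearson's
#' chi-squared test (no continuity correction); if any expected cell is below
#' 1 a warning is raised and Fisher's exact test is used instead. The
#' per-cluster outcome rate carries a Wilson 95% interval.
#'
#' @param cluster_labels Cluster labels.
#' @param outcome Binary outcome (0/1 or logical).
#' @return Data frame: cluster, n, n_event, rate, lower, upper, p, test.
#' @export
chi2_enrichment <- function(cluster_labels, outcome) {
  cluster_labels <- factor(cluster_labels)
  outcome <- as.integer(outcome)
  stopifnot(length(cluster_labels) == length(outcome), all(outcome %in% 0:1))
  rows <- lapply(levels(cluster_labels), function(cl) {
    inc <- cluster_labels == cl
    tab <- rbind(c(sum(outcome[inc]), sum(!outcome[inc])),
                 c(sum(outcome[!inc]), sum(!outcome[!inc])))
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(expected < 1)) {
      warning("expected cell < 1 for cluster ", cl, "; using Fisher's exact test")
      p <- stats::fisher.test(tab)$p.value
      test <- "fisher"
    } else {
      p <- stats::chisq.test(tab, correct = FALSE)$p.value
      test <- "chi2"
    }
    ci <- wilson_ci(sum(outcome[inc]), sum(inc))
    data.frame(cluster = cl, n = sum(inc), n_event = sum(outcome[inc]),
               rate = ci[1], lower = ci[2], upper = ci[3], p = p, test = test,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-cluster, per-period event percentages
#'
#' Fraction of each cluster whose first qualifying event falls in each
#' follow-up period (whole years after therapy start: an event at time t
#' belongs to the period containing `floor(t)`). Percentages carry Wilson 95%
#' intervals; the never-event remainder completes the partition.
#'
#' @param event_years Time to first qualifying event (years; `NA` or `Inf` if
#'   none; use the event time only for patients with the event).
#' @param has_event Logical, whether the patient had the event.
#' @param cluster_labels Cluster labels.
#' @param periods List of `c(first_year, last_year)` integer pairs; default
#'   `list(c(0,1), c(2,5), c(6,10), c(11,20))`. Must be disjoint and ordered.
#' @return Data frame: cluster, period, n, n_event, pct, lower, upper.
#' @export
period_breakdown <- function(event_years, has_event, cluster_labels,
                             periods = list(c(0, 1), c(2, 5), c(6, 10), c(11, 20))) {
  lo <- vapply(periods, `[`, numeric(1), 1)
  hi <- vapply(periods, `[`, numeric(1), 2)
  if (any(hi < lo) || any(lo[-1] <= hi[-length(hi)]))
    stop("periods must be ordered and non-overlapping")
  cluster_labels <- factor(cluster_labels)
  yr <- floor(event_years)
  rows <- lapply(levels(cluster_labels), function(cl) {
    inc <- cluster_labels == cl
    n <- sum(inc)
    per <- lapply(seq_along(periods), function(k) {
      x <- sum(inc & has_event & !is.na(yr) & yr >= lo[k] & yr <= hi[k])
      ci <- wilson_ci(x, n)
      data.frame(cluster = cl, period = sprintf("%g-%g", lo[k], hi[k]),
                 n = n, n_event = x, pct = 100 * ci[1],
                 lower = 100 * ci[2], upper = 100 * ci[3],
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, per)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Survival stratified by biomarker bins
#'
#' Bins a biomarker at guideline thresholds, estimates Kaplan-Meier curves per
#' bin with BH-adjusted pairwise log-rank tests, and fits a Cox model with the
#' lowest bin as reference. Default thresholds: NT-proBNP (pg/mL) 0-125,
#' 125-900, >900; Troponin T (ug/L) <=0.01, 0.01-0.05, >0.05.
#'
#' @param time,status Follow-up time (years) and event indicator.
#' @param biomarker Numeric biomarker values (natural units).
#' @param breaks Bin boundaries passed to [cut()] (right-closed, lowest
#'   included), e.g. `c(0, 125, 900, Inf)`.
#' @param labels Optional bin labels.
#' @return List with `km` (a `surv_by_group`), `hr` (a `hazard_estimates`, or
#'   `NULL` with a single non-empty bin) and `bins` (the factor used).
#' @export
biomarker_km <- function(time, status, biomarker, breaks, labels = NULL) {
  bins <- cut(biomarker, breaks = breaks, labels = labels,
              include.lowest = TRUE, right = TRUE)
  empty <- levels(bins)[table(bins) == 0]
  if (length(empty)) {
    warning("dropping empty bin(s): ", paste(empty, collapse = ", "))
    bins <- droplevels(bins)
  }
  keep <- !is.na(bins)
  km <- km_by_group(time[keep], status[keep], bins[keep])
  hr <- NULL
  if (nlevels(bins) >= 2) {
    df <- data.frame(time = time[keep], status = status[keep], bin = bins[keep])
    hr <- cox_hr(df, "time", "status", "bin")
  }
  list(km = km, hr = hr, bins = bins)
}

#' Default guideline biomarker thresholds
#'
#' @return Named list of break vectors in natural units: NT-proBNP (pg/mL)
#'   `c(0, 125, 900, Inf)` and Troponin T (ug/L) `c(0, 0.01, 0.05, Inf)`.
#' @export
biomarker_thresholds <- function() {
  list(NTproBNP = c(0, 125, 900, Inf), TroponinT = c(0, 0.01, 0.05, Inf))
}
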