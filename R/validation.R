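# Train/test split validation of the stratification model and time-dependent
# AUROC of risk scores.

#' Plan a train/test split validation
#'
#' @param mode `"random"` (repeated random splits) or `"time"` (patients
#'   ordered by therapy start date; the earlier block is the training set).
#' @param fractions Length-2 vector `c(train, test)` summing to 1, both
#'   positive.
#' @param n_repeats Number of random repeats (random mode only, default 3).
#' @param seed Base seed; repeat r uses `seed + r - 1`.
#' @return Object of class `split_plan`.
#' @export
split_plan <- function(mode = c("random", "time"), fractions = c(0.5, 0.5),
                       n_repeats = 3, seed = 1L) {
  mode <- match.arg(mode)
  if (length(fractions) != 2 || abs(sum(fractions) - 1) > 1e-9)
    stop("fractions must be two values summing to 1")
  if (any(fractions <= 0)) stop("both split fractions must be positive")
  if (mode == "time") n_repeats <- 1L
  out <- list(mode = mode, fractions = fractions,
              n_repeats = as.integer(n_repeats), seed = as.integer(seed))
  class(out) <- "split_plan"
  out
}

#' Train/test validation of the similarity-network stratification
#'
#' For each split: fits the full model ([psn_fit()]) on the training patients
#' only (preprocessing statistics included), assigns the test patients via
#' [predict.psn_fit()], and tests whether the assigned test-set subgroups
#' separate overall survival and de novo cardiac events by omnibus log-rank.
#'
#' @param cohort A `synthetic_cohort` or compatible list with `measurements`,
#'   `static` and `events`.
#' @param plan A [split_plan()].
#' @param K Number of subgroups (default 4).
#' @param ... Passed to [psn_fit()] (metric, z_limit, window_days, ...).
#' @return Object of class `split_validation`: data frame `results` with one
#'   row per split (n_train, n_test, omnibus log-rank p for both endpoints and
#'   the test cluster sizes) plus the per-split fitted models in `fits`.
#' @export
run_split_validation <- function(cohort, plan, K = 4, ...) {
  stopifnot(inherits(plan, "split_plan"))
  outcomes <- classify_events(cohort$events)
  ids <- as.character(cohort$static$patient_id)
  n <- length(ids)
  n_train <- round(plan$fractions[1] * n)
  if (n_train < 2 || n - n_train < 2) stop("degenerate split: too few patients")
  splits <- lapply(seq_len(plan$n_repeats), function(r) {
    if (plan$mode == "random") {
      set.seed(plan$seed + r - 1L)
      train <- sample(ids, n_train)
    } else {
      ord <- order(cohort$static$therapy_start)
      train <- ids[ord[seq_len(n_train)]]
    }
    list(train = train, test = setdiff(ids, train))
  })
  fits <- vector("list", length(splits))
  rows <- vector("list", length(splits))
  for (r in seq_along(splits)) {
    sp <- splits[[r]]
    sub <- function(set) list(
      measurements = cohort$measurements[cohort$measurements$patient_id %in% set, ],
      static = cohort$static[ids %in% set, ]
    )
    fit <- psn_fit(sub(sp$train), K = K, seed = plan$seed + r - 1L, ...)
    test_labels <- predict(fit, newdata = sub(sp$test))
    ot <- outcomes[match(sp$test, outcomes$patient_id), ]
    g <- factor(test_labels[sp$test], levels = seq_len(K))
    present <- levels(droplevels(g))
    os <- suppressWarnings(km_by_group(ot$os_years, ot$death, g))
    dn <- suppressWarnings(km_by_group(ot$denovo_years, ot$de_novo_ctrcd, g))
    fits[[r]] <- fit
    rows[[r]] <- data.frame(
      split = r, mode = plan$mode, n_train = length(sp$train),
      n_test = length(sp$test), n_test_clusters = length(present),
      p_os_test = os$omnibus_p, p_denovo_test = dn$omnibus_p,
      test_sizes = paste(table(g), collapse = "/"), stringsAsFactors = FALSE
    )
  }
  out <- list(results = do.call(rbind, rows), fits = fits, plan = plan, K = K)
  class(out) <- "split_validation"
  out
}

#' @export
print.split_validation <- function(x, ...) {
  cat(sprintf("%s-split validation, %d split(s), K = %d\n",
              x$plan$mode, nrow(x$results), x$K))
  print(x$results[, c("split", "n_train", "n_test", "p_os_test",
                      "p_denovo_test", "test_sizes")],
        row.names = FALSE, digits = 3)
  invisible(x)
}

#' Time-dependent AUROC with censoring weights
#'
#' Cumulative/dynamic area under the ROC curve of a risk score at each
#' evaluation time: cases are subjects with an event by time t, controls those
#' still event-free, and cases are weighted by inverse probability of
#' censoring (Kaplan-Meier estimate of the censoring distribution). Tied
#' scores count 1/2.
#'
#' @param risk Numeric risk scores (higher = higher risk); must be finite.
#' @param time Follow-up times.
#' @param status Event indicator (1 = event).
#' @param eval_times Times at which to evaluate the AUC.
#' @return Data frame `time`, `auc`, `n_cases`, `n_controls`; evaluation times
#'   with no cases or no controls are skipped with a message.
#' @export
time_dependent_auroc <- function(risk, time, status, eval_times) {
  stopifnot(all(is.finite(risk)), length(risk) == length(time),
            length(time) == length(status))
  cens_fit <- survival::survfit(survival::Surv(time, 1 - status) ~ 1)
  G <- stats::stepfun(cens_fit$time, c(1, cens_fit$surv))
  g_at <- function(t) pmax(G(t), 1e-12)
  rows <- lapply(eval_times, function(t) {
    cases <- which(time <= t & status == 1)
    controls <- which(time > t)
    if (!length(cases) || !length(controls)) {
      message(sprintf("AUC(t = %g): undefined (%d cases, %d controls), skipped",
                      t, length(cases), length(controls)))
      return(NULL)
    }
    w <- 1 / g_at(pmin(time[cases], t))   # IPCW at the case's event time
    num <- 0
    for (k in seq_along(cases)) {
      cmp <- sign(risk[cases[k]] - risk[controls])
      num <- num + w[k] * sum((cmp + 1) / 2)
    }
    data.frame(time = t, auc = num / (sum(w) * length(controls)),
               n_cases = length(cases), n_controls = length(controls))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(time = numeric(0), auc = numeric(0),
                                      n_cases = integer(0), n_controls = integer(0))
  rownames(out) <- NULL
  out
}
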