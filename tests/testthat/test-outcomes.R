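mk_events <- function(df_events, terminal) {
  rbind(
    if (!is.null(df_events))
      data.frame(patient_id = df_events$patient_id, event_type = df_events$event_type,
                 days_from_therapy_start = df_events$day, is_death = 0L, is_censor = 0L),
    data.frame(patient_id = terminal$patient_id, event_type = terminal$what,
               days_from_therapy_start = terminal$day,
               is_death = as.integer(terminal$what == "death"),
               is_censor = as.integer(terminal$what == "censor"))
  )
}

test_that("events are classified as preexisting vs de novo with the boundary at day 0", {
  ev <- mk_events(
    data.frame(patient_id = c("a", "a", "b", "c"),
               event_type = c("HF", "AF", "MI", "stroke"),
               day = c(-100, 50, 0, 300)),
    data.frame(patient_id = c("a", "b", "c", "d"),
               what = c("death", "censor", "censor", "death"),
               day = c(400, 500, 600, 700))
  )
  ot <- classify_events(ev)
  expect_s3_class(ot, "outcome_table")
  a <- ot[ot$patient_id == "a", ]
  expect_true(a$preexisting && a$de_novo_ctrcd)
  expect_equal(a$denovo_years, 50 / 365.25)
  expect_equal(a$os_years, 400 / 365.25)
  expect_equal(a$death, 1L)
  b <- ot[ot$patient_id == "b", ]
  expect_true(b$de_novo_ctrcd)       # day-0 event counts as de novo
  expect_false(b$preexisting)
  d <- ot[ot$patient_id == "d", ]
  expect_false(d$de_novo_ctrcd)
  expect_equal(d$denovo_years, d$os_years)  # censored at end of observation
})

test_that("classification equals a row-wise brute-force comparison on random events", {
  coh <- planted_cohort(n = 300, seed = 41)
  ot <- classify_events(coh$events)
  ev <- coh$events[coh$events$is_death == 0 & coh$events$is_censor == 0, ]
  for (pid in sample(ot$patient_id, 40)) {
    rows <- ev[ev$patient_id == pid, ]
    expect_identical(ot$preexisting[ot$patient_id == pid],
                     any(rows$days_from_therapy_start < 0))
    expect_identical(ot$de_novo_ctrcd[ot$patient_id == pid],
                     any(rows$days_from_therapy_start >= 0))
  }
})

test_that("an event dated after the end of observation is a validation error", {
  ev <- mk_events(data.frame(patient_id = "a", event_type = "HF", day = 500),
                  data.frame(patient_id = "a", what = "death", day = 400))
  expect_error(classify_events(ev), "a")
})

test_that("Kaplan-Meier matches the hand product-limit and the brute-force oracle", {
  km <- km_by_group(c(1, 2, 3), c(1, 1, 1), rep("g", 3))
  expect_equal(km$curves$surv, c(2 / 3, 1 / 3, 0))

  none <- km_by_group(c(1, 2, 3), c(0, 0, 0), rep("g", 3))
  expect_true(all(none$curves$surv == 1))

  set.seed(20)
  for (rep in 1:10) {
    n <- sample(10:50, 1)
    time <- round(rexp(n, 0.2), 1) + 0.1
    status <- rbinom(n, 1, 0.7)
    if (!any(status == 1)) status[1] <- 1
    km2 <- km_by_group(time, status, rep("g", n))
    o <- oracle_km(time, status)
    got <- km2$curves[km2$curves$n_event > 0, ]
    expect_equal(got$time, o$time)
    expect_equal(got$surv, o$surv, tolerance = 1e-12)
    na2 <- cumulative_hazard_by_group(time, status, rep("g", n))
    ona <- oracle_na(time, status)
    gotna <- na2$curves[na2$curves$n_event > 0, ]
    expect_equal(gotna$cumhaz, ona$cumhaz, tolerance = 1e-12)
  }
})

test_that("pairwise log-rank p-values carry a valid BH adjustment", {
  coh <- planted_cohort(n = 600, seed = 11)
  ot <- classify_events(coh$events)
  g <- truth_of(coh, ot$patient_id)
  km <- km_by_group(ot$os_years, ot$death, g)
  pw <- km$pairwise
  expect_equal(nrow(pw), choose(4, 2))
  expect_true(all(pw$p_bh >= pw$p_raw - 1e-15))
  expect_equal(pw$p_bh, oracle_bh(pw$p_raw))
  # BH is monotone in the raw ranks
  o <- order(pw$p_raw)
  expect_true(all(diff(pw$p_bh[o]) >= -1e-15))
  # empty groups are dropped with a warning
  expect_warning(km_by_group(ot$os_years, ot$death,
                             factor(g, levels = 1:5)), "empty")
})

test_that("Nelson-Aalen tracks the true cumulative hazard of an exponential", {
  set.seed(21)
  n <- 5000; lam <- 0.3
  time <- rexp(n, lam)
  na <- cumulative_hazard_by_group(time, rep(1, n), rep("g", n))
  grid <- na$curves$time[na$curves$time <= quantile(time, 0.9)]
  est <- approx(na$curves$time, na$curves$cumhaz, xout = grid)$y
  # sup error against lambda * t within 3 MC standard errors of H(t)
  se <- sqrt((exp(lam * grid) - 1) / n)
  expect_true(all(abs(est - lam * grid) < 3 * se + 0.01))
})

test_that("Cox hazard ratios recover a planted effect and flag rank deficiency", {
  set.seed(22)
  n <- 5000
  x <- rbinom(n, 1, 0.5)
  time <- rexp(n, 0.1 * 2^x)
  cens <- rexp(n, 0.05)
  df <- data.frame(time = pmin(time, cens), status = as.integer(time <= cens), x = x)
  hr <- cox_hr(df, "time", "status", "x")
  expect_s3_class(hr, "hazard_estimates")
  expect_gt(hr$hr, 1.8); expect_lt(hr$hr, 2.2)
  expect_true(hr$lo <= hr$hr && hr$hr <= hr$hi)

  df$null_x <- rbinom(n, 1, 0.5)
  hr0 <- cox_hr(df, "time", "status", "null_x")
  expect_true(hr0$lo < 1 && hr0$hi > 1)

  df$x2 <- df$x
  expect_error(cox_hr(df, "time", "status", c("x", "x2")), "rank|singular|failed")
})

test_that("lowest-risk releveling sets the reference used for subgroup hazard ratios", {
  g <- rep(c("a", "b", "c"), each = 50)
  ev <- c(rbinom(50, 1, 0.5), rbinom(50, 1, 0.05), rbinom(50, 1, 0.3))
  expect_equal(levels(relevel_lowest_risk(g, ev))[1], "b")
})

test_that("chi-squared enrichment handles extreme, homogeneous and sparse tables", {
  # one cluster all positive, rest all negative
  lab <- rep(c("hot", "cold"), each = 100)
  out <- c(rep(1, 100), rep(0, 100))
  en <- chi2_enrichment(lab, out)
  expect_lt(en$p[en$cluster == "hot"], 1e-10)
  # perfectly homogeneous split: chi2 = 0, p = 1
  lab2 <- rep(c("x", "y"), each = 200)
  out2 <- rep(c(rep(1, 40), rep(0, 160)), 2)
  en2 <- chi2_enrichment(lab2, out2)
  expect_equal(en2$p, c(1, 1))
  expect_equal(en2$rate, c(0.2, 0.2))
  # Wilson interval brackets the rate
  expect_true(all(en2$lower < en2$rate & en2$rate < en2$upper))
  # sparse expected cells fall back to the exact test with a warning
  w <- capture_warnings(en3 <- chi2_enrichment(c("a", "a", "b", "b"), c(1, 0, 0, 0)))
  expect_true(all(grepl("Fisher", w)) && length(w) >= 1)
  expect_identical(unique(en3$test), "fisher")
})

test_that("period breakdown partitions first events into whole-year bins", {
  yrs <- c(0.5, 0.5, 0.5, 3, 12)
  has <- c(TRUE, TRUE, TRUE, TRUE, TRUE)
  cl <- rep("c1", 5)
  pb <- period_breakdown(yrs, has, cl)
  expect_equal(pb$n_event[pb$period == "0-1"], 3)
  expect_equal(pb$n_event[pb$period == "2-5"], 1)
  expect_equal(pb$n_event[pb$period == "11-20"], 1)
  expect_equal(sum(pb$n_event), 5)
  # percentages plus the never-event remainder complete the partition
  pb2 <- period_breakdown(c(0.5, NA, 7), c(TRUE, FALSE, TRUE), rep("c", 3))
  expect_equal(sum(pb2$pct) + 100 * 1 / 3, 100)
  expect_error(period_breakdown(yrs, has, cl, periods = list(c(0, 2), c(1, 5))),
               "overlap")
})

test_that("biomarker binning produces guideline groups, dropping empty bins", {
  set.seed(23)
  n <- 600
  bio <- exp(rnorm(n, log(300), 1))
  lam <- 0.05 * (1 + 2 * (bio > 900))
  time <- rexp(n, lam)
  res <- biomarker_km(time, rep(1, n), bio, breaks = biomarker_thresholds()$NTproBNP)
  expect_equal(length(res$km$groups), 3)
  top_hr <- res$hr[grepl("900", res$hr$term) & !grepl("125,900", res$hr$term), ]
  expect_gt(top_hr$hr, 1.5)
  expect_warning(
    biomarker_km(time, rep(1, n), pmin(bio, 800), breaks = c(0, 125, 900, Inf)),
    "empty")
  single <- biomarker_km(time, rep(1, n), bio, breaks = c(0, Inf))
  expect_null(single$hr)
})
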