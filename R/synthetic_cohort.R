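# Synthetic cardio-oncology cohort generator.
#
# Emulates the statistical structure the downstream analysis assumes: latent
# patient subgroups with shifted biomarker levels and trajectories, irregular
# echo-style visit schedules, cause-specific cardiac-event and death hazards,
# independent right censoring, and MCAR missingness.

# Longitudinal variable catalogue: population mean/sd in natural units,
# measurement-error sd (natural units), plausible range for clamping, category.
.psn_variables <- function() {
  data.frame(
    variable = c("NTproBNP", "TroponinT", "creatinine", "LVEF", "BMI",
                 "sodium", "potassium", "hemoglobin", "EDV", "ESV"),
    unit = c("pg/mL", "ug/L", "mg/dL", "%", "kg/m2",
             "mmol/L", "mmol/L", "g/dL", "mL", "mL"),
    category = c("cardiac", "cardiac", "lab", "echocardiogram", "demographics",
                 "lab", "lab", "lab", "echocardiogram", "echocardiogram"),
    mean = c(300, 0.030, 0.95, 58, 28, 140, 4.2, 12.5, 120, 50),
    sd = c(250, 0.030, 0.25, 7, 6, 3, 0.4, 1.8, 25, 15),
    err_sd_frac = c(0.30, 0.30, 0.20, 0.25, 0.10, 0.30, 0.30, 0.25, 0.25, 0.25),
    lo = c(0, 0, 0.2, 10, 12, 120, 2.5, 5, 40, 10),
    hi = c(35000, 10, 15, 85, 70, 160, 7, 20, 400, 300),
    stringsAsFactors = FALSE
  )
}

# Per-subgroup mean shifts (multiples of feature_shift, in nominal-sd units)
# across the variable catalogue. Rows = subgroup archetypes: 1 = cardiac-
# dominant high-risk (elevated natriuretic peptide and troponin, reduced LVEF,
# dilated ventricle), 2 = reference low-risk, 3 = renal/metabolic (elevated
# creatinine and BMI, mild cardiac involvement), 4 = advanced-cancer/cachexia
# (elevated NT-proBNP, low BMI and hemoglobin, late stage). Columns follow
# .psn_variables() order: NTproBNP, TroponinT, creatinine, LVEF, BMI, sodium,
# potassium, hemoglobin, EDV, ESV. Directions are deliberately non-collinear:
# the cosine geometry downstream distinguishes profile directions, not
# magnitudes.
.psn_shift_pattern <- function(n_subgroups) {
  base <- rbind(
    c(1.00, 1.00, 0.00, -1.00,  0.00,  0.00,  0.00,  0.00,  0.75,  1.00),
    c(0.00, 0.00, 0.00,  0.00,  0.00,  0.00,  0.00,  0.00,  0.00,  0.00),
    c(0.00, 0.00, 1.00,  0.00,  1.00, -0.50,  0.75, -0.25,  0.00,  0.00),
    c(0.75, 0.25, 0.25,  0.00, -1.00, -0.75, -0.25, -1.00, -0.50, -0.25)
  )
  if (n_subgroups <= 4) return(base[seq_len(n_subgroups), , drop = FALSE])
  extra <- t(vapply(seq_len(n_subgroups - 4), function(g) {
    s <- 0.25 * g
    c(s, -s, s, -0.25 * s, 0.75 * s, 0, 0, s, -s, 0)
  }, numeric(10)))
  rbind(base, extra)
}

# Per-subgroup trajectory slopes (nominal-sd units per year): the cardiac-
# dominant group shows rising natriuretic peptide/troponin and declining LVEF
# over follow-up, the others milder drifts.
.psn_slope_pattern <- function(n_subgroups) {
  base <- rbind(
    c(0.075, 0.050, 0.025, -0.050, 0.000, 0.000, 0.000,  0.000,  0.025,  0.025),
    c(0.000, 0.000, 0.000,  0.000, 0.000, 0.000, 0.000,  0.000,  0.000,  0.000),
    c(0.040, 0.025, 0.030, -0.025, 0.010, 0.000, 0.010,  0.000,  0.000,  0.000),
    c(0.050, 0.025, 0.000, -0.015, -0.025, 0.000, 0.000, -0.025,  0.000,  0.000)
  )
  if (n_subgroups <= 4) return(base[seq_len(n_subgroups), , drop = FALSE])
  rbind(base, matrix(0, n_subgroups - 4, 10))
}

.psn_event_types <- c("AF", "CAD", "HF", "MI", "stroke")

#' Configuration for the synthetic cardio-oncology cohort
#'
#' Defaults emulate a referral cardio-oncology cohort: four latent subgroups
#' with distinct cardiac-event and death hazards, biomarker mean shifts on
#' NT-proBNP (pg/mL), Troponin T (ug/L), creatinine (mg/dL), LVEF (%) and BMI
#' (kg/m2), roughly one echocardiogram visit per year over up to 20 years of
#' follow-up, and independent exponential right censoring.
#'
#' @param n_patients Cohort size.
#' @param n_subgroups Number of latent subgroups (>= 2, default 4).
#' @param subgroup_proportions Simplex vector of subgroup membership
#'   probabilities (default mirrors observed subgroup sizes 13.5/39/20.5/27%).
#' @param feature_shift Magnitude (population-sd units) of the planted
#'   per-subgroup mean shifts on the signal variables.
#' @param visit_rate Expected echo visits per year (homogeneous Poisson).
#' @param surveillance_years Length of the echo surveillance window after
#'   therapy start (years): visits are scheduled within the first
#'   `surveillance_years` of follow-up (or until death/censoring if earlier),
#'   reflecting that imaging concentrates around active treatment rather than
#'   spreading uniformly over two decades.
#' @param followup_horizon Administrative follow-up horizon in years.
#' @param death_hazards Per-subgroup all-cause death rate (1/year).
#' @param event_hazards Per-subgroup x per-event-type matrix of cause-specific
#'   rates (1/year), columns AF, CAD, HF, MI, stroke. Defaults distribute
#'   `ctrcd_hazards` over event types with weights 0.3/0.2/0.3/0.1/0.1.
#' @param ctrcd_hazards Per-subgroup total de novo cardiac-event rate (1/year);
#'   used only to build the default `event_hazards`.
#' @param preexisting_prob Probability a patient carries a cardiac event dated
#'   before therapy start.
#' @param censor_rate Independent censoring rate (1/year).
#' @param missing_rate MCAR probability that any single measurement is missing.
#' @param within_sd Between-patient spread within a subgroup, as a fraction
#'   of the variable's nominal (cohort-level) sd; the nominal sd also absorbs
#'   the between-subgroup shifts, so within-subgroup spread is smaller.
#' @param noise_cor Correlation of the additive patient-level noise shared
#'   across longitudinal variables (0 = independent noise).
#' @param severity_sd Log-sd of a multiplicative patient severity factor that
#'   scales each patient's whole deviation from the cohort means, inducing
#'   positive noise correlation across all variables (sicker patients deviate
#'   more on everything). 0 (default) disables it. It perturbs deviation
#'   magnitudes while preserving profile directions.
#' @param axis_frac Fraction of within-subgroup variance aligned with the
#'   subgroup's own archetype direction (a latent disease-severity axis):
#'   within the cardiac-dominant subgroup, say, NT-proBNP, troponin and LVEF
#'   co-vary, giving the variable networks genuine subgroup-specific
#'   correlation structure. 0 makes within-subgroup noise independent; the
#'   reference (zero-shift) subgroup has no axis regardless.
#' @param seed Integer seed; identical configurations reproduce identical
#'   cohorts byte for byte.
#' @return An object of class `cohort_config` (a validated list).
#' @export
cohort_config <- function(n_patients = 2000,
                          n_subgroups = 4,
                          subgroup_proportions = NULL,
                          feature_shift = 2,
                          visit_rate = 1.0,
                          surveillance_years = 5,
                          followup_horizon = 20,
                          death_hazards = NULL,
                          event_hazards = NULL,
                          ctrcd_hazards = NULL,
                          preexisting_prob = 0.17,
                          censor_rate = 0.08,
                          missing_rate = 0.05,
                          within_sd = 0.5,
                          noise_cor = 0,
                          severity_sd = 0,
                          axis_frac = 0.4,
                          seed = 1L) {
  if (n_subgroups < 2) stop("n_subgroups must be >= 2")
  if (is.null(subgroup_proportions)) {
    subgroup_proportions <- if (n_subgroups == 4) c(0.135, 0.390, 0.205, 0.270)
      else rep(1 / n_subgroups, n_subgroups)
  }
  if (length(subgroup_proportions) != n_subgroups)
    stop("subgroup_proportions must have length n_subgroups")
  if (abs(sum(subgroup_proportions) - 1) > 1e-12)
    stop("subgroup_proportions must sum to 1")
  if (any(subgroup_proportions < 0)) stop("subgroup_proportions must be non-negative")
  if (is.null(death_hazards)) {
    death_hazards <- if (n_subgroups == 4) c(0.08, 0.02, 0.045, 0.13)
      else seq(0.03, 0.13, length.out = n_subgroups)
  }
  if (is.null(ctrcd_hazards)) {
    ctrcd_hazards <- if (n_subgroups == 4) c(0.20, 0.02, 0.10, 0.05)
      else seq(0.02, 0.2, length.out = n_subgroups)
  }
  if (is.null(event_hazards)) {
    weights <- c(AF = 0.3, CAD = 0.2, HF = 0.3, MI = 0.1, stroke = 0.1)
    event_hazards <- outer(ctrcd_hazards, weights)
    colnames(event_hazards) <- .psn_event_types
  }
  event_hazards <- as.matrix(event_hazards)
  if (!all(dim(event_hazards) == c(n_subgroups, 5)))
    stop("event_hazards must be an n_subgroups x 5 matrix (AF, CAD, HF, MI, stroke)")
  dimnames(event_hazards) <- list(NULL, .psn_event_types)
  rates <- c(death_hazards, event_hazards, censor_rate, visit_rate, missing_rate)
  if (any(rates < 0) || any(!is.finite(rates))) stop("all rates must be finite and >= 0")
  if (length(death_hazards) != n_subgroups) stop("death_hazards must have length n_subgroups")
  if (missing_rate >= 1) stop("missing_rate must be < 1")
  if (noise_cor < 0 || noise_cor >= 1) stop("noise_cor must be in [0, 1)")
  if (within_sd <= 0) stop("within_sd must be positive")
  if (severity_sd < 0) stop("severity_sd must be >= 0")
  if (axis_frac < 0 || axis_frac >= 1) stop("axis_frac must be in [0, 1)")
  if (followup_horizon <= 0) stop("followup_horizon must be positive")
  if (surveillance_years <= 0) stop("surveillance_years must be positive")
  cfg <- list(
    n_patients = as.integer(n_patients), n_subgroups = as.integer(n_subgroups),
    subgroup_proportions = subgroup_proportions, feature_shift = feature_shift,
    visit_rate = visit_rate, surveillance_years = surveillance_years,
    followup_horizon = followup_horizon,
    death_hazards = death_hazards, event_hazards = event_hazards,
    ctrcd_hazards = ctrcd_hazards, preexisting_prob = preexisting_prob,
    censor_rate = censor_rate, missing_rate = missing_rate,
    within_sd = within_sd, noise_cor = noise_cor, severity_sd = severity_sd,
    axis_frac = axis_frac, seed = as.integer(seed)
  )
  class(cfg) <- "cohort_config"
  cfg
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat(sprintf("  %d patients, %d subgroups (proportions %s)\n", x$n_patients,
              x$n_subgroups, paste(signif(x$subgroup_proportions, 3), collapse = "/")))
  cat(sprintf("  feature shift %.2f sd; visit rate %.2f/yr; horizon %g yr\n",
              x$feature_shift, x$visit_rate, x$followup_horizon))
  cat(sprintf("  death hazards %s /yr; censor %.3g/yr; seed %d\n",
              paste(signif(x$death_hazards, 3), collapse = "/"), x$censor_rate, x$seed))
  invisible(x)
}

#' Generate a synthetic cardio-oncology cohort
#'
#' Draws subgroup memberships, per-patient linear biomarker trajectories
#' observed at irregular Poisson visit times, cause-specific exponential event
#' and death times truncated at the follow-up horizon, and independent
#' exponential censoring. A mandatory baseline visit at day 0 is always
#' included, and every patient has at least two visits.
#'
#' @param config A [cohort_config()] object.
#' @return An object of class `synthetic_cohort`: a list with `static`
#'   (demographics and therapy start), `measurements` (long format:
#'   patient_id, variable, value, days_from_therapy_start), `events`
#'   (patient_id, event_type, days_from_therapy_start, is_death, is_censor;
#'   one terminal death-or-censor row per patient), `truth` (planted subgroup
#'   labels), `variables` (units and category metadata) and the config.
#' @export
#' @examples
#' coh <- generate_cohort(cohort_config(n_patients = 50, seed = 7))
#' head(coh$measurements)
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_patients
  G <- config$n_subgroups
  vars <- .psn_variables()
  nv <- nrow(vars)
  shift <- .psn_shift_pattern(G) * config$feature_shift  # columns = catalogue order
  slope <- .psn_slope_pattern(G)

  ids <- sprintf("P%05d", seq_len(n))
  grp <- sample.int(G, n, replace = TRUE, prob = config$subgroup_proportions)

  ## static table -------------------------------------------------------------
  age <- pmin(pmax(round(stats::rnorm(n, 63, 11)), 25), 92)
  sex <- ifelse(stats::runif(n) < 0.59, "F", "M")
  tumor <- ifelse(stats::runif(n) < 0.39, "hematologic", "solid")
  stage_probs <- rbind(
    matrix(rep(c(0.25, 0.30, 0.25, 0.20), G - 1), G - 1, 4, byrow = TRUE),
    c(0.10, 0.20, 0.30, 0.40)  # worst-mortality subgroup skews to late stage
  )
  stage <- vapply(grp, function(g) sample.int(4, 1, prob = stage_probs[min(g, G), ]),
                  integer(1))
  start_day <- sort(sample.int(7200, n, replace = TRUE))  # ~20y accrual window
  therapy_start <- as.Date("1997-03-01") + start_day
  static <- data.frame(
    patient_id = ids, age = age, sex = sex, tumor_class = tumor,
    tumor_stage = stage, therapy_start = therapy_start,
    stringsAsFactors = FALSE
  )

  ## follow-up, death, censoring ---------------------------------------------
  rexp_or_inf <- function(rate, m) if (rate > 0) stats::rexp(m, rate) else rep(Inf, m)
  death_t <- vapply(grp, function(g) {
    if (config$death_hazards[g] > 0) stats::rexp(1, config$death_hazards[g]) else Inf
  }, numeric(1))
  censor_t <- rexp_or_inf(config$censor_rate, n)
  fu_end <- pmin(censor_t, config$followup_horizon)   # admin + random censoring
  obs_end <- pmin(death_t, fu_end)                    # end of observation
  died <- death_t <= fu_end

  ## cardiac events ------------------------------------------------------------
  ev_list <- vector("list", n)
  for (i in seq_len(n)) {
    lam <- config$event_hazards[grp[i], ]
    et <- ifelse(lam > 0, stats::rexp(5, pmax(lam, 1e-300)), Inf)
    et[lam == 0] <- Inf
    keep <- which(et <= obs_end[i])
    rows <- if (length(keep)) {
      data.frame(patient_id = ids[i], event_type = .psn_event_types[keep],
                 days_from_therapy_start = round(et[keep] * 365.25),
                 is_death = 0L, is_censor = 0L, stringsAsFactors = FALSE)
    } else NULL
    if (stats::runif(1) < config$preexisting_prob) {
      pre <- data.frame(
        patient_id = ids[i],
        event_type = sample(.psn_event_types, 1, prob = c(0.3, 0.2, 0.3, 0.1, 0.1)),
        days_from_therapy_start = -round(stats::runif(1, 1, 730)),
        is_death = 0L, is_censor = 0L, stringsAsFactors = FALSE)
      rows <- rbind(rows, pre)
    }
    term <- data.frame(patient_id = ids[i],
                       event_type = if (died[i]) "death" else "censor",
                       days_from_therapy_start = round(obs_end[i] * 365.25),
                       is_death = as.integer(died[i]),
                       is_censor = as.integer(!died[i]), stringsAsFactors = FALSE)
    ev_list[[i]] <- rbind(rows, term)
  }
  events <- do.call(rbind, ev_list)
  rownames(events) <- NULL

  ## longitudinal measurements -------------------------------------------------
  rho <- config$noise_cor
  shared <- stats::rnorm(n)  # patient-level factor shared across variables
  sev <- if (config$severity_sd > 0)
    exp(config$severity_sd * stats::rnorm(n) - config$severity_sd^2 / 2)
  else rep(1, n)
  # unit archetype directions for the within-subgroup severity axis
  axis_dir <- .psn_shift_pattern(G)
  axis_norm <- sqrt(rowSums(axis_dir^2))
  axis_dir <- axis_dir / ifelse(axis_norm > 0, axis_norm, 1)
  meas_list <- vector("list", n)
  for (i in seq_len(n)) {
    g <- grp[i]
    horizon_i <- max(min(obs_end[i], config$surveillance_years), 1 / 365.25)
    n_extra <- stats::rpois(1, config$visit_rate * horizon_i)
    if (n_extra < 1) n_extra <- 1  # every patient has >= 2 visits
    # echo scheduling is month-granular: quantize to a 30-day grid, which also
    # keeps two-visit slope estimates away from near-zero time spans
    end_day <- max(1, floor(horizon_i * 365.25))
    tdays <- pmin(pmax(30L, 30L * round(
      stats::runif(n_extra, 1, horizon_i * 365.25) / 30)), end_day)
    tdays <- sort(unique(c(0L, tdays)))
    if (length(tdays) < 2) tdays <- c(0L, max(1L, round(end_day / 2)))
    tyears <- tdays / 365.25
    nt <- length(tdays)
    base_shift <- shift[g, ] * vars$sd
    slope_v <- sev[i] * slope[g, ] * vars$sd
    # one latent severity draw spread along the unit archetype direction;
    # sqrt(nv) keeps the average per-variable variance contribution = axis_frac
    ax <- if (axis_norm[g] > 0 && config$axis_frac > 0)
      sqrt(config$axis_frac) * stats::rnorm(1) * axis_dir[g, ] * sqrt(nv)
    else numeric(nv)
    noise_i <- sqrt(1 - config$axis_frac) *
      (sqrt(1 - rho) * stats::rnorm(nv) + sqrt(rho) * shared[i]) + ax
    intercept <- vars$mean + sev[i] * (base_shift + vars$sd * config$within_sd * noise_i)
    vals <- matrix(rep(intercept, each = nt), nt, nv) +
      outer(tyears, slope_v) +
      matrix(stats::rnorm(nt * nv), nt, nv) *
        rep(vars$sd * vars$err_sd_frac, each = nt)
    vals <- pmin(pmax(vals, rep(vars$lo, each = nt)), rep(vars$hi, each = nt))
    meas_list[[i]] <- data.frame(
      patient_id = ids[i],
      variable = rep(vars$variable, each = nt),
      value = as.vector(vals),
      days_from_therapy_start = rep(tdays, nv),
      stringsAsFactors = FALSE
    )
  }
  measurements <- do.call(rbind, meas_list)
  rownames(measurements) <- NULL
  if (config$missing_rate > 0) {
    keep <- stats::runif(nrow(measurements)) >= config$missing_rate
    # never drop a patient's whole series: keep at least the baseline row
    keep[!duplicated(paste(measurements$patient_id, measurements$variable))] <- TRUE
    measurements <- measurements[keep, , drop = FALSE]
    rownames(measurements) <- NULL
  }

  out <- list(
    static = static, measurements = measurements, events = events,
    truth = data.frame(patient_id = ids, subgroup = grp, stringsAsFactors = FALSE),
    variables = vars[, c("variable", "unit", "category")],
    config = config
  )
  class(out) <- "synthetic_cohort"
  out
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d patients, %d measurements, %d event rows\n",
              nrow(x$static), nrow(x$measurements), nrow(x$events)))
  cat("  planted subgroup sizes:",
      paste(table(x$truth$subgroup), collapse = "/"), "\n")
  invisible(x)
}

#' Write a synthetic cohort to delimited files
#'
#' Writes `static.csv`, `measurements.csv`, `events.csv`, `truth.csv` and
#' `config.json` (exact round trip via [read_cohort()]).
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("static.csv", "measurements.csv", "events.csv",
                            "truth.csv", "config.json"))
  utils::write.csv(cohort$static, paths[1], row.names = FALSE)
  utils::write.csv(cohort$measurements, paths[2], row.names = FALSE)
  utils::write.csv(cohort$events, paths[3], row.names = FALSE)
  utils::write.csv(cohort$truth, paths[4], row.names = FALSE)
  writeLines(config_to_json(cohort$config), paths[5])
  invisible(paths)
}

#' Read a cohort previously written by [write_cohort()]
#' @param dir Directory containing the csv files.
#' @return A `synthetic_cohort` (truth/config present only if on disk).
#' @export
read_cohort <- function(dir) {
  static <- utils::read.csv(file.path(dir, "static.csv"), stringsAsFactors = FALSE)
  static$therapy_start <- as.Date(static$therapy_start)
  out <- list(
    static = static,
    measurements = utils::read.csv(file.path(dir, "measurements.csv"),
                                   stringsAsFactors = FALSE),
    events = utils::read.csv(file.path(dir, "events.csv"), stringsAsFactors = FALSE),
    variables = .psn_variables()[, c("variable", "unit", "category")]
  )
  tp <- file.path(dir, "truth.csv")
  if (file.exists(tp)) out$truth <- utils::read.csv(tp, stringsAsFactors = FALSE)
  cp <- file.path(dir, "config.json")
  if (file.exists(cp)) out$config <- config_from_json(paste(readLines(cp), collapse = "\n"))
  class(out) <- "synthetic_cohort"
  out
}

#' Serialize a cohort configuration to JSON
#' @param config A `cohort_config`.
#' @return A JSON string; [config_from_json()] restores an identical object.
#' @export
config_to_json <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  x <- unclass(config)
  x$event_hazards <- as.data.frame(x$event_hazards)
  jsonlite::toJSON(x, digits = NA, auto_unbox = TRUE, pretty = TRUE)
}

#' Restore a cohort configuration from JSON
#' @param json JSON string produced by [config_to_json()].
#' @return A validated `cohort_config`.
#' @export
config_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  x$event_hazards <- as.matrix(x$event_hazards)
  do.call(cohort_config, x)
}
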