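test_that("trajectory features match closed forms on exact lines", {
  f <- derive_longitudinal_features(c(0, 30, 60), c(0, 1, 2))
  expect_equal(unname(f["slope"]), 1 / 30)
  expect_equal(unname(f["max"]), 2)
  expect_equal(unname(f["min"]), 0)
  expect_equal(unname(f["max_increase_3mo"]), 2)
  expect_equal(unname(f["max_decrease_3mo"]), 0)

  g <- derive_longitudinal_features(c(0, 200), c(5, 3))
  expect_true(is.na(g["max_increase_3mo"]))
  expect_true(is.na(g["max_decrease_3mo"]))
  expect_equal(unname(g["slope"]), -0.01)

  expect_true(all(is.na(derive_longitudinal_features(numeric(0), numeric(0)))))
  one <- derive_longitudinal_features(5, 7)
  expect_equal(unname(one["max"]), 7)
  expect_true(is.na(one["slope"]))
})

test_that("window features equal the exhaustive pair scan and slope equals lm", {
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(3:20, 1)
    t <- sort(sample(0:400, n))
    v <- rnorm(n)
    f <- derive_longitudinal_features(t, v, window_days = 92)
    o <- oracle_window_features(t, v, 92)
    expect_equal(unname(f["max_increase_3mo"]), o$max_increase)
    expect_equal(unname(f["max_decrease_3mo"]), o$max_decrease)
    expect_equal(unname(f["slope"]), unname(coef(lm(v ~ t))[2]))
  }
})

test_that("feature derivation is order-invariant and averages duplicate times", {
  set.seed(7)
  t <- c(0, 30, 30, 90, 200)
  v <- rnorm(5)
  f1 <- derive_longitudinal_features(t, v)
  perm <- sample(5)
  f2 <- derive_longitudinal_features(t[perm], v[perm])
  expect_equal(f1, f2)
  # duplicates at t=30 averaged
  f3 <- derive_longitudinal_features(c(0, 30, 90, 200),
                                     c(v[1], mean(v[2:3]), v[4], v[5]))
  expect_equal(f1, f3)
})

test_that("outlier flagging removes gross errors and spares clean columns", {
  set.seed(1)
  x <- cbind(a = rnorm(999), b = rep(5, 999))
  x <- rbind(x, c(1e6, 5))
  fm <- structure(list(x = x, ids = as.character(1:1000),
                       feature_info = data.frame(feature = c("a", "b"),
                                                 base_variable = c("a", "b"),
                                                 kind = "static"),
                       scaled = FALSE), class = "feature_matrix")
  out <- suppressMessages(remove_outliers(fm, z_limit = 4))
  expect_identical(which(is.na(out$x[, "a"])), 1000L)  # exactly the planted error
  expect_equal(sum(is.na(out$x[, "b"])), 0)            # constant column untouched
  expect_equal(out$n_outliers, 1L)

  inf_out <- suppressMessages(remove_outliers(fm, z_limit = Inf))
  expect_equal(inf_out$x, fm$x)                        # identity at infinite limit
})

test_that("mean imputation then z-scoring matches hand computation", {
  x <- cbind(v = c(1, NA, 3))
  fm <- structure(list(x = x, ids = as.character(1:3),
                       feature_info = data.frame(feature = "v",
                                                 base_variable = "v",
                                                 kind = "static"),
                       scaled = FALSE), class = "feature_matrix")
  out <- impute_and_scale(fm)
  # imputed 2; population sd of (1,2,3) = sqrt(2/3)
  expect_equal(unname(out$x[, 1]), c(-1, 0, 1) / sqrt(2 / 3))
  expect_equal(unname(out$x[2, 1]), 0)  # imputed entries sit at 0 after scaling
  expect_true(out$mask[2, 1])

  # post-scaling column invariants
  set.seed(3)
  y <- matrix(rnorm(200), 20, 10)
  y[sample(200, 30)] <- NA
  fm2 <- structure(list(x = y, ids = as.character(1:20),
                        feature_info = data.frame(feature = paste0("f", 1:10),
                                                  base_variable = paste0("f", 1:10),
                                                  kind = "static"),
                        scaled = FALSE), class = "feature_matrix")
  out2 <- impute_and_scale(fm2)
  expect_false(anyNA(out2$x))
  expect_true(all(abs(colMeans(out2$x)) < 1e-9))
  expect_true(all(abs(sqrt(colMeans(sweep(out2$x, 2, colMeans(out2$x))^2)) - 1) < 1e-9))
})

test_that("degenerate columns are handled: all-missing dropped, zero-variance flagged", {
  x <- cbind(a = c(1, 2, 3), b = c(NA, NA, NA), c = c(5, 5, 5))
  fm <- structure(list(x = x, ids = as.character(1:3),
                       feature_info = data.frame(feature = c("a", "b", "c"),
                                                 base_variable = c("a", "b", "c"),
                                                 kind = "static"),
                       scaled = FALSE), class = "feature_matrix")
  expect_warning(out <- impute_and_scale(fm), "all-missing")
  expect_false("b" %in% colnames(out$x))
  expect_identical(out$zero_variance, "c")
  expect_equal(unname(out$x[, "c"]), c(0, 0, 0))  # centred, not scaled
})

test_that("imputation and scaling commute with patient reordering", {
  set.seed(9)
  y <- matrix(rnorm(120), 12, 10)
  y[sample(120, 15)] <- NA
  mk <- function(m) structure(list(x = m, ids = rownames(m),
                                   feature_info = data.frame(
                                     feature = colnames(m),
                                     base_variable = colnames(m), kind = "static"),
                                   scaled = FALSE), class = "feature_matrix")
  dimnames(y) <- list(paste0("p", 1:12), paste0("f", 1:10))
  perm <- sample(12)
  a <- impute_and_scale(mk(y))
  b <- impute_and_scale(mk(y[perm, ]))
  expect_equal(a$x[perm, ], b$x)
})

test_that("feature matrix is built per patient x variable and slopes are unbiased", {
  coh <- planted_cohort(n = 1000, seed = 31)
  fm <- build_feature_matrix(coh$measurements, coh$static)
  expect_equal(rownames(fm$x), coh$static$patient_id)
  expect_true(all(c("NTproBNP_max", "LVEF_slope", "age", "sex_male") %in% colnames(fm$x)))

  # LVEF slope (per day): planted per-subgroup slope recovered without bias
  tr <- truth_of(coh, rownames(fm$x))
  sd_lvef <- 7
  pat <- psnstrat:::.psn_slope_pattern(4)
  for (g in c(1, 2)) {
    est <- fm$x[tr == g, "LVEF_slope"]
    est <- est[is.finite(est)]
    planted <- pat[g, 4] * sd_lvef / 365.25
    mc_se <- sd(est) / sqrt(length(est))
    expect_lt(abs(mean(est) - planted), 2 * mc_se + 1e-8)
  }
})

test_that("train-set transform applies to held-out patients without leakage", {
  coh <- planted_cohort(n = 300, seed = 41)
  ids <- coh$static$patient_id
  train <- ids[1:200]; test <- ids[201:300]
  sub <- function(set) list(
    measurements = coh$measurements[coh$measurements$patient_id %in% set, ],
    static = coh$static[ids %in% set, ])
  fm_tr <- impute_and_scale(suppressMessages(remove_outliers(
    build_feature_matrix(sub(train)$measurements, sub(train)$static))))
  fm_te_raw <- build_feature_matrix(sub(test)$measurements, sub(test)$static)
  fm_te <- apply_preprocess(fm_te_raw, fm_tr)
  expect_identical(colnames(fm_te$x), colnames(fm_tr$x))
  expect_false(anyNA(fm_te$x))
  # a raw value transformed by hand: (x - center) / scale
  j <- which(colnames(fm_tr$x) == "age")
  expect_equal(fm_te$x[1, j],
               unname((fm_te_raw$x[1, "age"] - fm_tr$center[j]) / fm_tr$scale[j]))
})
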