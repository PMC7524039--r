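test_that("imputation is a no-op on complete data and exact on noiseless fixtures", {
  sim <- small_sim(seed = 2)
  expect_identical(impute_for_fit(sim$data)$values, sim$data$values)

  # ROI that is an exact linear function of the covariates within each site
  cv <- tibble::tibble(
    subject_id = sprintf("s%02d", 1:14),
    site = rep(c("a", "b"), each = 7),
    dx = rep(c(1, 0, 1, 0, 1, 0, 1), 2),
    age = c(30, 41, 25, 52, 37, 44, 29, 33, 48, 21, 39, 55, 27, 36),
    sex = rep(c(0, 1, 0, 1, 1, 0, 1), 2))
  y <- 1 + 0.5 * cv$age + 2 * cv$dx - 0.3 * cv$sex
  m <- tibble::tibble(subject_id = cv$subject_id, roiX = y,
                      roiY = seq_len(14) * 1.0)
  m$roiX[c(2, 9)] <- NA
  d <- roi_dataset(m, cv)
  imp <- impute_for_fit(d)
  expect_equal(imp$values[2, "roiX"],
               1 + 0.5 * cv$age[2] + 2 * cv$dx[2] - 0.3 * cv$sex[2],
               tolerance = 1e-10)
  expect_equal(imp$values[9, "roiX"],
               1 + 0.5 * cv$age[9] + 2 * cv$dx[9] - 0.3 * cv$sex[9],
               tolerance = 1e-10)
  # observed cells untouched
  obs <- !is.na(d$values)
  expect_identical(imp$values[obs], d$values[obs])
})

test_that("imputation errors name inestimable site/ROI pairs and falls back on rank deficiency", {
  sim <- small_sim(n_sites = 2, n_per_site = 10, n_rois = 2, seed = 3)
  d <- sim$data
  v <- d$values
  v[d$covariates$site == "site01", 1] <- NA  # entire site/ROI missing
  d_allmiss <- roi_dataset(
    dplyr::bind_cols(tibble::tibble(subject_id = rownames(v)),
                     tibble::as_tibble(v)), d$covariates)
  expect_error(impute_for_fit(d_allmiss), "roi01_thickavg.*site01")

  v2 <- d$values
  v2[which(d$covariates$site == "site01")[1:7], 1] <- NA  # 3 < 5 observed
  d_few <- roi_dataset(
    dplyr::bind_cols(tibble::tibble(subject_id = rownames(v2)),
                     tibble::as_tibble(v2)), d$covariates)
  expect_error(impute_for_fit(d_few), "only 3 observed")

  # constant sex within the site with the hole -> local design rank-deficient,
  # observed site/ROI mean used
  cv <- tibble::tibble(
    subject_id = sprintf("s%02d", 1:14),
    site = rep(c("a", "b"), each = 7),
    dx = rep(c(1, 0, 1, 0, 1, 0, 1), 2),
    age = c(30, 41, 25, 52, 37, 44, 29, 33, 48, 21, 39, 55, 27, 36),
    sex = c(rep(0, 7), c(0, 1, 0, 1, 1, 0, 1)))
  m <- tibble::tibble(subject_id = cv$subject_id,
                      roiX = c(1, 2, 3, 4, 5, 6, NA, 8:14),
                      roiY = 1:14 * 1.0)
  d2 <- roi_dataset(m, cv)
  imp <- impute_for_fit(d2)
  expect_equal(unname(imp$values[7, "roiX"]), mean(1:6))
})

test_that("zero-variance ROIs are excluded at fit and passed through at apply", {
  sim <- generate_dataset(synth_config(
    n_sites = 3, n_per_site = 30, n_thickness = 5, g = 0.2,
    inject_constant_roi = TRUE, seed = 4))
  d <- sim$data
  m <- combat_fit(d)
  expect_false(m$included_rois[["constant_roi"]])
  expect_true(all(m$included_rois[1:5]))
  expect_warning(h <- combat_apply(m, d), "constant_roi")
  expect_identical(h$values[, "constant_roi"], d$values[, "constant_roi"])
  expect_false(identical(h$values[, 1], d$values[, 1]))
})

test_that("combat_apply never imputes: missing cells stay missing, observed cells change", {
  sim <- small_sim(n_sites = 4, n_per_site = 50, missing_rate = 0.1, seed = 6)
  d <- sim$data
  m <- combat_fit(d)
  h <- combat_apply(m, d)
  expect_identical(is.na(h$values), is.na(d$values))
  expect_identical(dim(h$values), dim(d$values))
  expect_identical(colnames(h$values), colnames(d$values))
})

test_that("harmonize() equals explicit fit+apply, and per-group harmonization matches per-subset runs", {
  sim <- generate_dataset(synth_config(
    n_sites = 3, n_per_site = 40, n_thickness = 3, n_area = 3, g = 0.2,
    seed = 7))
  d <- sim$data
  expect_identical(harmonize(d)$values, combat_apply(combat_fit(d), d)$values)

  groups <- roi_type_groups(roi_names(d))
  expect_named(groups, c("thickness", "area"))
  h_grp <- harmonize(d, groups = groups)
  for (g in groups) {
    sub <- roi_dataset(
      dplyr::bind_cols(tibble::tibble(subject_id = rownames(d$values)),
                       tibble::as_tibble(d$values[, g, drop = FALSE])),
      d$covariates)
    h_sub <- combat_apply(combat_fit(sub), sub)
    expect_identical(h_grp$values[, g], h_sub$values)
  }
  expect_error(harmonize(d, groups = list(a = roi_names(d)[1:2])),
               "partition")
})

test_that("single vs per-type harmonization give nearly identical Hedges' g", {
  sim <- generate_dataset(synth_config(
    n_sites = 8, n_per_site = 80, n_thickness = 6, n_area = 6, n_volume = 4,
    g = c(-0.4, 0.3), seed = 11))
  d <- sim$data
  g_single <- suppressWarnings(run_pipeline(d, "combatmega"))$g
  g_split <- suppressWarnings(run_pipeline(
    d, "combatmega",
    harmonization_groups = roi_type_groups(roi_names(d))))$g
  expect_lt(max(abs(g_single - g_split)), 0.02)
})

test_that("unseen sites and covariate mismatches are rejected at apply time", {
  sim <- small_sim(n_sites = 4, seed = 9)
  d <- sim$data
  train <- harmon:::filter_sites(d, c("site01", "site02", "site03"))
  m <- combat_fit(train)
  expect_error(combat_apply(m, d), "site04")
  # a model fitted with an extra covariate cannot be applied without it
  d_icv <- d
  d_icv$covariates$icv <- rnorm(nrow(d$values), 1500, 100)
  m_icv <- combat_fit(d_icv, covariates = c("dx", "age", "sex", "icv"))
  expect_error(combat_apply(m_icv, d), "icv")
  # and fit/apply across sets works when contracts hold
  h <- combat_apply(m, harmon:::filter_sites(d, "site02"))
  expect_identical(nrow(h$values), sum(d$covariates$site == "site02"))
})

test_that("fit requires 2+ sites each with 2+ subjects", {
  sim <- small_sim(n_sites = 2, n_per_site = 20, seed = 10)
  d <- sim$data
  one_site <- harmon:::filter_sites(d, "site01")
  expect_error(combat_fit(one_site), "at least 2 sites")
  keep <- c(which(d$covariates$site == "site01"),
            which(d$covariates$site == "site02")[1])
  tiny <- roi_dataset(
    dplyr::bind_cols(tibble::tibble(subject_id = rownames(d$values)[keep]),
                     tibble::as_tibble(d$values[keep, , drop = FALSE])),
    d$covariates[keep, ])
  expect_error(combat_fit(tiny), "at least 2 subjects")
})

test_that("the weighted unshrunk additive estimates sum to zero within each ROI", {
  sim <- small_sim(n_sites = 5, n_per_site = c(20, 35, 50, 65, 80), seed = 12)
  m <- combat_fit(sim$data)
  w <- as.integer(table(sim$data$covariates$site))
  expect_lt(max(abs(colSums(m$gamma_hat * w))), 1e-8)
  expect_true(all(m$delta_star > 0))
})

test_that("harmonization shrinks per-site residual means and equalizes variances", {
  sim <- small_sim(n_sites = 6, n_per_site = 100, n_rois = 8,
                   site_mean_spread = 0.4, gamma_tau = 0.4, seed = 13)
  d <- sim$data
  h <- harmonize(d)
  X <- build_design(d$covariates, terms = c("age", "sex"))
  site <- d$covariates$site
  site_stats <- function(vals) {
    sapply(seq_len(ncol(vals)), function(r) {
      res <- stats::lm.fit(X, vals[, r])$residuals
      ms <- tapply(res, site, mean)
      vs <- tapply(res, site, stats::var)
      c(mean_abs = mean(abs(ms)), spread = max(vs) / min(vs))
    })
  }
  raw <- site_stats(d$values)
  adj <- site_stats(h$values)
  expect_true(all(adj["mean_abs", ] < raw["mean_abs", ]))
  expect_true(all(adj["spread", ] < raw["spread", ]))
})

test_that("the diagnosis effect survives harmonization without bias", {
  n_rep <- 200
  g_true <- 0.4
  bias <- vapply(seq_len(n_rep), function(i) {
    sim <- generate_dataset(synth_config(
      n_sites = 4, n_per_site = 40, n_thickness = 4, g = g_true, seed = 1000 + i))
    d <- sim$data
    h <- harmonize(d)
    X <- build_design(d$covariates, terms = c("age", "sex"))
    mean(vapply(seq_len(ncol(h$values)), function(r) {
      harmon:::ols_fit(h$values[, r], X)$coef
    }, numeric(1))) - g_true  # resid_sd = 1, so beta_dx = g
  }, numeric(1))
  expect_lt(abs(mean(bias)), 2 * stats::sd(bias) / sqrt(n_rep))
})

test_that("null site effects leave the data essentially unchanged as n grows", {
  rms <- vapply(c(100, 400, 1600), function(n) {
    sim <- generate_dataset(synth_config(
      n_sites = 5, n_per_site = n, n_thickness = 6, g = 0,
      site_mean_spread = 0, gamma_tau = 0, delta_shape = Inf, seed = 9))
    d <- sim$data
    h <- harmonize(d)
    sqrt(mean((h$values - d$values)^2))
  }, numeric(1))
  expect_true(all(diff(rms) < 0))
  expect_lt(rms[3], 0.05)
})

test_that("a fitted model survives the JSON round trip", {
  sim <- generate_dataset(synth_config(
    n_sites = 3, n_per_site = 30, n_thickness = 4, g = 0.2,
    inject_constant_roi = TRUE, seed = 14))
  d <- sim$data
  m <- combat_fit(d)
  path <- tempfile(fileext = ".json")
  write_combat_model(m, path)
  m2 <- read_combat_model(path)
  expect_equal(m2$alpha, m$alpha)
  expect_equal(m2$gamma_star, m$gamma_star)
  expect_equal(m2$delta_star, m$delta_star)
  expect_identical(m2$included_rois, m$included_rois)
  h1 <- suppressWarnings(combat_apply(m, d))
  h2 <- suppressWarnings(combat_apply(m2, d))
  expect_equal(h1$values, h2$values, tolerance = 1e-12)
})

test_that("tidy and glance summarize a fitted model", {
  sim <- small_sim(n_sites = 3, n_per_site = 25, n_rois = 4, seed = 15)
  m <- combat_fit(sim$data)
  td <- tidy(m)
  expect_identical(nrow(td), 12L)
  expect_named(td, c("site", "roi", "gamma_hat", "gamma_star",
                     "delta_hat", "delta_star"))
  gl <- glance(m)
  expect_identical(gl$n_sites, 3L)
  expect_identical(gl$n_rois_harmonized, 4L)
})
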