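test_that("hedges_g matches its closed form and symmetries", {
  # zero difference: only the variance term remains
  h0 <- hedges_g(0, 1.5, 12, 15)
  J0 <- 1 - 3 / (4 * (12 + 15 - 2) - 1)
  expect_equal(h0$g, 0)
  expect_equal(h0$var_g, J0^2 * (27 / (12 * 15)))

  # d = 0.5 with n1 = n2 = 10: J at df = 18 computed independently
  h1 <- hedges_g(0.5, 1, 10, 10)
  expect_equal(h1$g, 0.5 * (1 - 3 / 71))
  expect_equal(h1$df, 18)

  # covariates reduce the df used by the correction
  h2 <- hedges_g(0.5, 1, 10, 10, n_covariates = 2)
  expect_equal(h2$df, 16)
  expect_lt(h2$g, h1$g)

  # group swap: g antisymmetric, var symmetric when n1 = n2
  ha <- hedges_g(0.7, 2, 14, 14)
  hb <- hedges_g(-0.7, 2, 14, 14)
  expect_equal(ha$g, -hb$g)
  expect_equal(ha$var_g, hb$var_g)

  expect_error(hedges_g(1, 0, 10, 10), "positive")
  expect_error(hedges_g(1, 1, 1, 10), "at least 2")
})

test_that("site_linear_model recovers exact coefficients on noiseless data", {
  cv <- tibble::tibble(subject_id = sprintf("s%02d", 1:12), site = "a",
                       dx = rep(c(1, 0), 6), age = seq(20, 53, 3),
                       sex = rep(c(0, 1), each = 6))
  X <- build_design(cv, terms = "age")
  y <- 2 * cv$dx + 0.1 * cv$age
  fit <- site_linear_model(y, X)
  expect_equal(fit$coef, 2, tolerance = 1e-10)
  expect_lt(fit$se, 1e-8)

  # equal group means, no covariates -> zero coefficient
  X0 <- build_design(cv, terms = character(0))
  y0 <- rep(c(5, 5), 6)
  expect_equal(site_linear_model(y0 + 0 * cv$dx, X0)$coef, 0)

  # missing cells: the fit uses the observed subset only
  y_na <- y; y_na[1:3] <- NA
  fit_na <- site_linear_model(y_na, X)
  expect_identical(fit_na$n, 9L)
  expect_identical(fit_na$n_case, sum(cv$dx[-(1:3)] == 1))

  expect_error(site_linear_model(y, X[, c(1, 3)]), "diagnosis|subscript")
  expect_error(site_linear_model(y[1:3], X[1:3, ]), "too few")
})

test_that("holm_adjust matches the brute-force step-down on worked and random cases", {
  expect_equal(holm_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.04, 0.04))
  expect_equal(holm_adjust(c(1, 1, 1)), c(1, 1, 1))
  expect_equal(holm_adjust(0.2), 0.2)
  expect_error(holm_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  # independent step-down oracle: adj_(k) = max_{j<=k} min(1, (m-j+1) p_(j))
  holm_oracle <- function(p) {
    m <- length(p)
    ord <- order(p)
    adj_sorted <- cummax(pmin(1, (m - seq_len(m) + 1) * p[ord]))
    out <- numeric(m)
    out[ord] <- adj_sorted
    out
  }
  set.seed(42)
  for (i in 1:20) {
    p <- runif(sample(2:12, 1))^sample(1:3, 1)
    adj <- holm_adjust(p)
    expect_equal(adj, holm_oracle(p))
    expect_true(all(adj >= p))
    expect_identical(order(adj[order(p)]), seq_along(p))  # monotone
  }
})

test_that("re_meta_pool reproduces a hand-computed DerSimonian-Laird pool", {
  eff <- tibble::tibble(g = c(0.3, 0.5), var_g = c(0.01, 0.01))
  # by hand: w0 = 100 each; fixed-effect mean 0.4; Q = 100*0.01 + 100*0.01 = 2;
  # denom = 200 - 20000/200 = 100; tau2 = (2 - 1)/100 = 0.01;
  # w = 1/(0.01 + 0.01) = 50 each -> pooled 0.4, var = 1/100
  pool <- re_meta_pool(eff, method = "DL")
  expect_equal(pool$g, 0.4)
  expect_equal(pool$tau2, 0.01)
  expect_equal(pool$var_g, 0.01)
  expect_equal(pool$p, 2 * pnorm(-0.4 / 0.1))

  # degenerate single-site pool
  one <- re_meta_pool(tibble::tibble(g = 0.3, var_g = 0.01))
  expect_equal(one$g, 0.3)
  expect_equal(one$tau2, 0)
  expect_equal(one$p, 2 * pnorm(-3))

  # homogeneous effects with equal variances: tau2 = 0, pooled = common g
  hom <- re_meta_pool(tibble::tibble(g = rep(0.25, 5), var_g = rep(0.02, 5)))
  expect_equal(hom$g, 0.25)
  expect_equal(hom$tau2, 0)
})

test_that("the internal pooling engine agrees with metafor", {
  skip_if_not_installed("metafor")
  set.seed(31)
  for (i in 1:12) {
    k <- sample(2:25, 1)
    eff <- tibble::tibble(g = rnorm(k, 0.2, 0.2),
                          var_g = runif(k, 0.002, 0.08))
    for (method in c("REML", "DL")) {
      a <- re_meta_pool(eff, method, engine = "internal")
      b <- re_meta_pool(eff, method, engine = "metafor")
      # agreement up to the two optimizers' convergence criteria
      expect_equal(a$g, b$g, tolerance = 1e-4)
      expect_equal(a$tau2, b$tau2, tolerance = 1e-3)
      expect_equal(logit_p(a$p), logit_p(b$p), tolerance = 1e-3)
      # pooled variance can never beat the best site plus heterogeneity
      expect_lte(a$var_g, min(eff$var_g) + a$tau2 + 1e-12)
    }
  }
})

test_that("mixed model matches pooled OLS when the site variance is truly zero", {
  sim <- generate_dataset(synth_config(
    n_sites = 8, n_per_site = 100, n_thickness = 3, g = 0.3,
    site_mean_spread = 0, gamma_tau = 0, delta_shape = Inf, seed = 2))
  d <- sim$data
  mm <- suppressWarnings(mixed_effects_model(d$values[, 1], d$covariates))
  of <- harmon:::ols_fit(d$values[, 1], build_design(d$covariates))
  expect_equal(mm$coef, of$coef, tolerance = 1e-6)

  # same response through the pooled-effect stage and the mixed model:
  # Hedges' g agrees in the no-site-effect limit
  res_ols <- hedges_g(of$coef, of$sigma, sum(d$covariates$dx == 1),
                      sum(d$covariates$dx == 0), n_covariates = 2)
  res_mm <- hedges_g(mm$coef, mm$sd_resid, mm$n_case, mm$n_control,
                     n_covariates = 2)
  expect_equal(res_mm$g, res_ols$g, tolerance = 1e-3)
})

test_that("mixed model recovers a planted effect within 2 standard errors", {
  sim <- generate_dataset(synth_config(
    n_sites = 20, n_per_site = 50, n_thickness = 1, g = 0.4, seed = 17))
  d <- sim$data
  mm <- suppressWarnings(mixed_effects_model(d$values[, 1], d$covariates))
  expect_lt(abs(mm$coef - 0.4), 2 * mm$se)
  expect_true(mm$p < 0.05)
})

test_that("the three pipelines agree on effect sizes and signs at consortium scale", {
  g_true <- c(-0.4, -0.3, -0.2, -0.1, 0, 0.1, 0.2, 0.3, 0.4, 0.25)
  sim <- generate_dataset(synth_config(
    n_sites = 20, n_per_site = 300, n_thickness = 10, g = g_true, seed = 19))
  d <- sim$data
  res <- lapply(c("remeta", "memega", "combatmega"), function(pl) {
    suppressWarnings(run_pipeline(d, pl))$g
  })
  expect_lt(max(abs(res[[1]] - res[[2]])), 0.05)
  expect_lt(max(abs(res[[1]] - res[[3]])), 0.05)
  expect_lt(max(abs(res[[2]] - res[[3]])), 0.05)
  strong <- abs(g_true) >= 0.2
  for (g_est in res) {
    expect_identical(sign(g_est[strong]), sign(g_true[strong]))
  }
})

test_that("run_pipeline output satisfies the effect-result contract", {
  sim <- small_sim(n_sites = 5, n_per_site = 60, n_rois = 6, seed = 21)
  res <- suppressWarnings(run_pipeline(sim$data, "remeta"))
  expect_s3_class(res, "effect_results")
  expect_identical(nrow(res), 6L)
  expect_true(all(res$var_g > 0))
  expect_true(all(res$ci_low < res$ci_high))
  expect_true(all(res$p >= 0 & res$p <= res$p_holm & res$p_holm <= 1))
  expect_true(all(res$tau2 >= 0))
  res_cm <- suppressWarnings(run_pipeline(sim$data, "combatmega"))
  expect_true(all(is.na(res_cm$tau2)))

  const <- sim$data
  const$values[] <- 1
  expect_error(suppressWarnings(run_pipeline(const, "combatmega")),
               "zero-variance")
})

test_that("sites with fewer than two subjects per group are dropped from pooling only", {
  sim <- small_sim(n_sites = 3, n_per_site = 30, n_rois = 2, seed = 23)
  d <- sim$data
  # make site03 all-control: inestimable for RE-Meta stage one
  d$covariates$dx[d$covariates$site == "site03"] <- 0
  eff <- site_effects(d)
  expect_false("site03" %in% eff$site)
  res <- suppressWarnings(run_pipeline(d, "remeta"))
  expect_identical(nrow(res), 2L)
})
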