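#' Hedges' g from a model coefficient
#'
#' Converts a case-control mean difference (a model coefficient for the
#' diagnosis indicator) into the small-sample-corrected standardized mean
#' difference and its sampling variance:
#' `d = coef / sd_pooled`, `J = 1 - 3 / (4 df - 1)` with
#' `df = n1 + n2 - 2 - n_covariates`, `g = J d`, and
#' `var_g = J^2 * ((n1 + n2) / (n1 n2) + d^2 / (2 (n1 + n2)))`.
#'
#' @param coef Mean difference (cases minus controls), any measurement unit.
#' @param sd_pooled Standardizer (> 0), typically the model residual SD.
#' @param n1,n2 Group sizes (cases, controls), both at least 2.
#' @param n_covariates Number of covariates adjusted for in the model
#'   (beyond the intercept and the diagnosis indicator); reduces the
#'   degrees of freedom used by the bias-correction factor.
#' @return A tibble with columns `g`, `var_g`, and `df`. Vectorized.
#' @export
hedges_g <- function(coef, sd_pooled, n1, n2, n_covariates = 0) {
  if (any(sd_pooled <= 0)) stop("sd_pooled must be positive", call. = FALSE)
  if (any(n1 < 2) || any(n2 < 2)) {
    stop("both groups need at least 2 subjects", call. = FALSE)
  }
  df <- n1 + n2 - 2 - n_covariates
  J <- 1 - 3 / (4 * df - 1)
  d <- coef / sd_pooled
  g <- J * d
  var_g <- J^2 * ((n1 + n2) / (n1 * n2) + d^2 / (2 * (n1 + n2)))
  tibble::tibble(g = g, var_g = var_g, df = df)
}

#' Per-site linear model for one ROI
#'
#' Ordinary least squares of one ROI's values on a design matrix whose
#' first non-intercept column is the diagnosis indicator; rows with a
#' missing measurement are dropped (listwise within the ROI).
#'
#' @param y Numeric vector of one ROI's values for the subjects of one site
#'   (`NA` allowed).
#' @param X Design matrix from [build_design()] (must contain a `dx`
#'   column).
#' @return A list: `coef` (diagnosis coefficient), `se`, `df` (residual),
#'   `sigma` (residual SD), `n_case`, `n_control`, `n`.
#' @export
site_linear_model <- function(y, X) {
  obs <- which(!is.na(y))
  n <- length(obs)
  p <- ncol(X)
  if (n <= p) stop("too few observed values (n <= number of parameters)",
                   call. = FALSE)
  dx <- X[obs, "dx"]
  if (length(unique(dx)) < 2L) {
    stop("only one diagnosis level present", call. = FALSE)
  }
  fit <- ols_fit(y[obs], X[obs, , drop = FALSE])
  if (is.null(fit)) stop("rank-deficient design", call. = FALSE)
  c(fit, list(n_case = sum(dx == 1), n_control = sum(dx == 0), n = n))
}

# least-squares core: diagnosis coefficient, its SE, residual df and SD.
# Returns NULL on rank deficiency.
ols_fit <- function(y, X) {
  p <- ncol(X)
  qx <- qr(X)
  if (qx$rank < p) return(NULL)
  coefs <- qr.coef(qx, y)
  res <- y - as.numeric(X %*% coefs)
  df <- length(y) - p
  sigma2 <- sum(res^2) / df
  xtx_inv <- chol2inv(qr.R(qx))
  j <- match("dx", colnames(X))
  list(coef = unname(coefs[j]), se = sqrt(sigma2 * xtx_inv[j, j]),
       df = df, sigma = sqrt(sigma2))
}

#' Per-site, per-ROI case-control effect sizes
#'
#' First stage of the random-effects meta-analysis: within each site, each
#' ROI is regressed on diagnosis plus covariates, and the diagnosis
#' coefficient is converted to Hedges' g with [hedges_g()] using the local
#' residual SD. Sites contributing fewer than 2 observed subjects per
#' diagnosis group for an ROI (or with a degenerate local design) are
#' skipped for that ROI.
#'
#' @param data An [roi_dataset].
#' @param covariates Covariate columns beyond diagnosis, default
#'   `c("age", "sex")`.
#' @return A tibble: `roi`, `site`, `g`, `var_g`, `n_case`, `n_control`.
#' @export
site_effects <- function(data, covariates = c("age", "sex")) {
  stopifnot(inherits(data, "roi_dataset"))
  site <- data$covariates$site
  rois <- roi_names(data)
  out <- vector("list", nlevels(site))
  for (k in seq_len(nlevels(site))) {
    s <- levels(site)[k]
    rows <- which(site == s)
    cov_s <- data$covariates[rows, , drop = FALSE]
    if (length(unique(cov_s$dx)) < 2L) next
    X <- tryCatch(build_design(cov_s, terms = covariates),
                  error = function(e) NULL)
    if (is.null(X)) next
    Ys <- data$values[rows, , drop = FALSE]
    fits <- ols_fit_matrix(Ys, X)
    keep <- !is.na(fits$coef) & fits$sigma > 0 &
      fits$n_case >= 2L & fits$n_control >= 2L
    if (!any(keep)) next
    hg <- hedges_g(fits$coef[keep], fits$sigma[keep],
                   fits$n_case[keep], fits$n_control[keep],
                   n_covariates = length(covariates))
    out[[k]] <- tibble::tibble(
      roi = rois[keep], site = s, g = hg$g, var_g = hg$var_g,
      n_case = fits$n_case[keep], n_control = fits$n_control[keep])
  }
  dplyr::bind_rows(out)
}

# OLS of every ROI column on a shared design; complete columns share one QR,
# columns with missing cells fall back to a per-column fit. Columns that are
# inestimable (too few rows, one diagnosis level, rank deficiency) come back
# as NA.
ols_fit_matrix <- function(Y, X) {
  n_roi <- ncol(Y)
  p <- ncol(X)
  j <- match("dx", colnames(X))
  res <- list(coef = rep(NA_real_, n_roi), se = rep(NA_real_, n_roi),
              df = rep(NA_real_, n_roi), sigma = rep(NA_real_, n_roi),
              n_case = rep(NA_integer_, n_roi),
              n_control = rep(NA_integer_, n_roi))
  complete <- !apply(Y, 2, anyNA)
  if (any(complete) && nrow(X) > p) {
    qx <- qr(X)
    if (qx$rank == p) {
      B <- qr.coef(qx, Y[, complete, drop = FALSE])
      rs <- Y[, complete, drop = FALSE] - X %*% B
      df <- nrow(X) - p
      sigma2 <- colSums(rs^2) / df
      xtx_inv <- chol2inv(qr.R(qx))
      res$coef[complete] <- B[j, ]
      res$se[complete] <- sqrt(sigma2 * xtx_inv[j, j])
      res$df[complete] <- df
      res$sigma[complete] <- sqrt(sigma2)
      res$n_case[complete] <- sum(X[, j] == 1)
      res$n_control[complete] <- sum(X[, j] == 0)
    }
  }
  for (r in which(!complete)) {
    y <- Y[, r]
    obs <- !is.na(y)
    if (sum(obs) <= p) next
    fit <- ols_fit(y[obs], X[obs, , drop = FALSE])
    if (is.null(fit)) next
    res$coef[r] <- fit$coef; res$se[r] <- fit$se
    res$df[r] <- fit$df; res$sigma[r] <- fit$sigma
    res$n_case[r] <- sum(X[obs, j] == 1)
    res$n_control[r] <- sum(X[obs, j] == 0)
  }
  res
}

#' Pool per-site effect sizes by random-effects meta-analysis
#'
#' Inverse-variance pooling with between-site heterogeneity `tau^2`:
#' weights `w_i = 1 / (var_i + tau^2)`. `tau^2` is estimated by REML by
#' default (DerSimonian-Laird via `method = "DL"`); the pooled estimate is
#' tested against a standard normal.
#'
#' @param effects A tibble with columns `g` and `var_g`, one row per site
#'   (for a single ROI); at least one row.
#' @param method Heterogeneity estimator: `"REML"` (default) or `"DL"`.
#' @param engine `"internal"` (default) profiles the restricted likelihood
#'   in `tau^2` directly, which keeps the cost of the many thousands of
#'   pooled fits inside permutation loops negligible; `"metafor"` delegates
#'   to [metafor::rma()]. The two agree to numerical precision (asserted in
#'   the test suite).
#' @return A one-row tibble: `g`, `var_g`, `ci_low`, `ci_high`, `p`,
#'   `tau2`, `n_sites`.
#' @export
re_meta_pool <- function(effects, method = c("REML", "DL"),
                         engine = c("internal", "metafor")) {
  if (nrow(effects) == 0L) stop("no site effects to pool", call. = FALSE)
  method <- match.arg(method)
  engine <- match.arg(engine)
  yi <- effects$g
  vi <- effects$var_g
  if (engine == "metafor") {
    fit <- tryCatch(
      suppressWarnings(metafor::rma(yi = yi, vi = vi, method = method,
                                    test = "z")),
      error = function(e) NULL)
    if (is.null(fit) && method != "DL") {
      # Fisher scoring can oscillate; retry with step halving first
      fit <- tryCatch(
        suppressWarnings(metafor::rma(
          yi = yi, vi = vi, method = method, test = "z",
          control = list(stepadj = 0.5, maxiter = 1000))),
        error = function(e) NULL)
    }
    if (is.null(fit) && method != "DL") {
      warning("REML did not converge; falling back to DerSimonian-Laird")
      fit <- suppressWarnings(metafor::rma(yi = yi, vi = vi, method = "DL",
                                           test = "z"))
    }
    return(tibble::tibble(
      g = as.numeric(fit$b), var_g = as.numeric(fit$se)^2,
      ci_low = fit$ci.lb, ci_high = fit$ci.ub,
      p = fit$pval, tau2 = fit$tau2, n_sites = length(yi)))
  }
  tau2 <- if (method == "DL") tau2_dl(yi, vi) else tau2_reml(yi, vi)
  w <- 1 / (vi + tau2)
  b <- sum(w * yi) / sum(w)
  se <- sqrt(1 / sum(w))
  z <- b / se
  tibble::tibble(
    g = b, var_g = se^2,
    ci_low = b - stats::qnorm(0.975) * se,
    ci_high = b + stats::qnorm(0.975) * se,
    p = 2 * stats::pnorm(-abs(z)), tau2 = tau2, n_sites = length(yi))
}

# DerSimonian-Laird moment estimator of between-site heterogeneity
tau2_dl <- function(yi, vi) {
  k <- length(yi)
  if (k < 2L) return(0)
  w <- 1 / vi
  yw <- sum(w * yi) / sum(w)
  q <- sum(w * (yi - yw)^2)
  denom <- sum(w) - sum(w^2) / sum(w)
  max(0, (q - (k - 1)) / denom)
}

# REML estimate: maximize the restricted profile log-likelihood in tau^2
# (unimodal in tau^2 for the random-effects location model); the boundary
# tau^2 = 0 is checked explicitly.
tau2_reml <- function(yi, vi) {
  k <- length(yi)
  if (k < 2L) return(0)
  nll <- function(tau2) {
    w <- 1 / (vi + tau2)
    b <- sum(w * yi) / sum(w)
    0.5 * (sum(log(vi + tau2)) + log(sum(w)) + sum(w * (yi - b)^2))
  }
  upper <- max(stats::var(yi) * 4, max(vi) * 4, 1e-6)
  opt <- stats::optimize(nll, c(0, upper), tol = 1e-10)
  if (nll(0) <= opt$objective) 0 else opt$minimum
}

#' Linear mixed-effects model with a random site intercept for one ROI
#'
#' REML fit of `y ~ dx + covariates + (1 | site)`; the diagnosis p-value
#' uses Satterthwaite-approximated degrees of freedom (falling back, with a
#' warning, to a t reference with `n - p - 1` df if that fails). A singular
#' fit (site variance at the boundary) proceeds with variance 0 and a
#' warning.
#'
#' @param y Numeric vector across all subjects (`NA` allowed).
#' @param covariates A covariate tibble (as in an [roi_dataset]) with `dx`
#'   and `site`.
#' @param terms Covariate columns beyond diagnosis.
#' @return A list: `coef`, `se`, `p`, `sd_resid` (residual SD), `sd_total`
#'   (sqrt of residual + site variance), `n_case`, `n_control`.
#' @export
mixed_effects_model <- function(y, covariates, terms = c("age", "sex")) {
  obs <- !is.na(y)
  dat <- as.data.frame(covariates[obs, c("dx", terms, "site")])
  dat$.y <- y[obs]
  if (nlevels(droplevels(dat$site)) < 2L) {
    stop("mixed model needs at least 2 sites with observed values",
         call. = FALSE)
  }
  form <- stats::reformulate(c("dx", terms, "(1 | site)"), response = ".y")
  fit <- suppressMessages(lmerTest::lmer(
    form, data = dat, REML = TRUE,
    control = lme4::lmerControl(calc.derivs = FALSE,
                                check.conv.singular = "ignore")))
  if (lme4::isSingular(fit, tol = 1e-5)) {
    warning("site variance estimated at the boundary (0); proceeding")
  }
  co <- tryCatch(summary(fit)$coefficients, error = function(e) NULL)
  n <- nrow(dat)
  p_cols <- 1L + 1L + length(terms)
  if (!is.null(co) && "dx" %in% rownames(co) && ncol(co) >= 5 &&
      is.finite(co["dx", 5])) {
    est <- co["dx", 1]; se <- co["dx", 2]; pval <- co["dx", 5]
  } else {
    warning("Satterthwaite df unavailable; using t with df = n - p - 1")
    fe <- lme4::fixef(fit)
    est <- fe[["dx"]]
    se <- sqrt(diag(as.matrix(stats::vcov(fit))))[[2]]
    pval <- 2 * stats::pt(-abs(est / se), df = n - p_cols - 1)
  }
  sd_resid <- stats::sigma(fit)
  vc <- as.data.frame(lme4::VarCorr(fit))
  site_var <- vc$vcov[vc$grp == "site"][1]
  list(coef = est, se = se, p = pval, sd_resid = sd_resid,
       sd_total = sqrt(sd_resid^2 + site_var),
       n_case = sum(dat$dx == 1), n_control = sum(dat$dx == 0))
}

#' Holm step-down adjustment of p-values
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values controlling the familywise error rate.
#' @export
holm_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "holm")
}

#' Run a case-control comparison pipeline over all ROIs
#'
#' The three analytic strategies for multi-site case-control data:
#' \describe{
#'   \item{`"remeta"`}{Random-effects meta-analysis: per-site OLS per ROI,
#'     Hedges' g per site, inverse-variance pooling with REML `tau^2`.}
#'   \item{`"memega"`}{Mixed-effects mega-analysis: one linear mixed model
#'     per ROI on the pooled subjects with a random site intercept.}
#'   \item{`"combatmega"`}{ComBat mega-analysis: harmonize with
#'     [combat_fit()]/[combat_apply()] (diagnosis and covariates protected),
#'     then one pooled OLS per ROI with no site term.}
#' }
#' Every pipeline reports per-ROI Hedges' g (standardized by the model
#' residual SD, degrees of freedom reduced by the number of covariates),
#' a 95% CI `g +/- 1.96 sqrt(var_g)`, the model's two-sided p-value, and
#' Holm-adjusted p-values over the full ROI family.
#'
#' @param data An [roi_dataset].
#' @param pipeline One of `"remeta"`, `"memega"`, `"combatmega"`.
#' @param covariates Covariate columns beyond diagnosis, default
#'   `c("age", "sex")`.
#' @param tau2_method Heterogeneity estimator for `"remeta"`.
#' @param standardizer For `"memega"`: `"residual"` (default; within-site
#'   residual SD, comparable with the ComBat pipeline where site variance
#'   has been removed) or `"total"` (sqrt of residual + site variance).
#' @param harmonization_groups For `"combatmega"`: `NULL` for a single
#'   harmonization, or a partition of the ROI names (see [harmonize()]).
#' @return A tibble of class `effect_results`: one row per ROI with
#'   `roi`, `pipeline`, `g`, `var_g`, `ci_low`, `ci_high`, `p`, `p_holm`,
#'   and `tau2` (`NA` except for `"remeta"`). ROIs with zero observed
#'   variance (or, for `"remeta"`, no eligible site) are dropped with a
#'   warning; an empty result is an error.
#' @export
run_pipeline <- function(data,
                         pipeline = c("combatmega", "memega", "remeta"),
                         covariates = c("age", "sex"),
                         tau2_method = "REML",
                         standardizer = c("residual", "total"),
                         harmonization_groups = NULL) {
  stopifnot(inherits(data, "roi_dataset"))
  pipeline <- match.arg(pipeline)
  standardizer <- match.arg(standardizer)
  has_var <- apply(data$values, 2, function(y) {
    y <- y[!is.na(y)]
    length(y) >= 2L && max(y) > min(y)
  })
  if (!all(has_var)) {
    warning("dropping zero-variance ROI(s): ",
            paste(roi_names(data)[!has_var], collapse = ", "))
    data <- with_values(data, data$values[, has_var, drop = FALSE])
  }
  if (ncol(data$values) == 0L) {
    stop("no ROI left after zero-variance exclusion", call. = FALSE)
  }

  res <- switch(pipeline,
    remeta = pipeline_remeta(data, covariates, tau2_method),
    memega = pipeline_memega(data, covariates, standardizer),
    combatmega = pipeline_combatmega(data, covariates, harmonization_groups))
  if (nrow(res) == 0L) stop("pipeline produced no ROI results", call. = FALSE)
  res$p_holm <- holm_adjust(res$p)
  res <- dplyr::relocate(res, "roi", "pipeline", "g", "var_g",
                         "ci_low", "ci_high", "p", "p_holm", "tau2")
  class(res) <- c("effect_results", class(res))
  res
}

pipeline_remeta <- function(data, covariates, tau2_method) {
  eff <- site_effects(data, covariates)
  if (nrow(eff) == 0L) {
    stop("no site provides estimable case-control effects", call. = FALSE)
  }
  skipped <- setdiff(roi_names(data), unique(eff$roi))
  if (length(skipped)) {
    warning("ROI(s) with no eligible site skipped in RE-Meta: ",
            paste(skipped, collapse = ", "))
  }
  eff |>
    dplyr::group_by(.data$roi) |>
    dplyr::group_modify(~ re_meta_pool(.x, method = tau2_method)) |>
    dplyr::ungroup() |>
    dplyr::mutate(pipeline = "RE-Meta") |>
    dplyr::select(-"n_sites")
}

pipeline_memega <- function(data, covariates, standardizer) {
  rois <- roi_names(data)
  res <- withCallingHandlers(
    lapply(rois, function(r) {
      fit <- mixed_effects_model(data$values[, r], data$covariates,
                                 terms = covariates)
      sdz <- if (standardizer == "residual") fit$sd_resid else fit$sd_total
      hg <- hedges_g(fit$coef, sdz, fit$n_case, fit$n_control,
                     n_covariates = length(covariates))
      tibble::tibble(roi = r, pipeline = "ME-Mega", g = hg$g,
                     var_g = hg$var_g,
                     ci_low = hg$g - 1.96 * sqrt(hg$var_g),
                     ci_high = hg$g + 1.96 * sqrt(hg$var_g),
                     p = fit$p, tau2 = NA_real_)
    }),
    warning = function(w) {
      if (grepl("boundary", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  dplyr::bind_rows(res)
}

pipeline_combatmega <- function(data, covariates, groups) {
  harm <- harmonize(data, covariates = c("dx", covariates), groups = groups)
  X <- build_design(harm$covariates, terms = covariates)
  fits <- ols_fit_matrix(harm$values, X)
  keep <- !is.na(fits$coef) & fits$sigma > 0 &
    fits$n_case >= 2L & fits$n_control >= 2L
  if (!any(keep)) return(tibble::tibble())
  hg <- hedges_g(fits$coef[keep], fits$sigma[keep],
                 fits$n_case[keep], fits$n_control[keep],
                 n_covariates = length(covariates))
  tibble::tibble(
    roi = roi_names(harm)[keep], pipeline = "ComBat-Mega", g = hg$g,
    var_g = hg$var_g,
    ci_low = hg$g - 1.96 * sqrt(hg$var_g),
    ci_high = hg$g + 1.96 * sqrt(hg$var_g),
    p = 2 * stats::pt(-abs(fits$coef[keep] / fits$se[keep]),
                      df = fits$df[keep]),
    tau2 = NA_real_)
}

#' Forest-style plot of per-ROI effect sizes
#'
#' @param object An `effect_results` tibble from [run_pipeline()].
#' @param ... Unused.
#' @return A ggplot: Hedges' g with 95% CIs, ROIs ordered by effect size.
#' @method autoplot effect_results
#' @export
autoplot.effect_results <- function(object, ...) {
  df <- dplyr::arrange(tibble::as_tibble(object), .data$g)
  df$roi <- factor(df$roi, levels = unique(df$roi))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$g, y = .data$roi,
                                   colour = .data$pipeline)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$ci_low,
                                          xmax = .data$ci_high),
                             position = ggplot2::position_dodge(width = 0.5),
                             size = 0.25) +
    ggplot2::labs(x = "Hedges' g (cases - controls)", y = NULL,
                  colour = NULL) +
    ggplot2::theme_minimal()
}
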