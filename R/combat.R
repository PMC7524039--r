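#' Temporarily impute missing measurements for harmonization fitting
#'
#' Fills each missing cell with the fitted value of an ordinary
#' least-squares model of the observed cells of that ROI on the covariates,
#' fitted separately within each site (`y = a + X b` per site and ROI).
#' The completed copy exists only so the harmonization parameters can be
#' estimated without errors; imputations are never written back to the
#' caller's data and [combat_apply()] never imputes.
#'
#' @param data An [roi_dataset].
#' @param covariates Covariate columns used by the local models, diagnosis
#'   included (default `c("dx", "age", "sex")`).
#' @return An [roi_dataset] with no missing cells; observed cells unchanged.
#' @details A site/ROI pair with missing cells must retain at least
#'   `length(covariates) + 2` observed cells to fit the local model;
#'   otherwise an error names the pair. If the local design is rank
#'   deficient within a site (e.g. a single-sex site), the site/ROI observed
#'   mean is used instead.
#' @export
impute_for_fit <- function(data, covariates = c("dx", "age", "sex")) {
  stopifnot(inherits(data, "roi_dataset"))
  Y <- data$values
  if (!anyNA(Y)) return(data)
  X <- design_from_terms(data$covariates, covariates)
  site <- data$covariates$site
  p <- ncol(X)
  for (s in levels(site)) {
    rows <- which(site == s)
    Ys <- Y[rows, , drop = FALSE]
    miss_cols <- which(colSums(is.na(Ys)) > 0L)
    for (r in miss_cols) {
      obs <- !is.na(Ys[, r])
      n_obs <- sum(obs)
      if (n_obs < length(covariates) + 2L) {
        stop(sprintf(
          "cannot impute ROI '%s' at site '%s': only %d observed value(s)",
          colnames(Y)[r], s, n_obs), call. = FALSE)
      }
      Xs <- X[rows, , drop = FALSE]
      qr_x <- qr(Xs[obs, , drop = FALSE])
      if (qr_x$rank < p) {
        fitted_miss <- rep(mean(Ys[obs, r]), sum(!obs))
      } else {
        beta <- qr.coef(qr_x, Ys[obs, r])
        fitted_miss <- as.numeric(Xs[!obs, , drop = FALSE] %*% beta)
      }
      Y[rows[!obs], r] <- fitted_miss
    }
  }
  with_values(data, Y)
}

# intercept + named covariate columns, 0/1 coding for binaries
design_from_terms <- function(covariates, terms) {
  include_dx <- "dx" %in% terms
  build_design(covariates, terms = setdiff(terms, "dx"),
               include_diagnosis = include_dx)[,
    c("(Intercept)", terms), drop = FALSE]
}

#' Fit ComBat harmonization parameters
#'
#' Estimates additive (location) and multiplicative (scale) site effects for
#' every ROI under the model `y = alpha + X beta + gamma_site + delta_site *
#' eps`, shrinking the per-site estimates toward site-level parametric
#' empirical-Bayes priors (normal for the additive effects, inverse-gamma
#' for the variance effects) shared across ROIs. Fitting and application are
#' separated so parameters found on one set (e.g. a training set) can be
#' applied to another; see [combat_apply()].
#'
#' @param data An [roi_dataset]; at least two sites, each with at least two
#'   subjects.
#' @param covariates Covariates whose effects are modelled (and thereby
#'   protected from removal), diagnosis included; default
#'   `c("dx", "age", "sex")`.
#' @param tol,max_iter Convergence tolerance (maximum relative change of the
#'   shrunken effects) and iteration cap for the empirical-Bayes fixed-point
#'   iteration.
#' @return A `combat_model`: per-ROI grand intercepts `alpha`, covariate
#'   coefficients `beta`, pooled residual variances `sigma2`, EB-shrunk site
#'   effects `gamma_star` and `delta_star` (sites x ROIs), the site-level
#'   hyperparameters, the ROI inclusion mask `included_rois`, and the site
#'   and covariate rosters.
#' @details ROIs whose observed values have no variance are excluded from
#'   harmonization (recorded in `included_rois`) instead of erroring.
#'   Missing cells are temporarily completed with [impute_for_fit()] before
#'   fitting; the imputations are not retained. `alpha` and `beta` come from
#'   a pooled least-squares fit with per-site intercepts under a
#'   sample-size-weighted sum-to-zero constraint, the canonical ComBat
#'   identifiability choice; the empirical-Bayes step matches the reference
#'   implementation in the sva package (method-of-moments hyperparameters,
#'   fixed-point iteration for the posterior site effects).
#' @export
combat_fit <- function(data, covariates = c("dx", "age", "sex"),
                       tol = 1e-4, max_iter = 1000L) {
  stopifnot(inherits(data, "roi_dataset"))
  site <- droplevels(data$covariates$site)
  n_i <- table(site)
  if (nlevels(site) < 2L) stop("combat_fit needs at least 2 sites",
                               call. = FALSE)
  if (any(n_i < 2L)) {
    stop("every site needs at least 2 subjects (offending: ",
         paste(names(n_i)[n_i < 2], collapse = ", "), ")", call. = FALSE)
  }

  Y_all <- data$values
  obs_var <- apply(Y_all, 2, function(y) {
    y <- y[!is.na(y)]
    length(y) >= 2L && max(y) > min(y)
  })
  included <- stats::setNames(obs_var, colnames(Y_all))
  if (!any(included)) stop("no ROI with non-zero variance", call. = FALSE)

  data_inc <- with_values(data, Y_all[, included, drop = FALSE])
  data_imp <- impute_for_fit(data_inc, covariates)
  Y <- data_imp$values
  n <- nrow(Y)

  X_mod <- design_from_terms(data$covariates, covariates)
  batchmod <- stats::model.matrix(~ 0 + site)
  colnames(batchmod) <- levels(site)
  design <- cbind(batchmod, X_mod[, -1, drop = FALSE])
  if (qr(design)$rank < ncol(design)) {
    stop("site indicators and covariates are confounded (rank-deficient design)",
         call. = FALSE)
  }
  S <- nlevels(site)
  B <- solve(crossprod(design), crossprod(design, Y))
  w <- as.numeric(n_i) / n
  grand_mean <- as.numeric(crossprod(w, B[seq_len(S), , drop = FALSE]))
  resid <- Y - design %*% B
  var_pooled <- colMeans(resid^2)
  if (any(var_pooled <= 0)) {
    stop("zero pooled residual variance for ROI(s): ",
         paste(colnames(Y)[var_pooled <= 0], collapse = ", "), call. = FALSE)
  }
  beta <- B[-seq_len(S), , drop = FALSE]
  stand_mean <- matrix(grand_mean, n, ncol(Y), byrow = TRUE) +
    X_mod[, -1, drop = FALSE] %*% beta
  Z <- (Y - stand_mean) / matrix(sqrt(var_pooled), n, ncol(Y), byrow = TRUE)

  gamma_hat <- t(vapply(levels(site),
                        function(s) colMeans(Z[site == s, , drop = FALSE]),
                        numeric(ncol(Z))))
  delta_hat <- t(vapply(levels(site),
                        function(s) apply(Z[site == s, , drop = FALSE], 2,
                                          stats::var),
                        numeric(ncol(Z))))
  dimnames(gamma_hat) <- dimnames(delta_hat) <-
    list(levels(site), colnames(Y))

  gamma_bar <- rowMeans(gamma_hat)
  t2 <- apply(gamma_hat, 1, stats::var)
  m_d <- rowMeans(delta_hat)
  s2_d <- apply(delta_hat, 1, stats::var)
  a_prior <- (2 * s2_d + m_d^2) / s2_d
  b_prior <- (m_d * s2_d + m_d^3) / s2_d

  gamma_star <- gamma_hat
  delta_star <- delta_hat
  if (ncol(Z) < 2L) {
    warning("fewer than 2 ROIs: empirical-Bayes shrinkage skipped")
  } else {
    for (k in seq_len(S)) {
      Zi <- Z[site == levels(site)[k], , drop = FALSE]
      eb <- eb_site_solve(Zi, gamma_hat[k, ], delta_hat[k, ],
                          gamma_bar[k], t2[k], a_prior[k], b_prior[k],
                          tol = tol, max_iter = max_iter,
                          site_label = levels(site)[k])
      gamma_star[k, ] <- eb$gamma
      delta_star[k, ] <- eb$delta
    }
  }

  structure(list(
    alpha = stats::setNames(grand_mean, colnames(Y)),
    beta = beta,
    sigma2 = var_pooled,
    gamma_star = gamma_star,
    delta_star = delta_star,
    gamma_hat = gamma_hat,
    delta_hat = delta_hat,
    hyper = tibble::tibble(site = levels(site), gamma_bar = gamma_bar,
                           tau2 = t2, a_prior = a_prior, b_prior = b_prior,
                           n = as.integer(n_i)),
    included_rois = included,
    site_levels = levels(site),
    covariate_names = covariates
  ), class = "combat_model")
}

# EB fixed point for one site, vectorized over ROIs. The update and stopping
# rule follow the reference sva implementation (relative change against the
# previous iterate, signed denominators included) so fits agree with it to
# numerical identity on complete data.
eb_site_solve <- function(Zi, g_hat, d_hat, g_bar, t2, a, b,
                          tol, max_iter, site_label) {
  n <- nrow(Zi)
  g_old <- g_hat
  d_old <- d_hat
  change <- 1
  count <- 0L
  while (change > tol) {
    g_new <- (t2 * n * g_hat + d_old * g_bar) / (t2 * n + d_old)
    sum2 <- colSums((Zi - matrix(g_new, n, ncol(Zi), byrow = TRUE))^2)
    d_new <- (0.5 * sum2 + b) / (n / 2 + a - 1)
    change <- max((abs(g_new - g_old) / g_old), (abs(d_new - d_old) / d_old))
    g_old <- g_new
    d_old <- d_new
    count <- count + 1L
    if (count >= max_iter) {
      stop("empirical-Bayes iteration did not converge for site '",
           site_label, "' within ", max_iter, " iterations", call. = FALSE)
    }
  }
  list(gamma = g_old, delta = d_old)
}

#' @export
print.combat_model <- function(x, ...) {
  cat(sprintf(
    "<combat_model> %d sites, %d/%d ROIs harmonized, covariates: %s\n",
    length(x$site_levels), sum(x$included_rois), length(x$included_rois),
    paste(x$covariate_names, collapse = ", ")))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted harmonization model
#'
#' One row per site x ROI with the raw and shrunken additive and
#' multiplicative site-effect estimates.
#'
#' @param x A `combat_model`.
#' @param ... Unused.
#' @method tidy combat_model
#' @export
tidy.combat_model <- function(x, ...) {
  rois <- colnames(x$gamma_star)
  tidyr::expand_grid(site = x$site_levels, roi = rois) |>
    dplyr::mutate(
      gamma_hat = as.vector(t(x$gamma_hat)),
      gamma_star = as.vector(t(x$gamma_star)),
      delta_hat = as.vector(t(x$delta_hat)),
      delta_star = as.vector(t(x$delta_star)))
}

#' @rdname tidy.combat_model
#' @method glance combat_model
#' @export
glance.combat_model <- function(x, ...) {
  tibble::tibble(
    n_sites = length(x$site_levels),
    n_rois = length(x$included_rois),
    n_rois_harmonized = sum(x$included_rois),
    covariates = paste(x$covariate_names, collapse = ","))
}

#' Apply fitted harmonization parameters to a dataset
#'
#' Removes the estimated site effects from each observed measurement:
#' standardized residuals `(y - alpha - X beta - gamma*) / delta*` are
#' rescaled and the grand intercept and covariate effects are added back, so
#' covariate (including diagnosis) signal is preserved and harmonized values
#' stay on the original measurement scale. Missing cells are never imputed
#' and remain missing in the output; ROIs excluded at fit time pass through
#' unchanged with a warning.
#'
#' @param model A `combat_model` from [combat_fit()].
#' @param data An [roi_dataset] whose sites are all present in the model and
#'   whose covariate columns include the model's covariates.
#' @return An [roi_dataset] of the same shape, subject order, and ROI order.
#' @export
combat_apply <- function(model, data) {
  stopifnot(inherits(model, "combat_model"), inherits(data, "roi_dataset"))
  site <- as.character(data$covariates$site)
  unseen <- setdiff(unique(site), model$site_levels)
  if (length(unseen)) {
    stop("site(s) not present at fit time: ",
         paste(unseen, collapse = ", "),
         " (refit with all sites to harmonize them)", call. = FALSE)
  }
  missing_cov <- setdiff(model$covariate_names, names(data$covariates))
  if (length(missing_cov)) {
    stop("covariate column(s) required by the model are absent: ",
         paste(missing_cov, collapse = ", "), call. = FALSE)
  }
  rois <- names(model$included_rois)
  if (!identical(colnames(data$values), rois)) {
    if (!setequal(colnames(data$values), rois)) {
      stop("ROI columns do not match the fitted model", call. = FALSE)
    }
  }
  excluded <- names(model$included_rois)[!model$included_rois]
  excluded <- intersect(excluded, colnames(data$values))
  if (length(excluded)) {
    warning("ROI(s) excluded at fit time pass through unharmonized: ",
            paste(excluded, collapse = ", "))
  }
  inc <- intersect(names(model$included_rois)[model$included_rois],
                   colnames(data$values))
  Y <- data$values
  X_mod <- design_from_terms(data$covariates, model$covariate_names)
  idx <- match(site, model$site_levels)
  n <- nrow(Y)

  Yi <- Y[, inc, drop = FALSE]
  alpha <- model$alpha[inc]
  beta <- model$beta[, inc, drop = FALSE]
  sigma <- sqrt(model$sigma2[inc])
  stand_mean <- matrix(alpha, n, length(inc), byrow = TRUE) +
    X_mod[, -1, drop = FALSE] %*% beta
  Z <- (Yi - stand_mean) / matrix(sigma, n, length(inc), byrow = TRUE)
  Zadj <- (Z - model$gamma_star[idx, inc, drop = FALSE]) /
    sqrt(model$delta_star[idx, inc, drop = FALSE])
  Y[, inc] <- Zadj * matrix(sigma, n, length(inc), byrow = TRUE) + stand_mean
  with_values(data, Y)
}

#' Harmonize a dataset in one step, optionally per ROI group
#'
#' Convenience wrapper running [combat_fit()] followed by [combat_apply()]
#' on the same data. When `groups` is supplied (a named list of ROI-name
#' vectors partitioning the ROI set, e.g. thickness / surface area / volume),
#' each group is fitted and harmonized independently and the columns are
#' rebound in the original order.
#'
#' @inheritParams combat_fit
#' @param groups `NULL` for a single harmonization of all ROIs, or a list of
#'   character vectors that partition `roi_names(data)`.
#' @return A harmonized [roi_dataset].
#' @export
harmonize <- function(data, covariates = c("dx", "age", "sex"),
                      groups = NULL) {
  if (is.null(groups)) {
    return(combat_apply(combat_fit(data, covariates), data))
  }
  all_rois <- unlist(groups, use.names = FALSE)
  if (anyDuplicated(all_rois) || !setequal(all_rois, roi_names(data))) {
    stop("`groups` must partition the ROI set (no overlap, no omission)",
         call. = FALSE)
  }
  Y <- data$values
  for (g in groups) {
    sub <- with_values(data, data$values[, g, drop = FALSE])
    harm <- combat_apply(combat_fit(sub, covariates), sub)
    Y[, g] <- harm$values
  }
  with_values(data, Y)
}

#' Group ENIGMA-style ROI names by measurement type
#'
#' Splits ROI names into thickness (`*_thickavg`), surface area
#' (`*_surfavg`), and volume (everything else) groups, the conventional
#' per-data-type harmonization split.
#'
#' @param rois Character vector of ROI names.
#' @return A named list of character vectors (empty groups dropped).
#' @export
roi_type_groups <- function(rois) {
  grp <- list(
    thickness = rois[grepl("_thickavg$", rois)],
    area = rois[grepl("_surfavg$", rois)],
    volume = rois[!grepl("_thickavg$|_surfavg$", rois)])
  grp[vapply(grp, length, integer(1)) > 0L]
}

#' Serialize / restore a fitted harmonization model as JSON
#'
#' Arrays are written row-major with explicit site and ROI rosters so models
#' can be exchanged across languages.
#'
#' @param model A `combat_model`.
#' @param path Output (input) file path.
#' @return `write_combat_model()` returns `model` invisibly;
#'   `read_combat_model()` returns a `combat_model`.
#' @export
write_combat_model <- function(model, path) {
  stopifnot(inherits(model, "combat_model"))
  obj <- list(
    sites = model$site_levels,
    rois = names(model$included_rois),
    included_rois = unname(model$included_rois),
    covariates = model$covariate_names,
    alpha = unname(model$alpha),
    beta = lapply(seq_len(nrow(model$beta)), function(i) unname(model$beta[i, ])),
    beta_rows = rownames(model$beta),
    sigma2 = unname(model$sigma2),
    gamma_star = lapply(seq_len(nrow(model$gamma_star)),
                        function(i) unname(model$gamma_star[i, ])),
    delta_star = lapply(seq_len(nrow(model$delta_star)),
                        function(i) unname(model$delta_star[i, ])),
    gamma_hat = lapply(seq_len(nrow(model$gamma_hat)),
                       function(i) unname(model$gamma_hat[i, ])),
    delta_hat = lapply(seq_len(nrow(model$delta_hat)),
                       function(i) unname(model$delta_hat[i, ])),
    hyper = model$hyper)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(model)
}

#' @rdname write_combat_model
#' @export
read_combat_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  rois <- obj$rois
  inc_rois <- rois[obj$included_rois]
  as_mat <- function(x, rows) {
    m <- do.call(rbind, lapply(seq_along(rows), function(i) as.numeric(x[i, ])))
    dimnames(m) <- list(rows, inc_rois)
    m
  }
  beta <- do.call(rbind, lapply(seq_len(nrow(obj$beta)),
                                function(i) as.numeric(obj$beta[i, ])))
  dimnames(beta) <- list(obj$beta_rows, inc_rois)
  structure(list(
    alpha = stats::setNames(as.numeric(obj$alpha), inc_rois),
    beta = beta,
    sigma2 = stats::setNames(as.numeric(obj$sigma2), inc_rois),
    gamma_star = as_mat(obj$gamma_star, obj$sites),
    delta_star = as_mat(obj$delta_star, obj$sites),
    gamma_hat = as_mat(obj$gamma_hat, obj$sites),
    delta_hat = as_mat(obj$delta_hat, obj$sites),
    hyper = tibble::as_tibble(obj$hyper),
    included_rois = stats::setNames(obj$included_rois, rois),
    site_levels = obj$sites,
    covariate_names = obj$covariates
  ), class = "combat_model")
}
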