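#' Logit transform of p-values
#'
#' `ln(p / (1 - p))`, which equalizes sensitivity to differences across the
#' whole p-value range: 0.6 vs 0.4 maps to 0.4 vs -0.4 (difference 0.8),
#' while 0.003 vs 0.001 maps to -5.8 vs -6.9 (difference 1.1). Values are
#' clipped to `[eps, 1 - eps]` before the transform so underflowing
#' p-values never produce infinities.
#'
#' @param p Numeric vector of probabilities in `[0, 1]`.
#' @param eps Clipping bound, default `1e-15`.
#' @return `log(p / (1 - p))`, vectorized.
#' @export
logit_p <- function(p, eps = 1e-15) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("p must lie in [0, 1]", call. = FALSE)
  }
  p <- pmin(pmax(p, eps), 1 - eps)
  log(p / (1 - p))
}

#' Derive a child seed from a master seed and a counter
#'
#' Deterministic counter-based derivation used for all nested randomness
#' (per-permutation, per-replicate, per-site draws), so results do not
#' depend on loop order and every run is reproducible from the master seed
#' alone. Arithmetic is exact in doubles and the result stays below 2^31.
#'
#' @param seed Master seed (integer).
#' @param counter Non-negative integer counter.
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, counter) {
  m <- 2147483647
  x <- (as.numeric(seed) %% m) * 48271 %% m
  as.integer((x + 65537 * as.numeric(counter)) %% (m - 1) + 1)
}

#' Permute diagnosis labels within each site
#'
#' The Draper-Stoneman scheme: diagnosis labels are shuffled independently
#' within each site while measurements and all other covariates stay fixed,
#' so per-site case/control counts are preserved exactly and every compared
#' method sees the identical permuted data.
#'
#' @param data An [roi_dataset].
#' @param seed Optional integer seed; the same seed gives the identical
#'   permutation.
#' @return The dataset with permuted `dx`.
#' @export
permute_within_site <- function(data, seed = NULL) {
  stopifnot(inherits(data, "roi_dataset"))
  if (!is.null(seed)) set.seed(seed)
  cov <- data$covariates
  for (s in levels(cov$site)) {
    idx <- which(cov$site == s)
    if (length(idx) > 1L) {
      cov$dx[idx] <- cov$dx[idx][sample.int(length(idx))]
    }
  }
  structure(list(values = data$values, covariates = cov),
            class = "roi_dataset")
}

#' Permutation comparison of statistical significance between two pipelines
#'
#' Tests whether pipeline A yields systematically smaller p-values than
#' pipeline B beyond chance. The observed statistic is the median over ROIs
#' of `logit(p_A) - logit(p_B)` on the true labels. Its null distribution
#' comes from rerunning *both* pipelines on the same within-site
#' label-permuted data and keeping only the ROI-median difference, which
#' sidesteps any multiplicity correction. The reported probability is
#' one-sided (smaller = A more significant) with +1 smoothing:
#' `(1 + #\{null <= observed\}) / (n_perm + 1)`, i.e. never below the
#' permutation granularity floor.
#'
#' @param data An [roi_dataset].
#' @param pipeline_a,pipeline_b Pipeline names as in [run_pipeline()].
#' @param covariates Covariates beyond diagnosis.
#' @param n_perm Number of permutations.
#' @param seed Master seed; permutation `t` uses `derive_seed(seed, t)`.
#' @param ... Further arguments passed to [run_pipeline()].
#' @return A `significance_comparison`: `observed_median`, `null_medians`,
#'   `n_perm`, `prob`, and the two per-ROI p-value sets.
#' @export
compare_significance <- function(data, pipeline_a, pipeline_b,
                                 covariates = c("age", "sex"),
                                 n_perm = 1000L, seed = 1L, ...) {
  med_diff <- function(d) {
    pa <- run_pipeline_quiet(d, pipeline_a, covariates, ...)
    pb <- run_pipeline_quiet(d, pipeline_b, covariates, ...)
    joined <- dplyr::inner_join(
      dplyr::select(tibble::as_tibble(pa), "roi", p_a = "p"),
      dplyr::select(tibble::as_tibble(pb), "roi", p_b = "p"),
      by = "roi")
    stats::median(logit_p(joined$p_a) - logit_p(joined$p_b))
  }
  observed <- med_diff(data)
  null_medians <- vapply(seq_len(n_perm), function(t) {
    perm <- permute_within_site(data, seed = derive_seed(seed, t))
    tryCatch(med_diff(perm), error = function(e) {
      stop("pipeline failure at permutation ", t, ": ",
           conditionMessage(e), call. = FALSE)
    })
  }, numeric(1))
  structure(list(
    pipeline_a = pipeline_a, pipeline_b = pipeline_b,
    observed_median = observed, null_medians = null_medians,
    n_perm = n_perm,
    prob = (1 + sum(null_medians <= observed)) / (n_perm + 1)
  ), class = "significance_comparison")
}

run_pipeline_quiet <- function(data, pipeline, covariates, ...) {
  suppressWarnings(run_pipeline(data, pipeline = pipeline,
                                covariates = covariates, ...))
}

#' @export
print.significance_comparison <- function(x, ...) {
  cat(sprintf(
    "<significance_comparison> %s vs %s\n  observed median logit-p difference: %.3f\n  null range over %d permutations: [%.3f, %.3f]\n  one-sided prob (A more significant): %.4g\n",
    x$pipeline_a, x$pipeline_b, x$observed_median, x$n_perm,
    min(x$null_medians), max(x$null_medians), x$prob))
  invisible(x)
}

#' @rdname compare_significance
#' @param x A `significance_comparison`.
#' @method tidy significance_comparison
#' @export
tidy.significance_comparison <- function(x, ...) {
  tibble::tibble(pipeline_a = x$pipeline_a, pipeline_b = x$pipeline_b,
                 observed_median = x$observed_median, n_perm = x$n_perm,
                 prob = x$prob)
}

#' @rdname compare_significance
#' @param object A `significance_comparison`.
#' @method autoplot significance_comparison
#' @export
autoplot.significance_comparison <- function(object, ...) {
  df <- tibble::tibble(null_median = object$null_medians)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$null_median)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$observed_median,
                        colour = "red", linewidth = 1) +
    ggplot2::labs(
      x = sprintf("median logit-p difference (%s - %s)",
                  object$pipeline_a, object$pipeline_b),
      y = "permutations",
      title = "Observed (red) vs null median significance difference") +
    ggplot2::theme_minimal()
}

#' Small-subset statistical power of the pipelines
#'
#' Repeatedly reruns the pipelines on random subsets of sites and counts how
#' often each "ground-truth" ROI is detected (Holm-adjusted p < `alpha`).
#' Ground-truth ROIs are those strongly significant on the full data under
#' *all* pipelines (Holm-adjusted p < `fwer_threshold`). Per-ROI power is
#' compared between pipeline pairs with a Wilcoxon signed-rank test.
#'
#' @param data An [roi_dataset] with more sites than `subset_size`.
#' @param pipelines Pipelines to evaluate.
#' @param covariates Covariates beyond diagnosis.
#' @param subset_size Number of sites per replicate (without replacement).
#' @param n_reps Number of replicates.
#' @param fwer_threshold Full-data Holm threshold defining the ROI filter.
#' @param alpha Detection threshold on the Holm-adjusted p within subsets.
#' @param seed Master seed; replicate `t` uses `derive_seed(seed, t)`.
#' @param ... Further arguments passed to [run_pipeline()].
#' @return A `power_result`: tibble `power` (per ROI x pipeline detection
#'   proportion), tibble `wilcoxon` (pairwise signed-rank p-values over the
#'   per-ROI power values), the ROI filter, `subset_size`, `n_reps`.
#' @export
subset_power <- function(data,
                         pipelines = c("remeta", "memega", "combatmega"),
                         covariates = c("age", "sex"),
                         subset_size = 10L, n_reps = 500L,
                         fwer_threshold = 0.001, alpha = 0.05,
                         seed = 1L, ...) {
  stopifnot(inherits(data, "roi_dataset"))
  sites <- site_levels(data)
  if (length(sites) < subset_size) {
    stop("subset_size cannot exceed the number of sites", call. = FALSE)
  }
  full <- lapply(pipelines, function(pl) {
    run_pipeline_quiet(data, pl, covariates, ...)
  })
  names(full) <- pipelines
  sig_sets <- lapply(full, function(res) res$roi[res$p_holm < fwer_threshold])
  roi_filter <- Reduce(intersect, sig_sets)
  if (length(roi_filter) == 0L) {
    stop("empty ROI filter: no ROI significant at Holm p < ",
         fwer_threshold, " under all pipelines", call. = FALSE)
  }
  detect <- array(
    NA, dim = c(n_reps, length(roi_filter), length(pipelines)),
    dimnames = list(NULL, roi_filter, pipelines))
  for (t in seq_len(n_reps)) {
    set.seed(derive_seed(seed, t))
    sub_sites <- sample(sites, subset_size)
    sub <- filter_sites(data, sub_sites)
    for (pl in pipelines) {
      res <- run_pipeline_quiet(sub, pl, covariates, ...)
      hit <- stats::setNames(res$p_holm < alpha, res$roi)
      detect[t, , pl] <- unname(hit[roi_filter])
    }
  }
  power_tbl <- tidyr::expand_grid(pipeline = pipelines, roi = roi_filter) |>
    dplyr::mutate(power = purrr::map2_dbl(
      .data$pipeline, .data$roi,
      ~ mean(detect[, .y, .x], na.rm = TRUE)))
  pairs <- utils::combn(pipelines, 2, simplify = FALSE)
  wilcox_tbl <- purrr::map_dfr(pairs, function(pr) {
    pa <- power_tbl$power[power_tbl$pipeline == pr[1]]
    pb <- power_tbl$power[power_tbl$pipeline == pr[2]]
    wp <- if (all(pa == pb)) {
      NA_real_  # degenerate: all per-ROI powers tied
    } else {
      suppressWarnings(stats::wilcox.test(pa, pb, paired = TRUE)$p.value)
    }
    tibble::tibble(pipeline_a = pr[1], pipeline_b = pr[2],
                   mean_power_a = mean(pa), mean_power_b = mean(pb),
                   wilcoxon_p = wp)
  })
  structure(list(power = power_tbl, wilcoxon = wilcox_tbl,
                 roi_filter = roi_filter, subset_size = subset_size,
                 n_reps = n_reps, alpha = alpha,
                 fwer_threshold = fwer_threshold),
            class = "power_result")
}

#' @export
print.power_result <- function(x, ...) {
  means <- x$power |>
    dplyr::group_by(.data$pipeline) |>
    dplyr::summarise(power = mean(.data$power))
  cat(sprintf("<power_result> %d ROIs, %d reps of %d-site subsets\n",
              length(x$roi_filter), x$n_reps, x$subset_size))
  for (i in seq_len(nrow(means))) {
    cat(sprintf("  %-12s %.1f%%\n", means$pipeline[i], 100 * means$power[i]))
  }
  invisible(x)
}

#' @rdname subset_power
#' @param x,object A `power_result`.
#' @method tidy power_result
#' @export
tidy.power_result <- function(x, ...) x$power

#' @rdname subset_power
#' @method autoplot power_result
#' @export
autoplot.power_result <- function(object, ...) {
  ggplot2::ggplot(object$power,
                  ggplot2::aes(x = .data$pipeline, y = .data$power)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey90") +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.5) +
    ggplot2::labs(x = NULL, y = "per-ROI detection proportion",
                  title = sprintf("Power over %d-site subsets",
                                  object$subset_size)) +
    ggplot2::theme_minimal()
}

#' Empirical familywise error rate under within-site permutation
#'
#' Permutes diagnosis within site and counts, per pipeline, the proportion
#' of permutations in which at least one ROI reaches a Holm-adjusted
#' p < `alpha`. With the same master seed and counter scheme as
#' [compare_significance()], the two evaluations reuse identical
#' permutation draws when run jointly.
#'
#' @inheritParams compare_significance
#' @param pipelines Pipelines to evaluate.
#' @param alpha Familywise significance threshold.
#' @return A tibble: `pipeline`, `fwer`, `n_perm`.
#' @export
empirical_fwer <- function(data,
                           pipelines = c("remeta", "memega", "combatmega"),
                           covariates = c("age", "sex"),
                           n_perm = 200L, alpha = 0.05, seed = 1L, ...) {
  any_sig <- matrix(NA, n_perm, length(pipelines),
                    dimnames = list(NULL, pipelines))
  for (t in seq_len(n_perm)) {
    perm <- permute_within_site(data, seed = derive_seed(seed, t))
    for (pl in pipelines) {
      res <- run_pipeline_quiet(perm, pl, covariates, ...)
      any_sig[t, pl] <- any(res$p_holm < alpha)
    }
  }
  tibble::tibble(pipeline = pipelines,
                 fwer = colMeans(any_sig),
                 n_perm = n_perm)
}

#' Intra-site to total variance ratio per ROI
#'
#' Diagnostic of how much measurement variance is attributable to site:
#' the pooled within-site residual variance (after adjusting for diagnosis
#' and covariates within each site) divided by the total residual variance
#' (same adjustment, ignoring site). Values near 1 mean negligible site
#' effects; the smaller the ratio, the more a harmonization or site-aware
#' model stands to gain.
#'
#' @param data An [roi_dataset] with at least 2 sites.
#' @param covariates Covariate columns used for adjustment (diagnosis
#'   included), default `c("dx", "age", "sex")`.
#' @return A tibble: `roi`, `intra_site_var`, `total_var`, `ratio`.
#'   Degenerate ROIs are skipped with a warning.
#' @export
variance_ratio <- function(data, covariates = c("dx", "age", "sex")) {
  stopifnot(inherits(data, "roi_dataset"))
  site <- data$covariates$site
  if (nlevels(site) < 2L) stop("need at least 2 sites", call. = FALSE)
  X <- design_from_terms(data$covariates, covariates)
  res <- lapply(roi_names(data), function(r) {
    y <- data$values[, r]
    rss_w <- 0; df_w <- 0
    for (s in levels(site)) {
      rows <- site == s & !is.na(y)
      n_s <- sum(rows)
      Xs <- X[rows, , drop = FALSE]
      qx <- qr(Xs)
      if (n_s <= qx$rank) next
      rs <- qr.resid(qx, y[rows])
      rss_w <- rss_w + sum(rs^2)
      df_w <- df_w + n_s - qx$rank
    }
    obs <- !is.na(y)
    qx_t <- qr(X[obs, , drop = FALSE])
    df_t <- sum(obs) - qx_t$rank
    if (df_w <= 0 || df_t <= 0) return(NULL)
    total <- sum(qr.resid(qx_t, y[obs])^2) / df_t
    if (total <= 0) return(NULL)
    tibble::tibble(roi = r, intra_site_var = rss_w / df_w,
                   total_var = total, ratio = (rss_w / df_w) / total)
  })
  keep <- !vapply(res, is.null, logical(1))
  if (any(!keep)) {
    warning("skipping degenerate ROI(s): ",
            paste(roi_names(data)[!keep], collapse = ", "))
  }
  dplyr::bind_rows(res[keep])
}
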