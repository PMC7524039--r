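# Small in-code fixtures shared across test files.

# deterministic multi-site dataset without site effects unless asked for
small_sim <- function(n_sites = 4, n_per_site = 40, n_rois = 6, g = 0.3,
                      site_mean_spread = 0.3, gamma_tau = 0.3,
                      delta_shape = 6, delta_scale = 5,
                      missing_rate = 0, seed = 1) {
  generate_dataset(synth_config(
    n_sites = n_sites, n_per_site = n_per_site, n_thickness = n_rois,
    g = g, site_mean_spread = site_mean_spread, gamma_tau = gamma_tau,
    delta_shape = delta_shape, delta_scale = delta_scale,
    missing_rate = missing_rate, seed = seed))
}

# hand-built five-subject tables for I/O tests
toy_measure_tbl <- function(ids = c("s1", "s2", "s3", "s4", "s5")) {
  tibble::tibble(
    subject_id = ids,
    roiA = c(1.1, 2.2, 3.3, 4.4, 5.5),
    roiB = c(0.5, 0.6, 0.7, 0.8, 0.9))
}

toy_cov_tbl <- function(ids = c("s1", "s2", "s3", "s4", "s5")) {
  tibble::tibble(
    subject_id = ids,
    site = c("a", "a", "a", "b", "b"),
    dx = c(1, 0, 1, 0, 1),
    age = c(30, 40, 20, 50, 35),
    sex = c(0, 1, 0, 1, 1))
}

write_toy_files <- function(measures, covariates, dir = tempfile("toy")) {
  dir.create(dir)
  mp <- file.path(dir, "measures.csv")
  cp <- file.path(dir, "covariates.csv")
  readr::write_csv(measures, mp, na = "")
  readr::write_csv(covariates, cp, na = "")
  list(measures = mp, covariates = cp, dir = dir)
}
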