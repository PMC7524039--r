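#' Multi-site ROI measurement dataset
#'
#' Bundles a subject-by-ROI measurement matrix with its covariate table.
#' Measurements are real-valued (mm for cortical thickness, mm^2 for surface
#' area, mm^3 for volume; units are carried, not interpreted) and may contain
#' `NA` for missing cells. Covariates must be complete: rows with missing
#' covariate values are rejected at construction.
#'
#' @param measures A data frame with one row per subject: a subject-ID column
#'   (`id_col`) followed by numeric ROI columns. Empty cells are missing
#'   measurements.
#' @param covariates A data frame with the same subject-ID column, a site
#'   column (`site_col`), a binary diagnosis column `dx` (1 = case), and any
#'   further covariates (e.g. `age`, `sex`, `icv`). No missing values allowed.
#' @param id_col,site_col Names of the subject-ID and site columns.
#' @return An object of class `roi_dataset` with elements `values` (numeric
#'   matrix, subjects x ROIs, rownames = subject IDs, `NA` = missing) and
#'   `covariates` (a tibble, first column `subject_id`, second `site` as a
#'   factor, then the remaining covariates; row order matches `values`).
#' @details Subjects appearing in only one of the two tables are dropped
#'   (inner join by exact, case-sensitive ID match). Duplicated IDs in either
#'   table, zero overlapping subjects, non-numeric measurement entries,
#'   missing covariate values, or a diagnosis column without both levels are
#'   errors.
#' @export
roi_dataset <- function(measures, covariates, id_col = "subject_id",
                        site_col = "site") {
  measures <- tibble::as_tibble(measures)
  covariates <- tibble::as_tibble(covariates)
  for (nm in c(id_col)) {
    if (!nm %in% names(measures)) {
      stop("measurement table lacks column '", nm, "'", call. = FALSE)
    }
  }
  if (!id_col %in% names(covariates)) {
    stop("covariate table lacks column '", id_col, "'", call. = FALSE)
  }
  if (!site_col %in% names(covariates)) {
    stop("covariate table lacks site column '", site_col, "'", call. = FALSE)
  }
  ids_m <- as.character(measures[[id_col]])
  ids_c <- as.character(covariates[[id_col]])
  if (anyDuplicated(ids_m)) {
    stop("duplicated subject IDs in measurement table: ",
         paste(unique(ids_m[duplicated(ids_m)]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(ids_c)) {
    stop("duplicated subject IDs in covariate table: ",
         paste(unique(ids_c[duplicated(ids_c)]), collapse = ", "),
         call. = FALSE)
  }
  common <- intersect(ids_m, ids_c)
  if (length(common) == 0L) {
    stop("no overlapping subject IDs between measurement and covariate tables",
         call. = FALSE)
  }
  measures <- measures[match(common, ids_m), , drop = FALSE]
  covariates <- covariates[match(common, ids_c), , drop = FALSE]

  roi_cols <- setdiff(names(measures), id_col)
  if (length(roi_cols) == 0L) stop("no ROI columns found", call. = FALSE)
  if (anyDuplicated(roi_cols)) stop("duplicated ROI names", call. = FALSE)
  vals <- lapply(roi_cols, function(nm) {
    x <- measures[[nm]]
    if (is.character(x)) {
      xt <- trimws(x)
      num <- suppressWarnings(as.numeric(xt))
      bad <- !is.na(xt) & xt != "" & is.na(num)
      if (any(bad)) {
        stop("non-numeric measurement in ROI '", nm, "' (e.g. \"",
             xt[bad][1], "\")", call. = FALSE)
      }
      num
    } else if (is.numeric(x) || is.logical(x)) {
      as.numeric(x)
    } else {
      stop("ROI column '", nm, "' is not numeric", call. = FALSE)
    }
  })
  values <- do.call(cbind, vals)
  dimnames(values) <- list(common, roi_cols)

  cov <- covariates
  names(cov)[names(cov) == id_col] <- "subject_id"
  names(cov)[names(cov) == site_col] <- "site"
  cov$subject_id <- as.character(cov$subject_id)
  cov$site <- factor(cov$site)
  cov <- dplyr::relocate(cov, "subject_id", "site")
  other <- setdiff(names(cov), c("subject_id", "site"))
  if (anyNA(cov)) {
    bad <- names(cov)[vapply(cov, anyNA, logical(1))]
    stop("missing covariate values in column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if ("dx" %in% names(cov)) {
    dx <- cov$dx
    if (is.logical(dx)) dx <- as.integer(dx)
    if (!all(dx %in% c(0, 1))) {
      stop("diagnosis column 'dx' must be coded 0/1", call. = FALSE)
    }
    if (length(unique(dx)) < 2L) {
      stop("diagnosis column 'dx' must contain both cases and controls",
           call. = FALSE)
    }
    cov$dx <- as.numeric(dx)
  }
  if (any(table(cov$site) < 1L)) stop("empty site level", call. = FALSE)

  structure(list(values = values, covariates = cov), class = "roi_dataset")
}

#' @export
print.roi_dataset <- function(x, ...) {
  v <- x$values
  n_miss <- sum(is.na(v))
  cat(sprintf(
    "<roi_dataset> %d subjects x %d ROIs, %d sites, %.1f%% missing cells\n",
    nrow(v), ncol(v), nlevels(x$covariates$site),
    100 * n_miss / length(v)))
  cat("covariates:", paste(setdiff(names(x$covariates),
                                   c("subject_id", "site")), collapse = ", "),
      "\n")
  invisible(x)
}

#' @rdname roi_dataset
#' @param data An `roi_dataset`.
#' @export
roi_names <- function(data) colnames(data$values)

#' @rdname roi_dataset
#' @export
site_levels <- function(data) levels(data$covariates$site)

#' Read a multi-site ROI dataset from delimited files
#'
#' Reads a wide measurement table (one row per subject, one column per ROI)
#' and a covariate table, and aligns them by subject ID (inner join, exact
#' case-sensitive match). Empty measurement cells become missing values;
#' non-empty non-numeric measurement cells are an error, as are missing
#' covariate values.
#'
#' @param measurements_path,covariates_path Paths to CSV or TSV files with a
#'   header row. Files ending in `.tsv` are read as tab-separated, anything
#'   else as comma-separated.
#' @param site_column Name of the site-label column in the covariate file.
#' @param id_column Name of the shared subject-ID column.
#' @return An [roi_dataset].
#' @export
load_dataset <- function(measurements_path, covariates_path,
                         site_column = "site", id_column = "subject_id") {
  measures <- read_table_auto(measurements_path, all_character = TRUE)
  covariates <- read_table_auto(covariates_path)
  roi_dataset(measures, covariates, id_col = id_column, site_col = site_column)
}

read_table_auto <- function(path, all_character = FALSE) {
  delim <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  ct <- if (all_character) readr::cols(.default = readr::col_character())
        else readr::cols()
  readr::read_delim(path, delim = delim, col_types = ct,
                    na = c("", "NA"), progress = FALSE,
                    show_col_types = FALSE)
}

#' Write a dataset back to delimited files
#'
#' Writes the measurement matrix (and optionally the covariates) in the same
#' wide layout accepted by [load_dataset()]: one row per subject, subject-ID
#' column first, then one numeric column per ROI. Missing measurements are
#' written as empty cells, so `load_dataset(write_dataset(x))` round-trips
#' the numeric content exactly.
#'
#' @param data An [roi_dataset].
#' @param measurements_path Output path for the measurement table.
#' @param covariates_path Optional output path for the covariate table.
#' @return `data`, invisibly.
#' @export
write_dataset <- function(data, measurements_path, covariates_path = NULL) {
  stopifnot(inherits(data, "roi_dataset"))
  tab <- tibble::as_tibble(data$values)
  tab <- dplyr::bind_cols(tibble::tibble(subject_id = rownames(data$values)),
                          tab)
  delim <- if (grepl("\\.tsv$", measurements_path, ignore.case = TRUE)) "\t" else ","
  readr::write_delim(tab, measurements_path, delim = delim, na = "")
  if (!is.null(covariates_path)) {
    delim_c <- if (grepl("\\.tsv$", covariates_path, ignore.case = TRUE)) "\t" else ","
    readr::write_delim(data$covariates, covariates_path, delim = delim_c,
                       na = "")
  }
  invisible(data)
}

#' Build a fixed-effects design matrix from covariates
#'
#' Constructs the design used throughout: an intercept column of ones,
#' the diagnosis indicator (first non-intercept column, the coefficient of
#' interest), then the remaining covariates. Binary covariates are coded
#' 0/1; continuous covariates are passed through unscaled, so fitted
#' coefficients and harmonized values stay on the original measurement scale.
#'
#' @param covariates A covariate tibble (as in an [roi_dataset]).
#' @param terms Character vector of covariate column names beyond diagnosis
#'   (e.g. `c("age", "sex")`).
#' @param include_diagnosis If `TRUE` (default) the `dx` column is included
#'   right after the intercept.
#' @return A numeric matrix with column names; full column rank is enforced.
#' @export
build_design <- function(covariates, terms = c("age", "sex"),
                         include_diagnosis = TRUE) {
  covariates <- tibble::as_tibble(covariates)
  wanted <- c(if (include_diagnosis) "dx", terms)
  missing_cols <- setdiff(wanted, names(covariates))
  if (length(missing_cols)) {
    stop("covariate column(s) not found: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  cols <- lapply(wanted, function(nm) {
    x <- covariates[[nm]]
    if (is.logical(x)) return(as.numeric(x))
    if (is.factor(x) || is.character(x)) {
      lev <- sort(unique(as.character(x)))
      if (length(lev) > 2L) {
        stop("covariate '", nm, "' has more than two levels; recode manually",
             call. = FALSE)
      }
      return(as.numeric(as.character(x) == lev[length(lev)]))
    }
    as.numeric(x)
  })
  X <- cbind(`(Intercept)` = rep(1, nrow(covariates)),
             do.call(cbind, stats::setNames(cols, wanted)))
  colnames(X) <- c("(Intercept)", wanted)
  if (qr(X)$rank < ncol(X)) {
    stop("design matrix is rank deficient (constant or collinear covariate)",
         call. = FALSE)
  }
  X
}

# subset an roi_dataset to a set of sites (drops unused levels)
filter_sites <- function(data, sites) {
  keep <- data$covariates$site %in% sites
  cov <- data$covariates[keep, , drop = FALSE]
  cov$site <- droplevels(cov$site)
  structure(list(values = data$values[keep, , drop = FALSE],
                 covariates = cov),
            class = "roi_dataset")
}

# replace the measurement matrix, keeping covariates
with_values <- function(data, values) {
  structure(list(values = values, covariates = data$covariates),
            class = "roi_dataset")
}
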