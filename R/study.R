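#' Assemble a multi-subject study from per-subject time-series matrices
#'
#' A study is the package's basic container: one row per subject, with the
#' observed region-by-time matrix held in a list column. All subjects must
#' share the same regions in the same column order; the number of time
#' points may vary across subjects.
#'
#' @param series Named list of numeric matrices, one per subject, each
#'   `T x n` with identical column names (region names). If columns are
#'   unnamed, regions are named `R1..Rn`.
#' @param group Optional vector of known subgroup labels (e.g. the true
#'   labels of simulated data), recycled against `series`.
#' @return A tibble of class `mdm_study` with columns `subject_id`,
#'   `group` (may be `NA`) and `series` (list of matrices), plus
#'   attributes `regions` and `standardized`.
#' @export
#' @examples
#' y <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("A", "B")))
#' mdm_study(list(s1 = y))
mdm_study <- function(series, group = NA) {
  stopifnot(is.list(series), length(series) >= 1)
  if (is.null(names(series)) || any(names(series) == "")) {
    names(series) <- sprintf("subj%02d", seq_along(series))
  }
  series <- lapply(series, as.matrix)
  n <- ncol(series[[1]])
  regions <- colnames(series[[1]])
  if (is.null(regions)) regions <- paste0("R", seq_len(n))
  for (i in seq_along(series)) {
    m <- series[[i]]
    if (ncol(m) != n) {
      stop("subject '", names(series)[i], "' has ", ncol(m),
           " regions; expected ", n)
    }
    if (nrow(m) < 2) stop("each subject needs at least 2 time points")
    if (anyNA(m) || any(!is.finite(m))) {
      stop("subject '", names(series)[i], "' has missing/non-finite values")
    }
    colnames(series[[i]]) <- regions
  }
  out <- tibble::tibble(
    subject_id = names(series),
    group = rep_len(group, length(series)),
    series = unname(series)
  )
  structure(out,
    class = c("mdm_study", class(out)),
    regions = regions, standardized = FALSE
  )
}

#' @export
print.mdm_study <- function(x, ...) {
  cat("<mdm_study> ", nrow(x), " subject(s), ",
      length(attr(x, "regions")), " regions (",
      paste(head(attr(x, "regions"), 4), collapse = ", "),
      if (length(attr(x, "regions")) > 4) ", ..." else "", ")",
      if (isTRUE(attr(x, "standardized"))) " [standardized]", "\n",
      sep = "")
  NextMethod()
}

n_regions <- function(study) length(attr(study, "regions"))

#' Standardize every region series to mean zero and unit variance
#'
#' Column-wise location/scale standardization, applied per subject. Scores
#' and priors in this package assume unit-scale data, so this is on by
#' default throughout the pipeline.
#'
#' @param study An [mdm_study()].
#' @return The study with each column of each subject's series centred to
#'   mean 0 and scaled to sample standard deviation 1.
#' @export
standardize_study <- function(study) {
  regions <- attr(study, "regions")
  study$series <- purrr::map2(study$series, study$subject_id, function(m, id) {
    s <- apply(m, 2, sd)
    if (any(s == 0 | !is.finite(s))) {
      bad <- regions[which(s == 0 | !is.finite(s))[1]]
      stop("region '", bad, "' is constant for subject '", id,
           "'; cannot standardize")
    }
    scale(m, center = TRUE, scale = s)[, , drop = FALSE]
  })
  attr(study, "standardized") <- TRUE
  study
}

#' Read a study from a manifest of per-subject CSV files
#'
#' The manifest is a CSV with columns `subject_id`, `path` and optionally
#' `group`. Each referenced file holds one subject's series: `T` rows by
#' `n` regions with a header row of region names. Relative paths are
#' resolved against the manifest's directory.
#'
#' @param manifest Path to the manifest CSV.
#' @return An [mdm_study()].
#' @export
read_study <- function(manifest) {
  man <- readr::read_csv(manifest, show_col_types = FALSE)
  stopifnot(all(c("subject_id", "path") %in% names(man)))
  base <- dirname(manifest)
  paths <- ifelse(file.exists(man$path), man$path, file.path(base, man$path))
  series <- lapply(paths, function(p) {
    as.matrix(readr::read_csv(p, show_col_types = FALSE))
  })
  names(series) <- man$subject_id
  mdm_study(series, group = if ("group" %in% names(man)) man$group else NA)
}

#' Write a study as per-subject CSV files plus a manifest
#'
#' @param study An [mdm_study()].
#' @param dir Output directory (created if absent).
#' @return The manifest path, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, paste0(study$subject_id, ".csv"))
  purrr::walk2(study$series, paths, function(m, p) {
    readr::write_csv(tibble::as_tibble(m), p)
  })
  man <- tibble::tibble(
    subject_id = study$subject_id,
    path = basename(paths),
    group = study$group
  )
  mpath <- file.path(dir, "manifest.csv")
  readr::write_csv(man, mpath)
  invisible(mpath)
}
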