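#' Score every admissible parent set for every node and subject
#'
#' Computes the local log predictive likelihood `c_i(r, Pa)` for each
#' subject `i`, node `r` and parent set `Pa` of size up to `max_parents`,
#' maximizing over the prior's discount grid. This cached table is the
#' expensive step of the whole pipeline; every search and group method
#' afterwards works from it.
#'
#' @param study An [mdm_study()].
#' @param max_parents Cap on parent-set size. Defaults to `n - 1` for
#'   `n <= 12` and 4 otherwise. Studies with `n > 20` must set it.
#' @param prior An [mdm_prior()].
#' @param standardize Standardize each subject's series first (default).
#' @return A tibble of class `mdm_scores` with columns `subject_id`,
#'   `node`, `pset` (parent bitmask), `n_parents`, `score` and `delta`
#'   (the discount attaining the maximum). Rows are in canonical
#'   (size, mask) order within each (subject, node).
#' @export
#' @examples
#' study <- simulate_study(mdm_sim_spec(n_nodes = 3, t_len = 60,
#'   groups = list(list(label = "a", size = 1))), seed = 1)$study
#' score_study(study, max_parents = 1)
score_study <- function(study, max_parents = NULL, prior = mdm_prior(),
                        standardize = TRUE) {
  n <- n_regions(study)
  if (is.null(max_parents)) {
    if (n > 20) {
      stop("n = ", n, " regions: set max_parents explicitly (hard cap 20 ",
           "for unrestricted enumeration)")
    }
    max_parents <- if (n <= 12) n - 1L else 4L
  }
  stopifnot(max_parents >= 0, max_parents <= n - 1)
  if (standardize && !isTRUE(attr(study, "standardized"))) {
    study <- standardize_study(study)
  }
  rows <- purrr::map2(study$series, study$subject_id, function(m, id) {
    purrr::map(seq_len(n), function(r) {
      masks <- enumerate_psets(setdiff(seq_len(n), r), max_parents)
      sc <- score_sets_cpp(m, r, masks, prior$delta_grid,
                           prior$c0_scale, prior$n0, prior$d0)
      if (prior$burn_in > 0) {
        sc <- score_masks_burnin(m, r, masks, prior)
      }
      best <- max.col(sc, ties.method = "last")
      tibble::tibble(
        subject_id = id, node = r, pset = masks,
        n_parents = popcount(masks),
        score = sc[cbind(seq_along(masks), best)],
        delta = prior$delta_grid[best]
      )
    })
  })
  out <- dplyr::bind_rows(purrr::flatten(rows))
  if (any(!is.finite(out$score))) stop("non-finite local scores produced")
  new_mdm_scores(out, n = n, max_parents = as.integer(max_parents),
                 regions = attr(study, "regions"), prior = prior)
}

score_masks_burnin <- function(m, r, masks, prior) {
  t(vapply(masks, function(mask) {
    F <- build_regressors(m, r, mask_to_nodes(mask))
    vapply(prior$delta_grid, function(d) {
      filter_node(m[, r], F, prior, delta = d)$total
    }, numeric(1))
  }, numeric(length(prior$delta_grid))))
}

new_mdm_scores <- function(tbl, n, max_parents, regions, prior) {
  structure(tbl,
    class = c("mdm_scores", class(tibble::tibble())),
    n = n, max_parents = max_parents, regions = regions, prior = prior
  )
}

#' @export
print.mdm_scores <- function(x, ...) {
  cat("<mdm_scores> ", length(unique(x$subject_id)), " subject(s), n = ",
      attr(x, "n"), ", max_parents = ", attr(x, "max_parents"), "\n",
      sep = "")
  NextMethod()
}

scores_attrs <- function(x) {
  list(n = attr(x, "n"), max_parents = attr(x, "max_parents"),
       regions = attr(x, "regions"), prior = attr(x, "prior"))
}

#' Restrict a score table to a subset of subjects
#'
#' @param scores An `mdm_scores` table.
#' @param subjects Subject ids to keep.
#' @return An `mdm_scores` table with the same attributes.
#' @export
scores_subset <- function(scores, subjects) {
  a <- scores_attrs(scores)
  out <- dplyr::filter(tibble::as_tibble(scores),
                       .data$subject_id %in% subjects)
  new_mdm_scores(out, a$n, a$max_parents, a$regions, a$prior)
}

#' Sum local scores over subjects (the common-structure score)
#'
#' Entrywise sum of the per-subject score tables over a common parent-set
#' space: the score a shared network would receive if all the given
#' subjects had that structure, with subject-specific parameters.
#'
#' @param scores An `mdm_scores` table (possibly several subjects).
#' @param subjects Which subjects to sum over (default: all in `scores`).
#' @return An `mdm_scores` table with a single synthetic subject id
#'   `"<summed>"`.
#' @export
sum_scores <- function(scores, subjects = NULL) {
  a <- scores_attrs(scores)
  tbl <- tibble::as_tibble(scores)
  if (!is.null(subjects)) {
    missing <- setdiff(subjects, unique(tbl$subject_id))
    if (length(missing) > 0) {
      stop("no cached scores for subject(s): ",
           paste(missing, collapse = ", "))
    }
    tbl <- dplyr::filter(tbl, .data$subject_id %in% subjects)
  }
  counts <- dplyr::count(tbl, .data$node, .data$pset)
  if (length(unique(counts$n)) != 1) {
    stop("subjects do not share a common parent-set space")
  }
  out <- tbl |>
    dplyr::group_by(.data$node, .data$pset, .data$n_parents) |>
    dplyr::summarise(score = sum(.data$score), delta = NA_real_,
                     .groups = "drop") |>
    dplyr::arrange(.data$node, .data$n_parents, .data$pset) |>
    dplyr::mutate(subject_id = "<summed>", .before = 1)
  new_mdm_scores(out, a$n, a$max_parents, a$regions, a$prior)
}

#' Write or read a score table as CSV
#'
#' Columnar serialization (`subject_id`, `node`, `pset`, `n_parents`,
#' `score`, `delta`) so the expensive scoring step can be cached across
#' analyses. Table attributes are stored in a `# mdm_scores n=... `
#' comment header.
#'
#' @param scores An `mdm_scores` table.
#' @param path Output path.
#' @return `write_scores` returns `path` invisibly; `read_scores` returns
#'   the `mdm_scores` table (with a default prior attached).
#' @export
write_scores <- function(scores, path) {
  hdr <- sprintf("# mdm_scores n=%d max_parents=%d regions=%s",
                 attr(scores, "n"), attr(scores, "max_parents"),
                 paste(attr(scores, "regions"), collapse = "|"))
  writeLines(hdr, path)
  readr::write_csv(tibble::as_tibble(scores), path, append = TRUE,
                   col_names = TRUE)
  invisible(path)
}

#' @rdname write_scores
#' @export
read_scores <- function(path) {
  hdr <- readLines(path, n = 1)
  m <- regmatches(hdr, regexec(
    "n=([0-9]+) max_parents=([0-9]+) regions=(\\S+)", hdr))[[1]]
  if (length(m) != 4) stop("not an mdm_scores file: ", path)
  tbl <- readr::read_csv(path, skip = 1, show_col_types = FALSE)
  new_mdm_scores(tbl, as.integer(m[2]), as.integer(m[3]),
                 strsplit(m[4], "|", fixed = TRUE)[[1]], mdm_prior())
}
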