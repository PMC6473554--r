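#' Virtual-typical-subject group network
#'
#' Averages the raw series pointwise across subjects to form a single
#' "typical subject", standardizes the average, scores it, and searches.
#' Strength summaries come from the one fitted typical subject. Subjects
#' with differing lengths are truncated to the shortest with a warning.
#'
#' @param study An [mdm_study()].
#' @param search `"ipa"` or `"dgm"`.
#' @param max_parents,prior Passed to [score_study()].
#' @return A fitted [mdm_network()].
#' @export
vts_group <- function(study, search = c("ipa", "dgm"), max_parents = NULL,
                      prior = mdm_prior()) {
  search <- match.arg(search)
  if (nrow(study) == 1) {
    warning("single subject: VTS reduces to the individual search")
  }
  t_lens <- vapply(study$series, nrow, integer(1))
  t_min <- min(t_lens)
  if (any(t_lens != t_min)) {
    warning("subjects differ in length; truncating to T = ", t_min)
  }
  avg <- Reduce(`+`, lapply(study$series, function(m) {
    m[seq_len(t_min), , drop = FALSE]
  })) / nrow(study)
  typical <- mdm_study(list(typical = avg))
  attr(typical, "regions") <- attr(study, "regions")
  sc <- score_study(typical, max_parents = max_parents, prior = prior)
  net <- search_network(sc, search)
  fit_network(avg, net, prior)
}

#' Common-structure group network
#'
#' Sums the cached local scores entrywise over subjects and searches the
#' summed table: one shared structure, subject-specific parameters.
#' Strengths are the average of the per-subject smoothed summaries under
#' the common structure.
#'
#' @param scores An `mdm_scores` table for the study.
#' @param study The [mdm_study()] the scores came from (for strength
#'   fitting; optional).
#' @param search `"ipa"` or `"dgm"`.
#' @param subjects Optional subset of subjects.
#' @return An [mdm_network()]; fitted with averaged strengths when
#'   `study` is supplied.
#' @export
cs_group <- function(scores, study = NULL, search = c("ipa", "dgm"),
                     subjects = NULL) {
  search <- match.arg(search)
  net <- search_network(sum_scores(scores, subjects), search)
  if (!is.null(study)) {
    ids <- if (is.null(subjects)) study$subject_id else subjects
    net <- average_strengths(study, net, ids,
                             prior = attr(scores, "prior"))
  }
  net
}

#' Individual-structure group network (majority vote of edges)
#'
#' Includes a directed edge iff it is present in strictly more than
#' `threshold * S` of the individual networks. The result may be cyclic.
#'
#' @param networks List of [mdm_network()] on a common node set.
#' @param threshold Inclusion fraction (strict inequality). Default 1/2;
#'   use 2/3 for the "popular edges" reference graph.
#' @return An [mdm_network()] (total score `NA`; structure only).
#' @export
is_group <- function(networks, threshold = 0.5) {
  if (length(networks) == 0) stop("no networks given")
  n <- length(networks[[1]]$parents)
  S <- length(networks)
  counts <- matrix(0L, n, n)  # counts[p, r]: edge p -> r
  for (net in networks) {
    stopifnot(length(net$parents) == n)
    ed <- network_edges(net)
    counts[cbind(ed$from, ed$to)] <- counts[cbind(ed$from, ed$to)] + 1L
  }
  parents <- integer(n)
  for (r in seq_len(n)) {
    keep <- which(counts[, r] > threshold * S)
    parents[r] <- nodes_to_mask(keep)
  }
  mdm_network(parents, networks[[1]]$regions, search = "is")
}

# Average the fitted smoothed summaries of a fixed structure over a set
# of subjects; attaches the averaged strengths tibble to the network.
average_strengths <- function(study, network, subjects,
                              prior = mdm_prior()) {
  rows <- study[study$subject_id %in% subjects, ]
  fits <- lapply(rows$series, fit_network, network = network, prior = prior)
  st <- dplyr::bind_rows(lapply(fits, function(f) f$strengths))
  network$strengths <- st |>
    dplyr::group_by(.data$from_node, .data$to_node) |>
    dplyr::summarise(theta_bar = mean(.data$theta_bar),
                     sigma2_bar = mean(.data$sigma2_bar),
                     delta = mean(.data$delta), .groups = "drop")
  network$total_score <- sum(vapply(fits, function(f) f$total_score,
                                    numeric(1)))
  network
}

#' Standardised connectivity strength of a fitted subgroup network
#'
#' For each edge of `network`, averages the smoothed coefficient location
#' and scale over time and over the subgroup's members, then reports the
#' standardised mean `Zbar = theta_bar / sqrt(sigma2_bar / (T * S_g))`.
#' Edges with `|Zbar| >= z_cut` are flagged.
#'
#' @param study An [mdm_study()].
#' @param network An [mdm_network()] (the subgroup's structure).
#' @param subjects Members of the subgroup (default: all subjects).
#' @param prior An [mdm_prior()].
#' @param z_cut Significance flag threshold on `|Zbar|` (default 2).
#' @return A tibble of class `mdm_strength` with per-edge `theta_bar`,
#'   `sigma2_bar`, `z_bar` and `significant`, plus attributes `T_len` and
#'   `S_g`.
#' @export
strength_zbar <- function(study, network, subjects = NULL,
                          prior = mdm_prior(), z_cut = 2) {
  if (is.null(subjects)) subjects <- study$subject_id
  S_g <- length(subjects)
  if (S_g == 0) stop("empty subgroup")
  T_len <- min(vapply(study$series[study$subject_id %in% subjects],
                      nrow, integer(1)))
  net <- average_strengths(study, network, subjects, prior)
  regions <- attr(study, "regions")
  out <- net$strengths |>
    dplyr::filter(!is.na(.data$from_node)) |>
    dplyr::mutate(
      from = regions[.data$from_node], to = regions[.data$to_node],
      z_bar = .data$theta_bar / sqrt(.data$sigma2_bar / (T_len * S_g)),
      significant = abs(.data$z_bar) >= z_cut
    ) |>
    dplyr::select("from", "to", "from_node", "to_node", "theta_bar",
                  "sigma2_bar", "z_bar", "significant")
  structure(out, class = c("mdm_strength", class(tibble::tibble())),
            T_len = T_len, S_g = S_g)
}

#' Standardised difference in connectivity strength between subgroups
#'
#' Welch-type two-sample standardisation of the difference of averaged
#' smoothed coefficients:
#' `Dbar = (theta_g - theta_l) / sqrt(s2_g/(T*S_g) + s2_l/(T*S_l))`.
#' Antisymmetric in the two subgroups. Edges present in only one summary
#' are dropped with a message.
#'
#' @param summary_g,summary_l `mdm_strength` tibbles from
#'   [strength_zbar()] for the two subgroups.
#' @return A tibble with per-edge `d_bar`.
#' @export
strength_diff <- function(summary_g, summary_l) {
  Tg <- attr(summary_g, "T_len"); Sg <- attr(summary_g, "S_g")
  Tl <- attr(summary_l, "T_len"); Sl <- attr(summary_l, "S_g")
  j <- dplyr::inner_join(
    tibble::as_tibble(summary_g), tibble::as_tibble(summary_l),
    by = c("from", "to", "from_node", "to_node"), suffix = c("_g", "_l")
  )
  dropped <- nrow(summary_g) + nrow(summary_l) - 2 * nrow(j)
  if (dropped > 0) {
    message(dropped, " edge(s) present in only one subgroup were dropped")
  }
  dplyr::mutate(
    j,
    d_bar = (.data$theta_bar_g - .data$theta_bar_l) /
      sqrt(.data$sigma2_bar_g / (Tg * Sg) + .data$sigma2_bar_l / (Tl * Sl))
  ) |>
    dplyr::select("from", "to", "from_node", "to_node", "theta_bar_g",
                  "theta_bar_l", "d_bar")
}

#' Binomial edge-frequency test with FDR correction
#'
#' For every directed edge, tests whether the proportion of a subgroup's
#' individual networks containing it exceeds `p0` (one-sided exact
#' binomial), then applies Benjamini-Hochberg across all `n(n-1)` ordered
#' node pairs.
#'
#' @param networks List of the subgroup members' individual
#'   [mdm_network()]s.
#' @param p0 Null inclusion probability (default 0.5).
#' @param fdr_q FDR level (default 0.05).
#' @return A tibble with one row per ordered node pair: `count`, `p`,
#'   `q`, `significant`.
#' @export
significant_edges <- function(networks, p0 = 0.5, fdr_q = 0.05) {
  stopifnot(length(networks) >= 1)
  n <- length(networks[[1]]$parents)
  S <- length(networks)
  counts <- matrix(0L, n, n)
  for (net in networks) {
    ed <- network_edges(net)
    counts[cbind(ed$from, ed$to)] <- counts[cbind(ed$from, ed$to)] + 1L
  }
  pairs <- expand.grid(from = seq_len(n), to = seq_len(n))
  pairs <- pairs[pairs$from != pairs$to, ]
  k <- counts[cbind(pairs$from, pairs$to)]
  p <- pbinom(k - 1, S, p0, lower.tail = FALSE)
  q <- p.adjust(p, method = "BH")
  regions <- networks[[1]]$regions
  tibble::tibble(
    from = regions[pairs$from], to = regions[pairs$to],
    from_node = pairs$from, to_node = pairs$to,
    count = k, total = S, p = p, q = q, significant = q <= fdr_q
  )
}
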